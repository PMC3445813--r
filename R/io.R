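TRIAL_COLUMNS <- c("trial_index", "onset_s", "trial_type", "condition",
                   "valid_actions", "previous_action", "response", "rt_s")

#' Write a trial table
#'
#' Tab-separated, one row per trial, `NA` for omissions and null-event
#' fields; times in seconds at full double precision, so tables round-trip
#' losslessly through [read_trial_table()].
#'
#' @param trials trial-table data.frame.
#' @param path output path.
#' @return `trials`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(trials)
}

#' Read and validate a trial table
#'
#' Reads a tab-separated trial table, checks the schema, and normalizes
#' units and sentinels: a millisecond RT column (`rt_ms`) is converted to
#' seconds, omissions and null events are parsed to `NA`, and responses
#' outside the trial's valid-action set are flagged as commission errors in
#' a logical `commission` column (they are excluded from fitting by
#' [fit_design()], and the count is reported in a message).
#'
#' @param path input path.
#' @return validated trial-table data.frame with attribute `n_commission`.
#' @export
read_trial_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", "n/a", ""))
  if ("rt_ms" %in% names(tab) && !"rt_s" %in% names(tab)) {
    tab$rt_s <- tab$rt_ms / 1000
    tab$rt_ms <- NULL
  }
  missing_cols <- setdiff(TRIAL_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("trial table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(tab), c(TRIAL_COLUMNS, "first_action", "commission"))
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  bad_type <- !tab$trial_type %in% c("choice", "specified", "null")
  if (any(bad_type))
    stop("invalid trial_type at row(s): ",
         paste(which(bad_type), collapse = ", "))
  act <- tab$trial_type != "null"
  bad_cond <- act & !tab$condition %in% CONDITIONS
  if (any(bad_cond))
    stop("invalid condition at row(s): ",
         paste(which(bad_cond), collapse = ", "))
  bad_rt <- act & !is.na(tab$rt_s) & (tab$rt_s <= 0)
  if (any(bad_rt))
    stop("non-positive rt_s at row(s): ", paste(which(bad_rt), collapse = ", "))
  if (is.null(tab$first_action)) tab$first_action <- FALSE
  valid <- parse_actions(tab$valid_actions)
  commission <- !is.na(tab$response) & act &
    !mapply(function(r, v) r %in% v, tab$response, valid)
  tab$commission <- commission
  if (any(commission))
    message(sum(commission), " commission error(s) flagged (response ",
            "outside the valid-action set)")
  attr(tab, "n_commission") <- sum(commission)
  tab
}

#' Read a run configuration
#'
#' Reads a YAML or JSON configuration file with optional blocks `session`
#' (arguments of [session_spec()]), `fit` (arguments of [fit_config()]),
#' `designs` (integer design indices into [enumerate_designs()]), and
#' `seed`. Missing blocks fall back to the package defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with elements `session` (a `session_spec`), `fit`
#'   (a `fit_config`), `designs` (list of `model_design`), and `seed`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path)
  sess_args <- raw$session
  if (!is.null(sess_args$proportions))
    sess_args$proportions <- unlist(sess_args$proportions)
  designs <- if (is.null(raw$designs)) list()
             else enumerate_designs()[unlist(raw$designs)]
  list(session = do.call(session_spec, as.list(sess_args)),
       fit = do.call(fit_config, as.list(raw$fit)),
       designs = designs,
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}

#' Write a fit result as JSON
#'
#' @param fit a `fit_result` from [fit_design()].
#' @param path output path.
#' @return the serialized list, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(
    design = lapply(unclass(fit$design), isTRUE),
    params = list(mean_rates = fit$params$mean_rates,
                  rate_sds = fit$params$rate_sds,
                  threshold = fit$params$threshold,
                  start_range = fit$params$start_range,
                  non_decision = fit$params$non_decision,
                  specified_rates = fit$params$specified_rates),
    mods = lapply(fit$mods, function(m)
      list(ratios = as.list(m$ratios), scope = m$scope,
           parameter = m$parameter)),
    g_squared = fit$g_squared, k = fit$k, n = fit$n, bic = fit$bic,
    restarts = fit$restarts, best_restart = fit$best_restart,
    converged = fit$converged, seed = fit$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(obj)
}

#' Write a run manifest
#'
#' Records what produced a set of artifacts: package version, seeds,
#' configuration, and MD5 checksums of the input files, so a pipeline run
#' can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param config named list of configuration values (seeds included).
#' @param inputs character vector of input file paths to checksum.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config = list(), inputs = character()) {
  manifest <- list(
    package = "lbadecide",
    version = as.character(utils::packageVersion("lbadecide")),
    config = config,
    input_md5 = as.list(md5sum(inputs)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
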
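#' Constrained LBA model designs
#'
#' A model design is a combination of six binary structural features that
#' together define one constrained variant of the LBA model:
#'
#' \describe{
#'   \item{f1}{start-point range `c0` varies by accumulator (prior action bias).}
#'   \item{f2}{response threshold `b` is modulated by condition.}
#'   \item{f3}{mean accumulation rates are modulated by condition.}
#'   \item{f4}{non-decision time `t0` is modulated by condition.}
#'   \item{f5}{mean rates are equal across accumulators in the specified-action
#'     conditions (one shared free rate per specified condition).}
#'   \item{f6}{condition modulations apply to all active accumulators rather
#'     than only to the accumulator matching the previous action.}
#' }
#'
#' The features are not independent. Two meaningfulness rules apply:
#' `f6` is interpretable only when at least one parameter is condition-modulated
#' (`f2`, `f3`, or `f4`), and `f5` is interpretable only when rates are
#' condition-modulated (`f3`) -- without `f3` the specified-trial rates are the
#' shared baseline rates, so equalizing them only in specified trials would
#' itself be a condition-dependent rate change. Under these rules exactly 46 of
#' the 64 flag combinations are meaningful.
#'
#' @param f1,f2,f3,f4,f5,f6 logical feature flags.
#' @param normalize if `TRUE`, uninterpretable flags are switched off instead
#'   of raising an error.
#'
#' @return An object of class `model_design`.
#' @export
#' @examples
#' model_design(f3 = TRUE)            # the rate-modulation design
#' model_design()                     # the simplest (all-off) design
model_design <- function(f1 = FALSE, f2 = FALSE, f3 = FALSE, f4 = FALSE,
                         f5 = FALSE, f6 = FALSE, normalize = FALSE) {
  flags <- c(f1 = isTRUE(f1), f2 = isTRUE(f2), f3 = isTRUE(f3),
             f4 = isTRUE(f4), f5 = isTRUE(f5), f6 = isTRUE(f6))
  if (!design_meaningful(flags)) {
    if (!normalize)
      stop("uninterpretable design: f6 requires one of f2/f3/f4 and f5 requires f3")
    if (flags["f5"] && !flags["f3"]) flags["f5"] <- FALSE
    if (flags["f6"] && !any(flags[c("f2", "f3", "f4")])) flags["f6"] <- FALSE
  }
  structure(as.list(flags), class = "model_design")
}

# meaningfulness predicate over a named logical vector of the six flags
design_meaningful <- function(flags) {
  flags <- unlist(flags)[paste0("f", 1:6)]
  if (flags["f6"] && !any(flags[c("f2", "f3", "f4")])) return(FALSE)
  if (flags["f5"] && !flags["f3"]) return(FALSE)
  TRUE
}

#' @export
print.model_design <- function(x, ...) {
  on <- names(x)[unlist(x)]
  cat("LBA model design:",
      if (length(on)) paste(on, collapse = " + ") else "(all features off)",
      "\n  free parameters:", parameter_count(x), "\n")
  invisible(x)
}

#' @export
format.model_design <- function(x, ...) {
  paste0(ifelse(unlist(x[paste0("f", 1:6)]), "1", "0"), collapse = "")
}

#' Enumerate all meaningful model designs
#'
#' Generates every distinct, meaningful combination of the six model features
#' (see [model_design()] for the meaningfulness rules), in a stable order:
#' sorted by the number of active features, then lexicographically by feature
#' index. Design 1 is the all-features-off model; the singleton designs follow
#' at indices 2 (f1), 3 (f2, condition-modulated threshold), 4 (f3,
#' condition-modulated rates applied to the repetition accumulator), and
#' 5 (f4, condition-modulated non-decision time).
#'
#' @return A list of `model_design` objects with a `design_index` attribute on
#'   each element.
#' @export
#' @examples
#' designs <- enumerate_designs()
#' length(designs)  # 46
enumerate_designs <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  names(grid) <- paste0("f", 1:6)
  keep <- apply(grid, 1, design_meaningful)
  grid <- grid[keep, , drop = FALSE]
  n_on <- rowSums(grid)
  # order: fewer features first, then lexicographically by the tuple of
  # active feature indices, so f1-only, f2-only, f3-only, f4-only follow the
  # null design at indices 2..5
  key <- apply(grid, 1, function(f) paste(which(f), collapse = ""))
  grid <- grid[order(n_on, key), , drop = FALSE]
  designs <- lapply(seq_len(nrow(grid)), function(i) {
    d <- do.call(model_design, as.list(grid[i, ]))
    attr(d, "design_index") <- i
    d
  })
  designs
}

#' Number of free parameters of a model design
#'
#' The baseline parameterization has 11 free parameters (four rate means, four
#' rate SDs, threshold, start range, non-decision time). Each
#' condition-modulated parameter (`f2`, `f3`, `f4`) adds one ratio per
#' non-baseline condition (+3 each); per-accumulator start ranges (`f1`) add 3;
#' equal specified-trial rates (`f5`) replace the two specified-condition rate
#' ratios with two shared free rate means (net 0). Counts are nominal: the
#' LBA's scale non-identifiability is not subtracted.
#'
#' @param design a `model_design`.
#' @return integer count of free scalar parameters.
#' @export
#' @examples
#' parameter_count(model_design())          # 11
#' parameter_count(model_design(f3 = TRUE)) # 14
parameter_count <- function(design) {
  stopifnot(inherits(design, "model_design"))
  11L + 3L * sum(unlist(design[c("f1", "f2", "f3", "f4")]))
}

#' Tabulate the design space
#'
#' @param designs list from [enumerate_designs()] (the default).
#' @return A data.frame with one row per design: index, the six feature flags,
#'   and the free-parameter count.
#' @export
design_table <- function(designs = enumerate_designs()) {
  do.call(rbind, lapply(designs, function(d) {
    data.frame(design = attr(d, "design_index"),
               f1 = d$f1, f2 = d$f2, f3 = d$f3, f4 = d$f4, f5 = d$f5,
               f6 = d$f6, n_params = parameter_count(d))
  }))
}

#' Serialize / deserialize designs and modulation sets
#'
#' @param x a `model_design` or `modulation_set`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `design_to_json` returns JSON (invisibly when written to a file);
#'   `design_from_json` returns the reconstructed object.
#' @export
design_to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "model_design")) {
    list(type = "model_design", flags = lapply(unclass(x), isTRUE))
  } else if (inherits(x, "modulation_set")) {
    list(type = "modulation_set", ratios = as.list(x$ratios),
         scope = x$scope, parameter = x$parameter)
  } else stop("x must be a model_design or modulation_set")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname design_to_json
#' @param json JSON string or file path produced by [design_to_json()].
#' @export
design_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  switch(obj$type,
    model_design = do.call(model_design, obj$flags),
    modulation_set = modulation_set(
      choice_rep_available = obj$ratios$choice_rep_available,
      specified_rep = obj$ratios$specified_rep,
      specified_nonrep = obj$ratios$specified_nonrep,
      scope = obj$scope, parameter = obj$parameter),
    stop("unknown serialized type: ", obj$type))
}
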
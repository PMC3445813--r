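#' LBA parameter set for one participant
#'
#' Bundles the baseline linear ballistic accumulator parameters: per-accumulator
#' mean accumulation rates and rate standard deviations (evidence units per
#' second), a response threshold `b`, the upper limit `c0` of the uniform
#' start-point distribution, and a constant non-decision time `t0` (seconds).
#'
#' The start point of each accumulator is drawn uniformly on `[0, c0]`, so the
#' threshold must exceed the start range (an accumulator can never begin at or
#' above threshold). `start_range` is a scalar by default; a length-4 vector is
#' allowed for designs in which the start range varies by accumulator.
#'
#' @param mean_rates numeric(4), mean accumulation rate per accumulator.
#' @param rate_sds numeric(4), rate standard deviation per accumulator; all > 0.
#' @param threshold scalar response threshold `b` > 0.
#' @param start_range scalar or numeric(4) start-point range `c0` in
#'   `[0, threshold)`.
#' @param non_decision scalar non-decision time `t0` >= 0, seconds.
#' @param specified_rates optional named numeric with elements
#'   `specified_rep` and `specified_nonrep`: single shared rate means used in
#'   the specified-action conditions by designs that equalize rates across
#'   accumulators there.
#'
#' @return An object of class `lba_params`.
#' @export
#' @examples
#' lba_params(mean_rates = rep(1.5, 4), rate_sds = rep(0.5, 4),
#'            threshold = 1, start_range = 0.3, non_decision = 0.2)
lba_params <- function(mean_rates, rate_sds, threshold, start_range,
                       non_decision, specified_rates = NULL) {
  mean_rates <- as.numeric(mean_rates)
  rate_sds <- as.numeric(rate_sds)
  if (length(mean_rates) != N_ACTIONS || length(rate_sds) != N_ACTIONS)
    stop("mean_rates and rate_sds must each have length ", N_ACTIONS)
  if (!all(rate_sds > 0)) stop("rate_sds must all be > 0")
  if (length(threshold) != 1L || threshold <= 0) stop("threshold must be a positive scalar")
  if (!length(start_range) %in% c(1L, N_ACTIONS)) stop("start_range must be scalar or length 4")
  if (any(start_range < 0)) stop("start_range must be >= 0")
  if (any(start_range >= threshold)) stop("threshold must exceed start_range")
  if (length(non_decision) != 1L || non_decision < 0) stop("non_decision must be a scalar >= 0")
  if (!is.null(specified_rates)) {
    if (!all(c("specified_rep", "specified_nonrep") %in% names(specified_rates)))
      stop("specified_rates must be named with specified_rep and specified_nonrep")
    if (any(specified_rates <= 0)) stop("specified_rates must be > 0")
  }
  structure(
    list(mean_rates = mean_rates, rate_sds = rate_sds,
         threshold = as.numeric(threshold),
         start_range = as.numeric(start_range),
         non_decision = as.numeric(non_decision),
         specified_rates = specified_rates),
    class = "lba_params")
}

#' @export
print.lba_params <- function(x, ...) {
  cat("LBA parameters\n")
  cat("  mean rates: ", paste(signif(x$mean_rates, 4), collapse = ", "), "\n")
  cat("  rate SDs:   ", paste(signif(x$rate_sds, 4), collapse = ", "), "\n")
  cat("  threshold b:", signif(x$threshold, 4),
      " start range c0:", paste(signif(x$start_range, 4), collapse = ", "),
      " non-decision t0:", signif(x$non_decision, 4), "s\n")
  if (!is.null(x$specified_rates))
    cat("  specified-condition shared rates:",
        paste(names(x$specified_rates), signif(x$specified_rates, 4),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Condition-wise modulation ratios for one model parameter
#'
#' A modulation set quantifies, for one parameter (mean rate, threshold, or
#' non-decision time), the multiplicative change in each non-baseline condition
#' relative to the baseline (choice, repetition-absent) condition. One ratio is
#' shared across accumulators and across previous-action identities, so the
#' effect of the previous response is quantified regardless of which action it
#' was.
#'
#' With `scope = "repetition"` the ratio multiplies only the accumulator
#' matching the previous action (for specified conditions, the single active
#' accumulator); with `scope = "all"` it multiplies every active accumulator.
#'
#' @param choice_rep_available ratio applied in repetition-available choice
#'   trials (> 0).
#' @param specified_rep ratio applied in specified repetition trials (> 0).
#' @param specified_nonrep ratio applied in specified non-repetition trials
#'   (> 0).
#' @param scope `"repetition"` (default) or `"all"`.
#' @param parameter which parameter is modulated: `"mean_rate"`,
#'   `"threshold"`, or `"non_decision"`.
#'
#' @return An object of class `modulation_set`.
#' @export
modulation_set <- function(choice_rep_available = 1, specified_rep = 1,
                           specified_nonrep = 1,
                           scope = c("repetition", "all"),
                           parameter = c("mean_rate", "threshold", "non_decision")) {
  ratios <- c(choice_rep_available = choice_rep_available,
              specified_rep = specified_rep,
              specified_nonrep = specified_nonrep)
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("modulation ratios must be finite and > 0")
  structure(
    list(ratios = ratios, scope = match.arg(scope),
         parameter = match.arg(parameter)),
    class = "modulation_set")
}

#' @export
print.modulation_set <- function(x, ...) {
  cat("Modulation of", x$parameter, "(scope:", x$scope, ")\n")
  print(signif(x$ratios, 4))
  invisible(x)
}

# normalize a modulation argument into a named list keyed by parameter
as_modulation_list <- function(mods) {
  if (is.null(mods)) return(list())
  if (inherits(mods, "modulation_set")) mods <- list(mods)
  if (!all(vapply(mods, inherits, logical(1), "modulation_set")))
    stop("mods must be a modulation_set or a list of them")
  pars <- vapply(mods, `[[`, character(1), "parameter")
  if (anyDuplicated(pars)) stop("duplicate modulation_set for parameter: ",
                                pars[duplicated(pars)][1])
  names(mods) <- pars
  mods
}
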
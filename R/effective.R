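#' Effective per-trial accumulator parameters
#'
#' Expands a baseline parameter set into the effective per-accumulator
#' parameters for one trial, given the model design, the modulation ratios,
#' the trial's condition, the previous action, and the set of valid actions.
#'
#' The baseline condition (choice, repetition-absent) always returns the base
#' values. In other conditions, each condition-modulated parameter (per the
#' design's `f2`/`f3`/`f4` flags) is multiplied by its condition-specific
#' ratio; with scope `"repetition"` (design `f6` off) the ratio applies only
#' to the accumulator whose action matches the previous action (for specified
#' conditions, the single active accumulator), with scope `"all"` (`f6` on) to
#' every active accumulator. Designs with `f5` replace the specified-condition
#' rate means with the shared free rate in `base$specified_rates`.
#'
#' @param base an [lba_params()] object.
#' @param mods a [modulation_set()] or list of them (one per modulated
#'   parameter); may be `NULL` when the design modulates nothing.
#' @param design a [model_design()].
#' @param condition one of `"choice_rep_available"`, `"choice_rep_absent"`,
#'   `"specified_rep"`, `"specified_nonrep"`.
#' @param previous_action integer action id in 1..4.
#' @param valid_actions integer vector of valid action ids (3 for choice, 1
#'   for specified trials).
#'
#' @return A list with elements `actions`, `mean_rates`, `rate_sds`,
#'   `threshold`, `start_range`, `non_decision`, each aligned with
#'   `actions` (the sorted valid action ids).
#' @export
#' @examples
#' base <- lba_params(rep(1, 4), rep(0.3, 4), 1, 0.2, 0.15)
#' mod <- modulation_set(choice_rep_available = 0.7, parameter = "mean_rate")
#' effective_params(base, mod, model_design(f3 = TRUE),
#'                  "choice_rep_available", previous_action = 1,
#'                  valid_actions = c(1, 2, 3))
effective_params <- function(base, mods, design, condition, previous_action,
                             valid_actions) {
  stopifnot(inherits(base, "lba_params"), inherits(design, "model_design"))
  condition <- match.arg(condition, CONDITIONS)
  valid_actions <- sort(as.integer(valid_actions))
  if (anyDuplicated(valid_actions) || any(!valid_actions %in% seq_len(N_ACTIONS)))
    stop("valid_actions must be distinct action ids in 1..", N_ACTIONS)
  is_choice <- condition %in% c("choice_rep_available", "choice_rep_absent")
  if (is_choice && length(valid_actions) != 3L)
    stop("choice conditions require 3 valid actions, got ", length(valid_actions))
  if (!is_choice && length(valid_actions) != 1L)
    stop("specified conditions require exactly 1 valid action")
  needs_prev <- condition != BASELINE_CONDITION || is_choice
  previous_action <- as.integer(previous_action)
  if (needs_prev && (length(previous_action) != 1L || is.na(previous_action)))
    stop("previous_action must be a single action id for condition ", condition)
  # condition/previous-action consistency
  prev_in <- previous_action %in% valid_actions
  ok <- switch(condition,
    choice_rep_available = prev_in,
    choice_rep_absent = !prev_in,
    specified_rep = prev_in,
    specified_nonrep = !prev_in)
  if (!ok)
    stop("previous action ", previous_action,
         if (prev_in) " must not be " else " must be ",
         "in the valid set for condition ", condition)

  mods <- as_modulation_list(mods)
  mu <- base$mean_rates[valid_actions]
  sigma <- base$rate_sds[valid_actions]
  b <- rep(base$threshold, length(valid_actions))
  c0 <- if (length(base$start_range) == 1L)
    rep(base$start_range, length(valid_actions)) else base$start_range[valid_actions]
  t0 <- rep(base$non_decision, length(valid_actions))

  # f5: equal rates across accumulators in the specified conditions
  if (design$f5 && !is_choice) {
    if (is.null(base$specified_rates))
      stop("design has f5 on but base$specified_rates is missing")
    mu[] <- base$specified_rates[[condition]]
  }

  if (condition != BASELINE_CONDITION) {
    scope_all <- isTRUE(design$f6)
    target <- if (scope_all) rep(TRUE, length(valid_actions))
              else valid_actions == previous_action | !is_choice
    flag_of <- c(mean_rate = "f3", threshold = "f2", non_decision = "f4")
    for (par in names(mods)) {
      if (!isTRUE(design[[flag_of[[par]]]])) next
      if (par == "mean_rate" && design$f5 && !is_choice) next
      r <- mods[[par]]$ratios[[condition]]
      switch(par,
        mean_rate = { mu[target] <- mu[target] * r },
        threshold = { b[target] <- b[target] * r },
        non_decision = { t0[target] <- t0[target] * r })
    }
    if (any(b <= c0))
      stop("effective threshold does not exceed start range after modulation")
  }

  list(actions = valid_actions, mean_rates = mu, rate_sds = sigma,
       threshold = b, start_range = c0, non_decision = t0)
}
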
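#' Expected accumulation rate of the winning accumulator
#'
#' Given that the winner started on average at `c0/2` and reached the
#' threshold `b` exactly at the decision time `t - t0`, its expected rate is
#' `(b - c0/2) / (t - t0)`.
#'
#' @param threshold response threshold `b` (> `start_range / 2`).
#' @param start_range start-point range `c0`.
#' @param rt observed response time `t` (s).
#' @param non_decision non-decision time `t0` (s); must satisfy `rt > t0`.
#' @return expected winner rate, evidence units per second. Vectorized.
#' @export
#' @examples
#' expected_winner_rate(1, 0, 1, 0)        # 1
#' expected_winner_rate(1, 0.5, 1.5, 0.5)  # 0.75
expected_winner_rate <- function(threshold, start_range, rt, non_decision) {
  if (any(rt <= non_decision))
    stop("rt must exceed the non-decision time (rt faster than t0)")
  if (any(threshold <= start_range / 2))
    stop("threshold must exceed start_range / 2")
  (threshold - start_range / 2) / (rt - non_decision)
}

#' Expected rate of a losing accumulator (upper-truncated normal mean)
#'
#' A loser's sampled rate is below the winner's realized rate, so its
#' distribution is a normal truncated from above at `upper_bound`. The
#' expectation is `mu - sigma * phi(z) / Phi(z)` with
#' `z = (upper_bound - mu) / sigma` (an inverse Mills ratio). The hazard term
#' is evaluated in the log domain so the expression stays numerically stable
#' far into the lower tail (`z << 0`).
#'
#' @param mean,sd untruncated normal mean and SD (`sd > 0`).
#' @param upper_bound truncation point (the realized winner rate).
#' @return expected truncated rate; always `< upper_bound`. Vectorized.
#' @export
#' @examples
#' truncated_loser_rate(0, 1, 0)    # -dnorm(0)/pnorm(0) = -0.7979
truncated_loser_rate <- function(mean, sd, upper_bound) {
  if (any(sd <= 0)) stop("sd must be > 0")
  z <- (upper_bound - mean) / sd
  # phi(z)/Phi(z), stable for very negative z
  mills <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
  mean - sd * mills
}

#' Expected accumulated activity of one trial
#'
#' Computes the expected area under each valid accumulator's activation
#' trajectory up to the decision time `T = rt - t0`, using the trial's
#' condition-specific effective parameters. Every accumulator starts on
#' average at `c0/2`. The winner ramps linearly from `c0/2` to its threshold:
#' area `= (b + c0/2) * T / 2`. Each loser ramps at its expected truncated
#' rate (bounded above by the winner's expected rate): signed area
#' `= (c0/2) * T + E[rate] * T^2 / 2`; negative expected loser rates are
#' allowed (activation is not floored at zero) and flagged. Specified trials
#' have a single valid accumulator, so the trial EAA equals the winner term.
#'
#' @param eff effective per-accumulator parameters from [effective_params()].
#' @param winner winning (responded) action id; must be in `eff$actions`.
#' @param rt response time (s); must exceed the winner's non-decision time.
#' @return list of class `eaa_record`: `duration`, `winner_rate`,
#'   `loser_rates` (named, possibly empty), `eaa_winner`, `eaa_losers`
#'   (summed), `eaa_total`, and `negative_loser_rate` flag.
#' @export
trial_eaa <- function(eff, winner, rt) {
  wi <- match(winner, eff$actions)
  if (is.na(wi)) stop("winner ", winner, " is not among the valid actions")
  t0 <- eff$non_decision[wi]
  if (rt <= t0)
    stop("rt (", rt, ") does not exceed the non-decision time (", t0,
         "); trial must be excluded")
  T <- rt - t0
  bw <- eff$threshold[wi]
  c0w <- eff$start_range[wi]
  w_rate <- expected_winner_rate(bw, c0w, rt, t0)
  eaa_w <- 0.5 * (bw + c0w / 2) * T
  li <- setdiff(seq_along(eff$actions), wi)
  l_rates <- numeric(0)
  l_areas <- numeric(0)
  if (length(li)) {
    l_rates <- truncated_loser_rate(eff$mean_rates[li], eff$rate_sds[li],
                                    w_rate)
    l_areas <- (eff$start_range[li] / 2) * T + 0.5 * l_rates * T^2
    names(l_rates) <- names(l_areas) <- eff$actions[li]
  }
  structure(list(
    duration = T,
    winner = winner,
    winner_rate = w_rate,
    loser_rates = l_rates,
    eaa_winner = eaa_w,
    eaa_losers = sum(l_areas),
    loser_areas = l_areas,
    eaa_total = eaa_w + sum(l_areas),
    negative_loser_rate = any(l_rates < 0)), class = "eaa_record")
}

#' Per-trial EAA table for a participant
#'
#' Applies [trial_eaa()] to every responded action trial of a trial table,
#' using each trial's condition-specific effective parameters (including any
#' modulation of the repetition accumulator). Trials whose RT does not exceed
#' the effective non-decision time are excluded and counted (attribute
#' `n_excluded`), not silently zeroed.
#'
#' @param trials trial table (see [read_trial_table()]).
#' @param base,mods,design fitted parameters, modulations, and design.
#' @return data.frame with one row per included trial: `trial_index`,
#'   `onset_s`, `condition`, `rt_s`, `duration`, `winner_rate`, `eaa_winner`,
#'   `eaa_losers`, `eaa_total`, `negative_loser_rate`; attributes
#'   `n_excluded` and `excluded_trials`.
#' @export
compute_eaa <- function(trials, base, mods, design) {
  act <- trials[trials$trial_type %in% c("choice", "specified") &
                  !is.na(trials$response) & !is.na(trials$rt_s), , drop = FALSE]
  valid <- parse_actions(act$valid_actions)
  rows <- vector("list", nrow(act))
  excluded <- logical(nrow(act))
  for (i in seq_len(nrow(act))) {
    eff <- effective_params(base, mods, design, act$condition[i],
                            act$previous_action[i], valid[[i]])
    rec <- tryCatch(trial_eaa(eff, act$response[i], act$rt_s[i]),
                    error = function(e) NULL)
    if (is.null(rec)) { excluded[i] <- TRUE; next }
    rows[[i]] <- data.frame(
      trial_index = act$trial_index[i], onset_s = act$onset_s[i],
      condition = act$condition[i], rt_s = act$rt_s[i],
      duration = rec$duration, winner_rate = rec$winner_rate,
      eaa_winner = rec$eaa_winner, eaa_losers = rec$eaa_losers,
      eaa_total = rec$eaa_total,
      negative_loser_rate = rec$negative_loser_rate)
  }
  out <- do.call(rbind, rows[!excluded])
  attr(out, "n_excluded") <- sum(excluded)
  attr(out, "excluded_trials") <- act$trial_index[excluded]
  out
}

#' Residualize EAA against single-trial RT
#'
#' Removes the component of the EAA vector collinear with RT by least-squares
#' projection on an intercept and RT, returning residuals that are mean-zero
#' and uncorrelated with RT. Used to show that the EAA regressor carries
#' information beyond a linear RT effect.
#'
#' @param eaa,rt numeric vectors of equal length (>= 3).
#' @return numeric vector of residuals.
#' @export
residualize_eaa <- function(eaa, rt) {
  if (length(eaa) != length(rt)) stop("eaa and rt must have equal length")
  if (length(eaa) < 3) stop("need at least 3 trials to residualize")
  if (isTRUE(all.equal(var(rt), 0)) || var(rt) == 0)
    stop("rt vector is constant; projection beyond the intercept is undefined")
  residuals(lm(eaa ~ rt))
}

#' Export a BIDS-style events table with EAA modulators
#'
#' Writes a tab-separated events file (columns `onset`, `duration`,
#' `trial_type`, then the parametric modulators `eaa` and `eaa_residual`)
#' suitable for first-level GLM software. `duration` is the cue duration.
#'
#' @param eaa_table output of [compute_eaa()].
#' @param path output TSV path.
#' @param cue_duration event duration in seconds.
#' @param mean_center if `TRUE`, modulator columns are mean-centered.
#' @return the events data.frame, invisibly.
#' @export
write_events_tsv <- function(eaa_table, path, cue_duration = 1,
                             mean_center = FALSE) {
  ev <- data.frame(
    onset = eaa_table$onset_s,
    duration = cue_duration,
    trial_type = ifelse(startsWith(eaa_table$condition, "choice"),
                        "choice", "specified"),
    eaa = eaa_table$eaa_total,
    eaa_residual = residualize_eaa(eaa_table$eaa_total, eaa_table$rt_s))
  if (mean_center) {
    ev$eaa <- ev$eaa - mean(ev$eaa)
    # residuals are mean-zero by construction
  }
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ev)
}
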
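QLEVELS <- c(0.1, 0.3, 0.5, 0.7, 0.9)
# observed multinomial mass between consecutive RT quantiles
QBIN_PROPS <- c(0.1, 0.2, 0.2, 0.2, 0.2, 0.1)

# sorted complements: EXCL_LOOKUP[a, ] = the three actions != a
EXCL_LOOKUP <- t(vapply(1:4, function(a) setdiff(1:4, a), integer(3)))

#' Simulate one LBA race trial
#'
#' Draws independent uniform start points on `[0, c0]` and independent normal
#' accumulation rates for each valid accumulator, races them to threshold, and
#' returns the winning action and its response time (accumulation duration
#' plus non-decision time). Accumulators whose sampled rate is not positive
#' never finish; if no accumulator finishes by the deadline the trial is an
#' omission (`selected_action` and `rt` are `NA`).
#'
#' @param eff effective per-accumulator parameters, as returned by
#'   [effective_params()].
#' @param deadline response deadline in seconds (the trial duration).
#' @return list with `selected_action` (action id or `NA`) and `rt` (seconds
#'   or `NA`).
#' @export
simulate_trial <- function(eff, deadline = 2.4) {
  k <- length(eff$actions)
  start <- eff$start_range * runif(k)
  rate <- eff$mean_rates + eff$rate_sds * rnorm(k)
  finish <- ifelse(rate > 0,
                   pmax(eff$threshold - start, 0) / rate + eff$non_decision,
                   Inf)
  i <- which.min(finish)
  if (!is.finite(finish[i]) || finish[i] > deadline)
    return(list(selected_action = NA_integer_, rt = NA_real_))
  list(selected_action = eff$actions[i], rt = finish[i])
}

# Per-condition trial layout: previous actions, valid-set matrix V (actions),
# modulation mask M, and the selection-category map (1 = repetition / cued,
# then non-previous valid actions in ascending index order). Uses the current
# RNG stream.
condition_layout <- function(condition, n, prev_mix = rep(0.25, 4)) {
  condition <- match.arg(condition, CONDITIONS)
  prev <- sample.int(4L, n, replace = TRUE, prob = prev_mix)
  if (condition == "choice_rep_available") {
    # exclude one finger drawn uniformly from the three non-previous ones
    excl <- EXCL_LOOKUP[cbind(prev, sample.int(3L, n, replace = TRUE))]
    V <- EXCL_LOOKUP[excl, , drop = FALSE]
    M <- V == prev
    c1 <- as.integer(!M[, 1]); c2 <- c1 + !M[, 2]; c3 <- c2 + !M[, 3]
    catmap <- cbind(ifelse(M[, 1], 1L, 1L + c1),
                    ifelse(M[, 2], 1L, 1L + c2),
                    ifelse(M[, 3], 1L, 1L + c3))
    cats <- c("repetition", "nonrep_1", "nonrep_2")
  } else if (condition == "choice_rep_absent") {
    V <- EXCL_LOOKUP[prev, , drop = FALSE]
    M <- matrix(FALSE, n, 3L)
    catmap <- matrix(rep(1:3, each = n), n, 3L)
    cats <- c("nonrep_1", "nonrep_2", "nonrep_3")
  } else if (condition == "specified_rep") {
    V <- matrix(prev, ncol = 1L)
    M <- matrix(TRUE, n, 1L)
    catmap <- matrix(1L, n, 1L)
    cats <- "cued"
  } else {
    cue <- EXCL_LOOKUP[cbind(prev, sample.int(3L, n, replace = TRUE))]
    V <- matrix(cue, ncol = 1L)
    M <- matrix(TRUE, n, 1L)
    catmap <- matrix(1L, n, 1L)
    cats <- "cued"
  }
  list(condition = condition, prev = prev, V = V, M = M,
       catmap = catmap, categories = cats, k = ncol(V))
}

# Length-4 parameter vectors plus this condition's modulation ratios, ready
# for the compiled race kernel. The ratio for an unmodulated parameter is 1.
condition_inputs <- function(base, mods, design, condition) {
  mods <- as_modulation_list(mods)
  mu <- base$mean_rates
  is_choice <- condition %in% c("choice_rep_available", "choice_rep_absent")
  r <- c(mean_rate = 1, threshold = 1, non_decision = 1)
  if (condition != BASELINE_CONDITION) {
    flag_of <- c(mean_rate = "f3", threshold = "f2", non_decision = "f4")
    for (par in names(mods)) {
      if (isTRUE(design[[flag_of[[par]]]]))
        r[[par]] <- mods[[par]]$ratios[[condition]]
    }
  }
  if (design$f5 && !is_choice) {
    if (is.null(base$specified_rates))
      stop("design has f5 on but base$specified_rates is missing")
    mu <- rep(base$specified_rates[[condition]], N_ACTIONS)
    r[["mean_rate"]] <- 1
  }
  c0 <- if (length(base$start_range) == 1L)
    rep(base$start_range, N_ACTIONS) else base$start_range
  list(mu = mu, sd = base$rate_sds,
       b = rep(base$threshold, N_ACTIONS), c0 = c0,
       t0 = rep(base$non_decision, N_ACTIONS),
       r_mu = r[["mean_rate"]], r_b = r[["threshold"]],
       r_t0 = r[["non_decision"]])
}

# Vectorized simulation of n trials of one condition. Uses the current RNG
# stream unless pre-drawn variates are supplied in `draws` (list with Z, U).
simulate_condition <- function(base, mods, design, condition, n,
                               prev_mix = rep(0.25, 4), deadline = 2.4,
                               layout = NULL, draws = NULL) {
  if (is.null(layout)) layout <- condition_layout(condition, n, prev_mix)
  k <- layout$k
  if (is.null(draws))
    draws <- list(Z = matrix(rnorm(n * k), n, k),
                  U = matrix(runif(n * k), n, k))
  inp <- condition_inputs(base, mods, design, condition)
  res <- race_sim_cpp(inp$mu, inp$sd, inp$b, inp$c0, inp$t0,
                      inp$r_mu, inp$r_b, inp$r_t0,
                      layout$V, layout$M, draws$Z, draws$U, deadline)
  category <- layout$catmap[cbind(seq_len(n), res$slot)]
  data.frame(previous_action = layout$prev, winner = res$winner,
             rt = res$rt, category = category)
}

#' Model-predicted condition summary from numerical simulation
#'
#' Simulates `n_sim` trials of one condition (previous actions drawn from
#' `prev_mix`, valid-action sets constructed per the condition's repetition
#' rule) and summarizes them: RT quantiles at levels 0.1/0.3/0.5/0.7/0.9 over
#' responded trials, per-action selection probabilities, selection-category
#' probabilities relative to the previous action, and the omission rate.
#'
#' @inheritParams simulate_condition
#' @param n_sim number of simulated trials (>= 1000).
#' @param seed optional integer seed; when given, results are reproducible.
#' @param keep_sample if `TRUE` the simulated responded RTs are retained in
#'   the result (`rt_sample`), e.g. for binning against observed quantiles.
#' @return An object of class `condition_summary`.
#' @export
predict_summaries <- function(base, mods, design, condition,
                              prev_mix = rep(0.25, 4), n_sim = 1e5,
                              seed = NULL, deadline = 2.4,
                              keep_sample = FALSE) {
  if (n_sim < 1000) stop("n_sim must be at least 1000")
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_condition(base, mods, design, condition, n_sim,
                            prev_mix = prev_mix, deadline = deadline)
  resp <- !is.na(sim$rt)
  if (!any(resp))
    stop("all ", n_sim, " simulated trials of condition ", condition,
         " were omissions; parameters cannot produce responses by the deadline")
  rts <- sim$rt[resp]
  ncat <- if (startsWith(condition, "choice")) 3L else 1L
  out <- structure(list(
    condition = condition,
    rt_quantiles = quantile(rts, QLEVELS, names = TRUE, type = 7),
    selection_probs = tabulate(sim$winner[resp], 4L) / n_sim,
    category_probs = setNames(tabulate(sim$category[resp], ncat) / sum(resp),
                              if (ncat == 3L) c("repetition", "nonrep_1",
                                                "nonrep_2")[seq_len(ncat)]
                              else "cued"),
    n_trials = n_sim,
    omission_rate = mean(!resp),
    prev_mix = prev_mix / sum(prev_mix),
    seed = seed), class = "condition_summary")
  if (condition == "choice_rep_absent")
    names(out$category_probs) <- c("nonrep_1", "nonrep_2", "nonrep_3")
  if (keep_sample) out$rt_sample <- rts
  out
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("Condition summary:", x$condition, "(n =", x$n_trials, ")\n")
  cat("  RT quantiles (s):\n")
  print(signif(x$rt_quantiles, 4))
  if (!is.null(x$category_probs)) {
    cat("  selection categories:\n")
    print(signif(x$category_probs, 4))
  }
  cat("  omission rate:", signif(x$omission_rate, 4), "\n")
  invisible(x)
}
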
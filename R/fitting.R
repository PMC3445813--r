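#' Fit configuration
#'
#' Controls the quantile-G2 fitting procedure: the number of simulated trials
#' per condition used for model predictions, the multi-restart schedule, the
#' simplex termination rule, and the random-start search ranges.
#'
#' Defaults follow the reference procedure: predictions from 100,000
#' simulations per condition, 20 restarts each started from the best of 100
#' random candidate parameter sets, and a 10,000-iteration simplex cap.
#' Reduced settings (e.g. `n_sim = 20000, restarts = 5`) give desk-scale fits.
#'
#' @param n_sim simulated trials per condition per objective evaluation.
#' @param restarts number of independent simplex restarts.
#' @param candidates random candidate parameter sets evaluated per restart;
#'   the best seeds the simplex.
#' @param maxit simplex iteration cap.
#' @param reltol relative G2 convergence tolerance of the simplex.
#' @param deadline response deadline (s).
#' @param min_trials minimum responded trials per condition.
#' @param eps floor on model-predicted proportions; default `1/(2 * n_sim)`.
#' @param pin_rate_sd if `TRUE`, the first accumulator's rate SD is fixed at
#'   1 as the scale unit instead of being fitted, resolving the LBA's scale
#'   non-identifiability; all 11 nominal parameters are free by default, and
#'   reported parameter counts stay nominal either way.
#' @param ranges named list of random-start ranges: `mu`, `sd`, `b` (each
#'   `c(lo, hi)`), `c0_frac` (start range as a fraction of threshold),
#'   `t0` (lower bound; the upper bound is the smallest observed RT), and
#'   `ratio`.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_sim = 1e5, restarts = 20, candidates = 100,
                       maxit = 10000, reltol = 1e-4, deadline = 2.4,
                       min_trials = 10, eps = NULL, pin_rate_sd = FALSE,
                       ranges = list(mu = c(0.5, 5), sd = c(0.2, 2),
                                     b = c(0.5, 3), c0_frac = c(0.02, 0.9),
                                     t0 = c(0.05, NA), ratio = c(0.3, 3))) {
  if (is.null(eps)) eps <- 1 / (2 * n_sim)
  structure(list(n_sim = n_sim, restarts = restarts, candidates = candidates,
                 maxit = maxit, reltol = reltol, deadline = deadline,
                 min_trials = min_trials, eps = eps,
                 pin_rate_sd = pin_rate_sd, ranges = ranges),
            class = "fit_config")
}

# parse "1,2,3" valid-action strings into a list of integer vectors
parse_actions <- function(x) {
  lapply(strsplit(as.character(x), ","), function(v) sort(as.integer(v)))
}

# selection category of one response relative to the previous action:
# 1 = repetition (or the cued action), otherwise 1 + rank of the response
# among the non-previous valid actions in ascending index order
response_category <- function(response, previous, valid) {
  if (is.na(response)) return(NA_integer_)
  if (response == previous) return(1L)
  nonprev <- sort(valid[valid != previous])
  off <- if (previous %in% valid) 1L else 0L
  off + match(response, nonprev)
}

#' Summarize observed behaviour in one condition
#'
#' Computes the observed fitting summary for a single experimental condition:
#' RT quantiles at 0.1/0.3/0.5/0.7/0.9 (linear-interpolation empirical
#' quantiles, R type 7), the implied RT-bin counts (proportions 0.1/0.2/0.2/
#' 0.2/0.2/0.1 of responded trials), selection-category counts relative to the
#' previous action for choice conditions, per-action selection probabilities,
#' the omission rate, and the empirical previous-action mix.
#'
#' @param trials data.frame of trials from one condition with columns
#'   `condition`, `previous_action`, `response`, `rt_s`, `valid_actions`.
#' @param min_trials floor on responded trials; fewer is an error naming the
#'   condition.
#' @return list of class `condition_summary` with observed counts.
#' @export
summarize_condition <- function(trials, min_trials = 10) {
  condition <- unique(trials$condition)
  if (length(condition) != 1L)
    stop("trials must come from a single condition, got: ",
         paste(condition, collapse = ", "))
  condition <- match.arg(condition, CONDITIONS)
  resp <- !is.na(trials$response) & !is.na(trials$rt_s)
  n_resp <- sum(resp)
  if (n_resp < min_trials)
    stop("condition ", condition, " has only ", n_resp,
         " responded trials (minimum ", min_trials, ")")
  rts <- trials$rt_s[resp]
  qs <- quantile(rts, QLEVELS, names = TRUE, type = 7)
  is_choice <- startsWith(condition, "choice")
  cat_counts <- NULL
  if (is_choice) {
    valid <- parse_actions(trials$valid_actions[resp])
    cats <- mapply(response_category, trials$response[resp],
                   trials$previous_action[resp], valid)
    cat_counts <- tabulate(cats, 3L)
    names(cat_counts) <- if (condition == "choice_rep_available")
      c("repetition", "nonrep_1", "nonrep_2")
    else c("nonrep_1", "nonrep_2", "nonrep_3")
  }
  structure(list(
    condition = condition,
    rt_quantiles = qs,
    bin_counts = n_resp * QBIN_PROPS,
    cat_counts = cat_counts,
    selection_probs = tabulate(trials$response[resp], 4L) / n_resp,
    n_trials = nrow(trials),
    n_resp = n_resp,
    omission_rate = 1 - n_resp / nrow(trials),
    prev_mix = tabulate(trials$previous_action[resp], 4L) / n_resp),
    class = "condition_summary")
}

# 2 * sum(O * log(O / E)) with E = n * pmax(p, eps); zero-observed bins
# contribute 0
gsq_terms <- function(obs_counts, pred_props, eps) {
  n <- sum(obs_counts)
  e <- n * pmax(pred_props, eps)
  pos <- obs_counts > 0
  2 * sum(obs_counts[pos] * log(obs_counts[pos] / e[pos]))
}

#' Likelihood-ratio chi-square between observed and predicted summaries
#'
#' For each condition, compares observed RT-bin counts (the six bins delimited
#' by the five observed quantiles) with the model's predicted bin proportions,
#' and for choice conditions additionally the observed selection-category
#' counts with the predicted category probabilities:
#' `G2 = 2 * sum(O * log(O / E))`. Predicted proportions are floored at `eps`
#' so the statistic stays finite for the optimizer; zero-observed bins
#' contribute 0.
#'
#' @param observed named list (by condition) of observed summaries from
#'   [summarize_condition()].
#' @param predicted named list (by condition); each element either carries
#'   `bin_props` (length 6) and optionally `cat_props`, or an `rt_sample`
#'   (plus `category` sample) from which proportions are derived by binning
#'   at the observed quantiles.
#' @param eps floor for predicted proportions.
#' @return the G-squared statistic (dimensionless).
#' @export
g_squared <- function(observed, predicted, eps = 1e-6) {
  conds <- names(observed)
  if (!setequal(conds, names(predicted)))
    stop("observed and predicted must cover the same conditions")
  total <- 0
  for (cn in conds) {
    obs <- observed[[cn]]
    pred <- predicted[[cn]]
    bin_props <- pred$bin_props
    if (is.null(bin_props)) {
      if (is.null(pred$rt_sample))
        stop("predicted[[", cn, "]] has neither bin_props nor rt_sample")
      edges <- obs$rt_quantiles
      counts <- tabulate(findInterval(pred$rt_sample, edges) + 1L,
                         length(edges) + 1L)
      bin_props <- counts / length(pred$rt_sample)
    }
    total <- total + gsq_terms(obs$bin_counts, bin_props, eps)
    if (!is.null(obs$cat_counts) && sum(obs$cat_counts) > 0) {
      cat_props <- if (!is.null(pred$cat_props)) pred$cat_props
                   else pred$category_probs
      if (is.null(cat_props))
        stop("predicted[[", cn, "]] lacks category proportions")
      total <- total + gsq_terms(obs$cat_counts, cat_props, eps)
    }
  }
  total
}

#' Multinomial-deviance BIC
#'
#' `BIC = G2 + k * log(n)`, with `k` the number of free parameters and `n`
#' the participant's fitted (responded) trial count. Summing these values
#' over participants scores a design at the group level.
#'
#' @param fit a `fit_result`, or a numeric G-squared value.
#' @param k,n free-parameter count and fitted trial count (ignored when `fit`
#'   is a `fit_result`).
#' @return numeric BIC value.
#' @export
#' @examples
#' bic(10, k = 3, n = 756)  # 10 + 3 * log(756)
bic <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "fit_result")) {
    g2 <- fit$g_squared; k <- fit$k; n <- fit$n
  } else g2 <- fit
  if (is.null(k) || is.null(n)) stop("k and n are required")
  if (n <= 0) stop("n must be positive")
  g2 + k * log(n)
}

# ---- parameter vector <-> model parameters ---------------------------------

C0_FRAC_MAX <- 0.95  # keeps threshold > start range under the transform

# ordered free-parameter layout of a design; pinning sd1 = 1 removes it
param_map <- function(design, pin_rate_sd = FALSE) {
  nm <- c(paste0("mu", 1:4),
          paste0("sd", if (pin_rate_sd) 2:4 else 1:4), "b")
  nm <- c(nm, if (design$f1) paste0("c0_", 1:4) else "c0", "t0")
  if (design$f2) nm <- c(nm, paste0("rb_", MODULATED_CONDITIONS))
  if (design$f3) {
    nm <- if (design$f5)
      c(nm, "rm_choice_rep_available", "mu_specified_rep", "mu_specified_nonrep")
    else c(nm, paste0("rm_", MODULATED_CONDITIONS))
  }
  if (design$f4) nm <- c(nm, paste0("rt_", MODULATED_CONDITIONS))
  nm
}

# unconstrained theta -> (lba_params, modulation list); t0_max is the
# smallest observed RT (non-decision time cannot exceed it)
theta_to_params <- function(theta, design, t0_max, pin_rate_sd = FALSE) {
  nm <- param_map(design, pin_rate_sd)
  names(theta) <- nm
  mu <- unname(exp(theta[paste0("mu", 1:4)]))
  sd <- if (pin_rate_sd) c(1, unname(exp(theta[paste0("sd", 2:4)])))
        else unname(exp(theta[paste0("sd", 1:4)]))
  b <- unname(exp(theta["b"]))
  c0 <- b * C0_FRAC_MAX *
    unname(plogis(theta[if (design$f1) paste0("c0_", 1:4) else "c0"]))
  t0 <- 0.05 + (t0_max - 0.05) * unname(plogis(theta["t0"]))
  spec <- NULL
  mods <- list()
  if (design$f2)
    mods <- c(mods, list(modulation_set(
      exp(theta[["rb_choice_rep_available"]]),
      exp(theta[["rb_specified_rep"]]), exp(theta[["rb_specified_nonrep"]]),
      scope = if (design$f6) "all" else "repetition",
      parameter = "threshold")))
  if (design$f3) {
    if (design$f5) {
      spec <- c(specified_rep = exp(theta[["mu_specified_rep"]]),
                specified_nonrep = exp(theta[["mu_specified_nonrep"]]))
      mods <- c(mods, list(modulation_set(
        exp(theta[["rm_choice_rep_available"]]), 1, 1,
        scope = if (design$f6) "all" else "repetition",
        parameter = "mean_rate")))
    } else {
      mods <- c(mods, list(modulation_set(
        exp(theta[["rm_choice_rep_available"]]),
        exp(theta[["rm_specified_rep"]]), exp(theta[["rm_specified_nonrep"]]),
        scope = if (design$f6) "all" else "repetition",
        parameter = "mean_rate")))
    }
  }
  if (design$f4)
    mods <- c(mods, list(modulation_set(
      exp(theta[["rt_choice_rep_available"]]),
      exp(theta[["rt_specified_rep"]]), exp(theta[["rt_specified_nonrep"]]),
      scope = if (design$f6) "all" else "repetition",
      parameter = "non_decision")))
  base <- lba_params(mu, sd, b, c0, t0, specified_rates = spec)
  list(base = base, mods = as_modulation_list(mods))
}

# one random candidate drawn uniformly from the search ranges, returned on
# the unconstrained theta scale
random_theta <- function(design, ranges, t0_max, pin_rate_sd = FALSE) {
  runi <- function(r, n = 1) runif(n, r[1], r[2])
  nm <- param_map(design, pin_rate_sd)
  th <- numeric(length(nm))
  names(th) <- nm
  sdnm <- nm[startsWith(nm, "sd")]
  th[paste0("mu", 1:4)] <- log(runi(ranges$mu, 4))
  th[sdnm] <- log(runi(ranges$sd, length(sdnm)))
  th["b"] <- log(runi(ranges$b))
  c0nm <- nm[startsWith(nm, "c0")]
  th[c0nm] <- qlogis(runi(ranges$c0_frac, length(c0nm)) / C0_FRAC_MAX)
  t0hi <- min(t0_max - 1e-3, if (is.na(ranges$t0[2])) Inf else ranges$t0[2])
  t0 <- runif(1, ranges$t0[1] + 1e-4, max(t0hi, ranges$t0[1] + 2e-4))
  th["t0"] <- qlogis(min(0.999, max(1e-3, (t0 - 0.05) / (t0_max - 0.05))))
  rnm <- grep("^r[bmt]_", nm, value = TRUE)
  th[rnm] <- log(runi(ranges$ratio, length(rnm)))
  mnm <- grep("^mu_specified", nm, value = TRUE)
  th[mnm] <- log(runi(ranges$mu, length(mnm)))
  th
}

PENALTY <- 1e8

# G2 objective over the four conditions, using fixed layouts/draws (common
# random numbers) so the surface is deterministic within a restart. Works
# directly on the unconstrained vector (no per-evaluation object
# construction): the hot path inside the simplex.
make_objective <- function(design, obs, layouts, draws, t0_max, config) {
  force(design); force(obs); force(layouts); force(draws)
  nm <- param_map(design, config$pin_rate_sd)
  i_mu <- match(paste0("mu", 1:4), nm)
  i_sd <- match(paste0("sd", 1:4), nm)           # NA where pinned
  i_b <- match("b", nm)
  i_c0 <- if (design$f1) match(paste0("c0_", 1:4), nm)
          else rep(match("c0", nm), 4)
  i_t0 <- match("t0", nm)
  ratio_idx <- function(prefix) {
    ii <- match(paste0(prefix, MODULATED_CONDITIONS), nm)
    names(ii) <- MODULATED_CONDITIONS
    ii
  }
  i_rb <- if (design$f2) ratio_idx("rb_")
  i_rm <- if (design$f3 && !design$f5) ratio_idx("rm_")
  i_rm1 <- if (design$f3 && design$f5) match("rm_choice_rep_available", nm)
  i_msp <- if (design$f3 && design$f5)
    c(specified_rep = match("mu_specified_rep", nm),
      specified_nonrep = match("mu_specified_nonrep", nm))
  i_rt <- if (design$f4) ratio_idx("rt_")
  is_choice <- setNames(startsWith(CONDITIONS, "choice"), CONDITIONS)

  function(theta) {
    mu <- exp(theta[i_mu])
    sd <- if (config$pin_rate_sd) c(1, exp(theta[i_sd[2:4]]))
          else exp(theta[i_sd])
    b <- exp(theta[i_b])
    c0 <- b * C0_FRAC_MAX * plogis(theta[i_c0])
    t0 <- 0.05 + (t0_max - 0.05) * plogis(theta[i_t0])
    # threshold modulation must not push the threshold into the start range
    if (design$f2 && b * min(1, exp(theta[i_rb])) <= max(c0))
      return(PENALTY)
    b4 <- rep(b, 4L)
    t4 <- rep(t0, 4L)
    total <- 0
    for (cn in CONDITIONS) {
      o <- obs[[cn]]
      r_mu <- r_b <- r_t0 <- 1
      mu_c <- mu
      if (cn != BASELINE_CONDITION) {
        if (design$f2) r_b <- exp(theta[i_rb[[cn]]])
        if (design$f4) r_t0 <- exp(theta[i_rt[[cn]]])
        if (design$f3) {
          if (!design$f5) r_mu <- exp(theta[i_rm[[cn]]])
          else if (is_choice[[cn]]) r_mu <- exp(theta[i_rm1])
          else mu_c <- rep(exp(theta[i_msp[[cn]]]), 4L)
        }
      }
      res <- race_fit_cpp(mu_c, sd, b4, c0, t4, r_mu, r_b, r_t0,
                          layouts[[cn]]$V, layouts[[cn]]$M,
                          draws[[cn]]$Z, draws[[cn]]$U,
                          config$deadline, o$rt_quantiles,
                          layouts[[cn]]$catmap, length(layouts[[cn]]$categories))
      if (res$n_resp == 0) return(PENALTY)
      total <- total + gsq_terms(o$bin_counts, res$bins / res$n_resp, config$eps)
      if (!is.null(o$cat_counts) && length(res$cats) > 1L)
        total <- total + gsq_terms(o$cat_counts, res$cats / res$n_resp, config$eps)
    }
    if (!is.finite(total)) return(PENALTY)
    total
  }
}

# split a participant table into per-condition observed summaries; drops null
# events, the flagged first action trial, and commission errors
prepare_observed <- function(trials, min_trials) {
  trials <- trials[trials$trial_type %in% c("choice", "specified"), , drop = FALSE]
  if (!is.null(trials$first_action))
    trials <- trials[!trials$first_action, , drop = FALSE]
  valid <- parse_actions(trials$valid_actions)
  commission <- !is.na(trials$response) &
    !mapply(function(r, v) r %in% v, trials$response, valid)
  if (any(commission)) {
    message(sum(commission), " commission error(s) excluded from fitting")
    trials <- trials[!commission, , drop = FALSE]
  }
  obs <- lapply(CONDITIONS, function(cn)
    summarize_condition(trials[trials$condition == cn, , drop = FALSE],
                        min_trials = min_trials))
  names(obs) <- CONDITIONS
  obs
}

#' Fit one model design to one participant's trials
#'
#' Minimizes the quantile/selection G-squared statistic between the observed
#' condition summaries and model predictions from `n_sim` simulations per
#' condition, by Nelder-Mead simplex with multiple restarts. Each restart
#' draws `candidates` random parameter sets uniformly from the search ranges,
#' starts the simplex from the best of them, and reuses one fixed set of
#' simulation random numbers across objective evaluations so the surface is
#' deterministic. The restart with the lowest final G-squared wins.
#'
#' @param trials participant trial table (see [read_trial_table()] for the
#'   schema); all four conditions must be present.
#' @param design a [model_design()].
#' @param config a [fit_config()].
#' @param seed integer seed; the fit is fully reproducible from it.
#' @return An object of class `fit_result`: the fitted `params` and `mods`,
#'   `g_squared`, parameter count `k`, fitted trial count `n`, `bic`,
#'   restart diagnostics, and the observed summaries.
#' @export
fit_design <- function(trials, design, config = fit_config(), seed = 1) {
  stopifnot(inherits(design, "model_design"))
  obs <- prepare_observed(trials, config$min_trials)
  t0_max <- min(vapply(obs, function(o) o$rt_quantiles[[1]], numeric(1)))
  t0_max <- min(min(trials$rt_s, na.rm = TRUE), t0_max)
  n_fit <- sum(vapply(obs, `[[`, numeric(1), "n_resp"))

  best <- NULL
  restart_g2 <- numeric(config$restarts)
  for (r in seq_len(config$restarts)) {
    set.seed(derive_seed(seed, r))
    layouts <- lapply(CONDITIONS, function(cn)
      condition_layout(cn, config$n_sim, obs[[cn]]$prev_mix))
    names(layouts) <- CONDITIONS
    draws <- lapply(layouts, function(l)
      list(Z = matrix(rnorm(config$n_sim * l$k), config$n_sim, l$k),
           U = matrix(runif(config$n_sim * l$k), config$n_sim, l$k)))
    objective <- make_objective(design, obs, layouts, draws, t0_max, config)
    cand <- replicate(config$candidates,
                      random_theta(design, config$ranges, t0_max,
                                   config$pin_rate_sd))
    cand_g2 <- apply(cand, 2, objective)
    theta0 <- cand[, which.min(cand_g2)]
    # simplex with re-initialization: R's Nelder-Mead can report convergence
    # with a collapsed simplex far from a minimum, so restart it from its own
    # endpoint until the improvement falls below reltol or the total
    # function-evaluation budget (maxit) is spent
    th <- theta0
    g_prev <- min(cand_g2)
    evals <- 0
    repeat {
      opt <- optim(th, objective, method = "Nelder-Mead",
                   control = list(maxit = max(100, config$maxit - evals),
                                  reltol = config$reltol))
      evals <- evals + opt$counts[[1]]
      improved <- g_prev - opt$value > config$reltol * (abs(opt$value) +
                                                          config$reltol)
      th <- opt$par
      g_prev <- opt$value
      if (!improved || evals >= config$maxit) break
    }
    restart_g2[r] <- opt$value
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$restart <- r
    }
  }
  if (!is.finite(best$value) || best$value >= PENALTY)
    stop("no restart produced a finite G-squared; check data and ranges")
  pars <- theta_to_params(best$par, design, t0_max, config$pin_rate_sd)
  k <- parameter_count(design)  # nominal count, pinned or not
  structure(list(
    design = design, params = pars$base, mods = pars$mods,
    g_squared = best$value, k = k, n = n_fit,
    bic = best$value + k * log(n_fit),
    restarts = config$restarts, restart_g2 = restart_g2,
    best_restart = best$restart,
    converged = best$convergence == 0, seed = seed,
    observed = obs, config = config, theta = best$par,
    t0_max = t0_max), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("LBA fit (design ", format(x$design), "): G2 = ",
      signif(x$g_squared, 5), ", k = ", x$k, ", n = ", x$n,
      ", BIC = ", signif(x$bic, 6), "\n", sep = "")
  cat("  best restart", x$best_restart, "of", x$restarts,
      if (x$converged) "(converged)" else "(iteration cap reached)", "\n")
  print(x$params)
  for (m in x$mods) print(m)
  invisible(x)
}

#' Observed vs model-predicted condition summaries of a fit
#'
#' Re-simulates the fitted model at the fitted parameters and tabulates, per
#' condition, the observed and predicted RT quantiles and selection-category
#' probabilities (the per-participant fit surface).
#'
#' @param fit a `fit_result`.
#' @param n_sim simulation size for the predictions.
#' @param seed seed for the prediction simulation.
#' @return data.frame with one row per condition x quantity.
#' @export
fit_summary_table <- function(fit, n_sim = fit$config$n_sim, seed = fit$seed) {
  rows <- lapply(CONDITIONS, function(cn) {
    o <- fit$observed[[cn]]
    p <- predict_summaries(fit$params, fit$mods, fit$design, cn,
                           prev_mix = o$prev_mix, n_sim = n_sim,
                           seed = seed + match(cn, CONDITIONS),
                           deadline = fit$config$deadline)
    qrow <- data.frame(condition = cn,
                       quantity = paste0("rt_q", QLEVELS),
                       observed = as.numeric(o$rt_quantiles),
                       predicted = as.numeric(p$rt_quantiles))
    crow <- NULL
    if (!is.null(o$cat_counts)) {
      crow <- data.frame(condition = cn,
                         quantity = paste0("p_", names(o$cat_counts)),
                         observed = as.numeric(o$cat_counts / o$n_resp),
                         predicted = as.numeric(p$category_probs))
    }
    rbind(qrow, crow)
  })
  do.call(rbind, rows)
}
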
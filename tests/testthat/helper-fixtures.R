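# shared fixtures and independent oracles used across test files

# a plausible symmetric participant: ~0.5-0.8 s RTs, few omissions at 2.4 s
base_params <- function() {
  lba_params(mean_rates = rep(1.5, 4), rate_sds = rep(0.5, 4),
             threshold = 1, start_range = 0.3, non_decision = 0.2)
}

rate_mods <- function(cra = 0.7, sr = 1.3, snr = 1.15) {
  modulation_set(choice_rep_available = cra, specified_rep = sr,
                 specified_nonrep = snr, parameter = "mean_rate")
}

design_null <- function() model_design()
design_rate <- function() model_design(f3 = TRUE)

# small fit configuration for unit tests (acceptance uses larger settings)
quick_config <- function(n_sim = 4000, restarts = 2, candidates = 20,
                         maxit = 400) {
  fit_config(n_sim = n_sim, restarts = restarts, candidates = candidates,
             maxit = maxit)
}

# a synthetic participant generated from known parameters
make_participant <- function(seed = 1, mods = rate_mods(),
                             design = design_rate(), base = base_params()) {
  session <- generate_session(session_spec(), seed = seed)
  generate_behavior(session, base, mods, design, seed = seed + 5000)
}

# ---- closed-form LBA finishing-time distribution (independent oracle) ------
# start point U(0, c0), rate N(mu, sigma); accumulators with non-positive
# rates never finish, which these expressions account for

oracle_lba_cdf <- function(t, b, c0, mu, sigma) {
  if (c0 == 0) return(1 - pnorm((b / t - mu) / sigma))
  z1 <- (b - c0 - t * mu) / (t * sigma)
  z2 <- (b - t * mu) / (t * sigma)
  1 + (b - c0 - t * mu) / c0 * pnorm(z1) -
    (b - t * mu) / c0 * pnorm(z2) +
    t * sigma / c0 * (dnorm(z1) - dnorm(z2))
}

oracle_lba_pdf <- function(t, b, c0, mu, sigma) {
  if (c0 == 0) return(dnorm((b / t - mu) / sigma) * b / (t^2 * sigma))
  z1 <- (b - c0 - t * mu) / (t * sigma)
  z2 <- (b - t * mu) / (t * sigma)
  (-mu * pnorm(z1) + sigma * dnorm(z1) +
     mu * pnorm(z2) - sigma * dnorm(z2)) / c0
}

# P(accumulator 1 finishes first) for a two-accumulator race, by quadrature
oracle_winner_prob2 <- function(b, c0, mu1, s1, mu2, s2) {
  integrate(function(t)
    vapply(t, function(tt)
      oracle_lba_pdf(tt, b, c0, mu1, s1) *
        (1 - oracle_lba_cdf(tt, b, c0, mu2, s2)), numeric(1)),
    0, Inf, rel.tol = 1e-10)$value
}

# exact signed-rank two-sided p by enumeration of all 2^n sign vectors
oracle_signrank_p <- function(values, null_location = 0) {
  d <- values - null_location
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# longest same-value run in a sequence
max_run <- function(x) max(rle(x)$lengths)
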
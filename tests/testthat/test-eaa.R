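test_that("expected winner rate follows (b - c0/2) / (t - t0)", {
  expect_equal(expected_winner_rate(1, 0, 1, 0), 1)
  expect_equal(expected_winner_rate(1, 0.5, 1.5, 0.5), 0.75)
  # homogeneity: doubling the decision time halves the rate
  r1 <- expected_winner_rate(1.2, 0.4, 0.8, 0.3)
  r2 <- expected_winner_rate(1.2, 0.4, 1.3, 0.3)
  expect_equal(r2, r1 / 2)
  expect_error(expected_winner_rate(1, 0, 0.2, 0.3), "non-decision")
})

test_that("truncated loser rates match sampling oracles and limits", {
  # standard normal truncated above 0: -phi(0)/Phi(0)
  expect_equal(truncated_loser_rate(0, 1, 0), -dnorm(0) / pnorm(0),
               tolerance = 1e-12)
  # truncation vanishes as the bound recedes
  expect_equal(truncated_loser_rate(2, 0.5, 1e6), 2)
  # rejection-sampling oracle
  set.seed(9)
  x <- rnorm(2e6, 2, 0.5)
  expect_equal(truncated_loser_rate(2, 0.5, 1), mean(x[x < 1]),
               tolerance = 2e-3)
  expect_lt(truncated_loser_rate(2, 0.5, 1), 1)
  # numerically stable far into the lower tail (naive form is 0/0)
  deep <- truncated_loser_rate(5, 0.25, 1)
  expect_true(is.finite(deep) && deep < 1)
  # never exceeds the bound, across a parameter sweep
  grid <- expand.grid(mu = c(-1, 0, 1, 3), sd = c(0.2, 1), bnd = c(-2, 0, 2))
  vals <- truncated_loser_rate(grid$mu, grid$sd, grid$bnd)
  expect_true(all(vals < grid$bnd))
})

test_that("trial EAA matches the quadrature oracle on random draws", {
  set.seed(17)
  for (i in 1:200) {
    b <- runif(1, 0.6, 2)
    c0 <- runif(1, 0, 0.8 * b)
    t0 <- runif(1, 0.05, 0.3)
    rt <- t0 + runif(1, 0.1, 1.5)
    mu <- runif(3, 0.5, 3)
    sd <- runif(3, 0.2, 1.5)
    base <- lba_params(c(mu, 1), c(sd, 1), b, c0, t0)
    eff <- effective_params(base, NULL, model_design(), "choice_rep_absent",
                            4, 1:3)
    winner <- sample(1:3, 1)
    rec <- trial_eaa(eff, winner, rt)
    # oracle: numeric integration of the three expected linear trajectories
    T <- rt - t0
    wr <- (b - c0 / 2) / T
    area_w <- integrate(function(s) c0 / 2 + wr * s, 0, T,
                        rel.tol = 1e-12)$value
    li <- setdiff(1:3, winner)
    area_l <- sum(vapply(li, function(j) {
      lr <- truncated_loser_rate(mu[j], sd[j], wr)
      integrate(function(s) c0 / 2 + lr * s, 0, T, rel.tol = 1e-12)$value
    }, numeric(1)))
    expect_equal(rec$eaa_winner, area_w, tolerance = 1e-8)
    expect_equal(rec$eaa_total, area_w + area_l, tolerance = 1e-8)
    expect_equal(rec$eaa_total, rec$eaa_winner + rec$eaa_losers,
                 tolerance = 1e-12)
    # losers never out-rate the winner
    expect_true(all(rec$loser_rates < rec$winner_rate))
  }
})

test_that("specified trials reduce to the winner triangle area", {
  base <- lba_params(rep(1, 4), rep(0.3, 4), 1, 0, 0)
  eff <- effective_params(base, NULL, model_design(), "specified_rep", 2, 2)
  rec <- trial_eaa(eff, 2, 1)
  expect_equal(rec$eaa_total, 0.5)          # 1/2 * b * T
  expect_equal(rec$eaa_total, rec$eaa_winner)
  expect_length(rec$loser_rates, 0)
  # symmetric losers accrue equal areas
  base2 <- base_params()
  eff2 <- effective_params(base2, NULL, model_design(), "choice_rep_absent",
                           4, 1:3)
  rec2 <- trial_eaa(eff2, 2, 0.8)
  expect_equal(unname(rec2$loser_areas[1]), unname(rec2$loser_areas[2]))
})

test_that("EAA grows with RT and RT-fast trials are excluded, not zeroed", {
  base <- base_params()
  eff <- effective_params(base, NULL, model_design(), "choice_rep_absent",
                          4, 1:3)
  rts <- seq(0.3, 2.2, by = 0.1)
  tot <- vapply(rts, function(t) trial_eaa(eff, 1, t)$eaa_total, numeric(1))
  expect_true(all(diff(tot) > 0))
  expect_error(trial_eaa(eff, 1, 0.1), "excluded")
  # table-level computation flags and counts exclusions
  trials <- make_participant(seed = 41)
  trials$rt_s[which(!is.na(trials$rt_s))[1]] <- 0.01  # force one exclusion
  tab <- compute_eaa(trials, base_params(), rate_mods(), design_rate())
  expect_equal(attr(tab, "n_excluded"), 1L)
  expect_equal(tab$eaa_total, tab$eaa_winner + tab$eaa_losers,
               tolerance = 1e-12)
  spec_rows <- startsWith(tab$condition, "specified")
  expect_equal(tab$eaa_total[spec_rows], tab$eaa_winner[spec_rows])
})

test_that("residualized EAA is orthogonal to RT and centered", {
  set.seed(51)
  rt <- runif(100, 0.4, 1.2)
  # affine in RT: residuals vanish
  expect_equal(residualize_eaa(3 + 2 * rt, rt), rep(0, 100),
               ignore_attr = TRUE, tolerance = 1e-10)
  # generic vectors: residuals orthogonal to RT and mean zero
  eaa <- rt^2 + rnorm(100, 0, 0.1)
  res <- residualize_eaa(eaa, rt)
  expect_lt(abs(sum(res * rt)), 1e-8 * sqrt(sum(res^2) * sum(rt^2)) + 1e-10)
  expect_equal(mean(res), 0, tolerance = 1e-12)
  # orthogonal input passes through centered
  x <- rnorm(50)
  rt2 <- runif(50)
  xo <- residuals(lm(x ~ rt2))
  expect_equal(residualize_eaa(xo, rt2), xo, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_error(residualize_eaa(1:5, rep(1, 5)), "constant")
})
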
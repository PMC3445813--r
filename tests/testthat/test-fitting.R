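make_condition_df <- function(condition, rt, response, previous, valid) {
  data.frame(condition = condition, rt_s = rt, response = response,
             previous_action = previous, valid_actions = valid,
             stringsAsFactors = FALSE)
}

test_that("observed condition summaries use interpolated quantiles and counts", {
  df <- make_condition_df("specified_rep", c(1, 2, 3, 4, 5) * 1,
                          response = rep(2L, 5), previous = rep(2L, 5),
                          valid = rep("2", 5))
  s <- summarize_condition(df, min_trials = 5)
  expect_equal(s$rt_quantiles[["50%"]], 3)
  expect_equal(sum(s$bin_counts), 5)
  # degenerate choice: all responses are one action
  df2 <- make_condition_df("choice_rep_absent", runif(12, 0.4, 0.8),
                           response = rep(3L, 12), previous = rep(1L, 12),
                           valid = rep("2,3,4", 12))
  s2 <- summarize_condition(df2, min_trials = 10)
  expect_equal(unname(s2$cat_counts), c(0, 12, 0))
  expect_equal(s2$selection_probs, c(0, 0, 1, 0))
  # too few trials names the offending condition
  expect_error(summarize_condition(df2[1:3, ], min_trials = 10),
               "choice_rep_absent")
})

test_that("observed summaries agree with simulator predictions from the same model", {
  base <- base_params()
  set.seed(21)
  sim <- lbadecide:::simulate_condition(base, NULL, design_null(),
                                        "choice_rep_absent", 2000)
  resp <- !is.na(sim$rt)
  df <- make_condition_df("choice_rep_absent", sim$rt[resp],
                          sim$winner[resp], sim$previous_action[resp],
                          vapply(sim$previous_action[resp], function(p)
                            paste(setdiff(1:4, p), collapse = ","),
                            character(1)))
  s <- summarize_condition(df)
  p <- predict_summaries(base, NULL, design_null(), "choice_rep_absent",
                         n_sim = 1e5, seed = 22)
  expect_equal(unname(s$rt_quantiles), unname(p$rt_quantiles),
               tolerance = 0.03)
  expect_equal(unname(s$cat_counts / s$n_resp), unname(p$category_probs),
               tolerance = 0.05)
})

test_that("G-squared matches hand-computed values and its invariances", {
  obs1 <- list(A = list(rt_quantiles = 1:5, bin_counts = rep(0, 6),
                        cat_counts = c(10, 10), n_resp = 20))
  pred1 <- list(A = list(bin_props = rep(1 / 6, 6), cat_props = c(0.9, 0.1)))
  # 2 * (10 ln(10/18) + 10 ln(10/2)) = 20.433025
  expect_equal(g_squared(obs1, pred1), 20.43302495, tolerance = 1e-8)
  # observed proportions equal to predictions give exactly zero
  obs0 <- list(A = list(rt_quantiles = 1:5,
                        bin_counts = 60 * lbadecide:::QBIN_PROPS,
                        cat_counts = c(30, 20, 10), n_resp = 60))
  pred0 <- list(A = list(bin_props = lbadecide:::QBIN_PROPS,
                         cat_props = c(0.5, 1 / 3, 1 / 6)))
  expect_equal(g_squared(obs0, pred0), 0)
  # doubling all observed counts doubles the statistic
  obs2 <- obs1
  obs2$A$cat_counts <- obs1$A$cat_counts * 2
  obs2$A$n_resp <- 40
  expect_equal(g_squared(obs2, pred1), 2 * g_squared(obs1, pred1))
  # nonnegative for arbitrary mismatches
  pred2 <- list(A = list(bin_props = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1),
                         cat_props = c(0.2, 0.8)))
  expect_gt(g_squared(obs1, pred2), 0)
  # mismatched condition sets are rejected
  expect_error(g_squared(obs1, list(B = pred1$A)), "same conditions")
})

test_that("the deviance BIC follows G2 + k log(n)", {
  expect_equal(bic(0, k = 0, n = 100), 0)
  expect_equal(bic(10, k = 3, n = 756), 29.88412413, tolerance = 1e-8)
  # equal-fit designs differ by the parameter penalty alone
  expect_equal(bic(42, k = 14, n = 756) - bic(42, k = 11, n = 756),
               3 * log(756))
  expect_error(bic(10, k = 3, n = 0), "positive")
})

test_that("fits are reproducible from the seed and structurally coherent", {
  trials <- make_participant(seed = 31)
  cfg <- quick_config()
  f1 <- fit_design(trials, design_null(), cfg, seed = 7)
  f2 <- fit_design(trials, design_null(), cfg, seed = 7)
  expect_identical(f1$g_squared, f2$g_squared)
  expect_identical(f1$theta, f2$theta)
  expect_equal(f1$k, 11L)
  expect_equal(f1$bic, f1$g_squared + f1$k * log(f1$n))
  expect_gte(f1$g_squared, 0)
  # fitted trial count equals the responded, non-first, action trials
  act <- trials[trials$trial_type != "null" & !trials$first_action, ]
  expect_equal(f1$n, sum(!is.na(act$response)))
  expect_s3_class(f1$params, "lba_params")
})

test_that("pinning a rate SD fixes the scale without changing nominal counts", {
  trials <- make_participant(seed = 37)
  cfg <- quick_config(n_sim = 2000, restarts = 1, candidates = 10,
                      maxit = 150)
  cfg$pin_rate_sd <- TRUE
  fit <- fit_design(trials, design_null(), cfg, seed = 13)
  expect_equal(fit$params$rate_sds[1], 1)
  expect_equal(fit$k, 11L)  # counts stay nominal
})

test_that("a nested design never fits better than its richer extension", {
  trials <- make_participant(seed = 33)
  cfg <- quick_config(n_sim = 4000, restarts = 2, candidates = 30,
                      maxit = 600)
  f_null <- fit_design(trials, design_null(), cfg, seed = 11)
  f_rate <- fit_design(trials, design_rate(), cfg, seed = 11)
  # optimizer tolerance: the richer model could stall slightly above
  expect_lte(f_rate$g_squared, f_null$g_squared + 2)
})

test_that("the observed-vs-predicted table covers quantiles and categories", {
  trials <- make_participant(seed = 35)
  cfg <- quick_config(n_sim = 4000, restarts = 1, candidates = 20,
                      maxit = 300)
  fit <- fit_design(trials, design_null(), cfg, seed = 3)
  tab <- fit_summary_table(fit, n_sim = 5000)
  expect_setequal(unique(tab$condition), lbadecide:::CONDITIONS)
  expect_true(all(c("observed", "predicted") %in% names(tab)))
  # 5 quantiles everywhere, plus 3 selection categories per choice condition
  expect_equal(nrow(tab), 4 * 5 + 2 * 3)
  expect_true(all(is.finite(tab$observed)) && all(is.finite(tab$predicted)))
})
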
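test_that("design enumeration matches the brute-force meaningfulness oracle", {
  designs <- enumerate_designs()
  # independent oracle: all 64 flag vectors, filtered by the stated rules
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  ok <- apply(grid, 1, function(f) {
    if (f[6] && !any(f[2:4])) return(FALSE) # scope needs a modulated parameter
    if (f[5] && !f[3]) return(FALSE)        # equal specified rates need f3
    TRUE
  })
  expect_length(designs, sum(ok))
  expect_length(designs, 46L)
  # duplicate-free
  ids <- vapply(designs, format, character(1))
  expect_false(anyDuplicated(ids) > 0)
  # closed under the meaningfulness predicate: re-filtering is a no-op
  expect_true(all(vapply(designs, function(d)
    lbadecide:::design_meaningful(unlist(unclass(d))), logical(1))))
})

test_that("the design list is anchored at the documented indices", {
  designs <- enumerate_designs()
  expect_equal(format(designs[[1]]), "000000")  # simplest model first
  # singleton designs in feature order; rate-modulation is fourth
  expect_equal(format(designs[[3]]), "010000")  # threshold by condition
  expect_equal(format(designs[[4]]), "001000")  # rates by condition
  expect_equal(format(designs[[5]]), "000100")  # non-decision by condition
  expect_true(designs[[4]]$f3 && !designs[[4]]$f6)
})

test_that("uninterpretable flag combinations are rejected or normalized", {
  expect_error(model_design(f6 = TRUE), "uninterpretable")
  expect_error(model_design(f5 = TRUE), "uninterpretable")
  d <- model_design(f5 = TRUE, f6 = TRUE, normalize = TRUE)
  expect_equal(format(d), "000000")
  d2 <- model_design(f2 = TRUE, f6 = TRUE)
  expect_true(d2$f6)
})

test_that("parameter counts follow the documented accounting", {
  expect_identical(parameter_count(model_design()), 11L)
  expect_identical(parameter_count(model_design(f3 = TRUE)), 14L)
  expect_identical(parameter_count(model_design(f3 = TRUE)) -
                     parameter_count(model_design()), 3L)
  # each modulated parameter adds one ratio per non-baseline condition
  expect_identical(parameter_count(model_design(f3 = TRUE, f4 = TRUE)),
                   parameter_count(model_design(f3 = TRUE)) + 3L)
  # monotone: turning any feature on never decreases the count
  for (d in enumerate_designs()) {
    flags <- unlist(unclass(d))
    for (f in names(flags)[!flags]) {
      richer <- flags; richer[f] <- TRUE
      if (!lbadecide:::design_meaningful(richer)) next
      expect_gte(parameter_count(do.call(model_design, as.list(richer))),
                 parameter_count(d))
    }
  }
})

test_that("effective parameters modulate only the targeted accumulators", {
  base <- lba_params(c(1, 1, 1, 1), rep(0.3, 4), 1, 0.2, 0.15)
  mod <- modulation_set(choice_rep_available = 0.7, parameter = "mean_rate")
  # repetition-only scope: only the previous action's accumulator changes
  eff <- effective_params(base, mod, model_design(f3 = TRUE),
                          "choice_rep_available", previous_action = 1,
                          valid_actions = c(1, 2, 3))
  expect_equal(eff$mean_rates, c(0.7, 1, 1))
  expect_equal(eff$actions, 1:3)
  # all-accumulator scope multiplies every valid accumulator
  base2 <- lba_params(c(1, 2, 1, 1), rep(0.3, 4), 1, 0.2, 0.15)
  mod2 <- modulation_set(choice_rep_available = 0.5, scope = "all",
                         parameter = "mean_rate")
  eff2 <- effective_params(base2, mod2, model_design(f3 = TRUE, f6 = TRUE),
                           "choice_rep_available", previous_action = 1,
                           valid_actions = c(1, 2, 4))
  expect_equal(eff2$mean_rates, c(0.5, 1.0, 0.5))
  # baseline condition returns base values unchanged
  eff3 <- effective_params(base2, mod2, model_design(f3 = TRUE, f6 = TRUE),
                           "choice_rep_absent", previous_action = 3,
                           valid_actions = c(1, 2, 4))
  expect_equal(eff3$mean_rates, base2$mean_rates[c(1, 2, 4)])
})

test_that("all-unit ratios are the identity and invalid sets are rejected", {
  base <- lba_params(c(1.2, 1.4, 1.6, 1.8), c(0.3, 0.4, 0.5, 0.6),
                     1.1, 0.25, 0.18)
  mods <- list(modulation_set(parameter = "mean_rate"),
               modulation_set(parameter = "threshold"),
               modulation_set(parameter = "non_decision"))
  design <- model_design(f2 = TRUE, f3 = TRUE, f4 = TRUE)
  cases <- list(
    list("choice_rep_available", 2, c(1, 2, 3)),
    list("choice_rep_absent", 4, c(1, 2, 3)),
    list("specified_rep", 3, 3),
    list("specified_nonrep", 3, 2))
  for (cs in cases) {
    eff <- effective_params(base, mods, design, cs[[1]], cs[[2]], cs[[3]])
    expect_equal(eff$mean_rates, base$mean_rates[cs[[3]]])
    expect_equal(eff$threshold, rep(base$threshold, length(cs[[3]])))
    expect_equal(eff$non_decision, rep(base$non_decision, length(cs[[3]])))
    # never returns parameters for non-presented actions
    expect_setequal(eff$actions, cs[[3]])
  }
  # condition / previous-action inconsistencies are rejected
  expect_error(effective_params(base, mods, design, "choice_rep_available",
                                4, c(1, 2, 3)), "must be")
  expect_error(effective_params(base, mods, design, "choice_rep_absent",
                                1, c(1, 2, 3)), "must not be")
  expect_error(effective_params(base, mods, design, "specified_rep",
                                1, 2), "must be")
})

test_that("designs and modulation sets round-trip through JSON", {
  d <- model_design(f2 = TRUE, f3 = TRUE, f6 = TRUE)
  expect_equal(format(design_from_json(design_to_json(d))), format(d))
  m <- modulation_set(0.7, 1.3, 1.15, scope = "all", parameter = "threshold")
  m2 <- design_from_json(design_to_json(m))
  expect_equal(m2$ratios, m$ratios)
  expect_equal(m2$scope, m$scope)
  tab <- design_table()
  expect_equal(nrow(tab), 46L)
  expect_equal(tab$n_params[1], 11L)
})
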
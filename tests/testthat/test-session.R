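test_that("default sessions carry the exact task composition", {
  s <- generate_session(seed = 1)
  expect_equal(nrow(s), 1008L)
  counts <- table(s$trial_type)
  expect_equal(unname(counts[c("choice", "specified", "null")]),
               c(504L, 252L, 252L), ignore_attr = TRUE)
  # repetition split exact within each action-trial type
  expect_equal(sum(s$condition == "choice_rep_available", na.rm = TRUE), 252L)
  expect_equal(sum(s$condition == "specified_rep", na.rm = TRUE), 126L)
  # onsets on the trial grid
  expect_equal(s$onset_s, (seq_len(1008) - 1) * 2.4)
  # determinism
  s2 <- generate_session(seed = 1)
  expect_identical(s, s2)
})

test_that("session invariants hold across many random seeds", {
  for (seed in 1:50) {
    s <- generate_session(seed = seed)
    expect_lte(max_run(s$trial_type), 4)
    act <- s[s$trial_type != "null", ]
    valid <- lapply(strsplit(act$valid_actions, ","), as.integer)
    prev_in <- mapply(function(p, v) p %in% v, act$previous_action, valid)
    expect_true(all(prev_in[act$condition == "choice_rep_available"]))
    expect_false(any(prev_in[act$condition == "choice_rep_absent"]))
    expect_true(all(act$cued_action[act$condition == "specified_rep"] ==
                      act$previous_action[act$condition == "specified_rep"]))
    snr <- act$condition == "specified_nonrep"
    expect_false(any(act$cued_action[snr] == act$previous_action[snr]))
    expect_equal(sum(act$first_action), 1L)
  }
})

test_that("infeasible specifications fail rather than loop forever", {
  # 8 choice trials, max run 1, nothing to interleave with
  spec <- session_spec(n_trials = 8,
                       proportions = c(choice = 1, specified = 0, null = 0),
                       max_run_same_type = 1)
  expect_error(generate_session(spec, seed = 1), "run-length")
  expect_error(session_spec(n_trials = 10,
                            proportions = c(choice = 0.51, specified = 0.25,
                                            null = 0.24)),
               "integer")
})

test_that("behaviour generation is deterministic and self-consistent", {
  b1 <- make_participant(seed = 61)
  b2 <- make_participant(seed = 61)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 1008L)
  act <- b1[b1$trial_type != "null", ]
  # realized conditions are consistent with the realized previous response
  valid <- lapply(strsplit(act$valid_actions, ","), as.integer)
  prev_in <- mapply(function(p, v) p %in% v, act$previous_action, valid)
  expect_true(all(prev_in == (act$condition %in%
                                c("choice_rep_available", "specified_rep"))))
  # responses always come from the valid set; RTs within the deadline
  resp <- !is.na(act$response)
  expect_true(all(mapply(function(r, v) r %in% v,
                         act$response[resp], valid[resp])))
  expect_true(all(act$rt_s[resp] > 0.2 & act$rt_s[resp] <= 2.4))
  # previous action chains through realized responses
  prev_chain <- act$previous_action[-1]
  expected_chain <- ifelse(is.na(act$response[-nrow(act)]),
                           act$previous_action[-nrow(act)],
                           act$response[-nrow(act)])
  expect_equal(prev_chain, expected_chain)
})

test_that("repetition behaviour tracks the generating modulation", {
  # beta = 1: repetition rate at the 33.33% chance level
  b <- make_participant(seed = 71, mods = NULL, design = design_null())
  cra <- b[!is.na(b$condition) & b$condition == "choice_rep_available" &
             !is.na(b$response) & !b$first_action, ]
  rep_rate <- mean(cra$response == cra$previous_action)
  n <- nrow(cra)
  expect_lt(abs(rep_rate - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / n))
  # beta = 0.6: repetition significantly below chance (binomial bound)
  b2 <- make_participant(seed = 72, mods = rate_mods(cra = 0.6))
  cra2 <- b2[!is.na(b2$condition) & b2$condition == "choice_rep_available" &
               !is.na(b2$response) & !b2$first_action, ]
  rep2 <- mean(cra2$response == cra2$previous_action)
  expect_lt(rep2, 1 / 3 - 3 * sqrt(1 / 3 * 2 / 3 / nrow(cra2)))
})

test_that("excessive omissions trigger the participant-exclusion warning", {
  slow <- lba_params(rep(0.4, 4), rep(0.15, 4), 2.2, 0.1, 0.3)
  sess <- generate_session(session_spec(n_trials = 120), seed = 3)
  expect_warning(
    tab <- generate_behavior(sess, slow, NULL, design_null(), seed = 4),
    "ceiling")
  expect_true(attr(tab, "high_omission"))
})
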
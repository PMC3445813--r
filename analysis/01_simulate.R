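#!/usr/bin/env Rscript

# Step 1 -- synthetic cohort.
#
# Generates a small cohort of synthetic participants performing the
# finger-tapping task (1008 trials each: 50% choice, 25% specified, 25% null,
# exact 50/50 repetition split, at most 4 consecutive same-type trials).
# Behaviour is simulated from the repetition-only rate-modulation LBA model:
# the previous action's accumulator accumulates at 0.7x its baseline rate in
# repetition-available choice trials, while specified trials run faster
# (ratios 1.3 repetition / 1.15 non-repetition), on top of participant-level
# rate and non-decision-time jitter.
#
# Writes results/cohort/participant_<p>.tsv and a manifest.

suppressPackageStartupMessages(library(lbadecide))

out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

seed <- 7
n_participants <- 4

group_base <- lba_params(mean_rates = rep(1.5, 4), rate_sds = rep(0.5, 4),
                         threshold = 1, start_range = 0.3, non_decision = 0.2)
mods <- modulation_set(choice_rep_available = 0.7, specified_rep = 1.3,
                       specified_nonrep = 1.15, parameter = "mean_rate")
design <- model_design(f3 = TRUE)   # design 4: rates vary, repetition-only

paths <- character(n_participants)
for (p in seq_len(n_participants)) {
  set.seed(seed * 1000 + p)
  base <- group_base
  base$mean_rates <- group_base$mean_rates * exp(rnorm(4, 0, 0.1))
  base$non_decision <- max(0.05, group_base$non_decision + rnorm(1, 0, 0.02))
  session <- generate_session(seed = seed * 1000 + p)
  trials <- generate_behavior(session, base, mods, design,
                              seed = seed * 1000 + 500 + p)
  cra <- subset(trials, condition == "choice_rep_available" &
                  !is.na(response) & !first_action)
  cat(sprintf(
    "participant %d: omission rate %.2f%%, repetition rate %.1f%% (chance 33.3%%)\n",
    p, 100 * attr(trials, "omission_rate"),
    100 * mean(cra$response == cra$previous_action)))
  paths[p] <- file.path(out_dir, sprintf("participant_%02d.tsv", p))
  write_trial_table(trials, paths[p])
}

write_manifest(file.path(out_dir, "manifest.json"),
               config = list(step = "simulate", seed = seed,
                             n_participants = n_participants,
                             design = format(design),
                             ratios = as.list(mods$ratios)),
               inputs = paths)
cat("wrote", n_participants, "trial tables under", out_dir, "\n")
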
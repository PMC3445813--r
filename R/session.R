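#' Session specification
#'
#' Describes the task design to generate: total trial count, the
#' choice/specified/null composition, the run-length constraint on trial
#' types, trial and cue durations, and the repetition split. Defaults match
#' the reference task: 1008 trials, 50% choice / 25% specified / 25% null,
#' at most 4 consecutive same-type trials, 2.4 s trials, 1 s cue, and an
#' exact 50/50 repetition split within the choice and specified trials.
#'
#' @param n_trials total trials.
#' @param proportions named numeric: `choice`, `specified`, `null`; must sum
#'   to 1 and yield integer counts.
#' @param max_run_same_type maximum run of consecutive same-type trials.
#' @param trial_duration,cue_duration seconds.
#' @param repetition_split proportion of repetition-available (choice) and
#'   repetition (specified) trials.
#' @return list of class `session_spec`.
#' @export
session_spec <- function(n_trials = 1008,
                         proportions = c(choice = 0.5, specified = 0.25,
                                         null = 0.25),
                         max_run_same_type = 4,
                         trial_duration = 2.4, cue_duration = 1,
                         repetition_split = 0.5) {
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  counts <- n_trials * proportions[c("choice", "specified", "null")]
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("n_trials x proportions must give integer counts")
  if (max_run_same_type < 1) stop("max_run_same_type must be >= 1")
  structure(list(n_trials = as.integer(n_trials),
                 counts = as.integer(round(counts)),
                 max_run_same_type = as.integer(max_run_same_type),
                 trial_duration = trial_duration,
                 cue_duration = cue_duration,
                 repetition_split = repetition_split),
            class = "session_spec")
}

# randomized type sequence with exact counts and no run longer than max_run;
# sequential sampling proportional to remaining counts, with restarts on
# dead ends
type_sequence <- function(counts, max_run, max_tries = 100) {
  types <- c("choice", "specified", "null")
  for (try in seq_len(max_tries)) {
    remaining <- counts
    seqv <- character(sum(counts))
    run_type <- ""
    run_len <- 0L
    ok <- TRUE
    for (i in seq_along(seqv)) {
      allowed <- remaining > 0L
      if (run_len >= max_run) allowed[types == run_type] <- FALSE
      if (!any(allowed)) { ok <- FALSE; break }
      idx <- which(allowed)
      pick <- if (length(idx) == 1L) idx
              else sample(idx, 1L, prob = remaining[idx])
      t <- types[pick]
      seqv[i] <- t
      remaining[pick] <- remaining[pick] - 1L
      if (t == run_type) run_len <- run_len + 1L
      else { run_type <- t; run_len <- 1L }
    }
    if (ok) return(seqv)
  }
  stop("could not build a type sequence satisfying the run-length ",
       "constraint after ", max_tries, " attempts")
}

#' Generate a task session
#'
#' Builds a randomized session: trial types with exact counts satisfying the
#' run-length constraint, repetition conditions assigned in an exact split
#' within the choice and within the specified trials, and a self-consistent
#' provisional action chain (previous action, valid-action sets, cues) built
#' with a uniform-random response placeholder for choice trials. The first
#' action trial receives a uniformly drawn pseudo-previous action and is
#' flagged (`first_action`); [generate_behavior()] later replaces the
#' placeholders with simulated responses and re-derives the valid sets from
#' the realized response chain.
#'
#' @param spec a [session_spec()].
#' @param seed optional integer seed.
#' @return data.frame of class `lba_session`: `trial_index`, `onset_s`,
#'   `trial_type`, `condition`, `valid_actions` (comma-separated ids),
#'   `cued_action`, `previous_action`, `planned_response`, `first_action`.
#' @export
generate_session <- function(spec = session_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  types <- type_sequence(spec$counts, spec$max_run_same_type)
  n <- length(types)
  n_rep <- function(m) {
    k <- round(m * spec$repetition_split)
    sample(c(rep(TRUE, k), rep(FALSE, m - k)))
  }
  cond <- rep(NA_character_, n)
  cond[types == "choice"] <- ifelse(n_rep(sum(types == "choice")),
                                    "choice_rep_available", "choice_rep_absent")
  cond[types == "specified"] <- ifelse(n_rep(sum(types == "specified")),
                                       "specified_rep", "specified_nonrep")
  valid <- rep(NA_character_, n)
  cued <- rep(NA_integer_, n)
  prev_col <- rep(NA_integer_, n)
  planned <- rep(NA_integer_, n)
  first <- rep(FALSE, n)
  prev <- sample.int(4L, 1L)  # pseudo-previous action for the first trial
  seen_action <- FALSE
  for (i in seq_len(n)) {
    if (types[i] == "null") next
    if (!seen_action) { first[i] <- TRUE; seen_action <- TRUE }
    prev_col[i] <- prev
    nonprev <- EXCL_LOOKUP[prev, ]
    if (cond[i] == "choice_rep_available") {
      v <- sort(c(prev, sample(nonprev, 2L)))
      planned[i] <- sample(v, 1L)
    } else if (cond[i] == "choice_rep_absent") {
      v <- nonprev
      planned[i] <- sample(v, 1L)
    } else if (cond[i] == "specified_rep") {
      v <- prev
      cued[i] <- prev
      planned[i] <- prev
    } else {
      v <- sample(nonprev, 1L)
      cued[i] <- v
      planned[i] <- v
    }
    valid[i] <- paste(v, collapse = ",")
    prev <- planned[i]
  }
  structure(data.frame(
    trial_index = seq_len(n),
    onset_s = (seq_len(n) - 1) * spec$trial_duration,
    trial_type = types,
    condition = cond,
    valid_actions = valid,
    cued_action = cued,
    previous_action = prev_col,
    planned_response = planned,
    first_action = first,
    stringsAsFactors = FALSE),
    class = c("lba_session", "data.frame"), spec = spec, seed = seed)
}

#' Simulate behaviour over a session
#'
#' Walks the session in order, maintaining the actual previous response
#' (chosen or cued). Each action trial's valid-action set is rebuilt from the
#' realized previous response according to the trial's repetition condition
#' (a chosen action changes subsequent repetition relations), the trial's
#' effective accumulator parameters are formed under the design and
#' modulations, and the race is simulated. Omitted trials leave the previous
#' response unchanged.
#'
#' @param session output of [generate_session()].
#' @param base an [lba_params()] set.
#' @param mods modulation set(s) (see [modulation_set()]), or `NULL`.
#' @param design a [model_design()].
#' @param seed integer seed.
#' @param deadline response deadline (s); defaults to the session's trial
#'   duration.
#' @param omission_ceiling warn (and flag the result) when the omission rate
#'   among action trials exceeds this proportion.
#' @return trial-table data.frame (columns `trial_index`, `onset_s`,
#'   `trial_type`, `condition`, `valid_actions`, `previous_action`,
#'   `response`, `rt_s`, `first_action`), with attributes `seed` and
#'   `omission_rate`.
#' @export
generate_behavior <- function(session, base, mods, design, seed = 1,
                              deadline = NULL, omission_ceiling = 0.35) {
  spec <- attr(session, "spec")
  if (is.null(deadline))
    deadline <- if (!is.null(spec)) spec$trial_duration else 2.4
  set.seed(seed)
  n <- nrow(session)
  valid <- rep(NA_character_, n)
  prev_col <- rep(NA_integer_, n)
  response <- rep(NA_integer_, n)
  rt <- rep(NA_real_, n)
  prev <- sample.int(4L, 1L)
  for (i in seq_len(n)) {
    if (session$trial_type[i] == "null") next
    cn <- session$condition[i]
    prev_col[i] <- prev
    nonprev <- EXCL_LOOKUP[prev, ]
    v <- switch(cn,
      choice_rep_available = sort(c(prev, sample(nonprev, 2L))),
      choice_rep_absent = nonprev,
      specified_rep = prev,
      specified_nonrep = sample(nonprev, 1L))
    valid[i] <- paste(v, collapse = ",")
    eff <- effective_params(base, mods, design, cn, prev, v)
    out <- simulate_trial(eff, deadline)
    response[i] <- out$selected_action
    rt[i] <- out$rt
    if (!is.na(out$selected_action)) prev <- out$selected_action
  }
  tab <- data.frame(
    trial_index = session$trial_index,
    onset_s = session$onset_s,
    trial_type = session$trial_type,
    condition = session$condition,
    valid_actions = valid,
    previous_action = prev_col,
    response = response,
    rt_s = rt,
    first_action = session$first_action,
    stringsAsFactors = FALSE)
  is_action <- tab$trial_type != "null"
  om <- mean(is.na(tab$response[is_action]))
  if (om > omission_ceiling)
    warning(sprintf("omission rate %.1f%% exceeds the %.0f%% ceiling",
                    100 * om, 100 * omission_ceiling))
  attr(tab, "seed") <- seed
  attr(tab, "omission_rate") <- om
  attr(tab, "high_omission") <- om > omission_ceiling
  tab
}
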
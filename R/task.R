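#' EEfRT task constants
#'
#' Fixed features of the Effort Expenditure for Rewards Task: the easy option
#' pays $1.00 for 30 presses (effort cost 0.3), the hard option pays a
#' variable $1.24-$4.30 for 100 presses (effort cost 1.0), and every trial
#' carries one of three win-probability levels (12/50/88%). Nominal trial
#' durations and the session time budget are carried as metadata only; timing
#' is never simulated.
#'
#' @return A named list of task constants.
#' @export
eefrt_task <- function() {
  list(
    easy_magnitude = 1.00,
    hard_magnitude_range = c(1.24, 4.30),
    easy_effort = 0.3,
    hard_effort = 1.0,
    prob_levels = c(0.12, 0.50, 0.88),
    analysis_trials = 50L,
    # metadata, not simulated
    easy_trial_seconds = 15, hard_trial_seconds = 30, budget_minutes = 20
  )
}

#' Generate a random EEfRT trial sequence
#'
#' Each trial draws its probability level uniformly from the three task levels
#' and its hard-option magnitude uniformly from $1.24-$4.30, rounded to cents.
#'
#' @param n_trials Number of trials (>= 0).
#' @param rng_seed Integer seed; the sequence is deterministic given the seed.
#' @return A data frame with columns `trial_index`, `prob_level`,
#'   `easy_magnitude`, `hard_magnitude`, `easy_effort`, `hard_effort`.
#' @export
generate_trial_sequence <- function(n_trials, rng_seed = NULL) {
  if (length(n_trials) != 1 || is.na(n_trials) || n_trials < 0) {
    stop("n_trials must be a single non-negative count")
  }
  n_trials <- as.integer(n_trials)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  tk <- eefrt_task()
  data.frame(
    trial_index = seq_len(n_trials),
    prob_level = if (n_trials) sample(tk$prob_levels, n_trials, replace = TRUE) else numeric(0),
    easy_magnitude = rep(tk$easy_magnitude, n_trials),
    hard_magnitude = round(runif(n_trials, tk$hard_magnitude_range[1],
                                 tk$hard_magnitude_range[2]), 2),
    easy_effort = rep(tk$easy_effort, n_trials),
    hard_effort = rep(tk$hard_effort, n_trials)
  )
}

session_columns <- function() {
  c("subject_id", "cohort", "trial_index", "prob_level", "easy_magnitude",
    "hard_magnitude", "choice", "random_assigned", "completed", "rewarded",
    "payoff")
}

#' Validate a session table
#'
#' A session table holds one row per trial with the schema documented in
#' [read_session_table()]. Checks column presence, domain constraints
#' (probability levels, magnitude range), logical invariants (rewarded implies
#' completed; payoff positive iff rewarded and equal to the chosen magnitude),
#' and per-subject trial-index contiguity. Violations are reported with row
#' numbers.
#'
#' @param sessions A session table (data frame).
#' @return The table, invisibly, if valid; otherwise an error naming rows.
#' @export
validate_sessions <- function(sessions) {
  missing <- setdiff(session_columns(), names(sessions))
  if (length(missing)) {
    stop("session table missing columns: ", paste(missing, collapse = ", "))
  }
  tk <- eefrt_task()
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      stop(sprintf("invalid session rows (%s): %s", what,
                   paste(head(rows, 10), collapse = ", ")))
    }
  }
  bad(!sessions$prob_level %in% tk$prob_levels, "prob_level not in 12/50/88%")
  bad(sessions$easy_magnitude != tk$easy_magnitude, "easy_magnitude != 1.00")
  bad(sessions$hard_magnitude < tk$hard_magnitude_range[1] - 1e-9 |
        sessions$hard_magnitude > tk$hard_magnitude_range[2] + 1e-9,
      "hard_magnitude outside $1.24-$4.30")
  bad(!sessions$choice %in% c("easy", "hard"), "choice not easy/hard")
  bad(!sessions$random_assigned %in% c(0, 1), "random_assigned not 0/1")
  bad(!sessions$completed %in% c(0, 1), "completed not 0/1")
  bad(!sessions$rewarded %in% c(0, 1), "rewarded not 0/1")
  bad(sessions$rewarded == 1 & sessions$completed == 0,
      "rewarded without completed")
  mag <- ifelse(sessions$choice == "hard", sessions$hard_magnitude,
                sessions$easy_magnitude)
  bad(sessions$rewarded == 1 & abs(sessions$payoff - mag) > 1e-9,
      "payoff != chosen magnitude when rewarded")
  bad(sessions$rewarded == 0 & sessions$payoff != 0,
      "nonzero payoff without reward")
  for (id in unique(sessions$subject_id)) {
    idx <- sessions$trial_index[sessions$subject_id == id]
    if (!identical(as.integer(idx), seq_along(idx))) {
      stop("subject ", id, ": trial indices not contiguous from 1")
    }
  }
  invisible(sessions)
}

#' Truncate and exclude sessions for analysis
#'
#' Keeps the first `max_trials` trials of each subject. Subjects with fewer
#' than `max_trials` trials are excluded (`too_few_trials`), as are subjects
#' whose freely made (non-forced) choices are all the same option
#' (`single_option`), mirroring the exclusion rules applied to the task data.
#' The operation is idempotent.
#'
#' @param sessions A validated session table.
#' @param max_trials Number of analysis trials per subject (default 50).
#' @return A list with `kept` (truncated session table) and `excluded`
#'   (data frame `subject_id`, `reason`).
#' @export
filter_sessions <- function(sessions, max_trials = 50L) {
  validate_sessions(sessions)
  kept <- list()
  excl <- list()
  for (id in unique(sessions$subject_id)) {
    s <- sessions[sessions$subject_id == id, , drop = FALSE]
    if (nrow(s) < max_trials) {
      excl[[id]] <- data.frame(subject_id = id, reason = "too_few_trials")
      next
    }
    s <- s[seq_len(max_trials), , drop = FALSE]
    free <- s$choice[s$random_assigned == 0]
    if (length(unique(free)) < 2) {
      excl[[id]] <- data.frame(subject_id = id, reason = "single_option")
      next
    }
    kept[[id]] <- s
  }
  list(
    kept = if (length(kept)) do.call(rbind, c(kept, make.row.names = FALSE))
           else sessions[0, , drop = FALSE],
    excluded = if (length(excl)) do.call(rbind, c(excl, make.row.names = FALSE))
               else data.frame(subject_id = character(0), reason = character(0))
  )
}

#' Read / write session tables
#'
#' Session CSV schema, one row per trial: `subject_id`, `cohort`,
#' `trial_index`, `prob_level`, `easy_magnitude`, `hard_magnitude`,
#' `choice` (easy|hard), `random_assigned` (0|1), `completed` (0|1),
#' `rewarded` (0|1), `payoff` (dollars). UTF-8 with a header row. Reading
#' validates every row; writing then reading is the identity.
#'
#' @param path CSV file path.
#' @return `read_session_table()` returns a validated session table.
#' @export
read_session_table <- function(path) {
  sessions <- read.csv(path, stringsAsFactors = FALSE)
  validate_sessions(sessions)
  sessions
}

#' @rdname read_session_table
#' @param sessions A validated session table to write.
#' @export
write_session_table <- function(sessions, path) {
  validate_sessions(sessions)
  write.csv(sessions[, session_columns()], path, row.names = FALSE)
  invisible(path)
}
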
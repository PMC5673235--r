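#' Construct the two-stage Markov decision task
#'
#' Builds the task specification: four first-stage states (two passive, `P1`
#' and `P2`, and two active, `A1` and `A2`, each with left/right actions), two
#' shared second-stage passive states (`S1`, `S2`), and terminal reward /
#' no-reward states. Transition probabilities are symmetric within a block:
#' the two second-stage reward probabilities are complements, the two passive
#' first-stage rows are complements, and the action-to-successor mapping is
#' inverted across the two active states. Blocks after the first are defined
#' by reversals of the transition probabilities at the first or the second
#' stage.
#'
#' @param p_first probability that passive state `P1` transitions to `S1`
#'   (the `P2` row is its complement).
#' @param p_action probability that the favoured action in `A1` leads to `S1`;
#'   the mapping is inverted in `A2`.
#' @param p_reward probability of reward in `S1` (complement in `S2`).
#' @param block_lengths trial counts per block; the default session is one
#'   block of 80 trials followed by two blocks of 60.
#' @param first_reversal_stage counterbalancing flag: stage ("first" or
#'   "second") at which the first within-session reversal occurs; the second
#'   reversal occurs at the other stage.
#' @param action_mapping counterbalancing flag for the hand assignment of the
#'   initially favoured action in `A1` ("standard" = left, "flipped" = right).
#' @param n_runs number of scanning runs of equal length.
#' @param timing list of timing constants, see [default_timing()].
#' @param reward_magnitude monetary value of one reward event (display
#'   metadata; rewards are coded r = 1 internally).
#' @return an object of class `acq_task`.
#' @export
build_task <- function(p_first = 0.7, p_action = 0.7, p_reward = 0.7,
                       block_lengths = c(80L, 60L, 60L),
                       first_reversal_stage = c("second", "first"),
                       action_mapping = c("standard", "flipped"),
                       n_runs = 4L, timing = default_timing(),
                       reward_magnitude = 0.10) {
  first_reversal_stage <- match.arg(first_reversal_stage)
  action_mapping <- match.arg(action_mapping)
  for (p in c(p_first, p_action, p_reward)) {
    if (!is.finite(p) || p < 0 || p > 1)
      stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  block_lengths <- as.integer(block_lengths)
  if (any(block_lengths <= 0)) stop("block lengths must be positive")
  n_trials <- sum(block_lengths)
  if (n_trials %% 4L != 0L)
    stop("session length must be divisible by 4 (randomized quartets)")
  if (n_trials %% n_runs != 0L)
    stop("session length must be divisible by the number of runs")

  base <- list(
    P = matrix(c(p_first, 1 - p_first, 1 - p_first, p_first),
               nrow = 2, byrow = TRUE,
               dimnames = list(c("P1", "P2"), c("S1", "S2"))),
    A = local({
      a <- array(NA_real_, dim = c(2, 2, 2),
                 dimnames = list(c("A1", "A2"), c("L", "R"), c("S1", "S2")))
      pl <- if (action_mapping == "standard") p_action else 1 - p_action
      a["A1", "L", ] <- c(pl, 1 - pl)
      a["A1", "R", ] <- c(1 - pl, pl)
      # mapping between actions and probabilities inverted across states
      a["A2", "L", ] <- c(1 - pl, pl)
      a["A2", "R", ] <- c(pl, 1 - pl)
      a
    }),
    R = stats::setNames(c(p_reward, 1 - p_reward), c("S1", "S2")),
    reversal_stage = "none")

  rev_stages <- if (first_reversal_stage == "second")
    c("second", "first") else c("first", "second")
  blocks <- vector("list", length(block_lengths))
  blocks[[1]] <- base
  if (length(blocks) > 1) {
    for (b in 2:length(blocks)) {
      stage <- rev_stages[((b - 2) %% 2) + 1]
      blocks[[b]] <- reverse_block(blocks[[b - 1]], stage)
    }
  }

  task <- list(
    passive_first_states = c("P1", "P2"),
    active_first_states = c("A1", "A2"),
    second_states = c("S1", "S2"),
    terminal_states = c("reward", "no_reward"),
    actions = c("L", "R"),
    probabilities = c(p_first = p_first, p_action = p_action,
                      p_reward = p_reward),
    block_lengths = block_lengths,
    n_trials = n_trials,
    n_runs = as.integer(n_runs),
    run_length = n_trials %/% as.integer(n_runs),
    counterbalance = c(first_reversal_stage = first_reversal_stage,
                       action_mapping = action_mapping),
    blocks = blocks,
    timing = timing,
    reward_magnitude = reward_magnitude)
  class(task) <- "acq_task"
  validate_task(task)
  task
}

#' Build a task from a YAML or JSON configuration file
#'
#' Accepts a file with any of the keys `probabilities` (sub-keys `p_first`,
#' `p_action`, `p_reward`), `block_lengths`, `counterbalance` (sub-keys
#' `first_reversal_stage`, `action_mapping`), `n_runs`, `timing` and
#' `reward_magnitude`; omitted keys fall back to the [build_task()] defaults.
#' Complement probabilities are always derived, never configured.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `acq_task`.
#' @export
task_from_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the jsonlite package is required to read JSON configs")
    jsonlite::fromJSON(path)
  }
  args <- list()
  for (p in c("p_first", "p_action", "p_reward"))
    if (!is.null(cfg$probabilities[[p]])) args[[p]] <- cfg$probabilities[[p]]
  if (!is.null(cfg$block_lengths)) args$block_lengths <- cfg$block_lengths
  for (p in c("first_reversal_stage", "action_mapping"))
    if (!is.null(cfg$counterbalance[[p]]))
      args[[p]] <- cfg$counterbalance[[p]]
  if (!is.null(cfg$n_runs)) args$n_runs <- cfg$n_runs
  if (!is.null(cfg$reward_magnitude))
    args$reward_magnitude <- cfg$reward_magnitude
  if (!is.null(cfg$timing))
    args$timing <- utils::modifyList(default_timing(), cfg$timing)
  do.call(build_task, args)
}

#' Default trial timing constants (seconds)
#'
#' Pre-trial cue 1 s, stimuli 1.5 s, interstimulus intervals 3.5 s, response
#' window 1.5 s, intertrial intervals drawn from a discrete uniform grid of
#' 51 values spanning 4 to 8 s in 80-ms steps. The outcome stimulus duration
#' defaults to 1.5 s to match the other stimuli.
#' @return named list of timing constants.
#' @export
default_timing <- function() {
  list(pretrial_cue_s = 1.0, stimulus_s = 1.5, isi_s = 3.5,
       response_window_s = 1.5, iti_range_s = c(4, 8),
       iti_increment_s = 0.08, outcome_s = 1.5)
}

#' @keywords internal
iti_grid <- function(timing) {
  seq(timing$iti_range_s[1], timing$iti_range_s[2],
      by = timing$iti_increment_s)
}

#' Apply a reversal to a block's transition tables
#'
#' A "first"-stage reversal swaps the two passive first-stage rows and inverts
#' the action-to-successor mapping within each active state; a "second"-stage
#' reversal swaps the two second-stage reward rows. Complements are preserved,
#' so all symmetry invariants continue to hold.
#' @param block a block table list (`P`, `A`, `R`).
#' @param stage "first" or "second".
#' @return a new block list with `reversal_stage` set.
#' @export
reverse_block <- function(block, stage = c("first", "second")) {
  stage <- match.arg(stage)
  out <- block
  if (stage == "first") {
    out$P <- block$P[c(2, 1), , drop = FALSE]
    rownames(out$P) <- rownames(block$P)
    out$A <- block$A
    out$A[, "L", ] <- block$A[, "R", ]
    out$A[, "R", ] <- block$A[, "L", ]
  } else {
    out$R <- stats::setNames(block$R[c(2, 1)], names(block$R))
  }
  out$reversal_stage <- stage
  out
}

#' @keywords internal
validate_task <- function(task) {
  for (b in task$blocks) {
    stopifnot(abs(rowSums(b$P) - 1) < 1e-12)
    for (s in 1:2) for (a in 1:2)
      stopifnot(abs(sum(b$A[s, a, ]) - 1) < 1e-12)
    # symmetry invariants
    stopifnot(abs(b$R[["S1"]] - (1 - b$R[["S2"]])) < 1e-12)
    stopifnot(abs(b$P["P1", "S1"] - (1 - b$P["P2", "S1"])) < 1e-12)
    stopifnot(all(abs(b$A["A1", , "S1"] - (1 - b$A["A2", , "S1"])) < 1e-12))
  }
  invisible(task)
}

#' Block index for a trial
#' @keywords internal
block_of_trial <- function(task, trial_index) {
  findInterval(trial_index, cumsum(task$block_lengths) + 1L) + 1L
}

#' Objectively better action in an active state
#'
#' Marginalizes reward probability over the two-step transition tables of a
#' block: P(reward | s, a) = sum over second-stage states of
#' P(s' | s, a) P(reward | s'). Returns the action with the greater
#' probability of eventually being rewarded, or `NA` on an exact tie (ties are
#' excluded from accuracy scoring).
#'
#' @param task an `acq_task`.
#' @param block block index.
#' @param active_state "A1" or "A2".
#' @return "L", "R" or `NA_character_`.
#' @export
better_action <- function(task, block, active_state) {
  stopifnot(active_state %in% task$active_first_states)
  b <- task$blocks[[block]]
  ev <- vapply(c("L", "R"), function(a)
    sum(b$A[active_state, a, ] * b$R), numeric(1))
  if (abs(ev[["L"]] - ev[["R"]]) < 1e-12) return(NA_character_)
  if (ev[["L"]] > ev[["R"]]) "L" else "R"
}

#' Sample a trial schedule (stimuli and timing only)
#'
#' Generates the trial-by-trial schedule for a session: trials are ordered in
#' randomized quartets each containing all four initial states exactly once,
#' intertrial intervals are drawn without replacement within a run from the
#' discrete 80-ms grid, and event onsets are laid out run-relative from the
#' timing constants. Choices, outcomes and errors are left unfilled. The
#' schedule is deterministic given the seed.
#'
#' @param task an `acq_task`.
#' @param seed optional integer seed.
#' @return a data.frame of class `acq_session` with one row per trial.
#' @export
sample_schedule <- function(task, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- task$n_trials
  states <- c("P1", "P2", "A1", "A2")
  first_state <- as.vector(vapply(seq_len(n %/% 4L),
                                  function(i) sample(states), character(4)))
  trial_type <- ifelse(first_state %in% task$active_first_states,
                       "active", "passive")
  run_index <- rep(seq_len(task$n_runs), each = task$run_length)
  block_index <- block_of_trial(task, seq_len(n))

  grid <- iti_grid(task$timing)
  iti_s <- numeric(n)
  for (r in seq_len(task$n_runs)) {
    idx <- which(run_index == r)
    iti_s[idx] <- if (length(idx) <= length(grid))
      sample(grid, length(idx)) else sample(grid, length(idx), replace = TRUE)
  }
  iti_s <- round(iti_s, 3)

  tm <- task$timing
  onset_iti <- onset_cue <- onset_first <- onset_second <-
    onset_outcome <- numeric(n)
  t0 <- 0
  for (i in seq_len(n)) {
    if (i > 1 && run_index[i] != run_index[i - 1]) t0 <- 0
    onset_iti[i] <- t0
    onset_cue[i] <- t0 + iti_s[i]
    onset_first[i] <- onset_cue[i] + tm$pretrial_cue_s
    onset_second[i] <- onset_first[i] + tm$stimulus_s + tm$isi_s
    onset_outcome[i] <- onset_second[i] + tm$stimulus_s + tm$isi_s
    t0 <- onset_outcome[i] + tm$outcome_s
  }

  session <- data.frame(
    trial_index = seq_len(n), run_index = run_index,
    block_index = block_index, trial_type = trial_type,
    first_state = first_state, action = NA_character_,
    second_state = NA_character_, reward = NA_integer_,
    error_flag = "none", rt_ms = NA_real_, iti_s = iti_s,
    onset_iti = round(onset_iti, 3), onset_cue = round(onset_cue, 3),
    onset_first = round(onset_first, 3),
    onset_second = round(onset_second, 3),
    onset_outcome = round(onset_outcome, 3),
    stringsAsFactors = FALSE)
  class(session) <- c("acq_session", "data.frame")
  session
}

#' Play out a single trial against the task
#'
#' Samples the second-stage state and the outcome from the block's transition
#' rows, using the current R random-number stream. Supplying an action on a
#' passive trial marks the trial `inappropriate`; omitting the action on an
#' active trial marks it `missed`; either error aborts the trial with no
#' outcome shown.
#'
#' @param task an `acq_task`.
#' @param trial a single-row slice of an `acq_session`.
#' @param action "L", "R" or `NULL`.
#' @return the completed trial row.
#' @export
run_trial <- function(task, trial, action = NULL) {
  stopifnot(nrow(trial) == 1)
  b <- task$blocks[[trial$block_index]]
  active <- trial$trial_type == "active"
  if (!active && !is.null(action)) {
    trial$error_flag <- "inappropriate"
    return(trial)
  }
  if (active && is.null(action)) {
    trial$error_flag <- "missed"
    return(trial)
  }
  p_s1 <- if (active) b$A[trial$first_state, action, "S1"]
          else b$P[trial$first_state, "S1"]
  s1 <- if (stats::runif(1) < p_s1) "S1" else "S2"
  r <- as.integer(stats::runif(1) < b$R[[s1]])
  trial$action <- if (active) action else NA_character_
  trial$second_state <- s1
  trial$reward <- r
  trial$error_flag <- "none"
  trial
}

#' Write a session table to TSV
#'
#' One row per trial, columns exactly the trial-record fields; missing values
#' are written as empty strings.
#' @param session an `acq_session` data.frame.
#' @param path output file path.
#' @export
write_session <- function(session, path) {
  utils::write.table(session, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a session table from TSV
#' @param path file written by [write_session()].
#' @return an `acq_session` data.frame.
#' @export
read_session <- function(path) {
  session <- utils::read.delim(path, sep = "\t", na.strings = "",
                               stringsAsFactors = FALSE)
  for (col in c("trial_index", "run_index", "block_index", "reward"))
    session[[col]] <- as.integer(session[[col]])
  for (col in c("rt_ms", "iti_s", "onset_iti", "onset_cue", "onset_first",
                "onset_second", "onset_outcome"))
    session[[col]] <- as.numeric(session[[col]])
  for (col in c("trial_type", "first_state", "action", "second_state",
                "error_flag"))
    session[[col]] <- as.character(session[[col]])
  session$error_flag[is.na(session$error_flag)] <- "none"
  class(session) <- c("acq_session", "data.frame")
  session
}

#' @export
print.acq_task <- function(x, ...) {
  cat("Two-stage Markov decision task\n")
  cat(sprintf("  trials: %d in blocks (%s), %d runs of %d\n", x$n_trials,
              paste(x$block_lengths, collapse = ", "), x$n_runs,
              x$run_length))
  cat(sprintf("  probabilities: first %.2f, action %.2f, reward %.2f\n",
              x$probabilities["p_first"], x$probabilities["p_action"],
              x$probabilities["p_reward"]))
  cat(sprintf("  counterbalance: first reversal at %s stage, %s mapping\n",
              x$counterbalance["first_reversal_stage"],
              x$counterbalance["action_mapping"]))
  invisible(x)
}

# ---- internal encoding shared with the C++ core ----

#' @keywords internal
encode_session <- function(session) {
  first_lv <- c("P1", "P2", "A1", "A2")
  list(
    trial_type = as.integer(session$trial_type == "active"),
    first = match(session$first_state, first_lv) - 1L,
    action = ifelse(is.na(session$action), -1L,
                    match(session$action, c("L", "R")) - 1L),
    second = ifelse(is.na(session$second_state), -1L,
                    match(session$second_state, c("S1", "S2")) - 1L),
    reward = ifelse(is.na(session$reward), -1L,
                    as.integer(session$reward)),
    error = as.integer(session$error_flag != "none"))
}

#' @keywords internal
session_prob_rows <- function(task, session) {
  n <- nrow(session)
  p_s1_a <- p_s1_b <- p_rw_s1 <- p_rw_s2 <- numeric(n)
  for (i in seq_len(n)) {
    b <- task$blocks[[session$block_index[i]]]
    if (session$trial_type[i] == "active") {
      p_s1_a[i] <- b$A[session$first_state[i], "L", "S1"]
      p_s1_b[i] <- b$A[session$first_state[i], "R", "S1"]
    } else {
      p_s1_a[i] <- b$P[session$first_state[i], "S1"]
      p_s1_b[i] <- NA_real_
    }
    p_rw_s1[i] <- b$R[["S1"]]
    p_rw_s2[i] <- b$R[["S2"]]
  }
  list(p_s1_a = p_s1_a, p_s1_b = p_s1_b,
       p_rw_s1 = p_rw_s1, p_rw_s2 = p_rw_s2)
}
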
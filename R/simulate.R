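#' Simulate an agent playing the task (closed loop)
#'
#' Samples a schedule, then plays it out in closed loop: the model's softmax
#' policy samples each choice, the task's block-wise transition rows sample
#' second-stage states and outcomes, and the agent's latent variables update
#' online. Optionally injects missed responses at a per-trial rate. Reaction
#' times are plumbing only: drawn from a lognormal and, when
#' `rt_coupling_ms > 0`, sped up linearly in the normalized absolute net
#' action-weight difference (easier choices are faster). Deterministic given
#' the seed.
#'
#' @param model an `acq_model` or name.
#' @param params named parameter vector.
#' @param task an `acq_task`.
#' @param seed optional integer seed.
#' @param miss_rate probability that an active trial is missed (default 0).
#' @param schedule optional pre-sampled schedule (an `acq_session`).
#' @param rt_median_ms,rt_sdlog,rt_coupling_ms reaction-time generator
#'   settings.
#' @return list of class `acq_sim`: `session` (completed `acq_session`) and
#'   `forward` (the generating pass, an `acq_forward`).
#' @export
simulate_agent <- function(model, params, task, seed = NULL, miss_rate = 0,
                           schedule = NULL, rt_median_ms = 820,
                           rt_sdlog = 0.15, rt_coupling_ms = 100) {
  spec <- if (is.character(model)) model_spec(model) else model
  par <- canonical_params(spec, params)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- sample_schedule(task)
  session <- schedule
  n <- nrow(session)

  error <- rep(0L, n)
  if (miss_rate > 0) {
    is_active <- session$trial_type == "active"
    error[is_active & stats::runif(n) < miss_rate] <- 1L
  }

  enc <- encode_session(session)
  enc$error <- pmax(enc$error, error)
  pr <- session_prob_rows(task, session)
  res <- .core_pass(enc$trial_type, enc$first, enc$action, enc$second,
                    enc$reward, enc$error, pr$p_s1_a, pr$p_s1_b,
                    pr$p_rw_s1, pr$p_rw_s2,
                    as.list(par), core_flags(spec), 1L)

  session <- fill_session(session, res, enc$error)
  session <- draw_rts(session, res$trace, rt_median_ms, rt_sdlog,
                      rt_coupling_ms)
  fp <- list(model = spec$name, params = par, loglik = res$loglik,
             ll = res$ll, n_choices = res$n_choices,
             trace = as_trace_df(res$trace, session), session = session)
  class(fp) <- "acq_forward"
  out <- list(session = session, forward = fp)
  class(out) <- "acq_sim"
  out
}

#' Simulate an agent yoked to an observed session
#'
#' Replays the observed stimulus schedule and reward contingencies: passive
#' trials are reproduced verbatim, error trials stay errors, and on valid
#' active trials only the choice is re-sampled from the model, with the
#' second-stage state and outcome then drawn from the task's true transition
#' rows for the chosen action. Trial count and timing are preserved.
#'
#' @param model an `acq_model` or name.
#' @param params named parameter vector.
#' @param observed_session the source `acq_session`.
#' @param task the `acq_task` providing the contingencies.
#' @param seed optional integer seed.
#' @return list of class `acq_sim` (see [simulate_agent()]).
#' @export
simulate_yoked <- function(model, params, observed_session, task,
                           seed = NULL) {
  spec <- if (is.character(model)) model_spec(model) else model
  par <- canonical_params(spec, params)
  if (!is.null(seed)) set.seed(seed)
  session <- observed_session
  enc <- encode_session(session)
  pr <- session_prob_rows(task, session)
  res <- .core_pass(enc$trial_type, enc$first, enc$action, enc$second,
                    enc$reward, enc$error, pr$p_s1_a, pr$p_s1_b,
                    pr$p_rw_s1, pr$p_rw_s2,
                    as.list(par), core_flags(spec), 2L)
  session <- fill_session(session, res, enc$error)
  # passive and error rows keep the source records (including RTs)
  redo <- session$trial_type == "active" & session$error_flag == "none"
  session$rt_ms[redo] <- NA_real_
  session <- draw_rts(session, res$trace, 820, 0.15, 100, only = redo)
  fp <- list(model = spec$name, params = par, loglik = res$loglik,
             ll = res$ll, n_choices = res$n_choices,
             trace = as_trace_df(res$trace, session), session = session)
  class(fp) <- "acq_forward"
  out <- list(session = session, forward = fp)
  class(out) <- "acq_sim"
  out
}

#' @keywords internal
fill_session <- function(session, res, error) {
  n <- nrow(session)
  session$action <- ifelse(is.na(res$action), NA_character_,
                           c("L", "R")[res$action + 1L])
  session$second_state <- ifelse(is.na(res$second_state), NA_character_,
                                 c("S1", "S2")[res$second_state + 1L])
  session$reward <- ifelse(is.na(res$reward), NA_integer_,
                           as.integer(res$reward))
  flag <- session$error_flag
  flag[error == 1L & session$trial_type == "active" &
         flag == "none"] <- "missed"
  session$error_flag <- flag
  session
}

#' @keywords internal
as_trace_df <- function(trace, session) {
  trace <- as.data.frame(trace)
  trace$trial_index <- session$trial_index
  trace
}

#' @keywords internal
draw_rts <- function(session, trace, rt_median_ms, rt_sdlog, rt_coupling_ms,
                     only = NULL) {
  trace <- as.data.frame(trace)
  idx <- session$trial_type == "active" & session$error_flag == "none"
  if (!is.null(only)) idx <- idx & only
  if (!any(idx)) return(session)
  dw <- abs(trace$Wstar_R - trace$Wstar_L)[idx]
  dwn <- if (max(dw, na.rm = TRUE) > 0) dw / max(dw, na.rm = TRUE) else dw
  base <- stats::rlnorm(sum(idx), log(rt_median_ms), rt_sdlog)
  session$rt_ms[idx] <- round(pmax(base - rt_coupling_ms * dwn, 150))
  session
}

#' Specification for a simulated cohort
#'
#' Generative parameter distributions default to independent truncated
#' normals with the fitted Good-learner group means and standard deviations;
#' see [generative_param_priors()].
#'
#' @param n_subjects number of agents.
#' @param model generating model name (recycled per subject if length 1).
#' @param param_means,param_sds named vectors for the truncated-normal draws;
#'   parameters with `sd = 0` are held at their mean.
#' @param task an `acq_task`.
#' @param miss_rate per-trial miss probability (default 3%, the order of the
#'   handful of missed trials real subjects produce).
#' @param seed master seed, expanded reproducibly to per-subject seeds.
#' @return list of class `acq_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, model = "ACQ(lambda)",
                        param_means = NULL, param_sds = NULL,
                        task = build_task(), miss_rate = 0.03, seed = 1) {
  pri <- generative_param_priors("good")
  if (is.null(param_means)) param_means <- pri$mean
  if (is.null(param_sds)) param_sds <- pri$sd
  out <- list(n_subjects = n_subjects, model = model,
              param_means = param_means, param_sds = param_sds,
              task = task, miss_rate = miss_rate, seed = seed)
  class(out) <- "acq_cohort_spec"
  out
}

#' Default generative parameter distributions
#'
#' Group-level means and standard deviations of the fitted
#' actor/critic/Q-learner parameters used as the default generative
#' distributions for simulated cohorts (independent truncated normals;
#' correlation structure is not modeled).
#'
#' @param group "good" or "poor" learner group.
#' @return list with named vectors `mean` and `sd`.
#' @export
generative_param_priors <- function(group = c("good", "poor")) {
  group <- match.arg(group)
  if (group == "good") {
    list(mean = c(alpha = 0.588, lambda = 0.682, w_q = 0.661, tau = 0.404,
                  beta_0 = 0.093, lambda_beta = 0.621, beta_r = 0.230),
         sd = c(alpha = 0.237, lambda = 0.323, w_q = 0.315, tau = 0.262,
                beta_0 = 0.366, lambda_beta = 0.375, beta_r = 0.425))
  } else {
    list(mean = c(alpha = 0.551, lambda = 0.687, w_q = 0.626, tau = 1.390,
                  beta_0 = -0.088, lambda_beta = 0.751, beta_r = 0.128),
         sd = c(alpha = 0.308, lambda = 0.431, w_q = 0.418, tau = 1.512,
                beta_0 = 0.521, lambda_beta = 0.281, beta_r = 0.673))
  }
}

#' @keywords internal
rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

#' @keywords internal
draw_params <- function(means, sds) {
  lower <- c(alpha = 0, lambda = 0, w_q = 0, alpha_star = 0, w_star = 0,
             tau = 0.02, beta_r = -Inf, beta_0 = -Inf, lambda_beta = 0,
             p_a1 = 0)
  upper <- c(alpha = 1, lambda = 1, w_q = 1, alpha_star = 1, w_star = 1,
             tau = Inf, beta_r = Inf, beta_0 = Inf, lambda_beta = 1,
             p_a1 = 1)
  stats::setNames(vapply(names(means), function(nm)
    rtruncnorm1(means[[nm]], sds[[nm]], lower[[nm]], upper[[nm]]),
    numeric(1)), names(means))
}

#' Generate a simulated cohort with its ground-truth ledger
#'
#' Draws per-subject generating parameters from the cohort's truncated-normal
#' distributions, simulates each agent in closed loop, and returns the
#' sessions together with a ledger of generating models and parameters for
#' recovery scoring. Byte-reproducible given the master seed.
#'
#' @param spec an `acq_cohort_spec`.
#' @param dir optional directory: sessions are written as TSV and the ledger
#'   as `ledger.tsv`.
#' @return list of class `acq_cohort`: `sessions` (list of `acq_session`),
#'   `forwards` (generating passes), `ledger` (data.frame), `task`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "acq_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  if (n == 0)
    return(structure(list(sessions = list(), forwards = list(),
                          ledger = data.frame(), task = spec$task),
                     class = "acq_cohort"))
  seeds <- sample.int(2^31 - 1, n)
  models <- rep_len(spec$model, n)
  sessions <- vector("list", n)
  forwards <- vector("list", n)
  led <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    par <- draw_params(spec$param_means, spec$param_sds)
    sim <- simulate_agent(models[i], par, spec$task,
                          miss_rate = spec$miss_rate)
    sessions[[i]] <- sim$session
    forwards[[i]] <- sim$forward
    led[[i]] <- data.frame(subject = sprintf("sim%03d", i),
                           model = models[i], seed = seeds[i],
                           t(par), stringsAsFactors = FALSE)
  }
  ledger <- do.call(rbind, led)
  names(sessions) <- names(forwards) <- ledger$subject
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(sessions))
      write_session(sessions[[id]], file.path(dir, paste0(id, ".tsv")))
    utils::write.table(ledger, file.path(dir, "ledger.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out <- list(sessions = sessions, forwards = forwards, ledger = ledger,
              task = spec$task)
  class(out) <- "acq_cohort"
  out
}
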
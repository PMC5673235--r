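#' The factorial model registry
#'
#' Enumerates the full nested family: a null intercept model, the
#' learning-independent hysteresis model, and 21 learning models — the pure
#' Q-learner Q(0); actor/critic AC(0), AC(1), AC(lambda); critic/Q-learner
#' CQ(0), CQ(1), CQ(lambda); the actor/critic/Q-learner hybrids ACQ(0),
#' ACQ(1), ACQ(lambda); the model-based planner MB; and each model-free
#' variant paired with the planner (+MB). A lambda suffix of 0 or 1 fixes the
#' eligibility parameter; the "(lambda)" suffix frees it. The 22 comparison
#' alternatives are the 21 learning models plus hysteresis; the null model is
#' the baseline.
#'
#' @return a data.frame with one row per model: component flags, the
#'   eligibility and weighting modes, the free-parameter count `k`, and the
#'   model class.
#' @export
model_registry <- function() {
  mf <- expand.grid(base = c("Q(0)", "AC(0)", "AC(1)", "AC(lambda)",
                             "CQ(0)", "CQ(1)", "CQ(lambda)",
                             "ACQ(0)", "ACQ(1)", "ACQ(lambda)"),
                    stringsAsFactors = FALSE)$base
  nm <- c("NULL", "HYST", mf, "MB", paste0(mf, "+MB"))
  reg <- do.call(rbind, lapply(nm, function(x)
    as.data.frame(parse_model_name(x), stringsAsFactors = FALSE)))
  reg$k <- vapply(reg$name, function(x) length(free_param_names(x)),
                  integer(1))
  reg
}

#' @keywords internal
parse_model_name <- function(name) {
  name <- normalize_model_name(name)
  mb <- grepl("\\+MB$", name) || name == "MB"
  base <- sub("\\+MB$", "", name)
  out <- list(name = name, critic = FALSE, actor = FALSE, qlearn = FALSE,
              pure_q = FALSE, mb = mb, lambda_mode = "none",
              wq_mode = "one", class = "learning")
  if (base == "NULL") {
    out$class <- "null"
  } else if (base == "HYST") {
    out$class <- "hysteresis"
  } else if (base == "MB") {
    # planner only
  } else {
    fam <- sub("\\(.*$", "", base)
    suf <- sub("^.*\\(", "", sub("\\)$", "", base))
    out$lambda_mode <- switch(suf, "0" = "zero", "1" = "one",
                              "lambda" = "free",
                              stop("unknown eligibility suffix: ", suf))
    if (fam == "Q") {
      out$qlearn <- TRUE; out$pure_q <- TRUE
      if (out$lambda_mode != "zero")
        stop("only Q(0) is defined: one action per episode")
      out$lambda_mode <- "none"
    } else if (fam == "AC") {
      out$critic <- TRUE; out$actor <- TRUE; out$wq_mode <- "zero"
    } else if (fam == "CQ") {
      out$critic <- TRUE; out$qlearn <- TRUE; out$wq_mode <- "one"
    } else if (fam == "ACQ") {
      out$critic <- TRUE; out$actor <- TRUE; out$qlearn <- TRUE
      out$wq_mode <- "free"
    } else stop("unknown model family: ", fam)
  }
  out
}

#' @keywords internal
normalize_model_name <- function(name) {
  name <- gsub("λ", "lambda", name)
  name <- gsub("\\s+", "", name)
  toupper_base <- toupper(sub("\\(lambda\\)", "(lambda)", name))
  gsub("\\(LAMBDA\\)", "(lambda)", toupper_base)
}

#' Resolve a model name to its specification
#'
#' @param name a model name, e.g. `"ACQ(lambda)+MB"` (a Greek lambda is
#'   accepted).
#' @return a list of class `acq_model` with component flags, parameter modes,
#'   and the free-parameter names.
#' @export
model_spec <- function(name) {
  spec <- parse_model_name(name)
  spec$free <- free_param_names(spec$name)
  spec$k <- length(spec$free)
  class(spec) <- "acq_model"
  spec
}

#' @keywords internal
free_param_names <- function(name) {
  s <- parse_model_name(name)
  if (s$class == "null") return("p_a1")
  free <- c("tau", "beta_r", "beta_0", "lambda_beta")
  if (s$critic || s$qlearn) free <- c("alpha", free)
  if (s$lambda_mode == "free") free <- append(free, "lambda", after = 1)
  if (s$wq_mode == "free" && (s$critic && s$qlearn && s$actor))
    free <- append(free, "w_q", after = match("tau", free) - 1)
  if (s$mb) {
    free <- append(free, "alpha_star", after = match("tau", free) - 1)
    if (s$critic || s$qlearn)  # planner alone has w* fixed at 1
      free <- append(free, "w_star", after = match("tau", free) - 1)
  }
  free
}

#' Full parameter vector with fixed values enforced
#'
#' Completes a (possibly partial) named parameter vector against a model
#' specification: free parameters keep the supplied values (or defaults),
#' structurally fixed parameters are overwritten (e.g. `w_q = 0` for AC
#' models, `w_q = 1` for CQ, `lambda` per the model suffix, `w_star = 0`
#' without the planner and 1 for the pure planner, zero learning rates for
#' the hysteresis and null models).
#'
#' @param spec an `acq_model` (or model name).
#' @param params named numeric vector of parameter values.
#' @return a full named parameter vector.
#' @export
canonical_params <- function(spec, params = numeric(0)) {
  if (is.character(spec)) spec <- model_spec(spec)
  full <- c(alpha = 0, lambda = 0, w_q = 1, alpha_star = 0, w_star = 0,
            tau = 1, beta_r = 0, beta_0 = 0, lambda_beta = 0, p_a1 = 0.5)
  if (length(params)) {
    stopifnot(!is.null(names(params)))
    bad <- setdiff(names(params), names(full))
    if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
    full[names(params)] <- params
  }
  if (spec$class %in% c("null", "hysteresis")) full["alpha"] <- 0
  if (spec$lambda_mode %in% c("zero", "none")) full["lambda"] <- 0
  if (spec$lambda_mode == "one") full["lambda"] <- 1
  if (spec$wq_mode == "zero") full["w_q"] <- 0
  if (spec$wq_mode == "one" && !spec$actor) full["w_q"] <- 1
  if (!spec$mb) { full["w_star"] <- 0; full["alpha_star"] <- 0 }
  if (spec$mb && !(spec$critic || spec$qlearn)) full["w_star"] <- 1
  check_param_bounds(full)
  full
}

#' @keywords internal
check_param_bounds <- function(p) {
  in01 <- c("alpha", "lambda", "w_q", "alpha_star", "w_star", "lambda_beta",
            "p_a1")
  if (any(p[in01] < 0 | p[in01] > 1))
    stop("parameters ", paste(in01[p[in01] < 0 | p[in01] > 1],
                              collapse = ", "), " must lie in [0, 1]")
  if (p[["tau"]] <= 0) stop("tau must be positive")
  invisible(p)
}

# ---- elementary learning operations (pure R; the C++ forward pass is the
#      orchestrated implementation, and these serve as its independent
#      building blocks in tests and in the extended regressor pass) ----

#' State-value-prediction error
#'
#' The critic's temporal-difference teaching signal,
#' `delta_V = r + V(s') - V(s)`, with the discount factor omitted (a single
#' reward at a fixed delay) and terminal values fixed at zero.
#'
#' @param V named numeric vector of state values (terminals may be omitted;
#'   absent states are an error unless `terminal`).
#' @param s_t,s_next state names; `s_next` may be "reward"/"no_reward"
#'   (value 0).
#' @param r_next observed reward on arrival (0 or 1).
#' @return the prediction error, a scalar.
#' @export
compute_svpe <- function(V, s_t, s_next, r_next) {
  v_next <- if (s_next %in% c("reward", "no_reward")) 0 else {
    if (!s_next %in% names(V)) stop("unknown state: ", s_next)
    V[[s_next]]
  }
  if (!s_t %in% names(V)) stop("unknown state: ", s_t)
  r_next + v_next - V[[s_t]]
}

#' Action-value-prediction error
#'
#' The Q-learner's teaching signal,
#' `delta_Q = r + max_a' Q(s', a') - Q(s, a)`. For an action-less successor
#' the max term is the pseudoaction entry `Q(s', A0)` (which aliases the
#' state value in the bridged critic/Q models), or 0 when no entry exists
#' (the pure Q(0) convention at terminals).
#'
#' @param Q named list: `Q[[state]]` is a named numeric vector over actions
#'   (use action name "A0" for pseudoaction entries).
#' @param s_t,a_t the predicting state-action pair.
#' @param s_next successor state name.
#' @param r_next observed reward on arrival.
#' @return the prediction error, a scalar.
#' @export
compute_avpe <- function(Q, s_t, a_t, s_next, r_next) {
  if (!s_t %in% names(Q) || !a_t %in% names(Q[[s_t]]))
    stop("unknown state-action pair: ", s_t, ", ", a_t)
  max_next <- if (s_next %in% names(Q)) max(Q[[s_next]]) else 0
  r_next + max_next - Q[[s_t]][[a_t]]
}

#' Eligibility-trace update within an episode
#'
#' Applies `value[n-th back] += alpha * lambda^n * delta` to entries listed
#' most-recent-first; the trace never crosses the episode (trial) boundary.
#'
#' @param values numeric vector of current values for the episode's entries,
#'   ordered most-recent-first.
#' @param delta the prediction error at the current step.
#' @param alpha learning rate in `[0, 1]`.
#' @param lambda eligibility in `[0, 1]`.
#' @return the updated values.
#' @export
apply_eligibility_updates <- function(values, delta, alpha, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  n <- seq_along(values) - 1
  values + alpha * lambda^n * delta
}

#' Model-based transition-learning step
#'
#' Computes the state-prediction error `delta* = 1 - T(s, a, s_next)`, then
#' moves probability mass toward the observed successor: the observed entry
#' is incremented by `alpha_star * delta*` and every other entry in the row
#' is scaled by `(1 - alpha_star)`, so the row still sums to one.
#'
#' @param T_row named numeric row over the feasible successors (sums to 1).
#' @param s_next the observed successor (must be feasible).
#' @param alpha_star model-based learning rate in `[0, 1]`.
#' @return list with the updated row `T_row` and the error `delta_star`.
#' @export
mb_observe <- function(T_row, s_next, alpha_star) {
  if (!s_next %in% names(T_row))
    stop("successor not feasible for this row: ", s_next)
  delta <- 1 - T_row[[s_next]]
  out <- T_row * (1 - alpha_star)
  out[[s_next]] <- T_row[[s_next]] + alpha_star * delta
  list(T_row = out, delta_star = delta)
}

#' Model-based planning by backward induction
#'
#' Evaluates the Bellman optimality values over the episode's directed
#' acyclic state graph: `Q*(s, a) = sum_s' T(s, a, s') (R(s') +
#' max_a' Q*(s', a'))`, with terminal values 0 and `R = 1` at the reward
#' terminal.
#'
#' @param T_list named list: `T_list[[state]][[action]]` is a named
#'   probability row over successors. Terminal states carry no entry.
#' @param R named numeric reward function over states (default: 1 for
#'   "reward", 0 otherwise).
#' @return named list `Q_star[[state]][[action]]`.
#' @export
mb_plan <- function(T_list, R = NULL) {
  rfun <- function(s) {
    if (!is.null(R) && s %in% names(R)) return(R[[s]])
    if (s == "reward") 1 else 0
  }
  qstar <- list()
  value_of <- function(s, depth = 0) {
    if (depth > 10) stop("cyclic state graph")
    if (!s %in% names(T_list)) return(0)  # terminal
    if (is.null(qstar[[s]])) {
      qs <- vapply(names(T_list[[s]]), function(a) {
        row <- T_list[[s]][[a]]
        sum(row * vapply(names(row), function(sp)
          rfun(sp) + value_of(sp, depth + 1), numeric(1)))
      }, numeric(1))
      qstar[[s]] <<- qs
    }
    max(qstar[[s]])
  }
  for (s in names(T_list)) value_of(s)
  qstar
}

#' Net action weights and net values
#'
#' Convex combinations of the actor's preference, the Q-learner's action
#' value, and the planner's value: `W = w_q Q + (1 - w_q) p` and
#' `W* = w* Q* + (1 - w*) W`. Also returns the net value
#' `Q^V = w_q Q + (1 - w_q) V` and net prediction error
#' `delta^{Q,V} = w_q delta_Q + (1 - w_q) delta_V` as diagnostics when their
#' inputs are supplied.
#'
#' @param p,Q,Q_star numeric (vectors align elementwise).
#' @param w_q,w_star weights in `[0, 1]`.
#' @param V,delta_Q,delta_V optional diagnostics inputs.
#' @return list with `W`, `W_star`, and optionally `Q_V`, `delta_QV`.
#' @export
net_weights <- function(p, Q, Q_star = 0, w_q, w_star = 0, V = NULL,
                        delta_Q = NULL, delta_V = NULL) {
  stopifnot(w_q >= 0, w_q <= 1, w_star >= 0, w_star <= 1)
  W <- w_q * Q + (1 - w_q) * p
  out <- list(W = W, W_star = w_star * Q_star + (1 - w_star) * W)
  if (!is.null(V)) out$Q_V <- w_q * Q + (1 - w_q) * V
  if (!is.null(delta_Q) && !is.null(delta_V))
    out$delta_QV <- w_q * delta_Q + (1 - w_q) * delta_V
  out
}

#' Cumulative perseveration bias for a state
#'
#' Sums exponentially decaying contributions of past choices in a state:
#' the choice made n visits ago contributes `beta_0 * lambda_beta^n` to its
#' action's bias. Decay is per completed visit to the state, not per trial.
#'
#' @param choice_history character vector of the actions chosen on past
#'   visits to the state, in chronological order.
#' @param beta_0 initial magnitude (may be negative: alternation).
#' @param lambda_beta inverse decay rate in `[0, 1]`.
#' @param actions action names.
#' @return named numeric vector of biases.
#' @export
perseveration_bias <- function(choice_history, beta_0, lambda_beta,
                               actions = c("L", "R")) {
  stopifnot(lambda_beta >= 0, lambda_beta <= 1)
  bias <- stats::setNames(numeric(length(actions)), actions)
  cc <- length(choice_history)
  if (cc == 0) return(bias)
  for (n in 0:(cc - 1)) {
    a <- choice_history[[cc - n]]
    bias[[a]] <- bias[[a]] + beta_0 * lambda_beta^n
  }
  bias
}

#' Softmax action probabilities with biases
#'
#' `pi(a)` proportional to `exp{(W*(s,a) + bias(s,a) + beta_r I_R(a)) / tau}`,
#' computed overflow-safely; with two actions this is a logistic function.
#'
#' @param W_star named numeric vector of net weights over actions.
#' @param biases named numeric vector of perseveration biases (default 0).
#' @param beta_r rightward constant bias (added to action "R").
#' @param tau softmax temperature, strictly positive.
#' @return named probability vector summing to 1.
#' @export
action_probabilities <- function(W_star, biases = NULL, beta_r = 0, tau) {
  if (tau <= 0) stop("tau must be positive")
  if (is.null(biases)) biases <- stats::setNames(numeric(length(W_star)),
                                                 names(W_star))
  z <- (W_star + biases[names(W_star)] +
          beta_r * as.numeric(names(W_star) == "R")) / tau
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# ---- orchestrated forward pass ----

#' @keywords internal
core_flags <- function(spec) {
  list(critic = spec$critic, actor = spec$actor, qlearn = spec$qlearn,
       pure_q = spec$pure_q, mb = spec$mb, is_null = spec$class == "null")
}

#' Deterministic forward pass of a model over a session
#'
#' Replays a session trial by trial, emitting every latent quantity the model
#' defines (state values, preferences, action values, planner values, net
#' weights, perseveration biases, and the state-value, action-value and
#' state-prediction errors at both within-trial transitions) together with
#' the model's choice probability at each valid active trial. Error trials
#' contribute no likelihood and trigger no updates. The per-trial event
#' grammar is first-stage -> second-stage -> terminal; eligibility traces do
#' not cross trials.
#'
#' @param model an `acq_model` or model name.
#' @param params named parameter vector (completed via [canonical_params()]).
#' @param session an `acq_session` with choices and outcomes filled in.
#' @return list of class `acq_forward`: `loglik`, per-trial log-likelihood
#'   `ll`, `n_choices`, and `trace` (a data.frame, one row per trial).
#' @export
forward_pass <- function(model, params, session) {
  spec <- if (is.character(model)) model_spec(model) else model
  par <- canonical_params(spec, params)
  enc <- encode_session(session)
  res <- .core_pass(enc$trial_type, enc$first, enc$action, enc$second,
                    enc$reward, enc$error,
                    numeric(nrow(session)), numeric(nrow(session)),
                    numeric(nrow(session)), numeric(nrow(session)),
                    as.list(par), core_flags(spec), 0L)
  trace <- as.data.frame(res$trace)
  trace$trial_index <- session$trial_index
  out <- list(model = spec$name, params = par, loglik = res$loglik,
              ll = res$ll, n_choices = res$n_choices, trace = trace,
              session = session)
  class(out) <- "acq_forward"
  out
}

#' Tidy event-level latent trace
#'
#' Flattens a forward pass into one row per within-trial transition (step 1:
#' first stage with its real action or pseudoaction; step 2: second stage
#' with the pseudoaction), carrying the latent values and prediction errors
#' attached to each event.
#'
#' @param fp an `acq_forward` from [forward_pass()].
#' @return a data.frame with columns trial, step, state, action, V, Q, p, W,
#'   Wstar, dV, dQ, dStar.
#' @export
latent_trace <- function(fp) {
  s <- fp$session
  tr <- fp$trace
  ok <- s$error_flag == "none"
  act <- s$trial_type == "active" & ok
  a_idx <- ifelse(is.na(s$action), NA, match(s$action, c("L", "R")))
  pick <- function(l, r) ifelse(!is.na(a_idx) & a_idx == 1, l, r)
  step1 <- data.frame(
    trial = s$trial_index, step = 1L, state = s$first_state,
    action = ifelse(act, s$action, "A0"),
    V = tr$V_first,
    Q = ifelse(act, pick(tr$Q_L, tr$Q_R), tr$V_first),
    p = ifelse(act, pick(tr$p_L, tr$p_R), NA_real_),
    W = ifelse(act, pick(tr$W_L, tr$W_R), NA_real_),
    Wstar = ifelse(act, pick(tr$Wstar_L, tr$Wstar_R), NA_real_),
    dV = tr$dV1, dQ = tr$dQ1, dStar = tr$dStar1,
    stringsAsFactors = FALSE)
  step2 <- data.frame(
    trial = s$trial_index, step = 2L, state = s$second_state,
    action = "A0", V = tr$V_second, Q = tr$V_second, p = NA_real_,
    W = NA_real_, Wstar = NA_real_,
    dV = tr$dV2, dQ = tr$dQ2, dStar = tr$dStar2,
    stringsAsFactors = FALSE)
  out <- rbind(step1, step2)
  out <- out[ok[match(out$trial, s$trial_index)], ]
  out[order(out$trial, out$step), ]
}

#' Write a tidy latent trace to TSV
#' @param fp an `acq_forward`.
#' @param path output path.
#' @export
write_trace <- function(fp, path) {
  utils::write.table(latent_trace(fp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.acq_model <- function(x, ...) {
  cat(sprintf("Model %s (%s): k = %d free parameters (%s)\n", x$name,
              x$class, x$k, paste(x$free, collapse = ", ")))
  invisible(x)
}

#' @export
print.acq_forward <- function(x, ...) {
  cat(sprintf("Forward pass of %s: %d valid choices, log-likelihood %.4f\n",
              x$model, x$n_choices, x$loglik))
  invisible(x)
}
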
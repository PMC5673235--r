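#' Choice accuracy with exclusions
#'
#' The proportion of valid choices matching the option more likely to
#' ultimately yield reward ([better_action()]). Excluded from the score:
#' error trials, trials in blocks where the two actions tie, and the first
#' encounter of each active state (by default per block, so that the
#' exclusion also applies after each reversal; set `first_encounter_scope =
#' "session"` to exclude only the session-initial encounters, or `"none"`).
#'
#' @param session an `acq_session`.
#' @param task the `acq_task`.
#' @param first_encounter_scope "block", "session" or "none".
#' @return list: `accuracy`, `n_scored`, `n_correct`, `n_excluded`.
#' @export
accuracy_score <- function(session, task,
                           first_encounter_scope = c("block", "session",
                                                     "none")) {
  first_encounter_scope <- match.arg(first_encounter_scope)
  active <- session$trial_type == "active"
  valid <- active & session$error_flag == "none"

  first_enc <- rep(FALSE, nrow(session))
  if (first_encounter_scope != "none") {
    grp <- if (first_encounter_scope == "block")
      paste(session$first_state, session$block_index) else session$first_state
    for (g in unique(grp[active])) {
      idx <- which(active & grp == g)
      first_enc[idx[1]] <- TRUE
    }
  }

  # better action per (block, state), computed once
  ba_tab <- outer(seq_along(task$blocks), task$active_first_states,
                  Vectorize(function(b, s) better_action(task, b, s)))
  rownames(ba_tab) <- as.character(seq_along(task$blocks))
  colnames(ba_tab) <- task$active_first_states
  ba <- rep(NA_character_, nrow(session))
  ba[valid] <- ba_tab[cbind(as.character(session$block_index[valid]),
                            session$first_state[valid])]
  scored <- valid & !first_enc & !is.na(ba)
  n_scored <- sum(scored)
  if (n_scored == 0) stop("no scorable trials")
  n_correct <- sum(session$action[scored] == ba[scored])
  list(accuracy = n_correct / n_scored, n_scored = n_scored,
       n_correct = n_correct,
       n_excluded = sum(valid) - n_scored)
}

#' One-tailed exact binomial test against chance
#'
#' Upper-tail probability `P(X >= n_correct)` under `X ~ Binomial(n_scored,
#' 0.5)`.
#'
#' @param n_correct number of correct choices.
#' @param n_scored number of scored choices (>= 1).
#' @return the one-tailed p-value.
#' @export
binomial_chance_test <- function(n_correct, n_scored) {
  stopifnot(n_scored >= 1, n_correct >= 0, n_correct <= n_scored)
  stats::pbinom(n_correct - 1, n_scored, 0.5, lower.tail = FALSE)
}

#' @keywords internal
active_weight_frame <- function(session, trace, weights = c("W", "Wstar")) {
  weights <- match.arg(weights)
  wl <- trace[[paste0(weights, "_L")]]
  wr <- trace[[paste0(weights, "_R")]]
  keep <- session$trial_type == "active" & session$error_flag == "none" &
    is.finite(wl) & is.finite(wr)
  data.frame(trial = session$trial_index[keep],
             state = session$first_state[keep],
             action = session$action[keep],
             rt_ms = session$rt_ms[keep],
             w_l = wl[keep], w_r = wr[keep],
             dw = wr[keep] - wl[keep], stringsAsFactors = FALSE)
}

#' @keywords internal
normalize_abs_max <- function(x) {
  m <- max(abs(x))
  if (m == 0) stop("degenerate predictor: all weight differences are zero")
  x / m
}

#' Logistic regression of choice on the net action-weight difference
#'
#' Models the probability of a right-action choice as a function of the
#' right-minus-left difference in net action weights, normalized by its
#' per-subject maximum absolute value. The per-subject slope feeds
#' group-level one-tailed t tests.
#'
#' @param session an `acq_session`.
#' @param trace the per-trial trace of a [forward_pass()] aligned to the
#'   session.
#' @param weights which weights to difference: model-free net weights `"W"`
#'   or planner-mixed `"Wstar"`.
#' @return list: `coefficient` (slope), `se`, `statistic`, `p_one_tailed`
#'   (positive direction), `n`.
#' @export
choice_weight_logistic <- function(session, trace, weights = "W") {
  d <- active_weight_frame(session, trace, weights)
  if (nrow(d) < 3) stop("too few valid choices")
  d$x <- normalize_abs_max(d$dw)
  fit <- stats::glm((action == "R") ~ x, family = stats::binomial(), data = d)
  co <- summary(fit)$coefficients
  list(coefficient = co["x", "Estimate"], se = co["x", "Std. Error"],
       statistic = co["x", "z value"],
       p_one_tailed = stats::pnorm(co["x", "z value"], lower.tail = FALSE),
       n = nrow(d))
}

#' Logistic regression of staying on the stay-minus-switch weights
#'
#' A "stay" choice repeats the previous action taken in the current state.
#' Staying is modeled as a function of the difference between the net weights
#' of the stay and switch options (normalized); the intercept captures a
#' residual stay tendency beyond what the weights predict, so a positive
#' intercept evidences perseveration and a negative one alternation. When the
#' weight predictor is degenerate (e.g. a pure hysteresis agent whose weights
#' are all zero) an intercept-only model is fitted and the slope is `NA`.
#'
#' @param session an `acq_session`.
#' @param trace aligned per-trial trace.
#' @param weights `"W"` or `"Wstar"`.
#' @return list: `stay_bias` (intercept), `se`, `statistic`, `p_one_tailed`
#'   (positive direction), `slope`, `n`.
#' @export
stay_switch_logistic <- function(session, trace, weights = "W") {
  d <- active_weight_frame(session, trace, weights)
  prev <- list()
  d$prev_action <- NA_character_
  for (i in seq_len(nrow(d))) {
    s <- d$state[i]
    if (!is.null(prev[[s]])) d$prev_action[i] <- prev[[s]]
    prev[[s]] <- d$action[i]
  }
  d <- d[!is.na(d$prev_action), ]
  if (nrow(d) < 3) stop("no repeat visits to any active state")
  d$stay <- d$action == d$prev_action
  w_prev <- ifelse(d$prev_action == "L", d$w_l, d$w_r)
  w_other <- ifelse(d$prev_action == "L", d$w_r, d$w_l)
  dx <- w_prev - w_other
  degenerate <- max(abs(dx)) == 0
  if (degenerate) {
    fit <- stats::glm(stay ~ 1, family = stats::binomial(), data = d)
    slope <- NA_real_
  } else {
    d$x <- normalize_abs_max(dx)
    fit <- stats::glm(stay ~ x, family = stats::binomial(), data = d)
    slope <- stats::coef(fit)[["x"]]
  }
  co <- summary(fit)$coefficients
  list(stay_bias = co["(Intercept)", "Estimate"],
       se = co["(Intercept)", "Std. Error"],
       statistic = co["(Intercept)", "z value"],
       p_one_tailed = stats::pnorm(co["(Intercept)", "z value"],
                                   lower.tail = FALSE),
       slope = slope, n = nrow(d))
}

#' Linear regression of reaction time on choice difficulty
#'
#' RT as a function of the normalized absolute net action-weight difference;
#' a negative slope means easier discriminations are answered faster.
#' Excessively fast contaminant responses are omitted below the threshold.
#'
#' @param session an `acq_session` with RTs.
#' @param trace aligned per-trial trace.
#' @param threshold_ms minimum credible RT (default 300 ms).
#' @param weights `"W"` or `"Wstar"`.
#' @return list: `coefficient` (ms per unit normalized difficulty), `se`,
#'   `statistic`, `p_one_tailed` (negative direction), `n`.
#' @export
rt_weight_regression <- function(session, trace, threshold_ms = 300,
                                 weights = "W") {
  d <- active_weight_frame(session, trace, weights)
  d <- d[!is.na(d$rt_ms) & d$rt_ms >= threshold_ms, ]
  if (nrow(d) < 3) stop("no usable reaction times after the cutoff")
  d$x <- normalize_abs_max(abs(d$dw))
  if (max(d$x) == min(d$x)) stop("degenerate predictor: constant difficulty")
  fit <- stats::lm(rt_ms ~ x, data = d)
  co <- summary(fit)$coefficients
  list(coefficient = co["x", "Estimate"], se = co["x", "Std. Error"],
       statistic = co["x", "t value"],
       p_one_tailed = stats::pt(co["x", "t value"], fit$df.residual),
       n = nrow(d))
}

#' Binned choice curve over the normalized weight difference
#'
#' Bins the per-subject-normalized net action-weight difference into the
#' fixed partition of `[-1, 1]` with edge bins of width 0.3 and inner bins of
#' width 0.2 (edges -1, -0.7, -0.5, -0.3, -0.1, 0.1, 0.3, 0.5, 0.7, 1), and
#' reports the observed right-choice probability per bin with its standard
#' error. Empty bins are reported with `NA`, not zero.
#'
#' @param sessions an `acq_session` or list of them.
#' @param traces matching per-trial trace(s).
#' @param weights `"W"` or `"Wstar"`.
#' @return data.frame: bin edges and midpoint, `p_right`, `sem`, `n`.
#' @export
choice_curve <- function(sessions, traces, weights = "W") {
  if (inherits(sessions, "data.frame")) {
    sessions <- list(sessions); traces <- list(traces)
  }
  edges <- c(-1, -0.7, -0.5, -0.3, -0.1, 0.1, 0.3, 0.5, 0.7, 1)
  xs <- numeric(0); ys <- logical(0)
  for (i in seq_along(sessions)) {
    d <- active_weight_frame(sessions[[i]], traces[[i]], weights)
    xs <- c(xs, normalize_abs_max(d$dw))
    ys <- c(ys, d$action == "R")
  }
  bin <- cut(xs, edges, include.lowest = TRUE)
  out <- data.frame(bin = levels(bin), lo = edges[-length(edges)],
                    hi = edges[-1])
  out$mid <- (out$lo + out$hi) / 2
  out$n <- as.integer(table(bin)[out$bin])
  out$p_right <- vapply(out$bin, function(b) {
    y <- ys[which(bin == b)]
    if (length(y) == 0) NA_real_ else mean(y)
  }, numeric(1))
  out$sem <- vapply(out$bin, function(b) {
    y <- ys[which(bin == b)]
    if (length(y) < 2) NA_real_ else stats::sd(y) / sqrt(length(y))
  }, numeric(1))
  out
}

#' Full behavioral report for one subject
#'
#' Bundles the accuracy score with its chance test and group label, the
#' model-derived choice and stay/switch logistic regressions, the RT
#' regression, and the binned choice curve. Excluded-trial counts accompany
#' every statistic.
#'
#' @param session an `acq_session`.
#' @param trace aligned per-trial trace from the fitted model's
#'   [forward_pass()].
#' @param task the `acq_task`.
#' @return list of class `acq_behavior_report`.
#' @export
behavior_report <- function(session, trace, task) {
  acc <- accuracy_score(session, task)
  p <- binomial_chance_test(acc$n_correct, acc$n_scored)
  out <- list(
    accuracy = acc$accuracy, n_scored = acc$n_scored,
    n_excluded = acc$n_excluded, chance_p = p,
    group = if (p < 0.05) "Good" else "Poor",
    choice_regression = try_or_na(choice_weight_logistic(session, trace)),
    stay_regression = try_or_na(stay_switch_logistic(session, trace)),
    rt_regression = try_or_na(rt_weight_regression(session, trace)),
    choice_curve = choice_curve(session, trace))
  class(out) <- "acq_behavior_report"
  out
}

#' @keywords internal
try_or_na <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

#' @export
print.acq_behavior_report <- function(x, ...) {
  cat(sprintf("Accuracy %.1f%% over %d scored choices (p = %.4g) -> %s\n",
              100 * x$accuracy, x$n_scored, x$chance_p, x$group))
  if (is.null(x$choice_regression$error))
    cat(sprintf("  choice ~ dW slope: %.3f (one-tailed p = %.3g)\n",
                x$choice_regression$coefficient,
                x$choice_regression$p_one_tailed))
  if (is.null(x$rt_regression$error))
    cat(sprintf("  RT ~ |dW| slope: %.1f ms (one-tailed p = %.3g)\n",
                x$rt_regression$coefficient, x$rt_regression$p_one_tailed))
  invisible(x)
}
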
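#' Negative log-likelihood of a model on a session
#'
#' Minus the summed log choice probabilities over all valid (non-error)
#' active trials, with choice probabilities from [forward_pass()].
#' Out-of-bounds parameters raise an error here; the optimizer's objective
#' maps them to `+Inf` instead.
#'
#' @param model an `acq_model` or name.
#' @param params named parameter vector.
#' @param session an `acq_session`.
#' @return the negative log-likelihood, a scalar.
#' @export
negative_log_likelihood <- function(model, params, session) {
  fp <- forward_pass(model, params, session)
  if (fp$n_choices < 1) stop("session contains no valid choices")
  -fp$loglik
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = 2 NLL + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param nll negative log-likelihood at the optimum.
#' @param k number of free parameters.
#' @param n_obs number of likelihood-bearing observations (valid choices).
#' @return the AICc value.
#' @export
aicc <- function(nll, k, n_obs) {
  if (n_obs <= k + 1) stop("AICc undefined: n_obs must exceed k + 1")
  2 * nll + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

# ---- bounded parameters via unconstrained reparameterization ----

#' @keywords internal
logistic <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
logit <- function(p) log(p / (1 - p))

.unit_params <- c("alpha", "lambda", "w_q", "alpha_star", "w_star",
                  "lambda_beta", "p_a1")
.log_params <- "tau"

#' @keywords internal
to_unconstrained <- function(params, free) {
  vapply(free, function(nm) {
    x <- params[[nm]]
    if (nm %in% .unit_params) logit(min(max(x, 1e-12), 1 - 1e-12))
    else if (nm %in% .log_params) log(x)
    else x
  }, numeric(1))
}

#' @keywords internal
from_unconstrained <- function(theta, free) {
  stats::setNames(vapply(seq_along(free), function(i) {
    nm <- free[i]
    if (nm %in% .unit_params) logistic(theta[i])
    else if (nm %in% .log_params) exp(theta[i])
    else theta[i]
  }, numeric(1)), free)
}

#' @keywords internal
random_start <- function(free) {
  vapply(free, function(nm) {
    if (nm %in% .unit_params) stats::runif(1, -2.5, 2.5)
    else if (nm %in% .log_params) stats::runif(1, log(0.05), log(3))
    else stats::runif(1, -1, 1)
  }, numeric(1))
}

#' Fit one model to one subject by maximum likelihood
#'
#' Optimizes the negative log-likelihood with the Nelder-Mead simplex on an
#' unconstrained reparameterization (logistic transform for unit-interval
#' parameters, log for the temperature) from multiple randomized start
#' points, and returns the best converged restart. Fully reproducible given
#' the seed. The one-parameter null model is optimized by golden-section
#' search on the transformed scale.
#'
#' @param model an `acq_model` or name.
#' @param session an `acq_session`.
#' @param n_restarts number of randomized starts (>= 1).
#' @param seed optional integer seed.
#' @return an object of class `acq_fit`: model name, fitted full parameter
#'   vector, `nll`, `n_obs`, `k`, `aicc`, a per-restart log, and a
#'   convergence flag.
#' @export
fit_subject <- function(model, session, n_restarts = 20, seed = NULL) {
  spec <- if (is.character(model)) model_spec(model) else model
  stopifnot(n_restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  free <- spec$free
  enc <- encode_session(session)
  n_obs <- sum(enc$trial_type == 1L & enc$error == 0L)
  if (n_obs < 1) stop("session contains no valid choices")
  zeros <- numeric(length(enc$first))
  flg <- core_flags(spec)

  # the transforms keep every parameter inside its bounds, so the objective
  # only has to splice free values into the completed template
  par_template <- as.list(canonical_params(spec))
  is_unit <- free %in% .unit_params
  is_log <- free %in% .log_params
  objective <- function(theta) {
    v <- theta
    v[is_unit] <- stats::plogis(theta[is_unit])
    v[is_log] <- exp(theta[is_log])
    pl <- par_template
    for (i in seq_along(free)) pl[[free[i]]] <- v[i]
    nll <- -.core_pass(enc$trial_type, enc$first, enc$action, enc$second,
                       enc$reward, enc$error, zeros, zeros, zeros, zeros,
                       pl, flg, 0L, FALSE)$loglik
    if (!is.finite(nll)) .Machine$double.xmax else nll
  }

  restarts <- data.frame(restart = seq_len(n_restarts), value = NA_real_,
                         converged = NA)
  best <- NULL
  for (i in seq_len(n_restarts)) {
    start <- random_start(free)
    if (length(free) == 1L) {
      opt <- stats::optimize(function(x) objective(x), c(-12, 12),
                             tol = 1e-10)
      res <- list(par = opt$minimum, value = opt$objective, convergence = 0L)
    } else {
      res <- stats::optim(start, objective, method = "Nelder-Mead",
                          control = list(maxit = 1000 + 600 * length(free),
                                         reltol = 1e-9))
    }
    restarts$value[i] <- res$value
    restarts$converged[i] <- res$convergence == 0L
    if (is.null(best) || res$value < best$value) best <- res
  }

  params <- canonical_params(spec, from_unconstrained(best$par, free))
  fit <- list(model = spec$name, params = params,
              theta = stats::setNames(best$par, free),
              nll = best$value, n_obs = n_obs, k = spec$k,
              aicc = aicc(best$value, spec$k, n_obs),
              converged = any(restarts$converged), restarts = restarts)
  class(fit) <- "acq_fit"
  if (!fit$converged)
    warning("no restart converged for model ", spec$name)
  fit
}

#' Fit the full factorial model set to one subject
#'
#' @param session an `acq_session`.
#' @param models character vector of model names (default: the complete
#'   registry, including the null baseline).
#' @param n_restarts randomized starts per model.
#' @param seed optional master seed; each model gets a derived sub-seed.
#' @return named list of `acq_fit` objects.
#' @export
fit_all_models <- function(session, models = model_registry()$name,
                           n_restarts = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(models))
  fits <- mapply(function(m, s)
    fit_subject(m, session, n_restarts = n_restarts, seed = s),
    models, seeds, SIMPLIFY = FALSE)
  names(fits) <- vapply(fits, `[[`, character(1), "model")
  fits
}

#' Factorial model comparison table
#'
#' Assembles per-subject fits into the comparison the factorial design calls
#' for: per subject and model the NLL, AICc, raw and penalized residual fit
#' relative to the hysteresis benchmark (positive = superior to hysteresis),
#' the per-subject best model by AICc (ties broken toward fewer parameters),
#' and a model-free / model-based classification of the winner.
#'
#' @param fits either a named list of `acq_fit`s for one subject, or a list
#'   of such lists (one element per subject).
#' @return list of class `acq_comparison`: `table` (subject x model rows),
#'   `summary` (group means per model), and `best` (one row per subject).
#' @export
compare_models <- function(fits) {
  if (inherits(fits[[1]], "acq_fit")) fits <- list(subject1 = fits)
  if (is.null(names(fits)))
    names(fits) <- paste0("subject", seq_along(fits))
  rows <- do.call(rbind, lapply(names(fits), function(id) {
    fl <- fits[[id]]
    if (!"HYST" %in% names(fl))
      stop("comparison requires a hysteresis fit as the benchmark")
    hyst <- fl[["HYST"]]
    do.call(rbind, lapply(fl, function(f) data.frame(
      subject = id, model = f$model, k = f$k, n_obs = f$n_obs, nll = f$nll,
      aicc = f$aicc,
      deviance_vs_hyst = 2 * (hyst$nll - f$nll),
      delta_aicc_vs_hyst = hyst$aicc - f$aicc,
      stringsAsFactors = FALSE)))
  }))
  rownames(rows) <- NULL

  alt <- rows[rows$model != "NULL", ]  # null is the baseline, not a rival
  best <- do.call(rbind, lapply(split(alt, alt$subject), function(d) {
    d <- d[order(d$aicc, d$k), ]
    spec <- model_spec(d$model[1])
    lab <- if (spec$class != "learning") "none"
           else if (spec$mb && (spec$critic || spec$qlearn)) "hybrid"
           else if (spec$mb) "MB" else "MF"
    data.frame(subject = d$subject[1], best_model = d$model[1],
               aicc = d$aicc[1], class = lab, stringsAsFactors = FALSE)
  }))
  rownames(best) <- NULL

  summary <- do.call(rbind, lapply(split(rows, rows$model), function(d)
    data.frame(model = d$model[1], k = d$k[1],
               mean_nll = mean(d$nll), mean_aicc = mean(d$aicc),
               mean_deviance_vs_hyst = mean(d$deviance_vs_hyst),
               mean_delta_aicc_vs_hyst = mean(d$delta_aicc_vs_hyst),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL

  out <- list(table = rows, summary = summary, best = best,
              n_alternatives = length(unique(alt$model)))
  class(out) <- "acq_comparison"
  out
}

#' Outcome sensitivity implied by fitted parameters
#'
#' `log(alpha (1 + lambda) / tau)`: the log ratio of the eligibility-adjusted
#' learning rate to the softmax temperature. Zero marks a balance between the
#' two; absolute insensitivity to outcomes (`alpha = 0`) yields `-Inf`.
#'
#' @param params named parameter vector (needs `alpha`, `lambda`, `tau`).
#' @return the sensitivity score.
#' @export
sensitivity <- function(params) {
  if (params[["tau"]] <= 0) stop("tau must be positive")
  if (params[["alpha"]] == 0) return(-Inf)
  log(params[["alpha"]] * (1 + params[["lambda"]]) / params[["tau"]])
}

#' Classify a subject by accuracy and model comparison
#'
#' Good learner if choice accuracy is significantly above the 50% chance
#' level by a one-tailed binomial test (p < 0.05); otherwise Poor learner;
#' a Poor learner is reclassified Nonperformer when the outcome-insensitive
#' hysteresis model attains the lowest AICc of all fitted alternatives.
#'
#' @param session an `acq_session`.
#' @param task the `acq_task` the session was played on.
#' @param fits optional named list of `acq_fit`s for the subject (required
#'   to detect Nonperformers).
#' @param alpha_level significance level for the binomial test.
#' @return list: `group`, `accuracy`, `n_scored`, `p_value`.
#' @export
classify_subject <- function(session, task, fits = NULL,
                             alpha_level = 0.05) {
  acc <- accuracy_score(session, task)
  p <- binomial_chance_test(acc$n_correct, acc$n_scored)
  group <- if (p < alpha_level) "Good" else "Poor"
  if (group == "Poor" && !is.null(fits)) {
    fl <- fits[names(fits) != "NULL"]
    aiccs <- vapply(fl, `[[`, numeric(1), "aicc")
    if (names(fl)[which.min(aiccs)] == "HYST") group <- "Nonperformer"
  }
  list(group = group, accuracy = acc$accuracy, n_scored = acc$n_scored,
       p_value = p)
}

#' Serialize a fit to JSON
#' @param fit an `acq_fit`.
#' @param path output path.
#' @export
write_fit <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the jsonlite package is required to write JSON fits")
  out <- list(model = fit$model, params = as.list(fit$params),
              nll = fit$nll, n_obs = fit$n_obs, k = fit$k,
              aicc = fit$aicc, converged = fit$converged,
              restarts = fit$restarts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a comparison table to TSV
#' @param comparison an `acq_comparison`.
#' @param path output path.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.table(comparison$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.acq_fit <- function(x, ...) {
  cat(sprintf("Fit of %s: NLL = %.3f, k = %d, n = %d, AICc = %.3f\n",
              x$model, x$nll, x$k, x$n_obs, x$aicc))
  free <- model_spec(x$model)$free
  print(round(x$params[free], 4))
  invisible(x)
}

#' @export
print.acq_comparison <- function(x, ...) {
  cat(sprintf("Factorial model comparison: %d alternatives, %d subject(s)\n",
              x$n_alternatives, length(unique(x$table$subject))))
  s <- x$summary[order(x$summary$mean_aicc), ]
  print(utils::head(s, 8), row.names = FALSE)
  invisible(x)
}
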
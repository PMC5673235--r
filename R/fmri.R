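#' Extended forward pass over the fMRI state chain
#'
#' For regressor construction the critic's state space is extended with the
#' intertrial fixation and the two pre-trial cues, chained
#' ITI -> cue -> first stage -> second stage -> terminal within each trial's
#' episode, so that state-value and state-value-prediction-error signals are
#' defined at every passive event. The values and errors at the fractal
#' states are identical to the behavioral pass (the extra upstream states
#' receive eligibility credit but never alter a downstream value), so
#' behavioral fits are unaffected; action values and action-value-prediction
#' errors are taken from the behavioral pass. Error trials trigger no
#' updates and carry no modulators.
#'
#' @param model an `acq_model` or name.
#' @param params named parameter vector.
#' @param session an `acq_session`.
#' @return list of class `acq_ext_forward`: the behavioral `acq_forward` plus
#'   `ext` — a per-trial data.frame with `V_iti`, `V_cue`, `V_first`,
#'   `V_second`, the four state-value-prediction errors `dV_cue` (at cue
#'   onset), `dV_first`, `dV_second`, `dV_outcome`, the action-value errors
#'   `dQ_second`, `dQ_outcome`, and `Q_chosen`.
#' @export
extended_forward_pass <- function(model, params, session) {
  spec <- if (is.character(model)) model_spec(model) else model
  par <- canonical_params(spec, params)
  fp <- forward_pass(spec, par, session)
  n <- nrow(session)
  al <- par[["alpha"]]; la <- par[["lambda"]]
  has_critic <- spec$critic

  V <- stats::setNames(numeric(8),
                       c("P1", "P2", "A1", "A2", "S1", "S2", "iti", "cue"))
  # two cue states, one shared fixation state
  V <- c(V, cue_passive = 0, cue_active = 0)
  ext <- data.frame(trial_index = session$trial_index,
                    V_iti = NA_real_, V_cue = NA_real_, V_first = NA_real_,
                    V_second = NA_real_, dV_cue = NA_real_,
                    dV_first = NA_real_, dV_second = NA_real_,
                    dV_outcome = NA_real_, dQ_second = NA_real_,
                    dQ_outcome = NA_real_, Q_chosen = NA_real_)
  for (i in seq_len(n)) {
    err <- session$error_flag[i] != "none"
    cue <- if (session$trial_type[i] == "active") "cue_active"
           else "cue_passive"
    s0 <- session$first_state[i]
    ext$V_iti[i] <- V[["iti"]]
    ext$V_cue[i] <- V[[cue]]
    ext$V_first[i] <- V[[s0]]
    if (err || !has_critic) {
      if (!has_critic && !err) {
        s1 <- session$second_state[i]
        ext$V_second[i] <- 0
        ext$dQ_second[i] <- fp$trace$dQ1[i]
        ext$dQ_outcome[i] <- fp$trace$dQ2[i]
        ext$Q_chosen[i] <- fp$trace$Q_chosen[i]
      }
      next
    }
    s1 <- session$second_state[i]
    r <- session$reward[i]
    ext$V_second[i] <- V[[s1]]
    # ITI -> cue
    d0 <- V[[cue]] - V[["iti"]]
    V[["iti"]] <- V[["iti"]] + al * d0
    # cue -> first stage
    dc <- V[[s0]] - V[[cue]]
    V[[cue]] <- V[[cue]] + al * dc
    V[["iti"]] <- V[["iti"]] + al * la * dc
    # first -> second stage
    d1 <- V[[s1]] - V[[s0]]
    V[[s0]] <- V[[s0]] + al * d1
    V[[cue]] <- V[[cue]] + al * la * d1
    V[["iti"]] <- V[["iti"]] + al * la^2 * d1
    # second stage -> terminal
    d2 <- r - V[[s1]]
    V[[s1]] <- V[[s1]] + al * d2
    V[[s0]] <- V[[s0]] + al * la * d2
    V[[cue]] <- V[[cue]] + al * la^2 * d2
    V[["iti"]] <- V[["iti"]] + al * la^3 * d2
    ext$dV_cue[i] <- d0; ext$dV_first[i] <- dc
    ext$dV_second[i] <- d1; ext$dV_outcome[i] <- d2
    ext$dQ_second[i] <- fp$trace$dQ1[i]
    ext$dQ_outcome[i] <- fp$trace$dQ2[i]
    ext$Q_chosen[i] <- fp$trace$Q_chosen[i]
  }
  out <- list(forward = fp, ext = ext, model = spec$name, params = par,
              session = session)
  class(out) <- "acq_ext_forward"
  out
}

#' Event timeline for the first-level design
#'
#' Lays out, per trial, the unmodulated indicator events (pre-trial cues by
#' type, passive fractal states, active states split by chosen hand,
#' rewarded and unrewarded outcomes, fixation onsets during ISIs and the ITI,
#' and separate events for error trials) and placeholder rows for the four
#' parametric regressors: state value (`value`; boxcars spanning each
#' stimulus plus the following interstimulus interval, since expectations
#' persist until the next relevant state), state-value-prediction error
#' (`svpe`; at the stimulus onset immediately following each predicting
#' state), action value (`avalue`; the active-state stimulus plus ISI) and
#' action-value-prediction error (`avpe`; during the states during and
#' immediately following active states). Modulator values are filled by
#' [attach_modulators()].
#'
#' @param session an `acq_session`.
#' @param timing timing constants; defaults to [default_timing()].
#' @return data.frame of class `acq_timeline`: run, trial, onset, duration,
#'   label, slot, modulator.
#' @export
build_timeline <- function(session, timing = default_timing()) {
  tm <- timing
  rows <- vector("list", nrow(session))
  stim <- tm$stimulus_s
  vdur <- tm$stimulus_s + tm$isi_s
  for (i in seq_len(nrow(session))) {
    s <- session[i, ]
    err <- s$error_flag != "none"
    active <- s$trial_type == "active"
    cue_lab <- if (active) "cue_active" else "cue_passive"
    ev <- list(
      data.frame(label = "fixation", slot = "iti", onset = s$onset_iti,
                 duration = s$iti_s),
      data.frame(label = cue_lab, slot = "cue", onset = s$onset_cue,
                 duration = tm$pretrial_cue_s),
      data.frame(label = "value", slot = "iti", onset = s$onset_iti,
                 duration = s$iti_s),
      data.frame(label = "value", slot = "cue", onset = s$onset_cue,
                 duration = tm$pretrial_cue_s),
      data.frame(label = "svpe", slot = "cue", onset = s$onset_cue,
                 duration = tm$pretrial_cue_s))
    if (err) {
      # modulated events are only emitted for completed trials
      ev <- c(ev[1:2], list(
        data.frame(label = "error", slot = "first", onset = s$onset_first,
                   duration = stim)))
    } else {
      first_lab <- if (!active) "state_passive"
                   else if (s$action == "L") "active_left" else "active_right"
      out_lab <- if (s$reward == 1) "outcome_rewarded" else
        "outcome_unrewarded"
      ev <- c(ev, list(
        data.frame(label = first_lab, slot = "first", onset = s$onset_first,
                   duration = stim),
        data.frame(label = "state_passive", slot = "second",
                   onset = s$onset_second, duration = stim),
        data.frame(label = out_lab, slot = "outcome",
                   onset = s$onset_outcome, duration = tm$outcome_s),
        data.frame(label = "fixation", slot = "isi1",
                   onset = s$onset_first + stim, duration = tm$isi_s),
        data.frame(label = "fixation", slot = "isi2",
                   onset = s$onset_second + stim, duration = tm$isi_s),
        data.frame(label = "value", slot = "first", onset = s$onset_first,
                   duration = vdur),
        data.frame(label = "value", slot = "second", onset = s$onset_second,
                   duration = vdur),
        data.frame(label = "svpe", slot = "first", onset = s$onset_first,
                   duration = stim),
        data.frame(label = "svpe", slot = "second", onset = s$onset_second,
                   duration = stim),
        data.frame(label = "svpe", slot = "outcome",
                   onset = s$onset_outcome, duration = tm$outcome_s)))
      if (active) {
        ev <- c(ev, list(
          data.frame(label = "avalue", slot = "first", onset = s$onset_first,
                     duration = vdur),
          data.frame(label = "avpe", slot = "second",
                     onset = s$onset_second, duration = stim),
          data.frame(label = "avpe", slot = "outcome",
                     onset = s$onset_outcome, duration = tm$outcome_s)))
      }
    }
    ev <- do.call(rbind, ev)
    ev$trial <- s$trial_index
    ev$run <- s$run_index
    rows[[i]] <- ev
  }
  out <- do.call(rbind, rows)
  out$modulator <- NA_real_
  out <- out[order(out$run, out$onset, out$label), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("acq_timeline", "data.frame")
  out
}

#' Attach latent modulators to a timeline
#'
#' Fills the parametric-modulator column of the `value`, `svpe`, `avalue`
#' and `avpe` rows from an extended forward pass. Positive and negative
#' prediction errors share a common linear scale (no rectification).
#'
#' @param timeline an `acq_timeline` from [build_timeline()].
#' @param ext an `acq_ext_forward` from [extended_forward_pass()] on the same
#'   session.
#' @return the timeline with `modulator` filled for modulated rows.
#' @export
attach_modulators <- function(timeline, ext) {
  e <- ext$ext
  idx <- match(timeline$trial, e$trial_index)
  if (anyNA(idx)) stop("timeline and trace are misaligned")
  key <- paste(timeline$label, timeline$slot)
  lut <- list("value iti" = e$V_iti, "value cue" = e$V_cue,
              "value first" = e$V_first, "value second" = e$V_second,
              "svpe cue" = e$dV_cue, "svpe first" = e$dV_first,
              "svpe second" = e$dV_second, "svpe outcome" = e$dV_outcome,
              "avpe second" = e$dQ_second, "avpe outcome" = e$dQ_outcome,
              "avalue first" = e$Q_chosen)
  for (k in names(lut)) {
    sel <- key == k
    timeline$modulator[sel] <- lut[[k]][idx[sel]]
  }
  mod <- timeline$label %in% c("value", "svpe", "avalue", "avpe")
  if (anyNA(timeline$modulator[mod]))
    stop("timeline and trace are misaligned: unmatched modulated events")
  timeline
}

#' Canonical double-gamma hemodynamic response
#'
#' The standard difference of two gamma densities: a response peaking near
#' 6 s minus an undershoot peaking near 16 s scaled by the peak-to-undershoot
#' ratio (6), normalized to unit peak height.
#'
#' @param t time in seconds (vector).
#' @param peak,undershoot gamma shape parameters (rate 1) for the response
#'   and undershoot lobes.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  tt <- seq(0, 32, by = 0.01)
  hmax <- max(stats::dgamma(tt, shape = peak, rate = 1) -
                stats::dgamma(tt, shape = undershoot, rate = 1) / ratio)
  h / hmax
}

#' Convolve a timeline and sample it at the scan repetition time
#'
#' Builds each regressor as a boxcar series on a fine (10-ms) grid —
#' modulated regressors carry their mean-centered modulator as boxcar
#' height, indicator regressors carry 1 — convolves with the canonical
#' double-gamma response, and samples at the repetition time. Runs are
#' treated independently. No orthogonalization is applied anywhere.
#'
#' @param timeline an `acq_timeline` with modulators attached.
#' @param tr repetition time in seconds (default 2.770).
#' @param run_length_s length of each run in seconds; defaults to the last
#'   event offset plus 16 s, rounded up to a whole volume.
#' @param dt fine-grid resolution in seconds.
#' @param center mean-center modulators per regressor and run (standard
#'   parametric-modulator convention).
#' @return object of class `acq_design`: a list with one design matrix per
#'   run (columns: regressors plus a constant) and the sampling metadata.
#' @export
convolve_and_sample <- function(timeline, tr = 2.770, run_length_s = NULL,
                                dt = 0.01, center = TRUE) {
  labels <- unique(timeline$label)
  mod_labels <- intersect(c("value", "svpe", "avalue", "avpe"), labels)
  runs <- sort(unique(timeline$run))
  kern <- hrf_double_gamma(seq(0, 32, by = dt))
  mats <- vector("list", length(runs))
  names(mats) <- paste0("run", runs)
  for (ri in seq_along(runs)) {
    ev <- timeline[timeline$run == runs[ri], ]
    rl <- if (is.null(run_length_s))
      tr * ceiling((max(ev$onset + ev$duration) + 16) / tr) else run_length_s
    if (any(ev$onset + ev$duration > rl + 1e-9))
      stop("events extend beyond the run length")
    ngrid <- ceiling(rl / dt)
    vols <- seq(0, rl - 1e-9, by = tr)
    cols <- matrix(0, nrow = length(vols), ncol = length(labels),
                   dimnames = list(NULL, labels))
    for (lb in labels) {
      sub <- ev[ev$label == lb, ]
      if (nrow(sub) == 0) next
      height <- if (lb %in% mod_labels) {
        if (center) sub$modulator - mean(sub$modulator) else sub$modulator
      } else rep(1, nrow(sub))
      x <- numeric(ngrid)
      for (j in seq_len(nrow(sub))) {
        i0 <- floor(sub$onset[j] / dt) + 1
        i1 <- min(ngrid, ceiling((sub$onset[j] + sub$duration[j]) / dt))
        if (i1 >= i0) x[i0:i1] <- x[i0:i1] + height[j]
      }
      conv <- stats::convolve(x, rev(kern), type = "open")[seq_len(ngrid)]
      cols[, lb] <- conv[pmin(ngrid, floor(vols / dt) + 1)]
    }
    mats[[ri]] <- cbind(cols, constant = 1)
  }
  out <- list(matrices = mats, tr = tr, dt = dt, labels = labels,
              modulated = mod_labels)
  class(out) <- "acq_design"
  out
}

#' Build the full first-level design for a session
#'
#' Convenience wrapper: extended forward pass, timeline, modulators,
#' convolution.
#'
#' @param model,params the model generating the regressors.
#' @param session an `acq_session`.
#' @param timing timing constants.
#' @param tr repetition time in seconds.
#' @return an `acq_design`.
#' @export
build_design_matrix <- function(model, params, session,
                                timing = default_timing(), tr = 2.770) {
  ext <- extended_forward_pass(model, params, session)
  tl <- build_timeline(session, timing)
  tl <- attach_modulators(tl, ext)
  convolve_and_sample(tl, tr = tr)
}

#' Correlation between convolved prediction-error regressors
#'
#' Pearson correlation between the convolved state-value and action-value
#' prediction-error columns, pooled over runs — the design's collinearity
#' diagnostic. No orthogonalization is applied.
#'
#' @param design an `acq_design` containing `svpe` and `avpe` columns.
#' @return the correlation coefficient.
#' @export
modulator_collinearity <- function(design) {
  stopifnot(inherits(design, "acq_design"))
  if (!all(c("svpe", "avpe") %in% design$labels))
    stop("design lacks svpe/avpe columns")
  sv <- unlist(lapply(design$matrices, function(m) m[, "svpe"]))
  av <- unlist(lapply(design$matrices, function(m) m[, "avpe"]))
  if (stats::sd(sv) == 0 || stats::sd(av) == 0)
    stop("constant regressor column")
  stats::cor(sv, av)
}

#' Export a timeline as a BIDS-style events table
#'
#' @param timeline an `acq_timeline`.
#' @param path output TSV path.
#' @export
write_events <- function(timeline, path) {
  ev <- data.frame(onset = timeline$onset, duration = timeline$duration,
                   trial_type = timeline$label, run = timeline$run,
                   trial = timeline$trial, modulator = timeline$modulator)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

#' Export three-column event files per regressor
#'
#' One whitespace-delimited file per regressor label and run with columns
#' onset, duration and weight (the modulator for parametric regressors, 1
#' for indicators).
#'
#' @param timeline an `acq_timeline` with modulators attached.
#' @param dir output directory.
#' @export
write_regressor_files <- function(timeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in unique(timeline$run)) {
    for (lb in unique(timeline$label)) {
      sub <- timeline[timeline$run == r & timeline$label == lb, ]
      if (nrow(sub) == 0) next
      w <- if (all(is.na(sub$modulator))) rep(1, nrow(sub)) else
        sub$modulator
      utils::write.table(
        data.frame(onset = sub$onset, duration = sub$duration, weight = w),
        file.path(dir, sprintf("run%d_%s.txt", r, lb)),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' @export
print.acq_design <- function(x, ...) {
  cat(sprintf("First-level design: %d run(s), TR = %.3f s, columns: %s\n",
              length(x$matrices), x$tr,
              paste(colnames(x$matrices[[1]]), collapse = ", ")))
  invisible(x)
}
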
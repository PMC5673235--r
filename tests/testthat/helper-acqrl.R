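# Shared fixtures and an independent reference route for the forward pass.

good_params <- function() {
  c(alpha = 0.588, lambda = 0.682, w_q = 0.661, tau = 0.404,
    beta_0 = 0.093, lambda_beta = 0.621, beta_r = 0.230)
}

# Build a session table by hand from a compact trial list.
manual_session <- function(trials) {
  n <- length(trials)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- trials[[i]]
    data.frame(
      trial_index = i, run_index = 1L,
      block_index = if (is.null(tr$block)) 1L else tr$block,
      trial_type = if (tr$state %in% c("A1", "A2")) "active" else "passive",
      first_state = tr$state,
      action = if (is.null(tr$action)) NA_character_ else tr$action,
      second_state = if (is.null(tr$second)) NA_character_ else tr$second,
      reward = if (is.null(tr$reward)) NA_integer_ else as.integer(tr$reward),
      error_flag = if (is.null(tr$error)) "none" else tr$error,
      rt_ms = if (is.null(tr$rt)) NA_real_ else tr$rt,
      iti_s = 4, stringsAsFactors = FALSE)
  }))
  tm <- default_timing()
  df$onset_iti <- (df$trial_index - 1) * 16.5
  df$onset_cue <- df$onset_iti + df$iti_s
  df$onset_first <- df$onset_cue + tm$pretrial_cue_s
  df$onset_second <- df$onset_first + tm$stimulus_s + tm$isi_s
  df$onset_outcome <- df$onset_second + tm$stimulus_s + tm$isi_s
  class(df) <- c("acq_session", "data.frame")
  df
}

# Independent forward-pass route: a plain R trial loop composed from the
# package's exported elementary operations. Used to cross-check the
# orchestrated C++ pass.
reference_nll <- function(model, params, session) {
  spec <- model_spec(model)
  par <- canonical_params(spec, params)
  V <- stats::setNames(numeric(6), c("P1", "P2", "A1", "A2", "S1", "S2"))
  pref <- list(A1 = c(L = 0, R = 0), A2 = c(L = 0, R = 0))
  Q <- list(A1 = c(L = 0, R = 0), A2 = c(L = 0, R = 0))
  hist <- list(A1 = character(0), A2 = character(0))
  Tl <- list(P1 = list(A0 = c(S1 = .5, S2 = .5)),
             P2 = list(A0 = c(S1 = .5, S2 = .5)),
             A1 = list(L = c(S1 = .5, S2 = .5), R = c(S1 = .5, S2 = .5)),
             A2 = list(L = c(S1 = .5, S2 = .5), R = c(S1 = .5, S2 = .5)),
             S1 = list(A0 = c(reward = .5, no_reward = .5)),
             S2 = list(A0 = c(reward = .5, no_reward = .5)))
  al <- par[["alpha"]]; la <- par[["lambda"]]
  nll <- 0
  for (i in seq_len(nrow(session))) {
    if (session$error_flag[i] != "none") next
    s0 <- session$first_state[i]
    s1 <- session$second_state[i]
    r <- session$reward[i]
    active <- session$trial_type[i] == "active"
    a <- session$action[i]
    if (active) {
      qs <- mb_plan(Tl)[[s0]][c("L", "R")]
      nets <- net_weights(p = pref[[s0]], Q = Q[[s0]], Q_star = qs,
                          w_q = par[["w_q"]], w_star = par[["w_star"]])
      if (spec$class == "null") {
        pi_a <- c(L = par[["p_a1"]], R = 1 - par[["p_a1"]])
      } else {
        bias <- perseveration_bias(hist[[s0]], par[["beta_0"]],
                                   par[["lambda_beta"]])
        pi_a <- action_probabilities(nets$W_star, bias, par[["beta_r"]],
                                     par[["tau"]])
      }
      nll <- nll - log(pi_a[[a]])
    }
    # step 1: first -> second, r = 0
    if (spec$critic) {
      dV1 <- compute_svpe(V, s0, s1, 0)
      if (active && spec$actor)
        pref[[s0]][[a]] <- apply_eligibility_updates(pref[[s0]][[a]], dV1,
                                                     al, la)
    }
    if (spec$qlearn && active && !spec$pure_q) {
      Qall <- c(Q, list(S1 = c(A0 = V[["S1"]]), S2 = c(A0 = V[["S2"]])))
      dQ1 <- compute_avpe(Qall, s0, a, s1, 0)
      Q[[s0]][[a]] <- Q[[s0]][[a]] + al * dQ1
    }
    if (spec$mb) {
      key <- if (active) a else "A0"
      obs <- mb_observe(Tl[[s0]][[key]], s1, par[["alpha_star"]])
      Tl[[s0]][[key]] <- obs$T_row
    }
    if (spec$critic) V[[s0]] <- V[[s0]] + al * dV1
    # step 2: second -> terminal; both deltas use pre-update values
    v1_pre <- V[[s1]]
    if (spec$critic) {
      dV2 <- compute_svpe(V, s1, if (r == 1) "reward" else "no_reward", r)
      upd <- apply_eligibility_updates(c(V[[s1]], V[[s0]]), dV2, al, la)
      V[[s1]] <- upd[1]; V[[s0]] <- upd[2]
      if (active && spec$actor)
        pref[[s0]][[a]] <- pref[[s0]][[a]] + al * la * dV2
    }
    if (spec$qlearn && active) {
      if (spec$pure_q) {
        dQ2 <- r - Q[[s0]][[a]]
        Q[[s0]][[a]] <- Q[[s0]][[a]] + al * dQ2
      } else {
        dQ2 <- r - v1_pre  # pseudoaction value aliases the state value
        Q[[s0]][[a]] <- Q[[s0]][[a]] + al * la * dQ2
      }
    }
    if (spec$mb) {
      obs <- mb_observe(Tl[[s1]][["A0"]],
                        if (r == 1) "reward" else "no_reward",
                        par[["alpha_star"]])
      Tl[[s1]][["A0"]] <- obs$T_row
    }
    if (active) hist[[s0]] <- c(hist[[s0]], a)
  }
  nll
}
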
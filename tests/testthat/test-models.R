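test_that("prediction-error primitives evaluate their defining rules", {
  V <- c(s1 = 0.2, s2 = 0.6)
  expect_equal(compute_svpe(c(s1 = 0, s2 = 0), "s1", "s2", 1), 1)
  expect_equal(compute_svpe(V, "s1", "s2", 0), 0.4)
  expect_equal(compute_svpe(V, "s2", "reward", 1), 0.4)  # terminal V = 0
  expect_error(compute_svpe(V, "nope", "s2", 0), "unknown")

  Q <- list(s1 = c(a = 0.3, b = 0.1), s2 = c(A0 = 0.5))
  expect_equal(compute_avpe(list(s1 = c(a = 0)), "s1", "a", "terminal", 1), 1)
  expect_equal(compute_avpe(Q, "s1", "a", "s2", 0), 0.2)
  expect_equal(compute_avpe(Q, "s1", "a", "terminal", 1), 0.7)
  expect_error(compute_avpe(Q, "s1", "zz", "s2", 0), "unknown")
})

test_that("eligibility updates decay geometrically and stop at lambda = 0", {
  expect_equal(apply_eligibility_updates(c(0, 0), 1, 0.5, 0.5), c(0.5, 0.25))
  expect_equal(apply_eligibility_updates(c(0.3, 0.4), 1, 0.5, 0),
               c(0.8, 0.4))
  expect_equal(apply_eligibility_updates(c(0, 0), 1, 0.5, 1), c(0.5, 0.5))
})

test_that("transition learning moves mass and keeps rows normalized", {
  row <- c(s1 = 0.5, s2 = 0.5)
  obs <- mb_observe(row, "s1", 0.2)
  expect_equal(obs$delta_star, 0.5)
  expect_equal(unname(obs$T_row), c(0.6, 0.4))
  expect_equal(sum(obs$T_row), 1, tolerance = 1e-12)
  # alpha* = 0 leaves the row unchanged
  obs0 <- mb_observe(row, "s2", 0)
  expect_equal(obs0$T_row, row)
  expect_equal(obs0$delta_star, 0.5)
  # geometric convergence to a deterministic transition
  r <- c(s1 = 0.5, s2 = 0.5)
  for (i in 1:20) {
    r <- mb_observe(r, "s1", 0.5)$T_row
    expect_equal(sum(r), 1, tolerance = 1e-12)
  }
  expect_lt(abs(r[["s1"]] - 1), 1e-5)
  expect_error(mb_observe(row, "s3", 0.2), "feasible")
})

test_that("planning by backward induction matches hand marginalization", {
  Tu <- list(A1 = list(L = c(S1 = .5, S2 = .5), R = c(S1 = .5, S2 = .5)),
             S1 = list(A0 = c(reward = .5, no_reward = .5)),
             S2 = list(A0 = c(reward = .5, no_reward = .5)))
  qs <- mb_plan(Tu)
  expect_equal(unname(qs$A1), c(0.5, 0.5))  # uniform prior reward rate
  Td <- list(A1 = list(L = c(S1 = 1, S2 = 0), R = c(S1 = 0, S2 = 1)),
             S1 = list(A0 = c(reward = 0.7, no_reward = 0.3)),
             S2 = list(A0 = c(reward = 0.3, no_reward = 0.7)))
  qd <- mb_plan(Td)
  expect_equal(qd$A1[["L"]], 0.7)
  expect_equal(qd$A1[["R"]], 0.3)
  # single pseudoaction: the max at the second stage is its only entry
  expect_equal(max(qd$S1), qd$S1[["A0"]])
})

test_that("net weights are the stated convex combinations", {
  nw <- net_weights(p = 0.2, Q = 0.6, w_q = 0.25)
  expect_equal(nw$W, 0.3)
  expect_equal(nw$W_star, 0.3)  # w* defaults to 0
  expect_equal(net_weights(p = 0.2, Q = 0.6, w_q = 0)$W, 0.2)
  expect_equal(net_weights(p = 0.2, Q = 0.6, w_q = 1)$W, 0.6)
  full <- net_weights(p = 0.2, Q = 0.6, Q_star = 0.9, w_q = 0.25,
                      w_star = 0.5, V = 0.4, delta_Q = 1, delta_V = -1)
  expect_equal(full$W_star, 0.5 * 0.9 + 0.5 * 0.3)
  expect_equal(full$Q_V, 0.25 * 0.6 + 0.75 * 0.4)
  expect_equal(full$delta_QV, 0.25 * 1 + 0.75 * -1)
})

test_that("perseveration bias decays per visit and starts at zero", {
  expect_equal(unname(perseveration_bias(character(0), 0.1, 0.5)), c(0, 0))
  b1 <- perseveration_bias("L", 0.1, 0.5)
  expect_equal(b1[["L"]], 0.1)
  expect_equal(b1[["R"]], 0)
  b2 <- perseveration_bias(c("L", "L"), 0.1, 0.5)
  expect_equal(b2[["L"]], 0.15)
  b3 <- perseveration_bias(c("L", "R"), 0.1, 0.5)
  expect_equal(b3[["L"]], 0.05)
  expect_equal(b3[["R"]], 0.1)
})

test_that("softmax choice is logistic, symmetric, and overflow-safe", {
  pi0 <- action_probabilities(c(L = 0.4, R = 0.4), tau = 1)
  expect_equal(unname(pi0), c(0.5, 0.5))
  pi1 <- action_probabilities(c(L = 0, R = 1), tau = 1)
  expect_equal(pi1[["R"]], 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(sum(pi1), 1)
  # tau -> 0+ approaches the argmax; no overflow
  pig <- action_probabilities(c(L = 0.2, R = 0.1), tau = 1e-12)
  expect_equal(pig[["L"]], 1)
  # rightward bias enters only the right action
  pib <- action_probabilities(c(L = 0, R = 0), beta_r = 0.5, tau = 1)
  expect_gt(pib[["R"]], 0.5)
  expect_error(action_probabilities(c(L = 0, R = 0), tau = 0), "positive")
})

test_that("model registry enumerates the factorial family with correct k", {
  reg <- model_registry()
  expect_equal(nrow(reg), 23L)  # 21 learning + hysteresis + null
  expect_equal(sum(reg$class == "learning"), 21L)
  k <- stats::setNames(reg$k, reg$name)
  expect_equal(k[["ACQ(lambda)"]], 7L)
  expect_equal(k[["ACQ(lambda)+MB"]], 9L)
  expect_equal(k[["HYST"]], 4L)
  expect_equal(k[["NULL"]], 1L)
  expect_equal(k[["Q(0)"]], 5L)
  expect_equal(k[["MB"]], 5L)
  expect_equal(k[["AC(lambda)"]], 6L)
  expect_equal(k[["CQ(0)+MB"]], 7L)
  # lambda-suffix semantics
  expect_equal(canonical_params("AC(0)", c(alpha = .5, tau = 1))[["lambda"]], 0)
  expect_equal(canonical_params("AC(1)", c(alpha = .5, tau = 1))[["lambda"]], 1)
  expect_true("lambda" %in% model_spec("AC(lambda)")$free)
  # Greek lambda accepted
  expect_equal(model_spec("ACQ(λ)+MB")$name, "ACQ(lambda)+MB")
  expect_error(model_spec("Q(lambda)"), "one action per episode")
})

test_that("forward pass agrees with the composed elementary-op reference", {
  task <- build_task()
  models <- c("ACQ(lambda)", "CQ(lambda)", "AC(lambda)", "Q(0)",
              "ACQ(lambda)+MB", "MB", "HYST", "NULL")
  for (seed in 1:3) {
    sim <- simulate_agent("ACQ(lambda)", good_params(), task, seed = seed,
                          miss_rate = 0.05)
    for (m in models) {
      par <- c(good_params(), alpha_star = 0.4, w_star = 0.35, p_a1 = 0.6)
      par <- par[intersect(names(par),
                           c(model_spec(m)$free, "alpha", "lambda", "tau"))]
      got <- negative_log_likelihood(m, par, sim$session)
      want <- reference_nll(m, par, sim$session)
      expect_equal(got, want, tolerance = 1e-12,
                   info = paste("model", m, "seed", seed))
    }
  }
})

test_that("hysteresis and null families leave all learned latents at zero", {
  task <- build_task()
  sim <- simulate_agent("ACQ(lambda)", good_params(), task, seed = 4)
  fp <- forward_pass("HYST", c(tau = .5, beta_r = .2, beta_0 = .3,
                               lambda_beta = .6), sim$session)
  act <- sim$session$trial_type == "active"
  expect_true(all(fp$trace$V_first == 0))
  expect_true(all(fp$trace$Q_L[act] == 0))
  expect_true(all(fp$trace$p_L[act] == 0))
  expect_true(all(fp$trace$W_L[act] == 0))
  # choices are driven by biases alone: first visit to each state is 50/50
  # before any bias accrues, aside from the constant rightward bias
  fp0 <- forward_pass("HYST", c(tau = .5, beta_r = 0, beta_0 = .3,
                                lambda_beta = .6), sim$session)
  first_act <- which(act)[1]
  expect_equal(fp0$trace$pi_L[first_act], 0.5)
  fpn <- forward_pass("NULL", c(p_a1 = 0.7), sim$session)
  expect_true(all(abs(fpn$trace$pi_L[act] - 0.7) < 1e-12))
})

test_that("one-trial convergence: alpha = lambda = 1 caches the return", {
  ses <- manual_session(list(
    list(state = "A1", action = "L", second = "S1", reward = 1),
    list(state = "P1", second = "S2", reward = 0)))
  fp <- forward_pass("AC(1)", c(alpha = 1, tau = 1), ses)
  tr <- latent_trace(fp)
  # after trial 1 the visited states carry the observed return
  expect_equal(fp$trace$dV1[1], 0)   # V(S1) - V(A1) = 0 initially
  expect_equal(fp$trace$dV2[1], 1)   # r - V(S1)
  # trial 2 reads back updated values: V(S1) = 1 was cached
  fp2 <- forward_pass("AC(1)", c(alpha = 1, tau = 1), rbind(
    ses, manual_session(list(list(state = "P2", second = "S1", reward = 1)))))
  expect_equal(fp2$trace$V_second[3], 1)
})

test_that("tidy latent trace has one row per within-trial transition", {
  task <- build_task()
  sim <- simulate_agent("ACQ(lambda)", good_params(), task, seed = 8,
                        miss_rate = 0.05)
  tr <- latent_trace(sim$forward)
  n_ok <- sum(sim$session$error_flag == "none")
  expect_equal(nrow(tr), 2L * n_ok)
  expect_setequal(unique(tr$step), c(1L, 2L))
  # pseudoaction rows alias the state value
  s2 <- tr[tr$step == 2L, ]
  expect_equal(s2$Q, s2$V)
  path <- tempfile(fileext = ".tsv")
  write_trace(sim$forward, path)
  expect_true(file.exists(path))
})
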
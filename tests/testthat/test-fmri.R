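test_that("extended pass leaves fractal-state values and errors unchanged", {
  task <- build_task()
  sim <- simulate_agent("ACQ(lambda)", good_params(), task, seed = 1,
                        miss_rate = 0.05)
  ext <- extended_forward_pass("ACQ(lambda)", good_params(), sim$session)
  fp <- ext$forward
  ok <- sim$session$error_flag == "none"
  expect_equal(ext$ext$V_first[ok], fp$trace$V_first[ok], tolerance = 1e-12)
  expect_equal(ext$ext$V_second[ok], fp$trace$V_second[ok],
               tolerance = 1e-12)
  expect_equal(ext$ext$dV_second[ok], fp$trace$dV1[ok], tolerance = 1e-12)
  expect_equal(ext$ext$dV_outcome[ok], fp$trace$dV2[ok], tolerance = 1e-12)
  # cue/fixation values stay within the value range the critic can produce
  expect_true(all(ext$ext$V_iti[ok] >= -1 & ext$ext$V_iti[ok] <= 1))
})

test_that("timelines carry the stated boxcar conventions", {
  task <- build_task()
  sim <- simulate_agent("ACQ(lambda)", good_params(), task, seed = 2,
                        miss_rate = 0.05)
  ses <- sim$session
  tl <- build_timeline(ses)
  tm <- default_timing()
  # value boxcars persist through the following ISI
  vfirst <- tl[tl$label == "value" & tl$slot == "first", ]
  expect_true(all(vfirst$duration == tm$stimulus_s + tm$isi_s))
  # prediction-error boxcars span only the stimulus
  svpe2 <- tl[tl$label == "svpe" & tl$slot == "second", ]
  expect_true(all(svpe2$duration == tm$stimulus_s))
  # event counts per label match hand counts from the schedule
  ok <- ses$error_flag == "none"
  act <- ses$trial_type == "active" & ok
  expect_equal(sum(tl$label == "cue_active"),
               sum(ses$trial_type == "active"))
  expect_equal(sum(tl$label == "active_left"),
               sum(ses$action[act] == "L"))
  expect_equal(sum(tl$label == "active_right"),
               sum(ses$action[act] == "R"))
  expect_equal(sum(tl$label == "outcome_rewarded"),
               sum(ses$reward[ok] == 1))
  expect_equal(sum(tl$label == "error"), sum(!ok))
  expect_equal(sum(tl$label == "avpe"), 2 * sum(act))
  # exactly one of left/right per valid active trial
  expect_equal(sum(tl$label %in% c("active_left", "active_right")),
               sum(act))
  # state_passive: first-stage passive fractals + all valid second stages
  expect_equal(sum(tl$label == "state_passive"),
               sum(ses$trial_type == "passive" & ok) + sum(ok))
  # onsets are ordered within runs
  for (r in unique(tl$run))
    expect_true(!is.unsorted(tl$onset[tl$run == r]))
})

test_that("modulators attach the right latent to the right event", {
  task <- build_task()
  sim <- simulate_agent("ACQ(lambda)", good_params(), task, seed = 3)
  ext <- extended_forward_pass("ACQ(lambda)", good_params(), sim$session)
  tl <- attach_modulators(build_timeline(sim$session), ext)
  mod <- tl$label %in% c("value", "svpe", "avalue", "avpe")
  expect_false(anyNA(tl$modulator[mod]))
  # a rewarded first trial of a naive agent has outcome SVPE = 1
  first_rew <- which(sim$session$reward == 1)[1]
  if (sim$session$trial_index[first_rew] == 1) {
    got <- tl$modulator[tl$label == "svpe" & tl$slot == "outcome" &
                          tl$trial == 1]
    expect_equal(got, 1)
  }
  # zero-learning trace: value modulators all zero, errors reward-driven
  ext0 <- extended_forward_pass("ACQ(lambda)",
                                replace(good_params(), "alpha", 0),
                                sim$session)
  tl0 <- attach_modulators(build_timeline(sim$session), ext0)
  expect_true(all(tl0$modulator[tl0$label == "value"] == 0))
  outc <- tl0$label == "svpe" & tl0$slot == "outcome"
  ok <- sim$session$error_flag == "none"
  expect_equal(tl0$modulator[outc],
               as.numeric(sim$session$reward[ok]))
  # avpe events exist only on active trials
  avpe_trials <- unique(tl$trial[tl$label == "avpe"])
  expect_true(all(sim$session$trial_type[avpe_trials] == "active"))
})

test_that("convolution is linear, causal, and zero for zero input", {
  task <- build_task()
  sim <- simulate_agent("ACQ(lambda)", good_params(), task, seed = 4)
  ext <- extended_forward_pass("ACQ(lambda)", good_params(), sim$session)
  tl <- attach_modulators(build_timeline(sim$session), ext)
  one_run <- tl[tl$run == 1, ]
  des <- convolve_and_sample(one_run, tr = 2.77)
  m <- des$matrices[[1]]
  expect_true(all(is.finite(m)))
  # zero input -> zero output
  empty <- one_run[one_run$label == "svpe", ]
  empty$modulator <- 0
  d0 <- convolve_and_sample(empty, tr = 2.77, center = FALSE)
  expect_true(all(d0$matrices[[1]][, "svpe"] == 0))
  # impulse response: single brief event reproduces the HRF shape
  imp <- one_run[1, ]
  imp$label <- "svpe"; imp$onset <- 10; imp$duration <- 0.01
  imp$modulator <- 1
  di <- convolve_and_sample(imp, tr = 0.5, run_length_s = 60,
                            center = FALSE)
  y <- di$matrices[[1]][, "svpe"]
  tpk <- (which.max(y) - 1) * 0.5
  expect_gt(tpk, 12)  # ~10 s onset + ~5-6 s to peak
  expect_lt(tpk, 19)
  expect_equal(y[seq_len(20)], rep(0, 20), tolerance = 1e-12)  # causal
  # linearity: summed timelines give summed designs
  half1 <- one_run[seq(1, nrow(one_run), by = 2), ]
  half2 <- one_run[seq(2, nrow(one_run), by = 2), ]
  rl <- 2.77 * ceiling((max(one_run$onset + one_run$duration) + 16) / 2.77)
  dsum <- convolve_and_sample(one_run, tr = 2.77, run_length_s = rl,
                              center = FALSE)
  d1 <- convolve_and_sample(half1, tr = 2.77, run_length_s = rl,
                            center = FALSE)
  d2 <- convolve_and_sample(half2, tr = 2.77, run_length_s = rl,
                            center = FALSE)
  for (lb in intersect(colnames(d1$matrices[[1]]),
                       colnames(d2$matrices[[1]]))) {
    if (lb == "constant") next
    expect_equal(dsum$matrices[[1]][, lb],
                 d1$matrices[[1]][, lb] + d2$matrices[[1]][, lb],
                 tolerance = 1e-10)
  }
  # determinism
  des2 <- convolve_and_sample(one_run, tr = 2.77)
  expect_identical(des$matrices, des2$matrices)
})

test_that("boxcar integral equals duration times modulator", {
  tl <- data.frame(run = 1, trial = 1, label = "svpe", slot = "x",
                   onset = c(5, 20), duration = c(2, 1.5),
                   modulator = c(0.8, -0.4))
  class(tl) <- c("acq_timeline", "data.frame")
  dt <- 0.01
  # reconstruct the pre-convolution boxcar exactly as the sampler does
  ngrid <- ceiling(60 / dt)
  x <- numeric(ngrid)
  for (j in 1:2) {
    i0 <- floor(tl$onset[j] / dt) + 1
    i1 <- ceiling((tl$onset[j] + tl$duration[j]) / dt)
    x[i0:i1] <- x[i0:i1] + tl$modulator[j]
  }
  expect_equal(sum(x) * dt, sum(tl$duration * tl$modulator),
               tolerance = 0.02)
})

test_that("the canonical response has the expected morphology", {
  t <- seq(0, 32, by = 0.01)
  h <- hrf_double_gamma(t)
  expect_equal(max(h), 1, tolerance = 1e-9)
  expect_equal(t[which.max(h)], 5, tolerance = 0.3)  # peak near 5-6 s
  expect_lt(min(h), 0)                               # undershoot
  expect_gt(t[which.min(h)], 10)
  expect_equal(h[t > 30], rep(0, sum(t > 30)), tolerance = 1e-3)
})

test_that("prediction-error regressors are correlated but dissociable", {
  task <- build_task()
  set.seed(5)
  rs <- vapply(1:4, function(i) {
    par <- acqrl:::draw_params(generative_param_priors("good")$mean,
                               generative_param_priors("good")$sd)
    sim <- simulate_agent("ACQ(lambda)", par, task)
    des <- build_design_matrix("ACQ(lambda)", par, sim$session)
    modulator_collinearity(des)
  }, numeric(1))
  expect_true(all(rs > 0))   # shared outcome-driven variance
  expect_true(all(rs < 1))   # dissociable by design
  expect_lt(mean(rs), 0.95)
  # identical columns give r = 1
  d <- list(matrices = list(run1 = cbind(svpe = c(1, 2, 3, 1),
                                         avpe = c(1, 2, 3, 1))),
            labels = c("svpe", "avpe"))
  class(d) <- "acq_design"
  expect_equal(modulator_collinearity(d), 1)
  # independent noise is near zero
  set.seed(6)
  d2 <- list(matrices = list(run1 = cbind(svpe = stats::rnorm(2000),
                                          avpe = stats::rnorm(2000))),
             labels = c("svpe", "avpe"))
  class(d2) <- "acq_design"
  expect_lt(abs(modulator_collinearity(d2)), 0.08)
  # constant column errors
  d3 <- list(matrices = list(run1 = cbind(svpe = rep(1, 5),
                                          avpe = 1:5)),
             labels = c("svpe", "avpe"))
  class(d3) <- "acq_design"
  expect_error(modulator_collinearity(d3), "constant")
})
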
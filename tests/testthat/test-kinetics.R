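test_that("closed-form induction matches limits and the ODE oracle", {
  # zero source, zero start
  tc <- simulate_induction(induction_model(0.05, 0, 0), c(0, 10, 20))
  expect_equal(as.vector(tc$values), c(0, 0, 0))

  # dX/dt = 0 identity: beta = alpha * x0 keeps X constant
  tc <- simulate_induction(induction_model(0.05, 0.05 * 3, 3), c(0, 10, 20))
  expect_equal(as.vector(tc$values), c(3, 3, 3))

  # one half-time reaches half of steady state (oracle: RK4 integration)
  a <- log(2) / 25
  tc <- simulate_induction(induction_model(a, a * 1, 0), c(0, 25))
  expect_equal(tc$values[2L, 1L], 0.5, tolerance = 1e-12)
  num <- ode_oracle(c(0, 25), a, a * 1, 0, step = 0.001)
  expect_lt(abs(tc$values[2L, 1L] - num[2L, 1L]), 1e-6)

  expect_error(simulate_induction(induction_model(0.1, 1, 0), c(-5, 0)),
               "negative time")
})

test_that("induction curves are monotone, bounded, and hit T1/2 exactly", {
  for (a in c(0.01, 0.1, 0.5)) {
    for (x0 in c(0, 0.2)) {
      b <- a * 4   # steady state 4 > x0
      m <- induction_model(a, b, x0)
      tt <- seq(0, 120, by = 1)
      x <- simulate_induction(m, tt)$values[, 1L]
      # strictly increasing until the gap to steady state hits
      # double-precision resolution, never decreasing after
      away <- (b / a - x[-length(x)]) > 1e-12
      expect_true(all(diff(x)[away] > 0))
      expect_true(all(diff(x) >= 0))
      expect_true(all(x <= b / a + 1e-12))
      # approach to steady state at 20 half-times
      x_late <- simulate_induction(m, 20 * log(2) / a)$values[1L, 1L]
      expect_equal(x_late, b / a, tolerance = 1e-6)
      # half the gap to steady state closes in one half-time
      x_half <- simulate_induction(m, log(2) / a)$values[1L, 1L]
      expect_equal(x_half - x0, 0.5 * (b / a - x0), tolerance = 1e-12)
    }
  }
})

test_that("decay simulation halves abundance every half-life", {
  tc <- simulate_decay(induction_model(0, 1, 5), c(0, 10, 20))
  expect_equal(as.vector(tc$values), c(5, 5, 5))
  tc <- simulate_decay(induction_model(log(2) / 25, 0, 1), 25)
  expect_equal(tc$values[1L, 1L], 0.5)
  tc <- simulate_decay(induction_model(log(2) / 10, 0, 8), c(0, 10, 20, 30))
  expect_equal(as.vector(tc$values), c(8, 4, 2, 1))
  expect_error(simulate_decay(induction_model(0.1, 0, 0), c(0, 5)),
               "x0 > 0")
})

test_that("fit_induction round-trips the simulator and flags flat input", {
  m <- induction_model(0.1, 0.1 * 16, 1)
  tc <- as_fold_course(simulate_induction(m, c(0, 5, 10, 15, 30, 45)))
  fit <- fit_induction(tc)
  expect_true(fit$converged)
  expect_equal(fit$alpha_hat, 0.1, tolerance = 1e-4 / 0.1)
  expect_equal(fit$fss_hat, 16, tolerance = 0.01 / 16)
  expect_lt(abs(fit$alpha_hat - 0.1) / 0.1, 0.001)

  flat <- time_course("flat", c(0, 5, 10, 20), rep(1, 4),
                      scale = "fold_over_t0")
  ffit <- fit_induction(flat)
  expect_false(ffit$converged)
  expect_equal(ffit$fss_hat, 1)

  expect_error(fit_induction(time_course("x", c(0, 5, 10), rep(2, 3),
                                         scale = "fold_over_t0")),
               ">= 4 distinct time points")
})

test_that("fit_induction recovers alpha from noisy replicated data", {
  m <- induction_model(0.1, 0.1 * 16, 1)
  errs <- vapply(1:50, function(s) {
    cfg <- generator_config(seed = s, noise_cv = 0.05, n_replicates = 4)
    fit <- fit_induction(gen_timecourse(cfg, m, "induction",
                                        "fold_over_t0"))
    abs(fit$alpha_hat - 0.1) / 0.1
  }, numeric(1L))
  expect_lt(median(errs), 0.10)
})

test_that("fit_decay recovers half-lives and hits the no-decay sentinel", {
  tc <- simulate_decay(induction_model(log(2) / 25, 0, 1), seq(0, 45, 5))
  expect_equal(fit_decay(tc)$half_life, 25, tolerance = 1e-9)

  # log2 values falling exactly 1 unit per 10 min
  tc <- time_course("x", seq(0, 40, 10), 2^(-seq(0, 40, 10) / 10),
                    scale = "absolute")
  expect_equal(fit_decay(tc)$half_life, 10, tolerance = 1e-12)

  flat <- time_course("x", c(0, 10, 20), rep(3, 3), scale = "absolute")
  fd <- fit_decay(flat)
  expect_equal(fd$slope_log2, 0, tolerance = 1e-12)
  expect_identical(fd$half_life, Inf)

  bad <- time_course("x", c(0, 10, 20), c(4, 0, 1), scale = "absolute")
  expect_error(fit_decay(bad), "time 10")
})

test_that("compare_decay returns the analytic slope difference", {
  tA <- simulate_decay(induction_model(log(2) / 25, 0, 4), seq(0, 45, 5),
                       condition = "control")
  tB <- simulate_decay(induction_model(log(2) / 12.5, 0, 4), seq(0, 45, 5),
                       condition = "tethered")
  cmp <- compare_decay(tA, tB)
  expect_equal(cmp$half_life_a, 25, tolerance = 1e-9)
  expect_equal(cmp$half_life_b, 12.5, tolerance = 1e-9)
  expect_equal(cmp$interaction, -1 / 12.5 + 1 / 25, tolerance = 1e-9)
  expect_lt(cmp$interaction_p, 0.05)

  same <- compare_decay(tA, simulate_decay(
    induction_model(log(2) / 25, 0, 4), seq(0, 45, 5), condition = "dup"))
  expect_equal(same$interaction, 0, tolerance = 1e-12)
  expect_equal(same$interaction_p, 1)
  expect_error(compare_decay(tA, tA), "distinct labels")
})

test_that("decay-rate comparison has calibrated type-I error", {
  m <- induction_model(log(2) / 25, 0, 8)
  ps <- vapply(1:100, function(s) {
    ca <- gen_timecourse(
      generator_config(seed = s, noise_cv = 0.05, n_replicates = 3,
                       time_grid = seq(0, 45, 5)), m, "decay",
      condition = "A")
    cb <- gen_timecourse(
      generator_config(seed = s + 50000, noise_cv = 0.05,
                       n_replicates = 3, time_grid = seq(0, 45, 5)),
      m, "decay", condition = "B")
    compare_decay(ca, cb)$interaction_p
  }, numeric(1L))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("mechanism classifier separates beta from alpha changes", {
  grid <- c(0, 5, 10, 15, 30, 45)
  ctrl <- as_fold_course(simulate_induction(classifier_base_model(), grid),
                         condition = "ctrl")
  # 4x transcription rate: constant upward shift of ~log2(4)
  up <- as_fold_course(
    simulate_induction(classifier_base_model(beta_scale = 4), grid),
    condition = "beta4")
  call_up <- classify_mechanism(ctrl, up)
  expect_identical(call_up$call, "transcription_shift")
  expect_equal(call_up$mean_shift_log2, 2.0, tolerance = 0.1 / 2.0)

  # halved decay rate: offset grows with time
  slow <- as_fold_course(
    simulate_induction(classifier_base_model(alpha_scale = 0.5), grid),
    condition = "alpha05")
  d <- log2(rowMeans(slow$values)) - log2(rowMeans(ctrl$values))
  expect_true(all(diff(d) > 0))
  expect_identical(classify_mechanism(ctrl, slow)$call, "decay_shift")

  # identity
  dup <- as_fold_course(simulate_induction(classifier_base_model(), grid),
                        condition = "dup")
  same <- classify_mechanism(ctrl, dup)
  expect_identical(same$call, "indistinguishable")
  expect_equal(same$mean_shift_log2, 0, tolerance = 1e-12)

  short <- as_fold_course(
    simulate_induction(classifier_base_model(), c(0, 5, 10)),
    condition = "short")
  expect_error(classify_mechanism(
    as_fold_course(simulate_induction(classifier_base_model(),
                                      c(0, 5, 10)), condition = "c2"),
    short), ">= 3 time points")
})

test_that("classifier interpolates a mismatched time grid", {
  ctrl <- as_fold_course(
    simulate_induction(classifier_base_model(), c(0, 5, 10, 15, 30, 45)),
    condition = "ctrl")
  trt <- as_fold_course(
    simulate_induction(classifier_base_model(beta_scale = 4),
                       c(0, 4, 8, 16, 32, 48)),
    condition = "trt")
  # the offset estimate survives re-gridding; the trend test is left
  # alone here because piecewise-linear re-gridding of a noiseless
  # curve leaves curvature artifacts in the offsets
  call <- classify_mechanism(ctrl, trt)
  expect_equal(call$mean_shift_log2, 2.0, tolerance = 0.1)
})
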
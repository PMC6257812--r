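test_that("causal filtering reproduces analytic white-noise variance", {
  sch <- switching_schedule(400, 400, 4, 4)
  tr <- gen_brownian_intensity(400, sch, seed = 1)
  dv <- derivative_series(tr)
  k <- std_kernel()
  xs <- filter_stimulus(k, dv)
  w <- rep(rev(k$weights), each = 2)  # per-frame coefficients
  expected <- sum(w^2) * 6 * 4        # frame variance = 6 * sigma2_update
  v <- var(xs$values[xs$valid])
  # the filtered series is autocorrelated over the 4 s support, so the
  # sample variance of ~8000 frames carries a relative SE near 0.1
  expect_lt(abs(v / expected - 1), 0.3)
  # zero kernel gives an all-zero signal
  k0 <- kernel(k$lag, k$weights * 0)
  expect_true(all(filter_stimulus(k0, dv)$values == 0))
  # identity kernel on a matched 0.1 s grid returns the input
  dv01 <- derivative_series(tr, frame_period = 0.1)
  kid <- kernel(-0.05, 1)
  out <- filter_stimulus(kid, dv01)
  expect_equal(out$values[out$valid], dv01$values[out$valid])
})

test_that("turn-triggered average vanishes for stimulus-independent turns", {
  sch <- switching_schedule(300, 300, 4, 4)
  tr <- gen_brownian_intensity(300, sch, seed = 2)
  dv <- derivative_series(tr)
  ds <- sim_simple(300, 40, seed = 3, rate = static_rate(3 / 60, 0, 0))$data
  ds$experiments[[1]]$stimulus <- NULL
  tta <- turn_triggered_average(ds, dv)
  bb <- suppressWarnings(bootstrap_tta(ds, dv, n_boot = 50, seed = 4))
  expect_true(mean(abs(tta$weights) < 3 * bb$band) > 0.9)
})

test_that("TTA recovers the generating kernel shape", {
  s <- sim_simple(900, 50, seed = 5,
                  rate = static_rate(3 / 60, 0.3, 0, form = "exp_linear"))
  tta <- turn_triggered_average(s$data, s$deriv)
  k <- std_kernel()
  pre <- round(tta$lag, 3) >= round(min(k$lag), 3) & tta$lag < 0
  truth <- k$weights[match(round(tta$lag[pre], 3), round(k$lag, 3))]
  expect_gt(cor(tta$weights[pre], truth), 0.9)
  expect_gt(attr(tta, "n_turns"), 1000)
})

test_that("bootstrap band behaves like a hierarchical SD estimate", {
  st <- sim_switching_study(2, 15, 240, seed = 6)
  bb <- bootstrap_tta(st$data, st$derivs, n_boot = 40, seed = 7)
  expect_true(all(bb$band >= 0))
  # duplicating the experiments shrinks the band roughly as 1/sqrt(k)
  dup <- st$data
  dup$experiments <- c(dup$experiments, dup$experiments,
                       dup$experiments, dup$experiments)
  bb4 <- bootstrap_tta(dup, c(st$derivs, st$derivs, st$derivs, st$derivs),
                       n_boot = 40, seed = 7)
  ratio <- median(bb4$band / bb$band)
  expect_gt(ratio, 0.25); expect_lt(ratio, 0.8)
  expect_warning(b1 <- bootstrap_tta(st$data, st$derivs, n_boot = 1,
                                     seed = 8),
                 "single replicate")
  expect_true(all(b1$band == 0))
})

test_that("Gaussian smoothing preserves mass and spreads a spike", {
  w <- rep(0, 40); w[20] <- 1
  k <- kernel(seq(-3.95, -0.05, by = 0.1), w)
  sm <- smooth_tta(k, sigma = 0.25)
  expect_equal(sum(sm$weights), 1, tolerance = 1e-3)
  lag <- k$lag
  mu <- sum(lag * sm$weights) / sum(sm$weights)
  sdv <- sqrt(sum((lag - mu)^2 * sm$weights) / sum(sm$weights))
  expect_equal(sdv, 0.25, tolerance = 0.02)
  tiny <- smooth_tta(k, sigma = 0.01)
  expect_equal(tiny$weights, k$weights, tolerance = 1e-6)
  expect_error(smooth_tta(k, sigma = 0), "positive")
})

test_that("kernel normalization gives unit low-variance output and 9x high", {
  st <- sim_switching_study(1, 10, 300, seed = 9, alphas = NULL)
  kn <- normalize_kernel(turn_triggered_average(st$data, st$derivs[[1]]),
                         st$derivs[[1]])
  xs <- suppressMessages(filter_stimulus(kn, st$derivs[[1]]))
  t <- (seq_along(xs$values) - 1) / 20
  cond <- condition_at(st$schedule, t)
  keep <- analysis_mask(300, 1 / 20, st$schedule, 0, 10)
  lowv <- var(xs$values[xs$valid & keep & cond == "low"])
  highv <- var(xs$values[xs$valid & keep & cond == "high"])
  expect_lt(abs(highv / lowv - 9), 2)
  # idempotence / scale invariance
  kn2 <- normalize_kernel(kn, st$derivs[[1]])
  expect_equal(kn2$weights, kn$weights, tolerance = 0.05)
  kd <- kernel(kn$lag, kn$weights * 2)
  expect_equal(normalize_kernel(kd, st$derivs[[1]])$weights, kn2$weights,
               tolerance = 1e-9)
})

test_that("binned turn rate arithmetic follows the counting formula", {
  d1 <- navadapt:::new_behavior_dataset(list(list(
    experiment_id = 1, stimulus = NULL,
    larvae = list(list(larva_id = 1,
                       run_intervals = data.frame(t0 = 0, t1 = 60),
                       turn_times = 60)))), 60, 1 / 20)
  fs <- structure(list(values = rnorm(1200), valid = rep(TRUE, 1200),
                       frame_period = 1 / 20, schedule = NULL),
                  class = "filtered_signal")
  br <- binned_turn_rate(d1, fs, n_bins = 1)
  expect_equal(br$n_run, 1200)
  expect_equal(br$n_turn, 1)
  expect_equal(br$rate, 1)       # 60 * (1/1200) * 20 = 1 min^-1
  expect_equal(br$sigma_rate, 1)
})

test_that("binned rates agree with the generating rate function", {
  s <- sim_simple(900, 50, seed = 10)
  br <- binned_turn_rate(s$data, s$filtered, n_bins = 8)
  pred <- 60 * rate_eval(std_rate(), br$center)
  ok <- abs(br$rate - pred) < 2 * br$sigma_rate
  expect_gt(mean(ok), 0.7)
  expect_equal(sum(br$n_turn), n_turns(s$data) -
                 sum(vapply(s$data$experiments[[1]]$larvae, function(l)
                   sum(!s$filtered$valid[navadapt:::turn_frame_index(
                     l$turn_times, 1 / 20)]), numeric(1))))
  # zero-turn bins report zero rate and uncertainty
  s0 <- sim_simple(120, 3, seed = 11, rate = static_rate(0.5 / 60, 0, 0))
  br0 <- binned_turn_rate(s0$data, s0$filtered, n_bins = 8)
  z <- br0$n_turn == 0
  if (any(z)) {
    expect_true(all(br0$rate[z] == 0))
    expect_true(all(br0$sigma_rate[z] == 0))
  }
})

test_that("derivative pipeline is invariant to constant intensity offsets", {
  sch <- switching_schedule(120, 120, 1, 1)
  tr <- gen_brownian_intensity(120, sch, seed = 12)
  tr2 <- tr
  tr2$intensities <- tr$intensities + 3  # still in range with sigma2 = 1
  expect_equal(derivative_series(tr2)$values, derivative_series(tr)$values,
               tolerance = 1e-12)
})
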
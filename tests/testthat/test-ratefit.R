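make_const_dataset <- function(duration, n_larvae, lam, seed) {
  sim_simple(duration, n_larvae, seed = seed, rate = static_rate(lam, 0, 0))
}

test_that("log-likelihood evaluates the point-process formula exactly", {
  # zero turns, constant rate r over N frames: LL = -r dt N
  d0 <- navadapt:::new_behavior_dataset(list(list(
    experiment_id = 1, stimulus = NULL,
    larvae = list(list(larva_id = 1,
                       run_intervals = data.frame(t0 = 0, t1 = 10),
                       turn_times = numeric(0))))), 10, 1 / 20)
  fs <- structure(list(values = rep(0, 200), valid = rep(TRUE, 200),
                       frame_period = 1 / 20, schedule = NULL),
                  class = "filtered_signal")
  r <- function(x) rep(0.8, length(x))
  expect_equal(loglik(d0, fs, r), -0.8 * (1 / 20) * 200)
  # single turn frame with r dt = 1/e: LL = log(r dt) - r dt = -1 - 1/e
  d1 <- navadapt:::new_behavior_dataset(list(list(
    experiment_id = 1, stimulus = NULL,
    larvae = list(list(larva_id = 1,
                       run_intervals = data.frame(t0 = 0, t1 = 0.05),
                       turn_times = 0.05)))), 0.05, 1 / 20)
  fs1 <- structure(list(values = 0, valid = TRUE, frame_period = 1 / 20,
                        schedule = NULL), class = "filtered_signal")
  expect_equal(loglik(d1, fs1, function(x) rep(20 / exp(1), length(x))),
               -1 - 1 / exp(1))
  # non-positive rate at a turn frame is flagged as -Inf
  expect_identical(as.numeric(loglik(d1, fs1, function(x) rep(0, length(x)))),
                   -Inf)
})

test_that("point-process LL matches the Bernoulli LL for small r dt", {
  s <- make_const_dataset(300, 10, 2 / 60, seed = 1)
  pf <- navadapt:::pooled_run_frames(s$data, s$filtered)
  r <- 2 / 60; dt <- 1 / 20
  ll_pp <- loglik(s$data, s$filtered, function(x) rep(r, length(x)))
  ll_bern <- sum(pf$turn) * log(1 - exp(-r * dt)) - sum(!pf$turn) * r * dt
  # agreement to first order in r dt (r dt ~ 0.0017)
  expect_lt(abs(ll_pp - ll_bern) / abs(ll_bern), r * dt)
})

test_that("LL is additive over experiments", {
  st <- sim_switching_study(2, 8, 240, seed = 2)
  r <- std_rate()
  ll_all <- loglik(st$data, st$filtered, r)
  ll_each <- vapply(1:2, function(i) {
    d <- st$data; d$experiments <- d$experiments[i]
    loglik(d, st$filtered[[i]], r)
  }, numeric(1))
  expect_equal(ll_all, sum(ll_each), tolerance = 1e-9)
})

test_that("static MLE recovers constant-rate data and beats the truth's LL", {
  s <- make_const_dataset(1200, 40, 3 / 60, seed = 3)
  fit <- fit_static_rate(s$data, s$filtered)
  se <- attr(fit, "se")
  expect_lt(abs(log(fit$lam0) - log(3 / 60)), 2.5 * se[1])
  expect_lt(abs(fit$b), 2.5 * se[2])
  expect_lt(abs(fit$c), 2.5 * se[3])
  expect_gte(attr(fit, "loglik") + 1e-6,
             loglik(s$data, s$filtered, static_rate(3 / 60, 0, 0)))
})

test_that("no coarse grid point beats the optimizer", {
  s <- make_const_dataset(300, 15, 3 / 60, seed = 4)
  fit <- fit_static_rate(s$data, s$filtered)
  best <- attr(fit, "loglik")
  for (lam in c(1, 2, 3, 4, 6) / 60)
    for (b in seq(-0.4, 0.4, by = 0.2))
      for (cc in seq(-0.1, 0.1, by = 0.05)) {
        ll <- loglik(s$data, s$filtered, static_rate(max(lam, 1e-9), b, cc))
        expect_lte(ll, best + 1e-6)
      }
})

test_that("rescaling models nest the null model at alpha = 1", {
  x <- seq(-3, 3, length.out = 31)
  base <- navadapt:::rescaling_rate("null", 0.05, 0.25, 0.03, NA, x, "low")
  for (kd in c("input", "output", "recentered_output"))
    expect_equal(navadapt:::rescaling_rate(kd, 0.05, 0.25, 0.03, 1, x,
                                           rep("low", length(x))),
                 base, tolerance = 1e-12)
})

test_that("null model is BIC-preferred on non-adapting data", {
  st <- sim_switching_study(2, 25, 480, half_period = 60, alphas = NULL,
                            seed = 5)
  keep <- analysis_mask(480, 1 / 20, st$schedule, 60, 15)
  fn <- fit_rescaling_model(st$data, st$filtered, "null", keep)
  fi <- fit_rescaling_model(st$data, st$filtered, "input", keep)
  expect_gte(fi$loglik + 1e-6, fn$loglik)      # nesting
  expect_lt(fi$loglik - fn$loglik, 4)          # no real adaptation signal
  expect_lt(bic(fn$loglik, fn$n_data, 3), bic(fi$loglik, fi$n_data, 4))
})

test_that("BIC formula and sample-size conventions", {
  expect_equal(bic(-100, 100, 4) - bic(-100, 100, 3), log(100))
  # counting frames (x20) instead of seconds shifts by log(20) ~ 3 per param
  shift <- (bic(-50, 2000 * 20, 4) - bic(-50, 2000 * 20, 3)) -
    (bic(-50, 2000, 4) - bic(-50, 2000, 3))
  expect_equal(shift, log(20))
  expect_lt(abs(log(20) - 3), 0.01)
  expect_error(bic(-10, 0, 3), "n_data")
})

test_that("jackknife normalization is exact for equal-length test sets", {
  st <- sim_switching_study(1, 12, 240, seed = 6)
  # duplicate the same experiment: all test sets have identical duration
  d <- st$data
  d$experiments <- list(d$experiments[[1]], d$experiments[[1]],
                        d$experiments[[1]])
  for (i in 1:3) d$experiments[[i]]$experiment_id <- i
  filt <- list(st$filtered[[1]], st$filtered[[1]], st$filtered[[1]])
  keep <- analysis_mask(240, 1 / 20, st$schedule, 60, 10)
  jk <- jackknife_compare(d, filt, kinds = c("null", "input"),
                          n_fit = 2, n_test = 1, keep = keep)
  expect_equal(jk$ll_norm, jk$ll, tolerance = 1e-9)
  expect_equal(nrow(jk), 6)  # 3 permutations x 2 models
  # identical held-out data under identical training sets: delta LL = 0
  nulls <- jk$ll[jk$model == "null"]
  expect_lt(diff(range(nulls)), 1e-6)
  expect_error(jackknife_compare(d, filt, n_fit = 1, n_test = 1),
               "n_fit")
})
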
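#' Static turn-rate nonlinearity
#'
#' The static stage of the LNP cascade: an exponential of a polynomial of
#' the filtered signal, \eqn{\lambda(x) = \lambda_0 \exp(b x + c x^2)}.
#' Rates are held in events/second internally; reported and plotted rates
#' are in min^-1 (factor 60).
#'
#' @param lam0 baseline rate lambda0 in s^-1 (non-negative; 0 gives a
#'   degenerate model that never turns, usable for simulation only).
#' @param b linear coefficient (per unit filtered signal).
#' @param c quadratic coefficient (0 for the exp-linear form).
#' @param form `"exp_quadratic"` or `"exp_linear"` (forces c = 0).
#' @export
static_rate <- function(lam0, b = 0, c = 0,
                        form = c("exp_quadratic", "exp_linear")) {
  form <- match.arg(form)
  if (lam0 < 0) stop("lam0 must be non-negative")
  if (form == "exp_linear") c <- 0
  structure(list(lam0 = lam0, b = b, c = c, form = form),
            class = "static_rate")
}

#' @export
print.static_rate <- function(x, ...) {
  cat(sprintf("<static_rate %s> lam0 = %.3f min^-1, b = %.3f, c = %.3f\n",
              x$form, 60 * x$lam0, x$b, x$c))
  invisible(x)
}

#' Evaluate a static rate function
#'
#' @param rate a [static_rate()].
#' @param x filtered-signal values.
#' @return rate in s^-1.
#' @export
rate_eval <- function(rate, x) {
  rate$lam0 * exp(rate$b * x + rate$c * x^2)
}

#' Gain trajectory
#'
#' Per-frame input gain alpha(t) (and optionally beta(t) for a second
#' channel) used to generate or describe adapting behavior,
#' r(t, x) = lambda(alpha(t) x).
#'
#' @param alpha numeric vector of per-frame gains (>= 0).
#' @param frame_period frame interval (s).
#' @param beta optional per-frame gain for the second channel.
#' @export
gain_trajectory <- function(alpha, frame_period = 1 / 20, beta = NULL) {
  if (any(alpha < 0)) stop("gains must be non-negative")
  if (!is.null(beta) && (length(beta) != length(alpha) || any(beta < 0)))
    stop("beta must match alpha in length and be non-negative")
  structure(list(frame_period = frame_period, alpha = alpha, beta = beta),
            class = "gain_trajectory")
}

#' Instant-switch ("step control") gain
#'
#' Builds the control gain used to check that estimator dynamics are not
#' analysis artifacts: the input rescaling switches instantly at every
#' variance switch, taking the value mapped to the active condition.
#'
#' @param schedule a [variance_schedule()].
#' @param alpha_by_condition named numeric, gains for `high` and `low`
#'   variance conditions (e.g. `c(high = 1, low = 2)`).
#' @param frame_period frame interval (s).
#' @param n_frames number of frames (defaults to schedule duration / frame).
#' @export
step_control_gain <- function(schedule, alpha_by_condition = c(high = 1, low = 2),
                              frame_period = 1 / 20, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- round(schedule$duration / frame_period)
  cond <- condition_at(schedule, (seq_len(n_frames) - 1) * frame_period)
  if (!all(unique(cond) %in% names(alpha_by_condition)))
    stop("alpha_by_condition is missing an entry for a scheduled condition")
  gain_trajectory(unname(alpha_by_condition[cond]), frame_period)
}

new_behavior_dataset <- function(experiments, duration,
                                 frame_period = 1 / 20) {
  for (e in experiments) {
    for (l in e$larvae) {
      ri <- l$run_intervals
      if (nrow(ri) && (any(ri$t1 <= ri$t0) ||
                       any(diff(as.vector(t(ri[, c("t0", "t1")]))) < -1e-9)))
        stop("run intervals must be ordered and disjoint")
      if (length(l$turn_times) &&
          !all(vapply(l$turn_times,
                      function(tt) any(abs(ri$t1 - tt) < 1e-9), logical(1))))
        stop("every turn time must equal the end of a run interval")
    }
  }
  structure(list(experiments = experiments, duration = duration,
                 frame_period = frame_period),
            class = "behavior_dataset")
}

#' @export
print.behavior_dataset <- function(x, ...) {
  nl <- sum(vapply(x$experiments, function(e) length(e$larvae), integer(1)))
  nt <- n_turns(x)
  cat(sprintf("<behavior_dataset> %d experiment(s), %d larvae, %d turns, %.0f s\n",
              length(x$experiments), nl, nt, x$duration))
  invisible(x)
}

#' Total number of turns in a dataset
#' @param data a `behavior_dataset`.
#' @export
n_turns <- function(data) {
  sum(vapply(data$experiments, function(e)
    sum(vapply(e$larvae, function(l) length(l$turn_times), integer(1))),
    integer(1)))
}

# Build one larva's run intervals from its turn frames (1-based, frame f
# covers ((f-1) dt, f dt]; the turn ends the run at time f*dt and the next
# run begins after `refractory` seconds).
larva_from_turn_frames <- function(id, turn_frames, duration, dt, refractory) {
  tt <- turn_frames * dt
  r_frames <- round(refractory / dt)
  starts <- c(0, (turn_frames + r_frames) * dt)
  ends <- c(tt, duration)
  keep <- starts < ends  # drop a zero-length trailing run
  list(larva_id = id,
       run_intervals = data.frame(t0 = starts[keep], t1 = ends[keep]),
       turn_times = tt)
}

sim_one_experiment <- function(rate_per_frame, n_larvae, duration, dt,
                               refractory, experiment_id, stimulus = NULL) {
  p <- 1 - exp(-rate_per_frame * dt)
  tf <- cpp_sim_turn_frames(p, n_larvae, round(refractory / dt))
  larvae <- lapply(seq_len(n_larvae), function(l)
    larva_from_turn_frames(l, tf[[l]], duration, dt, refractory))
  list(experiment_id = experiment_id, stimulus = stimulus, larvae = larvae)
}

#' Simulate Poisson turn decisions from an adaptive LNP model
#'
#' At each 1/20 s frame in a run, a turn occurs with probability
#' 1 - exp(-r dt) where r = lambda0 exp(b (alpha x) + c (alpha x)^2) is
#' evaluated on that frame's filtered signal and gain. After a turn the
#' larva is out of the run for `refractory` seconds (turn duration is not
#' modeled mechanistically; rate estimation conditions on run frames, so
#' results are insensitive to this choice), then a new run begins. All
#' larvae are independent and start running at t = 0.
#'
#' @param deriv a `derivative_series` (the model input).
#' @param kernel a `kernel` (see [turn_triggered_average()]); the filtered
#'   signal is its causal convolution with `deriv`.
#' @param rate a [static_rate()].
#' @param gain a [gain_trajectory()], or NULL for gain identically 1.
#' @param n_larvae number of larvae.
#' @param duration experiment duration (s).
#' @param seed integer RNG seed.
#' @param refractory out-of-run time after each turn (s).
#' @param experiment_id identifier stored with the experiment.
#' @return a `behavior_dataset` with one experiment (the filtered signal is
#'   attached to the experiment as `$stimulus`).
#' @export
simulate_turns <- function(deriv, kernel, rate, gain = NULL, n_larvae,
                           duration, seed = NULL, refractory = 2,
                           experiment_id = 1L) {
  stopifnot(inherits(rate, "static_rate"))
  dt <- deriv$frame_period
  n_frames <- round(duration / dt)
  if (length(deriv$values) < n_frames)
    stop("derivative series shorter than the requested duration")
  if (!is.null(seed)) set.seed(seed)
  xs <- filter_stimulus(kernel, deriv)
  x <- xs$values[seq_len(n_frames)]
  valid <- xs$valid[seq_len(n_frames)]
  alpha <- if (is.null(gain)) rep(1, n_frames) else gain$alpha
  if (length(alpha) < n_frames)
    stop("gain trajectory shorter than the experiment")
  r <- rate_eval(rate, alpha[seq_len(n_frames)] * x)
  r[!valid] <- 0  # no turns before the filter has full support
  exp1 <- sim_one_experiment(r, n_larvae, duration, dt, refractory,
                             experiment_id, stimulus = xs)
  new_behavior_dataset(list(exp1), duration, dt)
}

#' Simulate multisensory turn decisions
#'
#' Two-channel exp-linear LNP simulation with independent input rescaling
#' per channel: r = lambda0 exp(a alpha(t) x_o + b beta(t) x_L).
#'
#' @param xo,xl `filtered_signal` objects on the same frame grid (odor and
#'   light channels).
#' @param lam0 baseline rate (s^-1).
#' @param a,b channel coefficients.
#' @param gains a [gain_trajectory()] with both `alpha` and `beta` (NULL for
#'   both identically 1).
#' @param n_larvae,duration,seed,refractory,experiment_id as in
#'   [simulate_turns()].
#' @export
simulate_multisensory <- function(xo, xl, lam0, a, b, gains = NULL,
                                  n_larvae, duration, seed = NULL,
                                  refractory = 2, experiment_id = 1L) {
  if (abs(xo$frame_period - xl$frame_period) > 1e-12)
    stop("xo and xl must share the same frame grid")
  dt <- xo$frame_period
  n_frames <- round(duration / dt)
  if (length(xo$values) < n_frames || length(xl$values) < n_frames)
    stop("filtered signals shorter than the requested duration")
  if (!is.null(seed)) set.seed(seed)
  al <- if (is.null(gains)) rep(1, n_frames) else gains$alpha[seq_len(n_frames)]
  be <- if (is.null(gains) || is.null(gains$beta)) rep(1, n_frames)
        else gains$beta[seq_len(n_frames)]
  valid <- xo$valid[seq_len(n_frames)] & xl$valid[seq_len(n_frames)]
  r <- lam0 * exp(a * al * xo$values[seq_len(n_frames)] +
                  b * be * xl$values[seq_len(n_frames)])
  r[!valid] <- 0
  exp1 <- sim_one_experiment(r, n_larvae, duration, dt, refractory,
                             experiment_id,
                             stimulus = list(odor = xo, light = xl))
  new_behavior_dataset(list(exp1), duration, dt)
}

#' Simulate a multi-experiment study
#'
#' Convenience generator emulating the structure of a full variance-switching
#' study: each experiment gets a fresh Brownian stimulus realization drawn
#' under the same schedule, the population response is simulated from the
#' given LNP model, and the experiments are pooled into one dataset. The
#' study-scale defaults elsewhere in the package follow the reference
#' conditions (20 min experiments, ~40-50 larvae each, 60 s switching);
#' reduced scales are used in examples and tests.
#'
#' @param n_experiments number of experiments.
#' @param n_larvae larvae per experiment.
#' @param duration experiment duration (s).
#' @param schedule a [variance_schedule()] (per-experiment stimuli share it).
#' @param kernel the generating `kernel`.
#' @param rate the generating [static_rate()].
#' @param gain_fn NULL for no adaptation, or a function
#'   `(schedule, n_frames, deriv)` returning a [gain_trajectory()] (e.g. a
#'   wrapper around [step_control_gain()]).
#' @param seed integer seed; per-experiment streams are derived from it.
#' @param refractory out-of-run time after each turn (s).
#' @return a `behavior_dataset`; each experiment carries its own filtered
#'   signal in `$stimulus` and its derivative series in `$deriv`.
#' @export
simulate_study <- function(n_experiments, n_larvae, duration, schedule,
                           kernel, rate, gain_fn = NULL, seed = 1,
                           refractory = 2) {
  experiments <- vector("list", n_experiments)
  for (i in seq_len(n_experiments)) {
    set.seed((seed * 1000L + i) %% .Machine$integer.max)
    tr <- gen_brownian_intensity(duration, schedule)
    dv <- derivative_series(tr)
    n_frames <- round(duration / dv$frame_period)
    gain <- if (is.null(gain_fn)) NULL else gain_fn(schedule, n_frames, dv)
    ds <- simulate_turns(dv, kernel, rate, gain, n_larvae, duration,
                         refractory = refractory, experiment_id = i)
    e <- ds$experiments[[1]]
    e$deriv <- dv
    experiments[[i]] <- e
  }
  new_behavior_dataset(experiments, duration, 1 / 20)
}

# --- frame bookkeeping used by all analysis stages ---------------------------

# 1-based frame index of a turn at time tt: the frame ending at tt.
turn_frame_index <- function(turn_times, dt) {
  as.integer(round(turn_times / dt))
}

# Logical n_frames vector: frame f (covering ((f-1)dt, f dt]) is a run frame
# iff its start time lies inside a run interval [t0, t1). The turn frame is
# the last frame of its run and counts both as a run frame and a turn frame.
run_frame_mask <- function(larva, n_frames, dt) {
  mask <- logical(n_frames)
  ri <- larva$run_intervals
  for (k in seq_len(nrow(ri))) {
    f0 <- floor(ri$t0[k] / dt + 1e-9) + 1L
    f1 <- ceiling(ri$t1[k] / dt - 1e-9)
    if (f1 >= f0) mask[f0:min(f1, n_frames)] <- TRUE
  }
  mask
}
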
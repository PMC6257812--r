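#' @useDynLib navadapt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var dnorm optim optimize complete.cases
#' @importFrom utils head tail read.csv write.csv
NULL

new_stimulus_trace <- function(channel, update_period, intensities,
                               schedule, increments = NULL, kind = "walk") {
  stopifnot(update_period > 0, all(intensities >= 0 & intensities <= 255))
  structure(list(channel = channel, update_period = update_period,
                 intensities = intensities, schedule = schedule,
                 increments = increments, kind = kind,
                 duration = schedule$duration),
            class = "stimulus_trace")
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf(
    "<stimulus_trace '%s'> %s, %.0f s at %.4g s updates (%d values), mode %s\n",
    x$channel, x$kind, x$duration, x$update_period,
    length(x$intensities), x$schedule$mode))
  invisible(x)
}

#' Brownian random-walk light intensity
#'
#' Generates the intensity sequence used in the walk-stimulus experiments:
#' starting from I0 = 127, each 1/120 s update adds a Gaussian increment
#' N(0, sigma) whose variance comes from the active schedule segment, with
#' reflecting boundaries at 0 and 255 (I <- -I below 0, I <- 510 - I above
#' 255, applied iteratively). Sequences are kept in floating point; the
#' derivative of the walk is mean-zero white noise whose variance is set by
#' the schedule, while the levels themselves are approximately uniform on
#' [0, 255] in the long run.
#'
#' The returned trace stores the intensity at update times 0, 1/120, ...,
#' `duration` (so `duration * 120 + 1` values) and keeps the drawn
#' (pre-reflection) increments in `$increments` for diagnostics.
#'
#' @param duration experiment duration (s).
#' @param schedule a [variance_schedule()] with mode `increment_variance` or
#'   `triangle_sd`.
#' @param seed integer RNG seed (NULL to use the current RNG state).
#' @param channel channel label.
#' @param update_period update interval (s), 1/120 by default.
#' @param quantize if TRUE, round the stored intensities to integers (the
#'   hardware output format); analysis uses the floating-point values, so
#'   this defaults to FALSE.
#' @return a `stimulus_trace`.
#' @export
gen_brownian_intensity <- function(duration, schedule, seed = NULL,
                                   channel = "light",
                                   update_period = 1 / 120,
                                   quantize = FALSE) {
  if (duration <= 0) stop("duration must be positive")
  if (!inherits(schedule, "variance_schedule") ||
      !schedule$mode %in% c("increment_variance", "triangle_sd"))
    stop("schedule must have mode increment_variance or triangle_sd")
  if (abs(schedule$duration - duration) > 1e-9)
    stop("schedule does not cover the requested duration")
  if (!is.null(seed)) set.seed(seed)
  n_upd <- round(duration / update_period)
  # increment j updates the value at time (j-1)*up to the value at j*up;
  # its sigma is taken from the segment active at the update time j*up
  # (boundaries take effect at the first update at or after the switch)
  t_upd <- seq_len(n_upd) * update_period
  sig <- sigma_at(schedule, pmin(t_upd, duration - 1e-9))
  inc <- rnorm(n_upd, 0, sig)
  vals <- cpp_reflect_walk(inc, 127)
  if (quantize) vals <- round(vals)
  new_stimulus_trace(channel, update_period, vals, schedule,
                     increments = inc, kind = "walk")
}

#' Uncorrelated random light levels
#'
#' Generates the random-levels stimulus: a fresh intensity level is drawn
#' every 0.25 s from N(mean, sd) with sd from the active schedule segment;
#' out-of-range values are clipped to 0 or 255. The standard conditions use
#' mean 128 with sd 17 (low variance) or 51 (high variance).
#'
#' @param duration experiment duration (s).
#' @param mean mean intensity level.
#' @param sd_schedule a [variance_schedule()] with mode `level_sd`.
#' @param seed integer RNG seed.
#' @param channel channel label.
#' @param update_period level-update interval (s).
#' @return a `stimulus_trace` of kind `"levels"` (values at update times 0,
#'   0.25, ..., duration - 0.25; each level is held until the next update).
#' @export
gen_uncorrelated_intensity <- function(duration, mean = 128, sd_schedule,
                                       seed = NULL, channel = "light",
                                       update_period = 0.25) {
  if (duration <= 0) stop("duration must be positive")
  if (!inherits(sd_schedule, "variance_schedule") ||
      sd_schedule$mode != "level_sd")
    stop("sd_schedule must have mode level_sd")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / update_period)
  t_upd <- (seq_len(n) - 1) * update_period
  sdv <- schedule_value_at(sd_schedule, t_upd)
  if (any(sdv < 0)) stop("sd must be non-negative")
  vals <- rnorm(n, mean, sdv)
  vals <- pmin(pmax(vals, 0), 255)
  new_stimulus_trace(channel, update_period, vals, sd_schedule,
                     kind = "levels")
}

#' Correlated odor/light intensity pair
#'
#' Generates two Brownian intensity walks whose per-update increments
#' (s_o, s_l) each have variance sigma2 and scheduled correlation c:
#' \deqn{s_o = \sqrt{1-|c|}\, x_1 + \sqrt{|c|}\, x_3, \quad
#'       s_l = \sqrt{1-|c|}\, x_2 \pm \sqrt{|c|}\, x_3,}
#' with x1, x2, x3 independent N(0, sigma2) and the sign of the shared term
#' following the sign of c. The combined coordinate
#' \eqn{u = (s_o + s_l)/\sqrt{2}} then has variance \eqn{\sigma^2 (1 + c)},
#' so switching c between +0.8 and -0.8 at sigma2 = 5 switches the variance
#' of u between 9 and 1 while each marginal stays at 5.
#'
#' @param duration experiment duration (s).
#' @param sigma2 per-update increment variance of each channel.
#' @param corr_schedule a [variance_schedule()] with mode `correlation`.
#' @param seed integer RNG seed.
#' @param update_period update interval (s).
#' @return list with `stimulus_trace` elements `odor` and `light`.
#' @export
gen_correlated_pair <- function(duration, sigma2 = 5, corr_schedule,
                                seed = NULL, update_period = 1 / 120) {
  if (duration <= 0) stop("duration must be positive")
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  if (!inherits(corr_schedule, "variance_schedule") ||
      corr_schedule$mode != "correlation")
    stop("corr_schedule must have mode correlation")
  if (!is.null(seed)) set.seed(seed)
  n_upd <- round(duration / update_period)
  t_upd <- seq_len(n_upd) * update_period
  cc <- schedule_value_at(corr_schedule, pmin(t_upd, duration - 1e-9))
  if (any(abs(cc) > 1)) stop("|correlation| must be <= 1")
  s <- sqrt(sigma2)
  x1 <- rnorm(n_upd, 0, s); x2 <- rnorm(n_upd, 0, s); x3 <- rnorm(n_upd, 0, s)
  a <- sqrt(1 - abs(cc)); b <- sqrt(abs(cc))
  so <- a * x1 + b * x3
  sl <- a * x2 + sign(cc) * b * x3
  odor <- new_stimulus_trace("odor", update_period,
                             cpp_reflect_walk(so, 127), corr_schedule,
                             increments = so, kind = "walk")
  light <- new_stimulus_trace("light", update_period,
                              cpp_reflect_walk(sl, 127), corr_schedule,
                              increments = sl, kind = "walk")
  list(odor = odor, light = light)
}

#' Sinusoidal gas-concentration background
#'
#' The natural CO2 background: concentration(t) = mu + A sin(2 pi t / period),
#' sampled exactly on the 20 Hz behavior frame grid. The standard settings
#' are mu = 5%, period = 20 s, with A = 1% (low variance) or 4% (high).
#'
#' @param mu mean concentration (percent).
#' @param amplitude oscillation amplitude A (percent), `0 <= A <= mu`.
#' @param period oscillation period (s).
#' @param duration trace duration (s).
#' @param frame_period sampling interval (s).
#' @return list of class `concentration_trace` with `times` and
#'   `concentration`.
#' @export
gen_sinusoid_background <- function(mu = 5, amplitude = 1, period = 20,
                                    duration, frame_period = 1 / 20) {
  if (amplitude < 0 || amplitude > mu)
    stop("need 0 <= amplitude <= mu (concentration cannot go negative)")
  if (duration <= 0 || period <= 0) stop("duration and period must be positive")
  times <- seq(0, duration - frame_period, by = frame_period)
  structure(list(times = times,
                 concentration = mu + amplitude * sin(2 * pi * times / period),
                 mu = mu, amplitude = amplitude, period = period),
            class = "concentration_trace")
}

#' Per-frame intensity derivative
#'
#' Resamples a walk trace from its update grid to the 20 Hz behavior frame
#' grid: the value of frame k is the summed post-reflection intensity change
#' over the 6 updates falling in frame k, i.e. I(k/20) - I((k-1)/20). The
#' series telescopes, so its total sum equals the final minus initial
#' intensity.
#'
#' @param trace a `stimulus_trace` of kind `"walk"`.
#' @param frame_period behavior frame interval (s), 1/20 by default.
#' @return list of class `derivative_series` with `frame_period`, `values`
#'   (length duration * 20) and the trace's schedule.
#' @export
derivative_series <- function(trace, frame_period = 1 / 20) {
  stopifnot(inherits(trace, "stimulus_trace"))
  m <- frame_period / trace$update_period
  if (abs(m - round(m)) > 1e-8 || m < 1)
    stop("frame period must be an integer multiple of the update period")
  m <- round(m)
  n_frames <- (length(trace$intensities) - 1L) %/% m
  idx <- seq(1L, by = m, length.out = n_frames + 1L)
  vals <- diff(trace$intensities[idx])
  structure(list(frame_period = frame_period, values = vals,
                 schedule = trace$schedule, kind = "derivative"),
            class = "derivative_series")
}

#' Per-frame intensity level (mean-subtracted option)
#'
#' Resamples a random-levels trace onto the 20 Hz frame grid by holding each
#' level until its next update. Used as the model input for the
#' uncorrelated-levels stimulus, for which reverse correlation operates on
#' the (mean-subtracted) intensity itself rather than its derivative.
#'
#' @param trace a `stimulus_trace` of kind `"levels"`.
#' @param frame_period behavior frame interval (s).
#' @param subtract_mean subtract the stimulus mean (default TRUE).
#' @return a `derivative_series`-shaped object of kind `"level"`.
#' @export
intensity_series <- function(trace, frame_period = 1 / 20,
                             subtract_mean = TRUE) {
  stopifnot(inherits(trace, "stimulus_trace"))
  n_frames <- round(trace$duration / frame_period)
  t_fr <- (seq_len(n_frames) - 1) * frame_period
  idx <- pmin(floor(t_fr / trace$update_period) + 1L,
              length(trace$intensities))
  vals <- trace$intensities[idx]
  if (subtract_mean) vals <- vals - mean(trace$intensities)
  structure(list(frame_period = frame_period, values = vals,
                 schedule = trace$schedule, kind = "level"),
            class = "derivative_series")
}

#' Frame times of a derivative series
#'
#' Frame k of a derivative series covers ((k-1) dt, k dt]; by convention the
#' frame is stamped at its left edge (k-1) dt, matching 0-based frame
#' indexing of behavior frames.
#' @param deriv a `derivative_series`.
#' @export
frame_times <- function(deriv) {
  (seq_along(deriv$values) - 1) * deriv$frame_period
}
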
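#' Variance schedules
#'
#' A variance schedule describes how a stimulus statistic evolves over an
#' experiment. Four modes are supported:
#' \describe{
#'   \item{increment_variance}{`value` is the variance \eqn{\sigma^2} of the
#'     per-update Gaussian increment of a Brownian intensity walk.}
#'   \item{level_sd}{`value` is the standard deviation of independently drawn
#'     intensity levels (one new level per 0.25 s update).}
#'   \item{correlation}{`value` is the correlation coefficient \eqn{c \in
#'     [-1, 1]} between per-update increments of a correlated channel pair.}
#'   \item{triangle_sd}{the per-update increment standard deviation
#'     \eqn{\sigma(t)} rises and falls as a periodic triangle wave between
#'     `sigma_min` and `sigma_max`; the cycle starts at `sigma_min`.}
#' }
#' Segments must be contiguous, non-overlapping, and cover `[0, duration)`.
#'
#' @param mode one of `"increment_variance"`, `"level_sd"`, `"correlation"`,
#'   `"triangle_sd"`.
#' @param segments data frame with columns `t0`, `t1` (seconds) and `value`.
#'   Ignored for `triangle_sd`.
#' @param duration experiment duration in seconds (required for
#'   `triangle_sd`; otherwise inferred from the last segment).
#' @param period,sigma_min,sigma_max triangle-wave parameters (seconds,
#'   intensity units per update).
#' @return an object of class `variance_schedule`.
#' @export
variance_schedule <- function(mode, segments = NULL, duration = NULL,
                              period = 120, sigma_min = 1, sigma_max = 3) {
  mode <- match.arg(mode, c("increment_variance", "level_sd", "correlation",
                            "triangle_sd"))
  if (mode == "triangle_sd") {
    if (is.null(duration) || duration <= 0)
      stop("triangle_sd schedule requires a positive duration")
    if (sigma_min < 0 || sigma_max < sigma_min)
      stop("need 0 <= sigma_min <= sigma_max")
    segments <- data.frame(t0 = 0, t1 = duration, value = NA_real_)
  } else {
    if (is.null(segments) || nrow(segments) == 0L)
      stop("schedule requires at least one segment")
    segments <- segments[order(segments$t0), , drop = FALSE]
    if (any(abs(segments$t1[-nrow(segments)] - segments$t0[-1]) > 1e-9))
      stop("schedule segments must be contiguous and non-overlapping")
    if (segments$t0[1] != 0)
      stop("schedule must start at t = 0")
    if (mode %in% c("increment_variance", "level_sd") &&
        any(segments$value < 0))
      stop("variance/sd values must be non-negative")
    if (mode == "correlation" && any(abs(segments$value) > 1))
      stop("|correlation| must be <= 1")
    if (is.null(duration)) duration <- segments$t1[nrow(segments)]
    if (abs(segments$t1[nrow(segments)] - duration) > 1e-9)
      stop("schedule segments must cover [0, duration)")
  }
  structure(list(mode = mode, segments = segments, duration = duration,
                 period = period, sigma_min = sigma_min,
                 sigma_max = sigma_max),
            class = "variance_schedule")
}

#' Alternating high/low schedule
#'
#' Builds the square-wave schedule of variance-switching experiments: the
#' scheduled value alternates between `high` and `low` every `half_period`
#' seconds (60 s in the slow-switching experiments, 20 s in the
#' fast-switching ones).
#'
#' @param duration experiment duration (s).
#' @param half_period time between switches (s).
#' @param high,low the scheduled values in the two conditions.
#' @param mode schedule mode (see [variance_schedule()]).
#' @param first which condition is active at t = 0.
#' @export
switching_schedule <- function(duration, half_period, high, low,
                               mode = "increment_variance",
                               first = c("high", "low")) {
  first <- match.arg(first)
  n_seg <- ceiling(duration / half_period)
  t0 <- (seq_len(n_seg) - 1) * half_period
  t1 <- pmin(t0 + half_period, duration)
  vals <- rep(c(high, low), length.out = n_seg)
  if (first == "low") vals <- rep(c(low, high), length.out = n_seg)
  variance_schedule(mode, data.frame(t0 = t0, t1 = t1, value = vals),
                    duration = duration)
}

#' Scheduled value at given times
#'
#' Returns the value of the active segment at each time. Segment boundaries
#' take effect at the first update at or after the segment start, which is
#' what indexing by `t0 <= t < t1` implements. For `triangle_sd` schedules
#' the instantaneous standard deviation of the triangle wave is returned.
#'
#' @param schedule a [variance_schedule()].
#' @param times numeric vector of times (s).
#' @export
schedule_value_at <- function(schedule, times) {
  stopifnot(inherits(schedule, "variance_schedule"))
  if (schedule$mode == "triangle_sd") {
    ph <- (times %% schedule$period) / schedule$period  # 0..1, starts rising
    tri <- 1 - abs(2 * ph - 1)                          # 0 -> 1 -> 0
    return(schedule$sigma_min + (schedule$sigma_max - schedule$sigma_min) * tri)
  }
  seg <- schedule$segments
  idx <- findInterval(times, seg$t0)
  idx[idx < 1L] <- NA_integer_
  out <- seg$value[idx]
  out[times >= schedule$duration | times < 0] <- NA_real_
  out
}

#' Per-update increment standard deviation at given times
#'
#' For walk generation: maps the scheduled quantity to the sigma of the
#' per-update Gaussian increment.
#' @inheritParams schedule_value_at
#' @export
sigma_at <- function(schedule, times) {
  v <- schedule_value_at(schedule, times)
  switch(schedule$mode,
         increment_variance = sqrt(v),
         triangle_sd = v,
         stop("sigma_at() only applies to increment_variance/triangle_sd"))
}

#' High/low variance condition label at given times
#'
#' Labels each time as belonging to the high- or low-variance condition.
#' For `increment_variance` and `level_sd` schedules the larger scheduled
#' value is the high-variance condition. For `correlation` schedules the
#' *negative* correlation branch is the high-variance condition: with the
#' odor kernel opposite in sign to the light kernel, the effective combined
#' input has variance \eqn{\sigma^2 (1 - c)}, largest at negative c.
#'
#' @inheritParams schedule_value_at
#' @return character vector `"high"`/`"low"` (NA outside the schedule).
#' @export
condition_at <- function(schedule, times) {
  v <- schedule_value_at(schedule, times)
  vals <- unique(schedule$segments$value)
  if (schedule$mode == "triangle_sd")
    stop("condition_at() is undefined for triangle schedules")
  if (length(vals) == 1L) return(ifelse(is.na(v), NA_character_, "high"))
  hi <- if (schedule$mode == "correlation") min(vals) else max(vals)
  out <- ifelse(v == hi, "high", "low")
  out[is.na(v)] <- NA_character_
  out
}

#' Times at which the schedule switches condition
#'
#' @param schedule a [variance_schedule()].
#' @param to if given (`"high"` or `"low"`), only switches into that
#'   condition are returned (used as cycle starts for cycle averaging).
#' @export
switch_times <- function(schedule, to = NULL) {
  seg <- schedule$segments
  if (nrow(seg) < 2L) return(numeric(0))
  eps <- 1e-9
  cond <- condition_at(schedule, seg$t0 + eps)
  sw <- seg$t0[-1]
  cond_after <- cond[-1]
  if (!is.null(to)) sw <- sw[cond_after == to]
  sw
}
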
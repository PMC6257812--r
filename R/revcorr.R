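#' Linear filter kernel
#'
#' A kernel holds lagged weights on a 0.1 s grid spanning
#' `[-pre_window, +post_window]` around the turn. Lags are bin centers;
#' negative lags precede the turn. Only the pre-turn (causal) part is used
#' for filtering.
#'
#' @param lag bin-center lags (s), spaced by `bin`.
#' @param weights kernel weights (intensity-derivative units).
#' @param bin bin width (s), must be 0.1.
#' @param normalization `"raw"`, `"peak_scaled"` or
#'   `"unit_low_variance_output"`.
#' @export
kernel <- function(lag, weights, bin = 0.1, normalization = "raw") {
  stopifnot(length(lag) == length(weights), all(is.finite(weights)))
  if (abs(bin - 0.1) > 1e-12) stop("kernel bin width must be 0.1 s")
  structure(list(lag = lag, weights = weights, bin = bin,
                 normalization = normalization),
            class = "kernel")
}

#' @export
print.kernel <- function(x, ...) {
  cat(sprintf("<kernel> %d bins of %.1f s, lags [%.2f, %.2f] s, %s\n",
              length(x$lag), x$bin, min(x$lag), max(x$lag), x$normalization))
  invisible(x)
}

#' Canonical synthetic kernel
#'
#' A biphasic causal kernel with ~4 s of structure, used as the generating
#' truth in simulations: a fast positive lobe just before the turn and a
#' slower negative rebound. Scaled analytically so that filtering a
#' unit-variance (sigma^2 = 1 per update) Brownian derivative yields output
#' variance 1, so the low/high variance conditions of the standard stimulus
#' give filtered SD 1 and 3.
#'
#' @param pre_window pre-turn support (s).
#' @param bin bin width (s).
#' @param frame_period behavior frame interval (s).
#' @param update_period stimulus update interval (s).
#' @export
default_kernel <- function(pre_window = 4, bin = 0.1, frame_period = 1 / 20,
                           update_period = 1 / 120) {
  tau <- seq(bin / 2, pre_window - bin / 2, by = bin)
  w <- (tau / 0.4) * exp(1 - tau / 0.4) - 0.55 * (tau / 1.2) * exp(1 - tau / 1.2)
  m <- round(bin / frame_period)            # frames per kernel bin
  u <- round(frame_period / update_period)  # updates per frame
  # at sigma^2 = 1 per update, the per-frame derivative has variance u and
  # the filter output variance is u * m * sum(w^2)
  w <- w / sqrt(u * m * sum(w^2))
  kernel(-rev(tau), rev(w), bin, normalization = "unit_low_variance_output")
}

pre_turn_weights <- function(k) {
  # weights ordered by increasing |lag| (nearest the turn first)
  pre <- k$lag < 0
  w <- k$weights[pre]
  w[order(-k$lag[pre])]
}

#' Causal convolution of a kernel with the stimulus
#'
#' Computes the filtered signal x(t): each pre-turn kernel weight multiplies
#' the summed stimulus derivative in its 0.1 s lag bin ending at t. Post-turn
#' lags, if present with non-zero weight, are dropped with a message. The
#' first frames lacking full kernel support are masked invalid.
#'
#' @param kernel a [kernel()].
#' @param deriv a `derivative_series`.
#' @return object of class `filtered_signal` with `values`, `valid`,
#'   `frame_period` and the stimulus `schedule`.
#' @export
filter_stimulus <- function(kernel, deriv) {
  stopifnot(inherits(kernel, "kernel"), inherits(deriv, "derivative_series"))
  if (any(kernel$lag > 0 & kernel$weights != 0))
    message("dropping post-turn kernel lags for causal filtering")
  w <- pre_turn_weights(kernel)
  if (!length(w)) stop("kernel has no pre-turn lags")
  m <- round(kernel$bin / deriv$frame_period)
  cvec <- rep(w, each = m)
  vals <- as.numeric(stats::filter(deriv$values, cvec, sides = 1))
  valid <- !is.na(vals)
  vals[!valid] <- 0
  if (!any(valid)) stop("no frames with full kernel support")
  structure(list(values = vals, valid = valid,
                 frame_period = deriv$frame_period,
                 schedule = deriv$schedule),
            class = "filtered_signal")
}

#' @export
print.filtered_signal <- function(x, ...) {
  cat(sprintf("<filtered_signal> %d frames at %.3f s, %d valid, sd = %.3f\n",
              length(x$values), x$frame_period, sum(x$valid),
              stats::sd(x$values[x$valid])))
  invisible(x)
}

#' Frame-selection mask for the analysis discard policy
#'
#' Builds the logical per-frame mask implementing the standard discards:
#' the first `burn_in` seconds of each experiment (response to the novel
#' environment), the first `cycle_discard` seconds after every variance
#' switch (un-adapted transients; 15 s for 60 s half-cycles, 10 s for 20 s
#' half-cycles), and, optionally, frames outside one variance condition.
#'
#' @param duration experiment duration (s).
#' @param frame_period frame interval (s).
#' @param schedule optional [variance_schedule()] (needed for
#'   `cycle_discard` and `condition`).
#' @param burn_in initial discard (s).
#' @param cycle_discard post-switch discard (s).
#' @param condition NULL, `"high"` or `"low"`.
#' @export
analysis_mask <- function(duration, frame_period = 1 / 20, schedule = NULL,
                          burn_in = 60, cycle_discard = 0, condition = NULL) {
  n_frames <- round(duration / frame_period)
  t <- (seq_len(n_frames) - 1) * frame_period
  keep <- t >= burn_in
  if (!is.null(schedule) && cycle_discard > 0) {
    for (s in switch_times(schedule))
      keep[t >= s - 1e-9 & t < s + cycle_discard - 1e-9] <- FALSE
  }
  if (!is.null(condition)) {
    stopifnot(!is.null(schedule))
    keep <- keep & condition_at(schedule, t) %in% condition
  }
  keep
}

# Resolve a per-experiment quantity: `obj` may be a single object shared by
# all experiments or a list with one element per experiment.
per_experiment <- function(obj, i, class) {
  if (inherits(obj, class)) obj else obj[[i]]
}

# Pool run frames across experiments and larvae. Returns x at analyzed run
# frames, a turn flag per frame, the experiment index, and totals.
pooled_run_frames <- function(data, filtered, keep = NULL) {
  dt <- data$frame_period
  n_frames <- round(data$duration / dt)
  tgrid <- (seq_len(n_frames) - 1) * dt
  xs <- list(); turns <- list(); eidx <- list(); ts <- list()
  for (i in seq_along(data$experiments)) {
    e <- data$experiments[[i]]
    f <- per_experiment(filtered, i, "filtered_signal")
    base_keep <- f$valid[seq_len(n_frames)]
    if (!is.null(keep)) base_keep <- base_keep & keep[seq_len(n_frames)]
    for (l in e$larvae) {
      mask <- run_frame_mask(l, n_frames, dt) & base_keep
      if (!any(mask)) next
      tf <- turn_frame_index(l$turn_times, dt)
      is_turn <- logical(n_frames)
      is_turn[tf[tf >= 1 & tf <= n_frames]] <- TRUE
      xs[[length(xs) + 1L]] <- f$values[mask]
      turns[[length(turns) + 1L]] <- is_turn[mask]
      eidx[[length(eidx) + 1L]] <- rep.int(i, sum(mask))
      ts[[length(ts) + 1L]] <- tgrid[mask]
    }
  }
  if (!length(xs)) stop("no analyzable run frames")
  list(x = unlist(xs), turn = unlist(turns), exp = unlist(eidx),
       t = unlist(ts), dt = dt)
}

#' Turn-triggered average
#'
#' Estimates the linear kernel as the average stimulus snippet surrounding
#' every turn, in 0.1 s bins: the behavioral analogue of a spike-triggered
#' average. Turns without full window support are skipped; for the
#' random-levels stimulus, pass the mean-subtracted [intensity_series()] as
#' `deriv`.
#'
#' @param data a `behavior_dataset`.
#' @param deriv a `derivative_series`, or a list of them (one per
#'   experiment).
#' @param pre_window,post_window window around the turn (s).
#' @param keep optional logical frame mask restricting which turns enter
#'   (e.g. one variance condition).
#' @return a [kernel()] with raw normalization; attributes `n_turns`.
#' @export
turn_triggered_average <- function(data, deriv, pre_window = 5,
                                   post_window = 2, keep = NULL) {
  snip <- tta_matrix(data, deriv, pre_window, post_window, keep)
  if (!nrow(snip$mat)) stop("no turns with full window support")
  w <- colMeans(snip$mat)
  k <- kernel(snip$lag, w)
  attr(k, "n_turns") <- nrow(snip$mat)
  k
}

# Snippet matrix (one row per usable turn) on the 0.1 s lag grid.
tta_matrix <- function(data, deriv, pre_window, post_window, keep = NULL) {
  dt <- data$frame_period
  n_frames <- round(data$duration / dt)
  m <- round(0.1 / dt)
  n_pre <- round(pre_window / 0.1); n_post <- round(post_window / 0.1)
  off <- seq(-(n_pre * m) + 1L, n_post * m)
  rows <- list()
  for (i in seq_along(data$experiments)) {
    e <- data$experiments[[i]]
    dv <- per_experiment(deriv, i, "derivative_series")
    nd <- length(dv$values)
    for (l in e$larvae) {
      tf <- turn_frame_index(l$turn_times, dt)
      if (!is.null(keep)) tf <- tf[tf >= 1 & tf <= n_frames & keep[tf]]
      tf <- tf[tf - n_pre * m >= 0L & tf + n_post * m <= nd]
      if (!length(tf)) next
      idx <- outer(tf, off, `+`)
      rows[[length(rows) + 1L]] <-
        matrix(dv$values[idx], nrow = length(tf))
    }
  }
  mat <- do.call(rbind, c(rows, list(matrix(0, 0, length(off)))))
  # collapse m frames per 0.1 s bin
  if (nrow(mat)) {
    mat <- sapply(seq_len(n_pre + n_post), function(j)
      rowSums(mat[, ((j - 1) * m + 1):(j * m), drop = FALSE]))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  } else mat <- matrix(0, 0, n_pre + n_post)
  lag <- seq(-(n_pre - 0.5) * 0.1, (n_post - 0.5) * 0.1, by = 0.1)
  list(mat = mat, lag = lag)
}

#' Bootstrap uncertainty band for the turn-triggered average
#'
#' Hierarchical bootstrap respecting between-experiment correlations:
#' experiments are resampled with replacement, then larvae with replacement
#' within each chosen experiment; the band is the per-bin standard deviation
#' over the bootstrap TTAs. With a single experiment only larvae are
#' resampled (with a warning); with a single replicate the band is defined
#' as zero (with a warning).
#'
#' @inheritParams turn_triggered_average
#' @param n_boot number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @return list with `lag`, `band` (per-bin SD) and the bootstrap `ttas`
#'   matrix.
#' @export
bootstrap_tta <- function(data, deriv, n_boot = 100, seed = NULL,
                          pre_window = 5, post_window = 2, keep = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_exp <- length(data$experiments)
  if (n_exp < 2L)
    warning("single experiment: resampling larvae only")
  boots <- matrix(NA_real_, n_boot,
                  round(pre_window / 0.1) + round(post_window / 0.1))
  lag <- NULL
  for (bidx in seq_len(n_boot)) {
    ei <- if (n_exp >= 2L) sample.int(n_exp, n_exp, replace = TRUE)
          else rep(1L, n_exp)
    exps <- lapply(ei, function(j) {
      e <- data$experiments[[j]]
      li <- sample.int(length(e$larvae), length(e$larvae), replace = TRUE)
      e$larvae <- e$larvae[li]
      e
    })
    bd <- data; bd$experiments <- exps
    bderiv <- if (inherits(deriv, "derivative_series")) deriv else deriv[ei]
    k <- turn_triggered_average(bd, bderiv, pre_window, post_window, keep)
    boots[bidx, ] <- k$weights
    lag <- k$lag
  }
  band <- if (n_boot < 2L) {
    warning("band undefined for a single replicate; returning zeros")
    rep(0, ncol(boots))
  } else apply(boots, 2, stats::sd)
  list(lag = lag, band = band, ttas = boots)
}

#' Gaussian smoothing of a turn-triggered average
#'
#' Low-passes the kernel with a discrete Gaussian (default sigma 0.25 s) to
#' remove update-rate artifacts of the random-levels stimulus. The
#' convolution is edge-truncated and renormalized, so a constant kernel is
#' preserved exactly.
#'
#' @param k a [kernel()] on the 0.1 s grid.
#' @param sigma Gaussian SD (s).
#' @export
smooth_tta <- function(k, sigma = 0.25) {
  stopifnot(inherits(k, "kernel"))
  if (sigma <= 0) stop("sigma must be positive")
  half <- max(1L, ceiling(4 * sigma / k$bin))
  g <- dnorm(seq(-half, half) * k$bin, 0, sigma)
  n <- length(k$weights)
  sm <- vapply(seq_len(n), function(i) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= n
    sum(k$weights[j[ok]] * g[ok]) / sum(g[ok])
  }, numeric(1))
  kernel(k$lag, sm, k$bin, k$normalization)
}

#' Scale a kernel to unit low-variance output
#'
#' Rescales kernel weights so that the filtered signal has variance one over
#' the valid low-variance frames of the supplied stimulus, the convention
#' that puts the rate-function argument on a common scale across
#' experiments.
#'
#' @param k a [kernel()].
#' @param deriv a `derivative_series` whose schedule identifies the
#'   low-variance frames; if the schedule has a single condition all valid
#'   frames are used.
#' @param keep optional extra logical frame mask.
#' @export
normalize_kernel <- function(k, deriv, keep = NULL) {
  xs <- filter_stimulus(k, deriv)
  sel <- xs$valid
  sch <- deriv$schedule
  if (!is.null(sch) && sch$mode != "triangle_sd" &&
      length(unique(sch$segments$value)) > 1L) {
    t <- (seq_along(xs$values) - 1) * xs$frame_period
    sel <- sel & condition_at(sch, t) %in% "low"
  }
  if (!is.null(keep)) sel <- sel & keep[seq_along(sel)]
  s <- stats::sd(xs$values[sel])
  if (!is.finite(s) || s == 0) stop("degenerate kernel: zero output variance")
  kernel(k$lag, k$weights / s, k$bin, "unit_low_variance_output")
}

#' Scale a kernel to a common peak for display
#'
#' @param k a [kernel()].
#' @param peak target peak absolute value.
#' @export
peak_scale <- function(k, peak = 1) {
  m <- max(abs(k$weights))
  if (m == 0) stop("cannot peak-scale a zero kernel")
  kernel(k$lag, k$weights * peak / m, k$bin, "peak_scaled")
}

#' Binned turn rates over the filtered signal
#'
#' Direct, model-free estimate of the rate function: analyzed run frames are
#' split into `n_bins` equal-count bins of the filtered signal, and each
#' bin's turn rate is r = 60 (N_turn / N_run) / dt in min^-1 with Poisson
#' uncertainty sigma_r = 60 (sqrt(N_turn) / N_run) / dt. The frame of a turn
#' counts in N_turn and also as a run frame.
#'
#' @param data a `behavior_dataset`.
#' @param filtered a `filtered_signal` or list per experiment.
#' @param n_bins number of bins.
#' @param keep optional logical frame mask (discard policy / condition).
#' @return data frame with bin centers, edges, counts, `rate` and
#'   `sigma_rate` (min^-1); empty bins are flagged with NA rate.
#' @export
binned_turn_rate <- function(data, filtered, n_bins = 8, keep = NULL) {
  pf <- pooled_run_frames(data, filtered, keep)
  edges <- stats::quantile(pf$x, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE)
  edges[1] <- -Inf; edges[n_bins + 1] <- Inf
  bin <- findInterval(pf$x, edges, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  n_run <- tabulate(bin, n_bins)
  n_turn <- tabulate(bin[pf$turn], n_bins)
  rate <- ifelse(n_run > 0, 60 * (n_turn / n_run) / pf$dt, NA_real_)
  sigma <- ifelse(n_run > 0, 60 * (sqrt(n_turn) / n_run) / pf$dt, NA_real_)
  centers <- vapply(seq_len(n_bins), function(b)
    mean(pf$x[bin == b]), numeric(1))
  data.frame(bin = seq_len(n_bins), center = centers,
             lo = edges[-(n_bins + 1)], hi = edges[-1],
             n_turn = n_turn, n_run = n_run,
             rate = rate, sigma_rate = sigma)
}
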
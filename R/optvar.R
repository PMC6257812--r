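#' Configuration of the Bayesian variance estimator
#'
#' @param dt sampling interval Delta-t (s): the estimator reads the total
#'   change in light level over each interval.
#' @param tau diffusive-prior timescale (s): the assumed correlation time of
#'   environmental variance.
#' @param sigma_grid grid of candidate SD values; if NULL a 400-point
#'   log-spaced grid covering [0.1x, 10x] the pooled empirical SD of the
#'   samples is chosen when the estimator runs.
#' @export
var_estimator_config <- function(dt, tau, sigma_grid = NULL) {
  if (dt <= 0 || tau <= 0) stop("dt and tau must be positive")
  if (!is.null(sigma_grid)) {
    if (any(sigma_grid <= 0) || any(diff(sigma_grid) <= 0))
      stop("sigma_grid must be strictly increasing and positive")
  }
  structure(list(dt = dt, tau = tau, sigma_grid = sigma_grid),
            class = "var_estimator_config")
}

# Integration weights (cell widths by midpoints) for a non-uniform grid.
grid_widths <- function(grid) {
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  diff(c(grid[1] - (mids[1] - grid[1]), mids,
         grid[length(grid)] + (grid[length(grid)] - mids[length(mids)])))
}

# Transition matrix on a (possibly non-uniform) grid, acting on probability
# mass: Gaussian kernel of variance 2 dt / tau, destination cells weighted
# by their widths, column-normalized.
transition_matrix_nonuniform <- function(grid, step, tau) {
  sdv <- sqrt(2 * step / tau)
  w <- grid_widths(grid)
  K <- outer(grid, grid, function(a, b) dnorm(a - b, 0, sdv)) * w
  sweep(K, 2, colSums(K), "/")
}

#' Bayesian-optimal online variance estimate
#'
#' Recursive Bayes filter over the stimulus standard deviation: every `dt`
#' seconds the estimator observes s_i = I(t_i) - I(t_(i-1)), the total
#' change in light level over the interval, diffuses its sigma posterior
#' with a Gaussian kernel of variance 2 dt / tau, multiplies by the
#' N(s_i; 0, sigma_i^2) likelihood, and renormalizes. The posterior mode is
#' reported per sample and held constant between samples. The prior is on
#' sigma (not sigma^2), started uniform on the grid; the grid is truncated
#' at a small positive sigma, so an all-zero input drives the mode to the
#' smallest grid value. Posterior mass accumulating at the upper grid edge
#' raises a coverage error.
#'
#' @param trace a `stimulus_trace` (walk kind).
#' @param config a [var_estimator_config()].
#' @return object of class `var_estimate` with sample `times`,
#'   `sigma_mode`, the `config`, and the sample values `s`.
#' @export
bayes_variance_estimate <- function(trace, config) {
  stopifnot(inherits(trace, "stimulus_trace"),
            inherits(config, "var_estimator_config"))
  dt <- config$dt
  if (trace$duration < dt) stop("trace shorter than one sampling interval")
  up <- trace$update_period
  m <- round(dt / up)
  if (abs(dt / up - m) > 1e-6)
    stop("dt must be a multiple of the trace update period")
  idx <- seq(1L, length(trace$intensities), by = m)
  s <- diff(trace$intensities[idx])
  grid <- config$sigma_grid
  if (is.null(grid)) {
    s0 <- stats::sd(s)
    grid <- exp(seq(log(0.1 * s0), log(10 * s0), length.out = 400))
  }
  K <- transition_matrix_nonuniform(grid, dt, config$tau)
  G <- length(grid)
  gw <- grid_widths(grid)
  post <- gw / sum(gw)  # uniform density over the grid span
  mode <- numeric(length(s))
  edge_mass <- 0
  for (i in seq_along(s)) {
    prior <- as.numeric(K %*% post)
    lp <- log(pmax(prior, 1e-300)) + dnorm(s[i], 0, grid, log = TRUE)
    lp <- lp - max(lp)
    post <- exp(lp); post <- post / sum(post)
    # the posterior mode is a density mode: divide the per-cell mass by
    # the cell width before taking the argmax (matters on log grids)
    mi <- which.max(post / gw)
    if (mi == G)
      stop("posterior mode at the upper sigma grid edge: widen the grid")
    edge_mass <- edge_mass + post[G]
    mode[i] <- grid[mi]
  }
  if (edge_mass / length(s) > 1e-3)
    warning("mean posterior mass at the upper sigma grid edge exceeds 1e-3")
  structure(list(times = idx[-1] * up - up, sigma_mode = mode, s = s,
                 config = config, grid = grid),
            class = "var_estimate")
}

#' @export
print.var_estimate <- function(x, ...) {
  cat(sprintf(
    "<var_estimate> %d samples at dt = %.3g s, tau = %.3g s, sigma in [%.3g, %.3g]\n",
    length(x$sigma_mode), x$config$dt, x$config$tau,
    min(x$sigma_mode), max(x$sigma_mode)))
  invisible(x)
}

# Expand a sampled sigma estimate to the 20 Hz frame grid (held constant
# between samples; frames before the first sample get the first value).
sigma_per_frame <- function(est, n_frames, frame_period = 1 / 20) {
  t <- (seq_len(n_frames) - 1) * frame_period
  i <- findInterval(t, est$times)
  i[i < 1L] <- 1L
  est$sigma_mode[pmin(i, length(est$sigma_mode))]
}

#' Predicted gain from a variance estimate
#'
#' Maps an online SD estimate through the rescaling law
#' alpha(sigma) = alpha0 / sqrt(sigma^2 + sigma0^2) and renormalizes so the
#' mean predicted gain is 1 (the alpha0 scale is not identified by the law
#' alone).
#'
#' @param sigma_est numeric vector of SD estimates (per frame or per
#'   sample).
#' @param law a `rescaling_law` (see [fit_alpha_sigma_law()]); only
#'   `sigma0` matters after normalization.
#' @return numeric vector of predicted gains, mean 1.
#' @export
predict_alpha <- function(sigma_est, law) {
  stopifnot(inherits(law, "rescaling_law"))
  a <- 1 / sqrt(sigma_est^2 + law$sigma0^2)
  a / mean(a)
}

#' Predicted gain trajectory from a stimulus trace
#'
#' Runs the variance estimator on the raw intensity walk, converts the SD
#' estimate from intensity-change-over-dt units to per-update units (the
#' scale of the filtered signal under the unit-low-variance kernel
#' convention): for a Brownian walk, Var(s) = (dt / update_period) *
#' sigma_update^2. The converted estimate is mapped through the rescaling
#' law and normalized to mean gain 1 on the frame grid.
#'
#' @param trace a `stimulus_trace` (walk kind).
#' @param config a [var_estimator_config()].
#' @param law a `rescaling_law`.
#' @param n_frames number of behavior frames to cover.
#' @param frame_period behavior frame interval (s).
#' @return numeric vector of per-frame predicted gains (mean 1).
#' @export
predicted_gain <- function(trace, config, law, n_frames,
                           frame_period = 1 / 20) {
  est <- bayes_variance_estimate(trace, config)
  scale <- sqrt(config$dt / trace$update_period)
  sigf <- sigma_per_frame(est, n_frames, frame_period) / scale
  predict_alpha(sigf, law)
}

#' Likelihood grid search over estimator parameters
#'
#' Scores candidate (dt, tau) estimator settings against behavior: for each
#' cell, the stimulus of every experiment is run through the variance
#' estimator, the estimate is mapped to a predicted gain trajectory via the
#' rescaling law (normalized to mean 1 per experiment), the static rate
#' parameters are refit by maximum likelihood given that gain, and the
#' total data log-likelihood is recorded. The reported surface is relative
#' to its maximum (only differences are meaningful). An optional bootstrap
#' over experiments (holding the per-cell fitted parameters fixed)
#' approximates a 95% confidence region for the best cell.
#'
#' @inheritParams loglik
#' @param traces a `stimulus_trace` or list per experiment (the raw
#'   intensity walks).
#' @param law a `rescaling_law` supplying sigma0.
#' @param dt_grid,tau_grid candidate sampling intervals and prior
#'   timescales (s).
#' @param n_boot bootstrap replicates over experiments (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `grid_search_result`: `ll` matrix
#'   (dt x tau, relative to max), `best` (dt, tau), per-cell static fits,
#'   and optionally `boot_best` cells.
#' @export
grid_search <- function(data, filtered, traces, law, dt_grid, tau_grid,
                        keep = NULL, n_boot = 0, seed = NULL) {
  n_exp <- length(data$experiments)
  n_frames <- round(data$duration / data$frame_period)
  pf <- pooled_run_frames(data, filtered, keep)
  fi <- as.integer(round(pf$t / pf$dt)) + 1L
  ll <- matrix(NA_real_, length(dt_grid), length(tau_grid),
               dimnames = list(dt = signif(dt_grid, 3),
                               tau = signif(tau_grid, 3)))
  ll_exp <- array(NA_real_, c(length(dt_grid), length(tau_grid), n_exp))
  for (a in seq_along(dt_grid)) for (b in seq_along(tau_grid)) {
    cfg <- var_estimator_config(dt_grid[a], tau_grid[b])
    alpha_frames <- lapply(seq_len(n_exp), function(i) {
      tr <- per_experiment(traces, i, "stimulus_trace")
      predicted_gain(tr, cfg, law, n_frames, data$frame_period)
    })
    av <- numeric(length(pf$x))
    for (i in seq_len(n_exp)) av[pf$exp == i] <- alpha_frames[[i]][fi[pf$exp == i]]
    z <- av * pf$x
    st <- fit_static_frames(z[pf$turn], z, pf$dt)
    r <- rate_eval(st, z)
    ll[a, b] <- loglik_frames(r, pf$turn, pf$dt)
    for (i in seq_len(n_exp)) {
      sel <- pf$exp == i
      ll_exp[a, b, i] <- loglik_frames(r[sel], pf$turn[sel], pf$dt)
    }
  }
  best_idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  boot_best <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot_best <- t(vapply(seq_len(n_boot), function(bb) {
      ei <- sample.int(n_exp, n_exp, replace = TRUE)
      s <- apply(ll_exp[, , ei, drop = FALSE], c(1, 2), sum)
      which(s == max(s), arr.ind = TRUE)[1, ]
    }, numeric(2)))
    colnames(boot_best) <- c("dt_idx", "tau_idx")
  }
  structure(list(dt_grid = dt_grid, tau_grid = tau_grid,
                 ll = ll - max(ll),
                 best = c(dt = dt_grid[best_idx[1]],
                          tau = tau_grid[best_idx[2]]),
                 best_idx = best_idx, boot_best = boot_best),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d x %d cells, best dt = %.3g s, tau = %.3g s\n",
              length(x$dt_grid), length(x$tau_grid),
              x$best[["dt"]], x$best[["tau"]]))
  invisible(x)
}
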
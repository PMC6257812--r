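#' Alpha trajectory
#'
#' Posterior-mode input gain per tracker step, with posterior SD. Produced
#' by [track_alpha()] and friends.
#' @param times step start times (s).
#' @param alpha posterior mode per step.
#' @param sigma_alpha posterior SD per step.
#' @param prior_tau smoothness prior timescale (s).
#' @param step tracker step (s).
#' @param normalized TRUE once the trajectory has been scaled to mean 1.
#' @export
alpha_trajectory <- function(times, alpha, sigma_alpha, prior_tau, step,
                             normalized = FALSE) {
  stopifnot(length(times) == length(alpha),
            length(alpha) == length(sigma_alpha),
            all(alpha >= 0), all(sigma_alpha > 0))
  structure(list(times = times, alpha = alpha, sigma_alpha = sigma_alpha,
                 prior_tau = prior_tau, step = step, normalized = normalized),
            class = "alpha_trajectory")
}

#' @export
print.alpha_trajectory <- function(x, ...) {
  cat(sprintf(
    "<alpha_trajectory> %d steps of %.2g s from t = %.0f s, tau = %g s, mean = %.3f%s\n",
    length(x$alpha), x$step, x$times[1], x$prior_tau, mean(x$alpha),
    if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

# Column-normalized Gaussian transition matrix on a grid: diffusion kernel
# of variance 2 * step / tau (truncated at the grid edges).
transition_matrix <- function(grid, step, tau) {
  sdv <- sqrt(2 * step / tau)
  K <- outer(grid, grid, function(a, b) dnorm(a - b, 0, sdv))
  sweep(K, 2, colSums(K), "/")
}

# Per-step sufficient statistics of the pooled behavior frames.
step_stats <- function(pf, t_start, step, n_steps) {
  si <- floor((pf$t - t_start) / step) + 1L
  ok <- si >= 1L & si <= n_steps
  si <- si[ok]; x <- pf$x[ok]; turn <- pf$turn[ok]
  # xn: all run frames in the step (the rate integral); xt: turn frames
  list(
    xn = split(x, factor(si, levels = seq_len(n_steps))),
    xt = split(x[turn], factor(si[turn], levels = seq_len(n_steps)))
  )
}

# Grid log-likelihood of one tracker step for rate lambda(alpha * x).
step_loglik_grid <- function(grid, xt, xn, st, dt) {
  ll <- rep(0, length(grid))
  if (length(xt))
    ll <- ll + length(xt) * log(st$lam0 * dt) +
      st$b * grid * sum(xt) + st$c * grid^2 * sum(xt^2)
  if (length(xn))
    ll <- ll - st$lam0 * dt * cpp_exp_quad_rowsums(grid, xn, st$b, st$c)
  ll
}

#' Recursive Bayesian tracking of the input gain
#'
#' Grid-based forward filter for the time-varying input rescaling alpha(t)
#' in r(t, x) = lambda(alpha(t) x). At each tracker step the previous
#' posterior is diffused with a Gaussian kernel of variance 2 dt_track /
#' tau, multiplied by the Poisson likelihood of the step's turn/no-turn
#' observations (all 20 Hz behavior frames falling in the step, pooled over
#' experiments and larvae), and renormalized. Steps without behavioral data
#' return the diffused prior (pure prediction). The per-step posterior mode
#' and SD are reported; the initial posterior is uniform on the grid.
#'
#' @inheritParams loglik
#' @param static a fixed [static_rate()].
#' @param prior_tau smoothness timescale tau (s).
#' @param step tracker step (s): 0.1 for switching experiments, 1 for
#'   triangle-wave experiments.
#' @param alpha_grid gain grid (default 501 points on [0, 5]).
#' @param t_start tracking start (s); the first minute is left out as
#'   burn-in.
#' @param t_end tracking end (s), defaults to the experiment duration.
#' @return an [alpha_trajectory()].
#' @export
track_alpha <- function(data, filtered, static, prior_tau = 5, step = 0.1,
                        alpha_grid = seq(0, 5, length.out = 501),
                        t_start = 60, t_end = NULL, keep = NULL) {
  stopifnot(inherits(static, "static_rate"))
  if (is.null(t_end)) t_end <- data$duration
  n_steps <- floor((t_end - t_start) / step + 1e-9)
  if (n_steps < 1L) stop("no tracker steps between t_start and t_end")
  pf <- pooled_run_frames(data, filtered, keep)
  ss <- step_stats(pf, t_start, step, n_steps)
  K <- transition_matrix(alpha_grid, step, prior_tau)
  G <- length(alpha_grid)
  post <- rep(1 / G, G)
  mode <- numeric(n_steps); sdv <- numeric(n_steps)
  edge_hits <- 0L
  for (i in seq_len(n_steps)) {
    prior <- as.numeric(K %*% post)
    ll <- step_loglik_grid(alpha_grid, ss$xt[[i]], ss$xn[[i]], static, pf$dt)
    lp <- log(pmax(prior, 1e-300)) + ll
    lp <- lp - max(lp)
    post <- exp(lp)
    post <- post / sum(post)
    mi <- which.max(post)
    if (mi == 1L || mi == G) edge_hits <- edge_hits + 1L
    mode[i] <- alpha_grid[mi]
    mu <- sum(alpha_grid * post)
    sdv[i] <- sqrt(max(sum((alpha_grid - mu)^2 * post), 1e-12))
  }
  if (edge_hits > n_steps / 2)
    stop("posterior mode pinned at the grid edge: widen alpha_grid")
  alpha_trajectory(t_start + (seq_len(n_steps) - 1) * step, mode, sdv,
                   prior_tau, step)
}

# Expand a trajectory to per-frame gains (frames before t_start get the
# first tracked value).
alpha_per_frame <- function(traj, n_frames, frame_period) {
  t <- (seq_len(n_frames) - 1) * frame_period
  i <- findInterval(t, traj$times)
  i[i < 1L] <- 1L
  i[i > length(traj$alpha)] <- length(traj$alpha)
  traj$alpha[i]
}

#' Alternating static-rate / gain-trajectory fit
#'
#' The full estimation loop for time-varying input rescaling: starting from
#' alpha = 1, alternately (a) fit the static rate parameters by maximum
#' likelihood given the current alpha(t) (the rescaled input alpha x is the
#' regressor), and (b) re-track alpha(t) given the static rate, until the
#' total data log-likelihood improves by less than `tol`. On convergence
#' alpha is normalized so its mean over the tracked interval is 1, and the
#' static parameters are refit under the normalized trajectory.
#'
#' @inheritParams track_alpha
#' @param tol convergence tolerance on the log-likelihood (nats).
#' @param max_iter cap on outer iterations.
#' @return list with `static` ([static_rate()]), `trajectory`
#'   ([alpha_trajectory()], normalized) and `loglik_history`.
#' @export
iterate_fit <- function(data, filtered, prior_tau = 5, step = 0.1,
                        alpha_grid = seq(0, 5, length.out = 501),
                        t_start = 60, tol = 1e-4, max_iter = 4,
                        keep = NULL) {
  n_frames <- round(data$duration / data$frame_period)
  if (is.null(keep)) keep <- rep(TRUE, n_frames)
  keep <- keep & ((seq_len(n_frames) - 1) * data$frame_period >= t_start)
  st <- fit_static_rate(data, filtered, keep = keep)
  ll_hist <- numeric(0)
  traj <- NULL
  for (it in seq_len(max_iter)) {
    traj <- track_alpha(data, filtered, st, prior_tau, step, alpha_grid,
                        t_start, keep = keep)
    # fix the gauge: alpha and the rate slope only enter through alpha * x,
    # so pin mean(alpha) = 1 each iteration before refitting the static
    # parameters (otherwise b and 1/alpha drift jointly without bound)
    mbar <- mean(traj$alpha)
    traj$alpha <- traj$alpha / mbar
    traj$sigma_alpha <- traj$sigma_alpha / mbar
    traj$normalized <- TRUE
    af <- alpha_per_frame(traj, n_frames, data$frame_period)
    st <- refit_given_alpha(data, filtered, af, keep)
    ll <- attr(st, "loglik")
    ll_hist <- c(ll_hist, ll)
    if (it > 1L) {
      dll <- ll - ll_hist[it - 1L]
      if (dll < -tol)
        warning(sprintf("log-likelihood decreased by %.3g at iteration %d",
                        -dll, it))
      if (abs(dll) < tol) break
    }
  }
  list(static = st, trajectory = traj, loglik_history = ll_hist)
}

refit_given_alpha <- function(data, filtered, alpha_frames, keep) {
  pf <- pooled_run_frames(data, filtered, keep)
  fi <- as.integer(round(pf$t / pf$dt)) + 1L
  z <- alpha_frames[fi] * pf$x
  fit_static_frames(z[pf$turn], z, pf$dt)
}

#' Two-gain smoothness prior
#'
#' Random-walk prior on (alpha, beta) steps with inverse covariance
#' (1 / 2 dt) [[tau_alpha, tau_ab], [tau_ab, tau_beta]]. The default
#' tau_ab = 0 introduces no correlation between changes in alpha and beta.
#'
#' @param tau_alpha,tau_beta,tau_ab prior timescales (s).
#' @param step tracker step (s).
#' @export
alpha_beta_prior <- function(tau_alpha = 5, tau_beta = 5, tau_ab = 0,
                             step = 0.1) {
  M <- matrix(c(tau_alpha, tau_ab, tau_ab, tau_beta), 2)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("prior inverse covariance is not positive definite")
  structure(list(tau_alpha = tau_alpha, tau_beta = tau_beta, tau_ab = tau_ab,
                 step = step), class = "alpha_beta_prior")
}

#' Joint tracking of two channel gains
#'
#' 2D grid filter for independent input rescaling of two channels,
#' r = lambda0 exp(a alpha(t) x_o + b beta(t) x_L): the joint (alpha, beta)
#' posterior is diffused with the Gaussian transition implied by
#' [alpha_beta_prior()], multiplied by the step likelihood, renormalized,
#' and marginalized to per-channel modes and SDs. Only the uncorrelated
#' prior (tau_ab = 0) is supported, for which the transition is separable.
#'
#' @param data a `behavior_dataset`.
#' @param xo,xl `filtered_signal`s (or lists per experiment) for the two
#'   channels.
#' @param static an exp-linear [static_rate()]; its `b` slot is the odor
#'   coefficient `a` and `coef_l` the light coefficient.
#' @param coef_l light-channel coefficient b.
#' @param prior an [alpha_beta_prior()].
#' @param grid gain grid for both axes (default 101 points on [0, 4]).
#' @param t_start,t_end,keep as in [track_alpha()].
#' @return list of two [alpha_trajectory()]s, `alpha` and `beta`.
#' @export
track_alpha_beta <- function(data, xo, xl, static, coef_l,
                             prior = alpha_beta_prior(),
                             grid = seq(0, 4, length.out = 101),
                             t_start = 60, t_end = NULL, keep = NULL) {
  stopifnot(inherits(prior, "alpha_beta_prior"))
  if (prior$tau_ab != 0)
    stop("only the uncorrelated prior (tau_ab = 0) is implemented")
  if (is.null(t_end)) t_end <- data$duration
  step <- prior$step
  n_steps <- floor((t_end - t_start) / step + 1e-9)
  pfo <- pooled_run_frames(data, xo, keep)
  pfl <- pooled_run_frames(data, xl, keep)
  sso <- step_stats(pfo, t_start, step, n_steps)
  ssl <- step_stats(pfl, t_start, step, n_steps)
  Ka <- transition_matrix(grid, step, prior$tau_alpha)
  Kb <- transition_matrix(grid, step, prior$tau_beta)
  G <- length(grid)
  P <- matrix(1 / G^2, G, G)  # rows: alpha grid, cols: beta grid
  a <- static$b; b <- coef_l; lam0 <- static$lam0; dt <- pfo$dt
  out_a <- matrix(0, n_steps, 2); out_b <- matrix(0, n_steps, 2)
  for (i in seq_len(n_steps)) {
    P <- Ka %*% P %*% t(Kb)
    xo_n <- sso$xn[[i]]; xo_t <- sso$xt[[i]]
    xl_n <- ssl$xn[[i]]; xl_t <- ssl$xt[[i]]
    llA <- rep(0, G); llB <- rep(0, G)
    if (length(xo_t)) {
      llA <- llA + a * grid * sum(xo_t) + length(xo_t) * log(lam0 * dt)
      llB <- llB + b * grid * sum(xl_t)
    }
    LL <- outer(llA, llB, `+`)
    if (length(xo_n)) {
      U <- exp(a * outer(grid, xo_n))  # G x T
      V <- exp(b * outer(grid, xl_n))
      LL <- LL - lam0 * dt * (U %*% t(V))
    }
    LP <- log(pmax(P, 1e-300)) + LL
    LP <- LP - max(LP)
    P <- exp(LP); P <- P / sum(P)
    pa <- rowSums(P); pb <- colSums(P)
    out_a[i, ] <- marg_mode_sd(grid, pa)
    out_b[i, ] <- marg_mode_sd(grid, pb)
  }
  times <- t_start + (seq_len(n_steps) - 1) * step
  list(alpha = alpha_trajectory(times, out_a[, 1], out_a[, 2],
                                prior$tau_alpha, step),
       beta = alpha_trajectory(times, out_b[, 1], out_b[, 2],
                               prior$tau_beta, step))
}

marg_mode_sd <- function(grid, p) {
  p <- p / sum(p)
  mu <- sum(grid * p)
  c(grid[which.max(p)], sqrt(max(sum((grid - mu)^2 * p), 1e-12)))
}

#' Uncertainty-weighted cycle average of a trajectory
#'
#' Averages a tracked trajectory over repeated stimulus cycles: at each
#' cycle phase the values alpha(t_k + phase) are combined with weights
#' w_k proportional to 1 / sigma(t_k + phase), normalized to sum to 1.
#'
#' @param traj an [alpha_trajectory()].
#' @param switch_times cycle start times (s), e.g.
#'   `switch_times(schedule, to = "low")`.
#' @param cycle_len cycle length (s); inferred from consecutive switch
#'   times if omitted.
#' @return data frame with `phase`, `alpha` (weighted mean), `n_cycles`.
#' @export
cycle_average <- function(traj, switch_times, cycle_len = NULL) {
  if (!length(switch_times)) stop("need at least one cycle start")
  if (is.null(cycle_len)) {
    cycle_len <- if (length(switch_times) > 1L) min(diff(switch_times))
                 else max(traj$times) + traj$step - switch_times[1]
  }
  phases <- seq(0, cycle_len - traj$step, by = traj$step)
  out <- vapply(phases, function(ph) {
    tt <- switch_times + ph
    idx <- round((tt - traj$times[1]) / traj$step) + 1L
    ok <- idx >= 1L & idx <= length(traj$alpha)
    idx <- idx[ok]
    if (!length(idx)) return(c(NA_real_, 0))
    w <- 1 / traj$sigma_alpha[idx]
    w <- w / sum(w)
    c(sum(w * traj$alpha[idx]), length(idx))
  }, numeric(2))
  data.frame(phase = phases, alpha = out[1, ], n_cycles = out[2, ])
}

#' Rescaling law alpha(sigma)
#'
#' Fits the adapted rescaling rule \eqn{\alpha(\sigma) = \alpha_0 /
#' \sqrt{\sigma^2 + \sigma_0^2}} to cycle-averaged gain versus stimulus SD,
#' by nonlinear least squares. `sigma0` is the intrinsic-noise floor that
#' caps the gain at low stimulus variance; it is constrained to be
#' non-negative (clamped at 0 with a warning if the unconstrained optimum
#' is negative). The `rising` / `falling` splits (by the sign of the local
#' sigma trend) support the hysteresis check.
#'
#' @param alpha cycle-averaged gain values.
#' @param sigma matching stimulus SD values.
#' @param split `"all"`, `"rising"` or `"falling"`.
#' @return object of class `rescaling_law` with `alpha0` and `sigma0`.
#' @export
fit_alpha_sigma_law <- function(alpha, sigma,
                                split = c("all", "rising", "falling")) {
  split <- match.arg(split)
  stopifnot(length(alpha) == length(sigma))
  ok <- is.finite(alpha) & is.finite(sigma)
  if (split != "all") {
    trend <- c(diff(sigma), utils::tail(diff(sigma), 1))
    ok <- ok & if (split == "rising") trend > 0 else trend < 0
  }
  a <- alpha[ok]; s <- sigma[ok]
  if (length(a) < 3L) stop("too few points to fit the rescaling law")
  df <- data.frame(a = a, s = s)
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ a0 / sqrt(s^2 + s0^2), data = df,
                      start = list(a0 = stats::median(a * s), s0 = 0.5),
                      lower = c(1e-9, 0), upper = c(Inf, Inf)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # grid + profile fallback: for fixed s0, a0 is linear least squares
    s0g <- seq(0, 3 * max(s), length.out = 200)
    sse <- vapply(s0g, function(s0) {
      g <- 1 / sqrt(s^2 + s0^2)
      a0 <- sum(a * g) / sum(g^2)
      sum((a - a0 * g)^2)
    }, numeric(1))
    s0 <- s0g[which.min(sse)]
    g <- 1 / sqrt(s^2 + s0^2)
    a0 <- sum(a * g) / sum(g^2)
  } else {
    cf <- stats::coef(fit)
    a0 <- cf[["a0"]]; s0 <- cf[["s0"]]
  }
  if (s0 < 0) { warning("sigma0 clamped at 0"); s0 <- 0 }
  structure(list(alpha0 = a0, sigma0 = s0), class = "rescaling_law")
}

#' @export
print.rescaling_law <- function(x, ...) {
  cat(sprintf("<rescaling_law> alpha(sigma) = %.3f / sqrt(sigma^2 + %.3f^2)\n",
              x$alpha0, x$sigma0))
  invisible(x)
}
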
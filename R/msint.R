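#' Rotated odor/light coordinates
#'
#' Builds the rotated coordinate system over the two filtered channels:
#' u = cos(theta) x_o + sin(theta) x_L and v = -sin(theta) x_o +
#' cos(theta) x_L. The rotation preserves x_o^2 + x_L^2 framewise; the
#' validity mask is the AND of the inputs.
#'
#' @param xo,xl `filtered_signal`s on a common frame grid.
#' @param theta rotation angle in degrees.
#' @return list of class `rotated_coords` with `theta`, `u`, `v`.
#' @export
rotate_coords <- function(xo, xl, theta) {
  if (abs(xo$frame_period - xl$frame_period) > 1e-12 ||
      length(xo$values) != length(xl$values))
    stop("xo and xl must share the same frame grid")
  th <- theta * pi / 180
  mk <- function(vals) {
    structure(list(values = vals, valid = xo$valid & xl$valid,
                   frame_period = xo$frame_period,
                   schedule = xo$schedule),
              class = "filtered_signal")
  }
  structure(list(theta = theta,
                 u = mk(cos(th) * xo$values + sin(th) * xl$values),
                 v = mk(-sin(th) * xo$values + cos(th) * xl$values)),
            class = "rotated_coords")
}

# Pool the two channels over identical frame selections.
pooled_two_channel <- function(data, xo, xl, keep = NULL) {
  pfo <- pooled_run_frames(data, xo, keep)
  pfl <- pooled_run_frames(data, xl, keep)
  stopifnot(length(pfo$x) == length(pfl$x))
  list(xo = pfo$x, xl = pfl$x, turn = pfo$turn, t = pfo$t,
       exp = pfo$exp, dt = pfo$dt)
}

# Profile LL over lambda0 for r = lambda0 * g; g > 0 per frame.
profile_ll_factor <- function(log_g_turn, g_noturn, dt) {
  nt <- length(log_g_turn)
  S <- sum(g_noturn)
  if (!is.finite(S) || S <= 0 || nt == 0L) return(-1e12)
  lam0 <- nt / (dt * S)
  nt * log(lam0 * dt) + sum(log_g_turn) - nt
}

#' Rotation-angle fit for correlated two-channel stimuli
#'
#' Finds the single combination u = cos(theta) x_o + sin(theta) x_L that
#' drives turning, by joint maximum likelihood over (lambda0, a, theta,
#' alpha_u_low) in the exp-linear model r = lambda0 exp(a alpha_u u), with
#' alpha_u fixed at 1 in the high-variance (negative correlation) condition.
#' Theta is scanned on a coarse grid over (-90, 90] degrees and refined
#' locally, avoiding local optima in the joint fit. The two-coordinate
#' model r = lambda0 exp(a u + b v) is then refit at the chosen theta and
#' the orthogonal weight b is reported with a standard error (b near 0
#' validates the one-coordinate description).
#'
#' @param data a `behavior_dataset` from a correlation-switching
#'   experiment.
#' @param xo,xl the filtered odor and light signals (lists per experiment
#'   allowed).
#' @param keep logical frame mask; the standard policy drops the first 10 s
#'   of each 20 s cycle.
#' @param theta_grid coarse scan angles (degrees).
#' @return list with `theta`, `alpha_u_low`, `lam0`, `a`, `loglik`, and the
#'   orthogonal-weight check `b`, `b_se`.
#' @export
fit_theta <- function(data, xo, xl, keep = NULL,
                      theta_grid = seq(-87, 90, by = 3)) {
  pc <- pooled_two_channel(data, xo, xl, keep)
  sch <- schedule_of(xo)
  cond <- condition_at(sch, pc$t)
  low <- cond == "low"
  nt <- sum(pc$turn)
  ll_at_theta <- function(theta) {
    th <- theta * pi / 180
    u <- cos(th) * pc$xo + sin(th) * pc$xl
    # sufficient statistics: turn-frame sums and all-frame vectors (the
    # rate integral runs over every run frame) per condition
    sum_t_low <- sum(u[pc$turn & low]); sum_t_high <- sum(u[pc$turn & !low])
    un_low <- u[low]; un_high <- u[!low]
    nll <- function(p) {
      a <- p[1]; al <- exp(p[2])
      S <- sum(exp(a * al * un_low)) + sum(exp(a * un_high))
      if (!is.finite(S) || S <= 0 || nt == 0L) return(1e12)
      lam0 <- nt / (pc$dt * S)
      -(nt * log(lam0 * pc$dt) + a * al * sum_t_low + a * sum_t_high - nt)
    }
    o <- stats::optim(c(0.3, log(1.5)), nll, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-9))
    list(ll = -o$value, par = o$par)
  }
  scan <- lapply(theta_grid, ll_at_theta)
  lls <- vapply(scan, `[[`, numeric(1), "ll")
  i0 <- which.max(lls)
  gstep <- if (length(theta_grid) > 1L) max(diff(theta_grid)) else 2
  opt <- stats::optimize(function(th) ll_at_theta(th)$ll,
                         interval = theta_grid[i0] + c(-gstep, gstep),
                         maximum = TRUE, tol = 0.05)
  theta_hat <- opt$maximum
  inner <- ll_at_theta(theta_hat)
  a_hat <- inner$par[1]; alpha_low <- exp(inner$par[2])
  th <- theta_hat * pi / 180
  u <- cos(th) * pc$xo + sin(th) * pc$xl
  z <- ifelse(low, alpha_low, 1) * u
  lam0 <- sum(pc$turn) / (pc$dt * sum(exp(a_hat * z)))
  # two-coordinate validation at fixed theta
  v <- -sin(th) * pc$xo + cos(th) * pc$xl
  nll2 <- function(p) {
    lam <- exp(p[1]); a <- p[2]; b <- p[3]; al <- exp(p[4])
    zz <- ifelse(low, al, 1) * u
    r <- lam * exp(a * zz + b * v)
    ll <- loglik_frames(r, pc$turn, pc$dt)
    if (!is.finite(ll)) 1e12 else -ll
  }
  o2 <- stats::optim(c(log(lam0), a_hat, 0, log(alpha_low)), nll2,
                     method = "BFGS", hessian = TRUE,
                     control = list(maxit = 500, reltol = 1e-10))
  b_se <- tryCatch(sqrt(diag(solve(o2$hessian)))[3],
                   error = function(e) NA_real_)
  list(theta = theta_hat, alpha_u_low = alpha_low, lam0 = lam0, a = a_hat,
       loglik = inner$ll, b = o2$par[3], b_se = unname(b_se))
}

#' Compare multisensory integration models
#'
#' Fits the three candidate two-input rate functions to constant-variance
#' multisensory data and ranks them by BIC:
#' \describe{
#'   \item{independent_additive}{\eqn{\lambda_o(x_o) + \lambda_L(x_L)} —
#'     separate pathways whose turn decisions are OR-ed.}
#'   \item{early_linear}{\eqn{\lambda_1(a x_o + b x_L)} — the channels sum
#'     before a shared nonlinearity.}
#'   \item{multiplicative}{\eqn{\lambda_o(x_o)\, \lambda_L(x_L)} — the
#'     unisensory nonlinear outputs multiply.}
#' }
#' Each factor/argument is an exponential of a polynomial of the given
#' degree. At degree 1 the early-linear and multiplicative models are the
#' same function (\eqn{\lambda_0 e^{a x_o + b x_L} = \lambda_0 e^{a x_o}
#' e^{b x_L}}) and share one fit; at degree 2 they differ (4 vs 5
#' parameters) and the BIC accounts for the parameter counts
#' (independent_additive has 4 and 6).
#'
#' @inheritParams fit_theta
#' @param degree polynomial degree of each factor/argument (1 or 2).
#' @return data frame, one row per model, with `loglik`, `n_params`, `bic`
#'   and `delta_bic` (relative to the best), ordered best first; fitted
#'   parameters in the `params` list column.
#' @export
fit_integration_models <- function(data, xo, xl, degree = 1, keep = NULL) {
  stopifnot(degree %in% c(1, 2))
  pc <- pooled_two_channel(data, xo, xl, keep)
  n_data <- length(pc$xo) * pc$dt
  dt <- pc$dt
  xot <- pc$xo[pc$turn]; xlt <- pc$xl[pc$turn]
  xon <- pc$xo; xln <- pc$xl  # all run frames: the rate integral

  fit_factored <- function(expo_t, expo_n, n_par, start, par_fn) {
    # r = lam0 * exp(expo(params)); lam0 profiled out
    nll <- function(p) -profile_ll_factor(expo_t(p), exp(expo_n(p)), dt)
    best <- NULL
    for (s0 in start) {
      o <- stats::optim(s0, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
      if (is.null(best) || o$value < best$value) best <- o
    }
    lam0 <- sum(pc$turn) / (dt * sum(exp(expo_n(best$par))))
    list(loglik = -best$value, params = c(lam0 = lam0, par_fn(best$par)),
         n_params = n_par)
  }

  fits <- list()
  if (degree == 1) {
    f <- fit_factored(
      function(p) p[1] * xot + p[2] * xlt,
      function(p) p[1] * xon + p[2] * xln,
      3L, list(c(0.3, 0.3), c(0.3, -0.3)),
      function(p) c(a = p[1], b = p[2]))
    fits$early_linear <- f
    fits$multiplicative <- f  # identical at degree 1
  } else {
    fits$early_linear <- fit_factored(
      function(p) { a <- tanh(p[1]); m <- a * xot + sqrt(1 - a^2) * xlt
        p[2] * m + p[3] * m^2 },
      function(p) { a <- tanh(p[1]); m <- a * xon + sqrt(1 - a^2) * xln
        p[2] * m + p[3] * m^2 },
      4L, list(c(0.5, 0.4, 0.05), c(-0.5, 0.4, -0.05)),
      function(p) c(a = tanh(p[1]), b = p[2], c = p[3]))
    fits$multiplicative <- fit_factored(
      function(p) p[1] * xot + p[2] * xot^2 + p[3] * xlt + p[4] * xlt^2,
      function(p) p[1] * xon + p[2] * xon^2 + p[3] * xln + p[4] * xln^2,
      5L, list(c(0.3, 0.05, 0.3, 0.05), c(0.3, -0.05, 0.3, -0.05)),
      function(p) c(b1 = p[1], c1 = p[2], b2 = p[3], c2 = p[4]))
  }
  # independent additive: no profiling, both baselines free
  add_rate <- function(p) {
    if (degree == 1)
      function(xo_, xl_) exp(p[1]) * exp(p[2] * xo_) +
        exp(p[3]) * exp(p[4] * xl_)
    else
      function(xo_, xl_) exp(p[1]) * exp(p[2] * xo_ + p[3] * xo_^2) +
        exp(p[4]) * exp(p[5] * xl_ + p[6] * xl_^2)
  }
  nll_add <- function(p) {
    r <- add_rate(p)
    rt <- r(xot, xlt)
    if (any(rt <= 0) || any(!is.finite(rt))) return(1e12)
    ll <- sum(log(rt * dt)) - sum(r(xon, xln) * dt)
    if (!is.finite(ll)) 1e12 else -ll
  }
  lam_guess <- log(sum(pc$turn) / (dt * length(xon)) / 2)
  starts <- if (degree == 1)
    list(c(lam_guess, 0.3, lam_guess, 0.3),
         c(lam_guess, 0.5, lam_guess, -0.5))
  else
    list(c(lam_guess, 0.3, 0.02, lam_guess, 0.3, 0.02),
         c(lam_guess, 0.5, -0.02, lam_guess, -0.5, 0.02))
  best <- NULL
  for (s0 in starts) {
    o <- stats::optim(s0, nll_add, control = list(maxit = 3000))
    o <- stats::optim(o$par, nll_add, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  fits$independent_additive <- list(
    loglik = -best$value, params = best$par,
    n_params = if (degree == 1) 4L else 6L)

  out <- data.frame(
    model = names(fits),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_params = vapply(fits, `[[`, integer(1), "n_params"))
  out$bic <- bic(out$loglik, n_data, out$n_params)
  out <- out[order(out$bic), ]
  out$delta_bic <- out$bic - out$bic[1]
  out$params <- lapply(fits[out$model], `[[`, "params")
  rownames(out) <- NULL
  attr(out, "n_data") <- n_data
  out
}
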
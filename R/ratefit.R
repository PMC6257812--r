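#' Point-process log-likelihood of turn data
#'
#' The log-likelihood of the observed run/turn sequence under a rate model:
#' \deqn{LL = \sum_{turn} \log(r\,dt) - \sum_{run} r\,dt,}
#' the discrete form of the inhomogeneous point-process likelihood (event
#' terms plus the integrated rate over all frames in runs), and the
#' short-interval limit of the per-frame Bernoulli likelihood with turn
#' probability \eqn{1 - e^{-r\,dt}}. Frames with invalid filtered signal
#' are excluded from both sums. Natural logarithms; LL is additive over
#' experiments and larvae.
#'
#' @param data a `behavior_dataset`.
#' @param filtered a `filtered_signal` or list per experiment.
#' @param rate_fn a [static_rate()] or a function of the filtered signal
#'   returning rates in s^-1.
#' @param keep optional logical frame mask (discard policy).
#' @return log-likelihood in nats; `-Inf` (with attribute `bad_turn_frames`)
#'   if the model assigns a non-positive rate to a turn frame.
#' @export
loglik <- function(data, filtered, rate_fn, keep = NULL) {
  pf <- pooled_run_frames(data, filtered, keep)
  f <- if (inherits(rate_fn, "static_rate"))
    function(x) rate_eval(rate_fn, x) else rate_fn
  loglik_frames(f(pf$x), pf$turn, pf$dt)
}

loglik_frames <- function(r, turn, dt) {
  rt <- r[turn]
  if (any(rt <= 0)) {
    out <- -Inf
    attr(out, "bad_turn_frames") <- sum(rt <= 0)
    return(out)
  }
  sum(log(rt * dt)) - sum(r * dt)
}

# Profile log-likelihood for lambda0 at fixed (b, c): the rate integral
# runs over ALL run frames (x_all), so the lambda0 score is
# n_turn / lambda0 - dt * S_all, giving lambda0 = n_turn / (dt * S_all).
profile_ll_quadratic <- function(bc, x_turn, x_all, dt) {
  b <- bc[1]; c <- if (length(bc) > 1) bc[2] else 0
  S <- sum(exp(b * x_all + c * x_all^2))
  if (!is.finite(S) || S <= 0) return(-1e12)
  nt <- length(x_turn)
  if (nt == 0L) return(-1e12)
  lam0 <- nt / (dt * S)
  nt * log(lam0 * dt) + b * sum(x_turn) + c * sum(x_turn^2) - nt
}

#' Maximum-likelihood fit of a static rate function
#'
#' Fits \eqn{\lambda(x) = \lambda_0 \exp(bx + cx^2)} by unconstrained
#' maximization of the point-process log-likelihood. The baseline
#' \eqn{\lambda_0} is profiled out analytically; (b, c) are optimized
#' numerically with three fixed starting points to guard against local
#' optima. With `per_condition = TRUE` the high- and low-variance frames
#' (from the filtered signal's schedule) are fit independently.
#'
#' @inheritParams loglik
#' @param form `"exp_quadratic"` or `"exp_linear"`.
#' @param per_condition fit high and low variance separately.
#' @return a [static_rate()] with attributes `loglik`, `n_turns`,
#'   `n_frames`; or a list with elements `high` and `low`.
#' @export
fit_static_rate <- function(data, filtered, form = c("exp_quadratic",
                                                     "exp_linear"),
                            per_condition = FALSE, keep = NULL) {
  form <- match.arg(form)
  if (per_condition) {
    sch <- schedule_of(filtered)
    out <- lapply(c(high = "high", low = "low"), function(cond) {
      k2 <- condition_keep(data, sch, cond, keep)
      fit_static_rate(data, filtered, form, FALSE, k2)
    })
    return(out)
  }
  pf <- pooled_run_frames(data, filtered, keep)
  fit_static_frames(pf$x[pf$turn], pf$x, pf$dt, form)
}

schedule_of <- function(filtered) {
  f <- if (inherits(filtered, "filtered_signal")) filtered else filtered[[1]]
  if (is.null(f$schedule)) stop("filtered signal carries no schedule")
  f$schedule
}

#' Frame mask for one variance condition
#'
#' Logical per-frame mask selecting the frames whose schedule condition is
#' `cond`, optionally intersected with an existing mask.
#'
#' @param data a `behavior_dataset`.
#' @param schedule a [variance_schedule()].
#' @param cond `"high"` or `"low"`.
#' @param keep optional logical mask to intersect with.
#' @export
condition_keep <- function(data, schedule, cond, keep = NULL) {
  n_frames <- round(data$duration / data$frame_period)
  t <- (seq_len(n_frames) - 1) * data$frame_period
  k <- condition_at(schedule, t) %in% cond
  if (!is.null(keep)) k <- k & keep[seq_len(n_frames)]
  k
}

fit_static_frames <- function(x_turn, x_all, dt, form = "exp_quadratic") {
  if (length(x_turn) < 100L)
    warning("fewer than 100 turns: rate-function fit may be unstable")
  if (length(x_turn) == 0L) stop("no turns in the analyzed frames")
  nll <- function(p) -profile_ll_quadratic(p, x_turn, x_all, dt)
  starts <- if (form == "exp_linear") list(0, 0.3, -0.3)
            else list(c(0, 0), c(0.3, 0.1), c(-0.3, -0.1))
  best <- NULL
  for (s0 in starts) {
    o <- stats::optim(s0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$convergence != 0)
    warning("optimizer did not formally converge (code ",
            best$convergence, ")")
  b <- best$par[1]; cc <- if (form == "exp_linear") 0 else best$par[2]
  S <- sum(exp(b * x_all + cc * x_all^2))
  lam0 <- length(x_turn) / (dt * S)
  rate <- static_rate(lam0, b, cc, form)
  # standard errors from the observed information on (log lam0, b, c)
  se <- tryCatch({
    full_nll <- function(q) {
      r <- exp(q[1]) * exp(q[2] * x_all +
                             (if (form == "exp_linear") 0 else q[3]) * x_all^2)
      lt <- q[1] + q[2] * x_turn +
        (if (form == "exp_linear") 0 else q[3]) * x_turn^2
      -(sum(lt) + length(x_turn) * log(dt) - sum(r * dt))
    }
    q0 <- if (form == "exp_linear") c(log(lam0), b) else c(log(lam0), b, cc)
    H <- stats::optimHess(q0, full_nll)
    sqrt(diag(solve(H)))
  }, error = function(e) NULL)
  attr(rate, "loglik") <- -best$value
  attr(rate, "se") <- se  # on (log lam0, b[, c])
  attr(rate, "n_turns") <- length(x_turn)
  attr(rate, "n_frames") <- length(x_all)
  rate
}

# Per-frame rate of a rescaling model given condition labels ("high"/"low").
rescaling_rate <- function(kind, lam0, b, c, alpha_low, x, cond) {
  a <- ifelse(cond == "low", alpha_low, 1)
  base <- function(z) lam0 * exp(b * z + c * z^2)
  switch(kind,
         input = base(a * x),
         output = a * base(x),
         recentered_output = a * (base(x) - lam0) + lam0,
         null = base(x),
         stop("unknown rescaling kind"))
}

#' Fit a rescaling model of variance adaptation
#'
#' Joint maximum-likelihood fit over high- and low-variance frames of one of
#' the structural adaptation forms, with the high-variance gain fixed at 1:
#' \describe{
#'   \item{input}{\eqn{r = \lambda(\alpha_{cond}\, x)} — the gain rescales
#'     the filtered input.}
#'   \item{output}{\eqn{r = \alpha_{cond}\, \lambda(x)}.}
#'   \item{recentered_output}{\eqn{r = \alpha_{cond}(\lambda(x) - \lambda_0)
#'     + \lambda_0} — output rescaling preserving the basal rate (can
#'     produce negative rates, which are penalized).}
#'   \item{null}{no adaptation; shared \eqn{(\lambda_0, b, c)}, 3 free
#'     parameters instead of 4.}
#' }
#'
#' @inheritParams loglik
#' @param kind one of `"input"`, `"output"`, `"recentered_output"`,
#'   `"null"`.
#' @param keep logical frame mask; the standard policy drops the first 60 s
#'   and the first 15 s of each 60 s cycle (see [analysis_mask()]).
#' @return object of class `rescaling_fit` with the fitted [static_rate()],
#'   `alpha_low`, `loglik`, `n_params` and `n_data` (larva-seconds).
#' @export
fit_rescaling_model <- function(data, filtered,
                                kind = c("input", "output",
                                         "recentered_output", "null"),
                                keep = NULL) {
  kind <- match.arg(kind)
  sch <- schedule_of(filtered)
  pf <- pooled_run_frames(data, filtered, keep)
  cond <- condition_at(sch, pf$t)
  if (kind == "null") {
    st <- fit_static_frames(pf$x[pf$turn], pf$x, pf$dt)
    fit <- list(kind = "null", static = st, alpha_low = NA_real_,
                loglik = attr(st, "loglik"), n_params = 3L,
                n_data = length(pf$x) * pf$dt)
    return(structure(fit, class = "rescaling_fit"))
  }
  nll <- function(p) {
    r <- rescaling_rate(kind, exp(p[1]), p[2], p[3], exp(p[4]), pf$x, cond)
    ll <- loglik_frames(r, pf$turn, pf$dt)
    if (!is.finite(ll)) 1e12 else -ll
  }
  # start from the null fit with alpha_low near 1
  st0 <- fit_static_frames(pf$x[pf$turn], pf$x, pf$dt)
  starts <- list(c(log(st0$lam0), st0$b, st0$c, log(1.5)),
                 c(log(st0$lam0), st0$b, st0$c, log(1.05)),
                 c(log(st0$lam0), st0$b, st0$c, log(3)))
  best <- NULL
  for (s0 in starts) {
    o <- stats::optim(s0, nll, control = list(maxit = 2000,
                                              reltol = 1e-10))
    o <- stats::optim(o$par, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- best$par
  st <- static_rate(exp(p[1]), p[2], p[3])
  structure(list(kind = kind, static = st, alpha_low = exp(p[4]),
                 loglik = -best$value, n_params = 4L,
                 n_data = length(pf$x) * pf$dt),
            class = "rescaling_fit")
}

#' @export
print.rescaling_fit <- function(x, ...) {
  cat(sprintf(
    "<rescaling_fit %s> lam0 = %.3f min^-1, b = %.3f, c = %.3f, alpha_low = %s\n",
    x$kind, 60 * x$static$lam0, x$static$b, x$static$c,
    ifelse(is.na(x$alpha_low), "-", sprintf("%.3f", x$alpha_low))))
  cat(sprintf("  loglik = %.2f nats, %d params, n_data = %.0f larva-s, BIC = %.1f\n",
              x$loglik, x$n_params, x$n_data,
              bic(x$loglik, x$n_data, x$n_params)))
  invisible(x)
}

#' Bayes information criterion
#'
#' \eqn{BIC = \log(n_{data})\, n_{params} - 2\, LL} with natural logarithms.
#' The sample size is the total number of larva-seconds analyzed. A BIC
#' difference below -10 is considered highly significant (roughly p < 0.01).
#'
#' @param loglik log-likelihood (nats).
#' @param n_data sample size (larva-seconds).
#' @param n_params number of free parameters.
#' @export
bic <- function(loglik, n_data, n_params) {
  if (n_data <= 0) stop("n_data must be positive")
  log(n_data) * n_params - 2 * loglik
}

#' Jackknife comparison of rescaling models on held-out experiments
#'
#' For each permutation of the experiments into a fit set (`n_fit`) and a
#' test set (`n_test`, a standard split is 14 fit : 3 test of 17), each model is fit
#' on the fit set and the log-likelihood of the held-out data is evaluated
#' under the fitted model. Test log-likelihoods are normalized to the mean
#' held-out observation time, \eqn{\bar{LL}_j = LL_j \langle T\rangle /
#' T_j}. Permutations in which a model assigns a negative rate to held-out
#' data (possible for the recentered output model) are excluded and counted.
#'
#' @inheritParams fit_rescaling_model
#' @param kinds character vector of model kinds to compare.
#' @param n_fit,n_test experiments in the fit and test sets (must sum to the
#'   number of experiments).
#' @param max_perm cap on the number of permutations (all used if the number
#'   of subsets is below the cap; otherwise a random sample).
#' @param seed integer RNG seed (used only when sampling permutations).
#' @return data frame with one row per (permutation, model): the normalized
#'   test log-likelihood `ll_norm`; attribute `n_excluded` counts exclusions
#'   per model.
#' @export
jackknife_compare <- function(data, filtered, kinds = c("null", "input",
                                                        "output",
                                                        "recentered_output"),
                              n_fit, n_test, keep = NULL, max_perm = 100,
                              seed = NULL) {
  n_exp <- length(data$experiments)
  if (n_exp < 2L) stop("need at least two experiments")
  if (n_fit + n_test != n_exp) stop("n_fit + n_test must equal #experiments")
  sets <- utils::combn(n_exp, n_test, simplify = FALSE)
  if (length(sets) > max_perm) {
    if (!is.null(seed)) set.seed(seed)
    sets <- sets[sample.int(length(sets), max_perm)]
  }
  subset_data <- function(idx) {
    d <- data; d$experiments <- data$experiments[idx]; d
  }
  subset_filt <- function(idx) {
    if (inherits(filtered, "filtered_signal")) filtered else filtered[idx]
  }
  sch <- schedule_of(filtered)
  rows <- list(); excl <- stats::setNames(integer(length(kinds)), kinds)
  t_test <- numeric(0)
  res <- list()
  for (j in seq_along(sets)) {
    test_idx <- sets[[j]]
    fit_idx <- setdiff(seq_len(n_exp), test_idx)
    dfit <- subset_data(fit_idx); dtest <- subset_data(test_idx)
    ffit <- subset_filt(fit_idx); ftest <- subset_filt(test_idx)
    pf_test <- pooled_run_frames(dtest, ftest, keep)
    cond_test <- condition_at(sch, pf_test$t)
    Tj <- length(pf_test$x) * pf_test$dt
    lls <- vapply(kinds, function(kd) {
      fit <- fit_rescaling_model(dfit, ffit, kd, keep)
      r <- rescaling_rate(kd, fit$static$lam0, fit$static$b, fit$static$c,
                          fit$alpha_low, pf_test$x, cond_test)
      if (any(r <= 0)) return(NA_real_)
      loglik_frames(r, pf_test$turn, pf_test$dt)
    }, numeric(1))
    res[[j]] <- list(perm = j, ll = lls, T = Tj)
  }
  Tbar <- mean(vapply(res, `[[`, numeric(1), "T"))
  out <- do.call(rbind, lapply(res, function(r)
    data.frame(perm = r$perm, model = kinds,
               ll = unname(r$ll), T_test = r$T,
               ll_norm = unname(r$ll) * Tbar / r$T,
               row.names = NULL)))
  for (kd in kinds) excl[kd] <- sum(is.na(out$ll[out$model == kd]))
  attr(out, "n_excluded") <- excl
  out
}
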
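# Shared fixtures: small LNP populations built in code. Scales are kept
# modest; statistical assertions use tolerances appropriate for the turn
# counts they generate.

std_kernel <- function() default_kernel()

std_rate <- function() static_rate(3 / 60, b = 0.5, c = 0.03)

# One-experiment dataset with known generating model on a fresh stimulus.
sim_simple <- function(duration = 300, n_larvae = 30, seed = 1,
                       schedule = switching_schedule(duration, duration, 4, 4),
                       rate = std_rate(), gain = NULL, refractory = 2) {
  tr <- gen_brownian_intensity(duration, schedule, seed = seed)
  dv <- derivative_series(tr)
  ds <- simulate_turns(dv, std_kernel(), rate, gain, n_larvae, duration,
                       seed = seed + 1000, refractory = refractory)
  list(trace = tr, deriv = dv, data = ds,
       filtered = filter_stimulus(std_kernel(), dv), schedule = schedule)
}

# Multi-experiment switching study with step-control input rescaling.
sim_switching_study <- function(n_experiments = 2, n_larvae = 30,
                                duration = 360, half_period = 20,
                                alphas = c(high = 1, low = 2), seed = 7) {
  sch <- switching_schedule(duration, half_period, 9, 1)
  gain_fn <- if (is.null(alphas)) NULL else
    function(schedule, n_frames, deriv)
      step_control_gain(schedule, alphas, n_frames = n_frames)
  ds <- simulate_study(n_experiments, n_larvae, duration, sch, std_kernel(),
                       std_rate(), gain_fn, seed = seed)
  derivs <- lapply(ds$experiments, `[[`, "deriv")
  filt <- lapply(derivs, function(d)
    suppressMessages(filter_stimulus(std_kernel(), d)))
  list(data = ds, derivs = derivs, filtered = filt, schedule = sch)
}

# Independent brute-force forward filter used as the oracle for the grid
# tracker: plain R, explicit integrals on an arbitrary grid.
brute_filter <- function(grid, xt_list, xn_list, st, dt, step, tau) {
  sdv <- sqrt(2 * step / tau)
  # same diffusion operator (each source cell keeps its mass on the
  # truncated grid), written out loop-wise rather than as a matrix product
  col_mass <- vapply(grid, function(b)
    sum(dnorm(grid - b, 0, sdv)), numeric(1))
  post <- rep(1, length(grid)); post <- post / sum(post)
  modes <- numeric(length(xn_list))
  for (i in seq_along(xn_list)) {
    prior <- vapply(grid, function(g)
      sum(dnorm(g - grid, 0, sdv) * post / col_mass), numeric(1))
    prior <- prior / sum(prior)
    ll <- vapply(grid, function(g) {
      lt <- if (length(xt_list[[i]]))
        sum(log(st$lam0 * dt) + st$b * g * xt_list[[i]] +
              st$c * g^2 * xt_list[[i]]^2) else 0
      lt - sum(st$lam0 * exp(st$b * g * xn_list[[i]] +
                               st$c * g^2 * xn_list[[i]]^2) * dt)
    }, numeric(1))
    w <- prior * exp(ll - max(ll))
    post <- w / sum(w)
    modes[i] <- grid[which.max(post)]
  }
  modes
}
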
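# navadapt

Variance adaptation in navigational decision making: behavioral reverse
correlation and adaptive Linear–Nonlinear–Poisson (LNP) modelling of larval
*Drosophila* turn decisions, with Bayesian tracking of the time-varying
input gain.

Crawling larvae end runs (bouts of forward crawling) with turns, and the
decision to turn can be modelled as an inhomogeneous Poisson process whose
rate depends on recent sensory input:

    r(t) = λ(α(t) · x(t)),      λ(x) = λ₀ exp(b x + c x²),
    x(t) = (w ∗ dI/dt)(t)

where `dI/dt` is the time-derivative of the (light) stimulus intensity,
`w` a causal linear kernel estimated by turn-triggered averaging (the
behavioral analogue of a spike-triggered average), λ an exponential-
quadratic rate nonlinearity, and `α(t)` an *input rescaling* — the gain by
which the animal divides out the stimulus standard deviation as it adapts
to changes in environmental variance. The package implements, end to end
on synthetic data:

* **Stimulus generation** — reflected Brownian intensity walks with
  switching or triangle-wave variance schedules, uncorrelated random
  levels, correlated odor/light channel pairs, and sinusoidal gas
  backgrounds (`gen_brownian_intensity()`, `gen_uncorrelated_intensity()`,
  `gen_correlated_pair()`, `gen_sinusoid_background()`).
* **Population simulation** — Poisson turn decisions of independent larvae
  from an adaptive LNP cascade, including the instant-switch "step
  control" and two-channel multisensory variants (`simulate_turns()`,
  `step_control_gain()`, `simulate_multisensory()`, `simulate_study()`).
* **Reverse correlation** — turn-triggered averages with hierarchical
  bootstrap bands, kernel normalization, causal filtering and binned turn
  rates (`turn_triggered_average()`, `bootstrap_tta()`,
  `normalize_kernel()`, `filter_stimulus()`, `binned_turn_rate()`).
* **Likelihood modelling** — point-process maximum likelihood for static
  rates, the input/output/recentered-output rescaling model family, BIC
  and leave-k-experiments-out jackknife comparison (`fit_static_rate()`,
  `fit_rescaling_model()`, `bic()`, `jackknife_compare()`).
* **Gain tracking** — a recursive Bayesian grid filter for α(t) with a
  diffusive smoothness prior, its 2D (α, β) two-channel extension,
  uncertainty-weighted cycle averaging, and the rescaling law
  α(σ) = α₀/√(σ² + σ₀²) (`track_alpha()`, `iterate_fit()`,
  `track_alpha_beta()`, `cycle_average()`, `fit_alpha_sigma_law()`).
* **Optimal variance estimation** — a Bayes filter over the stimulus SD
  with a diffusive prior, the σ → α mapping, and the (Δt, τ) likelihood
  grid search against behavior (`bayes_variance_estimate()`,
  `predict_alpha()`, `grid_search()`).
* **Multisensory integration** — rotated odor/light coordinates, the
  combination-angle fit, and comparison of independent-additive,
  early-linear and multiplicative two-input rate models
  (`rotate_coords()`, `fit_theta()`, `fit_integration_models()`).

## Worked example

Simulate a variance-switching experiment (σ² alternating 9/1 every 60 s)
with a population whose gain doubles in the low-variance condition, then
recover the kernel and the rescaling by reverse correlation:

```r
library(navadapt)

sch   <- switching_schedule(duration = 600, half_period = 60, high = 9, low = 1)
trace <- gen_brownian_intensity(600, sch, seed = 1)
deriv <- derivative_series(trace)
gain  <- step_control_gain(sch, c(high = 1, low = 2))
data  <- simulate_turns(deriv, default_kernel(),
                        static_rate(3/60, b = 0.5, c = 0.03),
                        gain, n_larvae = 40, duration = 600, seed = 2)
data
#> <behavior_dataset> 1 experiment(s), 40 larvae, 2319 turns, 600 s

keep <- analysis_mask(600, schedule = sch, burn_in = 60, cycle_discard = 15)
tta  <- turn_triggered_average(data, deriv, keep = keep)
kern <- normalize_kernel(tta, deriv)
kern
#> <kernel> 70 bins of 0.1 s, lags [-4.95, 1.95] s, unit_low_variance_output

x   <- filter_stimulus(kern, deriv)
fit <- fit_rescaling_model(data, x, "input", keep)
fit
#> <rescaling_fit input> lam0 = 3.245 min^-1, b = 0.490, c = 0.007, alpha_low = 2.094
#>   loglik = -7883.79 nats, 4 params, n_data = 13284 larva-s, BIC = 15805.6
```

The estimated kernel is the turn-triggered average scaled so the filtered
signal has unit variance at low variance; the input-rescaling fit recovers
the generating gain ratio (α_low ≈ 2.09 against a true value of 2) and
baseline rate (3.2 min⁻¹ against 3), and beats the no-adaptation null by
ΔBIC = −164 on this single simulated experiment. `run_pipeline()` wraps
the whole chain — simulation, reverse correlation, model comparison and
gain tracking — behind one configuration object.

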
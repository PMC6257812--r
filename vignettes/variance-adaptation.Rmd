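---
title: "Modelling variance adaptation in larval navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling variance adaptation in larval navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(navadapt)
```

# The model

A crawling larva alternates runs with turns. We model the decision to end
a run as an inhomogeneous Poisson process driven by a
Linear–Nonlinear–Poisson (LNP) cascade: the time-derivative of stimulus
intensity is convolved with a causal kernel $w$ to give a filtered signal
$x(t)$; a static nonlinearity maps it to a turn rate

$$\lambda(x) = \lambda_0 \exp(b x + c x^2),$$

and turns are emitted stochastically at rate $r$. Adaptation to the
variance of the input is modelled as an *input rescaling*: a time-varying
gain multiplies the filtered signal before the nonlinearity,

$$r(t, x) = \lambda(\alpha(t)\, x(t)).$$

Two alternatives — output rescaling $r = \alpha\lambda(x)$ and recentered
output rescaling $r = \alpha(\lambda(x) - \lambda_0) + \lambda_0$ — are
implemented for model comparison (`fit_rescaling_model()`): with the gain
of the high-variance condition pinned at 1 each has four free parameters
$(\lambda_0, b, c, \alpha_{low})$, against three for the no-adaptation
null.

The data likelihood is the discrete point-process form over all analyzed
run frames (20 Hz),

$$LL = \sum_{\text{turn}} \log(r\,dt) \;-\; \sum_{\text{run frames}} r\,dt,$$

the short-interval limit of the per-frame Bernoulli likelihood with turn
probability $1 - e^{-r\,dt}$. Natural logarithms are used throughout;
rates are held in s$^{-1}$ internally and reported in min$^{-1}$.

# Stimuli

The main stimulus is a Brownian random walk of light intensity on the
0–255 hardware scale, updated at 120 Hz, starting at 127, with Gaussian
increments of scheduled variance and reflecting boundaries (`I \to -I`
below 0, `I \to 510 - I` above 255, applied iteratively). Its derivative
is mean-zero white noise whose variance is the experimental dial, while
the intensity itself stays uniform on the range in the long run —
variance changes cannot be confounded with mean-intensity adaptation.
Variance schedules (`variance_schedule()`) cover square-wave switching
(60 s or 20 s half-periods, $\sigma^2_{high} = 9\sigma^2_{low}$), a 120 s
period triangle wave in the standard deviation, random uncorrelated
levels redrawn every 0.25 s (mean 128, SD 17 or 51, clipped to range),
and correlated odor/light channel pairs built from three independent
Gaussian sources,

$$s_o = \sqrt{1-|c|}\,x_1 + \sqrt{|c|}\,x_3,\qquad
  s_l = \sqrt{1-|c|}\,x_2 \pm \sqrt{|c|}\,x_3,$$

which keeps each marginal increment variance at $\sigma^2$ while the
combined coordinate $(s_o + s_l)/\sqrt2$ has variance
$\sigma^2(1 + c)$; switching $c$ between $\pm 0.8$ at $\sigma^2 = 5$
switches the *joint* variance 9-fold with constant unisensory variance.
Because the odor and light kernels have opposite signs, the negative-$c$
branch is the behaviorally high-variance condition and is labelled so by
`condition_at()`.

Reflection is order-dependent (folding the free walk at the end gives a
different path), so the walk integration is a small C++ loop; the drawn
pre-reflection increments are kept on the trace for ensemble statistics.

# The synthetic population

`simulate_turns()` draws, at each 20 Hz frame of a run, a turn with
probability $1 - e^{-r\,dt}$ and then holds the larva out of the run for
a fixed 2 s refractory (turn duration is not modelled mechanistically;
all estimation conditions on run frames, so results are insensitive to
this choice, which is configurable). Larvae are independent, start
running at $t = 0$, and have no positions — the stimulus is spatially
uniform and the analysis needs only run intervals and turn times. The
default generating parameters are $\lambda_0 = 3\ \text{min}^{-1}$,
$b = 0.5$, $c = 0.03$ on the unit-low-variance filtered scale, chosen so
that simulated turn totals (a few turns per larva-minute) and the
dynamic range of the rate function (roughly 1–30 min$^{-1}$ over
$\pm 3$ SD) match the turn totals such experiments yield; the step-control gain uses
$\alpha_{high} = 1$, $\alpha_{low} = 2$. The study scale is ~10–30
experiments of 20 min with ~40–50 larvae each; examples and tests run
reduced scales (stated with each test) and their statistical tolerances
are derived from those scales.

What the generator does *not* emulate: larvae entering and leaving the
field of view, tracking/segmentation noise in event times, head sweeps
and turn-size decisions, arena geometry, and any slow non-stationarity of
behavior. Passing tests therefore validate the estimation chain under the
model's own assumptions, not the upstream video analysis.

# Reverse correlation

The kernel is the turn-triggered average (`turn_triggered_average()`):
the mean derivative trace in 0.1 s bins around every turn (5 s pre, 2 s
post by default; only the causal pre-turn part is used for filtering).
For the random-levels stimulus the mean-subtracted intensity itself is
the model input (`intensity_series()`) and the average is low-passed with
a Gaussian of $\sigma = 0.25$ s to remove the 4 Hz update artifact
(`smooth_tta()`). Uncertainty bands come from a two-level bootstrap —
experiments with replacement, then larvae with replacement within each
chosen experiment, 100 replicates — which respects between-experiment
correlation. The kernel is scaled so the filtered signal has unit
variance over low-variance frames (`normalize_kernel()`), putting rate
parameters on a common scale; with the standard 9:1 schedule the
high-variance filtered SD is then 3.

Binned rates use eight equal-count bins of the filtered signal over
analyzed run frames (equal-count placement avoids empty bins; the source
analysis does not state edge placement), with
$r = 60\,(N_{turn}/N_{run})/dt$ and Poisson uncertainty
$60\sqrt{N_{turn}}/(N_{run}\,dt)$.

Discard policy: the first 60 s of each experiment (response to the novel
environment), and for variance-conditioned analyses the first 15 s of
each 60 s half-cycle or 10 s of each 20 s half-cycle (un-adapted
transients); all configurable through `analysis_mask()`. Turns are
assigned to the frame ending at the turn time; that frame counts both as
a turn and as a run frame. Intervals are half-open $[t_0, t_1)$ and times
are seconds from experiment start.

# Tracking the gain

`track_alpha()` is a grid-based recursive Bayes filter: 501 gain values
uniform on $[0, 5]$, a Gaussian random-walk prior with per-step variance
$2\,\Delta t_{track}/\tau$ ($\tau = 5$ s; $\Delta t_{track} = 0.1$ s for
switching experiments, 1 s for triangle-wave experiments), and per-step
likelihoods that aggregate all 20 Hz frames falling in the step across
experiments and larvae. The posterior starts uniform (maximum entropy;
the choice washes out within a few $\tau$) and tracking starts at 60 s.
The reported trajectory is the per-step posterior *mode*, with the
posterior SD as its uncertainty; the transition matrix is
column-normalized so each source cell keeps its mass on the truncated
grid, and edge-pinned modes raise an error.

`iterate_fit()` alternates static-parameter MLE (with $\alpha(t)x$ as
the regressor) and re-tracking. Because only the product $\alpha b$ is
identified, the trajectory is renormalized to mean 1 every iteration.
With populations in the reference range the likelihood plateaus within a
few iterations; at small scale it can keep creeping by a few nats per
iteration as the flexible latent path absorbs sampling noise, so the
iteration cap (`max_iter`, default 4) is the effective stopping rule
there and the convergence tolerance (`tol = 1e-4` nats) matters only for
large data. Small non-monotone wiggles of the log-likelihood are
possible — the tracking step is a filter, not a joint maximization — and
produce a warning, not an error.

Two practical notes on interpreting trajectories. First, the per-step
posterior width is set by the Fisher information of that step's turns,
which scales as $(b\,x)^2$: low-variance segments carry roughly
$1/81$ the information of high-variance segments per turn, so raw modes
wander there. The scientific statements (flat gain, symmetric step
response, adaptation asymmetry) refer to the uncertainty-weighted
*cycle average* (`cycle_average()`, weights $\propto 1/\sigma$,
normalized to sum to 1 at each phase), which is what the estimation was
designed to feed. Second, the two-channel tracker
(`track_alpha_beta()`, 101×101 grid on $[0,4]^2$) implements the
uncorrelated prior ($\tau_{\alpha\beta} = 0$, the default) via a separable transition; a correlated prior is not
implemented.

The adapted rescaling law is fit by nonlinear least squares as
$\alpha(\sigma) = \alpha_0/\sqrt{\sigma^2 + \sigma_0^2}$
(`fit_alpha_sigma_law()`), with $\sigma_0 \ge 0$ enforced (clamped at 0
with a warning). $\sigma_0$ is weakly identified — it only bends the
curve near the smallest $\sigma$ — so end-to-end recoveries constrain it
loosely even when $\alpha_0$ is tight. Rising/falling subsets (by the
sign of the local $\sigma$ trend) support the hysteresis check.

# Optimal variance estimation

`bayes_variance_estimate()` filters the posterior over the stimulus SD:
every $\Delta t$ it observes the total intensity change $s_i$ over the
interval, diffuses with a Gaussian kernel of variance $2\Delta t/\tau$,
multiplies by $N(s_i; 0, \sigma_i^2)$, and renormalizes. The grid is 400
log-spaced points covering $[0.1\times, 10\times]$ the pooled empirical
SD by default; the prior is on $\sigma$ (not $\sigma^2$), truncated at a
small positive floor. On a non-uniform grid the reported mode is the
*density* mode (per-cell mass divided by cell width) — the mass mode is
biased toward wide cells. An all-zero input drives the mode to the grid
floor; posterior modes pinned at the upper edge raise a coverage error.

The estimate maps to a predicted gain through the rescaling law
(`predicted_gain()`), after converting the SD from
intensity-change-over-$\Delta t$ units to per-update (filtered-signal)
units by $\sqrt{\Delta t / \text{update period}}$, and normalizing the
mean gain to 1 (the absolute scale is not identified). The asymmetry of
adaptation — sudden gain drop after a variance increase, gradual rise
after a decrease — is a property of the gain $\alpha \propto 1/\sigma$:
large samples immediately exclude small $\sigma$, while small samples
only slowly accumulate evidence against large $\sigma$, and the
reciprocal's convexity sharpens the drop.

`grid_search()` scores candidate $(\Delta t, \tau)$ pairs against
behavior: per cell it re-runs the estimator on each experiment's
stimulus, predicts the gain, refits the static rate by MLE given that
gain, and records the total log-likelihood; only differences across the
surface are meaningful. The default grids span 0.25–3 s and 1–60 s in 12
log steps. The optional bootstrap confidence region resamples
experiments while holding each cell's fitted parameters fixed — an
approximation that avoids refitting per replicate.

# Multisensory analysis

For correlated two-channel stimuli, `fit_theta()` finds the single
combination $u = \cos\theta\, x_o + \sin\theta\, x_L$ driving turns, by
profile likelihood over a coarse $\theta$ scan (3° default) with local
refinement — the joint surface has local optima, so the scan comes
first. The orthogonal coordinate's weight $b$ is then refit at fixed
$\theta$ with a standard error from the observed information; $b \approx
0$ validates the one-coordinate description. The $\pm 0.8$ increment
correlation makes $\theta$ locally flat, so angle recoveries need larger
turn counts than rate-parameter recoveries.

`fit_integration_models()` compares three two-input rate functions:
independent additive $\lambda_o(x_o) + \lambda_L(x_L)$, early linear
$\lambda_1(a x_o + b x_L)$, and multiplicative
$\lambda_o(x_o)\lambda_L(x_L)$, each factor an exponential of a degree-1
or degree-2 polynomial. At degree 1 the early-linear and multiplicative
forms are algebraically identical and share one fit; at degree 2 the
multiplicative factorization
$\lambda_0 e^{b_1 x_o + c_1 x_o^2} e^{b_2 x_L + c_2 x_L^2}$ (5
parameters) is compared with the early-linear
$\lambda_0 e^{b(a x_o + \sqrt{1-a^2} x_L) + c(\cdot)^2}$ (4 parameters)
by BIC, which absorbs the parameter-count difference. The degree-2
parameterization is our exponential-of-quadratic reading of the
"product of unisensory nonlinearities" idea; other saturating forms
would serve the same comparison.

# Model comparison conventions

BIC is $\log(n_{data}) k - 2 LL$ with $n_{data}$ the total larva-seconds
analyzed (counting 20 Hz frames instead would shift comparisons by
$\log 20 \approx 3$ per extra parameter without changing any ranking);
differences below $-10$ are treated as highly significant. The jackknife
fits each model on all but `n_test` experiments (a standard split is
14 fit / 3 test of 17) and evaluates held-out log-likelihood, normalized
by observation time $\overline{LL}_j = LL_j \langle T\rangle / T_j$;
permutations where a model predicts a negative rate on test data (the
recentered output form can) are excluded and counted. A held-out margin
of 4.6 nats corresponds to a 100:1 likelihood ratio.

# Numerical choices and degenerate inputs

* Optimization is quasi-Newton (BFGS) on unconstrained transforms
  (log $\lambda_0$, log $\alpha$), with $\lambda_0$ profiled out
  analytically wherever the rate factorizes, and three fixed starting
  points per fit; rescaling-model fits start from the null fit.
* Standard errors come from the observed information at the optimum.
* Zero-noise schedules give constant traces; a zero kernel gives an
  all-zero filtered signal and normalization then fails loudly; fits
  with no turns, empty schedules, out-of-range correlations, negative
  amplitudes and mismatched frame grids raise errors rather than
  guessing.
* All randomness flows through explicit seeds; per-stage streams are
  derived from one global seed so changing one stage's replicate count
  does not perturb another stage's draws.

# Known limitations

The tracker is a forward filter; no smoothing (forward–backward) pass is
provided, so trajectory estimates lag slightly at sharp transitions.
The thinning simulation and the Poisson-form likelihood agree to
$O(r\,dt)$; with steep rate functions and extreme filtered values the
per-frame turn probability saturates and fitted slopes attenuate
slightly — visible only in the far tails of high-variance segments. The
2D tracker supports only the uncorrelated prior. Bootstrap confidence
regions for the $(\Delta t, \tau)$ search hold per-cell parameters
fixed. None of the quantities that depend on the original behavioral
recordings (fitted sampling timescales and condition gain ratios) are
reproduced as numbers; they are validated as recovery properties on
synthetic data generated under the same stimulus conditions.
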
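---
title: "Estimating sensitivity thresholds with Bayesian adaptive Yes-No and forced-choice methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sensitivity thresholds with Bayesian adaptive Yes-No and forced-choice methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quickSDT)
```

## The problem

A detection threshold summarises the sensitivity of an observer (human,
animal, or model) in a single number. Yes-No (YN) detection is statistically
the most efficient way to measure it, but the observer's *decision
criterion* — their willingness to say *Yes* — contaminates any threshold
defined on the raw psychometric function: a liberal observer and a sensitive
observer both say *Yes* to weak signals. quickSDT implements a family of
Bayesian adaptive procedures (qYN, qYNC, qYNR, qFC) that sidestep this by
estimating the *sensitivity threshold* — the signal contrast at which the
Signal Detection Theory sensitivity index d′ equals 1 — jointly with the
decision parameters, so the threshold estimate is criterion-free by
construction.

## The model

Sensitivity follows a saturating transducer of signal contrast $c$:

$$d'(c) = \frac{\beta\,(c/\tau)^{\gamma}}{\sqrt{(\beta^2-1) + (c/\tau)^{2\gamma}}},$$

with $\tau$ the contrast at which $d'=1$ (the quantity of interest),
$\gamma$ the steepness, and $\beta$ the asymptote, fixed at 5 because
performance differences above $d' \approx 4$ are practically unmeasurable.
Decision behaviour maps $d'$ to response probabilities through criteria in
z units:

* **simple detection (qYN)** — $\Psi_{yes}(c) = 1 - \Phi(\lambda - d'(c))$;
  the false-alarm rate is $1 - \Phi(\lambda)$. Three parameters
  $(\tau, \gamma, \lambda)$.
* **cued detection (qYNC)** — a pre-trial cue selects a lax or strict
  criterion. To enforce $\lambda_{lax} \le \lambda_{strict}$ the method
  estimates $\lambda_{strict}$ and the non-negative offset
  $\Delta\lambda = \lambda_{strict} - \lambda_{lax}$. Four parameters.
* **rated detection (qYNR)** — both criteria are held simultaneously and
  the response is ternary (*Yes* above strict, *No* below lax, *Not Sure*
  between). Same four parameters; collapsing *Yes* + *Not Sure* recovers the
  lax curve exactly.
* **forced choice (qFC)** — the decision variable is the difference of the
  two interval responses, so
  $\Psi_{I2} = 1 - \Phi(\lambda_{FC} - [d'(c_2) - d'(c_1)]/\sqrt{2})$.
  The $\sqrt{2}$ is forced by the unit-variance difference distribution and
  reproduces the textbook ~76% correct at $d' = 1$ under a neutral
  criterion; $\lambda_{FC} \ne 0$ models interval bias. The method selects
  both the contrast and the interval (signed contrast), and the stimulus
  space includes the double-blank condition.

Lapses (finger errors, blinks) occur at rate $\varepsilon = 2\%$ and are
distributed equally over the $K$ response categories:
$\Psi' = \varepsilon/K + (1-\varepsilon)\Psi$. The multiplicative form
alone would leave the upper asymptote at 100%; the symmetric form gives the
correct 99% cap for a binary task and bounds every response probability
away from zero, which also protects the Bayesian update from zero
likelihoods. $\beta$ and $\varepsilon$ are fixed, config-overridable, and
excluded from inference.

## The adaptive engine

The posterior lives on a discrete grid over the 3 or 4 task parameters
(log-spaced in $\tau$ and $\gamma$, linear in the criteria). Each trial:

1. For every candidate condition $s$, the predictive response distribution
   is $p(r|s) = \sum_\theta \Psi'(r|s,\theta)\,p_t(\theta)$ and the
   one-step-ahead expected posterior entropy is
   $E[H_{t+1}(s)] = \sum_r p(r|s)\, H(p_{t+1}(\cdot|s,r))$.
2. The condition minimising $E[H_{t+1}]$ is presented (exact ties broken
   uniformly at random from a dedicated seeded stream).
3. The posterior is updated by Bayes' rule with the observed response and
   becomes the next trial's prior.

Runs stop after a fixed trial count or when the threshold credible interval
is narrow enough. Entropies use natural logarithms (the argmin is
base-invariant) with the $0\log 0 = 0$ convention and a $10^{-300}$ floor
inside logarithms.

Two implementation notes that do not change results. First, response
probabilities per (condition, grid node) are precomputed once per task into
a likelihood table; a test asserts the cached and direct paths agree to
machine precision. Second, because $\sum_r \Psi'(r|s,\theta) = 1$, the
selection objective decomposes as
$E[H_{t+1}(s)] = H_t + \sum_r p(r|s)\log p(r|s) - \sum_\theta p_t(\theta) \sum_r \Psi' \log \Psi'$,
whose last term is a posterior expectation of a precomputable table; the
replicated-study driver uses this identity (and advances all replications
in lock-step as one matrix, with an in-place compiled update) so that a
trial costs two matrix products for an entire batch. The exhaustive-
enumeration oracle tests pin both paths to the definition.

### Priors

Each marginal is a hyperbolic secant, $\propto \operatorname{sech}(k\,u)$,
with $u = \log_{10}(x/\mathrm{mode})$ for $\tau$ and $\gamma$ and
$u = x - \mathrm{mode}$ (z units) for criteria; the confidence $k$ is the
reciprocal width in those units. This convention is a package decision —
the mode/confidence pairs in the literature on these methods are not
accompanied by an explicit scale — chosen so that published confidence
values (weak 1.6, strict 11.5 for the threshold; 6.1 for steepness; 2.1
for criteria) are usable verbatim. The joint prior is the normalised
product of marginals; as $k \to 0$ it tends to the uniform grid prior.

### Estimates

$\hat\tau = 10^{E[\log_{10}\tau]}$ under the marginal posterior (and
analogously for $\gamma$); criterion estimates are linear marginal means.
Credible intervals are central marginal quantile intervals, by default at
68.2% — the level is not dictated by the method and is configurable.

## The simulation harness

`run_study()` replicates full adaptive sessions against simulated observers
that answer from exactly the model above (including the lapse process —
matched-model simulation; a flag gives lapse-free observers). Observer
states are specified operationally, by null-stimulus response rates, and
converted through $\Phi^{-1}$:

* qYN: false-alarm rates 2.5, 10, 40%;
* qYNC: (strict, lax) false-alarm pairs (2.5, 10), (2.5, 40), (10, 40)%;
* qYNR: null (Yes, No) rates (2.5, 90), (2.5, 60), (10, 60)%;
* qFC: null Interval-2 rates 30, 50, 70% (interval bias ±20%).

All states share $\tau = 10\%$ contrast and $\gamma = 2$. Accuracy is the
mean threshold bias $10\log_{10}(\hat\tau/\tau)$ in dB (1 dB = 0.1 decimal
log units; the median is also reported), precision the standard deviation
of the estimates across replications.

The harness's default prior is the *weak matched* prior: marginals centred
on the simulated observer's generating parameters with the weak confidences
(1.6, 6.1, 2.1). The source methodology describes its simulation priors as
centred on the initial guess and calls mode-equals-truth "matched"; with the
observer states defined by their false-alarm rates, centring the criterion
prior on the state's true criterion is the faithful reading. The choice
matters: fixing the criterion prior mode at 1 z for all states biases the
trial-25 threshold estimate by about ±1 dB for the extreme states (upward
for the conservative observer, downward for the liberal one — the model
trades criterion against threshold), and `prior_mismatch_study()`
quantifies exactly this mechanism for the threshold prior, reproducing the
weak/strict × matched/mismatched design (which keeps its published fixed
criterion prior of (1, 2.1)).

### Problem sizes

The full-resolution grid is 59 (τ, 0.0025–1.25, log) × 58 (γ, 0.4–10,
log) × 56 (λ, −1–3, linear) with 120 log-spaced contrasts in
[0.001, 0.99]. Replicated studies default to a half-resolution grid
(30 × 29 × 28, 60 contrasts): after 25 trials the posterior is far wider
than the grid step, and a full-grid control run reproduced the trial-25
bias and precision of the coarse grid to within Monte-Carlo error. For the
four-parameter tasks, where no published grid exists, the package uses
30 × 29 × 20 (λ_strict) × 12 (Δλ, 0–2.5) with 40 contrasts (conditions are
doubled by the cue state or interval sign), and qFC uses a λ_FC axis of 28
points on −2–2, covering the ±20% interval-bias states with margin.
Studies run 300 replications per state by default (1000 matches the
reference scale), scoring checkpoints at trials 10/25/50/100.

`criterion_recovery()` reports the posterior-mean null-stimulus response
rates — the lapse-adjusted response probabilities at $d' = 0$ implied by
the criterion marginals — which is how the harness shows that response
states of equal sensitivity but different criterion are separated within
~25 trials. `stimulus_histograms()` exposes the sampling policy (ordinary
and cumulative, per cue state or interval): liberal states draw extra
low-contrast placements because only the lower asymptote separates a low
threshold from a liberal criterion. For interval-biased forced choice the
sampling is markedly asymmetric within the first ten trials, and the engine
concentrates on the interval the observer is biased *against*: that is
where the criterion-shifted psychometric limb is steep, hence informative
(for a neutral observer the two limbs are mirror images and sampling is
balanced).

### What the simulations do and do not show

Simulated observers are stationary, match the model family exactly, and
lapse independently at a known rate. Passing recovery tests therefore
demonstrates the correctness and efficiency of the inference machinery, not
robustness to criterion drift, learning, serial dependence, or transducer
misspecification in real observers — the method-of-constant-stimuli fitter
exists precisely so real datasets can test the model assumptions
(goodness-of-fit) independently of the adaptive machinery.

## The MCS joint fit

`fit_mcs()` fits count tables from method-of-constant-stimuli sessions
across any subset of the four tasks by maximum likelihood, with a *single*
$(\tau, \gamma)$ shared across tasks and up to six task-specific criteria
(one each for simple and FC, two each for cued and rated; rated cells use
the full trinomial). Optimisation is Nelder-Mead in transformed
coordinates — $\log_{10}\tau$, $\log_{10}\gamma$, raw criteria,
$\log_{10}\Delta$ to respect positivity and the criterion order — from a
data-driven start (null-condition rates through $\Phi^{-1}$) plus seeded
jittered restarts. Goodness-of-fit is a parametric-bootstrap deviance test
against the saturated multinomial model (simulate at the fit, refit,
compare deviances); parameter uncertainty comes from parametric-bootstrap
refits, with the threshold SE reported in dB. Degenerate zero-variance
bootstrap distributions are flagged rather than reported as spurious
certainty. `simulate_mcs()` generates the synthetic multi-task datasets
used throughout the tests; its default design mirrors the validation
layout (null + 7 log-spaced contrasts at 8–60% per YN task, five signed
levels + double blank for FC, 50 trials per condition).

## Numerical and design choices

* Contrast is a decimal fraction in (0, 1) internally; percent strings
  ("10%") are accepted at I/O boundaries. dB is $10\log_{10}$ of a ratio.
* The qYNC search space is the full (contrast × cue state) product — the
  engine chooses the cue, which is how the reference conditions are
  defined; an external cue schedule can be imposed by restricting the
  condition set for live experiments.
* The qFC stimulus space includes the double-blank condition by default
  (`include_null = FALSE` removes it).
* Reproducibility: a master seed spawns an independent uniform stream per
  replication (responses and tie-breaks pre-drawn per stream), so studies
  are bit-reproducible and replication results do not depend on batch
  order.
* Session logs are plain CSV plus a JSON sidecar (config snapshot, final
  estimates, package version, config hash); configs round-trip through
  YAML or JSON with unknown keys rejected by name.

## Known limitations

* Rating tasks with more than three categories and n-interval forced
  choice (n > 2) are out of scope, as are non-stationary observers and
  alternative selection objectives (e.g. minimum expected variance).
* Grid-based inference degrades if the true parameters approach the grid
  edges; the default ranges cover the intended regimes (false-alarm rates
  below ~75%, thresholds within the contrast range) and `parameter_grid()`
  accepts explicit axes when they do not.
* The trial-25 precision of qFC (~1.2 dB) is inherently worse than YN at
  matched trial counts — the truncated dynamic range of forced choice is
  the reason the YN methods exist.
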
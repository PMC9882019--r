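---
title: "Geometric model selection and simplicity preferences: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric model selection and simplicity preferences: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(occamfia)
```

This vignette is the package's own account of its science: the evidence
model and its expansion, the conventions every module shares, the task
and observer design, the estimation machinery, and the places where the
design was genuinely open and a choice had to be made.

## 1. The decision problem

A trial presents `N` points drawn iid from an isotropic 2D Gaussian with
standard deviation `sigma`, centered at an unknown location on one of two
displayed shapes. The observer reports which shape contains the source.
Each shape is a *model manifold*: a family of candidate Gaussian centers
with `d` free parameters — a point (`d = 0`), a straight segment or a
circular arc (`d = 1`). The normative solution compares marginal
likelihoods under equal model priors,

$$ p(X \mid M) = \int_0^\Lambda w(s)\, p(X \mid M, s)\, ds, $$

with `s` the arc-length coordinate and `w` the Jeffreys prior.

**Arc-length parameterization is canonical.** Every 1D manifold is
unit-speed parameterized on `[0, Lambda]`. Two simplifications follow:
the per-datum expected Fisher information is the constant
`g = 1/sigma^2` (independent of position *and* curvature), and the
Jeffreys prior `w ∝ sqrt(g)` is uniform, `1/Lambda`. All priors,
integrals, densities and regressors are expressed in `s`.

**Per-datum information convention.** `g` and `h` (the observed
information, `h(s) = (1 - (\bar c - \mu(s))\cdot \mu''(s))/\sigma^2` with
`\bar c` the data centroid) are per-datum quantities; the trial size `N`
appears explicitly in the expansion terms. With this convention `h` is an
unbiased, data-dependent version of `g`: averaged over data generated at
a fixed `s`, `h` converges to `g`, also on curved manifolds (a property
the test-suite checks by Monte Carlo).

## 2. The evidence expansion

Writing `L(s)` for the total log-likelihood, `ŝ` for its clamped
maximizer (the projection of the data centroid onto the shape, clamped to
the domain), `a = N h(ŝ)` and `b = L'(ŝ)`, a Laplace treatment of the
integral above gives

$$ \log p(X\mid M) \approx L(\hat s)
  \;-\; \frac d2 \log\frac N{2\pi}
  \;+\; \underbrace{\frac{b^2}{2a} + \log\!\Big[\Phi\big(\sqrt a(\Lambda-\hat s) - \tfrac b{\sqrt a}\big) - \Phi\big(-\sqrt a\,\hat s - \tfrac b{\sqrt a}\big)\Big]}_{\text{boundary}}
  \;-\; \log\!\int_0^\Lambda \sqrt{g}\,ds
  \;-\; \frac12 \log\frac{h(\hat s)}{g}. $$

The four penalty terms each measure one axis of model complexity:

* **dimensionality** — the BIC-like cost of having parameters at all;
  depends only on `d` and `N`;
* **boundary** — the cost of a maximum-likelihood estimate pinned to the
  edge of the domain ("parameter evaporation"). The factor above is the
  Gaussian mass of the local quadratic expansion that actually lies
  inside `[0, Lambda]`. At a deep-interior optimum (`b = 0`, `ŝ` far from
  both ends) it vanishes to within exponentially small truncation; at a
  boundary optimum it reduces to
  `½‖l̂‖²_{ĥ⁻¹} + log Φ(−‖l̂‖_{ĥ⁻¹})`, a function of the gradient length
  measured in the inverse observed-information metric (at zero gradient
  exactly `−log 2`: half the local Gaussian sits outside the family);
* **volume** — the log Jeffreys volume `log(Λ/σ)`: how many
  statistically distinguishable sources the family contains;
* **robustness** — the observed-vs-expected information mismatch at the
  fit, which for these families is pure curvature: `h = g` exactly on
  straight segments; on an arc of radius `r`, `h = R/(r σ²)` with `R` the
  centroid's distance from the center of curvature. Data centered near
  the center of curvature make the arc *more* attractive (many
  configurations are nearly equidistant), which this term credits.

**Why the two-sided boundary factor.** A textbook treatment adds a
boundary term only when `ŝ` is clamped, which makes the approximation
jump by `log 2` as the projection crosses an endpoint. The two-sided
truncated-Gaussian factor used here is continuous in the data, exact for
straight segments (where the likelihood really is Gaussian in `s`), and
agrees with the one-sided form wherever that form applies. The cost is
cosmetic: at interior optima near an edge the term is a small negative
number rather than exactly zero. The package treats that as a feature —
it is precisely the mass the family loses to its own boundary.

**Degenerate curvature.** On arcs, a clamped optimum can have `h ≤ 0`
(locally convex log-likelihood; e.g. the centroid on the far side of the
center of curvature). The expansion is then invalid: `fia_breakdown()`
returns the breakdown flagged `degenerate = TRUE` with non-finite
robustness/boundary terms, regression designs drop such trials with a
logged count, and FIA-strategy observers fall back to the exact marginal
on them. At the shipped geometries these trials are rare (well under 1%).

**Exact evidence.** `exact_log_marginal()` integrates in log space
(max-subtracted) with Gauss–Legendre rules, doubling the node count from
16 until successive estimates agree to `1e-8` (ceiling 4096 nodes, then a
hard error with the last delta). The vectorized decision path uses a
fixed 257-node rule for arcs — validated in the tests against the
adaptive rule — and closed forms for points and segments.

## 3. Task variants and calibration

The four shipped variants each isolate one term. The study that motivates
them pins the *difficulty* of the task, not its coordinates, so the
geometry below is the package's own choice, frozen in
`inst/extdata/default_config.yaml`:

| variant | up shape (canonical) | down shape | differing feature |
|---|---|---|---|
| dimensionality | point (0, 0.5) | segment length 2 at y = −0.5 | `d` |
| boundary | left-reaching segment, length 2, at y = 0.5 | right-reaching segment at y = −0.5 | endpoint projections |
| volume | segment length 0.5 | segment length 4 | `Λ` |
| robustness | segment length 2 | arc of equal length, radius 0.5 | curvature |

Shapes are mirrored about the x-axis at `y = ±0.5`; the boundary pair's
horizontal offsets make near-endpoint projections common; the robustness
arc bulges away from its partner with its center of curvature between the
shapes, so curvature effects vary strongly over trials. **Mirror
randomization** (which shape is on top, per trial) is not cosmetic: the
dimensionality and volume differences are constant within a variant and
only become identifiable in the regression because they flip sign with
the orientation while the up/down response bias does not. For the same
reason any cohort used to fit all four sensitivities must span variants
in which those constants differ (the package's defaults do).

**Calibration.** The remaining free scalar, `sigma` per variant, is set
by `calibrate_difficulty()`: the generative-accuracy advantage of a
deterministic exact-Bayes observer over a maximum-likelihood observer is
driven to 1 percentage point (the design property of the original
behavioral study, where it corresponds to ~5 extra correct trials in a
500-trial session — hence the 500-trial session default). The calibrator
fixes one set of latent draws (common random numbers), so the gap is a
smooth function of `sigma` that a coarse grid plus bisection can solve;
the smallest `sigma` attaining the target — the easier, rising branch —
is returned, keeping absolute accuracies in the 88–96% range. The shipped
values were produced with seed 20260920 and 120,000-trial evaluations and
live in the config, not in code. Blocks of 100 trials are recorded as
metadata only; no feedback-driven learning is simulated.

## 4. Observers

All strategies are deterministic or stochastic functions of the data
centroid (the centroid is sufficient for every score used). The
noise–integration–noise (NIN) family composes three mechanisms:

1. **sensory noise** `rho`: each observed point is corrupted by an
   isotropic Gaussian before deciding (the vectorized path applies
   `rho/sqrt(N)` at the centroid, which is distributionally identical);
2. **integration over latent causes** `integration_strength ∈ [0, 1]`:
   the per-model score interpolates linearly between the maximum
   log-likelihood (0) and the full log marginal (1). Both endpoints are
   pinned by the strategies they must reproduce (`max_likelihood`,
   `exact_bayes`); the linear blend between them is the simplest
   monotone path and is the package's choice where the construction was
   open;
3. **choice noise**: a softmax with temperature on the score difference
   (0 = argmax), then a uniform lapse mixture `λ/2 + (1−λ)·p`.

`posterior_sample` draws the choice with probability equal to the exact
posterior (probability matching). Exact score ties (measure-zero, e.g.
hand-built symmetric stimuli) are resolved by a seeded fair coin.
`boundary_map()` sweeps a single-datum stimulus over a grid and locates
the 0.5-crossing of P(choose model 2) along vertical transects by a
binomial-logistic fit (with a linear-interpolation fallback for
deterministic steps); integration shifts that boundary toward the more
flexible model, sensory noise shifts it the opposite way, choice noise
flattens the field without moving the crossing.

Sessions are scored twice: against the generating shape and against the
per-trial maximum-likelihood solution — the two notions of "correct"
that the task admits.

## 5. Sensitivity estimation

`build_design()` turns trials into regression rows: up-minus-down
differences, in nats, of the maximum log-likelihood (`ΔL`) and of the
four FIA terms (`ΔD, ΔB, ΔV, ΔR`). `fit_hierarchical()` fits

$$ P(\text{choose up}) = \mathrm{logistic}(\beta_0 + \beta_L ΔL + \beta_D ΔD + \beta_B ΔB + \beta_V ΔV + \beta_R ΔR) $$

with participant-level coefficients partially pooled:
`β_jk ~ Normal(μ_k, σ_k)`, weakly informative priors `Normal(0, 5)` on
means and half-`Normal(2.5)` on scales (on the standardized predictor
scale), sampled with JAGS in a *non-centered* parameterization (markedly
better mixing for logistic hierarchies). Predictors are scale-only
standardized internally and the draws mapped back, so the reported
coefficients are in nats: `β_L = 1` with all relative sensitivities 1 *is*
the FIA-posterior observer, which keeps "0 = maximum-likelihood,
1 = Bayes-optimal" literal. Defaults: 4 chains, 1000 warmup, 1000 kept
draws, split-R̂ < 1.01 to count as converged (non-converged fits warn and
are flagged; `summary` quantities should not be trusted from them).

**Relative sensitivity** is computed per draw — never as a ratio of
means — at both population level (from population-mean draws) and
participant level; draws with `|β_L|` below a guard (default 0.05 nats)
are excluded and counted, with a warning past 1%.

**Lapse extension.** `fit_lapse()` mixes the choice probability with a
uniform component, `λ/2 + (1−λ)·logistic(η)`, with participant-level `λ`
pooled on the logit scale (λ < 0.5 by construction). Ignoring a real
lapse shrinks the fitted slopes; modeling it restores them — the tests
check exactly this direction.

**WAIC** is computed from the pointwise posterior predictive density of
the kept draws (`-2 * (lppd - p_waic)`, with the variance form of
`p_waic`), with the standard paired standard error for model
differences.

## 6. Synthetic cohorts

Two planting policies, both required: **logistic** planting draws
participant coefficients from a chosen population distribution and
generates choices from the regression model itself — exact ground truth
for parameter recovery, isolating inference correctness from model
mismatch; **observer** planting simulates configured observers —
exercising the full nonlinear path from stimuli to choices. The
human-like demo regime plants relative sensitivities
{dimensionality 4.66, boundary 1.12, volume 0.23, robustness 2.21} with
`β_L = 1`; the printed population uncertainties of the source estimates
are posterior uncertainties of means, not heterogeneity scales, so the
planted between-participant scales are the package's choice (a few
tenths of a nat, ~25% of each mean). Every seed derives deterministically
from one master seed; two calls with the same spec are bitwise
identical. Choices on degenerate-breakdown trials under logistic planting
are fair coins (those trials are excluded from designs anyway).
`reference_bands()` rebuilds the "posterior-sampling observer" reference
distribution by simulating a cohort of such observers and fitting the
same hierarchical model.

## 7. Numerical choices, sizes, limitations

* Quadrature tolerances and node counts: section 2. Projection onto arcs
  is closed-form via the centroid's polar angle, clamped by circular
  angular distance, ties toward `s = 0`.
* Finite-difference oracles in the tests use central differences with
  step `1e-6·max(1, Λ)` for first derivatives and a 5-point stencil with
  step `~1e-3` for second derivatives (the balanced choices at double
  precision).
* Test-suite problem sizes are deliberate reductions: recovery cohorts
  run at 10 participants × 100 trials per variant with 3 × 800 draws
  (the full-scale study design is 50 × 500 with 4 × 1000), and the
  R̂ acceptance bar for these reduced fits is 1.1 rather than the 1.01
  default. The headline accuracy-gap check runs at full scale (100
  observers × 500 trials per strategy and variant) because it is cheap.
* What passing tests do *not* show: the synthetic generator emulates the
  structure of real sessions (variants, mirror randomization, block
  bookkeeping) but none of the messiness of human data — sequential
  effects, learning, attention lapses beyond the uniform-mixture kind,
  or stimulus-rendering nonidealities. Recovery results certify the
  estimation machinery, not the behavioral model.
* The FIA is an asymptotic device: at `N = 1` its boundary factor
  absorbs most of the domain truncation (visible in the README's worked
  example), and near-degenerate curvature trials can carry extreme
  robustness credits. Exact quadrature is always available as the
  reference and is what the ideal-observer simulations use.
* Out of scope by design: manifolds of dimension ≥ 2 or without
  closed-form projection, non-Gaussian observation noise, unequal model
  priors, reaction times, and any neural-network observers.
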
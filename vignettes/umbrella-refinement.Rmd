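---
title: "Umbrella refinement of conformational ensembles: model and methods"
author: "ureweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Umbrella refinement of conformational ensembles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ureweight)
```

## The problem

A conformational ensemble is a set of $N$ molecular conformers with
statistical weights $w_t \ge 0$, $\sum_t w_t = 1$. Molecular-dynamics
force fields produce such ensembles, but for flexible molecules —
intrinsically disordered proteins most prominently — the relative weights
of the populated states are often inaccurate: force fields are tuned for
minima, not for the barriers that set relative populations. NMR
experiments, on the other hand, measure population averages (chemical
shifts, three-bond $^3J$ couplings, NOE-derived distance bounds) over the
whole ensemble. Ensemble reweighting adjusts the simulated weights so that
the weighted averages of back-calculated observables agree with experiment
while staying as close as possible to the simulation prior.

For a per-conformer observable $O^{\mathrm{calc}}_t$ the comparison uses
the linear ensemble average $\langle O \rangle = \sum_t w_t
O^{\mathrm{calc}}_t$ (`linearAverage()`). NOE intensities fall off with
the sixth (or third) power of the interproton distance, so distances
compared to NOE bounds use the inverse-power mean
$(\sum_t w_t r_t^{-p})^{-1/p}$ (`noeAverage()`); close conformers
dominate, and the effective distance never exceeds the linear mean.

## The umbrella refinement model

Classical Bayesian ensemble refinement optimizes all $N$ weights directly.
This package instead parameterizes the refined weights through a bias
potential borrowed from umbrella sampling: reweighting an ensemble from
one potential-energy surface to another multiplies each conformer's weight
by $\exp(-V^{\mathrm{bias}}_t / k_BT)$. The bias is modeled as a sum of
harmonic terms in the normalized deviation of each observable,

$$V^{\mathrm{bias}}_t(\mathbf{k}) = \sum_{i=1}^{M} \frac{k_i}{2}
  \left(\frac{O^{\mathrm{exp}}_i - O^{\mathrm{calc}}_i(t)}{\sigma_i}\right)^2,
\qquad
w_t(\mathbf{k}) = \frac{w^0_t \, e^{-V^{\mathrm{bias}}_t(\mathbf{k})}}{Z(\mathbf{k})},$$

so only the $M$ force-constant-like parameters $k_i$ (one per observable,
$M \ll N$) are optimized (`weightsFromK()`, `optimizeK()`). A large $k_i$
makes the reweighting sensitive to disagreement in observable $i$; $k_i$
has a direct physical reading as an umbrella force constant. We work in
reduced units, $k_BT \equiv 1$: only $k_i/k_BT$ is identifiable, so $k$
absorbs the temperature.

The cost function balances fit against distortion,

$$\mathrm{cost}(\mathbf{k}) \;=\; \theta\, D_{\mathrm{KL}}(\mathbf{k})
  \;+\; \chi^2(\mathbf{k}),
\qquad
\chi^2 = \frac{1}{M}\sum_i
  \left(\frac{O^{\mathrm{exp}}_i - \langle O_i\rangle_w}{\sigma_i}\right)^2,$$

with the Kullback–Leibler divergence between prior $w^0$ and refined $w$
as regularizer. Both directions are implemented (`klForward()`,
`klReverse()`); the forward direction $D_{\mathrm{KL}}(w^0\Vert w)$ is the
default because its mode-covering behavior keeps probability on every
region the prior populates — the conservative choice for a maximum-entropy
style refinement — and, unlike Lagrange-multiplier constraint solvers, the
$k$-parameterization accommodates it at no extra cost. $\sigma_i$ is the
*total* uncertainty of observable $i$ (experimental and back-calculation
error combined upstream); the package never combines errors itself.

### NOE upper bounds

NOE-derived bounds are upper bounds on an $r^{-6}$-averaged distance. Two
things follow. First, distances are preconditioned by $r \mapsto r^{-6}$
(`preconditionNoe()`), which makes the observable linear in the weights;
bounds map as $b \mapsto b^{-6}$ and uncertainties by first-order
propagation $\sigma' = 6 b^{-7} \sigma$. Second, the bound is one-sided: a
conformer (or ensemble) whose effective distance is *below* the bound is
fully consistent with the experiment. In $r^{-6}$ space an upper distance
bound is violated when $\langle r^{-6}\rangle < b^{-6}$, so the $\chi^2$
residual is $\max(0,\, b^{-6} - \langle r^{-6}\rangle)/\sigma'$ and
satisfied bounds contribute zero, both to $\chi^2$ and (per conformer) to
the bias potential. Penalizing satisfaction would push the ensemble toward
the bound for no experimental reason. Set `noeOneSided = FALSE` to treat
bounds as two-sided targets instead.

### Optimization

`optimizeK()` minimizes the cost with BFGS (L-BFGS-B when `nonNegativeK =
TRUE`) from $\mathbf{k} = 0$, using analytic gradients of $\chi^2$ and of
both KL directions through the softmax structure of $w(\mathbf{k})$.
Starting at the identity guarantees the optimized cost never exceeds the
initial $\chi^2$, and the whole procedure is deterministic. Convergence is
declared on a relative cost change below `reltol` (default `1e-8`, at most
`maxit = 1000` iterations; hitting the cap flags `converged = FALSE` and
returns the best iterate). Normalization of $w(\mathbf{k})$ is
log-sum-exp stabilized, so extreme $k$ cannot overflow. $k$ is
unconstrained in sign by default: nothing in the model forbids negative
values, but they are unphysical for umbrella force constants, so the show
method flags them and `nonNegativeK = TRUE` enforces positivity.

Degenerate observables whose calculated values are constant across
conformers contribute a constant to the bias that cancels in $Z$: they
cannot steer the weights. They are retained in $\chi^2$ but produce a
warning.

## Choosing the regularization strength

$\theta$ is selected by k-fold cross-validation over the *observables*
(`crossValidateTheta()`): for each $\theta$ and fold, $\mathbf{k}$ is
optimized on the training observables only and scored on the held-out ones
with the sigmoid validation score
$\mathrm{sigmoid}(\ln(\chi^2/\chi^2_{\mathrm{init}}))$
(`validationScore()`): 0.5 means the refinement changed nothing for the
held-out data, below 0.5 means it improved observables it never saw, above
0.5 flags overfitting. Defaults: five folds; validation fraction
$1/n_{\mathrm{folds}}$ as a random partition (each observable held out
exactly once); a 75/25 split drawn independently per fold is supported for
very small observable sets. The $\theta$ grid has 40 log-spaced points in
$[10^{-3}, 10^2]$, bracketing everything from overfitting to no visible
reweighting. Successive grid points are warm-started from the previous
optimum, descending from large $\theta$; this changes no optimum, only
iteration counts.

`selectTheta()` returns the $\theta$ at the minimum of the mean validation
curve; candidates within 1% of the minimum are tied and the *largest* tied
$\theta$ wins — the weaker, more conservative refinement. A minimum
sitting at the top of the grid with a still-falling curve is a boundary
minimum: no recommendation is returned (`NA`), and an automatic run
refuses to proceed unless a fallback `forceTheta` is supplied, because
such refinements need manual inspection.

As a second guard against overfitting, the ensemble preservation
(`ensemblePreservation()`) reports the percent of the prior ensemble that
effectively survives:
$\mathrm{e.p.} = 100 \exp(-D_{\mathrm{KL}}(w \Vert w^0))$ (reverse
direction). It is exactly 100 for unchanged weights, decreases continuously
with distortion, and collapsing all weight onto one of $n$ equally
weighted prior conformers gives $100/n$ — near zero when a handful of
conformers carry everything. The definition is isolated behind this one
function: it satisfies every boundary property a preservation metric
needs, but other effective-sample-size flavors exist, and swapping the
definition touches nothing else.

## Synthetic validation systems

`makeGridSystem()` builds the fixture family used throughout the tests: a
dialanine-like system whose $\varphi/\psi$ plane is discretized into
$36 \times 36$ bins of $10^\circ$ (centers $-175^\circ, \dots, +175^\circ$),
with a free-energy surface assembled from periodic Gaussian basins and a
Boltzmann prior $w^0 \propto e^{-F}$. The default surface has a dominant
$\beta$-sheet-region basin at $(-155^\circ, 150^\circ)$ (4 $k_BT$ deep)
and a weaker $\alpha$-region one; a single zero-depth basin gives the
flat, equipotential prior. Observables are two Karplus-type couplings of
$\varphi$ and $\psi$ (`karplusJ3()`, with the 6.51/−1.76/1.60 and
7.09/−1.42/1.55 Hz coefficient sets, phase $-60^\circ$) and ten linear
shift-like functions of the bin centers with seeded coefficients
(±0.02 ppm/°, offsets in 0–10 ppm), with total uncertainties of 0.8 Hz
and 0.5 ppm — magnitudes typical of combined experimental plus
back-calculation errors for small peptides.

`makeRecoveryFixture()` creates ground-truth problems: experimental values
are ensemble averages under $w(\mathbf{k}^{\mathrm{true}})$ plus Gaussian
noise of `noiseSd` $\times\,\sigma_i$ (default 0.2; $k^{\mathrm{true}}$
drawn once, uniform in $[0.5, 2]$, unless supplied). All randomness sits
behind a single seed, and fixtures are bit-reproducible.

What these fixtures do *not* emulate: real back-calculator bias
(systematic, not zero-mean), correlated errors between observables,
conformer discretization error, and experimental data whose values are
partially unreachable by any reweighting. Passing recovery tests therefore
demonstrates the estimator's correctness and calibration inside its model
family, not the accuracy of any particular force field or shift predictor
on real data.

One validation suite does emulate the harder regime: the matched-strength
comparison against a direct $N$-dimensional weight optimizer (the
classical Bayesian refinement over all weights, reverse-KL regularized,
implemented only as a test oracle). Its fixture uses an equipotential
prior and experimental values with a reducible structured component plus
an orthogonal irreducible one, scaled so $\chi^2_{\mathrm{init}} = 1.51$
with roughly 38% reducible — the regime of an equipotential-prior
refinement against real peptide NMR data. On such data both optimizers
reach the same $\chi^2$ floor and agree within a few percent at matched
ensemble preservation. The comparison is made on the preservation range
both methods traverse: once the direct optimizer reaches the floor it
stops distorting (e.p. plateaus near 92 on these fixtures), while the
$k$-family keeps spending divergence, so lower preservation levels are not
attainable for the oracle. On fully-reducible recovery fixtures the two
methods genuinely differ at matched preservation (the linear-tilt family
of the direct method is more divergence-efficient than the quadratic-bias
family); similar results should be expected only when a substantial
irreducible residual dominates both.

## Numerical choices

* Weights must be normalized to $10^{-9}$ on input and are renormalized
  exactly on construction; downstream exponentials amplify drift.
* Zero prior weights are allowed (sparse priors); $w(\mathbf{k})$ is
  strictly positive on the prior's support for every finite $\mathbf{k}$
  and exactly zero off it.
* KL divergences are in nats; terms with $P(x) = 0$ contribute zero, and a
  proposal missing prior support returns `Inf` (impossible for
  `weightsFromK()` output).
* A validation-score $\chi^2$ of exactly zero is floored at a ratio of
  $10^{-12}$ rather than raising an error.
* Units: ppm for shifts, Hz for couplings, Å for distances and bounds,
  consistently across both input files.
* Problem sizes in the shipped validation suite: $36\times36$ grids
  (1296 conformers) with 12 observables for the headline suites, smaller
  $12\times12$–$18\times18$ grids for unit tests — large enough to be
  non-trivial, small enough to iterate on comfortably.

## Worked example

```{r example}
grid <- makeGridSystem(seed = 1)
fx <- makeRecoveryFixture(grid, noiseSd = 0.2, seed = 1)
scan <- crossValidateTheta(fx$prior, fx$obs, seed = 1)
scan
res <- optimizeK(thetaRecommended(scan), fx$prior, fx$obs)
res
```

The refined ensemble average of every observable can be compared against
the generating truth:

```{r recovery}
avg <- drop(crossprod(calcMatrix(fx$obs), weights(refinedWeights(res))))
summary(abs(avg - fx$targets) / sigmas(fx$obs))
```

## Limitations

* The bias-potential family ties each observable's tilt direction to its
  own deviation; observables with strongly correlated calculated values
  share force constants' effects in ways the per-observable $k$ does not
  resolve.
* Cross-validation over observables assumes the observables are
  (approximately) exchangeable carriers of the same underlying weights;
  with very few observables (under ~8) the validation curves become noisy
  and the 75/25 split option should be preferred.
* The cost surface over $\mathbf{k}$ is not convex; BFGS from
  $\mathbf{k}=0$ is deterministic and never worsens the prior, but on
  pathological surfaces a different branch can exist (warm-started
  $\theta$ paths in `crossValidateTheta()` follow one branch
  continuously).
* Back-calculation of observables from 3-D structures, trajectory
  handling and clustering live upstream; this package starts from the
  calculated-observables table.
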
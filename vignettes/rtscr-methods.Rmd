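---
title: "Random-thinning spatial capture-recapture: model, sampler, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-thinning spatial capture-recapture: model, sampler, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Camera-trap surveys of individually marked felids routinely produce
photographs that cannot be assigned to an individual — partial views,
blurred frames, single flanks.  Standard spatial capture-recapture (SCR)
discards those records, which is costly exactly where it hurts most: at
range margins, where densities and detection rates are low and every
detection carries real information.  The random-thinning SCR model (rt-SCR)
keeps the unidentified detections in the likelihood by treating individual
identification as a random thinning of the full encounter process.

## The model

Activity centers $s_i$, $i = 1, \dots, N$, are uniform over a state space
$S$ whose area converts abundance into density.  Detectors $j = 1, \dots, J$
sit at coordinates $x_j$, and the per-occasion encounter rate decays with
the Euclidean distance $d_{ij} = \lVert s_i - x_j \rVert$ as a half-normal,

$$\lambda_{ij} = \lambda_0 \exp\!\left(-\frac{d_{ij}^2}{2\sigma^2}\right),$$

so $\lambda_0$ is the encounter rate of an individual camped on a detector
and $\sigma$ (meters) is the spatial scale of movement.  Unknown $N$ is
handled by data augmentation: a superpopulation of size $M$ with membership
indicators $z_i \sim \text{Bernoulli}(\psi)$, $N = \sum_i z_i$.  Encounters
are Poisson,

$$y^{\text{full}}_{ijk} \mid z_i \sim \text{Poisson}(\lambda_{ij}\, z_i),$$

and each encounter retains its individual identity independently with
probability $\theta$:

$$y^{\text{ID}}_{ij} \sim \text{Binomial}(y^{\text{full}}_{ij}, \theta),
\qquad y^{\text{noID}}_{ij} = y^{\text{full}}_{ij} - y^{\text{ID}}_{ij}.$$

Only the trap-level sums $n^{\text{noID}}_{j} = \sum_i y^{\text{noID}}_{ij}$
of the unidentified side are observed.  The same individual can appear in
both the identified and the unidentified history of a trap.

## The sampler

`fit_rtscr()` runs a Metropolis-within-Gibbs sweep, implemented in C++:

1. **Allocation.**  The latent split of each trap's unidentified count among
   population members is conjugate: thinning a Poisson array and
   conditioning on the column sum leaves a multinomial with weights
   $z_i \lambda_{ij}$.  We sample that full conditional exactly, so the
   constraint $\sum_i y^{\text{noID}}_{ij} = n^{\text{noID}}_j$ holds by
   construction at every iteration (and is re-asserted at every retained
   draw).  A single-unit Metropolis-Hastings variant of this update is kept
   behind `mcmc_config(allocation = "mh")` purely as a cross-check; both
   kernels are verified against an exhaustive-enumeration oracle in the test
   suite (total variation below 0.02 on a fully enumerable instance).
2. **$\theta$ and $\psi$** are conjugate Beta draws.  A consequence of the
   model worth knowing: given the data, $\theta$'s full conditional is
   $\text{Beta}(a + \sum y^{\text{ID}}, b + \sum n^{\text{noID}})$ — the
   identified and unidentified totals are both observed, so the
   identification rate is estimated essentially for free.
3. **$z_i$** is Gibbs-updated for individuals with no current encounters
   (members with encounters are locked at $z_i = 1$).
4. **$\lambda_0, \sigma$** use adaptive random-walk Metropolis on the log
   scale.  Proposal scales adapt toward 25–45% acceptance during burn-in
   only, then freeze — the standard adapt-then-fix scheme that preserves the
   stationary distribution.
5. **$s_i$** are per-individual random walks, rejected outside $S$ (for a
   polygon mask the uniform prior is enforced by rejection rather than a
   likelihood trick).  Members with no encounters perform free uniform
   exploration, which is their correct full conditional.

Occasions are collapsed to trap totals with per-trap effort offsets
$E_j = \sum_k \text{operation}_{jk}$, a sufficient statistic because the
rate is time-constant; the forward simulator and the posterior-predictive
replication work per occasion, and for the three GoF statistics the two
parameterizations are distributionally identical because Poisson counts
aggregate.  The published equations index encounters both as $y_{ijk}$ and
$y_{ij}$; the collapsed-effort formulation is this package's choice and is
flagged as such.

Standard SCR (`fit_scr()`) is the same sampler with $\theta \equiv 1$ and
the unidentified counts dropped; with zero unidentified detections the two
models coincide exactly (same likelihood on identical states), which the
tests assert.

### Defaults and their reasons

* **Priors**: $\lambda_0 \sim U(0, 5)$, $\sigma \sim U(0, \text{buffer})$,
  $\theta, \psi \sim \text{Beta}(1,1)$.  The published analysis says only
  that it used vague priors, deferring the exact forms to its deposited
  code; these defaults are conventional SCR choices and are not claimed to
  match that code numerically.  All are configurable and recorded in the run
  metadata.
* **Augmentation size** `M`: four times the number of identified
  individuals, floor 50.  The fitter warns when the upper 95% CRI of $\psi$
  exceeds 0.9, the sign that $M$ truncates the $N$ posterior.
* **Initialization**: detected individuals start at the count-weighted
  centroid of their detection traps; $(\lambda_0, \sigma)$ at the maximizer
  of the complete-data Poisson likelihood on a coarse grid; chain starts are
  jittered for overdispersion.
* **Point estimates**: posterior means, except $N$ and $D$, which are
  medians because those posteriors are right-skewed.
* **Degenerate inputs**: a trap with unidentified counts but no live
  contributor (possible only in pathological states) force-activates the
  best-placed augmented individual instead of crashing; an all-unidentified
  dataset (zero identified individuals) is allowed with a warning.

## State space and buffer

The default state space is the trap bounding box buffered on all sides;
an optional polygon mask supports habitat-restricted spaces, with the
shoelace area and point-in-polygon rejection.  `fit_with_3sigma_buffer()`
automates the two-stage rule used in practice: fit on a wide provisional
buffer (default 15 km), set the buffer to $3\hat\sigma$, refit.  Densities
are robust to buffers beyond $3\sigma$ because individuals farther out have
negligible detection probability.

## Goodness of fit

`posterior_predictive_gof()` replicates detection data for all $M$
individuals from each sampled latent state, under the observed effort, and
compares three statistics: total detections, number of detected
individuals, number of visited traps.  Conventions, fixed and documented
because the source analysis does not state them:

* $p = \Pr(T^{\text{rep}} \ge T^{\text{obs}})$, ties counted in favor, so a
  replicate distribution degenerate at the observed value gives $p = 1$.
* Total detections and visited traps use all detections (identified plus
  unidentified); detected individuals counts identified individuals only,
  after thinning — the only combination that matches what is observable in
  the data.

## Derived quantities

* Density $D = 100\,N/\text{area}$, individuals per 100 km².
* Home range from $\sigma$ under bivariate-normal space use:
  $\pi (q\sigma)^2$ with $q = \sqrt{\chi^2_2(0.95)} = 2.447746$, reported in
  hectares.  The point estimate is the posterior mean of the per-draw
  transform, not the transform of the posterior mean — the standard summary
  of a derived quantity, and the two differ by a few hundred hectares at
  typical posterior spreads.
* Gelman-Rubin $\hat R$ in the Brooks-Gelman corrected form, with the
  conventional $\hat R < 1.1$ reading.
* The closure test follows the Otis et al. (1978) span statistic on binary
  per-occasion histories of identified individuals (the only ones with
  capture histories): for an individual caught on $n$ of $t$ occasions the
  null span distribution is
  $P(q) = (t-q)\binom{q-1}{n-2}/\binom{t}{n}$, and the standardized sum of
  span deviations is asymptotically normal.  Negative $Z$ with small
  one-sided $p$ flags a violation.  This is an in-package implementation
  from the published formula; which exact variant any given software default
  applies can differ, so matching a particular published $Z$ to the last
  digit is not guaranteed.
* `mean_max_distance()` is the usual MMDM descriptive: the mean over
  individuals detected at two or more traps of the maximum pairwise trap
  distance.
* `activity_center_surface()` grids the state space and averages the count
  of member activity centers per cell over draws, a realized-density
  surface whose mass equals the posterior mean of $N$.

## The synthetic-data generator and what passing tests mean

`simulate_dataset()` draws uniform activity centers, per-occasion Poisson
encounters masked by the operation matrix, and i.i.d. identity thinning —
exactly the fitted model.  The study-emulating preset `jaguar_design()`
encodes the survey conditions this package is organized around: 52 paired
stations treated as single detectors (pairing serves photo-identification,
not the encounter model), 91 daily occasions, two grid clusters at 1308 m
nearest-neighbour spacing (the survey's mean station spacing) separated so
that the 9150-m-buffered bounding box covers about 1941 km², staggered
downtime giving exactly 3779 active trap-days, and generative values
$N = 25$, $\lambda_0 = 0.047$, $\sigma = 3050$ m, $\theta = 0.87$.
Occasion length (one day) and the 30-minute event-deduplication window are
this package's decisions — the source survey reports events without
defining either — and both are configurable.

The generator does **not** emulate behavioral responses to traps,
sex-specific movement, temporal trends in the rate, non-uniform habitat
preference, or spatially correlated identification failure.  Parameter
recovery and GoF calibration on these simulations therefore demonstrate
the correctness of the implementation under the model's own assumptions,
not robustness to their violation.

## Problem sizes used in the checks

The test suite fits reduced-scale chains: parameter recovery runs 20
study-emulating replicates at 3 chains × 20,000 iterations (burn-in 5,000,
thin 10, M = 100); GoF calibration runs 20 replicates at 2 × 10,000; the
enumeration oracle uses a 2-trap, M = 3, 25-site instance where the exact
posterior is computable by brute force.  These sizes give Monte-Carlo error
comfortably below the tolerances asserted, while keeping the default suite
quick enough to run routinely.  The analysis scripts use the same reduced
chain lengths; the published-scale configuration (3 × 500,000, burn-in
100,000, thin 10) is a one-line change to `mcmc_config()` and is what
`analysis/05_reproduce_study.R` documents for real-data runs.

## Presentation choice

The repository is organized as an analysis workflow — numbered scripts
under `analysis/` that narrate simulate → fit → check → summarize — over a
fully tested package in `R/`.  The scripts are thin drivers; every
computation lives in package functions, so the same code paths serve the
scripts, the tests, and `scripts/acceptance.R`.

## Known limitations

* Null model only: no sex- or covariate-structured $\lambda_0$ or $\sigma$,
  no open-population dynamics, no partial-identity (single-flank) spatial
  matching, Euclidean distance only.
* The $\sigma$ update recomputes the full rate matrix; for surveys an order
  of magnitude larger than the present design a more aggressive caching
  scheme would pay.
* Coordinates must arrive projected in meters; the package does no
  geographic math.
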
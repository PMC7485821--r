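---
title: "Quality-score driven Bayesian optimisation of segmentation pipelines"
author: "segbo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-score driven Bayesian optimisation of segmentation pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segbo)
```

## The problem

Configuring an image-processing pipeline for cell profiling — window sizes,
threshold correction factors, size filters — is usually done by trial and
error. The search space is combinatorial, feedback is slow, and the process
is biased towards whoever happens to have image-analysis experience. segbo
replaces the trial-and-error loop with an interactive machine-learning one:
the user (or a rule, or a simulation) only has to say *how good* the output
of a configuration looks, on a 1 (poor) to 10 (excellent) scale, and a
Bayesian optimiser decides which configuration to try next.

Three ingredients make the whole loop testable on a desk with no human and
no external data: a reference two-stage segmentation pipeline with the
classic tunable settings, a seeded generator of fluorescence-like images
with known ground truth, and a simulated rater that converts mask overlap
into a rating.

## The surrogate model

The optimiser treats the mapping from a pipeline configuration $x$ to its
quality score $y$ as an unknown function observed with noise,
$y \sim \mathcal{N}(f(x), \sigma_n)$, and places a Gaussian-process prior
on $f$ with zero mean and squared-exponential covariance

$$ k(x, x') = \sigma_f \exp\!\left(-\tfrac{1}{2\sigma_\ell}\,\lVert x - x'\rVert^2\right), $$

with hyperparameters $\theta = \{\sigma_n, \sigma_f, \sigma_\ell\}$. Note
that $\sigma_\ell$ divides the squared distance directly, i.e. it is the
*squared* length-scale; the package implements this parameterisation
verbatim and documents it on every function that takes `theta`.

Numerical choices, each of which matters in practice:

* **Normalised inputs.** Configurations are encoded into $[0,1]^d$
  (each setting scaled by its own range) before any kernel computation.
  The kernel is isotropic, so without this a window measured in hundreds
  of pixels would drown a correction factor measured in tenths.
* **Centred scores.** The prior mean is zero, but ratings live on a 1–10
  scale; the score mean is subtracted before fitting and added back to
  predictions. Without centring, predictions far from the data revert to
  0, i.e. below the scale's floor, which distorts Expected Improvement.
* **Factorisation and jitter.** The covariance-plus-noise matrix is
  Cholesky-factorised with an unconditional diagonal jitter of $10^{-8}$,
  so duplicated configurations (which a grid search space produces
  readily) never break the factorisation. The factorised posterior is
  tested against a direct-inverse oracle at $10^{-8}$ tolerance.
* **Predictive variance includes $\sigma_n$.** Predictions are of the
  *observable* rating, not the latent $f$: the quantity the loop reasons
  about is the score the rater would actually produce.
* **Hyperparameters by marginal likelihood.** After the bootstrap phase,
  $\theta$ is re-estimated each iteration by multi-start (5 starts)
  L-BFGS-B maximisation of the log marginal likelihood over
  $\log \theta$, bounded in
  $\sigma_n \in [10^{-6}, 4]$, $\sigma_f \in [10^{-3}, 100]$,
  $\sigma_\ell \in [10^{-3}, 10]$, warm-started from the previous
  iteration's estimate. The returned $\theta$ never has a lower marginal
  likelihood than its starting point. There are no priors on the
  hyperparameters.

## The acquisition rule

Expected Improvement in maximisation form: with $s = \sqrt{\text{var}}$
and $\Delta = \mu - y_\text{best} - \xi$,

$$ \mathrm{EI} = \Delta\,\Phi(\Delta/s) + s\,\varphi(\Delta/s), $$

falling back to $\max(\Delta, 0)$ at $s = 0$. $y_\text{best}$ is the best
*observed* score. EI is maximised over a finite, seeded candidate set —
2048 stratified quasi-random points (Latin hypercube) plus the grid
neighbours of every configuration already evaluated — which keeps each
step deterministic given the master seed. The chosen point is snapped to
each setting's interval grid before execution (midpoint ties break toward
the lower value); the continuous proposal is logged alongside the executed
values, which is why iteration reports can show off-grid "new values".

The exploration offset defaults to $\xi = 0.5$: ratings are integers, so
half a rating step is the smallest meaningful improvement, and chasing
sub-step gains makes the loop crawl along single grid steps of a quantised
plateau instead of exploring. This was the single most consequential
tuning decision in the package; with $\xi$ near zero the surrogate, fit to
deterministic integer ratings, tends to collapse to near-zero noise and a
short length-scale, and the loop exploits its way into plateaus. $\xi$
remains a setting.

## The loop and its stopping rule

The optimiser starts with two randomly drawn configurations (the
bootstrap; at least two points are needed before hyperparameters can be
estimated), then iterates: fit the surrogate to all (configuration, score)
pairs, re-estimate $\theta$, propose by EI, execute the pipeline, obtain
the current quality score. The run stops as soon as the *quality gap*
$\max(\text{target QS} - \text{current QS}, 0)$ reaches zero — including
when a bootstrap evaluation already meets the target — or when the
post-bootstrap iteration budget is exhausted. A configuration that crashes
the pipeline is scored 1 and flagged rather than aborting the run, so the
optimiser can learn away from invalid corners of a raw numeric range; an
*evaluator* failure, by contrast, aborts (persisting a partial trace),
because without a rater the loop has no signal.

Every evaluation is appended to a trace (tab-separated text at full
precision, plus CSV and a quality-gap plot) from which the in-memory
training set can be reconstructed exactly.

## Scoring: manual, automated, composite

The *manual* evaluator shows the rater an outline overlay and takes an
integer 1–10 rating (re-querying up to three times on invalid input). The
*automated* evaluator takes up to four tolerance-range criteria on object
measurements (area, perimeter, solidity, eccentricity) and computes, per
criterion, the fraction of objects within bounds; the score is
$1 + 9 \cdot \text{mean pass fraction}$. This linear map is the module's
largest interpretive decision: it makes rule-based and human scores
commensurable, so the *composite* evaluator can take a weighted mean of
the two. A segmentation with zero objects scores 1 with a warning — bad
configurations legitimately produce empty masks and must remain scoreable.

## The reference pipeline

A deliberately CellProfiler-like two-stage pipeline, four tunable
settings: primary objects (nuclei) by Gaussian smoothing (sigma 1 px,
fixed), adaptive local-mean thresholding (box window of *Size of adaptive
window* pixels, replicated borders, multiplied by *Threshold correction
factor I*), hole filling, and removal of components whose equivalent
diameter falls below *Typical artifact diameter*; secondary objects
(cells) by a global Otsu threshold scaled by *Threshold correction factor
II*, grown from the primary seeds by intensity-guided seeded propagation
restricted to the foreground. Two implementation details worth knowing:

* Components are labelled with 8-connectivity and labels assigned in
  raster (column-major first-pixel) order, so masks are bit-identical
  across runs and platforms.
* The Otsu split for the secondary stage is computed on non-primary
  pixels. Bright nuclei otherwise pull the global threshold above the
  cell/background boundary, which both breaks the secondary stage and
  makes its correction factor inert.

Solidity uses the convex hull of pixel *corner* points, so a single pixel
has hull area 1 and solidity 1 rather than a division by zero.

## The synthetic scene and what it does not show

The generator renders elliptical cells (each containing a nucleus ellipse
and a few small elongated puncta near the border) at four fixed intensity
levels, plus a linear background gradient and additive Gaussian noise,
clipped to $[0,1]$. Placement is rejection sampling with non-overlap
margins; the same seed is bit-reproducible; nucleus masks are contained in
cell masks by construction, and per-class component counts equal the
placed object counts.

The reference scene is 144×144 px with 4 cells, nucleus semi-axes 7–10 px,
cell scale 1.9, intensities background 0.06 / cell 0.35 / nucleus 0.85 /
puncta 0.95, noise 0.015 and gradient 0.05. These values were calibrated
once, when the task was designed, so that (a) the task is honest — large
regions of the search space segment it badly — and (b) a known *oracle
configuration* (window 25, factor I 1.5, artifact diameter 7, factor II
1.0) achieves nucleus IoU above 0.8 on any seed, which anchors the
parameter-recovery tests. The search-space grids shipped with the package
(window 17–97 step 8; factor I 0.6–2.0 step 0.1; artifact diameter 0–15
step 1; factor II 0.6–1.5 step 0.1) put roughly 5% of configurations in
the high-quality region, so random search succeeds occasionally and the
comparison against it is meaningful.

What passing tests on this scene do **not** show: hard-edged ellipses are
easier to threshold than real point-spread-blurred cells; intensity levels
are globally constant rather than per-cell variable; there is no clumping,
no debris, no illumination field beyond a linear ramp. Results on the
synthetic task demonstrate that the *optimiser* works, not that the
reference pipeline is a good segmenter of real microscopy.

The simulated rater maps mask IoU to a rating as
$\mathrm{clamp}(1 + \mathrm{round}(9\,\mathrm{IoU}), 1, 10)$, rounding
halves away from zero (so IoU 0.5 rates 6, deterministically). An optional
mode flips the rating by ±1 with a given probability, emulating human
rating variability and exercising the surrogate's noise term; it is off by
default.

## Benchmarking conventions

IoU is pixel-wise, on binarised masks (any label > 0). Two empty masks
score 1 with a warning — the 0/0 case is read as perfect agreement, and
the shipped generator never produces empty truths. The random-search
baseline shares the optimiser's entire loop contract (bootstrap, stopping,
trace) with proposals drawn uniformly from the grid, and comparisons run
both methods on *paired* master seeds so they share bootstraps; the
benchmark reports mean ± one standard deviation of the best-so-far gap per
iteration, and the number of evaluations to reach a gap threshold,
censored at the full budget. Problem sizes used throughout the test suite
— 20 paired replicates at budget 40 for the efficiency comparison, 10 runs
at budget 30 against a held-out 10-image test set for generalisation — are
the package's desk-scale defaults for a laptop-class machine.

## Known limitations

* Only integer- and float-valued settings on linear interval grids:
  no categorical, conditional, or log-scaled parameters.
* One isotropic length-scale for all settings (no automatic relevance
  determination), so an irrelevant setting dilutes the kernel distance.
* EI over a finite candidate set is not a global maximiser of the
  acquisition surface; with an adversarial landscape and an unlucky seed
  a run can stall on a plateau within its budget (the efficiency claim is
  about means over replicates, not about every run).
* The shipped pipeline segments primary and secondary objects only; the
  generator's puncta masks exist for ground-truth completeness, not
  because a puncta-segmentation stage ships.
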
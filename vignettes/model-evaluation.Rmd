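---
title: "Evaluating models of fixation selection: measures, bounds, and corrections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating models of fixation selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeref)
```

## Scope and data model

A model of fixation selection outputs a *salience map*: one scalar per
image location predicting how strongly it attracts gaze. The empirical
ground truth is a table of discrete fixations — subject, image, stimulus
category, within-trial index, and an (x, y) position in screen pixels.
`gazeref` evaluates maps against such tables and, just as importantly,
estimates how well *any* model could do on a given dataset.

Coordinates follow raster conventions: x is the column, y the row, the
origin is the top-left corner, and valid positions live in the half-open
box `[0, W) × [0, H)` pixels. A coordinate denotes the centre of the
recorded gaze sample; when a fixation is looked up in a map, it receives
the value of the grid cell containing it, with no interpolation.
Angular quantities (kernel widths, disc radii) convert to pixels linearly
per axis via the display geometry; a single global stimulus extent is
assumed, without per-pixel tangent correction, which is accurate for the
small angles of screen-based experiments. Out-of-bounds samples — which
real trackers produce routinely — are dropped with a warning by default;
a strict reject-the-file policy is available.

## Fixation density maps

Density-based measures need an estimate of the fixation probability per
location. The package computes a *fixation density map* (FDM) by binning
fixations into a histogram with one bin per grid cell and smoothing with
a Gaussian kernel, then renormalizing to unit mass. The kernel width is
given as full width at half maximum in degrees of visual angle, default
2° — the scale of tracker calibration error and of the fovea — and
converted per axis to a standard deviation in grid cells,
σ = FWHM / (2√(2 ln 2)). Two numerical choices matter at the borders:

* the kernel is truncated at 4σ and **not** renormalized per pixel; mass
  smoothed off the screen is recovered by the single global
  normalization. Per-pixel border correction would change interior
  values, breaking the linearity that the cross-validation engine relies
  on (the FDM of pooled trials is exactly the normalized sum of per-trial
  smoothed histograms);
* when an FDM is needed at reduced resolution, the histogram is built at
  the target resolution and the kernel σ rescaled with it, rather than
  smoothing at full resolution and resampling. Block summation
  (`downsample()`) is used for changing the resolution of an existing
  map, because it conserves mass exactly.

Kernel σ is kept per axis (x and y pixel densities may differ), although
on the common 1280×960 px / 28.4°×21.3° geometry the axes are virtually
identical (45.07 px/° each).

## The AUC and its exact tie handling

For classification measures, positives are the salience values at
fixated cells and negatives come from one of three strategies: all map
cells, all non-fixated cells, or donor locations (e.g. cells fixated on
*other* images — the hook for centre-bias-corrected "shuffled" controls).

`auc_score()` uses only the unique positive values as thresholds.
Between two such thresholds the ROC curve runs horizontally (negatives
passing at constant TPR), so lower-sum integration over those runs is
exact; where positives and negatives share a value the curve is a
diagonal, integrated trapezoidally, so each tied pair earns half credit;
the final run to (1, 1) is closed the same way. Three identities follow,
and the test suite asserts each at 1e-12:

* equality with the Mann–Whitney pairwise statistic
  `(wins + ties/2) / (n_pos · n_neg)`;
* equality with trapezoidal integration of the full ROC over all pooled
  thresholds (`roc_curve()` / `roc_auc()`);
* exactly 0.5 for a constant map, exactly 1 under perfect separation.

Because the statistic is a mean over positives, AUC is linear under any
partition of the fixations — per-subject AUCs averaged with weights
|Pᵢ|/|P| equal the pooled AUC exactly. The same holds for NSS. This is
convenient (averages over subjects remain interpretable) but also means
these measures cannot reward a model for predicting behaviour *shared*
across subjects: KL divergence and correlation, which operate on density
estimates, do, and the suite demonstrates the contrast on a two-subject
fixture.

NSS uses the population SD of the map (the convention is configurable in
the sense that the z-scoring is explicit and documented; a constant map
raises an error rather than returning 0/0). The percentile measure
selects the top 100−p percent of *cells* by value (k-th largest value as
threshold), so on an all-distinct-values map the selected area is exactly
that fraction of the image and the uniform-fixation null is 0.20 for the
default p = 80. The ratio of medians scores each location by the disc
maximum within 5.6° (elliptical in cells under anisotropic pixels,
clipped at borders) and draws its control points uniformly, seeded. The
naive Bayes classifier uses equal-width bins over the pooled score range,
Laplace-smoothed training histograms, equal priors, and k-fold
cross-validation in which every point is tested exactly once; bin count,
fold count and the tie rule (ties → non-fixated) are stated because the
literature leaves them open.

## Theoretical maximum AUC

Treating the prediction as a probability density `p` over N cells, every
cell has both a finite chance of being fixated and of serving as a
control, so perfect classification is impossible. Under uniform controls
the best achievable AUC — attained by self-prediction — is the
probability-weighted pairwise statistic
Σᵢ Σⱼ pᵢ (1/N) [1(pᵢ>pⱼ) + ½·1(pᵢ=pⱼ)],
computed in O(N log N) by grouping equal values. It is 0.5 for the
uniform density, 1 − 1/(2N) for a delta, and < 1 otherwise. The
derivation assumes no spatial bias in the control distribution; the
package implements exactly this uniform-control case and records the
assumption in the result's parameters. Re-deriving the bound under a
biased control distribution would change the numbers but not the
principle, and is left out of scope.

## KL divergence and small-sample corrections

KL(P‖Q) = Σ pᵢ log(pᵢ/qᵢ) treats the model map (normalized) as a density
Q and the empirical FDM as P. Zero-valued predictions make the measure
infinite, so Q is floored at a configurable `q_floor` (default 10⁻¹² of
the uniform cell mass) and renormalized; 0·log 0 terms contribute 0. The
log base defaults to e (nats); reports should always state it.

Plug-in ("maximum likelihood") estimates of entropy — and hence KL — are
biased when the number of fixations is not much larger than the number
of bins, which makes scores computed from different sample sizes
incomparable. The package implements three corrections:

* **Miller–Madow**: ML + (m−1)/(2n) with m occupied bins;
* **Chao–Shen**: coverage C = 1 − f₁/n (f₁ singleton bins),
  coverage-adjusted probabilities p̃ᵢ = C·cᵢ/n, and Horvitz–Thompson
  weighting Ĥ = −Σ p̃ᵢ log p̃ᵢ / (1 − (1−p̃ᵢ)ⁿ). For KL the cross-entropy
  term is corrected the same way, −Σ p̃ᵢ log qᵢ / (1 − (1−p̃ᵢ)ⁿ), so the
  divergence is the corrected cross-entropy minus the corrected entropy.
  When every observation is a singleton the coverage is zero and the
  estimator refuses with guidance to increase n;
* **Jeffreys**: ½ added to every cell count before normalization — the
  Jeffreys/Krichevsky–Trofimov prior; the constant ½ is fixed by that
  definition. It works well when the underlying density is not too far
  from uniform and should be used cautiously otherwise.

`bias_simulation()` draws multinomial samples of increasing size from a
known density and tabulates each estimator's mean and SD, reproducing
the classic bias curves: plug-in KL against the generating density is
positive at every n and decays roughly like N/(2n); the corrected
estimators reach small bias once n is about half the number of bins.
Entropy/KL work uses a coarse grid by convention — bins sized so one bin
has the area of a 2°-diameter disc, 16×12 bins on the standard geometry
(`coarse_grid()`) — because the effective resolution of a 2°-smoothed
FDM is far below the pixel count. The acceptance suite runs a scaled-down
version of the bias experiment: n from 6 to 400 in steps of 10 with 200
replicates per size (the full-scale protocol, 6 to 800 in steps of 2 with
1000 replicates, produces the same curves with less Monte-Carlo noise and
is available through the same function and the `entropy-sim` CLI
subcommand).

## The reference frame

Two data-derived baselines bracket the useful range of any score:

* **Lower bound** (`lower_bound()`): predict one subject's fixations on
  one image with the FDM of *other* subjects on *other* images — the
  pure spatial bias, blind to both test subject and test image. Any
  model worth reporting must beat it.
* **Upper bound** (`upper_bound()`): predict a held-out subject from
  other subjects on the *same* image — inter-subject consistency, the
  ceiling for models that ignore subject identity.

Both are cross-validated over a configurable schedule (`cv_schedule()`):
training-set sizes per axis, repetitions per test, and explicit
round-robin balancing for training sets of one or two donors, where
independent random draws would over-use some donors. The default
schedule (subject sizes 1, 2, 4, 7, 13, 25, 47; image sizes 1, 2, 4, 8,
16, 32, 63; 47 repetitions, 63 for subject-specific runs) matches a
48-subject, 64-images-per-category study layout; the engine runs on any
dataset size, marking infeasible cells as missing. All bound
computations run per stimulus category and never pool across categories.
For KL-based bounds the working grid should be the coarse grid above and
test-set sizes kept constant, since the correction methods control the
test set, not the training set.

Subject idiosyncrasy enters in three stages:

1. `subject_bias_eval()`: the subject's own spatial bias from other
   images, versus a foreign subject's bias;
2. `pca_basis()` / `pca_clean_bias()`: a PCA across training subjects'
   bias maps yields the directions in which spatial biases vary;
   regressing a noisy subject bias onto the first k = 5 components (the
   variance spectrum drops fast, and with orthonormal components the
   least-squares weights are plain projections) denoises it. Component
   signs are arbitrary; the package fixes the largest-magnitude
   coefficient positive purely for reproducibility. The PCA is performed
   on smoothed FDM biases at the working scale, not on raw histograms —
   bias maps are whole-screen structures, and for bias-map work a broader
   kernel than the 2° default (5–8° FWHM) gives markedly more stable
   components. The eigenvalue-weighted sum of components
   (`eigen_weighted_bias()`) serves as the subject-blind control;
3. `combined_prediction()`: divide the inter-subject FDM point-wise by
   the training subjects' spatial bias (floored at 10⁻⁶ of uniform mass;
   the divisor's zeros are otherwise unconstrained), multiply by the
   *predicted subject's* own bias, and renormalize. With real subject
   idiosyncrasy this prediction can exceed the inter-subject upper
   bound — a caution against treating that bound as absolute.

## The synthetic generator as study design

`make_dataset()` draws every fixation from a three-component mixture:
a category-specific central-bias Gaussian, an image-specific hotspot
Gaussian (hotspot centres drawn once per image, shared by all subjects,
restricted to the central 80% of the screen so border truncation does not
dominate coarse grids), and a subject-idiosyncrasy Gaussian — the central
bias shifted by a per-subject offset that is a linear combination of a
small number of fixed component directions with Normal(0, subject_weight_sd)
weights. Draws are truncated to the screen by rejection, so each
component remains a proper renormalized truncated Gaussian and
`ground_truth_density()` can return the exact mixture analytically on any
grid. One root seed feeds three independent streams (image layout,
subject structure, fixation draws), so changing the number of subjects
does not reshuffle image layouts.

Defaults emulate a free-viewing study on two categories: 15 fixations
per trial; a tight central bias for outdoor "naturals" (per-axis SD
4.5°/3.5°) and a broader one for "urbans" (8°/6°), mirroring the common
observation that natural scenes evoke a stronger centre bias; two
hotspots per image with 1.5° SD; mixture weights (0.45, 0.40, 0.15); two
subject components with 1.5° weight SD. Under these conditions the
reference frame reproduces the qualitative structure of real data — the
upper bound exceeds the lower bound, both exceed chance, both rise with
training-set size, and the category with the stronger central bias has
the higher lower bound.

What the generator does **not** emulate: temporal structure (scan paths,
saccade amplitudes, fixation durations), object- or feature-based
salience (hotspots are isotropic Gaussians), tracker noise models, or
heavy-tailed idiosyncrasies. Passing tests therefore certify the
*machinery* — estimators, cross-validation hygiene, orderings — on data
whose generating process is known; they do not certify that any
particular real dataset satisfies the mixture assumptions.

The test suite fixes the study conditions it certifies: the
reference-frame ordering is checked on 12 subjects × 16 images × 15
fixations with a reduced schedule (subject sizes 1–11, image sizes 1–7,
3 repetitions); the PCA-recovery check uses 24 subjects × 48 images with
a dominant subject component (mixture weight 0.7, two planted
directions, 1.2° weight SD) — idiosyncrasy must dominate hotspot
variance for the planted subspace to be identifiable, and offsets must
stay moderate relative to the central-bias SD because a shifted Gaussian
is only first-order linear in its shift; the better-than-perfect check
uses 12 subjects × 16 images with half of all fixation mass
subject-specific (weight 0.5, 4° weight SD) and 5°-smoothed bias maps in
the division, since the point-wise ratio of two thinly-sampled 2° FDMs
is dominated by estimation noise. These sizes keep the full suite under
a few minutes on one CPU while leaving every assertion comfortably clear
of its Monte-Carlo error.

## Known limitations

* The theoretical AUC ceiling covers uniform controls only; no
  equilibration for spatially biased control sets.
* Shuffled-AUC exists only through the donor-negatives hook, not as a
  named measure; scan-path and temporal measures are out of scope.
* Entropy estimators beyond ML, Miller–Madow, Chao–Shen and Jeffreys
  (shrinkage, NSB, minimax, …) are not implemented, though the
  simulation harness's output schema accommodates externally computed
  values.
* Statistical testing of bound differences (ANOVAs, paired t-tests) is
  left to standard tools; the engine reports per-cell means, SDs and
  test counts so any such test can be run downstream.
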
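---
title: "Decoding visual stimuli from intra-V1 connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding visual stimuli from intra-V1 connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v1decode)
```

## The scientific problem

Primary visual cortex is retinotopically organized: every cortical site maps a
fixed visual-field location. Beyond local stimulus preferences, the
*correlations* between V1 sites form stimulus-conditioned networks. This
package implements a complete pipeline for asking whether the identity of a
compound (Navon) stimulus — a Global letter built from Local letters — can be
decoded from the topology of correlations *within* V1, how much of that
decoding survives when the stimulus-evoked response is removed, which
visual-field sub-networks carry the discriminative edges, and whether eye
movements could explain such decoding.

Because raw recordings of such experiments are rarely redistributable, the
package ships a first-class synthetic-data generator that emulates that design, and every downstream module is exercised and validated against it.

## The experimental design being emulated

The block design uses four conditions crossing letter identity (E, U) and
level (Global, Local): EG, EL, UG, UL. Each run holds 12 blocks of 44 s
(1 s cue, 19 s baseline, 20 s letter repetitions, 4 s report), three blocks
per condition in random order; sessions have 4 or 5 runs and the fMRI TR is
2.5 s. Stimuli are a 3 x 5 grid of figure-eight placeholders about 2.0
degrees of visual angle (DVA) wide and 5.3 DVA tall; letters are unveiled by
erasing segments — whole placeholders form a Global letter, a single modified
placeholder forms a Local one (`render_navon()`). Analysis is restricted to
vertices mapping the central 4 DVA of eccentricity.

`make_block_schedule()` reproduces this arithmetic exactly; with 5 runs the
per-condition concatenated stimulation epochs span 120 TR samples, with 4
runs 96. Block onsets advance on a 44 s grid that is not a multiple of the
TR, so epoch extraction and regressor construction round onsets to the
nearest TR; every block still contributes exactly 8 stimulation samples. Runs
are sized from the schedule (`ceiling(528 s / TR)` plus a 10-volume tail covering the final block's hemodynamic and FIR windows) so
that the last block's lag-shifted window always fits.

## The generative model of the synthetic cohort

`simulate_cohort()` writes each run as the sum of three sources:

* **Common evoked response.** Per condition, a cohort-level spatial pattern
  (one loading per vertex) times the condition's boxcar regressor convolved
  with the canonical double-gamma HRF (peak near 5 s, 32 s support,
  `canonical_hrf()`).
* **Idiosyncratic evoked response.** The same regressor with
  subject-specific multiplicative gain jitter and a subject-specific spatial
  pattern perturbation, both scaled by `idio_sd`. Individual evoked responses are known to differ without a canonical parametric form; gain-plus-pattern jitter is the simplest two-parameter realization.
* **Background activity.** AR(1) noise (coefficient 0.3, a typical fMRI
  residual autocorrelation; configurable) whose innovation covariance is
  condition-dependent during the lag-shifted stimulation epochs and isotropic
  elsewhere, matching the epoch segmentation downstream.

Condition-dependent network structure is *planted* as correlation increments
on disjoint vertex pairs (`effect_spec()`): mirror pairs across hemispheres
("interhemispheric") or consecutive within-hemisphere pairs
("intrahemispheric"). Pairwise planting keeps the covariance positive
definite for any increment below 1; a uniform increment on *all*
interhemispheric edges would make the covariance indefinite once
increment x pairs-per-vertex exceeds 1, so it cannot serve as a generative
model. The default positive-control spec (`"level_topology"`) plants
interhemispheric pairs (+0.35) for the two Global conditions and
intra-hemispheric pairs (+0.35) for the two Local conditions, emulating the
reported Level topology; letter identity carries no planted network
difference, so abstract Letter decoding from background structure should sit
at chance. Confound signals (a linear drift and six pseudo-motion random
walks) are mixed into the data with loadings proportional to the background
scale and returned for nuisance regression.

The vertex map (`build_retinotopic_map()`) is a jittered sunflower layout,
uniform in area over the 4-DVA disc, half the vertices per hemisphere with
the contralateral convention (left hemisphere maps the right hemifield).
Cortical-magnification-weighted density is deliberately not modeled: the
topology tests only need quadrant labels and hemisphere membership. The number of vertices is a free parameter rather than a fixed constant: per-subject vertex counts within a 4-DVA ROI vary with anatomy and surface resolution.

## Preprocessing schemes

`condition_series()` applies the fixed order: (1) nuisance regression of the
confounds plus a discrete-cosine drift basis implementing the 128 s high-pass
(`nuisance_regress()`), on full runs; (2) optionally a deconvolution GLM, on
full runs — canonical (each condition a 20 s boxcar convolved with the
canonical HRF) or FIR (19 unit impulses per condition at TR lags 0..18 from
stimulation onset, able to absorb any TR-locked response shape); (3) epoch
segmentation at the hemodynamic lag, per-segment linear detrending (mean and
slope), and concatenation per condition. Deconvolving after segmentation is
*not* equivalent and is not offered. The hemodynamic lag defaults to 5 s
(2 TRs, the canonical peak); it is exposed as a parameter because any value near the hemodynamic peak is defensible. The FIR window (19 x 2.5 s =
47.5 s from stimulation onset) slightly overlaps the next block; the joint
OLS fit handles the overlap and a collinearity warning is emitted if the
design degenerates.

## Connectivity and features

Within-subject matrices are plain Pearson correlations over the concatenated
epochs (`within_subject_matrix()`). Common-response (CR) matrices correlate
one subject's series with the grand average of all other subjects' series of
the same condition, in both directions, averaged into a symmetric matrix
(`common_response_matrix()`); averaging across subjects cancels activity not
shared by the cohort, so CR isolates the common evoked response while the
deconvolved schemes emphasize what remains after removing it.

Feature vectors (`to_features()`) take the row-major upper triangle
(diagonal excluded as uninformative self-correlation), apply the Fisher
r-to-z transform, and set negative values to zero. Rectification is applied
in z-space; since atanh is sign-preserving this is equivalent to rectifying
in r-space, and the choice is recorded here explicitly.
Edges are labeled by the unordered pair of visual-field quadrants of their
endpoints (`partition_subnetworks()`): four within-quadrant classes (ULq,
URq, LoLeq, LoRq) and six between-quadrant classes (LRup, LRlo horizontal;
UDle, UDr vertical; DiagP, DiagS diagonal). Label names follow the field's quadrant-pair shorthand; the upper-quadrant and upper-horizontal names are assigned systematically.

## Classification

All classifiers are linear soft-margin SVMs with C = 1 and no feature
standardization (rectified z features are already commensurate), preceded by
per-feature two-sample t-test selection at p < 0.01 on the *training data
only*. The equal-variance (Student) statistic is the default with a Welch
option. If no feature survives, the single smallest-p feature is kept with a
warning — a degenerate case only tiny training sets reach.

* **Specific (inter-subject) tests** (`loso_classify()`): leave-one-subject-out
  over one condition pair; with 26 subjects each fold trains on 50 samples
  and tests on the held-out subject's 2.
* **Abstract cross-classification** (`cross_classify()`): train on one pair
  (e.g. EG vs EL), test on the other (UG vs UL), both directions, accuracies
  averaged; no cross-validation is needed because training and test data are
  disjoint by construction.

An inter-subject variant of the abstract tests (`abstract_cross_loso()`)
checks that the transfer is stable across individuals. Its fold structure is
not uniquely determined by the idea of mixing leave-one-subject-out with
pair transfer; the implementation trains on one pair of the remaining n - 1
subjects and tests on the *other* pair of the held-out subject, in both
directions, which keeps both the subject split and the pair split strict.

Permutation tests (`permutation_test()`) shuffle training labels only —
within each training fold for LOSO, independently in both directions for
cross-classification — and use the add-one estimator
p = (1 + #{null >= observed})/(1 + n_perm), which cannot return zero.
Independent p-values are combined with Fisher's method
(`fisher_combine()`), referred to the chi-square with 2k df.

## Weight-map interpretation

Backward-model SVM weights are not directly interpretable; `haufe_transform()`
converts them to forward-model activations a = cov(X) w on the retained
features (zeros elsewhere). The scalar latent variance of the full forward
model is omitted: rankings and percentile cuts are scale-invariant.
`bootstrap_weight_maps()` resamples participants with replacement, retrains
both direction-specific Level classifiers per replicate, and transforms each.
Signs are fixed so positive activation supports Local and negative Global.
`summarize_maps()` averages the two direction maps within replicates, takes
the per-edge median across replicates, and marks the upper and lower 2.5% of
*nonzero-median* edges as significant (counts use the ceiling; ties break by
edge index). The percentile domain (nonzero-median edges rather than all
edges) is a documented choice of this implementation. Concordance
between directions is Kendall's W per replicate (midranks, tie correction)
over the union of edges retained in either direction — edges retained in
neither are excluded rather than midranked at zero — with a 95% BCa interval
(`bca_ci()`; the acceleration term uses jackknife values when supplied and 0
otherwise). For two raters, W = (1 + rho)/2 of the Spearman correlation, so
chance is 0.5. Counts of significant edges per sub-network feed a
chi-square homogeneity test with Monte-Carlo p for sparse tables
(`heterogeneity_test()`), a deliberate substitute for loglinear heterogeneity modeling, chosen for its transparent null.

## Gaze simulation

`build_gabor_bank()` models V1 as a pyramid of quadrature Gabor filters:
five frequencies (1, 2, 4, 8, 16 cycles/FOV), eight orientations, two
phases, tiled at 2, 8, 16, 64 and 256 evenly spaced positions — 346 nodes
after collapsing orientation and phase. Collapse is quadrature energy
(sqrt of summed squared phases) summed over orientations; plain summation is
available as an option. "Convolving stimuli with gaze" is implemented as
retina-centered translation per fixation (saccade-in-flight blur ignored).
Per-fixation node responses are expanded in time by holding each response
for the fixation's duration on a 1 ms grid, convolving with the canonical
HRF and sampling at the TR grid — computed exactly by step-response
superposition with the cumulative 1 ms HRF, which is algebraically identical
to dense convolution followed by decimation-by-sampling. No noise is added,
which if anything overstates the information available to the classifiers.
`run_sim_experiment()` feeds the resulting node-by-node correlation matrices
through the identical feature and classification pipeline. The node space is
the orientation/phase-collapsed units; the full filter space is available via
the collapse option.

The synthetic gaze generator (`simulate_gaze()`) is a stand-in for eye-tracker
recordings: fixation centers Gaussian around the lit-pixel centroid,
log-normal durations truncated at the 20 s epoch. Because it is a stand-in,
simulation findings about *specific* discriminations (driven by stimulus
geometry) are reproduced, but the generator makes no claim to reproduce
idiosyncratic human scan paths.

## Control-experiment statistics

`fixation_heatmap()` projects fixations as duration-weighted deltas,
smooths with a unit-mass 2D Gaussian (SDs of 5, 10, 20, 40 px in the
original), and downsizes by 0.25 using block *summation*, so total map mass
equals total fixation duration exactly (means would shrink mass 16-fold).
`fit_pixel_models()` fits, at every nonzero pixel,
`heatmap ~ 1 + Level + Letter + TrialOrder + Level:Letter + (1 | participant)`
by maximum likelihood. The fitter is a vectorized profiled-ML solver
specialized to the random-intercept structure: for each candidate variance
ratio the model whitens in closed form by group-mean shrinkage, reducing
every pixel to OLS; the ratio is selected per pixel on a log grid. It matches
`lme4::lmer(REML = FALSE)` coefficients to four decimals in the test suite
while being fast enough to sit inside a bootstrap. Wald t statistics use
between-within denominator degrees of freedom (n - participants - p + 1),
with +-0.5 sum-to-zero coding so the Level and Letter coefficients are
average condition differences.

`cluster_mass_bootstrap()` thresholds the parametric p-map at
alpha/n-nonzero-pixels, forms 8-connected clusters, and scores each by the
sum of the tested coefficient. The null resamples participants with
replacement after subtracting the tested effect's fitted contribution
(bootstrap under the null), refits, re-forms clusters under the same
threshold, and keeps the maximum absolute cluster mass per resample — the
conservative max-statistic choice for family-wise control; a pooled null is
the natural alternative and the max was chosen deliberately. When the
original maps have no supra-threshold pixel the result is empty and the
bootstrap is skipped.

## Numerical and design choices

* Correlations of exactly +-1 (possible in noiseless simulations) are
  clipped to +-(1 - 1e-7) before Fisher z, with a warning.
* Zero-variance vertices get zeroed matrix rows/columns with a warning.
* All randomness flows through explicit seeds; cohort generation,
  classification, bootstraps and simulations are bitwise reproducible, and
  the internal seeding restores the caller's RNG state.
* SVM fits are convex and deterministic given the data; libsvm (e1071)
  provides the solver.
* The permutation estimator adds one to numerator and denominator, so the
  smallest attainable p is 1/(n_perm + 1).

## What the tests do and do not show

The test-suite problem sizes are the package's own choices: calibration uses
200 null cohorts (10 subjects, 50 vertices, 199 permutations) and 500
pure-noise map simulations (199 bootstrap resamples); recovery uses 20 seeds
at 26 subjects and 100 vertices with 199 permutations and 200 bootstrap
replicates; the gaze negative control uses 50 seeds with a reduced
four-level bank on a 64 px field of view. Passing them shows the pipeline is
internally calibrated (type-I error at nominal rate, null accuracy at 0.5),
that its estimators agree with brute-force oracles, and that planted
condition-dependent network structure is recovered end to end with the
correct sub-network attribution. It does not show that real V1 data contain
such structure: the generator's evoked geometry, noise spectra and gaze
statistics are idealized, vertex layouts ignore cortical magnification, and
no claim about the original recordings follows from synthetic recovery.
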
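---
title: "Methods: how brainalign measures model-brain representational alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how brainalign measures model-brain representational alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainalign)
```

## The problem

Given layer-wise activations of an artificial network and multi-subject brain
responses (fMRI voxels, or EEG/MEG sensors over time) to the same stimulus
set, how similar are the two representations? brainalign implements the two
standard families of answers and several refinements of each:

* **Representational similarity analysis (RSA).** Each system is abstracted
  into a representational dissimilarity matrix (RDM): the symmetric
  conditions x conditions matrix of pairwise pattern dissimilarities. RDMs
  from incommensurable measurement spaces share a format, so alignment is the
  correlation between their vectorized off-diagonal upper triangles.
* **Voxelwise encoding.** A cross-validated linear regression maps model
  features directly onto each measurement channel; alignment is the held-out
  Pearson correlation between predicted and measured responses.

On top of these sit weighted RSA (nonnegative reweighting of several
predictor RDMs), searchlight RSA (a local RSA map over a volume), veRSA
(RSA between encoder-predicted and measured patterns), stacked encoding
(a simplex-weighted combination of several feature spaces), variance
partitioning (unique/shared R^2 decomposition across feature spaces),
centered kernel alignment, and distributional distances between
representations (Jensen-Shannon divergence, 1-D Wasserstein).

## Assumptions about the inputs

Brain responses are assumed fully preprocessed and averaged over repeated
presentations: one finite response vector per stimulus per channel. The
package never denoises, detrends or rescales silently; `zscore_channels()`
is available but must be called explicitly. Stimulus order is canonical —
lexicographic by stimulus id — and every consumer reorders its rows to it, so
all pairwise structures are comparable by construction. One RDM is computed
per subject and ROI from the provided (already averaged) responses; session-
level handling is upstream of this package.

## RDMs and their comparison

`compute_rdm()` supports `pearson` (1 minus Pearson r, in [0, 2]), `cosine`
(1 minus cosine similarity, in [0, 2]), `euclidean` (L2), and user-supplied
callables (validated on first use: one nonnegative finite scalar from two
vectors). Zero-variance patterns under `pearson` (and zero-norm patterns
under `cosine`) are hard errors naming the offending condition, not silent
`NaN`s — a `NaN` entry would silently poison every downstream correlation.
The chunked variant processes row blocks and is guaranteed to agree with the
plain path to 1e-10; the diagonal is forced to exactly zero and the matrix is
symmetrized by averaging with its transpose.

`compare_rdms()` correlates vectorized upper triangles (Pearson by default,
the field's standard for RDM-to-RDM comparison; Spearman and Kendall are
options). Comparing an RDM with itself returns exactly 1: the identical-input
case short-circuits the correlation so the self-comparison invariant holds
bit-exactly rather than to within a rounding error.

Subject averaging in `evaluate_rsa()` is either `direct` (mean of subject
correlations) or `squared` — defined here as the sign-preserving mean
`mean(sign(r) * r^2)`. The squared mode is conventionally described only by
name; the sign-preserving form was chosen so that anticorrelated subjects
reduce rather than inflate the score.

**Noise ceiling.** Leave-one-out convention: the upper bound averages each
subject's correlation with the group-mean RDM including that subject, the
lower bound with the mean excluding it. The lower bound never exceeds the
upper. Note that for fully unrelated subjects the upper bound is not zero but
about `1/sqrt(n_subjects)` — each subject's RDM is correlated with a mean
that contains it.

**Significance.** Default: a two-sided one-sample t test of per-subject
scores against zero, alpha 0.05, uncorrected; a seeded sign-flip permutation
test (10,000 flips, p = (1 + #as-extreme) / (1 + flips)) and
Benjamini-Hochberg correction across a batch are options. Zero-variance score
vectors are reported as p = 0 (nonzero common value) or p = 1 (all zero),
never `NaN`.

**Weighted RSA.** Vectorized predictor RDMs are regressed onto the
vectorized target with nonnegative least squares (Lawson-Hanson, via
pracma), without an intercept and without regularization — the common choice
for RDM reweighting. Cross-validation is at the level of condition pairs:
pairs are shuffled with a seed into k folds (default 5); the score is the
mean held-out Pearson correlation between the weighted prediction and the
target.

**Searchlight.** Spheres use Euclidean voxel distance with the center
included (default radius 2 voxels; the radius is a free parameter and is
exposed). Out-of-mask voxels get `NA`; a center whose sphere (intersected
with the mask) holds fewer than two voxels is scored `NA` with a warning
rather than aborting the map, so one pathological sphere cannot kill a whole
analysis. Volumes and score maps can be read from and written to NIfTI via
RNifti.

## Encoding models

`encoding_spec()` defaults encode the standard protocol: three
cross-validation folds, each an independent seeded 80/20 train/test split,
features reduced to 100 principal components, ordinary least squares. Three
*disjoint* folds of 20% would train on 80% only by coincidence of the
arithmetic; independent repeated splits are what "an 80/20 split across three
folds" actually specifies, so that is what is implemented.

Numerical choices:

* PCA is fitted on the training split only (test rows cannot leak into the
  components; a dedicated test permutes held-out rows and checks the fitted
  projection is unchanged). The component count is clamped to
  `min(requested, n_train - 1, n_features)` and recorded.
* OLS uses the SVD pseudo-inverse with a relative singular-value cutoff of
  1e-10, so rank-deficient designs (e.g. duplicated feature spaces) are
  handled without error.
* Ridge selects its penalty per fold by generalized cross-validation (GCV)
  over the grid {0.01, 0.1, 1, 10, 100, 1000}. GCV is known to become
  unreliable when the model can interpolate (effective degrees of freedom
  near the training size); with the default PCA-100 this regime is rare, but
  users fitting `pca_components = NULL` with more features than stimuli
  should prefer an explicit grid search.
* Channels that are constant in a test fold (in truth or prediction) get
  `NaN` correlations, are excluded from aggregate means, counted, and
  reported.

**Stacked encoding** fits one base encoder per feature space on an inner
80/20 split of the training data, then per channel solves the
simplex-constrained least-squares combination of the base models' held-out
inner predictions. The solver is projected gradient with fixed step 1/L
(L the largest eigenvalue of twice the Gram matrix), initialized at the best
single-space vertex — initialization plus monotone descent guarantee the
combined training objective never exceeds the best single space. Base
encoders are then refitted on the full outer training split and the weighted
combination is scored on the outer test split.

**veRSA** scores, per fold, the RDM correlation between encoder-predicted and
measured test patterns, and averages fold scores (it does not pool
predictions across folds; pooling would mix predictions from differently
trained models into one RDM).

## Variance partitioning

For 2-4 feature spaces, every non-empty subset's concatenated design is fit
by OLS with shared cross-validation folds, and the full-model R^2 is
decomposed into unique and shared commonality components by Moebius
inversion over the subset lattice. Cross-validated R^2 uses the training
mean as the test baseline, and negative values are deliberately kept:
truncating at zero would break the exact identity that components sum to the
full-model R^2. PCA is not applied inside variance partitioning — component
clamping would silently change subset R^2 values and break the algebraic
checks against a direct least-squares solve.

Finite-sample caution: cross-validated subset R^2 carries sampling noise, so
"orthogonal designs have zero shared variance" holds only asymptotically.
The package's own checks use 1500 stimuli with 4-column spaces, where the
shared component of a truly orthogonal design stays within 0.02 of zero; at
a few hundred stimuli, deviations of +-0.1 are normal and are a property of
cross-validated R^2, not of the decomposition.

Structured (nested) variance partitioning takes a user-declared hierarchy
and reports forward increments `R^2(first i) - R^2(first i-1)` (telescoping
to the full R^2 exactly) and backward decrements
`R^2(all) - R^2(all minus level i)`.

## Distributional metrics

Linear CKA is the core similarity for raw high-dimensional spaces:
`||X'Y||_F^2 / (||X'X||_F ||Y'Y||_F)` after column centering — invariant to
orthogonal rotation and isotropic scaling of either argument. An RBF-kernel
variant with the median-distance bandwidth heuristic is provided as an
extra.

Jensen-Shannon divergence and the 1-D Wasserstein distance compare two
*distributions* of representation values. Which distributions is a real
design decision: by default the package compares the vectorized RDM entries
of the two systems (well-posed whenever they share a stimulus set,
regardless of dimensionality); flattened raw activations are available
behind `mode = "activations"`. JSD uses 100 shared equal-width bins over the
pooled range and base-2 logarithms, so its value lives in [0, 1] with 1
attained on disjoint supports; zero-count bins need no smoothing because the
mixture denominator is positive wherever a numerator is. The bin count
matters for heavy-tailed samples — widening the range stretches bins and can
lower resolution where the mass is. W1 integrates |F_a - F_b| exactly over
the pooled sorted sample.

## The synthetic generator: what it does and does not emulate

`generate_synthetic_dataset()` draws a latent stimulus representation Z
(standard normal, `n_stimuli x n_latent`) that both model layers and
subjects observe through their own linear read-outs. Layer l is the additive
mixture `sqrt(f_l) Z A_l + sqrt(1 - f_l) E_l` with unit-norm Gaussian mixing
columns and independent unit-variance noise, so each feature has variance 1
whatever its signal fraction `f_l` — layers differ only in how much shared
structure they carry, never in scale. Subject s responds with `Z W_s` plus
i.i.d. noise of sd `subject_noise_sd`.

Defaults — 200 stimuli, 20 latent dimensions, 3 subjects, 30 channels, 60
features per layer, two layers with signal fractions (1, 0), noise sd 1 —
are a deliberately desk-scale caricature of a single-ROI fMRI study: one
clearly informative layer, one pure-noise control, and a moderate
single-subject signal-to-noise ratio.

What passing tests on this generator show: the estimators recover linear
shared structure, rank informative layers above uninformative ones, respect
their algebraic identities, and are reproducible. What they do not show:
robustness to nonlinear stimulus-response mappings, temporally correlated
noise, between-subject misalignment beyond random read-outs, voxel
correlation structure, or non-Gaussian activation statistics — all present
in real data and all outside this generator.

## Reproducibility and the pipeline

A pipeline run is defined by one JSON config (unknown keys are rejected with
a nearest-key suggestion). The single global seed fans out to per-stage
seeds via `stage_seed()`, a deterministic hash of the stage name — stages
never share an RNG stream, and adding a stage cannot shift another stage's
randomness. Reruns of one config produce byte-identical results CSVs; the
run manifest records the config, package version, derived stage seeds and
input checksums.

## Scale of the package's own checks

The test suite and the acceptance script run entirely on generated data at
the sizes above (the largest objects are a 12^3-voxel searchlight volume
with 20 stimuli and a 1500-stimulus orthogonal design for variance
partitioning), chosen so every property is measurable with comfortable
statistical margin while the whole suite stays fast on a single CPU.

## Known limitations

* Crossvalidated distance estimators (crossnobis) are not implemented; RDM
  metrics operate on provided (averaged) patterns.
* Group inference is limited to t and sign-flip permutation tests across
  subjects; no mixed-effects models.
* Searchlights are volumetric only; surface-based analysis and brain-surface
  rendering are out of scope by design.
* Stacked encoding and variance partitioning assume linear read-outs
  throughout; nonlinear encoders are out of scope.
* The shipped model registry is a curated starter (about forty entries); it
  is a plain JSON document intended to be extended, not an exhaustive model
  zoo, and the package neither downloads weights nor runs networks — feature
  extraction is delegated to user-supplied adapters.
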
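# brainalign

Tools for quantifying how well the internal representations of artificial
network models align with human brain responses — for cognitive and
computational neuroscientists comparing network layers (CNN stages,
transformer blocks, language-model layers) against fMRI ROIs or EEG/MEG
sensor patterns over a shared stimulus set.

## What it computes

Two complementary views of model-brain alignment, plus refinements of each:

**Representational similarity analysis.** Each system — a network layer or a
subject's ROI — is summarized by its representational dissimilarity matrix
(RDM): for patterns *x<sub>i</sub>* over conditions *i*, the matrix
*D<sub>ij</sub> = d(x<sub>i</sub>, x<sub>j</sub>)* with *d* one of
1 − Pearson *r*, 1 − cosine, Euclidean, or a user metric. The RSA score is
the correlation of the two RDMs' vectorized upper triangles. Around this:
subject averaging (direct or sign-preserving squared), leave-one-subject-out
noise ceilings, t/permutation group significance, weighted RSA
(nonnegative least squares over several predictor RDMs, pair-level CV), and
a volumetric searchlight that maps local RSA scores voxel by voxel.

**Voxelwise encoding.** Cross-validated linear (or ridge) regression from
layer activations to each measurement channel, scored by held-out Pearson
*r*; defaults are three seeded 80/20 splits with train-only PCA to 100
components. On top: stacked encoding (per-channel simplex-weighted
combination of several feature spaces), veRSA (RDM correlation between
predicted and measured test patterns), and unique/shared variance
partitioning across 2–4 feature spaces via subset-model R² and Möbius
inversion, with a structured (nested) variant along a declared feature
hierarchy.

Direct representation-level measures — linear CKA
(‖XᵀY‖²_F / (‖XᵀX‖_F ‖YᵀY‖_F) after centering), Jensen-Shannon divergence
and 1-D Wasserstein distance between representation distributions — plus a
searchable model-taxonomy registry, publication-style plots (per-layer bars
with ceilings and significance, best-layer view, time courses), a
reproducible run pipeline, and a synthetic dataset generator so the entire
workflow runs and is tested without any data downloads.

## Worked example

```r
library(brainalign)

# A synthetic study: 200 stimuli, two model layers (one informative, one
# pure noise), three subjects with moderate response noise.
ds <- generate_synthetic_dataset(synthetic_spec(seed = 7))

model_rdms <- lapply(ds$features,  function(f) compute_rdm(f$data, "pearson", source = f$layer))
brain_rdms <- lapply(ds$responses, function(b) compute_rdm(b$data, "pearson", source = b$subject))

evaluate_rsa(model_rdms, brain_rdms)
#> # A tibble: 2 x 7
#>   model  roi      score p_value significant ceiling_lower ceiling_upper
#> 1 layer1 sub01  0.439   0.00105 TRUE                0.328         0.712
#> 2 layer2 sub01 -0.00597 0.227   FALSE               0.328         0.712

linear_encoding(ds$features$layer1, ds$responses[[1]], encoding_spec(seed = 7))
#> <encoding_result: model/layer1 vs sub01/roi1, mean r = 0.651 (p = 0.000125)>

linear_cka(ds$features$layer1$data, ds$responses[[1]]$data)
#> [1] 0.537
```

Reading the numbers: the informative layer's RSA score (0.44) lands inside
the noise-ceiling band (0.33–0.71) — it explains about as much shared RDM
structure as an average subject does — and is significant across subjects,
while the noise layer sits at zero. The encoding model predicts held-out
responses at mean r = 0.65 per channel, and CKA gives a complementary
similarity (0.54) computed on the raw feature/response matrices rather than
on RDMs.

`plot_bars()`, `plot_best_layer()` and `plot_timecourse()` turn result
tables into figures; `run_pipeline()` executes a whole configured study
(generation/loading → evaluation → plots) with one seed and writes
`results.csv`, `figure.png` and a manifest. A thin command-line interface
covering the common steps ships at `inst/cli/brainalign`
(subcommands: `taxonomy`, `rdm`, `rsa`, `encode`, `metric`, `run`).

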
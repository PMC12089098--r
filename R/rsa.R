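#' Correlate two RDMs
#'
#' The RSA score: the correlation between the two RDMs' vectorized
#' off-diagonal upper triangles.
#'
#' @param a,b [rdm()] objects over the same conditions in the same order.
#' @param comparator `"pearson"` (default, the standard choice), `"spearman"`
#'   or `"kendall"`.
#' @return A correlation in \[-1, 1\].
#' @export
compare_rdms <- function(a, b, comparator = c("pearson", "spearman", "kendall")) {
  comparator <- match.arg(comparator)
  abort_if(!identical(a$condition_ids, b$condition_ids),
           "RDMs do not share condition order", "alignment_error")
  va <- vectorize_rdm(a); vb <- vectorize_rdm(b)
  abort_if(sd(va) == 0 || sd(vb) == 0,
           "constant RDM vector: correlation undefined", "degenerate_error")
  if (identical(va, vb)) return(1)  # exact self-comparison, no rounding
  cor(va, vb, method = comparator)
}

#' Group significance of per-subject RSA scores
#'
#' Tests whether subject-level scores differ from zero: `"ttest"` is a
#' two-sided one-sample t test; `"permutation"` is a sign-flip test
#' (two-sided, `n_perm` seeded flips, p estimated as (1 + #as-extreme) /
#' (1 + n_perm)). When several score vectors are passed together, the optional
#' Benjamini-Hochberg correction is applied across that batch.
#'
#' @param per_subject_r Numeric vector of scores, or a list of such vectors
#'   (a batch).
#' @param method `"ttest"` or `"permutation"`.
#' @param alpha Significance level (default 0.05).
#' @param correction `"none"` or `"fdr_bh"` across the batch.
#' @param n_perm Number of sign flips for the permutation test.
#' @param seed Seed for the sign flips.
#' @return A data.frame with columns `p_value`, `significant`, `degenerate`
#'   (one row per batch element).
#' @export
group_significance <- function(per_subject_r, method = c("ttest", "permutation"),
                               alpha = 0.05, correction = c("none", "fdr_bh"),
                               n_perm = 10000, seed = 1) {
  method <- match.arg(method); correction <- match.arg(correction)
  batch <- if (is.list(per_subject_r)) per_subject_r else list(per_subject_r)
  one <- function(r, i) {
    r <- as.numeric(r)
    if (method == "ttest") {
      abort_if(length(r) < 2, "t test needs >= 2 subjects", "validation_error")
      if (sd(r) <= sqrt(.Machine$double.eps) * max(abs(mean(r)), 1e-12)) {
        # Degenerate zero-variance case: identical scores. p = 0 when the
        # common value is nonzero (infinitely strong evidence under the t
        # model), p = 1 when it is zero. Never NaN.
        return(c(p = if (mean(r) == 0) 1 else 0, degen = 1))
      }
      c(p = t.test(r, mu = 0)$p.value, degen = 0)
    } else {
      abort_if(length(r) < 1, "permutation test needs >= 1 value",
               "validation_error")
      obs <- abs(mean(r))
      flips <- with_seed(stage_seed(seed, sprintf("signflip%d", i)), {
        matrix(sample(c(-1, 1), n_perm * length(r), replace = TRUE), n_perm)
      })
      null <- abs(flips %*% r) / length(r)
      c(p = (1 + sum(null >= obs - 1e-15)) / (1 + n_perm), degen = 0)
    }
  }
  res <- t(vapply(seq_along(batch), function(i) one(batch[[i]], i), c(p = 0, degen = 0)))
  p <- res[, "p"]
  if (correction == "fdr_bh") p <- p.adjust(p, method = "BH")
  data.frame(p_value = p, significant = p < alpha,
             degenerate = res[, "degen"] == 1)
}

#' Noise ceiling from per-subject RDMs
#'
#' Bounds the RSA score any model can reach given between-subject variability
#' (leave-one-out convention): the upper bound correlates each subject's RDM
#' with the group mean RDM including that subject; the lower bound with the
#' mean excluding it; both averaged over subjects.
#'
#' @param brain_rdms List of >= 2 subject [rdm()]s sharing condition order.
#' @param comparator As in [compare_rdms()].
#' @return List with `lower`, `upper`, `n_subjects`.
#' @export
noise_ceiling <- function(brain_rdms, comparator = "pearson") {
  ns <- length(brain_rdms)
  abort_if(ns < 2, "noise ceiling needs >= 2 subjects", "validation_error")
  ids <- brain_rdms[[1]]$condition_ids
  for (r in brain_rdms) abort_if(!identical(r$condition_ids, ids),
                                 "subject RDMs do not share condition order",
                                 "alignment_error")
  vs <- vapply(brain_rdms, vectorize_rdm, numeric(length(vectorize_rdm(brain_rdms[[1]]))))
  mean_all <- rowMeans(vs)
  upper <- mean(vapply(seq_len(ns), function(s)
    cor(vs[, s], mean_all, method = comparator), 0))
  lower <- mean(vapply(seq_len(ns), function(s)
    cor(vs[, s], rowMeans(vs[, -s, drop = FALSE]), method = comparator), 0))
  list(lower = lower, upper = upper, n_subjects = ns)
}

#' Standard RSA: model RDMs against per-subject brain RDMs
#'
#' For each model RDM, correlates it with every subject's brain RDM and
#' averages: `"direct"` mode is the plain mean of subject correlations;
#' `"squared"` is the sign-preserving mean of squared correlations
#' (`mean(sign(r) r^2)`), which emphasizes strong subjects without rewarding
#' anticorrelation. Group significance is computed across subjects, and a
#' leave-one-out noise ceiling is attached when >= 2 subjects are given.
#'
#' @param model_rdms List of model [rdm()]s (typically one per layer).
#' @param brain_rdms List of subject [rdm()]s for one ROI.
#' @param mode `"direct"` or `"squared"` averaging.
#' @param comparator As in [compare_rdms()].
#' @param significance `"ttest"` or `"permutation"`.
#' @param alpha,correction,seed Passed to [group_significance()].
#' @param roi ROI label for the output; default: first brain RDM's source.
#' @return A tibble with one row per model RDM: `model`, `roi`, `score`,
#'   `per_subject_r` (list-column), `averaging_mode`, `p_value`,
#'   `significant`, `ceiling_lower`, `ceiling_upper`.
#' @export
evaluate_rsa <- function(model_rdms, brain_rdms, mode = c("direct", "squared"),
                         comparator = "pearson",
                         significance = c("ttest", "permutation"),
                         alpha = 0.05, correction = "none", seed = 1,
                         roi = NULL) {
  mode <- match.arg(mode); significance <- match.arg(significance)
  abort_if(length(brain_rdms) < 1, "need at least one subject RDM",
           "validation_error")
  roi <- roi %||% brain_rdms[[1]]$source
  rs <- lapply(model_rdms, function(m)
    vapply(brain_rdms, function(b) compare_rdms(m, b, comparator), 0))
  score <- vapply(rs, function(r)
    if (mode == "direct") mean(r) else mean(sign(r) * r^2), 0)
  sig <- if (length(brain_rdms) >= 2 || significance == "permutation") {
    group_significance(rs, method = significance, alpha = alpha,
                       correction = if (correction == "none") "none" else "fdr_bh",
                       seed = seed)
  } else data.frame(p_value = NA_real_, significant = NA)[rep(1, length(rs)), ]
  ceiling <- if (length(brain_rdms) >= 2) noise_ceiling(brain_rdms, comparator)
             else list(lower = NA_real_, upper = NA_real_)
  tibble::tibble(
    model = vapply(model_rdms, function(m) m$source, ""),
    roi = roi, score = score, per_subject_r = rs, averaging_mode = mode,
    p_value = sig$p_value, significant = sig$significant,
    ceiling_lower = ceiling$lower, ceiling_upper = ceiling$upper)
}

#' Weighted RSA: reweight predictor RDMs to fit a target RDM
#'
#' Regresses the vectorized target RDM on one or more vectorized predictor
#' RDMs with nonnegative least squares (Lawson-Hanson), cross-validated at the
#' level of condition pairs: pairs are shuffled (seeded) into `folds` folds;
#' weights are fitted on the training pairs and scored by the Pearson
#' correlation between the weighted prediction and the target on held-out
#' pairs.
#'
#' @param predictor_rdms List of >= 1 predictor [rdm()]s.
#' @param target_rdm Target [rdm()].
#' @param folds Number of pair-level folds (>= 2).
#' @param seed Seed for the pair shuffle.
#' @return List with `weights` (nonnegative, fitted on all pairs, named by
#'   predictor source), `cv_score` (mean held-out correlation), and
#'   `fold_scores`.
#' @export
weighted_rsa <- function(predictor_rdms, target_rdm, folds = 5, seed = 1) {
  abort_if(length(predictor_rdms) < 1, "need >= 1 predictor RDM",
           "validation_error")
  abort_if(folds < 2, "need >= 2 folds", "validation_error")
  X <- vapply(predictor_rdms, function(r) {
    abort_if(!identical(r$condition_ids, target_rdm$condition_ids),
             "predictor and target RDMs do not share condition order",
             "alignment_error")
    vectorize_rdm(r)
  }, numeric(length(vectorize_rdm(target_rdm))))
  X <- cbind(X)
  y <- vectorize_rdm(target_rdm)
  m <- length(y)
  idx <- with_seed(stage_seed(seed, "wrsa_folds"), sample.int(m))
  fold_of <- rep_len(seq_len(folds), m)[order(idx)]  # balanced random folds
  fold_scores <- vapply(seq_len(folds), function(k) {
    tr <- fold_of != k; te <- !tr
    abort_if(sum(te) < 2 || sum(tr) < 2,
             "a fold holds fewer than 2 condition pairs", "fold_size_error")
    w <- pracma::lsqnonneg(X[tr, , drop = FALSE], y[tr])$x
    pred <- X[te, , drop = FALSE] %*% w
    if (sd(pred) == 0) 0 else cor(pred, y[te])
  }, 0)
  w_all <- pracma::lsqnonneg(X, y)$x
  names(w_all) <- vapply(predictor_rdms, function(r) r$source, "")
  list(weights = w_all, cv_score = mean(fold_scores), fold_scores = fold_scores)
}

# Integer offsets of voxels within a Euclidean sphere of the given radius.
sphere_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
}

#' Volumetric searchlight RSA
#'
#' Slides a sphere over every in-mask voxel of a 4-D response volume
#' (stimuli x X x Y x Z), computes the local brain RDM from the voxels inside
#' the sphere (intersected with the mask), correlates it with the model RDM,
#' and assigns the score to the sphere's center. Out-of-mask voxels get `NA`;
#' a center whose sphere holds fewer than 2 usable voxels is scored `NA` with
#' a warning rather than aborting the map.
#'
#' @param volume 4-D numeric array, stimuli x X x Y x Z.
#' @param mask 3-D logical array (X x Y x Z).
#' @param model_rdm Model [rdm()] over the same stimuli.
#' @param radius_vox Sphere radius in voxels (>= 1; Euclidean, center included).
#' @param metric RDM metric for the local brain RDMs.
#' @param comparator As in [compare_rdms()].
#' @return 3-D numeric array of scores (X x Y x Z).
#' @export
searchlight_rsa <- function(volume, mask, model_rdm, radius_vox = 2,
                            metric = "pearson", comparator = "pearson") {
  abort_if(length(dim(volume)) != 4, "volume must be stimuli x X x Y x Z",
           "shape_error")
  abort_if(!identical(dim(volume)[-1], dim(mask)),
           "mask shape must match the volume's spatial dims", "shape_error")
  abort_if(radius_vox < 1, "radius_vox must be >= 1", "validation_error")
  dims <- dim(mask)
  n_stim <- dim(volume)[1]
  abort_if(n_stim != length(model_rdm$condition_ids),
           "volume stimulus count does not match the model RDM",
           "alignment_error")
  flat <- matrix(volume, nrow = n_stim)  # stimuli x voxels, column-major voxels
  off <- sphere_offsets(radius_vox)
  scores <- array(NA_real_, dim = dims)
  centers <- which(mask, arr.ind = TRUE)
  n_skipped <- 0
  for (ci in seq_len(nrow(centers))) {
    cx <- centers[ci, 1]; cy <- centers[ci, 2]; cz <- centers[ci, 3]
    vx <- cx + off$dx; vy <- cy + off$dy; vz <- cz + off$dz
    ok <- vx >= 1 & vx <= dims[1] & vy >= 1 & vy <= dims[2] &
      vz >= 1 & vz <= dims[3]
    lin <- vx[ok] + (vy[ok] - 1) * dims[1] + (vz[ok] - 1) * dims[1] * dims[2]
    lin <- lin[mask[lin]]
    if (length(lin) < 2) { n_skipped <- n_skipped + 1; next }
    local <- flat[, lin, drop = FALSE]
    sc <- tryCatch({
      b <- compute_rdm(local, metric, condition_ids = model_rdm$condition_ids,
                       source = "searchlight")
      compare_rdms(model_rdm, b, comparator)
    }, brainalign_error = function(e) NA_real_)
    scores[cx, cy, cz] <- sc
  }
  if (n_skipped > 0)
    warning(sprintf("%d searchlight center(s) had < 2 usable voxels; scored NA",
                    n_skipped))
  scores
}

#' Read a volume or mask from NIfTI
#' @param path NIfTI file path.
#' @return Numeric array.
#' @export
read_nifti_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}

#' Write a searchlight score map to NIfTI
#' @param scores 3-D numeric array.
#' @param path Output `.nii`/`.nii.gz` path.
#' @export
write_nifti_map <- function(scores, path) {
  RNifti::writeNifti(RNifti::asNifti(scores), path)
  invisible(path)
}
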
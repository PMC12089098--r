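# Cross-validated (or in-sample) R^2 of an OLS fit of Y on the concatenation
# of the given feature matrices, averaged over channels and folds. The
# baseline for test sums of squares is the training mean, so CV R^2 can be
# negative (and must be allowed to be: truncation would break the
# inclusion-exclusion sum identity).
subset_r2 <- function(Xs, Y, folds, cv = TRUE) {
  X <- do.call(cbind, Xs)
  r2_on <- function(train, test) {
    fit <- fit_linear_map(X[train, , drop = FALSE], Y[train, , drop = FALSE])
    pred <- fit$predict(X[test, , drop = FALSE])
    mu <- colMeans(Y[train, , drop = FALSE])
    ss_res <- colSums((Y[test, , drop = FALSE] - pred)^2)
    ss_tot <- colSums(sweep(Y[test, , drop = FALSE], 2, mu)^2)
    mean(1 - ss_res / ss_tot)
  }
  if (!cv) {
    all <- seq_len(nrow(Y))
    return(r2_on(all, all))
  }
  mean(vapply(folds, function(f) r2_on(f$train, f$test), 0))
}

# All non-empty subsets of 1..k as index vectors, ordered by size then lexicon.
nonempty_subsets <- function(k) {
  subs <- unlist(lapply(seq_len(k), function(m)
    utils::combn(k, m, simplify = FALSE)), recursive = FALSE)
  subs
}

subset_label <- function(names, idx) paste(names[idx], collapse = "&")

#' Variance partitioning across 2-4 feature spaces
#'
#' Fits every non-empty subset of the predictor spaces (concatenated designs,
#' OLS, no PCA) with shared cross-validation folds, records each subset's
#' cross-validated R^2, and decomposes the full-model R^2 into the `2^k - 1`
#' unique and shared commonality components by Moebius inversion over the
#' subset lattice: the component common to exactly the spaces in `T` is
#' `C(T) = sum over S subset of T of (-1)^(|S|+1) R^2(S union complement(T))`.
#' Components always sum to the full-model R^2; individual components (and CV
#' R^2 values) may be negative.
#'
#' @param spaces Named list of 2-4 [feature_archive()]s (or matrices with id
#'   rownames).
#' @param brain A [brain_responses()] (or matrix).
#' @param spec An [encoding_spec()] supplying folds and seed.
#' @param cv Use cross-validated R^2 (default). `cv = FALSE` computes
#'   in-sample R^2 (mainly a hook for exact checks against direct
#'   least-squares).
#' @return A `variance_partition`: list with `predictor_names`, `subset_r2`
#'   (named by subset label, e.g. `"A&B"`), and `partitions` (named
#'   `"unique:A"`, `"shared:A&B"`, ...).
#' @export
variance_partition <- function(spaces, brain, spec = encoding_spec(), cv = TRUE) {
  k <- length(spaces)
  abort_if(k < 2 || k > 4, "variance partitioning supports 2 to 4 spaces",
           "validation_error")
  names(spaces) <- names(spaces) %||% vapply(spaces, function(f)
    if (inherits(f, "feature_archive")) f$layer else "space", "")
  als <- lapply(spaces, align_features_brain, brain = brain)
  ids <- als[[1]]$ids
  for (a in als) abort_if(!identical(a$ids, ids),
                          "feature spaces disagree on stimulus ids",
                          "alignment_error")
  Xs <- lapply(als, `[[`, "X")
  Y <- als[[1]]$Y
  folds <- lapply(seq_len(spec$n_folds), function(f)
    fold_split(length(ids), spec$test_fraction, f, spec$seed))
  subs <- nonempty_subsets(k)
  nm <- names(spaces)
  r2 <- stats::setNames(
    vapply(subs, function(s) subset_r2(Xs[s], Y, folds, cv), 0),
    vapply(subs, function(s) subset_label(nm, s), ""))
  lookup <- function(idx) if (length(idx) == 0) 0 else r2[[subset_label(nm, sort(idx))]]
  partitions <- stats::setNames(vapply(subs, function(T) {
    comp <- setdiff(seq_len(k), T)
    total <- 0
    for (S in c(list(integer(0)), nonempty_subsets(length(T)))) {
      Sidx <- T[S]
      total <- total + (-1)^(length(Sidx) + 1) * lookup(union(Sidx, comp))
    }
    total
  }, 0), vapply(subs, function(T)
    if (length(T) == 1) paste0("unique:", nm[T])
    else paste0("shared:", subset_label(nm, T)), ""))
  structure(list(predictor_names = nm, subset_r2 = r2, partitions = partitions),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("<variance_partition over %s: full R^2 = %.4f>\n",
              paste(x$predictor_names, collapse = ", "),
              x$subset_r2[[length(x$subset_r2)]]))
  print(round(x$partitions, 4))
  invisible(x)
}

#' Structured (nested) variance partitioning along a declared hierarchy
#'
#' For a user-declared ordered chain of feature spaces, computes the forward
#' increments `R^2(first i) - R^2(first i-1)` (what each level adds on top of
#' everything before it; they telescope to the full-model R^2) and the
#' backward decrements `R^2(all) - R^2(all minus level i)` (what each level
#' uniquely contributes given everything else). Both use the same shared
#' cross-validation folds as [variance_partition()].
#'
#' @param chain Ordered named list of >= 2 [feature_archive()]s (or matrices).
#' @param brain A [brain_responses()] (or matrix).
#' @param spec An [encoding_spec()].
#' @param cv As in [variance_partition()].
#' @return A `structured_vp`: list with `hierarchy`, `forward_increments`,
#'   `backward_decrements`, `full_r2`.
#' @export
structured_variance_partition <- function(chain, brain, spec = encoding_spec(),
                                          cv = TRUE) {
  k <- length(chain)
  abort_if(k < 2, "a hierarchy needs >= 2 levels", "validation_error")
  names(chain) <- names(chain) %||% vapply(chain, function(f)
    if (inherits(f, "feature_archive")) f$layer else "space", "")
  als <- lapply(chain, align_features_brain, brain = brain)
  ids <- als[[1]]$ids
  for (a in als) abort_if(!identical(a$ids, ids),
                          "feature spaces disagree on stimulus ids",
                          "alignment_error")
  Xs <- lapply(als, `[[`, "X")
  Y <- als[[1]]$Y
  folds <- lapply(seq_len(spec$n_folds), function(f)
    fold_split(length(ids), spec$test_fraction, f, spec$seed))
  prefix_r2 <- vapply(seq_len(k), function(i)
    subset_r2(Xs[seq_len(i)], Y, folds, cv), 0)
  full <- prefix_r2[k]
  forward <- diff(c(0, prefix_r2))
  backward <- vapply(seq_len(k), function(i)
    full - subset_r2(Xs[-i], Y, folds, cv), 0)
  structure(list(hierarchy = names(chain),
                 forward_increments = stats::setNames(forward, names(chain)),
                 backward_decrements = stats::setNames(backward, names(chain)),
                 full_r2 = full),
            class = "structured_vp")
}

#' @export
print.structured_vp <- function(x, ...) {
  cat(sprintf("<structured_vp: %s; full R^2 = %.4f>\n",
              paste(x$hierarchy, collapse = " -> "), x$full_r2))
  invisible(x)
}
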
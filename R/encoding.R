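#' Encoding-analysis specification
#'
#' Defaults reproduce the standard voxelwise-encoding protocol used throughout
#' the package: three cross-validation folds, each an independent seeded 80/20
#' train/test split (repeated random splits, so every fold trains on 80% of
#' stimuli), features reduced to 100 principal components fitted on the
#' training split only, ordinary least squares regression.
#'
#' @param n_folds Number of folds (>= 2 for significance; default 3).
#' @param test_fraction Held-out fraction per fold, in (0, 1) (default 0.2).
#' @param pca_components Principal components retained before regression
#'   (default 100; clamped to `min(n_train - 1, n_features)`); `NULL` disables
#'   PCA.
#' @param regression `"ols"` or `"ridge"` (per-fold alpha chosen by
#'   generalized cross-validation over `ridge_alphas`).
#' @param ridge_alphas Positive alpha grid for ridge GCV.
#' @param seed Seed driving all splits.
#' @return An `encoding_spec` list.
#' @export
encoding_spec <- function(n_folds = 3, test_fraction = 0.2, pca_components = 100,
                          regression = c("ols", "ridge"),
                          ridge_alphas = c(0.01, 0.1, 1, 10, 100, 1000),
                          seed = 1) {
  regression <- match.arg(regression)
  abort_if(n_folds < 2, "n_folds must be >= 2", "validation_error")
  abort_if(test_fraction <= 0 || test_fraction >= 1,
           "test_fraction must lie in (0, 1)", "validation_error")
  abort_if(any(ridge_alphas <= 0), "ridge alphas must be positive",
           "validation_error")
  structure(list(n_folds = as.integer(n_folds), test_fraction = test_fraction,
                 pca_components = if (is.null(pca_components)) NULL
                                  else as.integer(pca_components),
                 regression = regression, ridge_alphas = as.numeric(ridge_alphas),
                 seed = as.integer(seed)),
            class = "encoding_spec")
}

# Align a feature archive (or matrix) and brain responses on stimulus ids.
align_features_brain <- function(features, brain) {
  X <- if (inherits(features, "feature_archive")) features$data else features
  Y <- if (inherits(brain, "brain_responses")) brain$data else brain
  abort_if(length(dim(Y)) != 2, "brain responses must be stimuli x channels here",
           "shape_error")
  abort_if(is.null(rownames(X)) || is.null(rownames(Y)),
           "features and responses must carry stimulus-id rownames",
           "alignment_error")
  abort_if(!setequal(rownames(X), rownames(Y)),
           sprintf("feature/brain stimulus sets differ (e.g. %s)",
                   paste(head(c(setdiff(rownames(X), rownames(Y)),
                                setdiff(rownames(Y), rownames(X))), 3),
                         collapse = ", ")),
           "alignment_error")
  ord <- sort(rownames(X))
  list(X = X[ord, , drop = FALSE], Y = Y[ord, , drop = FALSE], ids = ord)
}

# Seeded train/test index split for fold k.
fold_split <- function(n, test_fraction, k, seed) {
  n_test <- max(1L, round(test_fraction * n))
  test <- with_seed(stage_seed(seed, sprintf("encoding_fold%d", k)),
                    sort(sample.int(n, n_test)))
  list(train = setdiff(seq_len(n), test), test = test)
}

# Fit a linear map X -> Y by SVD: OLS uses the pseudo-inverse (rank-deficient
# safe); ridge picks alpha from the grid by generalized cross-validation.
# Returns a predictor closure and the chosen alpha (0 for OLS).
fit_linear_map <- function(X, Y, regression = "ols", ridge_alphas = NULL) {
  mu_x <- colMeans(X); mu_y <- colMeans(Y)
  Xc <- sweep(X, 2, mu_x); Yc <- sweep(Y, 2, mu_y)
  sv <- svd(Xc)
  pos <- sv$d > sv$d[1] * 1e-10
  UtY <- crossprod(sv$u, Yc)
  if (regression == "ols") {
    alpha <- 0
    shrink <- ifelse(pos, 1 / sv$d, 0)
  } else {
    n <- nrow(X)
    gcv <- vapply(ridge_alphas, function(a) {
      f <- sv$d^2 / (sv$d^2 + a)
      df <- sum(f)
      res <- Yc - sv$u %*% (f * UtY)
      sum(res^2) / (n * (1 - df / n)^2)
    }, 0)
    alpha <- ridge_alphas[which.min(gcv)]
    shrink <- sv$d / (sv$d^2 + alpha)
  }
  beta <- sv$v %*% (shrink * UtY)
  list(alpha = alpha,
       predict = function(Xnew)
         sweep(sweep(Xnew, 2, mu_x) %*% beta, 2, mu_y, "+"))
}

# Two-sided one-sample t test across fold means that degrades gracefully when
# the folds are (numerically) identical: p = 0 for a nonzero common value,
# p = 1 for zero, never NaN or an error.
fold_ttest <- function(x) {
  degenerate <- sd(x) <= sqrt(.Machine$double.eps) * max(abs(mean(x)), 1e-12)
  if (degenerate) return(list(p.value = if (abs(mean(x)) < 1e-12) 1 else 0))
  t.test(x, mu = 0)
}

# Per-channel Pearson r between prediction and truth; constant channels on
# either side give NaN (excluded from aggregate means by callers).
per_channel_r <- function(pred, actual) {
  vapply(seq_len(ncol(actual)), function(j) {
    if (sd(actual[, j]) == 0 || sd(pred[, j]) == 0) return(NaN)
    cor(pred[, j], actual[, j])
  }, 0)
}

# One encoding fold: PCA (train-fitted, clamped) then the linear map.
fit_fold_encoder <- function(X, Y, train, spec) {
  Xtr <- X[train, , drop = FALSE]
  if (!is.null(spec$pca_components)) {
    pr <- fit_pca_projector(Xtr, spec$pca_components)
    Xtr <- pr$project(Xtr)
    proj <- pr$project
  } else proj <- identity
  fit <- fit_linear_map(Xtr, Y[train, , drop = FALSE],
                        spec$regression, spec$ridge_alphas)
  list(predict = function(rows) fit$predict(proj(X[rows, , drop = FALSE])),
       alpha = fit$alpha)
}

#' Linear (or ridge) voxelwise encoding
#'
#' Per fold: a seeded random train/test split; PCA fitted on the training
#' stimuli only; one linear map from components to all channels (OLS
#' pseudo-inverse, or ridge with per-fold GCV alpha selection); prediction of
#' the held-out stimuli; per-channel Pearson r. The aggregate `mean_r` is the
#' mean over folds of the mean over (non-degenerate) channels; a one-sample
#' two-sided t test across fold means gives the p value.
#'
#' @param features A [feature_archive()] (or stimuli x features matrix with id
#'   rownames).
#' @param brain A [brain_responses()] (or matrix with id rownames).
#' @param spec An [encoding_spec()].
#' @param model,layer Optional labels for the result record.
#' @return An `encoding_result`: list with `per_fold_per_channel_r`
#'   (folds x channels), `fold_mean_r`, `mean_r`, `p_value`, `significant`,
#'   `chosen_alphas`, `n_degenerate_channels`, plus the labels.
#' @export
linear_encoding <- function(features, brain, spec = encoding_spec(),
                            model = "model",
                            layer = if (inherits(features, "feature_archive"))
                              features$layer else "layer") {
  al <- align_features_brain(features, brain)
  n <- nrow(al$X)
  abort_if(n < 10, "need at least 10 stimuli for encoding", "validation_error")
  folds <- lapply(seq_len(spec$n_folds), function(k)
    fold_split(n, spec$test_fraction, k, spec$seed))
  alphas <- numeric(spec$n_folds)
  rmat <- matrix(NA_real_, spec$n_folds, ncol(al$Y))
  for (k in seq_len(spec$n_folds)) {
    enc <- fit_fold_encoder(al$X, al$Y, folds[[k]]$train, spec)
    alphas[k] <- enc$alpha
    pred <- enc$predict(folds[[k]]$test)
    rmat[k, ] <- per_channel_r(pred, al$Y[folds[[k]]$test, , drop = FALSE])
  }
  n_degen <- sum(is.nan(rmat))
  if (n_degen > 0)
    message(sprintf("%d constant fold/channel correlation(s) recorded as NaN and excluded",
                    n_degen))
  fold_mean_r <- rowMeans(rmat, na.rm = TRUE)
  tt <- fold_ttest(fold_mean_r)
  roi <- if (inherits(brain, "brain_responses"))
    sprintf("%s/%s", brain$subject, brain$roi) else "roi"
  structure(list(model = model, layer = layer, roi = roi,
                 per_fold_per_channel_r = rmat, fold_mean_r = fold_mean_r,
                 mean_r = mean(fold_mean_r), p_value = tt$p.value,
                 significant = tt$p.value < 0.05, chosen_alphas = alphas,
                 n_degenerate_channels = n_degen),
            class = "encoding_result")
}

#' @export
print.encoding_result <- function(x, ...) {
  cat(sprintf("<encoding_result: %s/%s vs %s, mean r = %.3f (p = %.3g)>\n",
              x$model, x$layer, x$roi, x$mean_r, x$p_value))
  invisible(x)
}

# Euclidean projection of a vector onto the probability simplex.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  pmax(v - (css[rho] - 1) / rho, 0)
}

# Simplex-constrained least squares min ||P w - y||^2, w >= 0, sum(w) = 1, by
# projected gradient with fixed step 1/L, initialized at the best vertex so
# the solution never does worse than the best single predictor.
simplex_weights <- function(P, y, max_iter = 500, tol = 1e-12) {
  k <- ncol(P)
  obj <- function(w) sum((P %*% w - y)^2)
  vertex_obj <- vapply(seq_len(k), function(j) sum((P[, j] - y)^2), 0)
  w <- rep(0, k); w[which.min(vertex_obj)] <- 1
  G <- crossprod(P)
  L <- 2 * max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  Pty <- crossprod(P, y)
  f <- obj(w)
  for (it in seq_len(max_iter)) {
    grad <- 2 * (G %*% w - Pty)
    w_new <- project_simplex(as.numeric(w - grad / L))
    f_new <- obj(w_new)
    if (f - f_new < tol * max(1, f)) { w <- w_new; f <- f_new; break }
    w <- w_new; f <- f_new
  }
  list(w = w, objective = f, best_single_objective = min(vertex_obj))
}

#' Stacked encoding over multiple feature spaces
#'
#' Combines >= 2 feature spaces into one prediction per channel. Per outer
#' fold: the training stimuli are further split (seeded 80/20); one base
#' encoder per feature space is fitted on the inner-training part; each base
#' model's held-out inner predictions are stacked and per-channel combination
#' weights on the probability simplex (nonnegative, summing to 1) are fitted
#' by projected gradient to minimize squared error; base encoders are then
#' refitted on the full outer training split and their weighted combination is
#' scored on the outer test split.
#'
#' @param feature_spaces Named list of >= 2 [feature_archive()]s (or matrices).
#' @param brain A [brain_responses()] (or matrix).
#' @param spec An [encoding_spec()].
#' @param model Label for the result record.
#' @return List with `result` (an `encoding_result` for the stacked
#'   prediction), `stack_weights` (spaces x channels, averaged over folds),
#'   `per_fold_weights` (folds x spaces x channels array), and
#'   `training_objectives` (per fold/channel: combined vs best single, from
#'   the inner fit).
#' @export
stacked_encoding <- function(feature_spaces, brain, spec = encoding_spec(),
                             model = "stacked") {
  abort_if(length(feature_spaces) < 2, "stacked encoding needs >= 2 feature spaces",
           "validation_error")
  names(feature_spaces) <- names(feature_spaces) %||%
    vapply(feature_spaces, function(f)
      if (inherits(f, "feature_archive")) f$layer else "space", "")
  als <- lapply(feature_spaces, align_features_brain, brain = brain)
  ids <- als[[1]]$ids
  for (a in als) abort_if(!identical(a$ids, ids),
                          "feature spaces disagree on stimulus ids",
                          "alignment_error")
  Y <- als[[1]]$Y
  n <- length(ids); k <- length(als); nc <- ncol(Y)
  folds <- lapply(seq_len(spec$n_folds), function(f)
    fold_split(n, spec$test_fraction, f, spec$seed))
  rmat <- matrix(NA_real_, spec$n_folds, nc)
  wts <- array(NA_real_, c(spec$n_folds, k, nc),
               dimnames = list(NULL, names(feature_spaces), NULL))
  obj_comb <- obj_best <- matrix(NA_real_, spec$n_folds, nc)
  for (f in seq_len(spec$n_folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    inner <- fold_split(length(tr), spec$test_fraction, f + 1000L, spec$seed)
    itr <- tr[inner$train]; ival <- tr[inner$test]
    inner_preds <- lapply(als, function(a)
      fit_fold_encoder(a$X, Y, itr, spec)$predict(ival))
    outer_preds <- lapply(als, function(a)
      fit_fold_encoder(a$X, Y, tr, spec)$predict(te))
    for (ch in seq_len(nc)) {
      P <- vapply(inner_preds, function(p) p[, ch], numeric(length(ival)))
      sw <- simplex_weights(P, Y[ival, ch])
      wts[f, , ch] <- sw$w
      obj_comb[f, ch] <- sw$objective
      obj_best[f, ch] <- sw$best_single_objective
      comb <- Reduce(`+`, Map(function(p, w) w * p[, ch], outer_preds,
                              as.list(sw$w)))
      rmat[f, ch] <- if (sd(Y[te, ch]) == 0 || sd(comb) == 0) NaN
                     else cor(comb, Y[te, ch])
    }
  }
  fold_mean_r <- rowMeans(rmat, na.rm = TRUE)
  tt <- fold_ttest(fold_mean_r)
  roi <- if (inherits(brain, "brain_responses"))
    sprintf("%s/%s", brain$subject, brain$roi) else "roi"
  result <- structure(
    list(model = model, layer = paste(names(feature_spaces), collapse = "+"),
         roi = roi, per_fold_per_channel_r = rmat, fold_mean_r = fold_mean_r,
         mean_r = mean(fold_mean_r), p_value = tt$p.value,
         significant = tt$p.value < 0.05,
         chosen_alphas = rep(NA_real_, spec$n_folds),
         n_degenerate_channels = sum(is.nan(rmat))),
    class = "encoding_result")
  list(result = result,
       stack_weights = apply(wts, c(2, 3), mean),
       per_fold_weights = wts,
       training_objectives = list(combined = obj_comb, best_single = obj_best))
}

#' veRSA: voxelwise-encoding RSA
#'
#' Per fold: fit the encoding model on the training stimuli, predict the
#' held-out stimuli's channel patterns, build one RDM from the predicted and
#' one from the measured test patterns, and correlate them. The returned score
#' is the mean over folds.
#'
#' @inheritParams linear_encoding
#' @param metric RDM metric for predicted/measured patterns.
#' @param comparator RDM-to-RDM comparator.
#' @return List with `score` (mean over folds) and `fold_scores`.
#' @export
versa <- function(features, brain, spec = encoding_spec(), metric = "pearson",
                  comparator = "pearson") {
  al <- align_features_brain(features, brain)
  n <- nrow(al$X)
  abort_if(n < 10, "need at least 10 stimuli for veRSA", "validation_error")
  folds <- lapply(seq_len(spec$n_folds), function(k)
    fold_split(n, spec$test_fraction, k, spec$seed))
  fold_scores <- vapply(seq_len(spec$n_folds), function(k) {
    te <- folds[[k]]$test
    abort_if(length(te) < 3, "test fold has fewer than 3 stimuli",
             "fold_size_error")
    enc <- fit_fold_encoder(al$X, al$Y, folds[[k]]$train, spec)
    pred <- enc$predict(te)
    ids <- al$ids[te]
    rp <- compute_rdm(pred, metric, condition_ids = ids, source = "predicted")
    rm_ <- compute_rdm(al$Y[te, , drop = FALSE], metric, condition_ids = ids,
                       source = "measured")
    compare_rdms(rp, rm_, comparator)
  }, 0)
  list(score = mean(fold_scores), fold_scores = fold_scores)
}
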
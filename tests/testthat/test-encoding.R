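# Noiseless linear ground truth: y = X W exactly.
noiseless_problem <- function(n = 200, p = 20, q = 30, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(sprintf("s%03d", 1:n), NULL))
  W <- matrix(rnorm(p * q), p)
  Y <- X %*% W
  rownames(Y) <- rownames(X)
  list(X = X, Y = Y)
}

test_that("noiseless linear responses are recovered essentially perfectly", {
  pb <- noiseless_problem()
  res <- linear_encoding(pb$X, pb$Y, encoding_spec(seed = 2))
  expect_gte(res$mean_r, 0.99)
  expect_equal(dim(res$per_fold_per_channel_r), c(3, 30))
})

test_that("unrelated responses score near zero", {
  set.seed(9)
  pb <- noiseless_problem()
  Ynull <- matrix(rnorm(200 * 30), 200, dimnames = list(rownames(pb$X), NULL))
  res <- linear_encoding(pb$X, Ynull, encoding_spec(seed = 2))
  expect_lt(abs(res$mean_r), 0.1)
})

test_that("the protocol is three folds of seeded 80/20 splits with train-only PCA", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_stimuli = 100, seed = 4))
  res <- linear_encoding(ds$features$layer1, ds$responses[[1]],
                         encoding_spec(seed = 7))
  expect_equal(nrow(res$per_fold_per_channel_r), 3)
  expect_equal(ncol(res$per_fold_per_channel_r), 30)
  # same seed reproduces; different seed moves the folds
  res2 <- linear_encoding(ds$features$layer1, ds$responses[[1]],
                          encoding_spec(seed = 7))
  expect_identical(res$per_fold_per_channel_r, res2$per_fold_per_channel_r)
  res3 <- linear_encoding(ds$features$layer1, ds$responses[[1]],
                          encoding_spec(seed = 8))
  expect_false(identical(res$per_fold_per_channel_r,
                         res3$per_fold_per_channel_r))
})

test_that("misaligned inputs raise an alignment error", {
  pb <- noiseless_problem(n = 30)
  Ybad <- pb$Y
  rownames(Ybad)[1] <- "other"
  expect_error(linear_encoding(pb$X, Ybad), class = "alignment_error")
})

test_that("ridge at vanishing alpha matches OLS on a full-rank design", {
  pb <- noiseless_problem(n = 120, p = 15, q = 8, seed = 3)
  noisy <- pb$Y + matrix(rnorm(120 * 8), 120)
  rownames(noisy) <- rownames(pb$X)
  ols <- linear_encoding(pb$X, noisy, encoding_spec(seed = 5))
  ridge <- linear_encoding(pb$X, noisy,
                           encoding_spec(regression = "ridge",
                                         ridge_alphas = 1e-8, seed = 5))
  expect_lt(abs(ols$mean_r - ridge$mean_r), 1e-6)
})

test_that("ridge selects stronger shrinkage per fold from the grid when needed", {
  set.seed(6)
  # weak-signal noisy problem: GCV should not pick the smallest alpha
  X <- matrix(rnorm(200 * 30), 200,
              dimnames = list(sprintf("s%03d", 1:200), NULL))
  Y <- X[, 1:3] %*% matrix(rnorm(9), 3) + 5 * matrix(rnorm(200 * 3), 200)
  rownames(Y) <- rownames(X)
  res <- linear_encoding(X, Y, encoding_spec(regression = "ridge",
                                             pca_components = NULL, seed = 1))
  expect_true(all(res$chosen_alphas %in% encoding_spec()$ridge_alphas))
  expect_true(any(res$chosen_alphas > 0.01))
})

test_that("encoding accuracy decreases monotonically with response noise", {
  rs <- vapply(c(0, 1, 4), function(sdv) {
    ds <- generate_synthetic_dataset(
      synthetic_spec(layer_signal_fractions = 1, subject_noise_sd = sdv,
                     seed = 11))
    mean(vapply(1:3, function(s)
      linear_encoding(ds$features$layer1, ds$responses[[s]],
                      encoding_spec(seed = 13))$mean_r, 0))
  }, 0)
  expect_true(all(diff(rs) < 0))
})

test_that("stacked encoding puts its weight on the informative space", {
  ds <- generate_synthetic_dataset(
    synthetic_spec(layer_signal_fractions = c(1, 0), subject_noise_sd = 0,
                   seed = 15))
  st <- stacked_encoding(list(informative = ds$features$layer1,
                              noise = ds$features$layer2),
                         ds$responses[[1]], encoding_spec(seed = 3))
  w <- st$per_fold_weights
  sums <- apply(w, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-8))
  expect_true(all(w >= -1e-12))
  expect_gte(mean(st$stack_weights["informative", ]), 0.9)
  expect_true(all(st$training_objectives$combined <=
                    st$training_objectives$best_single + 1e-9))
  expect_error(stacked_encoding(list(ds$features$layer1), ds$responses[[1]]),
               class = "validation_error")
})

test_that("veRSA scores a perfect encoder near 1 and a shuffled one near 0", {
  ds <- generate_synthetic_dataset(
    synthetic_spec(layer_signal_fractions = 1, subject_noise_sd = 0, seed = 17))
  v <- versa(ds$features$layer1, ds$responses[[1]], encoding_spec(seed = 19))
  expect_gte(v$score, 0.99)

  set.seed(20)
  X <- ds$features$layer1$data
  Yshuf <- ds$responses[[1]]$data[sample(nrow(X)), ]
  rownames(Yshuf) <- rownames(X)  # break the stimulus correspondence
  v0 <- versa(X, Yshuf, encoding_spec(seed = 19))
  expect_lt(abs(v0$score), 0.15)
})

test_that("veRSA is invariant to channel permutation", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_stimuli = 80, seed = 21))
  b <- ds$responses[[1]]
  v1 <- versa(ds$features$layer1, b, encoding_spec(seed = 23))
  perm <- sample(ncol(b$data))
  b2 <- brain_responses(b$subject, b$roi, b$data[, perm], b$stimulus_ids)
  v2 <- versa(ds$features$layer1, b2, encoding_spec(seed = 23))
  expect_equal(v1$score, v2$score, tolerance = 1e-10)
})
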
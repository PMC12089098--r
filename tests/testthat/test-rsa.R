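test_that("RDM self-comparison scores exactly 1 and inversion scores -1", {
  a <- random_rdm(8, seed = 1)
  expect_identical(compare_rdms(a, a), 1)
  flipped <- max(a$matrix) - a$matrix
  diag(flipped) <- 0
  b <- rdm(flipped, a$condition_ids, a$metric, "flipped")
  expect_equal(compare_rdms(a, b), -1)
})

test_that("compare_rdms equals the brute-force upper-triangle correlation", {
  for (seed in 1:5) {
    a <- random_rdm(8, seed = seed)
    b <- random_rdm(8, seed = seed + 100)
    expect_lt(abs(compare_rdms(a, b) - oracle_upper_tri_cor(a$matrix, b$matrix)),
              1e-12)
  }
})

test_that("mismatched or constant RDMs are rejected", {
  a <- random_rdm(8, seed = 1)
  b <- random_rdm(8, seed = 2, ids = sprintf("x%02d", 1:8))
  expect_error(compare_rdms(a, b), class = "alignment_error")
  const <- rdm(matrix(1, 4, 4) - diag(4), letters[1:4], "euclidean")
  expect_error(compare_rdms(const, random_rdm(4, 3, ids = letters[1:4])),
               class = "degenerate_error")
})

test_that("averaging modes combine subject correlations as documented", {
  m <- random_rdm(10, seed = 5, source = "model")
  # brain RDMs built so that r_s is known: use the model RDM itself and its flip
  flip_mat <- max(m$matrix) - m$matrix
  diag(flip_mat) <- 0
  flip <- rdm(flip_mat, m$condition_ids, m$metric, "flip")
  same <- evaluate_rsa(list(m), list(m, m), mode = "direct")
  expect_equal(same$score, 1)
  mixed <- evaluate_rsa(list(m), list(m, flip), mode = "squared")
  expect_equal(mixed$per_subject_r[[1]], c(1, -1))
  expect_equal(mixed$score, 0)  # sign-preserving squares cancel
  direct <- evaluate_rsa(list(m), list(m, flip), mode = "direct")
  expect_equal(direct$score, 0)
})

test_that("informative layers outrank noise layers in RSA", {
  wins <- 0L
  for (seed in 1:25) {
    ds <- generate_synthetic_dataset(
      synthetic_spec(n_stimuli = 80, layer_signal_fractions = c(1, 0),
                     n_features = 30, n_channels = 15, seed = seed))
    mr <- lapply(ds$features, function(f)
      compute_rdm(f$data, "pearson", source = f$layer))
    br <- lapply(ds$responses, function(b)
      compute_rdm(b$data, "pearson", source = b$subject))
    ev <- evaluate_rsa(mr, br)
    wins <- wins + (ev$score[ev$model == "layer1"] >
                      ev$score[ev$model == "layer2"])
  }
  expect_gte(wins, 24)
})

test_that("noise ceilings bound subject consistency", {
  m <- random_rdm(12, seed = 7)
  identical_subjects <- noise_ceiling(list(m, m, m))
  expect_equal(identical_subjects$lower, 1)
  expect_equal(identical_subjects$upper, 1)

  for (seed in 1:20) {
    rdms <- lapply(seq_len(4), function(s) random_rdm(10, seed * 10 + s))
    nc <- noise_ceiling(rdms)
    expect_lte(nc$lower, nc$upper + 1e-10)
  }
  expect_error(noise_ceiling(list(m)), class = "validation_error")
})

test_that("unrelated subjects give a lower ceiling near zero and an upper near 1/sqrt(n)", {
  lowers <- uppers <- numeric(10)
  for (seed in 1:10) {
    rdms <- lapply(seq_len(10), function(s) random_rdm(20, seed * 31 + s))
    nc <- noise_ceiling(rdms)
    lowers[seed] <- nc$lower; uppers[seed] <- nc$upper
  }
  expect_lt(abs(mean(lowers)), 0.15)
  # including the subject in the mean of 10 leaves ~1/sqrt(10) self-correlation
  expect_lt(abs(mean(uppers) - 1 / sqrt(10)), 0.15)
})

test_that("group significance behaves at its boundary cases", {
  perm <- group_significance(c(0, 0, 0), method = "permutation", seed = 2)
  expect_equal(perm$p_value, 1)

  tt <- group_significance(c(0.9, 0.91, 0.89), method = "ttest")
  expect_lt(tt$p_value, 0.001)

  degen <- group_significance(c(0.5, 0.5, 0.5), method = "ttest")
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 0)
  expect_false(is.nan(degen$p_value))
})

test_that("BH correction across a batch is monotone in raw-p rank", {
  set.seed(12)
  batch <- lapply(1:10, function(i) rnorm(5, mean = i / 20, sd = 0.2))
  raw <- group_significance(batch, method = "ttest", correction = "none")
  adj <- group_significance(batch, method = "ttest", correction = "fdr_bh")
  ord <- order(raw$p_value)
  expect_true(all(diff(adj$p_value[ord]) >= -1e-12))
  expect_true(all(adj$p_value >= raw$p_value - 1e-12))
})

test_that("permutation p is invariant to sign-preserving scaling", {
  set.seed(3)
  r <- rnorm(8, 0.2, 0.3)
  p1 <- group_significance(r, method = "permutation", seed = 5)$p_value
  p2 <- group_significance(10 * r, method = "permutation", seed = 5)$p_value
  expect_lt(abs(p1 - p2), 0.01)
})

test_that("weighted RSA recovers an exact predictor and keeps weights nonnegative", {
  target <- random_rdm(14, seed = 20, source = "target")
  res <- weighted_rsa(list(target), target, folds = 4, seed = 1)
  expect_gte(res$cv_score, 0.99)

  noise <- random_rdm(14, seed = 99, ids = target$condition_ids, source = "noise")
  res2 <- weighted_rsa(list(target, noise), target, folds = 4, seed = 1)
  expect_true(all(res2$weights >= 0))
  expect_lte(res2$weights["noise"], 0.05 * sum(res2$weights))
  expect_gte(res2$cv_score, 0.95)
})

test_that("searchlight localizes a planted representational signal", {
  set.seed(31)
  n_stim <- 20; dims <- c(12, 12, 12); ctr <- c(6, 6, 6)
  Z <- matrix(rnorm(n_stim * 5), n_stim)    # planted geometry inside the ball
  Z2 <- matrix(rnorm(n_stim * 5), n_stim)   # unrelated geometry elsewhere
  ids <- sprintf("s%02d", seq_len(n_stim))
  model_rdm <- compute_rdm(Z, "pearson", condition_ids = ids, source = "model")
  vol <- array(0, c(n_stim, dims))
  for (x in 1:12) for (y in 1:12) for (z in 1:12) {
    src <- if (sum((c(x, y, z) - ctr)^2) <= 9) Z else Z2
    vol[, x, y, z] <- src %*% rnorm(5) + 0.2 * rnorm(n_stim)
  }
  mask <- array(TRUE, dims)
  scores <- searchlight_rsa(vol, mask, model_rdm, radius_vox = 3)
  peak <- which(scores == max(scores, na.rm = TRUE), arr.ind = TRUE)
  expect_true(all(abs(peak[1, ] - ctr) <= 1))
})

test_that("a sphere covering the whole mask reproduces whole-ROI RSA everywhere", {
  set.seed(32)
  n_stim <- 12; dims <- c(3, 3, 2)
  vol <- array(rnorm(n_stim * prod(dims)), c(n_stim, dims))
  ids <- sprintf("s%02d", seq_len(n_stim))
  model_rdm <- compute_rdm(matrix(rnorm(n_stim * 6), n_stim), "pearson",
                           condition_ids = ids)
  mask <- array(TRUE, dims)
  scores <- searchlight_rsa(vol, mask, model_rdm, radius_vox = 10)
  whole <- compare_rdms(model_rdm,
                        compute_rdm(matrix(vol, n_stim), "pearson",
                                    condition_ids = ids))
  expect_equal(unname(as.numeric(scores)), rep(whole, prod(dims)))
})

test_that("searchlight null scores stay modest and empty masks give all-NaN", {
  set.seed(33)
  n_stim <- 20; dims <- c(8, 8, 8)
  vol <- array(rnorm(n_stim * prod(dims)), c(n_stim, dims))
  ids <- sprintf("s%02d", seq_len(n_stim))
  model_rdm <- compute_rdm(matrix(rnorm(n_stim * 6), n_stim), "pearson",
                           condition_ids = ids)
  mask <- array(TRUE, dims)
  scores <- searchlight_rsa(vol, mask, model_rdm, radius_vox = 2)
  expect_lt(quantile(abs(scores), 0.99, na.rm = TRUE), 0.5)

  none <- array(FALSE, dims)
  empty_map <- searchlight_rsa(vol, none, model_rdm, radius_vox = 2)
  expect_true(all(is.na(empty_map)))
})
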
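# Adapter whose payloads are comma-separated pixel strings; "pixels" returns
# them unchanged, "doubled" scales them.
parse_payload <- function(p) as.numeric(strsplit(p, ",", fixed = TRUE)[[1]])
toy_adapter <- model_adapter(
  list_layers = function() c("pixels", "doubled"),
  forward = function(p) {
    x <- parse_payload(p)
    list(pixels = x, doubled = 2 * x)
  },
  name = "toy")

two_pixel_stimuli <- stimulus_set(
  sprintf("img%d", 1:5),
  payloads = c("1,2", "3,4", "5,6", "7,8", "9,10"),
  modality = "text")

test_that("an identity adapter yields archives equal to the raw payload values", {
  archs <- extract_features(toy_adapter, two_pixel_stimuli, "pixels")
  expect_named(archs, "pixels")
  expect_identical(rownames(archs$pixels$data), two_pixel_stimuli$ids)
  expect_equal(unname(archs$pixels$data),
               matrix(as.numeric(1:10), 5, byrow = TRUE))
})

test_that("unknown layers and failing adapters produce named errors", {
  expect_error(extract_features(toy_adapter, two_pixel_stimuli, "blockX"),
               class = "layer_error")
  expect_error(extract_features(toy_adapter, two_pixel_stimuli, "blockX"),
               "pixels")
  broken <- model_adapter(function() "a",
                          function(p) stop("cannot read"))
  expect_error(extract_features(broken, two_pixel_stimuli, "a"),
               class = "extraction_error")
  expect_error(extract_features(broken, two_pixel_stimuli, "a"), "img1")
})

test_that("a seeded random linear adapter extracts identically on reruns", {
  set.seed(77)
  Wl <- matrix(rnorm(2 * 6), 2)
  lin <- model_adapter(function() "proj",
                       function(p) list(proj = parse_payload(p) %*% Wl))
  a <- extract_features(lin, two_pixel_stimuli, "proj")
  b <- extract_features(lin, two_pixel_stimuli, "proj")
  expect_identical(a, b)
})

test_that("row-major flattening round-trips arrays bit-exactly", {
  x <- array(rnorm(24), c(2, 3, 4))
  v <- flatten_activation(x)
  expect_identical(unflatten_activation(v, dim(x)), x)
  # row-major: last axis varies fastest
  expect_equal(v[1:4], x[1, 1, ])
  m <- matrix(1:6, 2, byrow = TRUE)
  expect_equal(flatten_activation(m), as.numeric(1:6))
})

test_that("PCA to the true rank preserves pairwise distances", {
  set.seed(5)
  basis <- matrix(rnorm(2 * 50), 2)
  X <- matrix(rnorm(100 * 2), 100) %*% basis  # rank-2 data in 50-d
  rownames(X) <- sprintf("s%03d", 1:100)
  arch <- feature_archive("L", X)
  red <- reduce_features(arch, reduction_spec("pca", n_components = 2))
  d_full <- dist(X); d_red <- dist(red$data)
  expect_lt(max(abs(d_full - d_red) / d_full), 1e-8)
  expect_equal(attr(red, "effective_components"), 2)
})

test_that("component counts are clamped and recorded", {
  X <- matrix(rnorm(30 * 20), 30, dimnames = list(sprintf("s%02d", 1:30), NULL))
  red <- reduce_features(feature_archive("L", X),
                         reduction_spec("pca", n_components = 100))
  expect_equal(attr(red, "effective_components"), 20)
  expect_equal(ncol(red$data), 20)
  red2 <- reduce_features(feature_archive("L", X[1:5, ]),
                          reduction_spec("pca", n_components = 100))
  expect_equal(attr(red2, "effective_components"), 4)  # n_fit - 1
})

test_that("sparse random projection is seed-deterministic", {
  X <- matrix(rnorm(40 * 30), 40, dimnames = list(sprintf("s%02d", 1:40), NULL))
  spec <- reduction_spec("srp", n_components = 10, seed = 3)
  a <- reduce_features(feature_archive("L", X), spec)
  b <- reduce_features(feature_archive("L", X), spec)
  expect_identical(a$data, b$data)
  spec2 <- reduction_spec("srp", n_components = 10, seed = 4)
  expect_false(identical(a$data,
                         reduce_features(feature_archive("L", X), spec2)$data))
})

test_that("PCA fitted on a subset ignores held-out rows (leakage guard)", {
  set.seed(11)
  X <- matrix(rnorm(60 * 15), 60,
              dimnames = list(sprintf("s%02d", 1:60), NULL))
  fit_ids <- rownames(X)[1:40]
  a <- reduce_features(feature_archive("L", X),
                       reduction_spec("pca", 5), fit_ids = fit_ids)
  Xperm <- X
  Xperm[41:60, ] <- X[sample(41:60), ]  # shuffle held-out rows only
  rownames(Xperm) <- rownames(X)
  b <- reduce_features(feature_archive("L", Xperm),
                       reduction_spec("pca", 5), fit_ids = fit_ids)
  expect_equal(a$data[1:40, ], b$data[1:40, ])
})

test_that("distance fidelity of PCA increases with retained components", {
  set.seed(21)
  X <- matrix(rnorm(60 * 50), 60,
              dimnames = list(sprintf("s%02d", 1:60), NULL))
  d_full <- as.numeric(dist(X))
  rho <- vapply(c(2, 8, 32), function(k) {
    red <- reduce_features(feature_archive("L", X), reduction_spec("pca", k))
    cor(d_full, as.numeric(dist(red$data)), method = "spearman")
  }, 0)
  expect_true(all(diff(rho) > 0))
})
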
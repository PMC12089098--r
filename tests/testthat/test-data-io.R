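test_that("feature archives round-trip bit-exactly, preserving key order", {
  arch <- feature_archive("conv1", list(img2 = c(1, 2), img1 = c(pi, exp(1))))
  path <- tempfile(fileext = ".rds")
  write_feature_archive(arch, path)
  back <- read_feature_archive(path)
  expect_identical(back$data, arch$data)
  expect_identical(rownames(back$data), c("img2", "img1"))
  expect_identical(back$layer, "conv1")
})

test_that("malformed archives are rejected", {
  expect_error(feature_archive("L", list(img1 = c(1, 2), img2 = 3)),
               class = "shape_error")
  trunc <- tempfile(fileext = ".rds")
  writeBin(as.raw(c(0x1f, 0x8b, 0x00)), trunc)
  suppressWarnings(expect_error(read_feature_archive(trunc),
                                class = "format_error"))
  expect_error(read_feature_archive(tempfile()), class = "format_error")
  not_arch <- tempfile(fileext = ".rds")
  saveRDS(list(1, 2), not_arch)
  expect_error(read_feature_archive(not_arch), class = "format_error")
})

test_that("the synthetic generator is deterministic and internally aligned", {
  spec <- synthetic_spec(n_stimuli = 50, n_subjects = 2, n_channels = 8,
                         n_features = 12, seed = 42)
  a <- generate_synthetic_dataset(spec)
  b <- generate_synthetic_dataset(spec)
  expect_identical(a, b)
  ids <- a$stimuli$ids
  for (f in a$features) expect_identical(rownames(f$data), ids)
  for (r in a$responses) expect_identical(r$stimulus_ids, ids)
  expect_equal(length(a$responses), 2)
  expect_equal(dim(a$features[[1]]$data), c(50, 12))
})

test_that("layer features have unit per-element variance for any signal fraction", {
  spec <- synthetic_spec(n_stimuli = 2000, n_latent = 20,
                         layer_signal_fractions = c(0, 0.3, 0.7, 1),
                         n_features = 40, n_subjects = 1, seed = 9)
  ds <- generate_synthetic_dataset(spec)
  for (f in ds$features) {
    v <- mean(apply(f$data, 2, var))
    expect_lt(abs(v - 1), 0.05)
  }
})

test_that("spec validation rejects out-of-range values", {
  expect_error(synthetic_spec(layer_signal_fractions = c(0.5, 1.2)),
               class = "validation_error")
  expect_error(synthetic_spec(subject_noise_sd = -1), class = "validation_error")
  expect_error(synthetic_spec(n_stimuli = 0), class = "validation_error")
  expect_error(synthetic_spec(n_latent = NaN), class = "validation_error")
})

make_layout <- function(n_stim = 10, subjects = c("sub1", "sub2"),
                        rois = c("V1", "FFA"), drop_id_from = NULL) {
  root <- tempfile("layout")
  dir.create(file.path(root, "stimuli"), recursive = TRUE)
  dir.create(file.path(root, "responses"))
  ids <- sprintf("img%02d", seq_len(n_stim))
  for (id in ids) writeLines(paste("caption", id),
                             file.path(root, "stimuli", paste0(id, ".txt")))
  for (s in subjects) for (r in rois) {
    keep <- if (!is.null(drop_id_from) && drop_id_from == paste(s, r)) ids[-1] else ids
    tab <- data.frame(stimulus_id = keep,
                      ch1 = seq_along(keep), ch2 = rev(seq_along(keep)))
    write.csv(tab, file.path(root, "responses", sprintf("%s_%s.csv", s, r)),
              row.names = FALSE)
  }
  root
}

test_that("dataset layouts load aligned to canonical stimulus order", {
  root <- make_layout()
  ds <- load_dataset_layout(root)
  expect_equal(length(ds$stimuli$ids), 10)
  expect_equal(length(ds$responses), 4)
  expect_setequal(vapply(ds$responses, `[[`, "", "roi"), c("V1", "FFA"))
  for (r in ds$responses) expect_identical(r$stimulus_ids, ds$stimuli$ids)
})

test_that("layout errors name the offending input", {
  root <- make_layout(drop_id_from = "sub1 V1")
  expect_error(load_dataset_layout(root), class = "alignment_error")
  expect_error(load_dataset_layout(root), "img01")

  empty <- tempfile("layout")
  dir.create(file.path(empty, "stimuli"), recursive = TRUE)
  dir.create(file.path(empty, "responses"))
  expect_error(load_dataset_layout(empty), class = "empty_dataset_error")
})

test_that("explicit z-scoring standardizes each channel", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_stimuli = 40, n_subjects = 1,
                                                  seed = 3))
  z <- zscore_channels(ds$responses[[1]])
  expect_equal(unname(colMeans(z$data)), rep(0, ncol(z$data)))
  expect_equal(unname(apply(z$data, 2, sd)), rep(1, ncol(z$data)))
})
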
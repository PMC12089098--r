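# Independent oracles used across tests. These deliberately use the slowest,
# most literal formulation of each quantity so they share no code with the
# implementation they check.

# Naive double-loop RDM.
oracle_rdm <- function(data, metric) {
  n <- nrow(data)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    D[i, j] <- switch(metric,
      pearson = 1 - cor(data[i, ], data[j, ]),
      cosine = 1 - sum(data[i, ] * data[j, ]) /
        (sqrt(sum(data[i, ]^2)) * sqrt(sum(data[j, ]^2))),
      euclidean = sqrt(sum((data[i, ] - data[j, ])^2)))
  }
  D
}

# Brute-force Pearson correlation over the strict upper triangles of two
# square matrices, accumulated pair by pair.
oracle_upper_tri_cor <- function(A, B) {
  n <- nrow(A)
  xs <- ys <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xs <- c(xs, A[i, j]); ys <- c(ys, B[i, j])
  }
  mx <- mean(xs); my <- mean(ys)
  sum((xs - mx) * (ys - my)) /
    sqrt(sum((xs - mx)^2) * sum((ys - my)^2))
}

# Random valid RDM over n conditions (from random Gaussian patterns).
random_rdm <- function(n, seed, ids = sprintf("c%02d", seq_len(n)),
                       source = "rand") {
  set.seed(seed)
  compute_rdm(matrix(rnorm(n * 15), n), "euclidean", condition_ids = ids,
              source = source)
}

# In-sample multiple-R^2 of Y on X by a direct least-squares solve (lm),
# averaged over channels.
oracle_insample_r2 <- function(X, Y) {
  mean(vapply(seq_len(ncol(Y)), function(j)
    summary(stats::lm(Y[, j] ~ X))$r.squared, 0))
}

# Straight-line evaluation of the linear CKA formula, term by term.
oracle_cka <- function(x, y) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  num <- 0
  for (i in seq_len(ncol(x))) for (j in seq_len(ncol(y)))
    num <- num + sum(xc[, i] * yc[, j])^2
  denx <- 0
  for (i in seq_len(ncol(x))) for (j in seq_len(ncol(x)))
    denx <- denx + sum(xc[, i] * xc[, j])^2
  deny <- 0
  for (i in seq_len(ncol(y))) for (j in seq_len(ncol(y)))
    deny <- deny + sum(yc[, i] * yc[, j])^2
  num / sqrt(denx * deny)
}

# Analytic JSD (base 2) between two normal densities by fine-grid quadrature.
oracle_gaussian_jsd <- function(mu1, mu2, sd1 = 1, sd2 = 1) {
  z <- seq(min(mu1, mu2) - 8, max(mu1, mu2) + 8, length.out = 200001)
  dz <- z[2] - z[1]
  p <- stats::dnorm(z, mu1, sd1); q <- stats::dnorm(z, mu2, sd2)
  m <- (p + q) / 2
  term <- function(u) {
    i <- u > 0
    sum(u[i] * log2(u[i] / m[i])) * dz
  }
  (term(p) + term(q)) / 2
}

# Tiny registry fixture used by several registry tests.
fixture_registry_records <- function() list(
  list(name = "AlexNet", framework_source = "tv", architecture_family = "CNN",
       modality = "vision", training_task = "classification",
       training_dataset = "ImageNet", training_method = "supervised",
       suggested_layers = list("features.2")),
  list(name = "ResNet-50", framework_source = "tv", architecture_family = "CNN",
       modality = "vision", training_task = "classification",
       training_dataset = "ImageNet", training_method = "supervised",
       suggested_layers = list("layer4")),
  list(name = "CLIP ViT-B/32", framework_source = "clip",
       architecture_family = "transformer", modality = "multimodal",
       training_task = "contrastive", training_dataset = "WIT",
       training_method = "self-supervised", suggested_layers = list()))

write_fixture_registry <- function(records, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(list(schema_version = "1", records = records), path,
                       auto_unbox = TRUE)
  path
}
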
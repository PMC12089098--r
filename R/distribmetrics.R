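#' Linear centered kernel alignment
#'
#' Similarity of two feature matrices over the same stimuli, invariant to
#' orthogonal rotation and isotropic scaling of either space: both matrices
#' are column-centered and the score is
#' `||X'Y||_F^2 / (||X'X||_F ||Y'Y||_F)`, in \[0, 1\].
#'
#' @param x,y Numeric matrices with the same number of rows (n >= 3).
#' @return CKA similarity in \[0, 1\].
#' @export
linear_cka <- function(x, y) {
  abort_if(!is.matrix(x) || !is.matrix(y) || nrow(x) != nrow(y),
           "x and y must be matrices over the same stimuli", "shape_error")
  abort_if(nrow(x) < 3, "need n >= 3 rows", "validation_error")
  assert_finite_matrix(x, "x"); assert_finite_matrix(y, "y")
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  abort_if(all(xc == 0) || all(yc == 0),
           "all-constant input: CKA undefined", "degenerate_error")
  num <- sum(crossprod(xc, yc)^2)
  den <- sqrt(sum(crossprod(xc)^2)) * sqrt(sum(crossprod(yc)^2))
  num / den
}

#' RBF-kernel centered kernel alignment
#'
#' Kernel variant of [linear_cka()] with a Gaussian kernel; the bandwidth
#' defaults to the median pairwise distance heuristic.
#'
#' @param x,y Numeric matrices with the same number of rows.
#' @param sigma_x,sigma_y Optional bandwidths; default: median pairwise
#'   Euclidean distance within each matrix.
#' @return CKA similarity in \[0, 1\].
#' @export
rbf_cka <- function(x, y, sigma_x = NULL, sigma_y = NULL) {
  gram <- function(m, sigma) {
    d <- as.matrix(dist(m))
    sigma <- sigma %||% stats::median(d[upper.tri(d)])
    abort_if(!is.finite(sigma) || sigma <= 0,
             "degenerate bandwidth: all points identical", "degenerate_error")
    exp(-d^2 / (2 * sigma^2))
  }
  center <- function(K) {
    n <- nrow(K)
    H <- diag(n) - 1 / n
    H %*% K %*% H
  }
  Kx <- center(gram(x, sigma_x)); Ky <- center(gram(y, sigma_y))
  sum(Kx * Ky) / (sqrt(sum(Kx * Kx)) * sqrt(sum(Ky * Ky)))
}

#' Jensen-Shannon divergence between two samples
#'
#' Histograms both samples on shared equal-width bins spanning the pooled
#' range and returns the base-2 Jensen-Shannon divergence of the two binned
#' distributions, in \[0, 1\] (0 for identical samples, 1 for disjoint
#' supports). Zero-count bins need no smoothing: terms with p = 0 contribute
#' nothing, and the mixture denominator is positive wherever p > 0.
#'
#' @param a,b Non-empty finite numeric samples (e.g. vectorized RDM entries of
#'   two systems).
#' @param n_bins Number of shared bins (default 100).
#' @return JSD in bits, in \[0, 1\].
#' @export
jensen_shannon <- function(a, b, n_bins = 100) {
  abort_if(length(a) == 0 || length(b) == 0, "empty sample", "validation_error")
  abort_if(any(!is.finite(a)) || any(!is.finite(b)), "samples must be finite",
           "validation_error")
  abort_if(n_bins < 2, "n_bins must be >= 2", "validation_error")
  lo <- min(a, b); hi <- max(a, b)
  if (lo == hi) return(0)  # all mass in one bin on both sides
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  binned <- function(x) {
    h <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(h, nbins = n_bins) / length(x)
  }
  p <- binned(a); q <- binned(b)
  m <- (p + q) / 2
  kl <- function(u, v) {
    i <- u > 0
    sum(u[i] * log2(u[i] / v[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' 1-D Wasserstein (earth mover's) distance between two samples
#'
#' The L1 distance between the two empirical quantile functions, computed
#' exactly from the sorted samples: integrates |F_a(z) - F_b(z)| over the
#' pooled support.
#'
#' @param a,b Non-empty finite numeric samples.
#' @return Nonnegative distance in the units of the samples.
#' @export
wasserstein1 <- function(a, b) {
  abort_if(length(a) == 0 || length(b) == 0, "empty sample", "validation_error")
  abort_if(any(!is.finite(a)) || any(!is.finite(b)), "samples must be finite",
           "validation_error")
  z <- sort(c(a, b))
  if (length(z) < 2) return(0)
  mids <- z[-length(z)]
  widths <- diff(z)
  fa <- findInterval(mids, sort(a)) / length(a)
  fb <- findInterval(mids, sort(b)) / length(b)
  sum(abs(fa - fb) * widths)
}

#' Distributional comparison of two representations
#'
#' Convenience front-end for comparing two systems' representations as
#' distributions. By default the compared samples are the vectorized RDM
#' entries of each system over the shared stimulus set (which makes the
#' comparison well-posed even when the two spaces have different
#' dimensionality); `mode = "activations"` compares the flattened raw values
#' instead.
#'
#' @param x,y Feature archives, [rdm()]s, or plain matrices.
#' @param kind `"cka"`, `"jsd"` or `"w1"`.
#' @param mode `"rdm"` (default) or `"activations"` for jsd/w1; ignored for
#'   cka, which always works on the raw matrices.
#' @param metric RDM metric used when `mode = "rdm"`.
#' @param n_bins Bins for JSD.
#' @return A single numeric score.
#' @export
compare_representations <- function(x, y, kind = c("cka", "jsd", "w1"),
                                    mode = c("rdm", "activations"),
                                    metric = "pearson", n_bins = 100) {
  kind <- match.arg(kind); mode <- match.arg(mode)
  as_mat <- function(o) if (inherits(o, "feature_archive")) o$data
                        else if (inherits(o, "brain_responses")) o$data else o
  if (kind == "cka") return(linear_cka(as_mat(x), as_mat(y)))
  sample_of <- function(o) {
    if (inherits(o, "rdm")) return(vectorize_rdm(o))
    m <- as_mat(o)
    if (mode == "rdm") vectorize_rdm(compute_rdm(m, metric)) else as.numeric(m)
  }
  if (kind == "jsd") jensen_shannon(sample_of(x), sample_of(y), n_bins)
  else wasserstein1(sample_of(x), sample_of(y))
}
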
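#' Representational dissimilarity matrices
#'
#' An RDM summarizes the representational geometry of a measurement space as a
#' symmetric conditions x conditions matrix of pairwise pattern
#' dissimilarities, with a zero diagonal. Because RDMs from different spaces
#' (a network layer, a subject's ROI) over the same stimulus set share a
#' format, they can be compared directly — the basis of RSA.
#'
#' @param matrix Symmetric numeric dissimilarity matrix, zero diagonal.
#' @param condition_ids Condition (stimulus) ids, in row order.
#' @param metric Name of the dissimilarity metric used.
#' @param source Provenance label (layer name or subject/ROI).
#' @return An `rdm` object.
#' @export
rdm <- function(matrix, condition_ids, metric, source = "") {
  n <- length(condition_ids)
  abort_if(!is.matrix(matrix) || nrow(matrix) != n || ncol(matrix) != n,
           "matrix must be square and match condition_ids", "shape_error")
  assert_finite_matrix(matrix, "RDM")
  abort_if(max(abs(matrix - t(matrix))) > 1e-10, "RDM must be symmetric",
           "validation_error")
  matrix <- (matrix + t(matrix)) / 2
  diag(matrix) <- 0
  dimnames(matrix) <- list(condition_ids, condition_ids)
  structure(list(matrix = matrix, condition_ids = as.character(condition_ids),
                 metric = metric, source = source),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm: %d conditions, metric '%s', source '%s'>\n",
              length(x$condition_ids), x$metric, x$source))
  invisible(x)
}

# Per-block pairwise dissimilarities; `xs`/`ys` are preprocessed row blocks.
.pairwise_block <- function(metric, xi, xj, p) {
  switch(metric,
    pearson = 1 - tcrossprod(xi, xj) / (p - 1),
    cosine = 1 - tcrossprod(xi, xj),
    euclidean = {
      ni <- rowSums(xi^2); nj <- rowSums(xj^2)
      sq <- outer(ni, nj, "+") - 2 * tcrossprod(xi, xj)
      sqrt(pmax(sq, 0))
    })
}

# Metric-specific row preprocessing so block products give the dissimilarity.
.preprocess_rows <- function(data, metric, condition_ids, axis_label = "condition") {
  if (metric == "pearson") {
    mu <- rowMeans(data)
    s <- apply(data, 1, sd)
    bad <- which(s == 0)
    abort_if(length(bad) > 0,
             sprintf("zero-variance row(s) under pearson metric: %s %s",
                     axis_label, paste(condition_ids[bad], collapse = ", ")),
             "degenerate_row_error")
    (data - mu) / s
  } else if (metric == "cosine") {
    nrm <- sqrt(rowSums(data^2))
    bad <- which(nrm == 0)
    abort_if(length(bad) > 0,
             sprintf("zero-norm row(s) under cosine metric: %s %s",
                     axis_label, paste(condition_ids[bad], collapse = ", ")),
             "degenerate_row_error")
    data / nrm
  } else data
}

#' Compute an RDM from a pattern matrix
#'
#' Dissimilarities between the rows of `data`: `"pearson"` is 1 minus the
#' Pearson correlation (range \[0, 2\]), `"cosine"` is 1 minus the cosine
#' similarity (range \[0, 2\]), `"euclidean"` is the L2 distance. A custom
#' metric may be given as a function of two vectors returning a nonnegative
#' scalar; it is validated on first use.
#'
#' @param data Numeric matrix, conditions x features (n >= 3 rows; >= 2
#'   columns for pearson).
#' @param metric `"pearson"`, `"cosine"`, `"euclidean"`, or a function.
#' @param condition_ids Row ids; default: rownames of `data`.
#' @param source Provenance label stored in the RDM.
#' @return An [rdm()].
#' @export
compute_rdm <- function(data, metric = c("pearson", "cosine", "euclidean"),
                        condition_ids = rownames(data), source = "") {
  compute_rdm_chunked(data, metric, chunk_size = nrow(data),
                      condition_ids = condition_ids, source = source)
}

#' Chunked RDM computation
#'
#' Identical result to [compute_rdm()] (within 1e-10 elementwise) for any
#' chunk size; row blocks of `chunk_size` bound peak memory for wide data.
#'
#' @inheritParams compute_rdm
#' @param chunk_size Positive integer block size.
#' @return An [rdm()].
#' @export
compute_rdm_chunked <- function(data, metric = c("pearson", "cosine", "euclidean"),
                                chunk_size, condition_ids = rownames(data),
                                source = "") {
  custom <- is.function(metric)
  if (!custom) metric <- match.arg(metric)
  abort_if(!is.matrix(data), "data must be a matrix", "shape_error")
  n <- nrow(data); p <- ncol(data)
  condition_ids <- as.character(condition_ids %||% seq_len(n))
  abort_if(n < 3, "need at least 3 conditions", "validation_error")
  abort_if(!custom && metric == "pearson" && p < 2,
           "pearson metric needs at least 2 features per pattern", "metric_error")
  assert_finite_matrix(data, "pattern data")
  abort_if(!is.numeric(chunk_size) || chunk_size < 1,
           "chunk_size must be a positive integer", "validation_error")
  chunk_size <- min(as.integer(chunk_size), n)

  D <- matrix(0, n, n)
  if (custom) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- metric(data[i, ], data[j, ])
      abort_if(!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0,
               "custom metric must return one nonnegative finite number",
               "metric_error")
      D[i, j] <- D[j, i] <- v
    }
  } else {
    x <- .preprocess_rows(data, metric, condition_ids)
    starts <- seq(1, n, by = chunk_size)
    for (a in starts) {
      ia <- a:min(a + chunk_size - 1, n)
      for (b in starts) {
        if (b < a) next
        ib <- b:min(b + chunk_size - 1, n)
        blk <- .pairwise_block(metric, x[ia, , drop = FALSE],
                               x[ib, , drop = FALSE], p)
        D[ia, ib] <- blk
        D[ib, ia] <- t(blk)
      }
    }
  }
  rdm(D, condition_ids, metric = if (custom) "custom" else metric, source = source)
}

#' One RDM per time point from time-resolved responses
#'
#' For EEG/MEG-style data (stimuli x channels x times), computes an RDM over
#' the channel dimension at each time point.
#'
#' @param resp A [brain_responses()] with a time axis.
#' @param metric As in [compute_rdm()].
#' @return An `rdm_series`: a list of [rdm()] sharing condition order, named by
#'   time index.
#' @export
rdm_series_from_timeseries <- function(resp, metric = "pearson") {
  abort_if(!inherits(resp, "brain_responses"), "resp must be brain_responses",
           "validation_error")
  abort_if(!has_time_axis(resp), "responses have no time axis", "shape_error")
  nt <- dim(resp$data)[3]
  times <- dimnames(resp$data)[[3]] %||% sprintf("t%03d", seq_len(nt))
  out <- lapply(seq_len(nt), function(t) {
    tryCatch(
      compute_rdm(resp$data[, , t], metric, condition_ids = resp$stimulus_ids,
                  source = sprintf("%s/%s@%s", resp$subject, resp$roi, times[t])),
      brainalign_error = function(e)
        abort_if(TRUE, sprintf("time point %s: %s", times[t],
                               conditionMessage(e)),
                 class(e)[1]))
  })
  structure(stats::setNames(out, times), class = "rdm_series")
}

#' Vectorize an RDM's upper triangle
#'
#' The canonical comparison space for RSA: off-diagonal upper-triangle entries
#' in row-major order, length `n (n - 1) / 2`.
#'
#' @param r An [rdm()] (or a bare symmetric matrix).
#' @return Numeric vector.
#' @export
vectorize_rdm <- function(r) {
  m <- if (inherits(r, "rdm")) r$matrix else r
  t(m)[lower.tri(m)]  # row-major upper triangle
}

#' Rebuild an RDM matrix from its vectorized upper triangle
#' @param v Vector as produced by [vectorize_rdm()].
#' @return Symmetric matrix with zero diagonal.
#' @export
unvectorize_rdm <- function(v) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  abort_if(n != round(n), "length is not a valid triangle size", "shape_error")
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- t(m)  # filled row-major upper triangle
  m + t(m)
}
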
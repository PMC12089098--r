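#' Model adapters
#'
#' The extractor is framework-agnostic: any model is wrapped in a small
#' adapter object with two functions. `list_layers()` returns the ordered
#' layer names the model exposes; `forward(payload)` maps one stimulus payload
#' (an image path, a caption string, or a numeric array, whatever the adapter
#' accepts) to a named list of numeric arrays, one per layer. Adapters must be
#' deterministic: the same payload yields identical arrays on every call.
#'
#' @param list_layers Zero-argument function returning layer names.
#' @param forward One-argument function `payload -> named list of arrays`.
#' @param name Optional adapter/model name.
#' @return A `model_adapter` object.
#' @export
model_adapter <- function(list_layers, forward, name = "adapter") {
  abort_if(!is.function(list_layers) || !is.function(forward),
           "list_layers and forward must be functions", "validation_error")
  structure(list(list_layers = list_layers, forward = forward, name = name),
            class = "model_adapter")
}

#' Extract per-layer activations for a stimulus set
#'
#' Runs the adapter over the stimuli in canonical order and collects one
#' [feature_archive()] per requested layer. Activations of any shape are
#' flattened to vectors in row-major order (a bijective, order-stable
#' flattening; [unflatten_activation()] restores the original array).
#'
#' @param adapter A [model_adapter()].
#' @param stimuli A [stimulus_set()]; payloads are fed to the adapter.
#' @param layers Layer names to keep; default: all layers the adapter lists.
#' @return Named list of [feature_archive()], one per layer, keys in stimulus
#'   order.
#' @export
extract_features <- function(adapter, stimuli, layers = NULL) {
  abort_if(!inherits(adapter, "model_adapter"), "not a model_adapter",
           "validation_error")
  available <- adapter$list_layers()
  layers <- layers %||% available
  unknown <- setdiff(layers, available)
  abort_if(length(unknown) > 0,
           sprintf("unknown layer(s) %s; available: %s",
                   paste(unknown, collapse = ", "),
                   paste(available, collapse = ", ")),
           "layer_error")
  payloads <- stimuli$payloads %||% stats::setNames(stimuli$ids, stimuli$ids)
  per_layer <- lapply(layers, function(l) vector("list", length(stimuli$ids)))
  names(per_layer) <- layers
  shapes <- vector("list", length(layers)); names(shapes) <- layers
  for (i in seq_along(stimuli$ids)) {
    id <- stimuli$ids[i]
    out <- tryCatch(adapter$forward(payloads[[id]]), error = function(e)
      abort_if(TRUE, sprintf("adapter failed on stimulus '%s': %s", id,
                             conditionMessage(e)), "extraction_error"))
    for (l in layers) {
      abort_if(is.null(out[[l]]),
               sprintf("adapter did not return layer '%s' for stimulus '%s'", l, id),
               "extraction_error")
      shapes[[l]] <- shapes[[l]] %||% (dim(out[[l]]) %||% length(out[[l]]))
      per_layer[[l]][[i]] <- flatten_activation(out[[l]])
    }
  }
  lapply(layers, function(l) {
    entries <- stats::setNames(per_layer[[l]], stimuli$ids)
    arch <- feature_archive(l, entries)
    attr(arch, "activation_shape") <- shapes[[l]]
    arch
  }) |> stats::setNames(layers)
}

#' Row-major flattening of an activation array
#'
#' @param x Numeric vector, matrix or array.
#' @return Numeric vector in row-major (C) order. `unflatten_activation()`
#'   inverts it given the original shape.
#' @export
flatten_activation <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(as.numeric(x))
  as.numeric(aperm(x, rev(seq_along(d))))
}

#' @rdname flatten_activation
#' @param v Flattened vector.
#' @param shape Original array dimensions.
#' @export
unflatten_activation <- function(v, shape) {
  if (length(shape) <= 1) return(as.numeric(v))
  aperm(array(v, dim = rev(shape)), rev(seq_along(shape)))
}

#' Dimensionality-reduction specification
#'
#' @param method `"none"`, `"pca"` (centered principal components, ordered by
#'   decreasing explained variance) or `"srp"` (seeded sparse random
#'   projection, Achlioptas construction).
#' @param n_components Requested output dimension (clamped, see
#'   [reduce_features()]).
#' @param seed Seed for the random projection.
#' @return A `reduction_spec` list.
#' @export
reduction_spec <- function(method = c("none", "pca", "srp"), n_components = 100,
                           seed = 1) {
  method <- match.arg(method)
  abort_if(n_components < 1, "n_components must be >= 1", "validation_error")
  structure(list(method = method, n_components = as.integer(n_components),
                 seed = as.integer(seed)),
            class = "reduction_spec")
}

# Fit a centered PCA on rows of `fit` and return a projector function.
fit_pca_projector <- function(fit, n_components) {
  k <- min(n_components, nrow(fit) - 1L, ncol(fit))
  k <- max(k, 1L)
  mu <- colMeans(fit)
  pc <- prcomp(fit, center = TRUE, scale. = FALSE, rank. = k)
  list(k = k, project = function(x)
    sweep(x, 2, mu, "-") %*% pc$rotation[, seq_len(k), drop = FALSE])
}

# Achlioptas sparse random projection: entries in {-1, 0, +1} * sqrt(3/k),
# P(+-1) = 1/6 each.
srp_matrix <- function(p, k, seed) {
  with_seed(seed, {
    u <- runif(p * k)
    v <- ifelse(u < 1 / 6, 1, ifelse(u < 2 / 6, -1, 0)) * sqrt(3 / k)
    matrix(v, p, k)
  })
}

#' Reduce feature archives to a lower dimension
#'
#' PCA is fitted on `fit_ids` only (default: all stimuli) and applied to all;
#' the effective number of components is clamped to
#' `min(n_components, n_fit - 1, n_features)` and recorded in the output's
#' `"effective_components"` attribute. SRP applies one shared seeded sparse
#' projection per archive.
#'
#' @param archives A [feature_archive()] or list of them.
#' @param spec A [reduction_spec()].
#' @param fit_ids Optional stimulus ids used to fit the reduction (prevents
#'   train/test leakage when the caller holds out data).
#' @return Archives of the same shape and keys, reduced.
#' @export
reduce_features <- function(archives, spec, fit_ids = NULL) {
  single <- inherits(archives, "feature_archive")
  if (single) archives <- list(archives)
  out <- lapply(archives, function(a) {
    x <- a$data
    fit_rows <- if (is.null(fit_ids)) seq_len(nrow(x)) else {
      missing <- setdiff(fit_ids, rownames(x))
      abort_if(length(missing) > 0,
               sprintf("fit ids absent from archive '%s': %s", a$layer,
                       paste(missing, collapse = ", ")), "validation_error")
      match(fit_ids, rownames(x))
    }
    abort_if(length(fit_rows) == 0, "empty fit set", "validation_error")
    red <- switch(spec$method,
      none = list(data = x, k = ncol(x)),
      pca = {
        pr <- fit_pca_projector(x[fit_rows, , drop = FALSE], spec$n_components)
        list(data = pr$project(x), k = pr$k)
      },
      srp = {
        k <- min(spec$n_components, ncol(x))
        R <- srp_matrix(ncol(x), k, stage_seed(spec$seed, a$layer))
        list(data = x %*% R, k = k)
      })
    rownames(red$data) <- rownames(x)
    b <- feature_archive(a$layer, red$data)
    attr(b, "effective_components") <- red$k
    attr(b, "reduction") <- spec$method
    b
  })
  if (single) out[[1]] else stats::setNames(out, names(archives))
}
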
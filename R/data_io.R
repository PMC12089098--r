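#' Stimulus set
#'
#' An ordered set of uniquely identified stimuli. The id order is canonical:
#' every object built from the set (feature archives, brain responses, RDMs)
#' keeps its rows in this order, so pairwise structures are always comparable.
#'
#' @param ids Character vector of unique stimulus ids.
#' @param payloads Per-id payload: image file paths (`modality = "image"`) or
#'   caption strings (`modality = "text"`). Named by id or aligned to `ids`.
#' @param modality `"image"` or `"text"`.
#' @return A `stimulus_set` object.
#' @export
stimulus_set <- function(ids, payloads = NULL, modality = c("image", "text")) {
  modality <- match.arg(modality)
  ids <- as.character(ids)
  abort_if(anyDuplicated(ids) > 0, "stimulus ids must be unique", "validation_error")
  abort_if(length(ids) == 0, "stimulus set is empty", "empty_dataset_error")
  if (!is.null(payloads)) {
    payloads <- as.character(payloads)
    abort_if(length(payloads) != length(ids),
             "payloads must align 1:1 with ids", "validation_error")
    names(payloads) <- ids
  }
  structure(list(ids = ids, payloads = payloads, modality = modality),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set: %d %s stimuli>\n", length(x$ids), x$modality))
  invisible(x)
}

#' Brain responses for one subject and ROI
#'
#' Responses are assumed fully preprocessed (the package never denoises or
#' rescales silently; see [zscore_channels()] for an explicit option). A plain
#' matrix gives stimuli x channels; a 3-D array adds a trailing time axis
#' (stimuli x channels x times) for EEG/MEG-style data.
#'
#' @param subject Subject identifier.
#' @param roi Region-of-interest name.
#' @param data Numeric matrix (stimuli x channels) or 3-D array
#'   (stimuli x channels x times); finite values only.
#' @param stimulus_ids Ids aligned to the first axis.
#' @return A `brain_responses` object.
#' @export
brain_responses <- function(subject, roi, data, stimulus_ids) {
  stimulus_ids <- as.character(stimulus_ids)
  abort_if(!(length(dim(data)) %in% c(2L, 3L)),
           "data must be a matrix or a 3-D array", "shape_error")
  abort_if(dim(data)[1] != length(stimulus_ids),
           "rows of data must align 1:1 with stimulus_ids", "alignment_error")
  abort_if(anyDuplicated(stimulus_ids) > 0, "stimulus ids must be unique",
           "validation_error")
  assert_finite_matrix(data, "brain responses")
  dimnames(data)[[1]] <- stimulus_ids
  structure(list(subject = as.character(subject), roi = as.character(roi),
                 data = data, stimulus_ids = stimulus_ids),
            class = "brain_responses")
}

#' @export
print.brain_responses <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_responses: subject %s, roi %s, %s>\n", x$subject, x$roi,
              paste(d, collapse = " x ")))
  invisible(x)
}

#' Does a brain-response object carry a time axis?
#' @param x A `brain_responses` object.
#' @return Logical.
#' @export
has_time_axis <- function(x) length(dim(x$data)) == 3L

#' Per-channel z-scoring (explicit, never applied silently)
#'
#' @param x A `brain_responses` object.
#' @return A `brain_responses` with each channel standardized across stimuli
#'   (within each time point if a time axis is present).
#' @export
zscore_channels <- function(x) {
  z <- function(m) {
    mu <- colMeans(m); s <- apply(m, 2, sd)
    abort_if(any(s == 0), "cannot z-score a constant channel", "validation_error")
    sweep(sweep(m, 2, mu, "-"), 2, s, "/")
  }
  if (has_time_axis(x)) {
    for (t in seq_len(dim(x$data)[3])) x$data[, , t] <- z(x$data[, , t])
  } else {
    x$data <- z(x$data)
  }
  x
}

#' Per-layer feature archive
#'
#' A keyed activation container for one named model layer: one flattened
#' activation vector per stimulus id, all the same length. Internally a
#' stimuli x features matrix whose rownames are the stimulus ids.
#'
#' @param layer Layer name.
#' @param entries Either a named list of equal-length numeric vectors (keys are
#'   stimulus ids) or a numeric matrix with rownames.
#' @return A `feature_archive` object.
#' @export
feature_archive <- function(layer, entries) {
  if (is.list(entries)) {
    abort_if(is.null(names(entries)) || anyDuplicated(names(entries)) > 0,
             "entries must be uniquely keyed by stimulus id", "validation_error")
    lens <- lengths(entries)
    abort_if(length(unique(lens)) > 1,
             sprintf("ragged activation vectors (lengths %s)",
                     paste(unique(lens), collapse = ", ")), "shape_error")
    mat <- do.call(rbind, lapply(entries, as.numeric))
    rownames(mat) <- names(entries)
  } else {
    abort_if(!is.matrix(entries) || is.null(rownames(entries)),
             "matrix entries must have stimulus-id rownames", "validation_error")
    mat <- entries
  }
  assert_finite_matrix(mat, sprintf("features of layer '%s'", layer))
  structure(list(layer = as.character(layer), data = mat),
            class = "feature_archive")
}

#' @export
print.feature_archive <- function(x, ...) {
  cat(sprintf("<feature_archive: layer '%s', %d stimuli x %d features>\n",
              x$layer, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Write / read a feature archive
#'
#' One compressed key-array file per layer (R serialization). The round trip
#' `read_feature_archive(write_feature_archive(f, p))` restores values and key
#' order bit-exactly.
#'
#' @param archive A `feature_archive`.
#' @param path Output file path (conventionally `<layer>.rds`).
#' @return `path`, invisibly.
#' @export
write_feature_archive <- function(archive, path) {
  abort_if(!inherits(archive, "feature_archive"),
           "not a feature_archive", "validation_error")
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname write_feature_archive
#' @export
read_feature_archive <- function(path) {
  abort_if(!file.exists(path), sprintf("no such archive: %s", path),
           "format_error")
  obj <- tryCatch(readRDS(path), error = function(e)
    abort_if(TRUE, sprintf("unreadable feature archive '%s': %s", path,
                           conditionMessage(e)), "format_error"))
  abort_if(!inherits(obj, "feature_archive"),
           sprintf("'%s' does not contain a feature archive", path), "format_error")
  obj
}

#' Sanitize a layer name into a file name
#' @param layer Layer name string.
#' @return A file-system-safe string.
#' @export
sanitize_layer_name <- function(layer) gsub("[^A-Za-z0-9._-]+", "_", layer)

#' Specification for the synthetic model-brain dataset generator
#'
#' The generator emulates the shared structure the package is built to detect:
#' a latent stimulus representation Z (standard normal) that both "model
#' layers" and "subjects" observe through their own linear read-outs. Layer l
#' mixes signal and noise additively, `sqrt(f_l) Z A_l + sqrt(1 - f_l) E_l`,
#' with unit-norm Gaussian mixing columns A_l and independent standard-normal
#' noise E_l, so every feature has unit variance regardless of its signal
#' fraction `f_l`. Subject s responds with `Z W_s + noise`, W_s a unit-norm
#' random read-out, noise i.i.d. normal with sd `subject_noise_sd`.
#'
#' @param n_stimuli,n_latent,n_subjects,n_channels Positive integers; defaults
#'   (200 stimuli, 20 latents, 3 subjects, 30 channels) give a realistic
#'   desk-scale fMRI-style problem.
#' @param layer_signal_fractions Numeric vector in \[0, 1\], one per synthetic
#'   layer: fraction of each layer's variance drawn from the shared latent.
#'   Default `c(1, 0)`: one fully informative layer and one pure-noise layer.
#' @param n_features Features per layer (recycled to the number of layers).
#' @param subject_noise_sd Nonnegative response noise sd (default 1, a
#'   moderate single-subject signal-to-noise ratio).
#' @param seed Integer seed; the whole draw is reproducible given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_stimuli = 200, n_latent = 20, n_subjects = 3,
                           n_channels = 30, layer_signal_fractions = c(1, 0),
                           n_features = 60, subject_noise_sd = 1, seed = 1) {
  s <- list(n_stimuli = n_stimuli, n_latent = n_latent, n_subjects = n_subjects,
            n_channels = n_channels,
            layer_signal_fractions = as.numeric(layer_signal_fractions),
            n_features = rep_len(as.integer(n_features),
                                 length(layer_signal_fractions)),
            subject_noise_sd = subject_noise_sd, seed = as.integer(seed))
  with(s, {
    abort_if(any(!is.finite(c(n_stimuli, n_latent, n_subjects, n_channels,
                              layer_signal_fractions, n_features,
                              subject_noise_sd, seed))),
             "synthetic spec values must be finite", "validation_error")
    abort_if(any(c(n_stimuli, n_latent, n_subjects, n_channels, n_features) < 1),
             "sizes must be positive integers", "validation_error")
    abort_if(any(layer_signal_fractions < 0 | layer_signal_fractions > 1),
             "layer_signal_fractions must lie in [0, 1]", "validation_error")
    abort_if(subject_noise_sd < 0, "subject_noise_sd must be nonnegative",
             "validation_error")
  })
  structure(s, class = "synthetic_spec")
}

# Gaussian matrix with unit-L2-norm columns: each element of Z %*% A then has
# variance exactly 1 when Z is standard normal.
unit_norm_mixing <- function(n_in, n_out) {
  a <- matrix(rnorm(n_in * n_out), n_in, n_out)
  sweep(a, 2, sqrt(colSums(a^2)), "/")
}

#' Generate a synthetic stimulus/model/brain dataset
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `stimuli` (a [stimulus_set()] of text captions),
#'   `features` (one [feature_archive()] per layer, named `layer1`, `layer2`,
#'   ...), and `responses` (one [brain_responses()] per subject, ROI `"roi1"`).
#'   Deterministic given `spec$seed`.
#' @export
generate_synthetic_dataset <- function(spec) {
  abort_if(!inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec",
           "validation_error")
  with_seed(spec$seed, {
    ids <- sprintf("stim%04d", seq_len(spec$n_stimuli))
    stimuli <- stimulus_set(
      ids, payloads = sprintf("synthetic caption for %s", ids), modality = "text")
    Z <- matrix(rnorm(spec$n_stimuli * spec$n_latent), spec$n_stimuli)
    features <- lapply(seq_along(spec$layer_signal_fractions), function(l) {
      f <- spec$layer_signal_fractions[l]
      p <- spec$n_features[l]
      A <- unit_norm_mixing(spec$n_latent, p)
      E <- matrix(rnorm(spec$n_stimuli * p), spec$n_stimuli)
      X <- sqrt(f) * (Z %*% A) + sqrt(1 - f) * E
      rownames(X) <- ids
      feature_archive(sprintf("layer%d", l), X)
    })
    names(features) <- vapply(features, `[[`, "", "layer")
    responses <- lapply(seq_len(spec$n_subjects), function(s) {
      W <- unit_norm_mixing(spec$n_latent, spec$n_channels)
      Y <- Z %*% W +
        spec$subject_noise_sd * matrix(rnorm(spec$n_stimuli * spec$n_channels),
                                       spec$n_stimuli)
      brain_responses(sprintf("sub%02d", s), "roi1", Y, ids)
    })
    list(stimuli = stimuli, features = features, responses = responses)
  })
}

#' Load a dataset from the documented on-disk layout
#'
#' Layout: `root/stimuli/` holds one file per stimulus (`.png`, `.jpg`,
#' `.jpeg` for images or `.txt` for captions; the file stem is the stimulus
#' id), and `root/responses/` holds one CSV per subject/ROI named
#' `<subject>_<roi>.csv` whose first column `stimulus_id` keys the remaining
#' channel columns. Stimulus order is canonical: lexicographic by id; response
#' rows are reordered to it.
#'
#' @param root Dataset root directory.
#' @return A list with `stimuli` (a [stimulus_set()]) and `responses` (a list
#'   of [brain_responses()], one per response file).
#' @export
load_dataset_layout <- function(root) {
  sdir <- file.path(root, "stimuli"); rdir <- file.path(root, "responses")
  abort_if(!dir.exists(sdir), sprintf("missing stimuli directory: %s", sdir),
           "validation_error")
  files <- sort(list.files(sdir, pattern = "\\.(png|jpg|jpeg|txt)$",
                           ignore.case = TRUE, full.names = TRUE))
  abort_if(length(files) == 0, sprintf("no stimuli found under %s", sdir),
           "empty_dataset_error")
  ids <- tools::file_path_sans_ext(basename(files))
  ord <- order(ids)
  ids <- ids[ord]; files <- files[ord]
  modality <- if (all(grepl("\\.txt$", files, ignore.case = TRUE))) "text" else "image"
  payloads <- if (modality == "text") {
    vapply(files, function(f) paste(readLines(f, warn = FALSE), collapse = " "), "")
  } else files
  stimuli <- stimulus_set(ids, payloads, modality)

  rfiles <- sort(list.files(rdir, pattern = "\\.csv$", full.names = TRUE))
  responses <- lapply(rfiles, function(f) {
    stem <- tools::file_path_sans_ext(basename(f))
    parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
    abort_if(length(parts) < 2,
             sprintf("response file '%s' does not follow <subject>_<roi>.csv",
                     basename(f)), "validation_error")
    tab <- read.csv(f, check.names = FALSE)
    abort_if(names(tab)[1] != "stimulus_id",
             sprintf("first column of %s must be 'stimulus_id'", basename(f)),
             "format_error")
    missing <- setdiff(ids, tab$stimulus_id)
    extra <- setdiff(tab$stimulus_id, ids)
    abort_if(length(missing) > 0 || length(extra) > 0,
             sprintf("response file '%s' misaligned with stimuli; missing: %s; unknown: %s",
                     basename(f),
                     paste(missing, collapse = ", ") %||% "",
                     paste(extra, collapse = ", ") %||% ""),
             "alignment_error")
    m <- as.matrix(tab[match(ids, tab$stimulus_id), -1, drop = FALSE])
    brain_responses(parts[1], paste(parts[-1], collapse = "_"), m, ids)
  })
  list(stimuli = stimuli, responses = responses)
}
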
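#' @name registry
#' @title Model taxonomy registry
#'
#' @description
#' A registry is a curated table of network models annotated with the
#' attributes that matter when choosing candidate models for a brain-alignment
#' study: architecture family, input modality, training task, training dataset
#' and training method, plus suggested layers to extract. The package ships a
#' starter registry (about forty models across vision, language, audio and
#' multimodal families) at
#' `system.file("extdata", "model_registry.json", package = "brainalign")`;
#' it is a plain JSON document users can extend.
#'
#' Registry JSON schema: a single object with `schema_version` (string) and
#' `records` (array). Each record has `name` (unique), `framework_source`,
#' `architecture_family`, `modality` (one of `"vision"`, `"language"`,
#' `"audio"`, `"multimodal"`), `training_task`, `training_dataset`,
#' `training_method` (one of `"supervised"`, `"self-supervised"`,
#' `"random-init"`, `"other"`), and `suggested_layers` (possibly empty array
#' of layer names).
NULL

.modalities <- c("vision", "language", "audio", "multimodal")
.training_methods <- c("supervised", "self-supervised", "random-init", "other")
.record_fields <- c("name", "framework_source", "architecture_family", "modality",
                    "training_task", "training_dataset", "training_method",
                    "suggested_layers")

#' Construct a model registry from a list of records
#'
#' @param records List of named lists, one per model record.
#' @param schema_version Schema version string.
#' @return A `model_registry`: a tibble with one row per model and a
#'   `suggested_layers` list-column, plus a `schema_version` attribute.
#' @export
model_registry <- function(records, schema_version = "1") {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    missing <- setdiff(setdiff(.record_fields, "suggested_layers"), names(r))
    abort_if(length(missing) > 0,
             sprintf("record %d ('%s') is missing field(s): %s",
                     i, r$name %||% "?", paste(missing, collapse = ", ")),
             "schema_error")
    abort_if(!(r$modality %in% .modalities),
             sprintf("record '%s': modality '%s' is not one of %s",
                     r$name, r$modality, paste(.modalities, collapse = ", ")),
             "schema_error")
    abort_if(!(r$training_method %in% .training_methods),
             sprintf("record '%s': training_method '%s' is not one of %s",
                     r$name, r$training_method,
                     paste(.training_methods, collapse = ", ")),
             "schema_error")
    tibble::tibble(
      name = r$name, framework_source = r$framework_source,
      architecture_family = r$architecture_family, modality = r$modality,
      training_task = r$training_task, training_dataset = r$training_dataset,
      training_method = r$training_method,
      suggested_layers = list(as.character(unlist(r$suggested_layers))))
  })
  out <- do.call(rbind, rows) %||% tibble::tibble()
  dup <- out$name[duplicated(out$name)]
  abort_if(length(dup) > 0,
           sprintf("duplicate model name(s): %s", paste(unique(dup), collapse = ", ")),
           "uniqueness_error")
  structure(out, schema_version = schema_version,
            class = c("model_registry", class(out)))
}

#' Load a model registry from a JSON file
#'
#' @param path Path to a registry JSON document (see [registry] for the schema).
#' @return A validated `model_registry`.
#' @export
load_registry <- function(path) {
  abort_if(!file.exists(path), sprintf("registry file not found: %s", path),
           "validation_error")
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    abort_if(TRUE, sprintf("registry is not valid JSON: %s",
                                           conditionMessage(e)), "schema_error")
                  })
  abort_if(is.null(doc$records), "registry JSON must have a 'records' array",
           "schema_error")
  model_registry(doc$records, schema_version = doc$schema_version %||% "1")
}

#' Write a model registry to a JSON file
#'
#' @param registry A `model_registry`.
#' @param path Output path. Round-trips through [load_registry()] identically.
#' @export
write_registry <- function(registry, path) {
  records <- lapply(seq_len(nrow(registry)), function(i) {
    r <- as.list(registry[i, setdiff(.record_fields, "suggested_layers")])
    r$suggested_layers <- registry$suggested_layers[[i]]
    r
  })
  jsonlite::write_json(
    list(schema_version = attr(registry, "schema_version") %||% "1",
         records = records),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Find models whose name contains a query string
#'
#' Case-insensitive substring match on model names; the empty query matches
#' everything. Results are sorted by name.
#'
#' @param registry A `model_registry`.
#' @param query Search string.
#' @return The matching subset of the registry, sorted by name.
#' @export
model_like_name <- function(registry, query = "") {
  hit <- grepl(tolower(query), tolower(registry$name), fixed = TRUE)
  out <- registry[hit, , drop = FALSE]
  out[order(out$name), , drop = FALSE]
}

#' Find models by exact attribute values
#'
#' Conjunction (AND) of case-insensitive exact matches on record attributes.
#' An empty filter list returns the full registry.
#'
#' @param registry A `model_registry`.
#' @param ... Named filters, e.g. `modality = "vision"`,
#'   `training_method = "supervised"`. A named list can be passed as
#'   `filters` instead.
#' @param filters Optional named list of filters (alternative to `...`).
#' @return The matching subset of the registry.
#' @export
find_model_by_custom <- function(registry, ..., filters = NULL) {
  f <- c(list(...), as.list(filters))
  bad <- setdiff(names(f), setdiff(.record_fields, "suggested_layers"))
  abort_if(length(bad) > 0,
           sprintf("unknown attribute(s): %s; valid keys are %s",
                   paste(bad, collapse = ", "),
                   paste(setdiff(.record_fields, "suggested_layers"),
                         collapse = ", ")),
           "attribute_error")
  keep <- rep(TRUE, nrow(registry))
  for (k in names(f)) {
    keep <- keep & (tolower(registry[[k]]) == tolower(as.character(f[[k]])))
  }
  registry[keep, , drop = FALSE]
}
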
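.config_defaults <- function() list(
  seed = 1L,
  output_dir = "brainalign_run",
  evaluation = "encoding",        # "encoding" or "rsa"
  synthetic = list(),             # args for synthetic_spec(); NULL w/ dataset_root
  dataset_root = NULL,            # load_dataset_layout() root (alternative input)
  feature_dir = NULL,             # directory of <layer>.rds archives, with dataset_root
  rdm_metric = "pearson",
  comparator = "pearson",
  averaging = "direct",
  encoding = list(),              # args for encoding_spec() (seed is derived)
  plot_kind = "bars_all_layers"   # "bars_all_layers" or "bars_best_layer"
)

#' Validate a run configuration
#'
#' Accepts a JSON file path or a named list; fills documented defaults,
#' rejects unknown keys (suggesting the nearest valid one) and invalid values.
#' A run is fully reproducible from its validated config: the global `seed`
#' fans out to per-stage seeds via [stage_seed()].
#'
#' @param config Path to a JSON config or a named list.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    abort_if(!file.exists(config), sprintf("config file not found: %s", config),
             "validation_error")
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  }
  abort_if(!is.list(config), "config must be a named list or JSON object",
           "validation_error")
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    nearest <- names(defaults)[apply(utils::adist(unknown, names(defaults)),
                                     1, which.min)]
    abort_if(TRUE, sprintf("unknown config key(s): %s (did you mean: %s?)",
                           paste(unknown, collapse = ", "),
                           paste(nearest, collapse = ", ")),
             "validation_error")
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  abort_if(!is.numeric(cfg$seed) || length(cfg$seed) != 1 || cfg$seed < 0 ||
             cfg$seed != round(cfg$seed),
           "seed must be a single nonnegative integer", "validation_error")
  cfg$seed <- as.integer(cfg$seed)
  abort_if(!(cfg$evaluation %in% c("encoding", "rsa")),
           "evaluation must be 'encoding' or 'rsa'", "validation_error")
  abort_if(!(cfg$plot_kind %in% c("bars_all_layers", "bars_best_layer")),
           "plot_kind must be 'bars_all_layers' or 'bars_best_layer'",
           "validation_error")
  abort_if(!(cfg$rdm_metric %in% c("pearson", "cosine", "euclidean")),
           "rdm_metric must be pearson, cosine or euclidean", "validation_error")
  structure(cfg, class = "run_config")
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    abort_if(TRUE, sprintf("[stage %s] %s", stage, conditionMessage(e)),
             "stage_error"))
}

#' Run the end-to-end walkthrough pipeline
#'
#' Executes input acquisition (the synthetic generator, or a dataset layout
#' plus precomputed feature archives), evaluation (per-layer RSA with noise
#' ceiling and significance, or per-layer linear encoding), and plotting, then
#' writes `results.csv`, `figure.png` and a `manifest.json` (config copy,
#' package version, derived stage seeds, input checksums) into the output
#' directory. Reruns from the same config produce byte-identical results CSVs.
#'
#' @param config A `run_config` (or anything [validate_config()] accepts).
#' @return Invisibly, a list with `results` (tibble), and the written paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(data = stage_seed(cfg$seed, "data"),
                encoding = stage_seed(cfg$seed, "encoding"),
                rsa = stage_seed(cfg$seed, "rsa"))

  inputs <- stage_error("extraction", {
    if (!is.null(cfg$dataset_root)) {
      ds <- load_dataset_layout(cfg$dataset_root)
      abort_if(is.null(cfg$feature_dir) || !dir.exists(cfg$feature_dir),
               sprintf("feature archive directory not found: %s",
                       cfg$feature_dir %||% "<missing>"), "validation_error")
      paths <- sort(list.files(cfg$feature_dir, pattern = "\\.rds$",
                               full.names = TRUE))
      abort_if(length(paths) == 0,
               sprintf("no feature archives under %s", cfg$feature_dir),
               "validation_error")
      feats <- lapply(paths, read_feature_archive)
      names(feats) <- vapply(feats, `[[`, "", "layer")
      list(stimuli = ds$stimuli, features = feats, responses = ds$responses,
           checksums = tools::md5sum(paths))
    } else {
      spec <- do.call(synthetic_spec,
                      utils::modifyList(list(seed = seeds$data),
                                        as.list(cfg$synthetic)))
      out <- generate_synthetic_dataset(spec)
      out$checksums <- character(0)
      out
    }
  })

  results <- stage_error("evaluation", {
    if (cfg$evaluation == "rsa") {
      model_rdms <- lapply(inputs$features, function(f)
        compute_rdm(f$data, cfg$rdm_metric, source = f$layer))
      rois <- split(inputs$responses,
                    vapply(inputs$responses, `[[`, "", "roi"))
      do.call(rbind, lapply(names(rois), function(roi) {
        brain_rdms <- lapply(rois[[roi]], function(b)
          compute_rdm(b$data, cfg$rdm_metric,
                      source = sprintf("%s/%s", b$subject, b$roi)))
        ev <- evaluate_rsa(model_rdms, brain_rdms, mode = cfg$averaging,
                           comparator = cfg$comparator, seed = seeds$rsa,
                           roi = roi)
        ev$layer <- ev$model; ev$model <- "synthetic"
        ev[, c("model", "layer", "roi", "score", "p_value", "significant",
               "ceiling_lower", "ceiling_upper")]
      }))
    } else {
      enc_spec <- do.call(encoding_spec,
                          utils::modifyList(list(seed = seeds$encoding),
                                            as.list(cfg$encoding)))
      rows <- list()
      for (f in inputs$features) for (b in inputs$responses) {
        r <- linear_encoding(f, b, enc_spec, model = "synthetic")
        rows[[length(rows) + 1]] <-
          data.frame(model = r$model, layer = r$layer, roi = b$roi,
                     subject = b$subject, score = r$mean_r,
                     p_value = r$p_value, significant = r$significant)
      }
      per_run <- do.call(rbind, rows)
      agg <- stats::aggregate(score ~ model + layer + roi, per_run, mean)
      agg$subject <- "mean"
      agg$p_value <- NA_real_; agg$significant <- NA
      tibble::as_tibble(rbind(per_run, agg[, names(per_run)]))
    }
  })

  paths <- stage_error("output", {
    results_path <- file.path(cfg$output_dir, "results.csv")
    write.csv(as.data.frame(results), results_path, row.names = FALSE)
    fig_path <- file.path(cfg$output_dir, "figure.png")
    plot_tab <- results[!is.na(results$score), , drop = FALSE]
    if ("subject" %in% names(plot_tab))
      plot_tab <- plot_tab[plot_tab$subject == "mean", , drop = FALSE]
    fig <- if (cfg$plot_kind == "bars_best_layer")
      plot_best_layer(plot_tab, file = fig_path)
    else plot_bars(plot_tab, file = fig_path)
    manifest <- list(
      package_version = as.character(utils::packageVersion("brainalign")),
      config = unclass(cfg), stage_seeds = seeds,
      input_checksums = as.list(inputs$checksums),
      n_stimuli = length(inputs$stimuli$ids))
    manifest_path <- file.path(cfg$output_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    list(results = results_path, figure = fig_path, manifest = manifest_path)
  })
  invisible(list(results = results, paths = paths))
}
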
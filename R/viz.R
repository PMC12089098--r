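#' Collect evaluation records into the plotting table
#'
#' Normalizes RSA / encoding results into the tidy table the plot functions
#' consume: one row per (model, layer, roi) with `score`, `significant`,
#' optional `ceiling_lower`/`ceiling_upper`, and `layer_index` (order of first
#' appearance within each model, used for the hue ramp and tie-breaks).
#'
#' @param results A data.frame/tibble with at least `model`, `layer`, `roi`,
#'   `score` columns, or a list of `encoding_result` objects.
#' @return A tibble.
#' @export
as_result_table <- function(results) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, TRUE, "encoding_result"))) {
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(model = r$model, layer = r$layer, roi = r$roi,
                 score = r$mean_r, p_value = r$p_value,
                 significant = r$significant)))
  }
  abort_if(!is.data.frame(results) || nrow(results) == 0,
           "results must be a non-empty table", "validation_error")
  need <- c("model", "layer", "roi", "score")
  missing <- setdiff(need, names(results))
  abort_if(length(missing) > 0,
           sprintf("results lack column(s): %s", paste(missing, collapse = ", ")),
           "validation_error")
  if (!"significant" %in% names(results)) results$significant <- FALSE
  results$layer_index <- stats::ave(
    seq_len(nrow(results)), results$model,
    FUN = function(i) match(results$layer[i], unique(results$layer[i])))
  tibble::as_tibble(results)
}

# Per-(model, layer) fill colors: one base hue per model, darker for earlier
# layers, lighter for later ones.
layer_hue_ramp <- function(tab) {
  models <- unique(tab$model)
  base <- grDevices::hcl(h = seq(15, 375, length.out = length(models) + 1)[-1],
                         c = 80, l = 55)
  names(base) <- models
  key <- paste(tab$model, tab$layer, sep = "\r")
  cols <- character(nrow(tab))
  for (m in models) {
    rows <- tab$model == m
    idx <- tab$layer_index[rows]
    k <- max(idx)
    ramp <- grDevices::colorRampPalette(c("grey15", base[m], "grey85"))(k + 2)
    cols[rows] <- ramp[idx + 1]
  }
  stats::setNames(cols, key)[!duplicated(key)]
}

finish_plot <- function(p, file, width = 8, height = 5) {
  if (!is.null(file)) ggplot2::ggsave(file, p, width = width, height = height)
  invisible(p)
}

#' Bar plot of evaluation scores for all layers
#'
#' One panel per ROI, one bar per (model, layer) in layer order, with a hue
#' ramp per model (darker bars are earlier layers). Significant results are
#' marked with an asterisk; the noise ceiling is drawn as a shaded band when
#' requested and present; pairwise significance brackets (paired two-sided t
#' over matched per-subject/per-fold scores, BH-FDR corrected) can be added.
#'
#' @param results See [as_result_table()].
#' @param show_ceiling Draw the `ceiling_lower`/`ceiling_upper` band.
#' @param show_significance Mark `significant` bars with an asterisk.
#' @param show_pairwise Add pairwise brackets (needs a `per_subject_r`
#'   list-column of matched score vectors).
#' @param alpha Significance level for the pairwise tests.
#' @param file Optional output path (`.png` or `.svg`); the ggplot object is
#'   returned invisibly either way, so tests can inspect it without rendering.
#' @return The ggplot object, invisibly.
#' @export
plot_bars <- function(results, show_ceiling = TRUE, show_significance = TRUE,
                      show_pairwise = FALSE, alpha = 0.05, file = NULL) {
  tab <- as_result_table(results)
  tab$bar <- paste(tab$model, tab$layer, sep = "\r")
  tab$bar <- factor(tab$bar, levels = unique(tab$bar))
  fills <- layer_hue_ramp(tab)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$bar, y = .data$score,
                                         fill = .data$bar)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = fills) +
    ggplot2::scale_x_discrete(labels = function(l) sub("\r", "\n", l)) +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (show_ceiling && "ceiling_lower" %in% names(tab) &&
      any(is.finite(tab$ceiling_lower))) {
    band <- unique(tab[is.finite(tab$ceiling_lower),
                       c("roi", "ceiling_lower", "ceiling_upper")])
    p <- p + ggplot2::geom_rect(
      data = band,
      ggplot2::aes(ymin = .data$ceiling_lower, ymax = .data$ceiling_upper),
      xmin = -Inf, xmax = Inf, alpha = 0.25, fill = "grey50",
      inherit.aes = FALSE)
  }
  if (show_significance && any(tab$significant, na.rm = TRUE)) {
    stars <- tab[which(tab$significant), , drop = FALSE]
    p <- p + ggplot2::geom_text(
      data = stars, label = "*", vjust = -0.3, size = 6,
      ggplot2::aes(x = .data$bar, y = .data$score), inherit.aes = FALSE)
  }
  if (show_pairwise && "per_subject_r" %in% names(tab)) {
    pw <- pairwise_significance(tab, alpha)
    if (nrow(pw) > 0) {
      pw$y <- max(tab$score, na.rm = TRUE) * (1.1 + 0.08 * seq_len(nrow(pw)))
      p <- p + ggplot2::geom_segment(
        data = pw, ggplot2::aes(x = .data$bar_a, xend = .data$bar_b,
                                y = .data$y, yend = .data$y),
        inherit.aes = FALSE)
    }
  }
  finish_plot(p, file)
}

# Pairwise paired t tests between bars within each ROI, BH-corrected.
pairwise_significance <- function(tab, alpha = 0.05) {
  out <- list()
  for (roi in unique(tab$roi)) {
    sub <- tab[tab$roi == roi, , drop = FALSE]
    if (nrow(sub) < 2) next
    pairs <- utils::combn(nrow(sub), 2)
    ps <- apply(pairs, 2, function(ij) {
      a <- sub$per_subject_r[[ij[1]]]; b <- sub$per_subject_r[[ij[2]]]
      if (length(a) != length(b) || length(a) < 2 || sd(a - b) == 0) return(NA_real_)
      t.test(a, b, paired = TRUE)$p.value
    })
    ps_adj <- p.adjust(ps, "BH")
    keep <- which(!is.na(ps_adj) & ps_adj < alpha)
    if (length(keep) > 0)
      out[[roi]] <- data.frame(roi = roi,
                               bar_a = sub$bar[pairs[1, keep]],
                               bar_b = sub$bar[pairs[2, keep]],
                               p_adj = ps_adj[keep])
  }
  if (length(out) == 0) data.frame(roi = character(), bar_a = character(),
                                   bar_b = character(), p_adj = numeric())
  else do.call(rbind, out)
}

#' Bar plot of each model's best layer only
#'
#' Condensed view: per (model, ROI), only the layer with the maximal score is
#' drawn; ties go to the earliest layer (lowest layer index).
#'
#' @inheritParams plot_bars
#' @return The ggplot object, invisibly.
#' @export
plot_best_layer <- function(results, show_ceiling = TRUE,
                            show_significance = TRUE, file = NULL) {
  tab <- as_result_table(results)
  best <- do.call(rbind, lapply(split(tab, paste(tab$model, tab$roi, sep = "\r")),
    function(g) g[order(-g$score, g$layer_index)[1], , drop = FALSE]))
  plot_bars(best, show_ceiling = show_ceiling,
            show_significance = show_significance, file = file)
}

#' Line plot of time-resolved scores
#'
#' One line per (model, layer) over time with a shaded across-subject SEM band
#' (half-width `sd / sqrt(n)` of the per-subject scores at each time point);
#' significant time points are marked along a baseline strip.
#'
#' @param series A data.frame with columns `time` (numeric), `model`, `layer`,
#'   and either `per_subject_r` (list-column of subject scores, from which
#'   mean and SEM are computed) or precomputed `score` and `sem` columns, plus
#'   optional `significant`.
#' @param file Optional output path.
#' @return The ggplot object, invisibly.
#' @export
plot_timecourse <- function(series, file = NULL) {
  abort_if(!is.data.frame(series) || nrow(series) == 0,
           "series must be a non-empty table", "validation_error")
  abort_if(length(unique(series$time)) < 2,
           "a time course needs >= 2 time points", "validation_error")
  if ("per_subject_r" %in% names(series)) {
    series$score <- vapply(series$per_subject_r, mean, 0)
    series$sem <- vapply(series$per_subject_r, function(r)
      sd(r) / sqrt(length(r)), 0)
  }
  abort_if(!"score" %in% names(series), "series needs scores", "validation_error")
  if (!"sem" %in% names(series)) series$sem <- 0
  if (!"significant" %in% names(series)) series$significant <- FALSE
  series$trace <- paste(series$model, series$layer)
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$time, y = .data$score,
                                            color = .data$trace,
                                            group = .data$trace)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$score - .data$sem,
                                      ymax = .data$score + .data$sem,
                                      fill = .data$trace),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "score", color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (any(series$significant)) {
    base_y <- min(series$score - series$sem) - 0.05 * diff(range(series$score))
    sig <- series[series$significant, , drop = FALSE]
    p <- p + ggplot2::geom_point(
      data = sig, ggplot2::aes(x = .data$time, color = .data$trace),
      y = base_y, shape = 15, size = 1.5, inherit.aes = FALSE)
  }
  finish_plot(p, file)
}
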
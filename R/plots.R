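# ggplot2 displays for the main result types. Each returns a ggplot object so
# callers can restyle or add layers.

#' Marker-panel score scatter for a cohort
#'
#' Plots each sample's mean centred expression over the luminal panel against
#' the basal panel, optionally coloured by a label column, visualising the
#' luminal / basal / non-type structure of a cohort.
#'
#' @param expr Median-centred log2 expression tibble.
#' @param signature Signature tibble (`gene`, `class`).
#' @param labels Optional tibble with `sample` plus a `label` (or `class`)
#'   column used for colour.
#' @return A ggplot object.
#' @export
plot_subtype_scores <- function(expr, signature, labels = NULL) {
  m <- expr_matrix(expr)
  lum <- intersect(signature$gene[signature$class == "luminal"], rownames(m))
  bas <- intersect(signature$gene[signature$class == "basal"], rownames(m))
  if (!length(lum) || !length(bas)) abort("signature panels not present in matrix")
  df <- tibble(sample = colnames(m),
               luminal_score = colMeans(m[lum, , drop = FALSE]),
               basal_score = colMeans(m[bas, , drop = FALSE]))
  if (!is.null(labels)) {
    lab <- labels
    if (!"label" %in% names(lab) && "class" %in% names(lab)) {
      lab <- dplyr::rename(lab, label = class)
    }
    df <- dplyr::left_join(df, dplyr::select(lab, sample, label), by = "sample")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$luminal_score, y = .data$basal_score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "Luminal panel score (centred log2)",
                  y = "Basal panel score (centred log2)") +
    ggplot2::theme_minimal()
  if ("label" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' @describeIn build_centroids Plot per-gene centroid values by class.
#' @param object A `centroid_model`.
#' @export
autoplot.centroid_model <- function(object, ...) {
  df <- tidy(object)
  df$gene <- factor(df$gene, levels = object$genes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$centroid,
                                   colour = .data$class, group = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "Centroid (centred log2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Volcano plot of a differential-expression result
#'
#' @param de Tibble from [differential_expression()].
#' @param q_threshold Highlighted FDR cutoff (default 0.1).
#' @param fc_threshold Linear fold-change guides (default 2).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, q_threshold = 0.1, fc_threshold = 2) {
  df <- dplyr::filter(de, !is.na(p))
  df$significant <- !is.na(df$q) & df$q < q_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 name = sprintf("q < %g", q_threshold)) +
    ggplot2::labs(x = "log2 fold change (group1 - group2)", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Transdifferentiation shift per sample
#'
#' Bars of the shift score (`d_basal - d_luminal`) from a set of
#' nearest-centroid calls; positive bars sit closer to the luminal centroid.
#'
#' @param calls A `subtype_calls` tibble from [classify_samples()].
#' @return A ggplot object.
#' @export
plot_shift_scores <- function(calls) {
  stopifnot(all(c("sample", "shift", "label") %in% names(calls)))
  df <- dplyr::arrange(tibble::as_tibble(calls), .data$shift)
  df$sample <- factor(df$sample, levels = df$sample)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$shift,
                                   fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Shift score (d_basal - d_luminal)") +
    ggplot2::theme_minimal()
}

#' Foreground vs background motif frequencies
#'
#' @param enrichment Tibble from [motif_enrichment()].
#' @return A ggplot object.
#' @export
plot_motif_enrichment <- function(enrichment) {
  df <- dplyr::filter(enrichment, !is.na(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bg_pct, y = .data$fg_pct,
                                   colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 name = "significant") +
    ggplot2::labs(x = "% of background sequences with motif",
                  y = "% of foreground sequences with motif") +
    ggplot2::theme_minimal()
}
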
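#' Agglomerative clustering of samples on expression profiles
#'
#' Hierarchically clusters sample columns with the chosen linkage and cuts the
#' merge tree into `k` groups. The default metric is correlation distance
#' (1 - Pearson correlation between sample profiles), the conventional choice
#' for expression-subtype work; Ward linkage uses the squared-distance variant
#' on Euclidean distances.
#'
#' @param expr Preprocessed log2 expression tibble (see
#'   [preprocess_expression()]).
#' @param k Number of clusters to cut (a cohort with luminal, basal and
#'   non-type groups uses `k = 3`).
#' @param linkage `"average"`, `"complete"` or `"ward"`.
#' @param metric `"correlation"` or `"euclidean"`.
#' @return An object of class `subtype_clusters` with the per-sample
#'   assignment, the `hclust` merge tree and the parameters used. `tidy()`
#'   returns the assignment, `glance()` the parameters.
#' @export
cluster_samples <- function(expr, k = 3, linkage = c("average", "complete", "ward"),
                            metric = c("correlation", "euclidean")) {
  linkage <- arg_match(linkage)
  metric <- arg_match(metric)
  check_expression(expr)
  m <- expr_matrix(expr)
  n <- ncol(m)
  if (n < 2L) abort("need >= 2 samples to cluster")
  if (k > n) abort(sprintf("k = %d exceeds number of samples (%d)", k, n))
  if (metric == "correlation") {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      abort(sprintf("zero-variance sample profile under correlation metric: %s",
                    paste(colnames(m)[sds == 0], collapse = ", ")))
    }
    d <- stats::as.dist(1 - stats::cor(m))
  } else {
    d <- stats::dist(t(m))
  }
  method <- c(average = "average", complete = "complete", ward = "ward.D2")[[linkage]]
  tree <- stats::hclust(d, method = method)
  assignment <- stats::cutree(tree, k = k)
  log_stage("cluster_samples", samples = n, k = k, linkage = linkage, metric = metric)
  structure(list(
    assignment = tibble(sample = colnames(m), cluster = unname(assignment)),
    tree = tree, k = as.integer(k), linkage = linkage, metric = metric
  ), class = "subtype_clusters")
}

#' @export
print.subtype_clusters <- function(x, ...) {
  cat(sprintf("<subtype_clusters> %d samples, k = %d (%s linkage, %s distance)\n",
              nrow(x$assignment), x$k, x$linkage, x$metric))
  print(table(x$assignment$cluster))
  invisible(x)
}

#' @rdname cluster_samples
#' @param x A `subtype_clusters` object.
#' @param ... Unused.
#' @export
tidy.subtype_clusters <- function(x, ...) x$assignment

#' @rdname cluster_samples
#' @export
glance.subtype_clusters <- function(x, ...) {
  tibble(n_samples = nrow(x$assignment), k = x$k, linkage = x$linkage,
         metric = x$metric, max_merge_height = max(x$tree$height))
}

#' Label clusters as luminal, basal or non-type from marker-panel scores
#'
#' For each cluster the luminal score is the mean median-centred expression
#' over luminal-signature genes (basal likewise). A cluster whose two scores
#' both fall below `nontype_threshold` is non-type ("low expression of both
#' marker panels" relative to the cohort median); otherwise it takes the label
#' of the larger score.
#'
#' @param expr The preprocessed (median-centred) expression tibble used for
#'   clustering.
#' @param clusters A `subtype_clusters` object (or a tibble with `sample` and
#'   `cluster` columns).
#' @param signature Signature tibble (`gene`, `class`); both classes must be
#'   non-empty.
#' @param nontype_threshold Score threshold below which both panels count as
#'   "low"; default 0, i.e. below the cohort-median profile.
#' @return A tibble with one row per cluster: `cluster`, `n_samples`,
#'   `luminal_score`, `basal_score`, `label`.
#' @export
label_clusters <- function(expr, clusters, signature, nontype_threshold = 0) {
  check_expression(expr)
  assignment <- if (inherits(clusters, "subtype_clusters")) clusters$assignment else clusters
  stopifnot(all(c("sample", "cluster") %in% names(assignment)))
  for (cls in subtype_classes) {
    if (!any(signature$class == cls)) abort(sprintf("signature has no %s genes", cls))
  }
  m <- expr_matrix(expr)
  panel_score <- function(cols, cls) {
    genes <- intersect(signature$gene[signature$class == cls], rownames(m))
    if (!length(genes)) abort(sprintf("no %s signature genes present in matrix", cls))
    mean(m[genes, cols, drop = FALSE])
  }
  out <- assignment |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      luminal_score = panel_score(sample, "luminal"),
      basal_score = panel_score(sample, "basal"),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = dplyr::case_when(
      luminal_score < nontype_threshold & basal_score < nontype_threshold ~ nontype_label,
      luminal_score >= basal_score ~ "luminal",
      TRUE ~ "basal"
    )) |>
    dplyr::arrange(cluster)
  log_stage("label_clusters", clusters = nrow(out),
            labels = paste(out$label, collapse = "/"))
  out
}

#' Per-sample subtype labels from cluster labelling
#'
#' Convenience join of a cluster assignment with its cluster-level labels.
#'
#' @param clusters A `subtype_clusters` object (or assignment tibble).
#' @param labelling Output of [label_clusters()].
#' @return A tibble with `sample`, `cluster`, `label`, `luminal_score`,
#'   `basal_score`.
#' @export
assign_subtypes <- function(clusters, labelling) {
  assignment <- if (inherits(clusters, "subtype_clusters")) clusters$assignment else clusters
  dplyr::left_join(assignment, labelling, by = "cluster") |>
    dplyr::select(sample, cluster, label, luminal_score, basal_score)
}
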
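#' Build per-class expression centroids with pooled within-class spread
#'
#' The centroid of class k at gene g is the mean centred-log2 expression over
#' that class's training samples. The per-gene pooled standard deviation is
#' `sqrt(sum_k sum_{i in k} (x_gi - centroid_kg)^2 / (n - K))`, and the
#' stabiliser `s0` is the median pooled sd across genes (fallback 1e-6 when
#' every pooled sd is zero), preventing near-zero-variance genes from
#' dominating the standardized discriminant.
#'
#' @param expr Centred log2 expression tibble.
#' @param labels Tibble with `sample` and `class` columns; every class needs at
#'   least one sample, and `n > K` overall so the pooled sd is defined.
#' @param genes Optional gene subset (order preserved); defaults to all genes.
#' @param selection Optional gene-selection table attached to the model (used
#'   by [train_clanc()]).
#' @return An object of class `centroid_model`: `classes`, `genes`, `centroid`
#'   (class x gene matrix), `pooled_sd`, `s0`, `n_per_class`.
#' @export
build_centroids <- function(expr, labels, genes = NULL, selection = NULL) {
  check_expression(expr)
  stopifnot(all(c("sample", "class") %in% names(labels)))
  m <- expr_matrix(expr)
  missing_samples <- setdiff(labels$sample, colnames(m))
  if (length(missing_samples)) {
    abort(sprintf("labelled sample(s) absent from matrix: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, rownames(m))
    if (length(missing_genes)) {
      abort(sprintf("gene(s) absent from matrix: %s", paste(missing_genes, collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  classes <- unique(labels$class)
  n_per_class <- vapply(classes, function(k) sum(labels$class == k), integer(1))
  if (any(n_per_class == 0L)) {
    abort(sprintf("class with 0 samples: %s", paste(classes[n_per_class == 0], collapse = ", ")))
  }
  n <- sum(n_per_class)
  K <- length(classes)
  if (n <= K) abort(sprintf("pooled sd undefined: n = %d samples <= K = %d classes", n, K))

  centroid <- t(vapply(classes, function(k) {
    rowMeans(m[, labels$sample[labels$class == k], drop = FALSE])
  }, numeric(nrow(m))))
  rownames(centroid) <- classes

  ss <- rowSums(vapply(classes, function(k) {
    cols <- labels$sample[labels$class == k]
    rowSums((m[, cols, drop = FALSE] - centroid[k, ])^2)
  }, numeric(nrow(m))))
  pooled_sd <- sqrt(ss / (n - K))
  s0 <- stats::median(pooled_sd)
  if (s0 == 0) s0 <- 1e-6

  log_stage("build_centroids", classes = K, genes = nrow(m), n_train = n)
  structure(list(classes = classes, genes = rownames(m), centroid = centroid,
                 pooled_sd = stats::setNames(pooled_sd, rownames(m)), s0 = s0,
                 n_per_class = n_per_class, selection = selection),
            class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf("<centroid_model> %d classes (%s), %d genes, s0 = %.4g\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$genes), x$s0))
  invisible(x)
}

#' @rdname build_centroids
#' @param x A `centroid_model`.
#' @param ... Unused.
#' @export
tidy.centroid_model <- function(x, ...) {
  out <- tibble(gene = rep(x$genes, times = length(x$classes)),
                class = rep(x$classes, each = length(x$genes)),
                centroid = as.vector(t(x$centroid)),
                pooled_sd = rep(unname(x$pooled_sd), times = length(x$classes)))
  if (!is.null(x$selection)) {
    out <- dplyr::left_join(out,
                            dplyr::select(x$selection, gene, selected_for = class, d),
                            by = "gene")
  }
  out
}

#' @rdname build_centroids
#' @export
glance.centroid_model <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_genes = length(x$genes), s0 = x$s0,
         n_train = sum(x$n_per_class))
}

#' ClaNC-style balanced gene selection for a nearest-centroid classifier
#'
#' For every candidate gene g and class k the class-specific standardized
#' statistic is `d_gk = (mean_gk - mean_g) / (m_k * (pooled_sd_g + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`. Each gene is assigned to the class maximizing
#' `|d_gk|` (ties in `|d|`, which are systematic for balanced two-class
#' designs, break toward positive `d`: a gene discriminates the class it is
#' overexpressed in); the top `ceiling(n_total / K)` genes per class by `|d|`
#' are taken (balanced allocation, ClaNC's default), any shortfall from a
#' class with too few assigned genes is filled with the best remaining genes,
#' and the set is trimmed back to `n_total` by dropping the smallest `|d|`.
#' Remaining ties break by gene id, making the selection deterministic.
#'
#' @param expr Centred log2 expression tibble.
#' @param labels Tibble with `sample`, `class`; every class needs >= 2 samples.
#' @param n_total Total number of genes to select (>= number of classes).
#' @param candidates Optional candidate gene universe (e.g. the signature gene
#'   list); defaults to all genes in the matrix.
#' @return A tibble, ordered by decreasing `|d|`, with columns `gene`, `class`
#'   (the class the gene discriminates), `d`, `abs_d`.
#' @export
select_clanc_genes <- function(expr, labels, n_total = 50, candidates = NULL) {
  check_expression(expr)
  m <- expr_matrix(expr)
  if (!is.null(candidates)) {
    cand <- intersect(candidates, rownames(m))
    if (!length(cand)) abort("no candidate genes present in matrix")
    m <- m[cand, , drop = FALSE]
  }
  classes <- unique(labels$class)
  K <- length(classes)
  if (n_total < K) abort(sprintf("n_total = %d < number of classes (%d)", n_total, K))
  n_per_class <- vapply(classes, function(k) sum(labels$class == k), integer(1))
  if (any(n_per_class < 2L)) {
    abort(sprintf("class with < 2 samples: %s",
                  paste(classes[n_per_class < 2], collapse = ", ")))
  }
  n <- sum(n_per_class)

  model <- build_centroids(expr_tibble(m), labels)
  overall <- rowMeans(m[, labels$sample, drop = FALSE])
  denom <- model$pooled_sd + model$s0
  d <- vapply(classes, function(k) {
    m_k <- sqrt(1 / n_per_class[[k]] - 1 / n)
    (model$centroid[k, ] - overall) / (m_k * denom)
  }, numeric(nrow(m)))
  colnames(d) <- classes

  # for balanced two-class designs |d| is identical across classes for every
  # gene, so |d| ties break toward positive d: a gene discriminates the class
  # it is overexpressed in
  pick_class <- function(dg) {
    a <- abs(dg)
    cand <- which(a >= max(a) - 1e-9 * max(max(a), 1))
    cand[which.max(dg[cand])]
  }
  best_class <- classes[apply(d, 1, pick_class)]
  stats <- tibble(gene = rownames(m), class = best_class,
                  d = d[cbind(seq_len(nrow(m)), match(best_class, classes))]) |>
    dplyr::mutate(abs_d = abs(d)) |>
    dplyr::arrange(dplyr::desc(abs_d), gene)

  if (nrow(stats) < n_total) {
    warn(sprintf("only %d candidate genes available (< n_total = %d); using all",
                 nrow(stats), n_total))
    return(stats)
  }
  quota <- ceiling(n_total / K)
  picked <- stats |>
    dplyr::group_by(class) |>
    dplyr::slice_head(n = quota) |>
    dplyr::ungroup()
  # a class short of its quota leaves a gap: fill with the best remaining
  # genes regardless of class, then trim the smallest |d| back to n_total
  if (nrow(picked) < n_total) {
    rest <- dplyr::filter(stats, !gene %in% picked$gene)
    picked <- dplyr::bind_rows(picked, utils::head(rest, n_total - nrow(picked)))
  }
  picked <- dplyr::arrange(picked, dplyr::desc(abs_d), gene)
  if (nrow(picked) > n_total) picked <- picked[seq_len(n_total), ]
  log_stage("select_clanc_genes", candidates = nrow(stats), selected = nrow(picked),
            per_class = paste(table(picked$class), collapse = "/"))
  picked
}

#' Train a ClaNC nearest-centroid subtype classifier
#'
#' Selects `n_genes` discriminant genes with [select_clanc_genes()] (restricted
#' to the signature when given) and builds the centroid model on them.
#'
#' @inheritParams select_clanc_genes
#' @param signature Optional signature tibble (`gene`, `class`) giving the
#'   candidate gene universe.
#' @param n_genes Total genes in the predictor (default 50).
#' @return A `centroid_model` restricted to the selected genes, with the
#'   selection table attached.
#' @export
train_clanc <- function(expr, labels, signature = NULL, n_genes = 50) {
  selection <- select_clanc_genes(expr, labels, n_total = n_genes,
                                  candidates = signature$gene)
  build_centroids(expr, labels, genes = selection$gene, selection = selection)
}

#' Spearman concordance between two models' class centroids
#'
#' Correlates the centroid vector of one class in model A with one class in
#' model B over the intersection of the two models' gene sets. The correlation
#' is Spearman's rho with average ranks for ties; the p-value uses the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df, or an
#' exact permutation p (all `n!` rank permutations) for `n <= 9`.
#'
#' @param model_a,model_b `centroid_model` objects.
#' @param class_a,class_b Class names to compare (default `"luminal"` in
#'   both).
#' @param exact Use the exact permutation p-value; defaults to `TRUE` when the
#'   gene intersection has at most 9 genes.
#' @return A one-row tibble: `class_a`, `class_b`, `rho`, `p`, `n_genes`,
#'   `method`.
#' @export
correlate_centroids <- function(model_a, model_b, class_a = "luminal",
                                class_b = class_a, exact = NULL) {
  stopifnot(inherits(model_a, "centroid_model"), inherits(model_b, "centroid_model"))
  if (!class_a %in% model_a$classes) abort(sprintf("model_a has no class '%s'", class_a))
  if (!class_b %in% model_b$classes) abort(sprintf("model_b has no class '%s'", class_b))
  shared <- intersect(model_a$genes, model_b$genes)
  n <- length(shared)
  if (n < 3L) abort(sprintf("only %d shared gene(s) between models (need >= 3)", n))
  x <- model_a$centroid[class_a, shared]
  y <- model_b$centroid[class_b, shared]
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    abort("zero rank variance in a centroid vector")
  }
  rho <- stats::cor(rx, ry)
  exact <- exact %||% (n <= 9L)
  if (exact && n <= 9L) {
    perms <- all_permutations(n)
    null_rho <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  tibble(class_a = class_a, class_b = class_b, rho = rho, p = p,
         n_genes = n, method = method)
}

# All permutations of 1..n as an n! x n matrix (used only for n <= 9).
#' @noRd
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}
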
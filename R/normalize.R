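#' Median-of-ratios library-size normalization
#'
#' Computes per-sample size factors against a per-gene geometric-mean reference
#' (the median of the geometric means, as used for RNA-seq fragment counts):
#' for gene g, `ref_g` is the geometric mean of its counts across samples
#' (genes with any zero count are excluded from the median but retained in the
#' output); the factor of sample j is the median over included genes of
#' `count_gj / ref_g`; normalized values are `count_gj / factor_j`.
#'
#' @param counts Expression tibble of raw non-negative counts (gene column
#'   first).
#' @return A list with `normalized` (counts-scale expression tibble) and
#'   `size_factors` (tibble with `sample`, `size_factor`).
#' @export
#' @examples
#' counts <- tibble::tibble(gene = c("A", "B"), S1 = c(2, 8), S2 = c(4, 16))
#' size_factor_normalize(counts)$size_factors
size_factor_normalize <- function(counts) {
  check_expression(counts, "counts")
  m <- expr_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  usable <- rowSums(m > 0) == ncol(m)
  if (!any(usable)) abort("cannot form reference: no gene has nonzero counts in all samples")
  ref <- exp(rowMeans(log(m[usable, , drop = FALSE])))
  factors <- apply(m[usable, , drop = FALSE] / ref, 2, stats::median)
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    abort("degenerate size factor (non-finite or <= 0)")
  }
  norm <- sweep(m, 2, factors, "/")
  log_stage("size_factor_normalize", genes = nrow(m), samples = ncol(m),
            reference_genes = sum(usable))
  list(normalized = expr_tibble(norm, scale_tag = "counts"),
       size_factors = tibble(sample = colnames(m), size_factor = unname(factors)))
}

#' Prepare an expression table for subtype analysis
#'
#' Restricts the matrix to signature genes present in the data (absent
#' signature genes are logged, not fatal), log2-transforms counts-scale input
#' with an offset, median-centres each gene across samples, and optionally
#' drops low-variance genes.
#'
#' @param expr Expression tibble (counts or log2 scale; see the `scale_tag`
#'   attribute set by [read_expression_matrix()]).
#' @param signature Signature tibble (`gene`, `class`) to restrict to, or
#'   `NULL` to keep all genes.
#' @param log_offset Offset used in `log2(x + log_offset)` for counts input.
#' @param min_variance_percentile Genes with variance below this percentile
#'   (0-100) of the per-gene variances are dropped; 0 keeps everything.
#' @param center `NULL` to centre each gene on its own median across samples
#'   (the default, for cohort discovery), or a named numeric vector of
#'   per-gene reference values — typically the training cohort's medians from
#'   the `gene_centers` attribute of its preprocessed table — so that query
#'   samples are placed on the training scale before classification.
#' @return A median-centred log2-scale expression tibble (`scale_tag` =
#'   `"log2"`, `centered` attribute `TRUE`, `gene_centers` attribute holding
#'   the values subtracted).
#' @export
preprocess_expression <- function(expr, signature = NULL, log_offset = 1,
                                  min_variance_percentile = 0, center = NULL) {
  check_expression(expr)
  m <- expr_matrix(expr)
  if (identical(expr_scale(expr), "counts")) {
    m <- log2(m + log_offset)
  }
  if (!is.null(signature)) {
    present <- intersect(signature$gene, rownames(m))
    absent <- setdiff(signature$gene, rownames(m))
    if (length(absent)) {
      log_stage("preprocess_expression",
                note = sprintf("%d signature gene(s) absent: %s", length(absent),
                               paste(absent, collapse = ", ")))
      warn(sprintf("%d signature gene(s) absent from matrix: %s",
                   length(absent), paste(absent, collapse = ", ")))
    }
    if (length(present) < 2L) abort("fewer than 2 signature genes present in matrix")
    m <- m[present, , drop = FALSE]
  }
  if (is.null(center)) {
    med <- apply(m, 1, stats::median)
  } else {
    missing_ref <- setdiff(rownames(m), names(center))
    if (length(missing_ref)) {
      abort(sprintf("no reference centre for gene(s): %s",
                    paste(missing_ref, collapse = ", ")))
    }
    med <- center[rownames(m)]
  }
  m <- m - med
  if (min_variance_percentile > 0) {
    v <- apply(m, 1, stats::var)
    keep <- v >= stats::quantile(v, min_variance_percentile / 100)
    m <- m[keep, , drop = FALSE]
  }
  log_stage("preprocess_expression", genes = nrow(m), samples = ncol(m))
  out <- expr_tibble(m, scale_tag = "log2")
  attr(out, "centered") <- TRUE
  attr(out, "gene_centers") <- med[rownames(m)]
  out
}
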
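#' Read a gene-by-sample expression table from TSV
#'
#' Expression tables are tab-separated with one header row: the first column
#' holds gene identifiers, every remaining column one sample. Values are either
#' raw non-negative counts (`scale_tag = "counts"`) or log2-scale expression
#' (`scale_tag = "log2"`); downstream functions use the tag to decide whether a
#' log transform is still needed. TSV (not CSV) avoids comma-containing gene
#' symbols.
#'
#' @param path Path to a TSV file.
#' @param scale_tag Declared scale of the values, `"log2"` or `"counts"`.
#' @return A tibble with a `gene` column followed by one numeric column per
#'   sample, carrying a `scale_tag` attribute. Row and column order are
#'   preserved from the file.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("gene\tS1\tS2\nGATA3\t5.0\t1.0", tf)
#' read_expression_matrix(tf, scale_tag = "log2")
read_expression_matrix <- function(path, scale_tag = c("log2", "counts")) {
  scale_tag <- arg_match(scale_tag)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort(sprintf("no genes in expression file '%s' (header only)", path))
  if (ncol(raw) < 2L) abort(sprintf("expression file '%s' has no sample columns", path))
  body <- raw[, -1, drop = FALSE]
  parsed <- suppressWarnings(lapply(body, as.numeric))
  for (j in seq_along(parsed)) {
    bad <- which(is.na(parsed[[j]]) & !is.na(body[[j]]))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at row %d (gene %s), column '%s' in '%s'",
                    body[[j]][bad[1]], bad[1], raw[[1]][bad[1]], colnames(body)[j], path))
    }
  }
  out <- tibble::as_tibble(c(list(gene = as.character(raw[[1]])), parsed))
  names(out) <- c("gene", colnames(body))
  check_expression(out)
  if (scale_tag == "counts") {
    m <- expr_matrix(out)
    if (any(m < 0, na.rm = TRUE)) {
      idx <- which(m < 0, arr.ind = TRUE)[1, ]
      abort(sprintf("negative count %.6g for gene %s, sample %s (scale_tag = 'counts')",
                    m[idx[1], idx[2]], rownames(m)[idx[1]], colnames(m)[idx[2]]))
    }
  }
  attr(out, "scale_tag") <- scale_tag
  log_stage("read_expression_matrix", genes = nrow(out), samples = ncol(out) - 1L,
            scale = scale_tag)
  out
}

#' Write an expression table to TSV
#'
#' Values are written at full decimal precision (up to 17 significant digits)
#' so a write/read round trip is bit-exact.
#'
#' @param expr Expression tibble (gene column first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  check_expression(expr)
  m <- expr_matrix(expr)
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 17, scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a luminal/basal gene signature from TSV
#'
#' A signature is a two-column table `(gene, class)` where the class is
#' `luminal` or `basal`; it is the gene universe to which clustering, centroid
#' construction and classifier gene selection are restricted.
#'
#' @param path Path to a two-column TSV without header.
#' @return A tibble with columns `gene` and `class` (lower-cased).
#' @export
read_gene_signature <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("gene", "class"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort(sprintf("empty signature file '%s'", path))
  out <- tibble(gene = as.character(raw$gene), class = tolower(as.character(raw$class)))
  bad <- setdiff(unique(out$class), subtype_classes)
  if (length(bad)) {
    abort(sprintf("unknown signature class label(s): %s (expected luminal/basal)",
                  paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(out$gene)) {
    abort(sprintf("duplicate gene(s) in signature: %s",
                  paste(unique(out$gene[duplicated(out$gene)]), collapse = ", ")))
  }
  log_stage("read_gene_signature", genes = nrow(out),
            luminal = sum(out$class == "luminal"), basal = sum(out$class == "basal"))
  out
}

#' Read a sample-to-group design table from TSV
#'
#' @param path Path to a two-column TSV without header: sample id, group label.
#' @return A tibble with columns `sample` and `group`.
#' @export
read_group_design <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("sample", "group"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort(sprintf("empty design file '%s'", path))
  if (anyDuplicated(raw$sample)) {
    abort(sprintf("duplicate sample(s) in design: %s",
                  paste(unique(raw$sample[duplicated(raw$sample)]), collapse = ", ")))
  }
  tibble(sample = as.character(raw$sample), group = as.character(raw$group))
}

# Check that every designed sample is a column of the expression table.
#' @noRd
check_design_against <- function(design, expr) {
  missing <- setdiff(design$sample, colnames(expr)[-1])
  if (length(missing)) {
    abort(sprintf("design sample(s) absent from expression table: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(design)
}
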
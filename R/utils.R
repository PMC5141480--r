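# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Convert a tidy expression table (first column = gene id, remaining columns =
# numeric sample values) into a genes x samples numeric matrix with rownames.
#' @noRd
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  genes <- as.character(expr[[1]])
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

# Inverse of expr_matrix(): matrix back to a tibble with a leading gene column.
#' @noRd
expr_tibble <- function(m, scale_tag = NULL) {
  out <- tibble::as_tibble(m, rownames = NA, .name_repair = "minimal")
  out <- tibble::add_column(out, gene = rownames(m), .before = 1)
  if (!is.null(scale_tag)) attr(out, "scale_tag") <- scale_tag
  out
}

# Scale tag of an expression table: explicit argument beats the attribute,
# which beats the declared default.
#' @noRd
expr_scale <- function(expr, default = "log2") {
  attr(expr, "scale_tag") %||% default
}

#' @noRd
check_expression <- function(expr, arg = "expr") {
  if (!is.data.frame(expr) || ncol(expr) < 2) {
    abort(sprintf("`%s` must be a data frame with a gene column and >= 1 sample column.", arg))
  }
  genes <- as.character(expr[[1]])
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene identifier(s): %s",
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  samples <- colnames(expr)[-1]
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample identifier(s): %s",
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  invisible(expr)
}

# Stage logging: input dimensions and parameters go to stderr so result tables
# stay clean on stdout.
#' @noRd
log_stage <- function(stage, ...) {
  info <- c(...)
  msg <- if (length(info)) {
    paste0(stage, ": ", paste(names(info), unname(info), sep = "=", collapse = ", "))
  } else {
    stage
  }
  message("[subtypekit] ", msg)
}

# Deterministic derived seeds: one base seed fans out to independent streams
# without the streams colliding; kept inside 32-bit integer range.
#' @noRd
derive_seed <- function(seed, stream, index = 0L) {
  (as.integer(seed) + 104729L * as.integer(stream) + 131L * as.integer(index)) %% 2147483647L
}

#' @noRd
subtype_classes <- c("luminal", "basal")

#' @noRd
nontype_label <- "non-type"
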
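# Small in-code fixtures shared across test files.

expr_fixture <- function(m, scale_tag = "log2") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, gene = rownames(m), .before = 1)
  attr(out, "scale_tag") <- scale_tag
  out
}

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# Two-class training fixture with hand-set, well-separated values.
toy_two_class <- function() {
  m <- rbind(
    g1 = c(2, 2.2, -2, -2.1),
    g2 = c(-1, -1.2, 1, 1.1),
    g3 = c(0.1, -0.1, 0.05, -0.05)
  )
  colnames(m) <- c("A1", "A2", "B1", "B2")
  list(expr = expr_fixture(m),
       labels = tibble::tibble(sample = colnames(m),
                               class = c("luminal", "luminal", "basal", "basal")),
       matrix = m)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
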
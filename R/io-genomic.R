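#' Read genomic intervals from a BED file
#'
#' BED coordinates are 0-based half-open (`start` inclusive, `end` exclusive)
#' and are kept that way throughout the package; any 1-based display is
#' labelled. BED3 and wider dialects are accepted; columns beyond name/score
#' are ignored with a logged note (tolerant-reader convention).
#'
#' @param path Path to a BED3+ file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name` and `score`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (!length(lines)) abort(sprintf("no intervals in BED file '%s'", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_seen <- lengths(fields)
  if (any(ncol_seen < 3L)) {
    abort(sprintf("line %d of '%s' has fewer than 3 BED columns", which(ncol_seen < 3L)[1], path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start_chr <- vapply(fields, `[[`, character(1), 2L)
  end_chr <- vapply(fields, `[[`, character(1), 3L)
  parse_coord <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad)) {
      abort(sprintf("non-integer %s coordinate '%s' at line %d of '%s'",
                    what, x[bad[1]], bad[1], path))
    }
    v
  }
  start <- parse_coord(start_chr, "start")
  end <- parse_coord(end_chr, "end")
  if (any(start < 0)) abort(sprintf("negative start at line %d of '%s'", which(start < 0)[1], path))
  if (any(start >= end)) {
    abort(sprintf("empty or inverted interval (start >= end) at line %d of '%s'",
                  which(start >= end)[1], path))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (max(ncol_seen) >= 4L) {
    out$name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_,
                       character(1))
  }
  if (max(ncol_seen) >= 5L) {
    out$score <- suppressWarnings(
      vapply(fields, function(f) if (length(f) >= 5L) as.numeric(f[[5L]]) else NA_real_,
             numeric(1)))
  }
  if (max(ncol_seen) > 6L) {
    log_stage("read_bed", note = sprintf("ignoring columns beyond 6 (%d seen)", max(ncol_seen)))
  }
  log_stage("read_bed", intervals = nrow(out), chroms = length(unique(out$chrom)))
  out
}

#' Write genomic intervals to a BED file
#'
#' @param peaks Interval tibble with `chrom`, `start`, `end` and optional
#'   `name`, `score` columns (0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  cols <- list(peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
               format(peaks$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(peaks)) {
    cols <- c(cols, list(ifelse(is.na(peaks$name), ".", peaks$name)))
    if ("score" %in% names(peaks)) {
      cols <- c(cols, list(ifelse(is.na(peaks$score), ".",
                                  format(peaks$score, digits = 17, scientific = FALSE,
                                         trim = TRUE))))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Record ids are the token before the first whitespace in the header;
#' sequences are returned upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA record id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  empty <- which(!nzchar(seqs))
  if (length(empty)) abort(sprintf("empty sequence for FASTA record '%s'", ids[empty[1]]))
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  set <- Biostrings::DNAStringSet(sequences)
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param counts 4 x L non-negative matrix of per-position base counts, rows in
#'   A, C, G, T order.
#' @param background Length-4 base background probabilities (must sum to 1
#'   within 1e-9); defaults to uniform.
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(motif_id, counts, background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) abort("PWM counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) abort("PWM must have length >= 1")
  if (any(counts < 0)) abort(sprintf("negative count in PWM '%s'", motif_id))
  if (abs(sum(background) - 1) > 1e-9) abort("PWM background must sum to 1 (tolerance 1e-9)")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = as.character(motif_id), counts = counts,
                 background = stats::setNames(as.numeric(background), c("A", "C", "G", "T"))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (length %d, consensus %s)\n",
              x$motif_id, ncol(x$counts), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-count base per position)
#'
#' @param pwm A `pwm` object.
#' @return A character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$counts)[apply(pwm$counts, 2, which.max)], collapse = "")
}

#' Read position frequency matrices in JASPAR-style format
#'
#' Each block is a `>id` header followed by four equal-length rows of counts in
#' A, C, G, T order; rows may use the bracketed JASPAR layout
#' (`A [ 8 0 ... ]`) or be bare numbers.
#'
#' @param path Path to a JASPAR-style PFM file.
#' @param background Background probabilities applied to every motif.
#' @return A list of `pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) abort(sprintf("no motif blocks in '%s'", path))
  ends <- c(heads[-1] - 1L, length(lines))
  pwms <- lapply(seq_along(heads), function(i) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- lines[(heads[i] + 1L):ends[i]]
    if (length(body) != 4L) {
      abort(sprintf("motif '%s' has %d count rows (expected 4: A, C, G, T)", id, length(body)))
    }
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*\\[|\\]$", "", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (anyNA(vals)) abort(sprintf("non-numeric count in motif '%s'", id))
      vals
    })
    if (length(unique(lengths(rows))) != 1L) {
      abort(sprintf("unequal row lengths in motif '%s'", id))
    }
    new_pwm(id, do.call(rbind, rows), background)
  })
  log_stage("read_jaspar", motifs = length(pwms))
  pwms
}
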
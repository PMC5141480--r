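# Interval <-> GRanges conversion. Interval tibbles are BED-style 0-based
# half-open; GRanges is 1-based closed, hence the +1 on start.
#' @noRd
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
}

#' @noRd
granges_to_peaks <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1,
         end = GenomicRanges::end(gr))
}

#' Consensus peaks shared between two ChIP-seq replicates
#'
#' Pools the two interval sets and merges them into maximal runs of
#' chained-overlapping intervals; a run is emitted as a consensus region when
#' it contains at least one replicate-1 and one replicate-2 interval that
#' mutually overlap by at least `min_overlap_bp` bp. The consensus span is the
#' union of the run's intervals. The number of consensus regions is the
#' "shared sites" count. The operation is symmetric in its arguments.
#'
#' @param rep1,rep2 Interval tibbles (`chrom`, `start`, `end`; 0-based
#'   half-open), e.g. from [read_bed()].
#' @param min_overlap_bp Minimum mutual overlap in bp (default 1).
#' @return An interval tibble of consensus regions with a `name` column
#'   (`consensus_00001`, ...).
#' @export
#' @examples
#' r1 <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' r2 <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' intersect_replicates(r1, r2)
intersect_replicates <- function(rep1, rep2, min_overlap_bp = 1L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(rep1)),
            all(c("chrom", "start", "end") %in% names(rep2)))
  only1 <- setdiff(unique(rep1$chrom), unique(rep2$chrom))
  only2 <- setdiff(unique(rep2$chrom), unique(rep1$chrom))
  if (length(only1) || length(only2)) {
    warn(sprintf("chromosome(s) present in one replicate only: %s",
                 paste(c(only1, only2), collapse = ", ")))
  }
  gr1 <- peaks_to_granges(rep1)
  gr2 <- peaks_to_granges(rep2)
  pooled <- suppressWarnings(c(gr1, gr2))
  # min.gapwidth = 0: merge only genuinely overlapping intervals, not bookended
  blocks <- GenomicRanges::reduce(pooled, min.gapwidth = 0L)
  has1 <- GenomicRanges::countOverlaps(blocks, gr1, minoverlap = min_overlap_bp) > 0
  has2 <- GenomicRanges::countOverlaps(blocks, gr2, minoverlap = min_overlap_bp) > 0
  # a run holding intervals from both replicates necessarily holds a directly
  # overlapping cross-replicate pair, but check it explicitly for the
  # configurable minimum overlap
  pairs <- GenomicRanges::findOverlaps(gr1, gr2, minoverlap = min_overlap_bp)
  anchor <- gr1[unique(S4Vectors::queryHits(pairs))]
  direct <- GenomicRanges::countOverlaps(blocks, anchor) > 0
  keep <- has1 & has2 & direct
  out <- granges_to_peaks(blocks[keep])
  out$name <- sprintf("consensus_%05d", seq_len(nrow(out)))
  log_stage("intersect_replicates", rep1 = nrow(rep1), rep2 = nrow(rep2),
            consensus = nrow(out))
  out
}

#' Extract fixed-width sequence windows around peak centres
#'
#' The window of a peak is `[centre - halfwidth, centre + halfwidth)` with
#' `centre = floor((start + end) / 2)`, clipped at chromosome ends (clipped
#' windows are shorter and logged). Sequences are returned upper-case.
#'
#' @param peaks Interval tibble (`chrom`, `start`, `end`).
#' @param genome Named character vector of chromosome sequences, e.g. from
#'   [read_fasta()].
#' @param halfwidth Window half-width in bp (default 100).
#' @return A tibble with `chrom`, `start`, `end` (window coordinates, 0-based
#'   half-open) and `seq`.
#' @export
extract_windows <- function(peaks, genome, halfwidth = 100L) {
  stopifnot(halfwidth >= 1L)
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing)) {
    abort(sprintf("chromosome(s) missing from genome: %s", paste(missing, collapse = ", ")))
  }
  centre <- floor((peaks$start + peaks$end) / 2)
  chrlen <- nchar(genome)[match(peaks$chrom, names(genome))]
  start <- pmax(centre - halfwidth, 0)
  end <- pmin(centre + halfwidth, chrlen)
  clipped <- sum(start != centre - halfwidth | end != centre + halfwidth)
  if (clipped > 0) {
    log_stage("extract_windows", note = sprintf("%d window(s) clipped at chromosome ends", clipped))
  }
  seqs <- toupper(substring(genome[match(peaks$chrom, names(genome))], start + 1, end))
  tibble(chrom = peaks$chrom, start = start, end = end, seq = unname(seqs))
}
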
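#' Simulate a replicate ChIP-seq peak experiment with planted motifs
#'
#' Generates a random genome (one chromosome), places non-overlapping binding
#' sites on it, and emits two replicate peak sets: `n_shared` sites appear in
#' both replicates (each replicate's interval jittered independently by at most
#' `jitter_max` bp) and `n_unique_each` sites are private to each replicate.
#' `n_background` additional intervals disjoint from all peaks serve as the
#' background set for enrichment testing. The motif consensus is planted (on a
#' random strand) at the centre of an exact quota of sites:
#' `round(fg_rate * n)` of the shared (and unique) sites and
#' `round(bg_rate * n)` of the background intervals. Quota sampling, rather
#' than Bernoulli draws, gives enrichment tests a deterministic ground truth.
#'
#' @param n_shared Number of binding sites present in both replicates.
#' @param n_unique_each Number of replicate-private sites per replicate.
#' @param genome_length Chromosome length in bp.
#' @param motif A [new_pwm()] object whose consensus is planted.
#' @param fg_rate Fraction of peak sites receiving a planted instance.
#' @param bg_rate Fraction of background intervals receiving a planted
#'   instance.
#' @param seed Integer seed.
#' @param n_background Number of background intervals (default `2 * n_shared`).
#' @param peak_width Width of every simulated interval in bp.
#' @param jitter_max Maximum absolute per-replicate jitter in bp.
#' @return A list of class `peak_experiment`: `rep1`, `rep2`, `background`
#'   (interval tibbles), `genome` (named character vector), `truth` (tibble
#'   with `site`, `kind`, `start`, `end`, `planted`, `strand`) and `motif_id`.
#' @export
simulate_peak_experiment <- function(n_shared, n_unique_each, genome_length, motif,
                                     fg_rate, bg_rate, seed,
                                     n_background = 2L * n_shared,
                                     peak_width = 200L, jitter_max = 10L) {
  stopifnot(inherits(motif, "pwm"), fg_rate >= 0, fg_rate <= 1,
            bg_rate >= 0, bg_rate <= 1, n_shared >= 0, n_unique_each >= 0,
            n_background >= 0, peak_width > ncol(motif$counts))
  n_sites <- n_shared + 2L * n_unique_each + n_background
  slot <- peak_width + 2L * jitter_max + 20L
  n_slots <- genome_length %/% slot
  if (n_slots < n_sites) {
    abort(sprintf("infeasible packing: %d sites need %d bp, genome is %d bp",
                  n_sites, n_sites * slot, genome_length))
  }
  set.seed(derive_seed(seed, 10L))
  genome <- paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
                  collapse = "")

  slots <- sort(sample.int(n_slots, n_sites))
  starts <- (slots - 1L) * slot + jitter_max  # room for jitter on both sides
  kind <- sample(c(rep("shared", n_shared), rep("unique1", n_unique_each),
                   rep("unique2", n_unique_each), rep("background", n_background)))

  plant_quota <- function(idx, rate) {
    k <- round(rate * length(idx))
    if (k == 0L) integer(0) else sample(idx, k)
  }
  peak_idx <- which(kind != "background")
  bg_idx <- which(kind == "background")
  planted_idx <- c(plant_quota(which(kind == "shared"), fg_rate),
                   plant_quota(which(kind == "unique1"), fg_rate),
                   plant_quota(which(kind == "unique2"), fg_rate),
                   plant_quota(bg_idx, bg_rate))

  consensus <- pwm_consensus(motif)
  w <- nchar(consensus)
  strand <- rep(NA_character_, n_sites)
  for (i in planted_idx) {
    strand[i] <- sample(c("+", "-"), 1L)
    ins <- if (strand[i] == "+") consensus else revcomp(consensus)
    # plant centred in the site so any window of halfwidth >= w/2 recovers it
    pos <- starts[i] + peak_width %/% 2L - w %/% 2L  # 0-based insert start
    substr(genome, pos + 1L, pos + w) <- ins
  }

  jitter <- function(n) sample(seq(-jitter_max, jitter_max), n, replace = TRUE)
  mk_peaks <- function(idx, jit, prefix) {
    tibble(chrom = "chr1", start = starts[idx] + jit, end = starts[idx] + jit + peak_width,
           name = sprintf("%s_%05d", prefix, seq_along(idx)))
  }
  rep1_idx <- which(kind %in% c("shared", "unique1"))
  rep2_idx <- which(kind %in% c("shared", "unique2"))
  rep1 <- mk_peaks(rep1_idx, jitter(length(rep1_idx)), "rep1")
  rep2 <- mk_peaks(rep2_idx, jitter(length(rep2_idx)), "rep2")
  background <- mk_peaks(bg_idx, 0L, "bg")

  truth <- tibble(site = sprintf("site_%05d", seq_len(n_sites)), kind = kind,
                  start = starts, end = starts + peak_width,
                  planted = seq_len(n_sites) %in% planted_idx, strand = strand)
  log_stage("simulate_peak_experiment", shared = n_shared, unique_each = n_unique_each,
            background = n_background, fg_rate = fg_rate, bg_rate = bg_rate, seed = seed)
  structure(list(rep1 = rep1, rep2 = rep2, background = background,
                 genome = c(chr1 = genome), truth = truth, motif_id = motif$motif_id),
            class = "peak_experiment")
}

# Reverse complement of an ACGTN string.
#' @noRd
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
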
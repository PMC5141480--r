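#' Scan parameters for PWM matching
#'
#' @param halfwidth Window half-width used when extracting sequences around
#'   peaks (bp; default 100).
#' @param score_threshold_rule `"fraction_of_max"` (threshold =
#'   `threshold_value` times the maximum achievable log-odds score) or
#'   `"logodds_absolute"` (threshold = `threshold_value` bits).
#' @param threshold_value Threshold parameter; for `fraction_of_max` it must
#'   lie in `(0, 1]` (default 0.8).
#' @param scan_both_strands Scan the reverse complement too (default `TRUE`).
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(halfwidth = 100L,
                        score_threshold_rule = c("fraction_of_max", "logodds_absolute"),
                        threshold_value = 0.8, scan_both_strands = TRUE) {
  score_threshold_rule <- arg_match(score_threshold_rule)
  stopifnot(halfwidth >= 1L)
  if (score_threshold_rule == "fraction_of_max" &&
      (threshold_value <= 0 || threshold_value > 1)) {
    abort("fraction_of_max threshold must lie in (0, 1]")
  }
  structure(list(halfwidth = as.integer(halfwidth),
                 score_threshold_rule = score_threshold_rule,
                 threshold_value = threshold_value,
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "scan_params")
}

# Log2-odds matrix of a PWM: pseudocount 0.5 added to every count before
# column normalization (avoids -Inf), then log2(prob / background). A fifth
# row handles N: the background-weighted average of the probability ratio is
# sum_b bg_b * p_b / bg_b = 1, so N contributes exactly 0 bits.
#' @noRd
pwm_logodds <- function(pwm, pseudocount = 0.5) {
  cnt <- pwm$counts + pseudocount
  probs <- sweep(cnt, 2, colSums(cnt), "/")
  lo <- log2(probs / pwm$background)
  rbind(lo, N = 0)
}

#' @noRd
encode_seq <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  codes <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(codes)) {
    abort(sprintf("invalid character '%s' in sequence", chars[which(is.na(codes))[1]]))
  }
  codes
}

# complement of integer-coded bases; N maps to itself
#' @noRd
complement_codes <- function(codes) c(4L, 3L, 2L, 1L, 5L)[codes]

# Best log-odds score over all offsets of one strand; returns c(score, offset).
#' @noRd
best_scan <- function(codes, lo) {
  w <- ncol(lo)
  n_off <- length(codes) - w + 1L
  if (n_off < 1L) return(c(-Inf, NA))
  score <- numeric(n_off)
  for (j in seq_len(w)) {
    score <- score + lo[cbind(codes[j:(j + n_off - 1L)], j)]
  }
  i <- which.max(score)
  c(score[i], i)
}

#' Scan a sequence with a position weight matrix
#'
#' Scores every offset with the log2-odds of the pseudocounted PWM against its
#' background (both strands when flagged); the sequence carries a hit when the
#' best score reaches the threshold. Ambiguous bases (`N`) contribute 0 bits.
#' A sequence shorter than the motif is a no-hit, not an error.
#'
#' @param sequence Nucleotide string (A/C/G/T/N).
#' @param pwm A [new_pwm()] object.
#' @param params A [scan_params()] object.
#' @return A one-row tibble: `motif_id`, `hit`, `best_score`, `best_pos`
#'   (1-based offset of the match start on the forward strand), `strand`,
#'   `threshold`, `max_score`.
#' @export
scan_pwm <- function(sequence, pwm, params = scan_params()) {
  stopifnot(inherits(pwm, "pwm"), inherits(params, "scan_params"))
  lo <- pwm_logodds(pwm)
  max_score <- sum(apply(lo[1:4, , drop = FALSE], 2, max))
  threshold <- if (params$score_threshold_rule == "fraction_of_max") {
    params$threshold_value * max_score
  } else {
    params$threshold_value
  }
  if (!nzchar(sequence)) {
    return(tibble(motif_id = pwm$motif_id, hit = FALSE, best_score = -Inf,
                  best_pos = NA_integer_, strand = NA_character_,
                  threshold = threshold, max_score = max_score))
  }
  codes <- encode_seq(sequence)
  w <- ncol(pwm$counts)
  fwd <- best_scan(codes, lo)
  best <- fwd[1]
  pos <- fwd[2]
  strand <- "+"
  if (params$scan_both_strands) {
    rc <- rev(complement_codes(codes))
    rev_hit <- best_scan(rc, lo)
    if (rev_hit[1] > best) {
      best <- rev_hit[1]
      # offset on the reverse complement maps back to the forward coordinates
      pos <- length(codes) - w + 2L - rev_hit[2]
      strand <- "-"
    }
  }
  if (!is.finite(best)) {
    return(tibble(motif_id = pwm$motif_id, hit = FALSE, best_score = -Inf,
                  best_pos = NA_integer_, strand = NA_character_,
                  threshold = threshold, max_score = max_score))
  }
  tibble(motif_id = pwm$motif_id, hit = best >= threshold - 1e-9, best_score = best,
         best_pos = as.integer(pos), strand = strand,
         threshold = threshold, max_score = max_score)
}

# Hit flags of one PWM over pre-encoded sequences (fast path for enrichment).
#' @noRd
scan_hits <- function(codes_list, rc_list, pwm, params) {
  lo <- pwm_logodds(pwm)
  max_score <- sum(apply(lo[1:4, , drop = FALSE], 2, max))
  threshold <- if (params$score_threshold_rule == "fraction_of_max") {
    params$threshold_value * max_score
  } else {
    params$threshold_value
  }
  w <- ncol(pwm$counts)
  vapply(seq_along(codes_list), function(i) {
    if (length(codes_list[[i]]) < w) return(NA)
    best <- best_scan(codes_list[[i]], lo)[1]
    if (params$scan_both_strands && best < threshold) {
      best <- max(best, best_scan(rc_list[[i]], lo)[1])
    }
    best >= threshold - 1e-9
  }, logical(1))
}

#' Motif enrichment in foreground vs background sequences
#'
#' Counts, per motif, the number of foreground and background sequences
#' containing at least one hit (binary per sequence, matching "% of sites
#' associated with a motif" semantics) and tests enrichment with a one-sided
#' Fisher exact test (alternative: foreground proportion greater), followed by
#' BH adjustment across motifs. A motif longer than every sequence yields an
#' `NA` row that is excluded from the adjustment.
#'
#' @param foreground,background Character vectors of sequences (e.g. the `seq`
#'   column of [extract_windows()]).
#' @param pwms A list of [new_pwm()] objects.
#' @param params A [scan_params()] object.
#' @param q_cutoff Significance cutoff on the BH-adjusted q (default 0.05).
#' @return A tibble with one row per motif: `motif_id`, `fg_hits`, `fg_total`,
#'   `bg_hits`, `bg_total`, `fg_pct`, `bg_pct`, `p`, `q`, `significant`.
#' @export
motif_enrichment <- function(foreground, background, pwms, params = scan_params(),
                             q_cutoff = 0.05) {
  if (!length(foreground) || !length(background)) {
    abort("foreground and background sequence lists must be non-empty")
  }
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  fg_codes <- lapply(foreground, encode_seq)
  bg_codes <- lapply(background, encode_seq)
  fg_rc <- lapply(fg_codes, function(x) rev(complement_codes(x)))
  bg_rc <- lapply(bg_codes, function(x) rev(complement_codes(x)))
  fg_total <- length(foreground)
  bg_total <- length(background)

  rows <- purrr::map(pwms, function(pwm) {
    fg <- scan_hits(fg_codes, fg_rc, pwm, params)
    bg <- scan_hits(bg_codes, bg_rc, pwm, params)
    if (all(is.na(fg)) && all(is.na(bg))) {
      return(tibble(motif_id = pwm$motif_id, fg_hits = NA_integer_, fg_total = fg_total,
                    bg_hits = NA_integer_, bg_total = bg_total,
                    fg_pct = NA_real_, bg_pct = NA_real_, p = NA_real_))
    }
    fg_hits <- sum(fg, na.rm = TRUE)
    bg_hits <- sum(bg, na.rm = TRUE)
    tab <- matrix(c(fg_hits, fg_total - fg_hits, bg_hits, bg_total - bg_hits), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    tibble(motif_id = pwm$motif_id, fg_hits = as.integer(fg_hits), fg_total = fg_total,
           bg_hits = as.integer(bg_hits), bg_total = bg_total,
           fg_pct = 100 * fg_hits / fg_total, bg_pct = 100 * bg_hits / bg_total, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- adjust_bh(out$p[ok])
  out$significant <- !is.na(out$q) & out$q < q_cutoff
  log_stage("motif_enrichment", motifs = nrow(out), fg = fg_total, bg = bg_total,
            significant = sum(out$significant))
  out
}

#' Dinucleotide-preserving shuffle of sequences
#'
#' Seeded background construction for motif enrichment: each sequence is
#' shuffled so that its dinucleotide counts are preserved, by walking a random
#' Euler path on the dinucleotide transition graph.
#'
#' @param sequences Character vector of sequences.
#' @param seed Integer seed.
#' @return A character vector of shuffled sequences.
#' @export
shuffle_dinucleotide <- function(sequences, seed = 1L) {
  set.seed(derive_seed(seed, 20L))
  vapply(sequences, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n < 3L) return(s)
    # successor lists of the dinucleotide walk, each shuffled except that the
    # last exit of each vertex is forced onto an arborescence into the end
    # vertex, which guarantees the walk consumes every edge (Euler path)
    succ <- split(chars[-1], chars[-n])
    verts <- names(succ)
    last <- chars[n]
    # random arborescence toward `last` over the vertices reachable in the walk
    repeat {
      arrow <- vapply(verts, function(v) sample(succ[[v]], 1L), character(1))
      # follow arrows from every vertex; all must reach `last`
      reaches <- vapply(verts, function(v) {
        seen <- character(0)
        while (v != last && !(v %in% seen)) {
          seen <- c(seen, v)
          v <- arrow[[v]]
        }
        v == last
      }, logical(1))
      if (all(reaches | verts == last)) break
    }
    shuffled <- lapply(verts, function(v) {
      rest <- succ[[v]]
      if (v != last) {
        drop <- match(arrow[[v]], rest)
        rest <- rest[-drop]
      }
      c(sample(rest), if (v != last) arrow[[v]])
    })
    names(shuffled) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1] <- chars[1]
    v <- chars[1]
    for (i in 2:n) {
      nxt <- shuffled[[v]][ptr[[v]]]
      ptr[[v]] <- ptr[[v]] + 1L
      out[i] <- nxt
      v <- nxt
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
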
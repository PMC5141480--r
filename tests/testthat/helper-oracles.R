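# Independent brute-force oracles. Each is a direct, unoptimised evaluation of
# the defining formula, kept free of any package internals so it can stand as
# an independent reference for the implementation.

# BH step-up by direct evaluation of q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- sapply(seq_len(m), function(i) {
    min(sapply(i:m, function(j) min(p[o][j] * m / j, 1)))
  })
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# One-sided (greater) Fisher p by hypergeometric tail enumeration.
oracle_fisher_greater <- function(fg_hits, fg_total, bg_hits, bg_total) {
  K <- fg_hits + bg_hits        # total hits drawn
  N <- fg_total + bg_total
  ks <- fg_hits:min(K, fg_total)
  sum(choose(fg_total, ks) * choose(bg_total, K - ks)) / choose(N, K)
}

# Median-of-ratios size factors by direct formula evaluation.
oracle_size_factors <- function(m) {
  usable <- apply(m, 1, function(r) all(r > 0))
  ref <- exp(rowMeans(log(m[usable, , drop = FALSE])))
  apply(m[usable, , drop = FALSE], 2, function(col) median(col / ref))
}

# Pooled two-sample t per gene, textbook formula.
oracle_pooled_t <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  t(sapply(seq_len(nrow(x1)), function(g) {
    m1 <- mean(x1[g, ]); m2 <- mean(x2[g, ])
    sp2 <- (sum((x1[g, ] - m1)^2) + sum((x2[g, ] - m2)^2)) / (n1 + n2 - 2)
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    c(t = tval, p = 2 * pt(-abs(tval), df = n1 + n2 - 2))
  }))
}

# ClaNC selection statistics and balanced pick by literal rule application.
oracle_clanc_select <- function(m, classes, n_total) {
  cls <- unique(classes)
  K <- length(cls)
  n <- length(classes)
  nk <- sapply(cls, function(k) sum(classes == k))
  overall <- rowMeans(m)
  cent <- sapply(cls, function(k) rowMeans(m[, classes == k, drop = FALSE]))
  ss <- rowSums(sapply(cls, function(k) {
    rowSums((m[, classes == k, drop = FALSE] - cent[, k])^2)
  }))
  pooled_sd <- sqrt(ss / (n - K))
  s0 <- median(pooled_sd); if (s0 == 0) s0 <- 1e-6
  d <- sapply(cls, function(k) {
    (cent[, k] - overall) / (sqrt(1 / nk[[k]] - 1 / n) * (pooled_sd + s0))
  })
  best <- apply(d, 1, function(dg) {
    a <- abs(dg)
    cand <- which(a >= max(a) - 1e-9 * max(max(a), 1))
    cand[which.max(dg[cand])]
  })
  df <- data.frame(gene = rownames(m), class = cls[best],
                   d = d[cbind(seq_len(nrow(m)), best)], stringsAsFactors = FALSE)
  df$abs_d <- abs(df$d)
  df <- df[order(-df$abs_d, df$gene), ]
  quota <- ceiling(n_total / K)
  picked <- do.call(rbind, lapply(cls, function(k) head(df[df$class == k, ], quota)))
  if (nrow(picked) < n_total) {
    rest <- df[!df$gene %in% picked$gene, ]
    picked <- rbind(picked, head(rest, n_total - nrow(picked)))
  }
  picked <- picked[order(-picked$abs_d, picked$gene), ]
  head(picked, n_total)
}

# Standardized nearest-centroid distances by explicit per-gene summation.
oracle_classify <- function(x, centroid, pooled_sd, s0) {
  sapply(rownames(centroid), function(k) {
    sum(((x - centroid[k, ]) / (pooled_sd + s0))^2)
  })
}

# All-pairs interval consensus: merge chained overlaps in the pooled set, keep
# runs holding a directly-overlapping cross-replicate pair, span = run union.
oracle_intersect <- function(rep1, rep2) {
  pool <- rbind(cbind(rep1[c("chrom", "start", "end")], src = 1),
                cbind(rep2[c("chrom", "start", "end")], src = 2))
  out <- NULL
  for (ch in unique(pool$chrom)) {
    p <- pool[pool$chrom == ch, ]
    p <- p[order(p$start, p$end), ]
    runs <- list()
    cur <- p[1, , drop = FALSE]
    cur_end <- p$end[1]
    members <- list(1L)
    run_rows <- list()
    idx <- 1L
    run <- p[1, , drop = FALSE]
    if (nrow(p) > 1) {
      for (i in 2:nrow(p)) {
        if (p$start[i] < cur_end) {          # strict: >= 1 bp overlap with run
          run <- rbind(run, p[i, ])
          cur_end <- max(cur_end, p$end[i])
        } else {
          run_rows <- c(run_rows, list(run))
          run <- p[i, , drop = FALSE]
          cur_end <- p$end[i]
        }
      }
    }
    run_rows <- c(run_rows, list(run))
    for (run in run_rows) {
      r1 <- run[run$src == 1, , drop = FALSE]
      r2 <- run[run$src == 2, , drop = FALSE]
      direct <- FALSE
      if (nrow(r1) && nrow(r2)) {
        for (a in seq_len(nrow(r1))) {
          for (b in seq_len(nrow(r2))) {
            if (min(r1$end[a], r2$end[b]) - max(r1$start[a], r2$start[b]) >= 1) {
              direct <- TRUE
            }
          }
        }
      }
      if (direct) {
        out <- rbind(out, data.frame(chrom = ch, start = min(run$start),
                                     end = max(run$end)))
      }
    }
  }
  if (is.null(out)) data.frame(chrom = character(), start = numeric(), end = numeric())
  else out[order(out$chrom, out$start), ]
}

# Exhaustive PWM scan: every offset, both strands, explicit per-base log-odds.
oracle_scan_best <- function(sequence, counts, pseudo = 0.5, bg = rep(0.25, 4)) {
  probs <- sweep(counts + pseudo, 2, colSums(counts + pseudo), "/")
  lo <- log2(probs / bg)
  rownames(lo) <- c("A", "C", "G", "T")
  score_at <- function(s, off, w) {
    sum(sapply(seq_len(w), function(j) {
      b <- substr(s, off + j - 1, off + j - 1)
      if (b == "N") 0 else lo[b, j]
    }))
  }
  w <- ncol(counts)
  rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(sequence, "")[[1]]), collapse = ""))
  best <- -Inf
  for (s in c(sequence, rc)) {
    if (nchar(s) >= w) {
      for (off in 1:(nchar(s) - w + 1)) {
        best <- max(best, score_at(s, off, w))
      }
    }
  }
  best
}

# Adjusted Rand index from the contingency table (closed form).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n <- length(a)
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Random small PWM with a strong consensus.
random_pwm <- function(id, width = 8, strength = 20) {
  cons <- sample(1:4, width, replace = TRUE)
  cnt <- matrix(1, 4, width)
  cnt[cbind(cons, seq_len(width))] <- strength
  new_pwm(id, cnt)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
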
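#' Per-gene two-group differential expression with moderated t-statistics
#'
#' Fits, for every gene, a pooled-variance two-sample t-test on log2
#' expression (`df = n - 2`). With `shrink = TRUE` (default) the per-gene
#' variance is replaced by the empirical-Bayes squeeze
#' `s~_g^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)` with the prior `(d0,
#' s0^2)` fitted by matching the mean and variance of `log s_g^2` across genes
#' (trigamma inversion), and the t-statistic gains `d0` prior degrees of
#' freedom. The log2 fold change is group1 mean minus group2 mean, group1
#' being the first group label listed in the design.
#'
#' Zero-variance genes with unequal means get `p = 0` (an infinite-t
#' surrogate) only when shrinkage keeps the squeezed variance positive; with
#' `shrink = FALSE` they are flagged `NA` and excluded from the BH adjustment,
#' with a logged note. A gene whose two group means are identical always gets
#' `t = 0, p = 1`.
#'
#' @param expr Log2-scale expression tibble.
#' @param design Tibble with `sample`, `group`; exactly two groups, each with
#'   >= 2 samples (>= 1 per group allowed with `shrink = TRUE`, where residual
#'   df is borrowed across genes).
#' @param shrink Apply the variance squeeze (default `TRUE`).
#' @return A tibble with one row per gene: `gene`, `mean1`, `mean2`, `sd1`,
#'   `sd2`, `log2fc`, `t`, `df`, `p`, `q` (BH-adjusted). The group-to-column
#'   mapping is stored in the `groups` attribute.
#' @export
differential_expression <- function(expr, design, shrink = TRUE) {
  check_expression(expr)
  check_design_against(design, expr)
  groups <- unique(design$group)
  if (length(groups) != 2L) {
    abort(sprintf("design must have exactly 2 groups (found %d)", length(groups)))
  }
  n1 <- sum(design$group == groups[1])
  n2 <- sum(design$group == groups[2])
  min_n <- if (shrink) 1L else 2L
  if (n1 < min_n || n2 < min_n) {
    abort(sprintf("each group needs >= %d samples (found %d and %d)", min_n, n1, n2))
  }
  n <- n1 + n2
  dg <- n - 2L
  if (dg < 1L) abort("need at least 3 samples overall (no residual degrees of freedom)")

  m <- expr_matrix(expr)
  x1 <- m[, design$sample[design$group == groups[1]], drop = FALSE]
  x2 <- m[, design$sample[design$group == groups[2]], drop = FALSE]
  mean1 <- rowMeans(x1)
  mean2 <- rowMeans(x2)
  ss <- rowSums((x1 - mean1)^2) + rowSums((x2 - mean2)^2)
  s2 <- if (dg > 0) ss / dg else rep(NA_real_, nrow(m))
  log2fc <- mean1 - mean2
  se_scale <- sqrt(1 / n1 + 1 / n2)

  if (shrink) {
    fit <- squeeze_variances(s2, dg)
    s2_used <- fit$var_post
    df_total <- fit$df_prior + dg
  } else {
    s2_used <- s2
    df_total <- rep(dg, nrow(m))
  }

  tval <- log2fc / (sqrt(s2_used) * se_scale)
  # numerator exactly zero -> no evidence regardless of the variance estimate
  tval[log2fc == 0] <- 0
  p <- 2 * stats::pt(-abs(tval), df = df_total)
  p[log2fc == 0] <- 1
  zero_var_diff <- is.finite(log2fc) & log2fc != 0 & s2_used == 0
  if (any(zero_var_diff, na.rm = TRUE)) {
    if (shrink) {
      p[zero_var_diff] <- 0
    } else {
      tval[zero_var_diff] <- NA_real_
      p[zero_var_diff] <- NA_real_
      log_stage("differential_expression",
                note = sprintf("%d zero-variance gene(s) with unequal means flagged NA",
                               sum(zero_var_diff)))
    }
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- adjust_bh(p[ok])

  log_stage("differential_expression", genes = nrow(m),
            groups = paste(groups, collapse = " vs "), n1 = n1, n2 = n2,
            shrink = shrink)
  out <- tibble(gene = rownames(m), mean1 = unname(mean1), mean2 = unname(mean2),
                sd1 = apply(x1, 1, stats::sd), sd2 = apply(x2, 1, stats::sd),
                log2fc = unname(log2fc), t = unname(tval),
                df = unname(df_total), p = unname(p), q = q)
  attr(out, "groups") <- stats::setNames(groups, c("mean1", "mean2"))
  out
}

# Moment-matched empirical-Bayes squeeze of per-gene sample variances.
# Fits (d0, s0^2) so that a scaled-F model reproduces the observed mean and
# variance of log s_g^2, then returns the posterior variances
# (d0 s0^2 + dg s_g^2) / (d0 + dg). Genes with s_g^2 = 0 enter the posterior
# with zero sample variance but are excluded from the moment fit.
#' @noRd
squeeze_variances <- function(s2, dg) {
  pos <- which(is.finite(s2) & s2 > 0)
  if (length(pos) < 2L) {
    # nothing to fit: fall back to no squeeze
    return(list(var_post = s2, df_prior = 0, var_prior = NA_real_))
  }
  z <- log(s2[pos])
  evar <- stats::var(z) - trigamma(dg / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2) + digamma(d0 / 2) - log(d0 / 2))
    var_post <- (d0 * s0_2 + dg * s2) / (d0 + dg)
  } else {
    d0 <- Inf
    s0_2 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2))
    var_post <- rep(s0_2, length(s2))
  }
  list(var_post = var_post, df_prior = d0, var_prior = s0_2)
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone, near
# linear in x), as is standard for this moment fit.
#' @noRd
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} (p_(j) * m / j)` on the sorted p-values, mapped back
#' to input order; ties share a q and the output preserves p-rank order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
adjust_bh <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Threshold genes by fold change
#'
#' Splits a differential-expression table into up- and down-regulated gene
#' lists by absolute fold change alone, with no significance filter (the
#' convention for tiny replicate numbers where variance estimates are
#' unstable). The boundary is inclusive: `log2fc` exactly at
#' `log2(fc_threshold)` counts as up.
#'
#' @param de Differential-expression tibble from
#'   [differential_expression()] (needs `gene` and `log2fc` columns).
#' @param fc_threshold Linear fold-change threshold, > 1 (default 2).
#' @return A tibble with `gene`, `log2fc` and `direction` (`"up"` or
#'   `"down"`), ordered by decreasing `|log2fc|`.
#' @export
fold_change_lists <- function(de, fc_threshold = 2) {
  if (fc_threshold <= 1) abort("fc_threshold must be > 1")
  cut <- log2(fc_threshold)
  de |>
    dplyr::filter(!is.na(log2fc), abs(log2fc) >= cut) |>
    dplyr::mutate(direction = ifelse(log2fc > 0, "up", "down")) |>
    dplyr::select(gene, log2fc, direction) |>
    dplyr::arrange(dplyr::desc(abs(log2fc)), gene)
}

#' Cross-cohort replicated transcription-factor screen
#'
#' A transcription factor replicates when it is significant (`q <
#' q_threshold`) in both cohorts and, when `require_same_direction` is on, its
#' fold change has the same sign in both. Direction is reported relative to
#' each cohort's first design group (`"up"` = higher in group 1).
#'
#' @param de_a,de_b Differential-expression tibbles from two cohorts sharing
#'   a gene identifier space.
#' @param tf_genes Character vector of transcription-factor gene ids to
#'   screen.
#' @param q_threshold Per-cohort FDR threshold (default 0.1).
#' @param require_same_direction Require sign agreement of `log2fc` (default
#'   `TRUE`).
#' @return A tibble with one row per screened TF found in both cohorts:
#'   `gene`, `log2fc_a`, `q_a`, `direction_a`, `log2fc_b`, `q_b`,
#'   `direction_b`, `significant_a`, `significant_b`, `replicated`.
#' @export
tf_screen <- function(de_a, de_b, tf_genes, q_threshold = 0.1,
                      require_same_direction = TRUE) {
  if (!length(tf_genes)) abort("tf_genes is empty")
  a <- dplyr::filter(de_a, gene %in% tf_genes)
  b <- dplyr::filter(de_b, gene %in% tf_genes)
  if (!nrow(a) || !nrow(b)) abort("tf_genes has empty intersection with a cohort's genes")
  out <- dplyr::inner_join(
    dplyr::select(a, gene, log2fc_a = log2fc, q_a = q),
    dplyr::select(b, gene, log2fc_b = log2fc, q_b = q),
    by = "gene"
  ) |>
    dplyr::mutate(
      direction_a = ifelse(log2fc_a > 0, "up", "down"),
      direction_b = ifelse(log2fc_b > 0, "up", "down"),
      significant_a = !is.na(q_a) & q_a < q_threshold,
      significant_b = !is.na(q_b) & q_b < q_threshold,
      replicated = significant_a & significant_b &
        (!require_same_direction | sign(log2fc_a) == sign(log2fc_b))
    )
  log_stage("tf_screen", screened = nrow(out), replicated = sum(out$replicated))
  out
}
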
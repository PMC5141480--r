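#' Classify samples against a nearest-centroid model
#'
#' For each query sample, the distance to class k is the variance-standardized
#' squared distance over the model's selected genes,
#' `d_k = sum_g ((x_g - centroid_kg) / (pooled_sd_g + s0))^2`.
#' The call is the distance-minimizing class, or `"ambiguous"` when the two
#' smallest distances differ by less than `1e-9` (a floating-point guard, not a
#' biological claim). For a luminal/basal model the transdifferentiation shift
#' is `d_basal - d_luminal`, so larger values mean closer to the luminal
#' centroid.
#'
#' Query samples must cover at least 80% of the model's genes; missing genes
#' are dropped pairwise with a logged note, supporting cross-platform
#' application.
#'
#' @param expr Query expression tibble (centred log2 scale, comparable to the
#'   training data).
#' @param model A `centroid_model`.
#' @return A tibble of class `subtype_calls`, one row per sample: `sample`,
#'   one `d_<class>` column per model class, `label`, `shift`.
#' @export
classify_samples <- function(expr, model) {
  stopifnot(inherits(model, "centroid_model"))
  check_expression(expr)
  m <- expr_matrix(expr)
  present <- intersect(model$genes, rownames(m))
  missing <- setdiff(model$genes, rownames(m))
  if (length(present) < 0.8 * length(model$genes)) {
    abort(sprintf("query covers only %d/%d model genes (< 80%%); missing: %s",
                  length(present), length(model$genes), paste(missing, collapse = ", ")))
  }
  if (length(missing)) {
    log_stage("classify_samples",
              note = sprintf("dropping %d model gene(s) absent from query: %s",
                             length(missing), paste(missing, collapse = ", ")))
  }
  denom <- model$pooled_sd[present] + model$s0
  x <- m[present, , drop = FALSE]
  dists <- vapply(model$classes, function(k) {
    colSums(((x - model$centroid[k, present]) / denom)^2)
  }, numeric(ncol(x)))
  if (ncol(x) == 1L) dists <- matrix(dists, nrow = 1, dimnames = list(colnames(x), model$classes))

  label <- apply(dists, 1, function(d) {
    o <- order(d)
    if (length(d) > 1L && d[o[2]] - d[o[1]] < 1e-9) "ambiguous" else model$classes[o[1]]
  })
  shift <- if (all(subtype_classes %in% model$classes)) {
    dists[, "basal"] - dists[, "luminal"]
  } else {
    rep(NA_real_, nrow(dists))
  }
  out <- tibble(sample = colnames(x))
  for (k in model$classes) out[[paste0("d_", k)]] <- unname(dists[, k])
  out$label <- unname(label)
  out$shift <- unname(shift)
  class(out) <- c("subtype_calls", class(out))
  attr(out, "model_genes") <- model$genes
  attr(out, "model_centroid") <- model$centroid
  out
}

#' Change in transdifferentiation shift between treated and control calls
#'
#' Positive values mean the treated sample moved toward the luminal centroid
#' relative to its control. Both call sets must come from the same model
#' (checked on the model's selected genes and centroid values).
#'
#' @param treated,control `subtype_calls` tibbles from [classify_samples()]
#'   against the same model; rows are paired positionally (or a single control
#'   row is recycled).
#' @return A numeric vector, `treated$shift - control$shift`.
#' @export
shift_score <- function(treated, control) {
  for (obj in list(treated, control)) {
    if (!inherits(obj, "subtype_calls")) abort("inputs must be subtype_calls tibbles")
  }
  same_model <- identical(attr(treated, "model_genes"), attr(control, "model_genes")) &&
    isTRUE(all.equal(attr(treated, "model_centroid"), attr(control, "model_centroid")))
  if (!same_model) abort("treated and control calls were made against different models")
  if (nrow(control) == 1L && nrow(treated) > 1L) {
    control <- control[rep(1L, nrow(treated)), ]
  }
  if (nrow(treated) != nrow(control)) {
    abort("treated and control must have the same number of rows (or one control row)")
  }
  treated$shift - control$shift
}

#' Consensus subtype call across replicates
#'
#' A class is the consensus only if every replicate carries that label; any
#' disagreement (including an `"ambiguous"` replicate) yields `"discordant"`.
#'
#' @param calls A `subtype_calls` tibble whose rows are replicate calls of the
#'   same condition, or a character vector of replicate labels (length >= 2).
#' @return A single label: a class name or `"discordant"`.
#' @export
#' @examples
#' consensus_call(c("luminal", "luminal"))
#' consensus_call(c("luminal", "basal"))
consensus_call <- function(calls) {
  labels <- if (is.data.frame(calls)) calls$label else calls
  if (length(labels) == 0L) abort("no replicate calls supplied")
  if (length(labels) < 2L) abort("need >= 2 replicate calls for a consensus")
  if (length(unique(labels)) == 1L && labels[1] != "ambiguous") labels[1] else "discordant"
}
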
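#' Configuration for a synthetic expression cohort
#'
#' The generator emulates a cohort with two latent molecular subtypes (luminal
#' and basal), each defined by a marker-gene panel, plus non-type samples low
#' in both panels. Defaults are the study conditions used throughout the
#' package's tests: a 2 log2-unit marker separation with per-gene Gaussian
#' noise of 0.5 log2 units.
#'
#' @param n_genes Total number of genes (markers included).
#' @param n_marker_per_class Marker genes per subtype panel.
#' @param n_luminal,n_basal,n_nontype Samples per class.
#' @param effect_size Log2-unit elevation of a class's own marker panel above
#'   baseline.
#' @param noise_sd Per-gene Gaussian noise standard deviation (log2 units).
#' @param batch_shift_sd Per-gene dataset-offset standard deviation used by
#'   [apply_batch_effect()] when no value is supplied there.
#' @param seed Integer seed; identical seeds reproduce the cohort bit-exactly.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 2000, n_marker_per_class = 25,
                          n_luminal = 20, n_basal = 20, n_nontype = 10,
                          effect_size = 2, noise_sd = 0.5,
                          batch_shift_sd = 0.5, seed = 1L) {
  stopifnot(n_genes >= 2 * n_marker_per_class, n_marker_per_class >= 1,
            n_luminal >= 0, n_basal >= 0, n_nontype >= 0,
            effect_size >= 0, noise_sd >= 0, batch_shift_sd >= 0)
  if (n_luminal + n_basal + n_nontype == 0L) {
    abort("cohort must contain at least one sample")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_marker_per_class = as.integer(n_marker_per_class),
                 n_luminal = as.integer(n_luminal), n_basal = as.integer(n_basal),
                 n_nontype = as.integer(n_nontype),
                 effect_size = effect_size, noise_sd = noise_sd,
                 batch_shift_sd = batch_shift_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

# Per-sample noise stream: sample i of a cohort always draws from the same
# derived seed, so re-drawing one sample's noise (perturbation) with the
# original stream reproduces the original values exactly.
#' @noRd
sample_noise <- function(config, index, n_genes) {
  set.seed(derive_seed(config$seed, 1L, index))
  rnorm(n_genes, mean = 0, sd = config$noise_sd)
}

#' Simulate an expression cohort with planted luminal/basal structure
#'
#' Baseline expression is drawn once per gene from N(6, 1) log2 units (a
#' typical bulk RNA dynamic range). Luminal samples have their luminal-marker
#' means raised by `effect_size` while basal markers sit at baseline; basal
#' samples the reverse; non-type samples sit at baseline on both panels.
#' Non-marker genes share one baseline across classes, giving an exact null
#' set. I.i.d. Gaussian noise with sd `noise_sd` is added per value.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `expr` (log2
#'   expression tibble), `labels` (`sample`, `class`), `markers` (the planted
#'   signature: `gene`, `class`), `templates` (class x gene matrix of expected
#'   values) and `config`.
#' @export
#' @examples
#' cohort <- simulate_expression_cohort(cohort_config(n_genes = 100, seed = 1))
#' cohort$labels
simulate_expression_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  ng <- config$n_genes
  nm <- config$n_marker_per_class
  lum_markers <- sprintf("LUM%03d", seq_len(nm))
  bas_markers <- sprintf("BAS%03d", seq_len(nm))
  null_genes <- sprintf("G%05d", seq_len(ng - 2L * nm))
  genes <- c(lum_markers, bas_markers, null_genes)

  set.seed(derive_seed(config$seed, 0L))
  baseline <- rnorm(ng, mean = 6, sd = 1)
  names(baseline) <- genes

  templates <- rbind(luminal = baseline, basal = baseline, `non-type` = baseline)
  templates["luminal", lum_markers] <- baseline[lum_markers] + config$effect_size
  templates["basal", bas_markers] <- baseline[bas_markers] + config$effect_size

  classes <- c(rep("luminal", config$n_luminal), rep("basal", config$n_basal),
               rep(nontype_label, config$n_nontype))
  samples <- c(sprintf("L%02d", seq_len(config$n_luminal)),
               sprintf("B%02d", seq_len(config$n_basal)),
               sprintf("N%02d", seq_len(config$n_nontype)))

  values <- vapply(seq_along(samples), function(i) {
    templates[classes[i], ] + sample_noise(config, i, ng)
  }, numeric(ng))
  rownames(values) <- genes
  colnames(values) <- samples

  log_stage("simulate_expression_cohort", genes = ng, samples = length(samples),
            effect_size = config$effect_size, noise_sd = config$noise_sd,
            seed = config$seed)
  structure(list(
    expr = expr_tibble(values, scale_tag = "log2"),
    labels = tibble(sample = samples, class = classes),
    markers = tibble(gene = c(lum_markers, bas_markers),
                     class = rep(c("luminal", "basal"), each = nm)),
    templates = templates,
    config = config
  ), class = "synthetic_cohort")
}

#' Add a dataset-wide batch shift to a synthetic cohort
#'
#' One offset per gene is drawn from N(0, `batch_shift_sd`^2) and added to all
#' samples, mimicking a platform/cohort shift. Labels, markers and templates
#' are shifted consistently, so between-sample differences are untouched.
#'
#' @param cohort A `synthetic_cohort`.
#' @param batch_shift_sd Offset standard deviation; defaults to the value in
#'   the cohort's config.
#' @param seed Seed for the offset draw; defaults to a stream derived from the
#'   cohort seed.
#' @return The shifted `synthetic_cohort`.
#' @export
apply_batch_effect <- function(cohort, batch_shift_sd = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  sdv <- batch_shift_sd %||% cohort$config$batch_shift_sd
  stopifnot(sdv >= 0)
  seed <- seed %||% derive_seed(cohort$config$seed, 2L)
  m <- expr_matrix(cohort$expr)
  set.seed(seed)
  offsets <- rnorm(nrow(m), mean = 0, sd = sdv)
  m <- m + offsets
  cohort$expr <- expr_tibble(m, scale_tag = "log2")
  cohort$templates <- sweep(cohort$templates, 2, -offsets)
  cohort$batch <- list(offsets = stats::setNames(offsets, rownames(m)),
                       batch_shift_sd = sdv, seed = seed)
  cohort
}

#' Partially shift samples toward the opposite subtype template
#'
#' Emulates a transdifferentiation experiment: the expected value of each
#' selected sample becomes the convex combination
#' `(1 - shift_fraction) * own template + shift_fraction * target template`,
#' which differs from the original only on marker genes. Noise for the
#' selected samples is re-drawn; with `seed = NULL` the samples' original
#' per-sample noise streams are reused, so `shift_fraction = 0` reproduces the
#' input values exactly.
#'
#' @param cohort A `synthetic_cohort`.
#' @param samples Sample ids to perturb.
#' @param shift_fraction Mixing fraction in `[0, 1]`.
#' @param target_class Template to move toward (`"luminal"` or `"basal"`).
#' @param seed Optional seed for re-drawing noise of the perturbed samples.
#' @return The perturbed `synthetic_cohort`, with a `perturbation` record.
#' @export
apply_perturbation <- function(cohort, samples, shift_fraction, target_class,
                               seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            shift_fraction >= 0, shift_fraction <= 1)
  if (!target_class %in% rownames(cohort$templates)) {
    abort(sprintf("no template for target class '%s'", target_class))
  }
  all_samples <- cohort$labels$sample
  unknown <- setdiff(samples, all_samples)
  if (length(unknown)) {
    abort(sprintf("unknown sample id(s): %s", paste(unknown, collapse = ", ")))
  }
  m <- expr_matrix(cohort$expr)
  ng <- nrow(m)
  for (s in samples) {
    i <- match(s, all_samples)
    own <- cohort$labels$class[i]
    mixed <- (1 - shift_fraction) * cohort$templates[own, ] +
      shift_fraction * cohort$templates[target_class, ]
    noise <- if (is.null(seed)) {
      sample_noise(cohort$config, i, ng)
    } else {
      set.seed(derive_seed(seed, 3L, i))
      rnorm(ng, mean = 0, sd = cohort$config$noise_sd)
    }
    m[, s] <- mixed + noise
  }
  cohort$expr <- expr_tibble(m, scale_tag = "log2")
  cohort$perturbation <- list(samples = samples, shift_fraction = shift_fraction,
                              target_class = target_class, seed = seed)
  log_stage("apply_perturbation", samples = length(samples),
            shift_fraction = shift_fraction, target = target_class)
  cohort
}
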
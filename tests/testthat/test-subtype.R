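# Normalization, preprocessing, clustering and cluster labelling.

test_that("size factors follow the median-of-ratios formula", {
  m <- matrix(c(2, 8, 50, 4, 16, 100), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  res <- quiet(size_factor_normalize(expr_fixture(m, "counts")))
  f <- res$size_factors$size_factor
  expect_equal(f, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(f[2] / f[1], 2, tolerance = 1e-12)
  # normalized values: both samples identical after scaling
  nm <- as.matrix(res$normalized[, -1])
  expect_equal(nm[, 1], nm[, 2])

  # identical samples -> all factors 1
  m2 <- cbind(S1 = c(3, 7), S2 = c(3, 7), S3 = c(3, 7))
  rownames(m2) <- c("a", "b")
  f2 <- quiet(size_factor_normalize(expr_fixture(m2, "counts")))$size_factors$size_factor
  expect_equal(f2, rep(1, 3))
})

test_that("size factors match the independent formula oracle on random counts", {
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(rpois(60, lambda = 50) + 1, nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    res <- quiet(size_factor_normalize(expr_fixture(m, "counts")))
    expect_equal(res$size_factors$size_factor, unname(oracle_size_factors(m)),
                 tolerance = 1e-12)
  }
})

test_that("all-zero genes are excluded from the reference but kept in output", {
  m <- rbind(a = c(2, 4), b = c(8, 16), z = c(0, 0))
  colnames(m) <- c("S1", "S2")
  res <- quiet(size_factor_normalize(expr_fixture(m, "counts")))
  expect_true("z" %in% res$normalized$gene)
  expect_equal(res$size_factors$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  allzero <- rbind(a = c(0, 1), b = c(1, 0))
  colnames(allzero) <- c("S1", "S2")
  expect_error(quiet(size_factor_normalize(expr_fixture(allzero, "counts"))),
               "cannot form reference")
})

test_that("scaling one library by c is absorbed into its size factor", {
  # the geometric-mean reference itself picks up c^(1/m), so the exact
  # equivariances are on factor ratios and on a single global rescaling of the
  # normalized matrix (visible already in the two-sample example above, where
  # a twofold library gives factors (1/sqrt(2), sqrt(2)), ratio exactly 2)
  set.seed(31)
  m <- matrix(rpois(40, 30) + 1, nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  base <- quiet(size_factor_normalize(expr_fixture(m, "counts")))
  m2 <- m; m2[, 3] <- m2[, 3] * 5
  scaled <- quiet(size_factor_normalize(expr_fixture(m2, "counts")))
  f0 <- base$size_factors$size_factor
  f1 <- scaled$size_factors$size_factor
  expect_equal(f1[3] / f1[1], 5 * f0[3] / f0[1], tolerance = 1e-12)
  expect_equal(f1[2] / f1[1], f0[2] / f0[1], tolerance = 1e-12)
  expect_equal(as.matrix(scaled$normalized[, -1]),
               as.matrix(base$normalized[, -1]) * 5^(1 / 5), tolerance = 1e-12)
})

test_that("preprocessing restricts to present signature genes and median-centres", {
  m <- rbind(KRT20 = c(1, 3, 5), KRT5 = c(2, 2, 2), OTHER = c(9, 9, 9))
  colnames(m) <- paste0("s", 1:3)
  sig <- tibble::tibble(gene = c("KRT20", "KRT5", "GONE"),
                        class = c("luminal", "basal", "basal"))
  expect_warning(suppressMessages(preprocess_expression(expr_fixture(m), sig)), "GONE")
  pre <- quiet(preprocess_expression(expr_fixture(m), sig))
  expect_setequal(pre$gene, c("KRT20", "KRT5"))
  expect_equal(unname(as.matrix(pre[pre$gene == "KRT20", -1])[1, ]), c(-2, 0, 2))
  # constant gene retained and centred to zero at percentile 0
  expect_equal(unname(as.matrix(pre[pre$gene == "KRT5", -1])[1, ]), c(0, 0, 0))
  # counts input is log2-transformed first
  cm <- rbind(KRT20 = c(0, 1, 3), KRT5 = c(1, 1, 1))
  colnames(cm) <- paste0("s", 1:3)
  prec <- quiet(preprocess_expression(expr_fixture(cm, "counts"),
                                      sig[1:2, ], log_offset = 1))
  expect_equal(unname(as.matrix(prec[prec$gene == "KRT20", -1])[1, ]),
               log2(c(1, 2, 4)) - 1)
  expect_error(quiet(preprocess_expression(expr_fixture(m), sig[3, , drop = FALSE])),
               "fewer than 2")
})

test_that("reference centring uses supplied per-gene values", {
  m <- rbind(a = c(5, 7), b = c(1, 3))
  colnames(m) <- c("s1", "s2")
  pre <- quiet(preprocess_expression(expr_fixture(m), center = c(a = 4, b = 0)))
  expect_equal(unname(as.matrix(pre[, -1])), rbind(c(1, 3), c(1, 3)))
  expect_error(quiet(preprocess_expression(expr_fixture(m), center = c(a = 4))), "b")
})

test_that("clustering separates duplicated profile groups and validates input", {
  m <- cbind(A1 = c(1, 0, 2), A2 = c(1, 0, 2), B1 = c(0, 2, 1), B2 = c(0, 2, 1))
  rownames(m) <- paste0("g", 1:3)
  cl <- quiet(cluster_samples(expr_fixture(m), k = 2))
  groups <- split(cl$assignment$sample, cl$assignment$cluster)
  expect_setequal(purrr::map_chr(groups, paste, collapse = ","),
                  c("A1,A2", "B1,B2"))
  expect_error(quiet(cluster_samples(expr_fixture(m), k = 5)), "exceeds")
  mz <- m; mz[, 2] <- 3
  expect_error(quiet(cluster_samples(expr_fixture(mz), k = 2, metric = "correlation")),
               "A2")
  expect_silent(suppressMessages(cluster_samples(expr_fixture(mz), k = 2,
                                                 metric = "euclidean")))
})

test_that("correlation-metric clustering is invariant to positive affine transforms", {
  set.seed(13)
  m <- matrix(rnorm(60), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  cl1 <- quiet(cluster_samples(expr_fixture(m), k = 3, metric = "correlation"))
  m2 <- sweep(sweep(m, 2, runif(6, 0.5, 3), "*"), 2, rnorm(6), "+")
  cl2 <- quiet(cluster_samples(expr_fixture(m2), k = 3, metric = "correlation"))
  expect_equal(oracle_ari(cl1$assignment$cluster, cl2$assignment$cluster), 1)
})

test_that("clustering is invariant to sample column order up to relabelling", {
  set.seed(17)
  co <- quiet(simulate_expression_cohort(
    cohort_config(n_genes = 100, n_luminal = 6, n_basal = 6, n_nontype = 3, seed = 9)))
  pre <- quiet(preprocess_expression(co$expr, co$markers))
  cl1 <- quiet(cluster_samples(pre, k = 3, metric = "euclidean"))
  perm <- sample(2:ncol(pre))
  pre2 <- pre[, c(1, perm)]
  cl2 <- quiet(cluster_samples(pre2, k = 3, metric = "euclidean"))
  joined <- dplyr::inner_join(cl1$assignment, cl2$assignment, by = "sample")
  expect_equal(oracle_ari(joined$cluster.x, joined$cluster.y), 1)
})

test_that("cluster labels follow the marker-score rule", {
  m <- rbind(L1 = c(1, 1, -1, -1, -0.5, -0.6), B1 = c(-1, -1, 1, 1, -0.5, -0.4))
  colnames(m) <- paste0("s", 1:6)
  sig <- tibble::tibble(gene = c("L1", "B1"), class = c("luminal", "basal"))
  assign <- tibble::tibble(sample = colnames(m), cluster = c(1, 1, 2, 2, 3, 3))
  lab <- quiet(label_clusters(expr_fixture(m), assign, sig))
  expect_equal(lab$label, c("luminal", "basal", "non-type"))
  expect_equal(lab$luminal_score, c(1, -1, -0.55))
  # labels never leave the three-value set; the zero matrix is all non-type
  mz <- matrix(0, 2, 6, dimnames = dimnames(m))
  labz <- quiet(label_clusters(expr_fixture(mz), assign, sig,
                               nontype_threshold = 1e-9))
  expect_true(all(labz$label == "non-type"))
  expect_error(quiet(label_clusters(expr_fixture(m), assign,
                                    sig[sig$class == "luminal", ])), "basal")
})

test_that("simulated three-class cohorts are recovered exactly (seeds 1-5)", {
  for (s in 1:5) {
    co <- quiet(simulate_expression_cohort(cohort_config(n_genes = 200, seed = s)))
    pre <- quiet(preprocess_expression(co$expr, co$markers))
    cl <- quiet(cluster_samples(pre, k = 3, metric = "euclidean"))
    expect_equal(oracle_ari(cl$assignment$cluster, co$labels$class), 1)
    lab <- quiet(label_clusters(pre, cl, co$markers))
    per_sample <- quiet(assign_subtypes(cl, lab))
    joined <- dplyr::inner_join(per_sample, co$labels, by = "sample")
    expect_true(all(joined$label == joined$class))
  }
})
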
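# Centroid construction, ClaNC gene selection, classification, shift scoring,
# consensus calls and centroid concordance.

test_that("centroids and pooled sd match the defining formulas", {
  toy <- toy_two_class()
  mod <- quiet(build_centroids(toy$expr, toy$labels))
  m <- toy$matrix
  for (g in rownames(m)) {
    expect_equal(mod$centroid["luminal", g], mean(m[g, 1:2]))
    expect_equal(mod$centroid["basal", g], mean(m[g, 3:4]))
    ss <- sum((m[g, 1:2] - mean(m[g, 1:2]))^2) + sum((m[g, 3:4] - mean(m[g, 3:4]))^2)
    expect_equal(unname(mod$pooled_sd[g]), sqrt(ss / (4 - 2)))
  }
  expect_equal(mod$s0, median(mod$pooled_sd))

  # single-sample class: centroid equals that sample
  labs1 <- tibble::tibble(sample = c("A1", "B1", "B2"),
                          class = c("luminal", "basal", "basal"))
  mod1 <- quiet(build_centroids(toy$expr[, c("gene", "A1", "B1", "B2")], labs1))
  expect_equal(unname(mod1$centroid["luminal", ]), unname(m[, "A1"]))

  # zero within-class spread engages the s0 fallback
  md <- cbind(A1 = c(0, 0), A2 = c(0, 0), B1 = c(2, 2), B2 = c(2, 2))
  rownames(md) <- c("g1", "g2")
  labs <- tibble::tibble(sample = colnames(md),
                         class = rep(c("luminal", "basal"), each = 2))
  modd <- quiet(build_centroids(expr_fixture(md), labs))
  expect_equal(unname(modd$pooled_sd), c(0, 0))
  expect_equal(modd$s0, 1e-6)

  expect_error(quiet(build_centroids(toy$expr[, c("gene", "A1", "B1")],
                                     tibble::tibble(sample = c("A1", "B1"),
                                                    class = c("luminal", "basal")))),
               "pooled sd undefined")
})

test_that("ClaNC selection is balanced and matches the brute-force oracle", {
  set.seed(101)
  for (i in 1:20) {
    ng <- sample(6:15, 1)
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    m <- matrix(rnorm(ng * (n1 + n2)), nrow = ng,
                dimnames = list(sprintf("g%02d", 1:ng),
                                c(paste0("a", 1:n1), paste0("b", 1:n2))))
    m[1:2, 1:n1] <- m[1:2, 1:n1] + 2
    labels <- tibble::tibble(sample = colnames(m),
                             class = rep(c("luminal", "basal"), c(n1, n2)))
    n_total <- sample(seq(2, min(ng, 8), by = 2), 1)
    sel <- quiet(select_clanc_genes(expr_fixture(m), labels, n_total = n_total))
    ora <- oracle_clanc_select(m, labels$class, n_total)
    expect_equal(nrow(sel), n_total)
    expect_setequal(sel$gene, ora$gene)
    expect_equal(sel$d[match(ora$gene, sel$gene)], ora$d, tolerance = 1e-12)
  }
})

test_that("balance contract: n_total = 4 over 2 classes picks 2 genes per class", {
  set.seed(5)
  m <- matrix(rnorm(12 * 8), nrow = 12,
              dimnames = list(sprintf("g%02d", 1:12), sprintf("s%d", 1:8)))
  m[1:6, 1:4] <- m[1:6, 1:4] + 3   # six luminal-favouring genes
  m[7:12, 5:8] <- m[7:12, 5:8] + 3 # six basal-favouring genes
  labels <- tibble::tibble(sample = colnames(m),
                           class = rep(c("luminal", "basal"), each = 4))
  sel <- quiet(select_clanc_genes(expr_fixture(m), labels, n_total = 4))
  expect_equal(sort(as.integer(table(sel$class))), c(2L, 2L))
})

test_that("a gene with identical class means is never selected over nonzero-d genes", {
  m <- rbind(flat = rep(1, 6), good = c(2, 2, 2, 0, 0, 0), ok = c(1, 1, 1, 0.5, 0.5, 0.5))
  m <- m + matrix(rnorm(18, sd = 0.01), nrow = 3)
  m["flat", ] <- c(1, 2, 3, 1, 2, 3)  # identical class means, nonzero variance
  colnames(m) <- paste0("s", 1:6)
  labels <- tibble::tibble(sample = colnames(m),
                           class = rep(c("luminal", "basal"), each = 3))
  sel <- quiet(select_clanc_genes(expr_fixture(m), labels, n_total = 2))
  expect_false("flat" %in% sel$gene)
})

test_that("too few candidates warns and uses all", {
  toy <- toy_two_class()
  expect_warning(sel <- suppressMessages(
    select_clanc_genes(toy$expr, toy$labels, n_total = 10)), "using all")
  expect_equal(nrow(sel), 3)
})

test_that("classification distances match brute force, midpoints are ambiguous", {
  toy <- toy_two_class()
  mod <- quiet(build_centroids(toy$expr, toy$labels))
  # hand query at the luminal centroid
  q <- matrix(mod$centroid["luminal", ], ncol = 1,
              dimnames = list(mod$genes, "Q1"))
  call <- quiet(classify_samples(expr_fixture(q), mod))
  expect_equal(call$d_luminal, 0)
  expect_identical(call$label, "luminal")
  expect_equal(call$shift, call$d_basal)

  # per-gene midpoint of the two centroids -> equal distances -> ambiguous
  mid <- matrix(colMeans(mod$centroid), ncol = 1, dimnames = list(mod$genes, "M"))
  callm <- quiet(classify_samples(expr_fixture(mid), mod))
  expect_identical(callm$label, "ambiguous")
  expect_equal(callm$d_luminal, callm$d_basal)
})

test_that("classifier equals exhaustive discriminant computation on random models", {
  set.seed(202)
  for (i in 1:50) {
    ng <- sample(2:5, 1)
    K <- sample(2:3, 1)
    classes <- c("luminal", "basal", "other")[seq_len(K)]
    nk <- sample(2:4, K, replace = TRUE)
    m <- matrix(rnorm(ng * sum(nk)), nrow = ng,
                dimnames = list(paste0("g", 1:ng), paste0("s", 1:sum(nk))))
    labels <- tibble::tibble(sample = colnames(m), class = rep(classes, nk))
    mod <- quiet(build_centroids(expr_fixture(m), labels))
    q <- matrix(rnorm(ng), ncol = 1, dimnames = list(rownames(m), "Q"))
    call <- quiet(classify_samples(expr_fixture(q), mod))
    ora <- oracle_classify(q[, 1], mod$centroid, mod$pooled_sd, mod$s0)
    for (k in classes) {
      expect_equal(call[[paste0("d_", k)]], unname(ora[k]), tolerance = 1e-12)
    }
    expect_identical(call$label, names(which.min(ora)))
  }
})

test_that("labels are scale-equivariant when the model is refit on scaled data", {
  toy <- toy_two_class()
  q <- matrix(c(1.5, -0.8, 0.02), ncol = 1, dimnames = list(c("g1", "g2", "g3"), "Q"))
  mod <- quiet(build_centroids(toy$expr, toy$labels))
  call <- quiet(classify_samples(expr_fixture(q), mod))
  for (c_scale in c(0.1, 3, 42)) {
    ms <- toy$matrix * c_scale
    mods <- quiet(build_centroids(expr_fixture(ms), toy$labels))
    calls <- quiet(classify_samples(expr_fixture(q * c_scale), mods))
    expect_identical(calls$label, call$label)
    expect_equal(calls$d_luminal, c_scale^0 * call$d_luminal, tolerance = 1e-9)
  }
})

test_that("insufficient gene coverage is fatal, partial coverage drops pairwise", {
  set.seed(30)
  m <- matrix(rnorm(10 * 6), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  labels <- tibble::tibble(sample = colnames(m),
                           class = rep(c("luminal", "basal"), each = 3))
  mod <- quiet(build_centroids(expr_fixture(m), labels))
  q_full <- matrix(rnorm(10), ncol = 1, dimnames = list(rownames(m), "Q"))
  q_missing1 <- q_full[1:9, , drop = FALSE]   # 90% coverage: allowed
  expect_silent(suppressMessages(classify_samples(expr_fixture(q_missing1), mod)))
  q_missing3 <- q_full[1:7, , drop = FALSE]   # 70% coverage: fatal
  expect_error(quiet(classify_samples(expr_fixture(q_missing3), mod)), "80%")
})

test_that("shift scores difference treated vs control and guard model identity", {
  toy <- toy_two_class()
  mod <- quiet(build_centroids(toy$expr, toy$labels))
  at <- function(v) expr_fixture(matrix(v, ncol = 1, dimnames = list(mod$genes, "X")))
  ctrl <- quiet(classify_samples(at(mod$centroid["basal", ]), mod))
  trt <- quiet(classify_samples(at(mod$centroid["luminal", ]), mod))
  expect_equal(shift_score(ctrl, ctrl), 0)
  # basal -> luminal covers the full inter-centroid discriminant span
  span <- trt$d_basal + ctrl$d_luminal
  expect_equal(shift_score(trt, ctrl), span)
  other <- quiet(build_centroids(toy$expr[toy$expr$gene != "g3", ], toy$labels))
  trt2 <- quiet(classify_samples(at(mod$centroid["luminal", ]), other))
  expect_error(shift_score(trt2, ctrl), "different models")
})

test_that("shift increases monotonically with planted transdifferentiation", {
  tr <- quiet(simulate_expression_cohort(
    cohort_config(n_genes = 120, n_nontype = 0, seed = 1)))
  ptr <- quiet(preprocess_expression(tr$expr, tr$markers))
  mod <- quiet(train_clanc(ptr, tr$labels, signature = tr$markers, n_genes = 20))
  ref <- attr(ptr, "gene_centers")
  cfg0 <- cohort_config(n_genes = 120, n_nontype = 0, noise_sd = 0, seed = 2)
  shift_at <- function(f) {
    co <- quiet(simulate_expression_cohort(cfg0))
    co <- quiet(apply_perturbation(co, "B01", f, "luminal"))
    pre <- quiet(preprocess_expression(co$expr, co$markers, center = ref))
    calls <- quiet(classify_samples(pre, mod))
    calls$shift[calls$sample == "B01"]
  }
  shifts <- vapply(c(0, 0.3, 0.6, 1), shift_at, numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("consensus requires unanimity across replicates", {
  expect_identical(consensus_call(c("luminal", "luminal")), "luminal")
  expect_identical(consensus_call(c("luminal", "basal")), "discordant")
  expect_identical(consensus_call(c("ambiguous", "luminal")), "discordant")
  expect_identical(consensus_call(c("ambiguous", "ambiguous")), "discordant")
  expect_identical(consensus_call(c("basal", "basal", "basal")), "basal")
  expect_error(consensus_call(character(0)), "no replicate")
})

test_that("centroid concordance: exact ranks, t approximation and permutation p", {
  toy <- toy_two_class()
  mod <- quiet(build_centroids(toy$expr, toy$labels))
  self <- quiet(correlate_centroids(mod, mod, "luminal"))
  expect_equal(self$rho, 1)

  # construct a model with exactly reversed centroid ranks
  m2 <- toy$matrix
  m2[, 1:2] <- -m2[, 1:2]  # flips luminal centroid ordering across genes
  mod2 <- quiet(build_centroids(expr_fixture(m2), toy$labels))
  rev_rho <- quiet(correlate_centroids(mod, mod2, "luminal"))
  expect_equal(rev_rho$rho, -1)

  expect_error(quiet(correlate_centroids(mod, mod2, "nope")), "nope")

  # t-approximation matches the closed formula on a larger model
  set.seed(77)
  mm <- matrix(rnorm(30 * 6), nrow = 30,
               dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
  labs <- tibble::tibble(sample = colnames(mm),
                         class = rep(c("luminal", "basal"), each = 3))
  ma <- quiet(build_centroids(expr_fixture(mm), labs))
  mb <- quiet(build_centroids(expr_fixture(mm + matrix(rnorm(180), 30)), labs))
  res <- quiet(correlate_centroids(ma, mb, "luminal", exact = FALSE))
  rho <- cor(rank(ma$centroid["luminal", ]), rank(mb$centroid["luminal", ]))
  tv <- rho * sqrt((30 - 2) / (1 - rho^2))
  expect_equal(res$rho, rho)
  expect_equal(res$p, 2 * pt(-abs(tv), 28))
  # and agrees with cor.test's large-sample Spearman rho
  ct <- suppressWarnings(cor.test(ma$centroid["luminal", ], mb$centroid["luminal", ],
                                  method = "spearman"))
  expect_equal(res$rho, unname(ct$estimate))

  # exact permutation p on a small shared gene set is a valid frequency
  small_a <- quiet(build_centroids(toy$expr, toy$labels))
  res_ex <- quiet(correlate_centroids(small_a, small_a, "luminal", "basal"))
  expect_identical(res_ex$method, "exact permutation")
  expect_gte(res_ex$p, 1 / factorial(3))
  expect_lte(res_ex$p, 1)
})

test_that("exact permutation p equals enumeration of rank correlations", {
  set.seed(88)
  m <- matrix(rnorm(6 * 6), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:6)))
  labs <- tibble::tibble(sample = colnames(m),
                         class = rep(c("luminal", "basal"), each = 3))
  ma <- quiet(build_centroids(expr_fixture(m), labs))
  mb <- quiet(build_centroids(expr_fixture(m + rnorm(36)), labs))
  res <- quiet(correlate_centroids(ma, mb, "luminal"))
  # brute-force enumeration over all 6! permutations
  x <- rank(ma$centroid["luminal", ]); y <- rank(mb$centroid["luminal", ])
  allp <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(allp(v[-i]), function(r) c(v[i], r)))
    out
  }
  null_rho <- vapply(allp(seq_len(6)), function(idx) cor(x, y[idx]), numeric(1))
  expect_equal(res$p, mean(abs(null_rho) >= abs(res$rho) - 1e-12))
})

test_that("same-class centroids agree across batch-shifted cohorts (seeds 1-10)", {
  for (s in 1:10) {
    co <- quiet(simulate_expression_cohort(cohort_config(n_genes = 150, seed = s)))
    a <- quiet(apply_batch_effect(co, 0.5, seed = s * 7 + 1))
    b <- quiet(apply_batch_effect(co, 0.5, seed = s * 13 + 2))
    pa <- quiet(preprocess_expression(a$expr, a$markers))
    pb <- quiet(preprocess_expression(b$expr, b$markers))
    ma <- quiet(build_centroids(pa, a$labels))
    mb <- quiet(build_centroids(pb, b$labels))
    same <- quiet(correlate_centroids(ma, mb, "luminal"))$rho
    cross <- quiet(correlate_centroids(ma, mb, "luminal", "basal"))$rho
    expect_gt(same, cross)
  }
})
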
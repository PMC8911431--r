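test_that("log2 fold change follows its closed form", {
  x <- make_expr(matrix(10, 2, 3), matrix(10, 2, 3))
  expect_equal(log2_fold_change(x, "g01", normalize = FALSE), 0)

  # A mean = 8 x B mean, tiny pseudocount: ~3
  x2 <- make_expr(matrix(80, 1, 3), matrix(10, 1, 3))
  expect_equal(log2_fold_change(x2, "g01", pseudocount = 1e-9,
                                normalize = FALSE), 3, tolerance = 1e-6)

  # means (10, 2.5) with pseudocount 0.5: log2(10.5 / 3)
  x3 <- make_expr(matrix(c(10, 10, 10), 1), matrix(c(2.5, 2.5, 2.5), 1))
  expect_equal(log2_fold_change(x3, "g01", pseudocount = 0.5,
                                normalize = FALSE),
               log2(10.5 / 3))
  expect_error(log2_fold_change(x3, "nope"), class = "crossdeg_lookup_error")
})

test_that("two-sample z test matches frozen arithmetic oracles", {
  # identical groups: z = 0, p = 1
  res0 <- fisher_z_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # zero SEs with unequal means: degenerate input
  expect_error(fisher_z_test(c(2, 2, 2), c(0, 0, 0)),
               class = "crossdeg_degenerate_error")

  # frozen: a = {2.0, 2.2, 1.8}, b = {0.9, 1.1, 1.0}
  # z = 1 / sqrt(0.04/3 + 0.01/3) = 7.7459667 (hand-checked against the
  # normal CDF before implementation); normal-reference p = 9.4857e-15
  res <- fisher_z_test(c(2.0, 2.2, 1.8), c(0.9, 1.1, 1.0),
                       reference = "normal")
  expect_equal(res$statistic, 7.7459666924, tolerance = 1e-9)
  expect_equal(res$p_value, 9.485738e-15, tolerance = 1e-5)
  res_t <- fisher_z_test(c(2.0, 2.2, 1.8), c(0.9, 1.1, 1.0))
  expect_equal(res_t$df, 4)
  expect_equal(res_t$p_value, 2 * pt(-7.7459666924, 4), tolerance = 1e-9)
})

test_that("z test is antisymmetric in group order", {
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(3 + i %% 3)
    b <- rnorm(3 + (i + 1) %% 4)
    f <- fisher_z_test(a, b)
    r <- fisher_z_test(b, a)
    expect_equal(f$statistic, -r$statistic)
    expect_equal(f$p_value, r$p_value)
  }
})

test_that("Benjamini-Hochberg step-up behaves as specified", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(1.0), 1.0)
  expect_error(benjamini_hochberg(c(0.5, 0)),
               class = "crossdeg_validation_error")
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))

  # permutation equivariance and order preservation
  set.seed(7)
  p <- runif(25)
  perm <- sample(25)
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
  adj <- benjamini_hochberg(p)
  expect_equal(order(adj, p), order(p, p))
})

test_that("gene-name filtering removes placeholder symbols", {
  rec <- tibble::tibble(gene = c("Alb", "LOC102546"))
  out <- filter_gene_names(rec, quiet = TRUE)
  expect_equal(out$gene, "Alb")
  expect_equal(attr(out, "n_removed"), 1L)

  empty <- filter_gene_names(rec[0, ], quiet = TRUE)
  expect_equal(nrow(empty), 0)

  # 50-gene synthetic table with 7 planted excluded names -> 43 survivors
  planted <- c("LOC100911", "RGD1311345", "Abc1-ps2", "hypothetical_orf1",
               "predicted_gene_3", "uncharacterized_4", "LOC688613")
  keep <- sprintf("Gene%02d", 1:43)
  tbl <- tibble::tibble(gene = sample(c(keep, planted)))
  out50 <- filter_gene_names(tbl, quiet = TRUE)
  expect_equal(nrow(out50), 43)
  expect_setequal(out50$gene, keep)

  # biotype column removes non-coding genes too
  bio <- tibble::tibble(gene = c("Alb", "Rn7sk"),
                        biotype = c("protein_coding", "snRNA"))
  expect_equal(filter_gene_names(bio, quiet = TRUE)$gene, "Alb")
})

test_that("call_degs composes the stages correctly", {
  # alpha = 0: empty result
  x <- simulate_counts(sim_config(seed = 31, n_genes = 20, n_deg = 0))
  expect_equal(nrow(call_degs(x, alpha = 0, filter_names = FALSE)), 0)

  # null matrices: adjusted-significant count stays near zero (FDR)
  hits <- vapply(1:30, function(s) {
    xs <- simulate_counts(sim_config(seed = 600 + s, n_genes = 50,
                                     n_deg = 0))
    nrow(call_degs(xs, alpha = 0.05, filter_names = FALSE))
  }, numeric(1))
  expect_lte(mean(hits), 0.05 * 50)

  # planted |log2| = 4 at low dispersion: recovery power frozen at >= 0.9
  # (full-scale simulation gave 0.999; see the methods vignette)
  found <- 0L
  total <- 0L
  for (s in 1:30) {
    xs <- simulate_counts(sim_config(seed = 1000 + s, n_genes = 100,
                                     n_deg = 10, log2_effect = 4,
                                     nb_dispersion = 0.05))
    degs <- call_degs(xs, alpha = 0.05, filter_names = FALSE)
    truth <- attr(xs, "truth")
    planted <- truth$gene[truth$planted_log2 != 0]
    found <- found + sum(planted %in% degs$gene)
    total <- total + length(planted)
  }
  expect_gte(found / total, 0.9)
})

test_that("null count matrices give approximately uniform p-values", {
  # fraction of raw p < 0.05 within +/- 2 SE of 0.05 across 200 matrices
  ps <- unlist(lapply(1:200, function(s) {
    xs <- simulate_counts(sim_config(seed = 5000 + s, n_genes = 50,
                                     n_deg = 0))
    attr(call_degs(xs, alpha = 0.05, filter_names = FALSE), "all_genes")$p
  }))
  se <- sqrt(0.05 * 0.95 / length(ps))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 2 * se)
})
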
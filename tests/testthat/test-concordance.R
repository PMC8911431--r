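test_that("correlation battery recovers perfect association", {
  up <- tibble::tibble(seed_log2 = 1:10 + 0.5,
                       partner_log2 = (1:10 + 0.5) * 2)
  b <- correlation_battery(up)
  expect_equal(c(b$r, b$R, b$tau, b$gamma), rep(1, 4))

  down <- up |> dplyr::mutate(partner_log2 = -partner_log2)
  bd <- correlation_battery(down)
  expect_equal(c(bd$r, bd$R, bd$tau, bd$gamma), rep(-1, 4))

  expect_error(correlation_battery(up |> dplyr::mutate(partner_log2 = 1)),
               class = "crossdeg_degenerate_error")
  expect_error(correlation_battery(up[1:2, ]),
               class = "crossdeg_input_error")

  td <- tidy(b)
  expect_equal(nrow(td), 4)
  expect_named(glance(b),
               c("r", "r_p", "spearman", "spearman_p", "tau", "tau_p",
                 "gamma", "gamma_p", "n"))
})

test_that("gamma matches the pair-enumeration oracle", {
  # fixed 10-point set with two ties; oracle value computed by explicit
  # O(n^2) enumeration: C = 39, D = 5, gamma = 34/44
  x <- c(1, 2, 3, 4, 5, 5, 6, 7, 8, 9)
  y <- c(2, 1, 4, 3, 6, 6, 5, 8, 7, 9)
  g <- goodman_kruskal_gamma(x, y)
  expect_equal(g$concordant, 39)
  expect_equal(g$discordant, 5)
  expect_equal(g$gamma, 34 / 44)
  expect_equal(g$gamma, oracle_gamma(x, y))

  # property: agreement with the oracle on random tied datasets
  set.seed(99)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    xs <- sample(1:12, n, replace = TRUE)
    ys <- xs * sample(c(-1, 1), 1) + sample(1:6, n, replace = TRUE)
    if (length(unique(xs)) < 2 || length(unique(ys)) < 2) next
    expect_equal(goodman_kruskal_gamma(xs, ys)$gamma, oracle_gamma(xs, ys))
  }
})

test_that("closed-form PCA agrees with a generic eigensolver", {
  pairs <- simulate_paired_log2(sim_config(seed = 5, rho = -0.29,
                                           n_pairs = 151))
  std <- impose_correlation(pairs$seed_log2, pairs$partner_log2, -0.29)
  p <- pca_2d_bootstrap(std, n_boot = 0, x = "x", y = "y")
  expect_equal(p$eigenvalues, c(1.29, 0.71), tolerance = 1e-12)

  # generic eigensolver on the same correlation matrix
  eig <- eigen(matrix(c(1, p$r, p$r, 1), 2))
  expect_equal(p$eigenvalues, eig$values, tolerance = 1e-10)
  for (comp in 1:2) {
    v <- eig$vectors[, comp]
    if (v[1] < 0) v <- -v
    expect_equal(unname(p$loadings[comp, ]), v, tolerance = 1e-10)
  }

  # negative correlation: PC1 is the half-difference direction
  expect_equal(unname(p$loadings[1, ]), c(1, -1) / sqrt(2))
  expect_equal(unname(p$loadings[2, ]), c(1, 1) / sqrt(2))

  # loadings stay orthonormal
  expect_equal(p$loadings %*% t(p$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(p$eigenvalues), 2)
})

test_that("PCA component order follows the correlation sign", {
  pos <- tibble::tibble(seed_log2 = c(1, 2, 3, 4, 5.5),
                        partner_log2 = c(1.2, 1.9, 3.4, 3.9, 5))
  pp <- pca_2d_bootstrap(pos, n_boot = 0)
  expect_gt(pp$r, 0)
  expect_equal(unname(pp$loadings[1, ]), c(1, 1) / sqrt(2))

  # r = 0: tie broken toward the difference direction
  zed <- impose_correlation(rnorm(20, 1, 2), rnorm(20), 0)
  pz <- pca_2d_bootstrap(zed, n_boot = 0, x = "x", y = "y")
  expect_equal(pz$eigenvalues, c(1, 1))
  expect_equal(unname(pz$loadings[1, ]), c(1, -1) / sqrt(2))

  # |r| = 1 warns about rank deficiency
  degen <- tibble::tibble(seed_log2 = 1:5, partner_log2 = -(1:5))
  expect_warning(pd <- pca_2d_bootstrap(degen, n_boot = 0),
                 "rank-deficient")
  expect_equal(pd$eigenvalues[2], 0)
})

test_that("bootstrap intervals are seeded and cover the point estimate", {
  pairs <- simulate_paired_log2(sim_config(seed = 8, rho = -0.4,
                                           n_pairs = 60))
  p1 <- pca_2d_bootstrap(pairs, n_boot = 199, seed = 42)
  p2 <- pca_2d_bootstrap(pairs, n_boot = 199, seed = 42)
  expect_identical(p1$bootstrap_intervals, p2$bootstrap_intervals)
  ci <- p1$bootstrap_intervals
  expect_true(all(ci$lower <= ci$estimate + 1e-12))
  expect_true(all(ci$upper >= ci$estimate - 1e-12))
  expect_equal(nrow(tidy(p1)), 4)
})

test_that("binomial sign test reproduces exact tails", {
  expect_equal(binomial_sign_test(6, 6), 0.6128, tolerance = 1e-4)
  expect_equal(binomial_sign_test(1, 1), 0.75)
  expect_equal(binomial_sign_test(10, 0), 2^-10)
  expect_equal(binomial_sign_test(24, 3), 3304 / 134217728)
  expect_true(is.na(binomial_sign_test(0, 0)))
  expect_error(binomial_sign_test(-1, 2),
               class = "crossdeg_validation_error")

  # symmetry, monotonicity in |a - b|, and exact-oracle agreement
  for (tot in c(1, 2, 5, 12, 19, 30)) {
    for (a in 0:tot) {
      b <- tot - a
      expect_equal(binomial_sign_test(a, b), binomial_sign_test(b, a))
      expect_equal(binomial_sign_test(a, b), oracle_binom_tail(a, b),
                   tolerance = 1e-12)
    }
    ps <- binomial_sign_test(seq(ceiling(tot / 2), tot),
                             tot - seq(ceiling(tot / 2), tot))
    expect_true(all(diff(ps) < 0))
  }
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(2^-10, 42), 42 / 1024)
  expect_equal(bonferroni(0.5, 42), 1)
  expect_equal(bonferroni(0.025, 2), 0.05)
  expect_error(bonferroni(0, 3), class = "crossdeg_validation_error")
})

test_that("sign-concordance table reproduces the published seed-gene rows", {
  seed <- tame_rat_degs()
  pairs <- pair_homologs(seed, hypertension_degs(), hemoglobin_pcdh_map())
  conc <- sign_concordance_table(seed, pairs)
  expect_equal(nrow(conc), 42)

  hbb <- conc[conc$gene == "Hbb-b1", ]
  expect_equal(c(hbb$n_pc1, hbb$n_pc2), c(24, 3))
  expect_equal(hbb$p, 3304 / 134217728)
  expect_equal(hbb$p_adj, 42 * 3304 / 134217728)

  pcdh <- conc[conc$gene == "Pcdhb9", ]
  expect_equal(c(pcdh$n_pc1, pcdh$n_pc2), c(10, 0))
  expect_equal(pcdh$p, 2^-10)
  expect_equal(pcdh$p_adj, 42 * 2^-10)

  # seed genes with no partner records carry an ND row
  nd <- conc[conc$gene == "Hnf4a", ]
  expect_equal(nd$flag, "ND")
  expect_true(is.na(nd$p) && is.na(nd$p_adj))
})

test_that("zero partner log2 values are excluded from the sign counts", {
  seed <- tibble::tibble(gene = "S1", log2 = -1)
  pairs <- tibble::tibble(seed_gene = "S1", seed_log2 = -1,
                          partner_gene = c("P1", "P2", "P3"),
                          partner_log2 = c(2, 0, -3),
                          study_id = paste0("st", 1:3), species = "x",
                          tissue = "t", family = NA_character_)
  conc <- sign_concordance_table(seed, pairs)
  expect_equal(conc$n_pc1, 1L)
  expect_equal(conc$n_pc2, 1L)
  expect_equal(conc$n_excluded_zero, 1L)

  expect_error(sign_concordance_table(tibble::tibble(gene = "S1", log2 = 0),
                                      pairs),
               class = "crossdeg_validation_error")
  expect_error(
    sign_concordance_table(seed,
                           pairs |> dplyr::mutate(seed_gene = "S2")),
    class = "crossdeg_validation_error"
  )
})

test_that("planted fully discordant families are Bonferroni-significant", {
  # 42 seed genes, 10 opposite-sign partners each: p_adj = 42 / 1024 < 0.05
  tabs <- simulate_deg_tables(sim_config(seed = 13, n_seed_genes = 42,
                                         frac_discordant = 1,
                                         family_size_range = c(10, 10)))
  pairs <- pair_homologs(tabs$seed_degs, tabs$partner_degs, tabs$map)
  conc <- sign_concordance_table(tabs$seed_degs, pairs)
  expect_true(all(conc$p_adj < 0.05))
})
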
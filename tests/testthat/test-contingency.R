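test_that("divergence polarization follows the fold-change sign", {
  div <- polarize_divergence(divergence_degs())
  hbb <- div[div$gene == "Hbb-b1" & div$tissue == "hippocampus", ]
  expect_equal(hbb$lineage_down, "domestic")
  p15 <- div[div$gene == "Pcdhb15", ]
  expect_equal(p15$lineage_down, "domestic")

  up <- polarize_divergence(tibble::tibble(gene = "X", log2 = 1))
  expect_equal(up$lineage_down, "wild")
  expect_error(polarize_divergence(tibble::tibble(gene = "X", log2 = 0)),
               class = "crossdeg_validation_error")
})

test_that("the lineage-by-direction table matches the published counts", {
  tab <- build_2x2(polarize_divergence(divergence_degs()),
                   hypertension_direction())
  expected <- matrix(c(10L, 0L, 0L, 10L), 2, byrow = TRUE,
                     dimnames = list(lineage = c("wild", "domestic"),
                                     direction = c("hypertensive",
                                                   "normotensive")))
  expect_equal(unclass(tab), expected, ignore_attr = "class")

  expect_equal(sum(build_2x2(polarize_divergence(divergence_degs())[0, ],
                             hypertension_direction())), 0)

  one <- polarize_divergence(tibble::tibble(gene = "X", log2 = -1,
                                            family = "fam"))
  ann <- tibble::tibble(family = "fam", down_effect = "hypertensive")
  t1 <- build_2x2(one, ann)
  expect_equal(t1["domestic", "hypertensive"], 1L, ignore_attr = TRUE)
  expect_equal(t1["wild", "normotensive"], 1L, ignore_attr = TRUE)

  expect_warning(
    build_2x2(polarize_divergence(tibble::tibble(gene = "X", log2 = -1,
                                                 family = "unknown")),
              ann),
    "excluded"
  )
})

test_that("Fisher exact test matches hand and enumeration oracles", {
  perfect <- matrix(c(10, 0, 0, 10), 2)
  fe <- fisher_exact(perfect)
  expect_equal(fe$one_sided_p, 1 / choose(20, 10), tolerance = 1e-10)
  expect_lt(fe$two_sided_p, 0.001)

  flat <- matrix(1, 2, 2)
  expect_equal(fisher_exact(flat)$two_sided_p, 1)

  set.seed(11)
  for (i in 1:40) {
    m <- matrix(rpois(4, sample(1:9, 1)), 2)
    if (sum(m) == 0) next
    o <- oracle_fisher(m)
    f <- fisher_exact(m)
    expect_equal(f$one_sided_p, o$one_sided, tolerance = 1e-7)
    expect_equal(f$two_sided_p, o$two_sided, tolerance = 1e-7)
  }
})

test_that("chi-square test uses the uncorrected statistic by default", {
  perfect <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(chi2_2x2(perfect)$statistic, 20.00)
  expect_equal(chi2_2x2(matrix(5, 2, 2))$statistic, 0)
  # Yates continuity correction: (|ad - bc| - n/2)^2 based statistic
  expect_equal(chi2_2x2(perfect, yates = TRUE)$statistic, 16.2)
  expect_error(chi2_2x2(matrix(c(3, 4, 0, 0), 2, byrow = FALSE)),
               class = "crossdeg_degenerate_error")
})

test_that("contingency invariances hold", {
  set.seed(23)
  for (i in 1:20) {
    m <- matrix(rpois(4, 6) + 1, 2)
    base_f <- fisher_exact(m)$two_sided_p
    swapped <- m[2:1, 2:1]  # simultaneous row and column swap
    expect_equal(fisher_exact(swapped)$two_sided_p, base_f)
    base_c <- chi2_2x2(m)$statistic
    expect_equal(chi2_2x2(m[2:1, ])$statistic, base_c)
    expect_equal(chi2_2x2(m[, 2:1])$statistic, base_c)
    expect_equal(chi2_2x2(t(m))$statistic, base_c)
  }
})

test_that("chi-square and Fisher p-values agree within a factor of 3", {
  set.seed(31)
  kept <- 0
  while (kept < 25) {
    m <- matrix(rpois(4, 12) + 3, 2)
    if (any(rowSums(m) < 10) || any(colSums(m) < 10) || any(m < 5)) next
    kept <- kept + 1
    pf <- fisher_exact(m)$two_sided_p
    pc <- chi2_2x2(m)$p_value
    expect_lt(max(pf, pc) / min(pf, pc), 3)
  }
})

test_that("binomial direction test matches exact tails", {
  expect_equal(binomial_direction_test(10, 10, "ge"), 2^-10)
  expect_equal(binomial_direction_test(8, 27, "le"),
               3505699 / 134217728, tolerance = 1e-12)
  expect_lt(binomial_direction_test(8, 27, "le"), 0.05)
  expect_equal(binomial_direction_test(6, 12, "two_sided"), 1)
  expect_error(binomial_direction_test(5, 4),
               class = "crossdeg_validation_error")

  # tail complementarity: P(X >= k) + P(X <= k) = 1 + P(X = k)
  for (n in c(1, 7, 20, 27)) {
    for (k in 0:n) {
      expect_equal(
        binomial_direction_test(k, n, "ge") +
          binomial_direction_test(k, n, "le"),
        1 + choose(n, k) / 2^n,
        tolerance = 1e-12
      )
    }
  }
})

test_that("SNP direction pattern tests read the bundled counts", {
  counts <- snp_counts()
  cand <- counts[counts$scope == "hypertension_candidate_markers", ]
  res <- snp_pattern_test(cand$n_gt, cand$n_lt, cand$n_toht, cand$n_fromht)
  expect_lt(res$p_ht_equivalence, 0.05)
  expect_equal(res$p_ht_equivalence, 3505699 / 134217728,
               tolerance = 1e-12)

  wg <- counts[counts$scope == "genome_wide_tbp_sites", ]
  res_wg <- snp_pattern_test(wg$n_gt, wg$n_lt)
  expect_gt(res_wg$p_drift_acceptance, 0.99)
  expect_true(is.na(res_wg$p_ht_equivalence))
})

test_that("contingency_report combines all three tests", {
  rep <- contingency_report(matrix(c(10, 0, 0, 10), 2))
  expect_equal(rep$chi2, 20)
  expect_equal(rep$binomial_row1_p, 2^-10)
  expect_equal(rep$binomial_product_p, 2^-20)
})
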
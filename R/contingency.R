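#' Polarize divergence fold changes into lineage expression states
#'
#' For DEG records of a domestic-versus-wild contrast, converts the signed
#' log2 fold change into which lineage shows downregulation of the gene,
#' relative to the most recent common ancestor: `log2 < 0` means the gene
#' is downregulated in the domestic lineage (and upregulated in the wild
#' one); `log2 > 0` the reverse. Zero fold changes have no polarity and are
#' an error.
#'
#' @param records Tibble of DEG records with `gene`, `log2` (contrast
#'   oriented domestic over wild), and optionally `family`, `tissue`.
#' @return The input with added columns `lineage_down` and `lineage_up`
#'   (each `"domestic"` or `"wild"`).
#' @examples
#' polarize_divergence(divergence_degs())
#' @export
polarize_divergence <- function(records) {
  if (any(records$log2 == 0)) {
    abort("log2 = 0 has undefined polarity.",
          class = "crossdeg_validation_error")
  }
  records |>
    mutate(
      lineage_down = ifelse(.data$log2 < 0, "domestic", "wild"),
      lineage_up = ifelse(.data$log2 < 0, "wild", "domestic")
    )
}

#' Build the lineage-by-direction 2x2 contingency table
#'
#' Crosses animal-lineage expression states with their annotated human
#' hypertension direction. Each polarized record contributes two
#' observations: (lineage showing downregulation, the annotated effect of
#' downregulating the human homolog) and (lineage showing upregulation,
#' the complementary effect). Rows are lineages (wild, domestic), columns
#' human directions (hypertensive, normotensive).
#'
#' @param polarities Output of [polarize_divergence()] with a `family`
#'   column.
#' @param annotations Tibble with `family` and `down_effect`
#'   (`"normotensive"` or `"hypertensive"`: the annotated consequence of
#'   downregulating the human homolog; upregulation is the complement).
#' @return A `contingency_2x2` object (an integer 2x2 matrix with dimnames
#'   `lineage` x `direction`). Records with no annotation are dropped with
#'   a warning.
#' @examples
#' build_2x2(polarize_divergence(divergence_degs()), hypertension_direction())
#' @export
build_2x2 <- function(polarities, annotations) {
  joined <- polarities |> left_join(annotations, by = "family")
  missing <- joined |> filter(is.na(.data$down_effect))
  if (nrow(missing) > 0L) {
    warn(paste0("No human-direction annotation for: ",
                paste(unique(missing$gene), collapse = ", "),
                "; records excluded."))
    joined <- joined |> filter(!is.na(.data$down_effect))
  }
  flip <- c(normotensive = "hypertensive", hypertensive = "normotensive")
  obs <- bind_rows(
    joined |> transmute(lineage = .data$lineage_down,
                        direction = .data$down_effect),
    joined |> transmute(lineage = .data$lineage_up,
                        direction = unname(flip[.data$down_effect]))
  )
  tab <- table(factor(obs$lineage, levels = c("wild", "domestic")),
               factor(obs$direction,
                      levels = c("hypertensive", "normotensive")))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(lineage = c("wild", "domestic"),
                              direction = c("hypertensive",
                                            "normotensive")))
  structure(m, class = c("contingency_2x2", "matrix"))
}

as_2x2 <- function(table) {
  m <- unclass(as.matrix(table))
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0) || sum(m) < 1) {
    abort("A 2x2 table of non-negative counts (n >= 1) is required.",
          class = "crossdeg_validation_error")
  }
  storage.mode(m) <- "double"
  m
}

#' Fisher exact test on a 2x2 table
#'
#' Hypergeometric exact test. The two-sided p-value sums all tables with
#' the observed margins whose point probability does not exceed the
#' observed one (the point-probability rule); the one-sided p-value is the
#' tail in the direction of the observed association (greater when
#' `ad >= bc`).
#'
#' @param table A 2x2 matrix of counts (or `contingency_2x2`).
#' @return A one-row tibble with `one_sided_p`, `two_sided_p`,
#'   `odds_ratio`.
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact <- function(table) {
  m <- as_2x2(table)
  two <- fisher.test(m)$p.value
  dir <- if (m[1, 1] * m[2, 2] >= m[1, 2] * m[2, 1]) "greater" else "less"
  one <- fisher.test(m, alternative = dir)$p.value
  tibble(one_sided_p = one, two_sided_p = min(two, 1),
         odds_ratio = unname(fisher.test(m)$estimate))
}

#' Pearson chi-square test on a 2x2 table
#'
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, by default without the
#' Yates continuity correction; p-value from the chi-square distribution
#' with 1 degree of freedom. A zero marginal makes the statistic undefined.
#'
#' @param table A 2x2 matrix of counts.
#' @param yates Apply the continuity correction.
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chi2_2x2(matrix(c(10, 0, 0, 10), 2))
#' @export
chi2_2x2 <- function(table, yates = FALSE) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Zero marginal: chi-square undefined.",
          class = "crossdeg_degenerate_error")
  }
  res <- suppressWarnings(chisq.test(m, correct = yates))
  tibble(statistic = unname(res$statistic), df = 1L,
         p_value = unname(res$p.value))
}

#' Exact binomial direction test
#'
#' Exact tail probabilities of `k` successes in `n` fair-coin trials:
#' `ge` is `P(X >= k)`, `le` is `P(X <= k)`, and `two_sided` doubles the
#' smaller tail (capped at 1).
#'
#' @param k Observed count, `0 <= k <= n`.
#' @param n Number of trials (>= 1).
#' @param alternative `"ge"`, `"le"`, or `"two_sided"`.
#' @return The exact p-value.
#' @examples
#' binomial_direction_test(8, 27, "le")  # 0.0261
#' @export
binomial_direction_test <- function(k, n,
                                    alternative = c("ge", "le",
                                                    "two_sided")) {
  alternative <- match.arg(alternative)
  if (n < 1 || k < 0 || k > n) {
    abort("Need 0 <= k <= n and n >= 1.",
          class = "crossdeg_validation_error")
  }
  ge <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  le <- pbinom(k, n, 0.5)
  switch(alternative,
         ge = ge,
         le = le,
         two_sided = min(1, 2 * min(ge, le)))
}

#' Directional SNP-marker pattern tests
#'
#' Summarizes a row of directional counts for candidate regulatory SNP
#' markers: of `n_res` candidate markers, `n_gt` increase and `n_lt`
#' decrease the binding affinity of the TATA-binding protein; optionally,
#' `n_toht` provoke and `n_fromht` prevent hypertension. Two exact
#' binomial quantities are reported, both stated as interpretations of the
#' conventional genome-scan summaries:
#' * `p_drift_acceptance`: the acceptance probability of the neutral-drift
#'   null that affinity-increasing markers are in the minority,
#'   `1 - P(X <= n_gt | n, 1/2)`;
#' * `p_ht_equivalence`: the one-sided exact tail for the
#'   provoke-versus-prevent split, `P(X <= min(n_toht, n_fromht))`.
#'
#' @param n_gt,n_lt Counts of affinity-increasing / -decreasing markers.
#' @param n_toht,n_fromht Optional counts of hypertension-provoking /
#'   -preventing markers.
#' @return A one-row tibble with the input counts and both p-values
#'   (`p_ht_equivalence` is `NA` when the direction counts are absent).
#' @examples
#' snp_pattern_test(n_gt = 8, n_lt = 19, n_toht = 8, n_fromht = 19)
#' @export
snp_pattern_test <- function(n_gt, n_lt, n_toht = NA_integer_,
                             n_fromht = NA_integer_) {
  n <- n_gt + n_lt
  p_drift <- 1 - binomial_direction_test(n_gt, n, "le")
  p_eq <- NA_real_
  if (!is.na(n_toht) && !is.na(n_fromht)) {
    if (n_toht + n_fromht != n) {
      warn("n_toht + n_fromht differs from n_gt + n_lt.")
    }
    p_eq <- binomial_direction_test(min(n_toht, n_fromht),
                                    n_toht + n_fromht, "le")
  }
  tibble(n_gt = n_gt, n_lt = n_lt, n_toht = n_toht, n_fromht = n_fromht,
         p_drift_acceptance = p_drift, p_ht_equivalence = p_eq)
}

#' Run all three tests on a lineage-by-direction table
#'
#' Convenience wrapper reporting the Fisher exact test, the Pearson
#' chi-square without continuity correction, per-row exact binomial tails
#' (each row's split of `n` observations between the two directions), and
#' their product.
#'
#' @param table A 2x2 matrix of counts (rows = lineages).
#' @return A one-row tibble.
#' @export
contingency_report <- function(table) {
  m <- as_2x2(table)
  fe <- fisher_exact(m)
  ch <- chi2_2x2(m)
  row_p <- vapply(1:2, function(i) {
    binomial_direction_test(max(m[i, ]), sum(m[i, ]), "ge")
  }, numeric(1))
  tibble(
    chi2 = ch$statistic, chi2_p = ch$p_value,
    fisher_one_sided_p = fe$one_sided_p,
    fisher_two_sided_p = fe$two_sided_p,
    binomial_row1_p = row_p[1], binomial_row2_p = row_p[2],
    binomial_product_p = prod(row_p)
  )
}
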
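#' Goodman-Kruskal gamma
#'
#' Rank association `(C - D) / (C + D)` over all unordered pairs of
#' observations, where C counts concordant and D discordant pairs; pairs
#' tied on either variable are dropped from both counts. The p-value uses
#' the standard asymptotic statistic
#' `z = gamma * sqrt((C + D) / (n (1 - gamma^2)))`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A one-row tibble with `gamma`, `concordant`, `discordant`,
#'   `statistic` (z), `p_value` (`NA` when `|gamma| = 1`, where the
#'   asymptotic variance vanishes).
#' @export
goodman_kruskal_gamma <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  prod <- dx * dy
  up <- upper.tri(prod)
  conc <- sum(prod[up] > 0)
  disc <- sum(prod[up] < 0)
  if (conc + disc == 0L) {
    abort("All pairs tied: gamma undefined.",
          class = "crossdeg_degenerate_error")
  }
  g <- (conc - disc) / (conc + disc)
  if (abs(g) < 1) {
    z <- g * sqrt((conc + disc) / (n * (1 - g^2)))
    p <- 2 * pnorm(-abs(z))
  } else {
    z <- NA_real_
    p <- NA_real_
  }
  tibble(gamma = g, concordant = conc, discordant = disc,
         statistic = z, p_value = p)
}

#' Correlation battery on paired log2 fold changes
#'
#' The four association measures used to relate seed-contrast and
#' partner-contrast fold changes of homologous genes: Pearson's r (t
#' reference), Spearman's R, Kendall's tau-b, and the Goodman-Kruskal
#' gamma (asymptotic z reference).
#'
#' @param pairs Tibble with numeric columns `seed_log2` and `partner_log2`
#'   (e.g. from [pair_homologs()] or [simulate_paired_log2()]), or any data
#'   frame whose columns are named by `x`/`y`.
#' @param x,y Column names holding the paired values.
#' @return An object of class `cor_battery`; see [tidy()] and [glance()]
#'   methods. Constant input is a degenerate-input error.
#' @examples
#' pairs <- simulate_paired_log2(sim_config(seed = 1))
#' correlation_battery(pairs)
#' @export
correlation_battery <- function(pairs, x = "seed_log2", y = "partner_log2") {
  xv <- pairs[[x]]
  yv <- pairs[[y]]
  n <- length(xv)
  if (n < 3L) {
    abort("At least 3 pairs are required.", class = "crossdeg_input_error")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Constant input: correlations undefined.",
          class = "crossdeg_degenerate_error")
  }
  pear <- cor.test(xv, yv, method = "pearson")
  ties <- anyDuplicated(xv) > 0L || anyDuplicated(yv) > 0L
  spear <- suppressWarnings(
    cor.test(xv, yv, method = "spearman", exact = !ties)
  )
  kend <- suppressWarnings(
    cor.test(xv, yv, method = "kendall", exact = (n <= 10L && !ties))
  )
  gam <- goodman_kruskal_gamma(xv, yv)
  structure(
    list(
      r = unname(pear$estimate), r_p = pear$p.value,
      R = unname(spear$estimate), R_p = spear$p.value,
      tau = unname(kend$estimate), tau_p = kend$p.value,
      gamma = gam$gamma, gamma_p = gam$p_value,
      n = n
    ),
    class = "cor_battery"
  )
}

#' @export
print.cor_battery <- function(x, ...) {
  cat("<cor_battery> n =", x$n, "pairs\n")
  fmt <- function(est, p) sprintf("% .3f (p = %.3g)", est, p)
  cat("  Pearson r:     ", fmt(x$r, x$r_p), "\n")
  cat("  Spearman R:    ", fmt(x$R, x$R_p), "\n")
  cat("  Kendall tau-b: ", fmt(x$tau, x$tau_p), "\n")
  cat("  G-K gamma:     ", fmt(x$gamma, x$gamma_p), "\n")
  invisible(x)
}

#' @rdname correlation_battery
#' @param x A `cor_battery` object.
#' @param ... Unused.
#' @export
tidy.cor_battery <- function(x, ...) {
  tibble(
    method = c("pearson", "spearman", "kendall", "gamma"),
    estimate = c(x$r, x$R, x$tau, x$gamma),
    p_value = c(x$r_p, x$R_p, x$tau_p, x$gamma_p)
  )
}

#' @rdname correlation_battery
#' @export
glance.cor_battery <- function(x, ...) {
  tibble(r = x$r, r_p = x$r_p, spearman = x$R, spearman_p = x$R_p,
         tau = x$tau, tau_p = x$tau_p, gamma = x$gamma,
         gamma_p = x$gamma_p, n = x$n)
}

#' Exact binomial sign-concordance test
#'
#' For `n1` opposite-sign and `n2` matching-sign homolog records of one seed
#' gene, the one-sided tail probability of the larger count under a fair
#' coin: `p = P(X >= max(n1, n2))` with `X ~ Binomial(n1 + n2, 1/2)`,
#' computed by exact tail summation. Symmetric in its arguments. Both
#' counts zero is "not detected": the result is `NA`.
#'
#' @param n_pc1,n_pc2 Non-negative integer counts (vectorized).
#' @return P-values in (0, 1], or `NA` where both counts are zero.
#' @examples
#' binomial_sign_test(6, 6)   # 0.6128
#' binomial_sign_test(10, 0)  # 2^-10
#' @export
binomial_sign_test <- function(n_pc1, n_pc2) {
  stopifnot(length(n_pc1) == length(n_pc2))
  if (any(n_pc1 < 0 | n_pc2 < 0, na.rm = TRUE)) {
    abort("Counts must be non-negative.", class = "crossdeg_validation_error")
  }
  n <- n_pc1 + n_pc2
  k <- pmax(n_pc1, n_pc2)
  out <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  out[n == 0L] <- NA_real_
  out
}

#' Bonferroni correction
#'
#' `min(1, p * m)` for `m` comparisons (vectorized over `p`).
#'
#' @param p P-values in (0, 1] (`NA` passed through).
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m) {
  if (m < 1) abort("`m` must be >= 1.", class = "crossdeg_validation_error")
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    abort("P-values must lie in (0, 1].", class = "crossdeg_validation_error")
  }
  pmin(1, p * m)
}

#' Per-seed-gene sign-concordance table
#'
#' For each seed DEG, counts homologous partner records whose log2 fold
#' change has the opposite (`n_pc1`) or the same (`n_pc2`) sign as the
#' seed's, tests the imbalance with [binomial_sign_test()], and applies a
#' Bonferroni correction. The counts are named after the principal
#' components of the paired log2 values: the difference-like component
#' loads on opposite-sign pairs and the sum-like component on same-sign
#' pairs. Partner records with log2 exactly 0 have no sign; they are
#' excluded from both counts and reported in `n_excluded_zero`. Seed genes
#' with no partner records get an "ND" (not detected) row with `NA`
#' p-values.
#'
#' @param seed Tibble of seed DEG records (`gene`, `log2`; no zero log2 --
#'   the seed sign must be defined).
#' @param pairs Tibble of homolog pairs from [pair_homologs()] (every
#'   `seed_gene` must appear in `seed`).
#' @param m Bonferroni multiplier; defaults to the number of seed genes
#'   (ND rows included).
#' @return A tibble sorted by gene: `gene`, `n_pc1`, `n_pc2`,
#'   `n_excluded_zero`, `p`, `p_adj`, `flag` (`"ND"` or `""`).
#' @examples
#' seed <- tame_rat_degs()
#' pairs <- pair_homologs(seed, hypertension_degs(), hemoglobin_pcdh_map())
#' sign_concordance_table(seed, pairs)
#' @export
sign_concordance_table <- function(seed, pairs, m = NULL) {
  stopifnot(is.data.frame(seed), is.data.frame(pairs))
  if (any(seed$log2 == 0)) {
    abort("Seed genes with log2 = 0 have undefined sign.",
          class = "crossdeg_validation_error")
  }
  extra <- setdiff(pairs$seed_gene, seed$gene)
  if (length(extra) > 0L) {
    abort(paste0("Pairs reference unknown seed genes: ",
                 paste(extra, collapse = ", ")),
          class = "crossdeg_validation_error")
  }
  m <- m %||% nrow(seed)
  counts <- pairs |>
    left_join(seed |> select("gene", seed_sign = "log2"),
              by = c("seed_gene" = "gene")) |>
    mutate(seed_sign = sign(.data$seed_sign),
           partner_sign = sign(.data$partner_log2)) |>
    group_by(.data$seed_gene) |>
    summarise(
      n_pc1 = sum(.data$partner_sign == -.data$seed_sign &
                    .data$partner_sign != 0),
      n_pc2 = sum(.data$partner_sign == .data$seed_sign &
                    .data$partner_sign != 0),
      n_excluded_zero = sum(.data$partner_sign == 0),
      .groups = "drop"
    )
  seed |>
    select(gene = "gene") |>
    left_join(counts, by = c("gene" = "seed_gene")) |>
    mutate(
      across(c("n_pc1", "n_pc2", "n_excluded_zero"),
             ~ tidyr::replace_na(.x, 0L)),
      p = binomial_sign_test(.data$n_pc1, .data$n_pc2),
      p_adj = bonferroni(.data$p, m),
      flag = ifelse(is.na(.data$p), "ND", "")
    ) |>
    arrange(.data$gene)
}
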
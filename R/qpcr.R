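#' Efficiency-corrected relative expression from quantification cycles
#'
#' Converts a target-gene quantification cycle (Cq) into expression
#' relative to one or more reference genes:
#' `E_t^(-Cq_t) / geomean_j(E_j^(-Cq_j))`, with per-gene amplification
#' factors E in (1, 2] (2 = perfect doubling). Multi-reference
#' normalization uses the geometric mean of the reference quantities. An
#' optional calibrator sample (same structure) scales the result, and any
#' common Cq baseline shift cancels between sample and calibrator.
#'
#' @param target_cq Target-gene Cq for the sample (scalar).
#' @param reference_cq Numeric vector of reference-gene Cqs (>= 1 gene).
#' @param target_efficiency Amplification factor of the target assay.
#' @param reference_efficiency Amplification factor(s) of the reference
#'   assays (recycled across references).
#' @param calibrator Optional list with elements `target_cq` and
#'   `reference_cq` for the calibrator sample.
#' @return Relative expression (dimensionless, > 0).
#' @examples
#' relative_expression(20, c(21, 21))                   # one cycle earlier
#' @export
relative_expression <- function(target_cq, reference_cq,
                                target_efficiency = 2,
                                reference_efficiency = 2,
                                calibrator = NULL) {
  if (length(reference_cq) < 1L || anyNA(reference_cq)) {
    abort("At least one reference Cq is required (no missing values).",
          class = "crossdeg_input_error")
  }
  eff <- c(target_efficiency, reference_efficiency)
  if (any(eff <= 1 | eff > 2)) {
    abort("Amplification efficiencies must lie in (1, 2].",
          class = "crossdeg_validation_error")
  }
  ref_eff <- rep_len(reference_efficiency, length(reference_cq))
  quant <- function(tc, rc) {
    target_efficiency^(-tc) / exp(mean(-rc * log(ref_eff)))
  }
  val <- quant(target_cq, reference_cq)
  if (!is.null(calibrator)) {
    val <- val / quant(calibrator$target_cq, calibrator$reference_cq)
  }
  val
}

#' Summarize qPCR measurements for one gene and group
#'
#' Per-animal means over technical replicates, then the arithmetic group
#' mean across animals. Accepts replicate-level data (columns `rat_id`,
#' `group`, `gene`, `value`) or per-animal summaries (`m0` instead of
#' `value`); missing replicate values ("not detected") are dropped from the
#' affected animal's mean.
#'
#' @param measurements Tibble of qPCR data.
#' @param gene,group Which gene and group to summarize.
#' @return A one-row tibble: `gene`, `group`, `n_rats`, `group_mean`,
#'   `group_sd` (SD of per-animal means; 0 for a single animal),
#'   `per_rat_means` (list column).
#' @examples
#' summarize_group(qpcr_study_data(), "Ascl3", "tame")
#' @export
summarize_group <- function(measurements, gene, group) {
  sel <- measurements |>
    filter(.data$gene == !!gene, .data$group == !!group)
  if (nrow(sel) == 0L) {
    abort(paste0("No measurements for ", gene, " / ", group, "."),
          class = "crossdeg_input_error")
  }
  value_col <- if ("value" %in% names(sel)) "value" else "m0"
  per_rat <- sel |>
    group_by(.data$rat_id) |>
    summarise(m0 = mean(.data[[value_col]], na.rm = TRUE),
              .groups = "drop") |>
    filter(is.finite(.data$m0))
  means <- per_rat$m0
  tibble(
    gene = gene, group = group, n_rats = length(means),
    group_mean = mean(means),
    group_sd = if (length(means) > 1L) sd(means) else 0,
    per_rat_means = list(setNames(means, per_rat$rat_id))
  )
}

#' Summarize every gene-by-group cell of a qPCR table
#'
#' @param measurements Tibble of qPCR data (see [summarize_group()]).
#' @return One row per (gene, group).
#' @export
summarize_qpcr <- function(measurements) {
  cells <- measurements |> distinct(.data$gene, .data$group)
  purrr::map2(cells$gene, cells$group,
              ~ summarize_group(measurements, .x, .y)) |>
    bind_rows() |>
    arrange(.data$gene, .data$group)
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum test with the exact permutation null: for combined sample sizes
#' up to `max_exact_n` the full distribution of U over all
#' `choose(n1 + n2, n1)` group labelings of the pooled (mid-)ranks is
#' enumerated, which remains exact under ties. Larger samples use the
#' normal approximation with tie correction. U counts pairs where an `a`
#' value exceeds a `b` value (ties count 1/2).
#'
#' @param a,b Numeric vectors (non-empty).
#' @param alternative `"two_sided"` (2 x smaller tail, capped at 1),
#'   `"greater"` (a tends larger), or `"less"`.
#' @param max_exact_n Largest combined size for exact enumeration.
#' @return A one-row tibble with `U`, `p_value`, `method`.
#' @examples
#' mann_whitney_exact(c(5, 6, 7), c(1, 2, 3))
#' @export
mann_whitney_exact <- function(a, b,
                               alternative = c("two_sided", "greater",
                                               "less"),
                               max_exact_n = 25L) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0L || n2 == 0L) {
    abort("Both groups must be non-empty.", class = "crossdeg_input_error")
  }
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 + n2 <= max_exact_n) {
    labelings <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[labelings], nrow = n1)) -
      n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_ge <- mean(u_all >= u_obs - eps)
    p_le <- mean(u_all <= u_obs + eps)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z_ge <- (u_obs - 0.5 - mu) / sqrt(sigma2)
    z_le <- (u_obs + 0.5 - mu) / sqrt(sigma2)
    p_ge <- pnorm(z_ge, lower.tail = FALSE)
    p_le <- pnorm(z_le)
    method <- "normal approximation"
  }
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two_sided = min(1, 2 * min(p_ge, p_le)))
  tibble(U = u_obs, p_value = p, method = method)
}

#' Correlate RNA-Seq and qPCR log2 fold changes
#'
#' Matches genes present in both inputs and delegates to
#' [correlation_battery()] on the paired log2 vectors -- the standard
#' cross-platform validation of a sequencing-derived fold-change estimate.
#'
#' @param rnaseq_log2,qpcr_log2 Tibbles with columns `gene`, `log2` (or
#'   named numeric vectors).
#' @return A `cor_battery` over the shared genes (>= 3 required).
#' @export
rnaseq_qpcr_correlation <- function(rnaseq_log2, qpcr_log2) {
  as_tbl <- function(v) {
    if (is.data.frame(v)) return(v)
    tibble(gene = names(v), log2 = unname(v))
  }
  r <- as_tbl(rnaseq_log2)
  q <- as_tbl(qpcr_log2)
  joined <- inner_join(r, q, by = "gene", suffix = c("_rnaseq", "_qpcr"))
  if (nrow(joined) < 3L) {
    abort("Fewer than 3 genes shared between the platforms.",
          class = "crossdeg_input_error")
  }
  correlation_battery(joined, x = "log2_rnaseq", y = "log2_qpcr")
}
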
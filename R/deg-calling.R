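#' Two-group expression matrix
#'
#' A minimal container for a gene-by-sample matrix of non-negative
#' expression values (counts or pre-normalized units) with a two-level group
#' factor over the samples. Group A is the first factor level; fold changes
#' are reported as A over B.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns; no negative values.
#' @param groups Factor (or coercible) of length `ncol(values)` with exactly
#'   two levels, each with at least two samples.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- matrix(rpois(24, 50), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
#' x <- expr_matrix(m, rep(c("A", "B"), each = 3))
#' @export
expr_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    abort("`values` must have gene rownames.", class = "crossdeg_input_error")
  }
  if (anyDuplicated(rownames(values))) {
    abort("Gene rownames must be unique.", class = "crossdeg_input_error")
  }
  if (any(values < 0)) {
    abort("Expression values must be non-negative.",
          class = "crossdeg_input_error")
  }
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (length(groups) != ncol(values)) {
    abort("`groups` must have one entry per sample column.",
          class = "crossdeg_input_error")
  }
  if (nlevels(groups) != 2L || any(table(groups) < 2L)) {
    abort("Exactly two groups with >= 2 samples each are required.",
          class = "crossdeg_input_error")
  }
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", paste(levels(x$groups), collapse = " vs "), ")\n",
      sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# counts-per-million library-size scaling
cpm_scale <- function(values) {
  libsize <- colSums(values)
  if (any(libsize == 0)) {
    abort("A sample column has zero total signal; cannot scale.",
          class = "crossdeg_input_error")
  }
  sweep(values, 2, libsize, "/") * 1e6
}

#' Per-gene log2 fold change between the two groups
#'
#' `log2((mean_A + pseudocount) / (mean_B + pseudocount))` where A is the
#' first group level, i.e. the sign convention "positive = up in A".
#'
#' @param x An [expr_matrix()].
#' @param gene Gene symbol (must be present).
#' @param pseudocount Positive stabilizer added to both group means.
#' @param normalize Scale samples to counts per million first (default TRUE;
#'   set FALSE for pre-normalized input).
#' @return A single log2 fold-change value.
#' @export
log2_fold_change <- function(x, gene, pseudocount = 0.5, normalize = TRUE) {
  stopifnot(inherits(x, "expr_matrix"), pseudocount > 0)
  if (!gene %in% rownames(x$values)) {
    abort(paste0("Gene not found: ", gene), class = "crossdeg_lookup_error")
  }
  vals <- if (normalize) cpm_scale(x$values) else x$values
  v <- vals[gene, ]
  a <- mean(v[x$groups == levels(x$groups)[1]])
  b <- mean(v[x$groups == levels(x$groups)[2]])
  log2((a + pseudocount) / (b + pseudocount))
}

#' Two-sample Z-test on (log-scale) expression values
#'
#' Computes `z = (mean(a) - mean(b)) / sqrt(se_a^2 + se_b^2)` with unpooled
#' standard errors. The inputs are taken as already being on the scale to be
#' tested (callers log-transform first). By default the p-value uses a
#' Student t reference with `n_a + n_b - 2` degrees of freedom: for the
#' balanced two-group designs this package targets the unpooled-SE
#' statistic coincides with the pooled one, so that reference is exactly
#' calibrated at the small group sizes typical of RNA-Seq designs.
#' `reference = "normal"` gives the literal standard-normal formulation
#' `p = 2 * (1 - pnorm(|z|))`, which is anti-conservative at small n.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param reference `"t"` (default) or `"normal"`.
#' @return A one-row tibble with `statistic` (z), `df` (`Inf` for
#'   the normal reference), and `p_value`. Identical degenerate groups
#'   (zero variance, equal means) give z = 0, p = 1; zero pooled SE with
#'   unequal means is an error.
#' @examples
#' fisher_z_test(log2(c(9, 11, 10)), log2(c(4, 5, 6)))
#' @export
fisher_z_test <- function(a, b, reference = c("t", "normal")) {
  reference <- match.arg(reference)
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each group needs >= 2 values.", class = "crossdeg_input_error")
  }
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  se2 <- va + vb
  d <- mean(a) - mean(b)
  if (se2 == 0) {
    if (d == 0) {
      return(tibble(statistic = 0, df = Inf, p_value = 1))
    }
    abort("Zero pooled standard error with unequal means: degenerate input.",
          class = "crossdeg_degenerate_error")
  }
  z <- d / sqrt(se2)
  if (reference == "normal") {
    tibble(statistic = z, df = Inf, p_value = 2 * pnorm(-abs(z)))
  } else {
    df <- length(a) + length(b) - 2
    tibble(statistic = z, df = df, p_value = 2 * pt(-abs(z), df))
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Validates that all p-values lie in (0, 1] and applies the step-up
#' false-discovery-rate adjustment (delegating to [stats::p.adjust()]);
#' the output preserves input order and is capped at 1.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    abort("All p-values must lie in (0, 1].",
          class = "crossdeg_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Default gene-name exclusion patterns
#'
#' Regular expressions (case-insensitive) matching hypothetical, tentative,
#' predicted, uncharacterized, pseudogene, and placeholder symbols that are
#' removed before reporting DEGs.
#'
#' @return Character vector of regexes.
#' @export
deg_exclusion_patterns <- function() {
  c("^LOC\\d+", "^RGD\\d+", "predicted", "hypothetical", "tentative",
    "uncharacterized", "-ps\\d*$")
}

#' Drop hypothetical / predicted / non-coding gene records
#'
#' Removes records whose symbol (or `description`, when present) matches any
#' exclusion pattern, and records annotated with a non-protein-coding
#' `biotype` when that column is present.
#'
#' @param records Tibble of DEG records with a `gene` column.
#' @param patterns Character vector of regexes; see
#'   [deg_exclusion_patterns()].
#' @param quiet Suppress the removal-count message.
#' @return The surviving records; the number removed is attached as
#'   attribute `n_removed`.
#' @export
filter_gene_names <- function(records, patterns = deg_exclusion_patterns(),
                              quiet = FALSE) {
  if (nrow(records) == 0L) {
    return(structure(records, n_removed = 0L))
  }
  hit <- rep(FALSE, nrow(records))
  fields <- records$gene
  if ("description" %in% names(records)) {
    fields <- paste(fields, records$description)
  }
  for (pat in patterns) {
    hit <- hit | grepl(pat, fields, ignore.case = TRUE)
  }
  if ("biotype" %in% names(records)) {
    hit <- hit | (!is.na(records$biotype) &
                    records$biotype != "protein_coding")
  }
  out <- records[!hit, , drop = FALSE]
  if (!quiet) {
    inform(sprintf("filter_gene_names: removed %d of %d records.",
                   sum(hit), nrow(records)))
  }
  structure(out, n_removed = sum(hit))
}

#' Call differentially expressed genes on a two-group matrix
#'
#' The light DE stage: per-gene log2 fold change and two-sample Z-test on
#' log2-transformed (optionally CPM-scaled) values, Benjamini-Hochberg
#' adjustment across all genes, gene-name filtering, then a threshold on
#' the adjusted p-value.
#'
#' @param x An [expr_matrix()].
#' @param alpha Adjusted-p threshold (default 0.05). `alpha = 0` returns an
#'   empty table.
#' @param pseudocount Positive stabilizer for the log transform.
#' @param normalize Counts-per-million scaling before testing.
#' @param reference P-value reference for [fisher_z_test()].
#' @param filter_names Apply [filter_gene_names()] before thresholding.
#' @param study_id,species,tissue,contrast Metadata stamped on the output
#'   records.
#' @return A tibble of DEG records (columns `study_id`, `species`, `tissue`,
#'   `contrast`, `gene`, `log2`, `p`, `p_adj`), sorted by gene. The full
#'   per-gene table (before thresholding) is attached as attribute
#'   `all_genes`.
#' @export
call_degs <- function(x, alpha = 0.05, pseudocount = 0.5, normalize = TRUE,
                      reference = c("t", "normal"), filter_names = TRUE,
                      study_id = "this_study", species = "unspecified",
                      tissue = "unspecified", contrast = "groupA_vs_groupB") {
  stopifnot(inherits(x, "expr_matrix"))
  if (alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].", class = "crossdeg_validation_error")
  }
  reference <- match.arg(reference)
  vals <- if (normalize) cpm_scale(x$values) else x$values
  lv <- log2(vals + pseudocount)
  ia <- x$groups == levels(x$groups)[1]
  ib <- !ia
  res <- purrr::map(seq_len(nrow(lv)), function(i) {
    fisher_z_test(lv[i, ia], lv[i, ib], reference = reference)
  })
  res <- bind_rows(res)
  tbl <- tibble(
    study_id = study_id, species = species, tissue = tissue,
    contrast = contrast, gene = rownames(x$values),
    log2 = log2((rowMeans(vals[, ia, drop = FALSE]) + pseudocount) /
                  (rowMeans(vals[, ib, drop = FALSE]) + pseudocount)),
    p = pmax(res$p_value, .Machine$double.xmin),
    p_adj = benjamini_hochberg(pmax(res$p_value, .Machine$double.xmin))
  )
  if (filter_names) tbl <- filter_gene_names(tbl, quiet = TRUE)
  out <- tbl |> filter(alpha > 0, .data$p_adj < alpha) |> arrange(.data$gene)
  attr(out, "all_genes") <- tbl
  out
}
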
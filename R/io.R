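#' Parse p-values printed as bounds or order-of-magnitude strings
#'
#' Published DEG tables often print significance as `<10^-4`, `10^-2`, or
#' `<0.05`. This parser returns the numeric bound together with a flag
#' marking values that were stated as upper bounds.
#'
#' @param x Character (or numeric) vector.
#' @return A tibble with `value` (numeric) and `bound` (logical: TRUE when
#'   the printed value was a `<` bound).
#' @examples
#' parse_pvalue(c("<10^-4", "0.05", "10^-2", "<0.001"))
#' @export
parse_pvalue <- function(x) {
  x <- as.character(x)
  x <- gsub("−", "-", trimws(x))  # unicode minus
  bound <- grepl("^<", x)
  core <- sub("^<", "", x)
  pow <- grepl("^10\\^?-?\\d+$", core)
  val <- rep(NA_real_, length(x))
  val[pow] <- 10^(as.numeric(sub("^10\\^?", "", core[pow])))
  val[!pow] <- suppressWarnings(as.numeric(core[!pow]))
  tibble(value = val, bound = bound)
}

deg_required_cols <- c("study_id", "species", "tissue", "contrast",
                       "gene", "log2", "p", "p_adj")

#' Read a DEG table from TSV
#'
#' Reads the tab-delimited DEG-record dialect used throughout the package
#' (columns `study_id`, `species`, `tissue`, `contrast`, `gene`, `log2`,
#' `p`, `p_adj`; header row). Significance columns may contain printed
#' bounds like `<10^-4`; they are parsed to the bound value and flagged in
#' `p_bound` / `p_adj_bound`. Malformed rows are reported with their line
#' numbers.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble of DEG records.
#' @export
read_deg_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  missing <- setdiff(deg_required_cols, names(raw))
  if (length(missing) > 0L) {
    abort(paste0("Missing required columns: ",
                 paste(missing, collapse = ", ")),
          class = "crossdeg_schema_error")
  }
  if (nrow(raw) == 0L) {
    return(raw |> mutate(log2 = numeric(0), p = numeric(0),
                         p_adj = numeric(0), p_bound = logical(0),
                         p_adj_bound = logical(0)))
  }
  log2v <- suppressWarnings(as.numeric(gsub("−", "-", raw$log2)))
  pp <- parse_pvalue(raw$p)
  pa <- parse_pvalue(raw$p_adj)
  bad <- which(!is.finite(log2v) | is.na(pp$value) | is.na(pa$value) |
                 is.na(raw$gene) | raw$gene == "")
  if (length(bad) > 0L) {
    abort(paste0("Malformed rows at data line(s): ",
                 paste(bad, collapse = ", ")),
          class = "crossdeg_row_error")
  }
  raw |>
    mutate(log2 = log2v, p = pp$value, p_bound = pp$bound,
           p_adj = pa$value, p_adj_bound = pa$bound)
}

#' Write a DEG table to TSV
#'
#' @param records Tibble of DEG records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(records, path) {
  readr::write_tsv(records |> select(any_of(c(deg_required_cols,
                                              "p_bound", "p_adj_bound"))),
                   path)
  invisible(path)
}

#' Read a homolog map from TSV
#'
#' Columns: `seed_gene`, `partner_gene`, optionally `partner_species`,
#' `family`. Duplicate (seed, partner, species) entries are an error.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_homolog_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("seed_gene", "partner_gene")
  missing <- setdiff(need, names(map))
  if (length(missing) > 0L) {
    abort(paste0("Missing required columns: ",
                 paste(missing, collapse = ", ")),
          class = "crossdeg_schema_error")
  }
  if (!"partner_species" %in% names(map)) {
    map$partner_species <- NA_character_
  }
  key <- paste(map$seed_gene, map$partner_gene, map$partner_species)
  if (anyDuplicated(key)) {
    abort("Duplicate (seed, partner, species) map entries.",
          class = "crossdeg_validation_error")
  }
  map
}

#' Read a qPCR measurement table from TSV
#'
#' Accepts replicate-level data (`rat_id`, `group`, `gene`, `replicate`,
#' `value`) or per-animal summaries (`rat_id`, `group`, `gene`, `m0`,
#' optionally `sem`); `ND` entries become missing values.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_qpcr_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA", "ND"))
  need <- c("rat_id", "group", "gene")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0L) {
    abort(paste0("Missing required columns: ",
                 paste(missing, collapse = ", ")),
          class = "crossdeg_schema_error")
  }
  if (!any(c("value", "m0") %in% names(tbl))) {
    abort("A `value` or `m0` column is required.",
          class = "crossdeg_schema_error")
  }
  num_cols <- intersect(c("replicate", "value", "m0", "sem"), names(tbl))
  tbl |> mutate(across(all_of(num_cols), as.numeric))
}
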
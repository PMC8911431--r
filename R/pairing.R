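#' Normalize a gene symbol for matching
#'
#' Case-folds to upper case and strips surrounding whitespace. Hyphens and
#' internal structure are preserved: family-level homology (e.g. a rodent
#' beta-globin matching a primate alpha-globin) is data, carried by the
#' curated map, never inferred by string surgery.
#'
#' @param symbol Character vector of gene symbols (non-empty after
#'   trimming).
#' @return Canonical upper-case symbols.
#' @examples
#' normalize_symbol(c("Pcdhb9", " HBB ", "Hbb-b1"))
#' @export
normalize_symbol <- function(symbol) {
  out <- toupper(trimws(symbol))
  if (any(is.na(out) | out == "")) {
    abort("Gene symbols must be non-empty.",
          class = "crossdeg_validation_error")
  }
  out
}

#' Pair seed DEGs with homologous partner DEGs
#'
#' Builds the paired fold-change set the concordance stage analyses. A pair
#' is emitted for every homolog-map entry whose seed and partner genes both
#' appear as DEGs -- one pair per partner study record, so a partner gene
#' differentially expressed in k studies/tissues yields k pairs. With
#' `fallback_exact_match = TRUE` (default), exact normalized-symbol matches
#' not already covered by the map are added, approximating implicit
#' one-to-one orthology.
#'
#' @param seed Tibble of seed DEG records (`gene`, `log2`, ...); gene
#'   symbols must be unique.
#' @param others Tibble of partner DEG records (`gene`, `log2`, `study_id`,
#'   `species`, `tissue`, ...).
#' @param map Optional homolog map tibble (`seed_gene`, `partner_gene`,
#'   optionally `partner_species`, `family`). Map entries whose seed gene is
#'   absent from `seed` raise a warning, not an error.
#' @param fallback_exact_match Add exact normalized-symbol matches.
#' @return A tibble of homolog pairs (`seed_gene`, `seed_log2`,
#'   `partner_gene`, `partner_log2`, `study_id`, `species`, `tissue`,
#'   `family`), deterministically sorted by (seed_gene, study_id,
#'   partner_gene); no duplicated (seed, partner, study, tissue) records.
#' @export
pair_homologs <- function(seed, others, map = NULL,
                          fallback_exact_match = TRUE) {
  stopifnot(is.data.frame(seed), is.data.frame(others))
  if (anyDuplicated(seed$gene)) {
    abort("Seed records must have unique gene symbols.",
          class = "crossdeg_validation_error")
  }
  seed_n <- seed |>
    transmute(seed_gene = .data$gene, seed_log2 = .data$log2,
              .seed_key = normalize_symbol(.data$gene))
  others_n <- others |>
    transmute(partner_gene = .data$gene, partner_log2 = .data$log2,
              study_id = .data$study_id, species = .data$species,
              tissue = .data$tissue,
              .partner_key = normalize_symbol(.data$gene))

  pieces <- list()
  if (!is.null(map) && nrow(map) > 0L) {
    map_n <- map |>
      mutate(.seed_key = normalize_symbol(.data$seed_gene),
             .partner_key = normalize_symbol(.data$partner_gene))
    if (!"family" %in% names(map_n)) map_n$family <- NA_character_
    missing <- setdiff(unique(map_n$.seed_key), seed_n$.seed_key)
    if (length(missing) > 0L) {
      orig <- unique(map_n$seed_gene[map_n$.seed_key %in% missing])
      warn(paste0("Homolog map references seed genes absent from the seed ",
                  "DEG table: ", paste(orig, collapse = ", ")))
    }
    pieces$mapped <- map_n |>
      select(".seed_key", ".partner_key", "family") |>
      distinct() |>
      inner_join(seed_n, by = ".seed_key") |>
      inner_join(others_n, by = ".partner_key",
                 relationship = "many-to-many")
  }
  if (fallback_exact_match) {
    pieces$exact <- seed_n |>
      inner_join(others_n, by = c(".seed_key" = ".partner_key"),
                 relationship = "many-to-many") |>
      mutate(family = NA_character_)
  }
  if (length(pieces) == 0L) {
    return(tibble(seed_gene = character(), seed_log2 = numeric(),
                  partner_gene = character(), partner_log2 = numeric(),
                  study_id = character(), species = character(),
                  tissue = character(), family = character()))
  }
  bind_rows(pieces) |>
    select("seed_gene", "seed_log2", "partner_gene", "partner_log2",
           "study_id", "species", "tissue", "family") |>
    distinct(.data$seed_gene, .data$partner_gene, .data$study_id,
             .data$tissue, .keep_all = TRUE) |>
    arrange(.data$seed_gene, .data$study_id, .data$partner_gene)
}
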
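#' Bundled example data
#'
#' Small curated tables shipped with the package, re-keyed from published
#' compilations, so the whole pipeline can be exercised without downloads:
#'
#' * `tame_rat_degs()`: the 42 statistically significant hippocampal DEGs
#'   of a tame-versus-aggressive rat contrast (gene, log2 fold change,
#'   printed significance bounds).
#' * `hypertension_degs()`: 37 hemoglobin-subunit and beta-protocadherin
#'   DEG records compiled from hypertensive-versus-normotensive
#'   transcriptomes of patients and animal models.
#' * `hemoglobin_pcdh_map()`: the curated family-level homolog map pairing
#'   the two seed genes (*Hbb-b1*, *Pcdhb9*) with those partner DEGs.
#' * `concordance_counts()`: per-seed-gene published opposite/matching sign
#'   counts with the printed p-values, for cross-checking the binomial
#'   sign test ("ND" rows have no partner records).
#' * `qpcr_study_data()`: per-animal qPCR relative expression (mean over
#'   three technical replicates, with its SEM) for *Ascl3* and *Defb17* in
#'   8 tame and 8 aggressive rats.
#' * `divergence_degs()`: ten hemoglobin/beta-protocadherin DEG records
#'   from domestic-versus-wild contrasts.
#' * `hypertension_direction()`: annotation of what downregulating each
#'   gene family does to human blood pressure.
#' * `snp_counts()`: directional counts of candidate promoter SNP markers
#'   (TATA-box binding affinity up/down; hypertension provoking/
#'   preventing) next to the genome-wide reference pattern.
#'
#' @return A tibble (see each description).
#' @name example_data
NULL

crossdeg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "crossdeg")
  if (path == "") {
    abort(paste0("Bundled file not found: ", file),
          class = "crossdeg_input_error")
  }
  path
}

#' @rdname example_data
#' @export
tame_rat_degs <- function() {
  read_deg_table(crossdeg_extdata("tame_aggressive_hippocampus_degs.tsv"))
}

#' @rdname example_data
#' @export
hypertension_degs <- function() {
  read_deg_table(crossdeg_extdata("hypertension_partner_degs.tsv"))
}

#' @rdname example_data
#' @export
hemoglobin_pcdh_map <- function() {
  read_homolog_map(crossdeg_extdata("hemoglobin_pcdh_map.tsv"))
}

#' @rdname example_data
#' @export
concordance_counts <- function() {
  readr::read_tsv(
    crossdeg_extdata("sign_concordance_counts.tsv"),
    col_types = readr::cols(gene = "c", n_pc1 = "i", n_pc2 = "i",
                            printed_p = "c", printed_p_adj = "c")
  )
}

#' @rdname example_data
#' @export
qpcr_study_data <- function() {
  read_qpcr_table(crossdeg_extdata("qpcr_relative_expression.tsv"))
}

#' @rdname example_data
#' @export
divergence_degs <- function() {
  read_deg_table(crossdeg_extdata("divergence_degs.tsv"))
}

#' @rdname example_data
#' @export
hypertension_direction <- function() {
  readr::read_tsv(crossdeg_extdata("hypertension_direction.tsv"),
                  col_types = "cc")
}

#' @rdname example_data
#' @export
snp_counts <- function() {
  readr::read_tsv(crossdeg_extdata("snp_direction_counts.tsv"),
                  col_types = readr::cols(scope = "c", .default = "i"))
}
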
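#' Run the cross-study concordance pipeline
#'
#' Orchestrates the analysis stages in their natural order -- pair
#' homologs, correlation battery, bootstrap PCA, sign-concordance table,
#' directional 2x2 contrasts, qPCR summaries -- on in-memory tables or on
#' TSV paths named in a configuration. Stages run only when their inputs
#' are supplied (or their toggle is on); every stage logs its input/output
#' row counts; all randomness flows from `seed`.
#'
#' @param seed_degs Seed-contrast DEG tibble (or TSV path).
#' @param partner_degs Partner DEG tibble (or TSV path).
#' @param map Optional homolog map tibble (or TSV path).
#' @param divergence Optional domestic-versus-wild DEG tibble (or path)
#'   with a `family` column.
#' @param direction Optional family-level human-direction annotation
#'   tibble (or path).
#' @param qpcr Optional qPCR measurement tibble (or path).
#' @param alpha Significance threshold carried into the summary.
#' @param m Bonferroni multiplier override (default: number of seed genes).
#' @param n_boot Bootstrap replicates for the PCA stage.
#' @param seed Integer RNG seed.
#' @param stages Character vector of stages to run, a subset of
#'   `c("pair", "correlate", "pca", "signtest", "contrast", "qpcr")`.
#' @param out_dir Optional directory: per-stage TSV/JSON artifacts and a
#'   `summary.json` are written there.
#' @param quiet Suppress per-stage row-count messages.
#' @return A named list bundle with the per-stage results that ran
#'   (`pairs`, `battery`, `pca`, `concordance`, `contrast`, `qpcr`) plus
#'   `summary` (a one-row tibble).
#' @examples
#' bundle <- run_pipeline(tame_rat_degs(), hypertension_degs(),
#'                        map = hemoglobin_pcdh_map(), n_boot = 99)
#' bundle$concordance
#' @export
run_pipeline <- function(seed_degs = NULL, partner_degs = NULL, map = NULL,
                         divergence = NULL, direction = NULL, qpcr = NULL,
                         alpha = 0.05, m = NULL, n_boot = 999L, seed = 1L,
                         stages = c("pair", "correlate", "pca", "signtest",
                                    "contrast", "qpcr"),
                         out_dir = NULL, quiet = FALSE) {
  if (length(stages) > 0L) {
    stages <- match.arg(stages, several.ok = TRUE)
  }
  if (alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1].", class = "crossdeg_validation_error")
  }
  load_tbl <- function(x, reader) {
    if (is.null(x) || is.data.frame(x)) x else reader(x)
  }
  seed_degs <- load_tbl(seed_degs, read_deg_table)
  partner_degs <- load_tbl(partner_degs, read_deg_table)
  map <- load_tbl(map, read_homolog_map)
  divergence <- load_tbl(divergence, read_deg_table)
  direction <- load_tbl(direction,
                        function(p) readr::read_tsv(p, col_types = "cc"))
  qpcr <- load_tbl(qpcr, read_qpcr_table)
  say <- function(...) if (!quiet) inform(sprintf(...))

  bundle <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "crossdeg_stage_error")
    })
  }

  can_pair <- "pair" %in% stages && !is.null(seed_degs) &&
    !is.null(partner_degs)
  if (can_pair) {
    bundle$pairs <- run_stage("pair",
                              pair_homologs(seed_degs, partner_degs, map))
    say("pair: %d seed x %d partner records -> %d pairs",
        nrow(seed_degs), nrow(partner_degs), nrow(bundle$pairs))
  }
  if ("correlate" %in% stages && !is.null(bundle$pairs) &&
        nrow(bundle$pairs) >= 3L) {
    bundle$battery <- run_stage("correlate",
                                correlation_battery(bundle$pairs))
    say("correlate: n = %d, r = %.3f", bundle$battery$n, bundle$battery$r)
  }
  if ("pca" %in% stages && !is.null(bundle$pairs) &&
        nrow(bundle$pairs) >= 3L) {
    bundle$pca <- run_stage("pca",
                            pca_2d_bootstrap(bundle$pairs, n_boot = n_boot,
                                             seed = seed))
    say("pca: eigenvalues %.3f / %.3f", bundle$pca$eigenvalues[1],
        bundle$pca$eigenvalues[2])
  }
  if ("signtest" %in% stages && !is.null(bundle$pairs) &&
        !is.null(seed_degs)) {
    bundle$concordance <- run_stage(
      "signtest", sign_concordance_table(seed_degs, bundle$pairs, m = m)
    )
    say("signtest: %d seed genes, %d testable rows",
        nrow(bundle$concordance), sum(bundle$concordance$flag == ""))
  }
  if ("contrast" %in% stages && !is.null(divergence) &&
        !is.null(direction)) {
    tab <- run_stage("contrast",
                     build_2x2(polarize_divergence(divergence), direction))
    bundle$contrast <- list(table = tab, tests = contingency_report(tab))
    say("contrast: 2x2 table n = %d", sum(tab))
  }
  if ("qpcr" %in% stages && !is.null(qpcr)) {
    bundle$qpcr <- run_stage("qpcr", summarize_qpcr(qpcr))
    say("qpcr: %d gene x group summaries", nrow(bundle$qpcr))
  }

  bundle$summary <- pipeline_summary(bundle, alpha)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

pipeline_summary <- function(bundle, alpha) {
  sig <- NA_integer_
  if (!is.null(bundle$concordance)) {
    sig <- sum(bundle$concordance$p_adj < alpha, na.rm = TRUE)
  }
  tibble(
    n_pairs = if (is.null(bundle$pairs)) NA_integer_
              else nrow(bundle$pairs),
    pearson_r = if (is.null(bundle$battery)) NA_real_
                else bundle$battery$r,
    pc1_eigenvalue = if (is.null(bundle$pca)) NA_real_
                     else bundle$pca$eigenvalues[1],
    n_significant_concordance = sig,
    fisher_two_sided_p = if (is.null(bundle$contrast)) NA_real_
                         else bundle$contrast$tests$fisher_two_sided_p,
    alpha = alpha
  )
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$pairs)) {
    readr::write_tsv(bundle$pairs, file.path(out_dir, "pairs.tsv"))
  }
  if (!is.null(bundle$battery)) {
    jsonlite::write_json(glance(bundle$battery),
                         file.path(out_dir, "correlations.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$pca)) {
    jsonlite::write_json(
      list(glance = glance(bundle$pca), loadings = tidy(bundle$pca)),
      file.path(out_dir, "pca.json"), auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(bundle$concordance)) {
    out <- bundle$concordance |>
      mutate(p_printed = print_style_p(.data$p),
             p_adj_printed = print_style_p(.data$p_adj))
    readr::write_tsv(out, file.path(out_dir, "sign_concordance.tsv"))
  }
  if (!is.null(bundle$contrast)) {
    jsonlite::write_json(
      list(table = as.data.frame(unclass(bundle$contrast$table)),
           tests = bundle$contrast$tests),
      file.path(out_dir, "contrast.json"), auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(bundle$qpcr)) {
    readr::write_tsv(bundle$qpcr |> select(-"per_rat_means"),
                     file.path(out_dir, "qpcr_summary.tsv"))
  }
  jsonlite::write_json(bundle$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the pipeline from a configuration file
#'
#' Reads a JSON (or YAML, when the `yaml` package is installed)
#' configuration whose entries are [run_pipeline()] arguments -- table
#' entries given as TSV paths, resolved relative to the configuration
#' file -- and executes the pipeline.
#'
#' @param path Path to a `.json` / `.yaml` / `.yml` configuration file.
#' @return The [run_pipeline()] bundle.
#' @export
run_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configuration requires the 'yaml' package.",
            class = "crossdeg_config_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg)) {
    abort("Configuration must be a mapping of run_pipeline() arguments.",
          class = "crossdeg_config_error")
  }
  unknown <- setdiff(names(cfg), names(formals(run_pipeline)))
  if (length(unknown) > 0L) {
    abort(paste0("Unknown configuration entries: ",
                 paste(unknown, collapse = ", ")),
          class = "crossdeg_config_error")
  }
  path_args <- intersect(names(cfg),
                         c("seed_degs", "partner_degs", "map",
                           "divergence", "direction", "qpcr"))
  for (arg in path_args) {
    if (is.character(cfg[[arg]]) && !file.exists(cfg[[arg]])) {
      cfg[[arg]] <- file.path(dirname(path), cfg[[arg]])
    }
    if (is.character(cfg[[arg]]) && !file.exists(cfg[[arg]])) {
      abort(paste0("Configured input does not exist: ", arg),
            class = "crossdeg_config_error")
    }
  }
  do.call(run_pipeline, cfg)
}

#' Render p-values the way published tables print them
#'
#' Two decimals for p >= 0.01, order of magnitude (`10^-k`) below that,
#' `ND` for missing.
#'
#' @param p Numeric vector.
#' @return Character vector.
#' @export
print_style_p <- function(p) {
  out <- ifelse(is.na(p), "ND",
                ifelse(p >= 0.01, sprintf("%.2f", p),
                       sprintf("10^%d", ceiling(log10(p)))))
  out
}
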
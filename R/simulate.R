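#' Simulation settings for synthetic meta-analysis inputs
#'
#' Bundles every knob the synthetic-data generators use, mirroring the study
#' designs the package analyses: paired log2 fold changes with a target
#' Pearson correlation (the observed cross-study correlation of homologous
#' DEGs), multi-study DEG tables in which one seed gene has several
#' family-level homologs with controllable sign agreement, negative-binomial
#' 3-vs-3 count matrices with planted DEGs, and qPCR triplicates for 8 + 8
#' animals.
#'
#' @param seed Integer RNG seed. All generator randomness flows from it; no
#'   global RNG state is touched.
#' @param n_pairs Number of homolog pairs for [simulate_paired_log2()].
#' @param rho Target Pearson correlation of the paired log2 values, in
#'   \[-1, 1\]. Default -0.29, the magnitude reported for stress-reactivity
#'   versus hypertension fold changes of homologous genes.
#' @param n_seed_genes Number of seed DEGs for [simulate_deg_tables()].
#' @param family_size_range Length-2 integer vector, min and max homologs per
#'   seed gene.
#' @param frac_discordant Fraction of seed genes planted with opposite-sign
#'   partners, in \[0, 1\]. The planted count is exactly
#'   `round(frac_discordant * n_seed_genes)`.
#' @param sigma_log2 Standard deviation of simulated log2 fold changes (> 0).
#' @param n_genes Number of genes in a simulated count matrix.
#' @param n_deg Number of planted differentially expressed genes.
#' @param log2_effect Absolute log2 effect size planted on DEGs.
#' @param nb_mean,nb_dispersion Negative-binomial mean and dispersion
#'   (variance = mu + dispersion * mu^2) for count matrices.
#' @param n_replicates Samples per group in the count design (default 3 vs 3).
#' @param n_rats Animals per group in the qPCR design (default 8 vs 8).
#' @param n_qpcr_replicates Technical replicates per animal (default 3).
#' @param n_qpcr_genes Genes in the simulated qPCR panel.
#' @param qpcr_effect Multiplicative group effect for simulated qPCR
#'   (tame / aggressive ratio of expected relative expression).
#' @param qpcr_cv Coefficient of variation of the log-normal qPCR noise.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_pairs = 151, rho = -0.29)
#' pairs <- simulate_paired_log2(cfg)
#' cor(pairs$seed_log2, pairs$partner_log2)
#' @export
sim_config <- function(seed = 1L,
                       n_pairs = 151L,
                       rho = -0.29,
                       n_seed_genes = 42L,
                       family_size_range = c(1L, 10L),
                       frac_discordant = 0.5,
                       sigma_log2 = 2,
                       n_genes = 100L,
                       n_deg = 10L,
                       log2_effect = 4,
                       nb_mean = 200,
                       nb_dispersion = 0.1,
                       n_replicates = 3L,
                       n_rats = 8L,
                       n_qpcr_replicates = 3L,
                       n_qpcr_genes = 2L,
                       qpcr_effect = 10,
                       qpcr_cv = 0.2) {
  cfg <- list(
    seed = as.integer(seed), n_pairs = as.integer(n_pairs), rho = rho,
    n_seed_genes = as.integer(n_seed_genes),
    family_size_range = as.integer(family_size_range),
    frac_discordant = frac_discordant, sigma_log2 = sigma_log2,
    n_genes = as.integer(n_genes), n_deg = as.integer(n_deg),
    log2_effect = log2_effect, nb_mean = nb_mean,
    nb_dispersion = nb_dispersion, n_replicates = as.integer(n_replicates),
    n_rats = as.integer(n_rats),
    n_qpcr_replicates = as.integer(n_qpcr_replicates),
    n_qpcr_genes = as.integer(n_qpcr_genes),
    qpcr_effect = qpcr_effect, qpcr_cv = qpcr_cv
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.finite(cfg$rho) || cfg$rho < -1 || cfg$rho > 1) {
    abort("`rho` must lie in [-1, 1].", class = "crossdeg_config_error")
  }
  if (cfg$frac_discordant < 0 || cfg$frac_discordant > 1) {
    abort("`frac_discordant` must lie in [0, 1].",
          class = "crossdeg_config_error")
  }
  if (!is.finite(cfg$sigma_log2) || cfg$sigma_log2 <= 0) {
    abort("`sigma_log2` must be > 0.", class = "crossdeg_config_error")
  }
  if (cfg$nb_dispersion <= 0) {
    abort("`nb_dispersion` must be > 0.", class = "crossdeg_config_error")
  }
  counts <- c(cfg$n_pairs, cfg$n_seed_genes, cfg$family_size_range,
              cfg$n_genes, cfg$n_replicates, cfg$n_rats,
              cfg$n_qpcr_replicates, cfg$n_qpcr_genes)
  if (any(counts < 1L)) {
    abort("All counts in a `sim_config` must be >= 1.",
          class = "crossdeg_config_error")
  }
  if (cfg$n_deg < 0L || cfg$n_deg > cfg$n_genes) {
    abort("`n_deg` must lie in [0, n_genes].",
          class = "crossdeg_config_error")
  }
  if (cfg$family_size_range[1] > cfg$family_size_range[2]) {
    abort("`family_size_range` must be (min, max) with min <= max.",
          class = "crossdeg_config_error")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " n_pairs:", x$n_pairs, " rho:", x$rho, "\n")
  cat("  seed genes:", x$n_seed_genes, " family size:",
      paste(x$family_size_range, collapse = "-"),
      " frac discordant:", x$frac_discordant, "\n")
  cat("  counts:", x$n_genes, "genes x", 2 * x$n_replicates,
      "samples (NB mean", x$nb_mean, ", dispersion", x$nb_dispersion, ")\n")
  cat("  qPCR:", 2 * x$n_rats, "animals x", x$n_qpcr_replicates,
      "replicates, effect", x$qpcr_effect, "\n")
  invisible(x)
}

#' Simulate paired log2 fold changes with a target correlation
#'
#' Draws `n_pairs` (seed, partner) log2 fold-change pairs from a zero-mean
#' bivariate normal with common variance `sigma_log2^2` and correlation
#' `rho`. This is the synthetic stand-in for the compiled set of homologous
#' DEG pairs whose fold changes correlate across a stress-reactivity and a
#' hypertension contrast. Continuous margins mean exact zeros never occur.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `seed_gene`, `seed_log2`, `partner_gene`,
#'   `partner_log2`, `study_id`, `species`, `tissue` (one row per pair).
#' @examples
#' pairs <- simulate_paired_log2(sim_config(seed = 7, rho = -0.29))
#' correlation_battery(pairs)
#' @export
simulate_paired_log2 <- function(config) {
  validate_sim_config(config)
  n <- config$n_pairs
  rho <- config$rho
  withr::with_seed(config$seed, {
    x <- rnorm(n)
    e <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * e
    tibble(
      seed_gene = sprintf("SG%03d", seq_len(n)),
      seed_log2 = config$sigma_log2 * x,
      partner_gene = sprintf("PG%03d", seq_len(n)),
      partner_log2 = config$sigma_log2 * y,
      study_id = "sim_study_1",
      species = "simulated",
      tissue = "simulated"
    )
  })
}

#' Simulate a seed DEG table, multi-study partner tables, and a homolog map
#'
#' Emulates the input triple the pairing stage consumes: one seed-contrast
#' DEG table, a stack of partner-study DEG records in which each seed gene
#' has a gene family of homologs, and the curated map joining them. A
#' planted-"discordant" seed gene gets partners whose log2 sign is always
#' opposite to its own; all other seed genes get same-sign partners, so the
#' downstream sign counter can be checked against ground truth exactly.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `seed_degs` (DEG records of the seed
#'   contrast), `partner_degs` (multi-study partner records), `map`
#'   (homolog map: `seed_gene`, `partner_gene`, `partner_species`, `family`),
#'   and `truth` (`seed_gene`, `discordant`).
#' @export
simulate_deg_tables <- function(config) {
  validate_sim_config(config)
  n <- config$n_seed_genes
  withr::with_seed(config$seed, {
    genes <- sprintf("Seed%03d", seq_len(n))
    seed_log2 <- config$sigma_log2 *
      sample(c(-1, 1), n, replace = TRUE) * (0.2 + abs(rnorm(n)))
    n_disc <- round(config$frac_discordant * n)
    disc <- rep(FALSE, n)
    disc[sample.int(n, n_disc)] <- TRUE
    sizes <- seq(config$family_size_range[1], config$family_size_range[2])
    fam_size <- sizes[sample.int(length(sizes), n, replace = TRUE)]

    seed_degs <- tibble(
      study_id = "sim_seed_study", species = "rat", tissue = "hippocampus",
      contrast = "tame_vs_aggressive", gene = genes, log2 = seed_log2,
      p = 1e-4, p_adj = 0.01
    )

    partner <- purrr::map(seq_len(n), function(i) {
      k <- fam_size[i]
      sgn <- if (disc[i]) -sign(seed_log2[i]) else sign(seed_log2[i])
      tibble(
        study_id = sprintf("sim_study_%02d", seq_len(k)),
        species = "simulated", tissue = sprintf("tissue_%02d", seq_len(k)),
        contrast = "hypertensive_vs_normotensive",
        gene = sprintf("%s_hom%02d", genes[i], seq_len(k)),
        log2 = sgn * config$sigma_log2 * (0.2 + abs(rnorm(k))),
        p = 1e-3, p_adj = 0.01,
        seed_gene = genes[i]
      )
    })
    partner_degs <- bind_rows(partner)
    map_tbl <- partner_degs |>
      transmute(seed_gene = .data$seed_gene, partner_gene = .data$gene,
                partner_species = .data$species,
                family = .data$seed_gene) |>
      distinct()
    partner_degs$seed_gene <- NULL
    list(
      seed_degs = seed_degs,
      partner_degs = partner_degs,
      map = map_tbl,
      truth = tibble(seed_gene = genes, discordant = disc)
    )
  })
}

#' Simulate a negative-binomial count matrix with planted DEGs
#'
#' Generates a gene-by-sample count matrix for a two-group design
#' (`n_replicates` per group) with negative-binomial noise. The first
#' `n_deg` genes carry a symmetric planted effect: group means differ by
#' `log2_effect` on the log2 scale (alternating direction).
#'
#' @param config A [sim_config()].
#' @return An [expr_matrix()] whose `truth` attribute is a tibble with
#'   `gene`, `planted_log2`.
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    n_g <- config$n_genes
    n_r <- config$n_replicates
    genes <- sprintf("Gene%04d", seq_len(n_g))
    planted <- rep(0, n_g)
    if (config$n_deg > 0L) {
      planted[seq_len(config$n_deg)] <-
        config$log2_effect * rep_len(c(1, -1), config$n_deg)
    }
    mu_a <- config$nb_mean * 2^(planted / 2)
    mu_b <- config$nb_mean * 2^(-planted / 2)
    size <- 1 / config$nb_dispersion
    vals_a <- matrix(rnbinom(n_g * n_r, mu = rep(mu_a, n_r), size = size),
                     nrow = n_g)
    vals_b <- matrix(rnbinom(n_g * n_r, mu = rep(mu_b, n_r), size = size),
                     nrow = n_g)
    values <- cbind(vals_a, vals_b)
    rownames(values) <- genes
    colnames(values) <- c(sprintf("groupA_%d", seq_len(n_r)),
                          sprintf("groupB_%d", seq_len(n_r)))
    x <- expr_matrix(values,
                     groups = factor(rep(c("groupA", "groupB"), each = n_r),
                                     levels = c("groupA", "groupB")))
    attr(x, "truth") <- tibble(gene = genes, planted_log2 = planted)
    x
  })
}

#' Simulate qPCR relative-expression triplicates
#'
#' Emulates the qPCR validation design: `n_rats` tame and `n_rats`
#' aggressive animals, `n_qpcr_replicates` technical replicates per animal
#' and gene, log-normal measurement noise, and a multiplicative group effect
#' (tame mean = `qpcr_effect` x aggressive mean).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `rat_id`, `group` (`"tame"`/`"aggressive"`),
#'   `gene`, `replicate`, `value`.
#' @export
simulate_qpcr <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    genes <- sprintf("Gene%02d", seq_len(config$n_qpcr_genes))
    design <- tidyr::expand_grid(
      group = c("aggressive", "tame"),
      rat = seq_len(config$n_rats),
      gene = genes,
      replicate = seq_len(config$n_qpcr_replicates)
    )
    sdlog <- sqrt(log(1 + config$qpcr_cv^2))
    mu <- ifelse(design$group == "tame", config$qpcr_effect, 1)
    design |>
      mutate(
        rat_id = paste0(substr(.data$group, 1, 1), .data$rat),
        value = mu * rlnorm(nrow(design), meanlog = -sdlog^2 / 2,
                            sdlog = sdlog)
      ) |>
      select("rat_id", "group", "gene", "replicate", "value")
  })
}

#' Rescale a paired sample to an exact sample correlation
#'
#' Constructs, from any paired numeric sample, a new pair of standardized
#' vectors whose sample Pearson correlation equals `rho` exactly (residual
#' orthogonalization followed by remixing). Useful for studying the
#' principal-component geometry at a stated correlation.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, non-constant).
#' @param rho Target sample correlation in (-1, 1).
#' @return A tibble with columns `x`, `y` (standardized; `cor(x, y) == rho`
#'   to machine precision).
#' @export
impose_correlation <- function(x, y, rho) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (!is.finite(rho) || rho <= -1 || rho >= 1) {
    abort("`rho` must lie in (-1, 1).", class = "crossdeg_config_error")
  }
  xs <- as.numeric(scale(x))
  e <- stats::residuals(stats::lm(y ~ x))
  es <- as.numeric(scale(e))
  ys <- rho * xs + sqrt(1 - rho^2) * es
  tibble(x = xs, y = as.numeric(scale(ys)))
}
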
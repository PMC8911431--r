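#' Bootstrap principal-component analysis of paired log2 fold changes
#'
#' Correlation-mode PCA of the two paired log2 variables. The 2x2 sample
#' correlation matrix `[[1, r], [r, 1]]` has the closed-form
#' eigendecomposition: eigenvalues `1 - r` and `1 + r` with eigenvectors
#' `(1, -1)/sqrt(2)` (the half-difference direction) and `(1, 1)/sqrt(2)`
#' (the half-sum direction). Components are ordered by descending
#' eigenvalue, so for negatively correlated pairs PC1 is the
#' half-difference of the two fold changes and PC2 their half-sum; at
#' zero correlation the tie is broken in favour of the difference
#' direction. The
#' sign convention makes the first loading of each component positive.
#'
#' Bootstrap uncertainty: `n_boot` resamples of the pairs with replacement;
#' each replicate's eigenvectors are sign-aligned to the point estimate by
#' dot product before percentile intervals are taken on the loadings.
#'
#' @param pairs Tibble with columns `seed_log2`, `partner_log2` (or as
#'   named by `x`/`y`); n >= 3.
#' @param n_boot Bootstrap replicates (default 999; 0 skips the bootstrap).
#' @param seed Integer RNG seed for the resampling.
#' @param x,y Column names of the paired values.
#' @param conf Confidence level for the percentile intervals.
#' @return An object of class `pca2d`: `loadings` (2x2, rows = components,
#'   columns = variables), `eigenvalues` (descending; they sum to 2),
#'   `r` (sample correlation), `bootstrap_intervals` (tibble),
#'   `n_boot`, `seed`, `n`. `|r| = 1` triggers a rank-deficiency warning
#'   (second eigenvalue 0).
#' @examples
#' pairs <- simulate_paired_log2(sim_config(seed = 3, rho = -0.29))
#' pca_2d_bootstrap(pairs, n_boot = 99, seed = 1)
#' @export
pca_2d_bootstrap <- function(pairs, n_boot = 999L, seed = 1L,
                             x = "seed_log2", y = "partner_log2",
                             conf = 0.95) {
  xv <- pairs[[x]]
  yv <- pairs[[y]]
  n <- length(xv)
  if (n < 3L) {
    abort("At least 3 pairs are required.", class = "crossdeg_input_error")
  }
  r <- cor(xv, yv)
  if (abs(r) >= 1 - 1e-12) {
    r <- sign(r)
    warn("Perfectly correlated input: correlation matrix is rank-deficient.")
  }
  point <- pca2d_closed_form(r)

  intervals <- NULL
  boot_loadings <- NULL
  if (n_boot > 0L) {
    boot_loadings <- withr::with_seed(seed, {
      purrr::map(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        rb <- suppressWarnings(cor(xv[idx], yv[idx]))
        if (is.na(rb)) rb <- 0
        lb <- pca2d_closed_form(rb)$loadings
        # sign-align each replicate component to the point estimate
        for (comp in 1:2) {
          if (sum(lb[comp, ] * point$loadings[comp, ]) < 0) {
            lb[comp, ] <- -lb[comp, ]
          }
        }
        lb
      })
    })
    arr <- simplify2array(boot_loadings)
    alpha <- (1 - conf) / 2
    grid <- tidyr::expand_grid(component = 1:2, variable = 1:2)
    intervals <- grid |>
      mutate(
        estimate = map2_dbl(.data$component, .data$variable,
                            ~ point$loadings[.x, .y]),
        lower = map2_dbl(.data$component, .data$variable,
                         ~ quantile(arr[.x, .y, ], alpha)),
        upper = map2_dbl(.data$component, .data$variable,
                         ~ quantile(arr[.x, .y, ], 1 - alpha)),
        component = paste0("PC", .data$component),
        variable = c(x, y)[.data$variable]
      )
  }
  structure(
    list(loadings = point$loadings, eigenvalues = point$eigenvalues,
         r = r, bootstrap_intervals = intervals, n_boot = n_boot,
         seed = seed, n = n, variables = c(x, y)),
    class = "pca2d"
  )
}

# closed-form eigendecomposition of [[1, r], [r, 1]]; difference direction
# first when r <= 0 (ties broken toward the difference direction, with a
# numerical tolerance so an exactly-decorrelated sample is a tie)
pca2d_closed_form <- function(r) {
  s <- 1 / sqrt(2)
  diff_vec <- c(s, -s)
  sum_vec <- c(s, s)
  if (r <= 1e-12) {
    loadings <- rbind(diff_vec, sum_vec)
    eigenvalues <- c(1 - r, 1 + r)
  } else {
    loadings <- rbind(sum_vec, diff_vec)
    eigenvalues <- c(1 + r, 1 - r)
  }
  dimnames(loadings) <- list(c("PC1", "PC2"), c("x", "y"))
  list(loadings = loadings, eigenvalues = eigenvalues)
}

#' @export
print.pca2d <- function(x, ...) {
  cat("<pca2d> correlation-mode PCA of", x$n, "pairs (r =",
      sprintf("%.3f", x$r), ")\n")
  cat("  eigenvalues:", sprintf("%.3f", x$eigenvalues), "\n")
  dir1 <- if (x$loadings[1, 2] < 0) "half-difference" else "half-sum"
  dir2 <- if (dir1 == "half-difference") "half-sum" else "half-difference"
  cat("  PC1 ~", dir1, " PC2 ~", dir2, "\n")
  if (!is.null(x$bootstrap_intervals)) {
    cat("  bootstrap:", x$n_boot, "replicates, seed", x$seed, "\n")
  }
  invisible(x)
}

#' @rdname pca_2d_bootstrap
#' @param object,x A `pca2d` object.
#' @param ... Unused.
#' @export
tidy.pca2d <- function(x, ...) {
  base <- tidyr::expand_grid(component = c("PC1", "PC2"),
                             variable = x$variables) |>
    mutate(loading = as.vector(t(x$loadings)))
  if (!is.null(x$bootstrap_intervals)) {
    base <- base |>
      left_join(x$bootstrap_intervals |> select(-"estimate"),
                by = c("component", "variable"))
  }
  base
}

#' @rdname pca_2d_bootstrap
#' @export
glance.pca2d <- function(x, ...) {
  tibble(r = x$r, eigenvalue_1 = x$eigenvalues[1],
         eigenvalue_2 = x$eigenvalues[2],
         prop_var_1 = x$eigenvalues[1] / 2, n = x$n, n_boot = x$n_boot)
}

#' @rdname pca_2d_bootstrap
#' @export
autoplot.pca2d <- function(object, ...) {
  dat <- tidy(object)
  p <- ggplot2::ggplot(dat,
                       ggplot2::aes(x = .data$variable, y = .data$loading,
                                    fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(y = "loading", x = NULL,
                  title = "Correlation-mode PCA loadings") +
    ggplot2::theme_minimal()
  if ("lower" %in% names(dat)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.2, position = ggplot2::position_dodge(0.9)
    )
  }
  p
}
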
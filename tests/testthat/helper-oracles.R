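# Independent oracles, deliberately naive: written against the definitions,
# not against the package's implementations.

# exact binomial max-tail by explicit summation of binomial coefficients
oracle_binom_tail <- function(a, b) {
  n <- a + b
  k <- max(a, b)
  if (n == 0) return(NA_real_)
  sum(choose(n, k:n)) / 2^n
}

# Goodman-Kruskal gamma by double loop over all unordered pairs
oracle_gamma <- function(x, y) {
  n <- length(x)
  conc <- 0L
  disc <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1L else if (s < 0) disc <- disc + 1L
    }
  }
  (conc - disc) / (conc + disc)
}

# Kendall tau-b by double loop
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- 0L; disc <- 0L; tx <- 0L; ty <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i])
      sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1L
      else if (sy == 0) ty <- ty + 1L
      else if (sx == sy) conc <- conc + 1L
      else disc <- disc + 1L
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Mann-Whitney exact two-sided p by full enumeration of group labelings
oracle_mw_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  lab <- combn(length(pooled), n1)
  u_all <- apply(lab, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  min(1, 2 * min(mean(u_all >= u_obs - eps), mean(u_all <= u_obs + eps)))
}

# Fisher exact one- and two-sided p by full hypergeometric enumeration
oracle_fisher <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[ks == a]
  two <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  greater <- sum(probs[ks >= a])
  less <- sum(probs[ks <= a])
  one <- if (a * d >= b * c) greater else less
  list(one_sided = one, two_sided = min(1, two))
}

# small balanced expression matrix built from explicit values
make_expr <- function(a_rows, b_rows, genes = NULL) {
  values <- cbind(a_rows, b_rows)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  rownames(values) <- genes
  colnames(values) <- c(paste0("a", seq_len(ncol(a_rows))),
                        paste0("b", seq_len(ncol(b_rows))))
  expr_matrix(values, rep(c("A", "B"), c(ncol(a_rows), ncol(b_rows))))
}
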
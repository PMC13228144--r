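# Independent brute-force oracles and small fixture generators.

# quadruple-sum definition of g2: within-individual cross-locus
# co-heterozygosity over its between-individual expectation, minus one
g2_oracle <- function(h) {
  n <- nrow(h); L <- ncol(h)
  num <- 0; den <- 0
  for (i in seq_len(n))
    for (l in seq_len(L))
      for (m in seq_len(L))
        if (l != m) num <- num + h[i, l] * h[i, m]
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j)
        for (l in seq_len(L))
          for (m in seq_len(L))
            if (l != m) den <- den + h[i, l] * h[j, m]
  if (den <= 0) return(NA_real_)
  (num / n) / (den / (n * (n - 1))) - 1
}

# per-pair double-loop KING-robust kinship
king_oracle <- function(g) {
  n <- nrow(g)
  phi <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    gi <- g[i, ok]; gj <- g[j, ok]
    hethet <- sum(gi == 1 & gj == 1)
    opp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
    den <- sum(gi == 1) + sum(gj == 1)
    phi[i, j] <- phi[j, i] <- if (den > 0) (hethet - 2 * opp) / den
                              else NA_real_
  }
  phi
}

random_gm <- function(n, L, miss = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  if (miss > 0) g[matrix(runif(n * L) < miss, n, L)] <- NA
  genotype_matrix(g)
}

# mis-specified control: selfing depth redrawn per locus instead of per
# individual, which destroys identity disequilibrium while keeping the
# same marginal heterozygote deficit
simulate_locus_independent <- function(freqs, s, n) {
  L <- length(freqs)
  G <- matrix(pmin(rgeom(n * L, 1 - s), 50L), n, L)
  a <- matrix(rbinom(n * L, 1, rep(freqs, each = n)), n, L)
  b <- matrix(rbinom(n * L, 1, rep(freqs, each = n)), n, L)
  ibd <- matrix(runif(n * L), n, L) < (1 - 0.5^G)
  genotype_matrix(a + ifelse(ibd, a, b))
}

equilibrium_g2 <- function(s) s / ((1 - s) * (4 - s))
equilibrium_fis <- function(s) s / (2 - s)
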
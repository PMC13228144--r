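# two diverged lineages fixed (or nearly fixed) for alternate alleles
fixed_pools_gm <- function(n_per = 6, L = 60, planted_admixed = 0) {
  pa <- rep(0.999, L); pb <- rep(0.001, L)
  ga <- matrix(rbinom(n_per * L, 2, pa), n_per, L, byrow = TRUE)
  gb <- matrix(rbinom(n_per * L, 2, pb), n_per, L, byrow = TRUE)
  g <- rbind(ga, gb)
  pops <- rep(c("A", "B"), each = n_per)
  if (planted_admixed > 0) {
    gh <- matrix(rbinom(planted_admixed * L, 1, pa) +
                 rbinom(planted_admixed * L, 1, pb),
                 planted_admixed, L)
    g <- rbind(g, gh)
    pops <- c(pops, rep("H", planted_admixed))
  }
  genotype_matrix(g, populations = pops)
}

test_that("K = 1 collapses to sample allele frequencies", {
  gm <- random_gm(10, 40, miss = 0.1, seed = 70)
  fit <- admixture_em(gm, K = 1, n_restarts = 1, seed = 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, 10))
  expect_equal(unname(fit$P[1, ]), unname(allele_frequencies(gm)),
               tolerance = 1e-5)
})

test_that("fixed-different lineages separate cleanly at K = 2", {
  set.seed(71)
  gm <- fixed_pools_gm()
  fit <- admixture_em(gm, K = 2, n_restarts = 3, seed = 2)
  q1 <- fit$Q[, which.max(fit$Q[1, ])]  # align labels to lineage A
  expect_lt(max(abs(q1[1:6] - 1)), 1e-3)
  expect_lt(max(abs(q1[7:12] - 0)), 1e-3)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  set.seed(72)
  gm <- random_gm(25, 80, miss = 0.1)
  fit <- admixture_em(gm, K = 3, n_restarts = 2, max_iter = 150, seed = 3)
  expect_true(all(diff(fit$ll_trace) > -1e-6 * abs(fit$ll_trace[-1])))
})

test_that("a planted 50/50 admixed individual is recovered", {
  set.seed(73)
  gm <- fixed_pools_gm(n_per = 8, L = 200, planted_admixed = 1)
  fit <- admixture_em(gm, K = 2, n_restarts = 3, seed = 4)
  expect_equal(unname(fit$Q[17, 1]), 0.5, tolerance = 0.02)
})

test_that("K greater than n errors", {
  gm <- random_gm(3, 10, seed = 74)
  expect_error(admixture_em(gm, K = 5, seed = 1), "exceeds")
})

test_that("supervised ancestry matches a grid-search oracle", {
  set.seed(75)
  L <- 150
  pa <- runif(L, 0.1, 0.9); pb <- runif(L, 0.1, 0.9)
  qtrue <- 0.3
  g <- rbinom(L, 2, qtrue * pa + (1 - qtrue) * pb)
  gm <- genotype_matrix(matrix(g, 1))
  got <- unname(supervised_ancestry(gm, pa, pb))
  grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(grid, function(q) {
    f <- pmin(pmax(q * pa + (1 - q) * pb, 1e-6), 1 - 1e-6)
    sum(g * log(f) + (2 - g) * log(1 - f))
  }, numeric(1))
  expect_lt(abs(got - grid[which.max(ll)]), 1e-3)
})

test_that("supervised ancestry hits the boundaries and symmetric center", {
  L <- 100
  pa <- rep(0.999, L); pb <- rep(0.001, L)
  gm <- genotype_matrix(rbind(rep(1L, L), rep(2L, L), rep(0L, L)))
  q <- unname(supervised_ancestry(gm, pa, pb))
  expect_equal(q[1], 0.5, tolerance = 1e-4)  # all-het at fixed loci
  expect_gte(q[2], 0.999)                    # pure pool A
  expect_lte(q[3], 0.001)
  gm_na <- genotype_matrix(matrix(NA_integer_, 1, L))
  expect_true(is.na(supervised_ancestry(gm_na, pa, pb)))
})

test_that("Evanno delta-K reproduces hand arithmetic", {
  base <- c(-100, -50, -45, -44)
  set.seed(76)
  ll <- rbind(base + rnorm(4, 0, 0.05), base + rnorm(4, 0, 0.05),
              base + rnorm(4, 0, 0.05))
  colnames(ll) <- 1:4
  ev <- evanno_delta_k(ll)
  expect_true(is.na(ev$delta_k[1]) && is.na(ev$delta_k[4]))
  expect_identical(ev$K[which.max(ev$delta_k)], 2L)
  # second differences: |45| at K=2 dwarfs |4| at K=3
  expect_gt(ev$delta_k[2] / ev$delta_k[3], 3)

  # linear log-likelihood (replicate-specific offsets keep the SD
  # positive): second differences are exactly zero, so delta-K is 0
  ll_lin <- rbind(seq(-90, -60, by = 10) + 0.3,
                  seq(-90, -60, by = 10) - 0.3)
  colnames(ll_lin) <- 1:4
  ev_lin <- evanno_delta_k(ll_lin)
  expect_equal(max(ev_lin$delta_k, na.rm = TRUE), 0)

  expect_error(evanno_delta_k(matrix(base, 1)), "replicate")
  expect_error(evanno_delta_k(ll[, 1:2]), "3 consecutive")
})

test_that("admixture degree is the population SD of membership rows", {
  expect_equal(admixture_degree(rbind(c(0.5, 0.5))), 0)
  expect_equal(admixture_degree(rbind(c(1, 0))), 0.5)
  expect_equal(admixture_degree(rbind(c(1, 0, 0))), sqrt(2) / 3)
})

test_that("PCA with mean imputation behaves like plain PCA when complete", {
  gm <- random_gm(12, 50, seed = 77)
  pc <- pca_mean_impute(gm, n_components = 3)
  ref <- prcomp(gm$genotypes, center = TRUE)
  expect_equal(abs(unname(pc$scores)), abs(unname(ref$x[, 1:3])),
               tolerance = 1e-8)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
})

test_that("PCA separates fixed-different groups on PC1 and handles duplicates", {
  set.seed(78)
  gm <- fixed_pools_gm(n_per = 5, L = 40)
  gm$genotypes[2, 1:4] <- NA  # exercise imputation
  pc <- pca_mean_impute(gm, 2)
  s1 <- pc$scores[, 1]
  expect_true(all(sign(s1[1:5]) == sign(s1[1])))
  expect_true(all(sign(s1[6:10]) == -sign(s1[1])))

  g <- gm$genotypes; g[is.na(g)] <- 0L
  gm2 <- genotype_matrix(rbind(g, g[1, , drop = FALSE]))
  pc2 <- pca_mean_impute(gm2, 2)
  expect_equal(pc2$scores[1, ], pc2$scores[11, ])
  expect_error(pca_mean_impute(gm, 100), "exceeds")
})
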
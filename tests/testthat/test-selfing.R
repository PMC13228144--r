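test_that("g2 closed form matches hand-evaluated examples", {
  h1 <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  expect_equal(multilocus_g2(h1)$g2, 0)
  h2 <- rbind(c(1, 1), c(0, 0), c(1, 1), c(0, 0))
  expect_equal(multilocus_g2(h2)$g2, 2)
  expect_error(multilocus_g2(h1[1:2, ]), "3 individuals")
  expect_error(multilocus_g2(h1[, 1, drop = FALSE]), "2 loci")
})

test_that("closed form equals the quadruple-sum oracle on random matrices", {
  set.seed(101)
  for (r in 1:40) {
    n <- sample(3:8, 1); L <- sample(2:12, 1)
    h <- matrix(rbinom(n * L, 1, runif(1, 0.1, 0.6)), n, L)
    got <- multilocus_g2(h)
    want <- g2_oracle(h)
    if (is.na(want)) expect_false(got$defined)
    else expect_equal(got$g2, want)
  }
})

test_that("independently permuted columns have mean g2 near zero", {
  set.seed(55)
  h <- matrix(rbinom(20 * 50, 1, 0.3), 20, 50)
  null <- selfpop:::g2_permutation_null(h, 400)
  expect_lt(abs(mean(null, na.rm = TRUE)),
            3 * sd(null, na.rm = TRUE) / sqrt(sum(!is.na(null))))
})

test_that("g2 <-> selfing conversion is exact and monotone", {
  expect_identical(as.numeric(g2_to_selfing(0)), 0)
  expect_equal(as.numeric(g2_to_selfing(2)), 0.8625, tolerance = 1e-4)
  expect_equal(as.numeric(g2_to_selfing(0.2857)), 0.5, tolerance = 1e-3)
  s <- seq(0, 0.99, by = 0.01)
  back <- as.numeric(g2_to_selfing(s / ((1 - s) * (4 - s))))
  expect_lt(max(abs(back - s)), 1e-10)
  neg <- g2_to_selfing(-0.3)
  expect_identical(as.numeric(neg), 0)
  expect_true(attr(neg, "clipped"))
})

test_that("F_IS conversion follows the mixed-mating equilibrium", {
  expect_identical(as.numeric(fis_to_selfing(0)), 0)
  expect_equal(as.numeric(fis_to_selfing(1 / 3)), 0.5)
  expect_identical(as.numeric(fis_to_selfing(1)), 1)
  expect_true(attr(fis_to_selfing(-0.2), "clipped"))
  expect_error(fis_to_selfing(-1), "undefined")
})

test_that("degenerate heterozygosity yields a flagged, not erroring, estimate", {
  gm <- genotype_matrix(matrix(rep(c(0L, 2L), 50), 5, 20))
  est <- estimate_selfing(gm, n_perm = 50, n_boot = 50, seed = 1)
  expect_false(est$defined)
  expect_true(is.na(est$s_hat))
  expect_true(is.na(est$p_value))
  # a single individual carrying all heterozygotes: between-individual
  # cross products vanish, denominator undefined
  g <- matrix(0L, 5, 20)
  g[1, ] <- 1L
  est2 <- estimate_selfing(genotype_matrix(g), n_perm = 0, n_boot = 0)
  expect_false(est2$defined)
})

test_that("permutation p-value uses the add-one convention and detects selfing", {
  set.seed(61)
  p <- runif(400, 0.1, 0.9)
  sim <- simulate_mixed_mating_population(p, s = 0.8, n = 20)
  est <- estimate_selfing(sim$genotypes, n_perm = 199, n_boot = 0)
  expect_identical(est$p_value, 1 / 200)  # no permutation can exceed
  expect_gt(est$s_hat, 0.5)
})

test_that("estimator recovers moderate selfing and subsamples loci", {
  set.seed(62)
  p <- runif(1500, 0.05, 0.95)
  sim <- simulate_mixed_mating_population(p, s = 0.5, n = 60)
  est <- estimate_selfing(sim$genotypes, max_loci = 800, n_perm = 200,
                          n_boot = 300, seed = 8)
  expect_identical(est$n_loci_used, 800L)
  expect_lt(abs(est$s_hat - 0.5), 3 * est$sd_s)
  expect_lt(est$p_value, 0.05)
  expect_named(coef(est), c("s", "g2"))
})

test_that("loci with heavy within-group missingness are dropped first", {
  set.seed(63)
  gm <- random_gm(10, 50)
  gm$genotypes[1:5, 1:10] <- NA  # 50% missing at loci 1-10
  est <- estimate_selfing(gm, n_perm = 0, n_boot = 0)
  expect_identical(est$n_loci_used, 40L)
})

test_that("selfing report mirrors the per-population table layout", {
  set.seed(64)
  p <- runif(300, 0.1, 0.9)
  a <- simulate_mixed_mating_population(p, 0.8, 10, population = "a")
  b <- simulate_mixed_mating_population(p, 0.0, 10, population = "b")
  gm <- genotype_matrix(rbind(a$genotypes$genotypes,
                              b$genotypes$genotypes),
                        sample_ids = c(a$genotypes$sample_ids,
                                       b$genotypes$sample_ids),
                        populations = c(a$genotypes$populations,
                                        b$genotypes$populations))
  rep_ <- selfing_report(gm, n_perm = 100, n_boot = 100, seed = 2)
  expect_identical(rep_$group, c("a", "b"))
  expect_identical(names(rep_),
                   c("group", "n", "H_O", "s", "sd", "p_value",
                     "n_loci_used"))
  expect_gt(rep_$s[1], rep_$s[2])
  expect_gt(rep_$H_O[2], rep_$H_O[1])
})
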
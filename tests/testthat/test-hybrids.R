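# fixed-difference parental pools: every locus fixed for opposite alleles
fixed_pools <- function(L = 400) {
  structure(list(freqs_a = rep(1 - 1e-9, L), freqs_b = rep(1e-9, L),
                 n_a = 5, n_b = 5, clusters = 1:2, threshold = 0.999),
            class = "parent_pools")
}

test_that("parent pools are built from pure individuals only", {
  g <- rbind(matrix(2L, 5, 4), matrix(0L, 5, 4), matrix(1L, 2, 4))
  gm <- genotype_matrix(g)
  Q <- rbind(matrix(c(1, 0), 5, 2, byrow = TRUE),
             matrix(c(0, 1), 5, 2, byrow = TRUE),
             matrix(c(0.5, 0.5), 2, 2))
  pools <- build_parent_pools(gm, Q)
  expect_equal(unname(pools$freqs_a), rep(1, 4))
  expect_equal(unname(pools$freqs_b), rep(0, 4))
  expect_identical(pools$n_a, 5L)

  # hand-computed subgroup frequencies on a 5 x 4 toy
  g2 <- rbind(c(0, 1, 2, 1), c(1, 1, 2, 0), c(0, 0, 2, 1),
              c(2, 2, 0, 0), c(2, 1, 0, 0))
  Q2 <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  pools2 <- build_parent_pools(genotype_matrix(g2), Q2, min_n = 2)
  expect_equal(unname(pools2$freqs_a), c(1 / 6, 2 / 6, 6 / 6, 2 / 6))
  expect_equal(unname(pools2$freqs_b), c(4 / 4, 3 / 4, 0, 0))

  expect_error(build_parent_pools(gm, Q, threshold = 1.1), "pool A")
})

test_that("F1 from fixed-difference pools is exactly heterozygous at q = 0.5", {
  sims <- simulate_hybrid_classes(fixed_pools(), n_per_class = 5,
                                  classes = "F1", seed = 1)
  expect_true(all(sims$sims$H_O == 1))
  expect_true(all(abs(sims$sims$q - 0.5) < 1e-3))
  expect_true(all(sims$genotypes$genotypes == 1L))
})

test_that("hybrid classes match Mendelian H_O and ancestry expectations", {
  sims <- simulate_hybrid_classes(fixed_pools(), n_per_class = 25, seed = 2)
  agg <- aggregate(cbind(q, H_O) ~ class, data = sims$sims, FUN = mean)
  row <- function(cl) agg[agg$class == cl, ]
  L <- 400; n <- 25
  se <- function(p) 3 * sqrt(p * (1 - p) / (L * n))
  expect_lt(abs(row("F2")$H_O - 0.5), se(0.5))
  expect_lt(abs(row("F1xA")$H_O - 0.5), se(0.5))
  expect_lt(abs(row("F1AxA")$H_O - 0.25), se(0.25))
  expect_lt(abs(row("F1xA")$q - 0.75), 0.02)
  expect_lt(abs(row("F1AxA")$q - 0.875), 0.02)
  expect_lt(abs(row("F1BxB")$q - 0.125), 0.02)
  # expectation ordering of class-mean ancestry
  expect_true(row("F1AxA")$q > row("F1xA")$q,
              row("F1xA")$q > row("F1")$q)
  expect_true(abs(row("F1")$q - row("F2")$q) < 0.05)
  expect_true(row("F1")$q > row("F1xB")$q,
              row("F1xB")$q > row("F1BxB")$q)
  expect_error(simulate_hybrid_classes(fixed_pools(), classes = "F3"),
               "unknown hybrid class")
})

test_that("selfing decay halves heterozygosity per generation, q stable", {
  sims <- simulate_hybrid_classes(fixed_pools(), n_per_class = 20,
                                  classes = "F1", seed = 3)
  expect_identical(selfing_decay(sims, 0)$genotypes$genotypes,
                   sims$genotypes$genotypes)
  aged <- selfing_decay(sims, 4, seed = 4)
  expect_equal(mean(aged$sims$H_O), 1 / 16, tolerance = 0.15)
  expect_lt(abs(mean(aged$sims$q) - 0.5), 0.02)
  # fully homozygous genotypes never change
  gm0 <- genotype_matrix(matrix(rep(c(0L, 2L), 50), 5, 20))
  expect_identical(selfing_decay(gm0, 7, seed = 1)$genotypes,
                   gm0$genotypes)
})

test_that("recency classifier is self-consistent and detects decay", {
  sims <- simulate_hybrid_classes(fixed_pools(), n_per_class = 25, seed = 5)
  fresh <- simulate_hybrid_classes(fixed_pools(), n_per_class = 5,
                                   classes = "F1", seed = 6)
  calls <- classify_recency(fresh$sims$q, fresh$sims$H_O, sims)
  expect_true(all(calls$call == "recent"))

  aged <- selfing_decay(fresh, 6, seed = 7)
  calls2 <- classify_recency(aged$sims$q, aged$sims$H_O, sims)
  expect_true(all(calls2$call == "historical"))

  # pure individual with no simulated mass within the maximal window
  # stays unresolved (backcross-to-B sims all sit near q = 0.125)
  far <- simulate_hybrid_classes(fixed_pools(), n_per_class = 25,
                                 classes = "F1BxB", seed = 8)
  calls3 <- classify_recency(0.999, 0.01, far)
  expect_identical(calls3$call, "unresolved")
  expect_true(is.na(calls3$env_lo))
})

test_that("window doubling widens until enough matches accumulate", {
  sdf <- data.frame(class = "F1", sample_id = paste0("s", 1:30),
                    q = rep(0.5, 30), H_O = runif(30, 0.4, 0.6))
  calls <- classify_recency(0.30, 0.5, sdf, q_window = 0.05,
                            min_matches = 20)
  expect_identical(calls$call, "recent")
  expect_gt(calls$window, 0.05)
  expect_identical(calls$n_matched, 30L)
})
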
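toy_config <- function(seed = 1) {
  scenario_config(
    n_loci = 400,
    lineages = data.frame(label = c("A", "B"), fst = c(0.2, 0.3)),
    populations = data.frame(code = c("p1", "p2"), lineage = c("A", "B"),
                             n = c(10, 8), s = c(0.8, 0.0)),
    seed = seed)
}

test_that("scenario config validates its fields", {
  expect_error(scenario_config(100, data.frame(label = "A", fst = 1),
                               data.frame(code = "p", lineage = "A", n = 3,
                                          s = 0.5), seed = 1), "fst")
  expect_error(scenario_config(100, data.frame(label = "A", fst = 0.1),
                               data.frame(code = "p", lineage = "A", n = 3,
                                          s = 1.5), seed = 1), "selfing")
  expect_error(scenario_config(100, data.frame(label = "A", fst = 0.1),
                               data.frame(code = "p", lineage = "A", n = 3,
                                          s = 0.5)), "seed")
  expect_s3_class(toy_config(), "scenario_config")
})

test_that("scenario config round-trips through YAML", {
  cfg <- toy_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  back <- read_scenario_config(path)
  expect_equal(back$populations, cfg$populations)
  expect_equal(back$lineages, cfg$lineages)
  expect_identical(back$seed, cfg$seed)
})

test_that("lineage frequencies are seeded, bounded, and follow the model", {
  cfg <- toy_config()
  f1 <- simulate_lineage_frequencies(cfg)
  f2 <- simulate_lineage_frequencies(cfg)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 1e-6 & f1 <= 1 - 1e-6))

  # F -> 0 recovers the ancestral frequencies
  cfg0 <- toy_config()
  cfg0$lineages$fst <- c(1e-6, 0)
  f0 <- simulate_lineage_frequencies(cfg0)
  p0 <- attr(f0, "ancestral")
  expect_identical(f0["B", ], pmin(pmax(p0, 1e-6), 1 - 1e-6))
  expect_lt(max(abs(f0["A", ] - p0)), 0.02)

  # Balding-Nichols moments at larger L: mean p0, variance F p0 (1 - p0)
  cfg2 <- scenario_config(10000,
                          data.frame(label = "A", fst = 0.3),
                          data.frame(code = "p", lineage = "A", n = 3,
                                     s = 0), seed = 99)
  fA <- simulate_lineage_frequencies(cfg2)
  p0 <- attr(fA, "ancestral")
  dev <- fA["A", ] - p0
  expect_lt(abs(mean(dev)), 0.01)
  expect_lt(abs(var(dev) - 0.3 * mean(p0 * (1 - p0))), 0.01)
})

test_that("mixed-mating sampler reproduces the geometric selfing-depth law", {
  p <- rep(0.5, 10)
  sim <- simulate_mixed_mating_population(p, s = 0.5, n = 3000, seed = 21)
  G <- sim$truth$G
  expect_equal(mean(G == 0), 0.5, tolerance = 0.05)
  expect_equal(mean(G), 1, tolerance = 0.1)  # s / (1 - s)
  expect_lte(max(G), 50)
  expect_warning(simulate_mixed_mating_population(p, s = 1, n = 5), "cap")
})

test_that("same seed reproduces simulations bit for bit", {
  p <- runif(100)
  a <- simulate_mixed_mating_population(p, 0.5, 20, seed = 3)
  b <- simulate_mixed_mating_population(p, 0.5, 20, seed = 3)
  expect_identical(a$genotypes$genotypes, b$genotypes$genotypes)
  expect_identical(a$truth$G, b$truth$G)
})

test_that("shared selfing depth creates identity disequilibrium; per-locus depth does not", {
  set.seed(77)
  p <- runif(2000, 0.05, 0.95)
  s <- 0.5
  shared <- simulate_mixed_mating_population(p, s, n = 200)
  g2_shared <- multilocus_g2(shared$genotypes)$g2
  indep <- simulate_locus_independent(p, s, n = 200)
  g2_indep <- multilocus_g2(indep)$g2
  expect_gt(g2_shared, 0.15)             # near s/((1-s)(4-s)) = 0.286
  expect_lt(abs(g2_indep), 0.05)         # no cross-locus correlation
  # both have the same marginal heterozygote deficit
  fis_shared <- diversity_summary(shared$genotypes)$groups$F_IS
  fis_indep <- diversity_summary(indep)$groups$F_IS
  expect_equal(fis_shared, fis_indep, tolerance = 0.1)
})

test_that("self_offspring follows the g-round Mendelian law", {
  row <- c(0L, 2L, 2L, 0L, NA)
  expect_identical(self_offspring(row, 0), row)
  expect_identical(self_offspring(row, 5, seed = 1), row)

  set.seed(31)
  hets <- rep(1L, 20000)
  out <- self_offspring(hets, 3)
  ph <- mean(out == 1)
  se <- sqrt(0.125 * 0.875 / 20000)
  expect_lt(abs(ph - 0.125), 3 * se)
  fixed <- out[out != 1L]
  expect_equal(mean(fixed == 2L), 0.5, tolerance = 0.02)
  expect_error(self_offspring(hets, -1), ">= 0")
})

test_that("missingness masking hits the requested mean and is seeded", {
  # the Beta law of per-individual rates is strongly right-skewed
  # (SD about 0.11), so the grand mean needs many individuals to settle
  gm <- random_gm(1500, 300, seed = 41)
  masked <- apply_missingness(gm, 0.065, seed = 42)
  expect_lt(abs(mean(is.na(masked$genotypes)) - 0.065), 0.01)
  again <- apply_missingness(gm, 0.065, seed = 42)
  expect_identical(masked$genotypes, again$genotypes)
  expect_identical(apply_missingness(gm, 0)$genotypes, gm$genotypes)
  expect_error(apply_missingness(gm, 1), "mean_rate")
})

test_that("study preset has the expected structure", {
  sim <- simulate_study("paper_like", seed = 5)
  expect_identical(length(unique(sim$genotypes$populations)), 30L)
  expect_identical(ncol(sim$genotypes$genotypes), 6000L)
  expect_identical(nrow(sim$truth), nrow(sim$genotypes$genotypes))
  expect_identical(nrow(sim$truth), 266L)
  expect_true(all(c("F1", "F1xA") %in% sim$truth$class))
  expect_true(any(sim$truth$g_post >= 4))

  # non-admixed invasive individuals less diverse than the outcrossing
  # native population
  d <- diversity_summary(sim$genotypes)
  inv <- sim$truth$class == "pure" &
    sim$truth$lineage %in% c("RED", "ORANGE", "YELLOW")
  agul <- sim$genotypes$populations == "ZA-AGUL" & sim$truth$class == "pure"
  expect_lt(mean(d$individuals$H_O[inv]),
            mean(d$individuals$H_O[agul]))
  expect_error(simulate_study("nope", seed = 1), "preset")
  expect_error(simulate_study("paper_like"), "seed")
})
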
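#' Scenario configuration for the synthetic-data generator
#'
#' Bundles and validates everything the generator needs: number of unlinked
#' loci, the ancestral allele-frequency law, lineage divergence parameters,
#' population specifications (lineage, size, selfing rate), per-individual
#' missingness law, optional planted admixture events, and a mandatory seed.
#'
#' @param n_loci Number of unlinked biallelic loci.
#' @param lineages Data frame with columns `label` and `fst` (an F_ST-like
#'   Balding-Nichols divergence parameter in `[0, 1)`; 0 copies the ancestral
#'   frequencies).
#' @param populations Data frame with columns `code`, `lineage`, `n`
#'   (number of non-admixed individuals; may be 0 for populations composed
#'   entirely of planted hybrids) and `s` (selfing rate in `[0, 1]`).
#' @param ancestral_range Length-2 numeric: bounds of the uniform ancestral
#'   allele-frequency law. Default `c(0.05, 0.95)`, keeping loci informative
#'   like SNP-discovery panels.
#' @param missingness List with `mean` (per-individual mean missing rate,
#'   `[0, 1)`) and `concentration` of the Beta law of per-individual rates.
#' @param admixture_events Optional data frame, one row per planted hybrid:
#'   `population` (host code), `parent_a`, `parent_b` (lineage labels),
#'   `class` (`"F1"` or `"F1xA"`, a first-generation backcross to parent A)
#'   and `g_post` (post-hybridization selfing generations; 0 = recent).
#' @param seed Mandatory integer seed.
#' @return Object of class `scenario_config` (a validated list).
#' @seealso [simulate_study()], [read_scenario_config()]
#' @export
scenario_config <- function(n_loci, lineages, populations,
                            ancestral_range = c(0.05, 0.95),
                            missingness = list(mean = 0.065,
                                               concentration = 4.25),
                            admixture_events = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  lineages <- as.data.frame(lineages)
  populations <- as.data.frame(populations)
  stopifnot(n_loci >= 1,
            all(c("label", "fst") %in% names(lineages)),
            all(c("code", "lineage", "n", "s") %in% names(populations)))
  if (any(lineages$fst < 0 | lineages$fst >= 1))
    stop("lineage fst must be in [0, 1)")
  if (any(populations$s < 0 | populations$s > 1))
    stop("population selfing rates must be in [0, 1]")
  if (any(populations$n < 0)) stop("population sizes must be >= 0")
  if (!all(populations$lineage %in% lineages$label))
    stop("population lineage not in lineage table")
  if (length(ancestral_range) != 2 || ancestral_range[1] >= ancestral_range[2]
      || ancestral_range[1] < 0 || ancestral_range[2] > 1)
    stop("invalid ancestral_range")
  if (missingness$mean < 0 || missingness$mean >= 1)
    stop("missingness mean must be in [0, 1)")
  if (!is.null(admixture_events)) {
    admixture_events <- as.data.frame(admixture_events)
    stopifnot(all(c("population", "parent_a", "parent_b", "class",
                    "g_post") %in% names(admixture_events)))
    if (!all(admixture_events$class %in% c("F1", "F1xA")))
      stop("planted hybrid class must be 'F1' or 'F1xA'")
    if (!all(admixture_events$population %in% populations$code))
      stop("admixture event host population unknown")
    if (!all(c(admixture_events$parent_a, admixture_events$parent_b) %in%
             lineages$label))
      stop("admixture event parent lineage unknown")
    if (any(admixture_events$g_post < 0)) stop("g_post must be >= 0")
  }
  tot <- tapply(populations$n, populations$code, sum)
  if (!is.null(admixture_events)) {
    extra <- table(admixture_events$population)
    tot[names(extra)] <- tot[names(extra)] + as.numeric(extra)
  }
  if (any(tot < 1)) stop("every population needs at least 1 individual")
  structure(list(n_loci = as.integer(n_loci), lineages = lineages,
                 populations = populations,
                 ancestral_range = as.numeric(ancestral_range),
                 missingness = missingness,
                 admixture_events = admixture_events,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config:", nrow(x$populations), "populations,",
      nrow(x$lineages), "lineages,", x$n_loci, "loci, seed", x$seed, "\n")
  invisible(x)
}

#' Read / write a scenario configuration (YAML)
#'
#' @param config A `scenario_config`.
#' @param path File path.
#' @return `read_scenario_config()` returns a validated `scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  x <- unclass(config)
  x$lineages <- as.list(x$lineages)
  x$populations <- as.list(x$populations)
  if (!is.null(x$admixture_events))
    x$admixture_events <- as.list(x$admixture_events)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  scenario_config(n_loci = x$n_loci,
                  lineages = as.data.frame(x$lineages),
                  populations = as.data.frame(x$populations),
                  ancestral_range = x$ancestral_range,
                  missingness = x$missingness,
                  admixture_events = if (!is.null(x$admixture_events))
                    as.data.frame(x$admixture_events) else NULL,
                  seed = x$seed)
}

#' Draw lineage allele frequencies under the Balding-Nichols model
#'
#' Draws ancestral frequencies from the configured uniform law and, for each
#' lineage with divergence parameter F, per-locus frequencies from
#' `Beta(p0 (1 - F) / F, (1 - p0)(1 - F) / F)` (star-shaped divergence).
#' `F = 0` copies the ancestral frequencies. Frequencies are clipped to
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; defaults to `config$seed`. Pass `NULL` to
#'   continue the current RNG stream.
#' @return Matrix of class `allele_freq_table`, lineages in rows (named by
#'   label), loci in columns, with the ancestral frequencies in attribute
#'   `"ancestral"`.
#' @export
simulate_lineage_frequencies <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  L <- config$n_loci
  p0 <- stats::runif(L, config$ancestral_range[1], config$ancestral_range[2])
  eps <- 1e-6
  out <- matrix(NA_real_, nrow(config$lineages), L,
                dimnames = list(config$lineages$label, NULL))
  for (k in seq_len(nrow(config$lineages))) {
    f <- config$lineages$fst[k]
    out[k, ] <- if (f == 0) p0 else
      stats::rbeta(L, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  }
  out <- pmin(pmax(out, eps), 1 - eps)
  attr(out, "ancestral") <- p0
  class(out) <- c("allele_freq_table", "matrix")
  out
}

# Geometric selfing-ancestry depth, capped so residual heterozygosity
# 2^-cap is numerically zero; s = 1 would otherwise never terminate.
draw_selfing_depth <- function(n, s, cap = 50L) {
  if (s >= 1) {
    warning("s = 1: selfing depth capped at ", cap)
    return(rep(cap, n))
  }
  pmin(stats::rgeom(n, 1 - s), cap)
}

#' Simulate a partially selfing population at mixed-mating equilibrium
#'
#' Draws `n` individuals from one lineage's allele frequencies under the
#' geometric selfing-depth model: each individual first draws its number of
#' consecutive selfing ancestor generations `G` with
#' `P(G = g) = (1 - s) s^g`, once, shared across loci. At each locus one
#' allele is drawn from the population frequency; with probability
#' `1 - (1/2)^G` the second allele is identical by descent (equal to the
#' first), otherwise drawn independently. The shared `G` is what generates
#' identity disequilibrium (correlated heterozygosity across loci), the
#' signal read by [multilocus_g2()]. At equilibrium
#' `F_IS = s / (2 - s)` and `g2 = s / ((1 - s)(4 - s))`.
#'
#' @param freqs Numeric vector of per-locus allele frequencies.
#' @param s Selfing rate in `[0, 1]`; `s = 1` is handled by capping `G` at
#'   50 (with a warning).
#' @param n Number of individuals.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @param population Population label for the result.
#' @param sample_prefix Prefix for generated sample ids.
#' @return List with `genotypes` (a [genotype_matrix]) and `truth` (data
#'   frame: sample_id, population, G).
#' @examples
#' p <- runif(500, 0.1, 0.9)
#' sim <- simulate_mixed_mating_population(p, s = 0.5, n = 50, seed = 1)
#' mean(sim$truth$G)  # about s / (1 - s) = 1
#' @export
simulate_mixed_mating_population <- function(freqs, s, n, seed = NULL,
                                             population = "pop1",
                                             sample_prefix = population) {
  stopifnot(s >= 0, s <= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  G <- draw_selfing_depth(n, s)
  a <- matrix(stats::rbinom(n * L, 1L, rep(freqs, each = n)), n, L)
  b <- matrix(stats::rbinom(n * L, 1L, rep(freqs, each = n)), n, L)
  ibd <- matrix(stats::runif(n * L), n, L) < (1 - 0.5^G)
  g <- a + ifelse(ibd, a, b)
  gm <- genotype_matrix(g, sample_ids = paste0(sample_prefix, "_",
                                               seq_len(n)),
                        populations = rep(population, n))
  truth <- data.frame(sample_id = gm$sample_ids, population = population,
                      G = G, stringsAsFactors = FALSE)
  list(genotypes = gm, truth = truth)
}

#' Self-fertilize genotypes for a number of generations
#'
#' Applies `generations` rounds of Mendelian self-fertilization to each
#' locus independently: homozygotes breed true, a heterozygote segregates
#' 1/4 : 1/2 : 1/4 each round. After `g` rounds a heterozygous locus remains
#' heterozygous with probability `(1/2)^g` and otherwise fixes to either
#' homozygote with equal probability; the implementation draws from this
#' exact `g`-round law directly. Missing stays missing.
#'
#' @param x Genotype vector, matrix (individuals in rows), or
#'   [genotype_matrix].
#' @param generations Non-negative integer number of selfing generations.
#' @param seed Integer seed, or `NULL`.
#' @return Same shape/class as `x`.
#' @export
self_offspring <- function(x, generations, seed = NULL) {
  if (generations < 0) stop("generations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "genotype_matrix")) {
    x$genotypes <- self_offspring(x$genotypes, generations)
    return(x)
  }
  if (generations == 0) return(x)
  g <- x
  het <- which(!is.na(g) & g == 1L)
  if (length(het)) {
    stay <- stats::runif(length(het)) < 0.5^generations
    fix2 <- stats::runif(length(het)) < 0.5
    g[het] <- ifelse(stay, 1L, ifelse(fix2, 2L, 0L))
  }
  g
}

#' Mask genotypes with per-individual Beta-distributed missingness
#'
#' Draws each individual's missing rate from a Beta law with the given mean
#' and concentration (shape1 = mean * concentration), then masks entries
#' uniformly at random within the individual. The default concentration of
#' 4.25 reproduces a strongly right-skewed missingness profile (mean 6.5%,
#' median about 1.6%) typical of reduced-representation sequencing.
#'
#' @param gm A [genotype_matrix].
#' @param mean_rate Mean per-individual missing rate, in `[0, 1)`.
#' @param concentration Beta concentration (shape1 + shape2). Default 4.25.
#' @param seed Integer seed, or `NULL`.
#' @return The masked [genotype_matrix]; `mean_rate = 0` returns the input.
#' @export
apply_missingness <- function(gm, mean_rate, concentration = 4.25,
                              seed = NULL) {
  if (mean_rate < 0 || mean_rate >= 1) stop("mean_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (mean_rate == 0) return(gm)
  g <- gm$genotypes
  n <- nrow(g); L <- ncol(g)
  rate <- stats::rbeta(n, mean_rate * concentration,
                       (1 - mean_rate) * concentration)
  mask <- matrix(stats::runif(n * L), n, L) < rate
  g[mask] <- NA_integer_
  gm$genotypes <- g
  gm
}

# one gamete per locus from a 0/1/2 genotype vector/matrix
mendel_gamete <- function(g) {
  out <- g / 2
  het <- which(!is.na(g) & g == 1L)
  if (length(het)) out[het] <- stats::rbinom(length(het), 1L, 0.5)
  out
}

# plant a single hybrid individual from two parental frequency vectors
plant_hybrid <- function(pa, pb, class, g_post) {
  L <- length(pa)
  f1 <- stats::rbinom(L, 1L, pa) + stats::rbinom(L, 1L, pb)
  g <- switch(class,
    F1 = f1,
    F1xA = mendel_gamete(f1) + stats::rbinom(L, 1L, pa),
    stop("unknown planted hybrid class: ", class))
  self_offspring(as.integer(g), g_post)
}

# population table of the bundled study-scale preset: 26 invasive European
# populations in three lineages plus 4 native South African populations,
# sizes and selfing rates spanning the mixed-mating range 0.23-0.99, one
# outcrossing native population with elevated diversity.
preset_populations <- function() {
  tab <- rbind(
    c("SU-NYKO", "RED",     8, 0.829), c("SU-HALL", "YELLOW",  8, 0.722),
    c("SU-SODV", "RED",     9, 0.777), c("SU-PULK", "RED",    18, 0.905),
    c("DE-REES", "RED",     9, 0.940), c("UK-MARS", "ORANGE", 18, 0.472),
    c("UK-MEER", "RED",     9, 0.938), c("UK-FAIR", "ORANGE",  9, 0.619),
    c("UK-AIDA", "ORANGE",  9, 0.536), c("UK-HOYL", "ORANGE",  9, 0.760),
    c("UK-FROD", "ORANGE",  1, 0.600), c("UK-POND", "ORANGE",  1, 0.600),
    c("UK-DEVO", "ORANGE",  9, 0.382), c("NL-LEEU", "YELLOW",  9, 0.887),
    c("NL-LEIH", "RED",     9, 0.880), c("NL-MARK", "ORANGE",  9, 0.364),
    c("PT-RIBE", "RED",    10, 0.792), c("PT-CMAR", "RED",     0, 0.755),
    c("ES-ODIE", "RED",    16, 0.352), c("ES-ROCI", "RED",     8, 0.758),
    c("ES-DEHE", "RED",     9, 0.233), c("ES-MART", "RED",     8, 0.662),
    c("ES-PDUQ", "RED",     9, 0.693), c("ES-DULC", "RED",     7, 0.567),
    c("ES-CADI", "RED",     9, 0.725), c("ES-PALM", "RED",     1, 0.700),
    c("ZA-CAPE", "CAPE",    9, 0.652), c("ZA-CLIF", "CLIF",   10, 0.985),
    c("ZA-GANS", "GANS",    8, 0.730), c("ZA-AGUL", "BLUE",    7, 0.000))
  data.frame(code = tab[, 1], lineage = tab[, 2],
             n = as.integer(tab[, 3]), s = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
}

preset_config <- function(seed) {
  lineages <- data.frame(
    label = c("RED", "ORANGE", "YELLOW", "CAPE", "CLIF", "GANS", "BLUE"),
    fst = c(0.25, 0.25, 0.20, 0.30, 0.30, 0.30, 0.35),
    stringsAsFactors = FALSE)
  # PT-CMAR: mostly historical RED x YELLOW hybrids (several selfing
  # generations after the cross) plus one recent backcross and two recent
  # F1s; ZA-AGUL additionally hosts two recent RED x BLUE F1s.
  events <- data.frame(
    population = c(rep("PT-CMAR", 9), "ZA-AGUL", "ZA-AGUL"),
    parent_a = "RED",
    parent_b = c(rep("YELLOW", 9), "BLUE", "BLUE"),
    class = c(rep("F1", 6), "F1xA", "F1", "F1", "F1", "F1"),
    g_post = c(4L, 5L, 6L, 7L, 8L, 4L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  scenario_config(n_loci = 6000L, lineages = lineages,
                  populations = preset_populations(),
                  admixture_events = events, seed = seed)
}

#' Simulate a full study-scale data set
#'
#' Generates a complete synthetic data set under a bundled preset:
#' `"paper_like"` emulates a two-range invasion design with 30 populations
#' (26 invasive across three diverged lineages, 4 native, one of them
#' outcrossing with elevated diversity), about 6,000 unlinked SNPs,
#' per-population selfing rates from 0.23 to 0.99, right-skewed
#' per-individual missingness (mean 6.5%), and planted inter-lineage
#' hybrids: recent F1s/backcrosses and historical F1s aged by 4-8
#' post-hybridization selfing generations.
#'
#' @param preset Preset name; currently `"paper_like"`.
#' @param seed Mandatory integer seed; all output is reproducible
#'   bit-for-bit given the seed.
#' @param config Optionally a custom [scenario_config()] overriding the
#'   preset.
#' @return List with `genotypes` (a [genotype_matrix]), `truth` (data frame
#'   with per-individual sample_id, population, lineage, class, G, parent_a,
#'   parent_b, q_true, g_post) and `config` (the `scenario_config` used).
#'   `class` is `"pure"`, `"F1"` or `"F1xA"`; `q_true` is the expected
#'   ancestry fraction from `parent_a`; `g_post > 0` marks historical
#'   hybrids.
#' @export
simulate_study <- function(preset = "paper_like", seed, config = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(config)) {
    if (!identical(preset, "paper_like")) stop("unknown preset: ", preset)
    config <- preset_config(seed)
  }
  set.seed(seed)
  freqs <- simulate_lineage_frequencies(config, seed = NULL)
  rows <- list(); truths <- list()
  for (i in seq_len(nrow(config$populations))) {
    pop <- config$populations[i, ]
    ids <- character(0)
    if (pop$n > 0) {
      sim <- simulate_mixed_mating_population(freqs[pop$lineage, ],
                                              s = pop$s, n = pop$n,
                                              population = pop$code)
      tr <- sim$truth
      tr$lineage <- pop$lineage; tr$class <- "pure"
      tr$parent_a <- NA_character_; tr$parent_b <- NA_character_
      tr$q_true <- NA_real_; tr$g_post <- 0L
      rows[[length(rows) + 1L]] <- sim$genotypes$genotypes
      truths[[length(truths) + 1L]] <- tr
      ids <- sim$truth$sample_id
    }
    ev <- config$admixture_events
    if (!is.null(ev)) ev <- ev[ev$population == pop$code, , drop = FALSE]
    if (!is.null(ev) && nrow(ev)) {
      hg <- matrix(NA_integer_, nrow(ev), config$n_loci)
      for (j in seq_len(nrow(ev)))
        hg[j, ] <- plant_hybrid(freqs[ev$parent_a[j], ],
                                freqs[ev$parent_b[j], ],
                                ev$class[j], ev$g_post[j])
      hid <- paste0(pop$code, "_", length(ids) + seq_len(nrow(ev)))
      rows[[length(rows) + 1L]] <- hg
      truths[[length(truths) + 1L]] <- data.frame(
        sample_id = hid, population = pop$code, G = NA_integer_,
        lineage = NA_character_, class = ev$class,
        parent_a = ev$parent_a, parent_b = ev$parent_b,
        q_true = ifelse(ev$class == "F1", 0.5, 0.75),
        g_post = as.integer(ev$g_post), stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truths)
  gm <- genotype_matrix(do.call(rbind, rows),
                        sample_ids = truth$sample_id,
                        populations = truth$population)
  gm <- apply_missingness(gm, config$missingness$mean,
                          config$missingness$concentration)
  list(genotypes = gm, truth = truth, config = config)
}
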
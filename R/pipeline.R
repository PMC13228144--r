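#' Convert coalescent-scale divergence to absolute time
#'
#' Applies the relation `tau = 2 mu t` between divergence in substitutions
#' per site (`tau`), the per-site per-generation mutation rate (`mu`) and
#' divergence time in generations, scaled by the generation time:
#' `t = generation_time * tau / (2 mu)` years before present.
#'
#' @param tau Divergence(s) in substitutions per site (non-negative).
#' @param mu Mutation rate per site per generation (default `7.0e-9`, a
#'   standard estimate for herbaceous annual plants).
#' @param generation_time Generation time in years (default 1).
#' @return Data frame of class `divergence_time`: `tau`, `mu`,
#'   `generation_time`, `t_years`.
#' @examples
#' divergence_time(8.4e-5)$t_years  # 6000 years
#' @export
divergence_time <- function(tau, mu = 7.0e-9, generation_time = 1) {
  if (mu <= 0) stop("mu must be > 0")
  if (any(tau < 0)) stop("tau must be non-negative")
  if (generation_time < 0) stop("generation_time must be non-negative")
  out <- data.frame(tau = tau, mu = mu, generation_time = generation_time,
                    t_years = generation_time * tau / (2 * mu))
  class(out) <- c("divergence_time", "data.frame")
  out
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    input = list(preset = "paper_like"),
    output_dir = NULL,
    filter = list(max_missing_frac = 0.1, min_maf = 0),
    kinship = list(within_population = TRUE),
    selfing = list(max_loci = 1000, n_perm = 1000, n_boot = 200,
                   lineage_q_threshold = 0.999),
    ancestry = list(k_range = c(2, 5), n_replicates = 2, n_restarts = 2,
                    max_iter = 1000, tol = 1e-5, k_for_pools = NULL),
    hybrids = list(n_per_class = 25, threshold = 0.999, q_window = 0.05,
                   min_matches = 20, band = c(2.5, 97.5),
                   admixed_max_q = 0.9),
    sfs = list(projection_n = NULL))
}

merge_config <- function(base, user) {
  # input is taken as supplied (no deep merge: an explicit input block
  # must say where the data come from); other blocks merge field-wise
  if (!is.null(user$input)) { base$input <- user$input; user$input <- NULL }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config$seed is required")
  if (is.null(cfg$input$preset) && is.null(cfg$input$files))
    stop("config$input needs either $preset or $files (path, format)")
  kr <- cfg$ancestry$k_range
  if (length(kr) != 2 || kr[1] < 1 || kr[2] < kr[1])
    stop("config$ancestry$k_range must be c(k_min, k_max) with k_min >= 1")
  with(cfg$filter, stopifnot(max_missing_frac >= 0, max_missing_frac <= 1,
                             min_maf >= 0, min_maf <= 0.5))
  invisible(cfg)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(d, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(d, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Sequences the package's stages on simulated or user-supplied genotypes:
#' locus filtering, KING-robust kinship screen (flagging clones and close
#' relatives), per-individual and per-population diversity, per-population
#' selfing rates, admixture-model ancestry over a K sweep with Evanno
#' delta-K, lineage-level selfing from high-purity cluster assignments,
#' parental-pool construction, hybrid-class simulation, recency
#' classification of admixed individuals, and a folded SFS per cluster. All
#' randomness flows from `config$seed`; rerunning with the same config and
#' seed reproduces every table byte for byte.
#'
#' @param config A list, or path to a YAML file, overriding the defaults:
#'   `seed`; `input` (either `preset = "paper_like"` or
#'   `files = list(path, format)`); `output_dir` (optional; tables are
#'   written there as TSV); `filter` (`max_missing_frac`, `min_maf`);
#'   `kinship` (`within_population`); `selfing` (`max_loci`, `n_perm`,
#'   `n_boot`, `lineage_q_threshold`); `ancestry` (`k_range`,
#'   `n_replicates`, `n_restarts`, `max_iter`, `tol`, `k_for_pools`);
#'   `hybrids` (`n_per_class`, `threshold`, `q_window`, `min_matches`,
#'   `band`, `admixed_max_q`); `sfs` (`projection_n`). The Evanno stage is
#'   skipped with a logged notice when the K range has fewer than 3 values.
#' @return Object of class `pipeline_report`: list with `diversity`,
#'   `selfing` (per-population table), `selfing_lineages`, `kinship_flags`,
#'   `ancestry` (fits per K), `evanno`, `Q` (at `k_for_pools`),
#'   `recency`, `hybrid_sims`, `sfs` (per cluster), `truth` (when
#'   simulated), `notes`, and `meta` (seed, config hash, dimensions).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  validate_pipeline_config(cfg)
  notes <- character(0)
  note <- function(msg) {
    message("[pipeline] ", msg)
    notes <<- c(notes, msg)
  }
  seed <- as.integer(cfg$seed)
  truth <- NULL
  if (!is.null(cfg$input$files)) {
    note(paste("reading genotypes from", cfg$input$files$path))
    gm <- read_genotypes(cfg$input$files$path, cfg$input$files$format)
  } else {
    note(paste("simulating preset", cfg$input$preset, "with seed", seed))
    sim <- simulate_study(cfg$input$preset, seed = seed)
    gm <- sim$genotypes
    truth <- sim$truth
  }
  set.seed(seed + 1L)
  if (!is.null(cfg$output_dir))
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  note(sprintf("filter: %d x %d input", nrow(gm$genotypes),
               ncol(gm$genotypes)))
  gm <- filter_loci(gm, cfg$filter$max_missing_frac, cfg$filter$min_maf)
  note(sprintf("filter: %d loci retained", ncol(gm$genotypes)))

  kin <- king_kinship(gm, within_population = cfg$kinship$within_population)
  kflags <- kinship_flags(kin)
  note(sprintf("kinship: %d flagged pairs (phi > 0.177)", nrow(kflags)))
  write_tsv(kflags, cfg$output_dir, "kinship_flags.tsv")

  div <- diversity_summary(gm)
  write_tsv(div$individuals, cfg$output_dir, "diversity_individuals.tsv")
  write_tsv(div$groups, cfg$output_dir, "diversity_groups.tsv")

  note("selfing: per-population estimates")
  selfing_pop <- selfing_report(gm, max_loci = cfg$selfing$max_loci,
                                n_perm = cfg$selfing$n_perm,
                                n_boot = cfg$selfing$n_boot,
                                seed = seed + 2L)
  write_tsv(selfing_pop, cfg$output_dir, "selfing_populations.tsv")

  ks <- seq(cfg$ancestry$k_range[1], cfg$ancestry$k_range[2])
  note(paste("ancestry: K sweep", paste(range(ks), collapse = "..")))
  fits <- list()
  ll <- matrix(NA_real_, cfg$ancestry$n_replicates, length(ks),
               dimnames = list(NULL, ks))
  for (j in seq_along(ks)) {
    reps <- lapply(seq_len(cfg$ancestry$n_replicates), function(r)
      admixture_em(gm, K = ks[j], n_restarts = cfg$ancestry$n_restarts,
                   tol = cfg$ancestry$tol,
                   max_iter = cfg$ancestry$max_iter,
                   seed = seed + 100L * j + r))
    ll[, j] <- vapply(reps, `[[`, numeric(1), "log_likelihood")
    fits[[as.character(ks[j])]] <- reps[[which.max(ll[, j])]]
  }
  evanno <- NULL
  if (length(ks) >= 3 && cfg$ancestry$n_replicates >= 2) {
    evanno <- evanno_delta_k(ll)
    write_tsv(evanno, cfg$output_dir, "evanno.tsv")
  } else note("evanno: skipped (needs >= 3 K values and >= 2 replicates)")

  k_pool <- cfg$ancestry$k_for_pools
  if (is.null(k_pool)) k_pool <- max(ks)
  fit <- fits[[as.character(k_pool)]]
  Q <- fit$Q
  qtab <- data.frame(sample_id = gm$sample_ids,
                     population = gm$populations, Q,
                     degree = admixture_degree(Q), check.names = FALSE)
  write_tsv(qtab, cfg$output_dir, "q_matrix.tsv")

  thr <- cfg$selfing$lineage_q_threshold
  assign_k <- max.col(Q)
  pure <- Q[cbind(seq_len(nrow(Q)), assign_k)] >= thr
  lineage_of <- ifelse(pure, paste0("cluster", assign_k), NA)
  selfing_lin <- NULL
  lin_sizes <- table(lineage_of[!is.na(lineage_of)])
  if (any(lin_sizes >= 3)) {
    keep <- which(!is.na(lineage_of) &
                  lineage_of %in% names(lin_sizes[lin_sizes >= 3]))
    selfing_lin <- selfing_report(gm[keep, ], grouping = lineage_of[keep],
                                  max_loci = cfg$selfing$max_loci,
                                  n_perm = cfg$selfing$n_perm,
                                  n_boot = cfg$selfing$n_boot,
                                  seed = seed + 3L)
    write_tsv(selfing_lin, cfg$output_dir, "selfing_lineages.tsv")
  }

  # recency of admixture, per pair of clusters with admixed individuals
  admixed <- which(apply(Q, 1, max) <= cfg$hybrids$admixed_max_q)
  recency <- NULL; hyb_sims <- NULL
  if (length(admixed)) {
    top2 <- t(apply(Q[admixed, , drop = FALSE], 1, function(r)
      sort(order(r, decreasing = TRUE)[1:2])))
    pairs <- unique(top2)
    hall <- rowMeans(gm$genotypes == 1L, na.rm = TRUE)
    for (pi in seq_len(nrow(pairs))) {
      pr <- pairs[pi, ]
      members <- admixed[top2[, 1] == pr[1] & top2[, 2] == pr[2]]
      pools <- tryCatch(
        build_parent_pools(gm, Q, clusters = pr,
                           threshold = cfg$hybrids$threshold),
        error = function(e) {
          note(paste("recency: skipping pair", pr[1], "-", pr[2], ":",
                     conditionMessage(e)))
          NULL
        })
      if (is.null(pools)) next
      sims <- simulate_hybrid_classes(pools,
                                      n_per_class = cfg$hybrids$n_per_class,
                                      seed = seed + 7L + pi)
      qe <- supervised_ancestry(gm[members, ], pools$freqs_a,
                                pools$freqs_b)
      calls <- classify_recency(qe, hall[members], sims,
                                q_window = cfg$hybrids$q_window,
                                band = cfg$hybrids$band,
                                min_matches = cfg$hybrids$min_matches)
      calls$pair <- paste0("cluster", pr[1], "-cluster", pr[2])
      sims$sims$pair <- calls$pair[1]
      recency <- rbind(recency, calls)
      hyb_sims <- rbind(hyb_sims, sims$sims)
    }
    if (!is.null(recency)) {
      write_tsv(recency, cfg$output_dir, "recency_calls.tsv")
      write_tsv(hyb_sims, cfg$output_dir, "hybrid_sims.tsv")
      note(sprintf("recency: %d calls (%d recent, %d historical)",
                   nrow(recency), sum(recency$call == "recent"),
                   sum(recency$call == "historical")))
    }
  } else note("recency: no admixed individuals found")

  sfs_list <- list()
  for (lin in names(lin_sizes[lin_sizes >= 2])) {
    idx <- which(!is.na(lineage_of) & lineage_of == lin)
    sf <- folded_sfs(gm, individuals = idx,
                     projection_n = cfg$sfs$projection_n)
    sfs_list[[lin]] <- sf
    if (!is.null(cfg$output_dir))
      write_sfs(sf, file.path(cfg$output_dir, paste0("sfs_", lin, ".txt")))
  }

  meta <- list(seed = seed, config_hash = config_hash(cfg),
               n_individuals = nrow(gm$genotypes),
               n_loci = ncol(gm$genotypes),
               package_version = as.character(utils::packageVersion("selfpop")))
  structure(list(diversity = div, selfing = selfing_pop,
                 selfing_lineages = selfing_lin, kinship = kin,
                 kinship_flags = kflags, ancestry = fits, evanno = evanno,
                 Q = Q, recency = recency, hybrid_sims = hyb_sims,
                 sfs = sfs_list, truth = truth, notes = notes,
                 config = cfg, meta = meta),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed ", x$meta$seed, ", ", x$meta$n_individuals,
      " individuals x ", x$meta$n_loci, " loci)\n", sep = "")
  cat("  populations analysed:", nrow(x$selfing), "\n")
  if (!is.null(x$evanno)) {
    pk <- x$evanno$K[which.max(x$evanno$delta_k)]
    cat("  Evanno delta-K peak at K =", pk,
        "(reported alongside the full table, not auto-selected)\n")
  }
  if (!is.null(x$recency))
    cat("  recency calls:", sum(x$recency$call == "recent"), "recent /",
        sum(x$recency$call == "historical"), "historical /",
        sum(x$recency$call == "unresolved"), "unresolved\n")
  cat("  notes:", length(x$notes), "\n")
  invisible(x)
}
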
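#' Build parental allele-frequency pools from pure individuals
#'
#' Selects, for two clusters, the individuals whose membership fraction
#' meets `threshold` ("pure" reference parents) and computes per-locus
#' allele frequencies from each pool, complete-case per locus.
#'
#' @param gm A [genotype_matrix].
#' @param Q Membership matrix (n x K), rows aligned with `gm`.
#' @param clusters Length-2 vector of cluster columns to use as parents A
#'   and B (default first two).
#' @param threshold Minimum membership for an individual to enter a pool
#'   (default 0.999).
#' @param min_n Minimum pool size (default 3).
#' @return List of class `parent_pools`: `freqs_a`, `freqs_b` (per-locus
#'   allele frequencies, `NaN` where a pool has no call), `n_a`, `n_b`,
#'   `clusters`, `threshold`.
#' @export
build_parent_pools <- function(gm, Q, clusters = c(1, 2), threshold = 0.999,
                               min_n = 3) {
  Q <- as.matrix(Q)
  stopifnot(nrow(Q) == nrow(gm$genotypes), length(clusters) == 2)
  pools <- lapply(clusters, function(k) which(Q[, k] >= threshold))
  names(pools) <- c("A", "B")
  for (side in c("A", "B"))
    if (length(pools[[side]]) < min_n)
      stop("parental pool ", side, " (cluster ",
           clusters[if (side == "A") 1 else 2], ") has only ",
           length(pools[[side]]), " pure individuals at threshold ",
           threshold)
  structure(list(freqs_a = allele_frequencies(gm[pools$A, ]),
                 freqs_b = allele_frequencies(gm[pools$B, ]),
                 n_a = length(pools$A), n_b = length(pools$B),
                 clusters = clusters, threshold = threshold),
            class = "parent_pools")
}

hybrid_class_labels <- c("F1", "F2", "F1xA", "F1xB",
                         "F1AxA", "F1AxB", "F1BxB", "F1BxA")

# one simulated individual of a hybrid class, built genealogically per
# locus from the two parental frequency vectors
simulate_hybrid_genotype <- function(pa, pb, class) {
  L <- length(pa)
  ga <- function() stats::rbinom(L, 1L, pa)
  gb <- function() stats::rbinom(L, 1L, pb)
  f1 <- function() ga() + gb()
  bxa <- function() mendel_gamete(f1()) + ga()  # first-generation backcross
  bxb <- function() mendel_gamete(f1()) + gb()
  switch(class,
    F1 = f1(),
    F2 = mendel_gamete(f1()) + mendel_gamete(f1()),
    F1xA = bxa(),
    F1xB = bxb(),
    F1AxA = mendel_gamete(bxa()) + ga(),
    F1AxB = mendel_gamete(bxa()) + gb(),
    F1BxB = mendel_gamete(bxb()) + gb(),
    F1BxA = mendel_gamete(bxb()) + ga(),
    stop("unknown hybrid class: ", class))
}

#' Simulate hybrid classes from two parental pools
#'
#' Generates genotypes for first- and second-generation hybrid classes by
#' genealogical construction per locus (HybridLab-style): F1 draws one
#' allele from each pool; F2 draws one gamete from each of two
#' independently simulated F1s; first-generation backcrosses (`F1xA`,
#' `F1xB`) combine an F1 gamete with a pool allele; second-generation
#' backcrosses (`F1AxA`, `F1AxB`, `F1BxB`, `F1BxA`) do the same from a
#' simulated first-generation backcross. For every simulated individual the
#' supervised admixture coefficient q (ancestry from pool A, via
#' [supervised_ancestry()] with the same pools) and observed heterozygosity
#' are recorded, the coordinates used by the recency classifier.
#'
#' Expected q per class: F1, F2 0.5; F1xA 0.75; F1AxA 0.875; F1xB 0.25;
#' F1BxB 0.125. With pools fixed for different alleles, F1 heterozygosity
#' is exactly 1, F2 and F1xA 0.5 in expectation, F1AxA 0.25.
#'
#' @param pools A `parent_pools` object, or a list with `freqs_a` and
#'   `freqs_b` on identical loci.
#' @param n_per_class Simulated individuals per class (default 25).
#' @param classes Subset of
#'   `c("F1","F2","F1xA","F1xB","F1AxA","F1AxB","F1BxB","F1BxA")`
#'   (default all eight).
#' @param seed Integer seed, or `NULL`.
#' @return Object of class `hybrid_class_set`: `sims` (data frame: class,
#'   sample_id, q, H_O), `genotypes` (a [genotype_matrix], populations set
#'   to the class label), `pools`, `n_per_class`, `seed`.
#' @export
simulate_hybrid_classes <- function(pools, n_per_class = 25,
                                    classes = hybrid_class_labels,
                                    seed = NULL) {
  bad <- setdiff(classes, hybrid_class_labels)
  if (length(bad)) stop("unknown hybrid class: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  pa <- pools$freqs_a; pb <- pools$freqs_b
  stopifnot(length(pa) == length(pb))
  ok <- !is.na(pa) & !is.nan(pa) & !is.na(pb) & !is.nan(pb)
  pa <- pa[ok]; pb <- pb[ok]
  g <- matrix(NA_integer_, length(classes) * n_per_class, length(pa))
  lab <- character(nrow(g))
  for (ci in seq_along(classes)) {
    for (j in seq_len(n_per_class)) {
      row <- (ci - 1L) * n_per_class + j
      g[row, ] <- as.integer(simulate_hybrid_genotype(pa, pb, classes[ci]))
      lab[row] <- classes[ci]
    }
  }
  ids <- paste0("sim_", lab, "_", rep(seq_len(n_per_class),
                                      times = length(classes)))
  gm <- genotype_matrix(g, sample_ids = ids, populations = lab)
  q <- supervised_ancestry(gm, pa, pb)
  ho <- rowMeans(g == 1L)
  structure(list(sims = data.frame(class = lab, sample_id = ids, q = q,
                                   H_O = ho, row.names = NULL,
                                   stringsAsFactors = FALSE),
                 genotypes = gm,
                 pools = list(freqs_a = pa, freqs_b = pb),
                 n_per_class = n_per_class, seed = seed),
            class = "hybrid_class_set")
}

#' @export
print.hybrid_class_set <- function(x, ...) {
  cat("hybrid_class_set:", nrow(x$sims), "simulated individuals (",
      x$n_per_class, "per class )\n")
  agg <- stats::aggregate(cbind(q, H_O) ~ class, data = x$sims, FUN = mean)
  print(agg[order(-agg$q), ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.hybrid_class_set <- function(x, ...) {
  cls <- factor(x$sims$class, levels = hybrid_class_labels)
  graphics::plot(x$sims$q, x$sims$H_O, col = as.integer(cls), pch = 19,
                 xlab = "ancestry coefficient q",
                 ylab = expression(H[O]), xlim = c(0, 1), ...)
  graphics::legend("topleft", legend = levels(droplevels(cls)),
                   col = seq_along(levels(droplevels(cls))), pch = 19,
                   cex = 0.7, bty = "n")
  invisible(x)
}

#' Age hybrids by post-hybridization selfing
#'
#' Applies `g` generations of Mendelian self-fertilization
#' ([self_offspring()]) to every individual. Ancestry q is unchanged in
#' expectation while heterozygosity decays by `(1/2)^g`, the signature that
#' separates historical from recent admixture.
#'
#' @param x A `hybrid_class_set` or a [genotype_matrix].
#' @param generations Non-negative number of selfing generations.
#' @param seed Integer seed, or `NULL`.
#' @return Same type as `x`; for a `hybrid_class_set`, `q` and `H_O` are
#'   recomputed from the aged genotypes.
#' @export
selfing_decay <- function(x, generations, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "genotype_matrix"))
    return(self_offspring(x, generations))
  stopifnot(inherits(x, "hybrid_class_set"))
  x$genotypes <- self_offspring(x$genotypes, generations)
  g <- x$genotypes$genotypes
  x$sims$H_O <- rowMeans(g == 1L, na.rm = TRUE)
  x$sims$q <- supervised_ancestry(x$genotypes, x$pools$freqs_a,
                                  x$pools$freqs_b)
  x
}

#' Classify admixed individuals as recent or historical hybrids
#'
#' Operationalizes the envelope comparison of empirical against simulated
#' hybrids: for each empirical (q, H_O) point, all simulated individuals
#' (any class) with `|q_sim - q| <= q_window` are pooled, the window
#' doubling until at least `min_matches` simulations are found or the
#' window reaches 0.5. The envelope is the given percentile band of the
#' matched simulated H_O values; an individual at or above the lower edge
#' is called `recent` (its diversity is explainable by some fresh hybrid
#' class of comparable ancestry), one below it `historical` (heterozygosity
#' already eroded by post-hybridization selfing), and one that never
#' accumulates `min_matches` matched simulations `unresolved`.
#'
#' @param q Empirical ancestry coefficients in `[0, 1]` (optionally named).
#' @param h_o Empirical observed heterozygosities, same length.
#' @param sims A `hybrid_class_set` (or its `sims` data frame).
#' @param q_window Initial half-width of the ancestry window (default
#'   0.05).
#' @param band Percentile band of the envelope (default `c(2.5, 97.5)`).
#' @param min_matches Minimum matched simulations for a defined envelope
#'   (default 20).
#' @return Data frame of class `recency_calls`: id, q, H_O, `env_lo`,
#'   `env_hi`, `n_matched`, `window`, `call` in
#'   `c("recent", "historical", "unresolved")`.
#' @export
classify_recency <- function(q, h_o, sims, q_window = 0.05,
                             band = c(2.5, 97.5), min_matches = 20) {
  sdf <- if (inherits(sims, "hybrid_class_set")) sims$sims else sims
  if (!nrow(sdf)) stop("no simulated hybrids supplied")
  stopifnot(length(q) == length(h_o), all(q >= 0 & q <= 1, na.rm = TRUE))
  ids <- if (!is.null(names(q))) names(q) else paste0("ind", seq_along(q))
  rows <- lapply(seq_along(q), function(i) {
    w <- q_window
    m <- abs(sdf$q - q[i]) <= w
    while (sum(m) < min_matches && w < 0.5) {
      w <- min(2 * w, 0.5)
      m <- abs(sdf$q - q[i]) <= w
    }
    if (sum(m) < min_matches)
      return(data.frame(id = ids[i], q = q[i], H_O = h_o[i],
                        env_lo = NA_real_, env_hi = NA_real_,
                        n_matched = sum(m), window = w,
                        call = "unresolved", stringsAsFactors = FALSE))
    env <- stats::quantile(sdf$H_O[m], band / 100, names = FALSE)
    data.frame(id = ids[i], q = q[i], H_O = h_o[i], env_lo = env[1],
               env_hi = env[2], n_matched = sum(m), window = w,
               call = if (h_o[i] >= env[1]) "recent" else "historical",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("recency_calls", "data.frame")
  out
}
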
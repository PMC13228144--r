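#' Multilocus identity disequilibrium (g2)
#'
#' Computes the multilocus identity-disequilibrium statistic g2 from a 0/1
#' heterozygosity indicator matrix `h` (individuals by loci): the ratio of
#' the mean cross-locus co-heterozygosity within individuals to its
#' between-individual (independence) expectation, minus one. With row sums
#' `r_i`, column sums `c_l` and total `T`, the closed form is
#' \deqn{\hat g_2 = \frac{(1/n)\sum_i (r_i^2 - r_i)}
#'  {(1/(n(n-1)))\,(T^2 - \sum_i r_i^2 - \sum_l c_l^2 + T)} - 1.}
#' g2 is zero under random mating, positive under variance in inbreeding
#' (e.g. mixed mating), and is the signal behind the RMES-style multilocus
#' selfing-rate estimator. Missing calls contribute 0 to `h` (complete-case
#' per cell); see [estimate_selfing()] for the surrounding locus filters.
#'
#' @param x A [genotype_matrix], or a 0/1 heterozygosity indicator matrix
#'   (`NA` allowed, treated as 0).
#' @return List with `g2` (`NA` with `defined = FALSE` when the denominator
#'   vanishes), the intermediate sums (`num`, `den`, `T`, `row_sums`,
#'   `col_sums`), `n` and `n_loci`.
#' @examples
#' h <- rbind(c(1, 1), c(0, 0), c(1, 1), c(0, 0))
#' multilocus_g2(h)$g2  # perfect identity disequilibrium: 2
#' @export
multilocus_g2 <- function(x) {
  h <- if (inherits(x, "genotype_matrix")) het_indicator(x) else as.matrix(x)
  h[is.na(h)] <- 0L
  n <- nrow(h); L <- ncol(h)
  if (n < 3L) stop("need at least 3 individuals")
  if (L < 2L) stop("need at least 2 loci")
  r <- rowSums(h); cl <- colSums(h); tot <- sum(r)
  num <- sum(r^2 - r) / n
  den <- (tot^2 - sum(r^2) - sum(cl^2) + tot) / (n * (n - 1))
  g2 <- if (den > 0) num / den - 1 else NA_real_
  list(g2 = g2, defined = den > 0, num = num, den = den, T = tot,
       row_sums = r, col_sums = cl, n = n, n_loci = L)
}

# g2 for many column-resampled/permuted replicates, given row-sum matrix
# r (n x B), per-replicate totals and column-sum-of-squares
g2_from_sums <- function(r, tot, sum_c2, n) {
  num <- colSums(r^2 - r) / n
  den <- (tot^2 - colSums(r^2) - sum_c2 + tot) / (n * (n - 1))
  ifelse(den > 0, num / den - 1, NA_real_)
}

#' Convert identity disequilibrium to a selfing rate
#'
#' Inverts the mixed-mating equilibrium relation
#' `g2 = s / ((1 - s)(4 - s))` implied by the geometric selfing-depth model,
#' i.e. solves `g2 s^2 - (5 g2 + 1) s + 4 g2 = 0` for the root in `[0, 1)`:
#' `s = ((5 g2 + 1) - sqrt((5 g2 + 1)^2 - 16 g2^2)) / (2 g2)`, with
#' `s(0) = 0` by continuity. The map is monotone; negative g2 (sampling
#' noise under little or no selfing) maps to `s = 0` with a `clipped`
#' attribute.
#'
#' @param g2 Identity disequilibrium value(s).
#' @return Selfing rate(s) in `[0, 1)`, attribute `clipped` marking negative
#'   inputs.
#' @examples
#' g2_to_selfing(0.5 / ((1 - 0.5) * (4 - 0.5)))  # 0.5
#' @export
g2_to_selfing <- function(g2) {
  s <- rep(NA_real_, length(g2))
  clipped <- !is.na(g2) & g2 < 0
  s[clipped] <- 0
  zero <- !is.na(g2) & g2 == 0
  s[zero] <- 0
  pos <- !is.na(g2) & g2 > 0
  if (any(pos)) {
    g <- g2[pos]
    b <- 5 * g + 1
    s[pos] <- (b - sqrt(b^2 - 16 * g^2)) / (2 * g)
  }
  attr(s, "clipped") <- clipped
  s
}

# forward map: equilibrium g2 implied by a selfing rate
selfing_to_g2 <- function(s) s / ((1 - s) * (4 - s))

# independently permute each column of h within individuals; returns the
# g2 of B permuted replicates. One order() call per chunk permutes all
# columns of several replicates at once.
g2_permutation_null <- function(h, B, chunk = NULL) {
  n <- nrow(h); L <- ncol(h)
  v <- as.numeric(h)
  sum_c2 <- sum(colSums(h)^2); tot <- sum(h)
  if (is.null(chunk)) chunk <- max(1L, min(B, floor(2e6 / (n * L))))
  out <- numeric(0)
  done <- 0L
  lcol <- NULL
  while (done < B) {
    k <- min(chunk, B - done)
    grp <- rep(seq_len(L * k), each = n)
    ord <- order(grp, stats::runif(n * L * k))
    rows <- (ord - 1L) %% n + 1L
    if (is.null(lcol) || length(lcol) != n * L * k)
      lcol <- rep(rep(seq_len(L) - 1L, each = n), times = k)
    m <- matrix(v[rows + lcol * n], n, L * k)
    r <- vapply(seq_len(k), function(b)
      rowSums(m[, ((b - 1L) * L + 1L):(b * L), drop = FALSE]),
      numeric(n))
    out <- c(out, g2_from_sums(r, tot, sum_c2, n))
    done <- done + k
  }
  out
}

# locus bootstrap of g2: resample columns with replacement B times
g2_locus_bootstrap <- function(h, B) {
  n <- nrow(h); L <- ncol(h)
  cl <- colSums(h)
  S <- matrix(0, L, B)
  idx <- matrix(sample.int(L, L * B, replace = TRUE), L, B)
  for (b in seq_len(B)) S[, b] <- tabulate(idx[, b], nbins = L)
  r <- h %*% S
  tot <- as.numeric(cl %*% S)
  sum_c2 <- as.numeric(cl^2 %*% S)
  g2_from_sums(r, tot, sum_c2, n)
}

# individual bootstrap of g2: resample rows with replacement B times.
# Row contents are fixed, so resampled row sums are r[idx]; column sums
# become weighted sums of the original rows.
g2_individual_bootstrap <- function(h, B) {
  n <- nrow(h)
  r0 <- rowSums(h)
  W <- matrix(0, n, B)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  for (b in seq_len(B)) W[, b] <- tabulate(idx[, b], nbins = n)
  num <- as.numeric((r0^2 - r0) %*% W) / n
  tot <- as.numeric(r0 %*% W)
  sum_r2 <- as.numeric(r0^2 %*% W)
  C <- crossprod(h, W)                    # L x B resampled column sums
  sum_c2 <- colSums(C^2)
  den <- (tot^2 - sum_r2 - sum_c2 + tot) / (n * (n - 1))
  ifelse(den > 0, num / den - 1, NA_real_)
}

#' Estimate the selfing rate from multilocus identity disequilibrium
#'
#' The package's main estimator, in the style of RMES: computes g2 on a
#' (sub)population's heterozygosity matrix, converts it to a selfing rate
#' via the mixed-mating equilibrium ([g2_to_selfing()]), attaches a
#' one-sided permutation p-value for the null of no identity disequilibrium
#' (each locus's heterozygosity column permuted independently across
#' individuals, destroying cross-locus association while preserving
#' per-locus heterozygote counts) and a bootstrap standard deviation of the
#' selfing rate. The bootstrap resamples individuals by default: the
#' sampling variance of g2 is dominated by between-individual variance in
#' realized selfing depth, so resampling loci (available via
#' `boot_units = "loci"`) reflects only the much smaller between-locus
#' component and badly understates the uncertainty at field-study sample
#' sizes.
#'
#' Loci with more than `max_locus_missing` missingness within the group are
#' dropped first; if more than `max_loci` loci remain, a seeded random
#' subsample is taken (mirroring common practice of estimating from a fixed
#' SNP panel). The permutation p-value follows the finite-sample convention
#' `(1 + exceedances) / (1 + n_perm)` and is never 0.
#'
#' @param gm A [genotype_matrix].
#' @param group Optional population label(s) selecting the individuals to
#'   use, or a logical/integer index vector; default all individuals.
#' @param max_loci Maximum number of loci used (default 1000).
#' @param n_perm Permutation replicates for the p-value (default 10000; 0
#'   skips the test).
#' @param n_boot Bootstrap replicates for the SD (default 1000; 0 skips).
#' @param boot_units `"individuals"` (default) or `"loci"`: what the SD
#'   bootstrap resamples.
#' @param max_locus_missing Per-locus missingness tolerance within the
#'   group (default 0.2).
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `selfing_estimate` with elements `g2_hat`,
#'   `s_hat`, `sd_s`, `p_value`, `defined`, `n_perm`, `n_boot`,
#'   `n_loci_used`, `n_individuals`, `group`. Degenerate input (no
#'   heterozygosity signal) yields a flagged undefined estimate rather than
#'   an error.
#' @examples
#' sim <- simulate_mixed_mating_population(runif(300, .2, .8), s = 0.5,
#'                                         n = 30, seed = 1)
#' estimate_selfing(sim$genotypes, n_perm = 200, n_boot = 100, seed = 2)
#' @export
estimate_selfing <- function(gm, group = NULL, max_loci = 1000,
                             n_perm = 10000, n_boot = 1000,
                             boot_units = c("individuals", "loci"),
                             max_locus_missing = 0.2, seed = NULL) {
  boot_units <- match.arg(boot_units)
  if (!is.null(group)) {
    idx <- if (is.character(group)) which(gm$populations %in% group)
           else group
    gm <- gm[idx, ]
  }
  n <- nrow(gm$genotypes)
  if (n < 3L) stop("need at least 3 individuals in the group")
  if (!is.null(seed)) set.seed(seed)
  miss <- colMeans(is.na(gm$genotypes))
  gm <- gm[, which(miss <= max_locus_missing)]
  h <- het_indicator(gm)
  h[is.na(h)] <- 0L
  if (ncol(h) > max_loci)
    h <- h[, sort(sample.int(ncol(h), max_loci)), drop = FALSE]
  label <- if (is.null(group) || !is.character(group)) "all"
           else paste(group, collapse = "+")
  out <- list(g2_hat = NA_real_, s_hat = NA_real_, sd_s = NA_real_,
              p_value = NA_real_, defined = FALSE,
              n_perm = n_perm, n_boot = n_boot, boot_units = boot_units,
              n_loci_used = ncol(h), n_individuals = n, group = label)
  class(out) <- "selfing_estimate"
  informative <- sum(colSums(h) > 0)
  if (ncol(h) < 2L || informative < 2L) return(out)
  st <- multilocus_g2(h)
  out$g2_hat <- st$g2
  out$defined <- st$defined
  if (!st$defined) return(out)
  out$s_hat <- as.numeric(g2_to_selfing(st$g2))
  if (n_perm > 0) {
    null <- g2_permutation_null(h, n_perm)
    ok <- !is.na(null)
    out$p_value <- (1 + sum(null[ok] >= st$g2)) / (1 + sum(ok))
  }
  if (n_boot > 0) {
    bg2 <- if (boot_units == "individuals") g2_individual_bootstrap(h, n_boot)
           else g2_locus_bootstrap(h, n_boot)
    out$sd_s <- stats::sd(as.numeric(g2_to_selfing(bg2)), na.rm = TRUE)
  }
  out
}

#' @export
print.selfing_estimate <- function(x, ...) {
  cat("Multilocus selfing-rate estimate (group: ", x$group, ")\n", sep = "")
  if (!x$defined) {
    cat("  undefined: no usable heterozygosity signal (",
        x$n_individuals, " individuals, ", x$n_loci_used, " loci)\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf("  g2 = %.4f,  s = %.3f", x$g2_hat, x$s_hat))
  if (!is.na(x$sd_s))
    cat(sprintf(" +/- %.3f (%s bootstrap)", x$sd_s,
                sub("s$", "", x$boot_units)))
  cat("\n")
  if (!is.na(x$p_value))
    cat(sprintf("  permutation P (g2 = 0): %.4g  (%d permutations)\n",
                x$p_value, x$n_perm))
  cat("  ", x$n_individuals, " individuals, ", x$n_loci_used,
      " loci\n", sep = "")
  invisible(x)
}

#' @export
coef.selfing_estimate <- function(object, ...) {
  c(s = object$s_hat, g2 = object$g2_hat)
}

#' @export
summary.selfing_estimate <- function(object, ...) {
  d <- data.frame(group = object$group, n = object$n_individuals,
                  n_loci = object$n_loci_used, g2 = object$g2_hat,
                  s = object$s_hat, sd = object$sd_s,
                  p_value = object$p_value)
  class(d) <- c("summary.selfing_estimate", "data.frame")
  d
}

#' Per-group selfing-rate report
#'
#' Runs [estimate_selfing()] for each group and assembles the columns of a
#' classic mating-system table: group, n, observed heterozygosity, selfing
#' rate with bootstrap SD, permutation p-value and loci used.
#'
#' @param gm A [genotype_matrix].
#' @param grouping Character vector of group labels per individual
#'   (default `gm$populations`).
#' @param min_n Minimum group size to attempt estimation (smaller groups get
#'   `NA` rows). Default 3.
#' @inheritParams estimate_selfing
#' @return Data frame, one row per group.
#' @export
selfing_report <- function(gm, grouping = NULL, max_loci = 1000,
                           n_perm = 10000, n_boot = 1000, min_n = 3,
                           seed = NULL) {
  if (is.null(grouping)) grouping <- gm$populations
  if (!is.null(seed)) set.seed(seed)
  div <- diversity_summary(gm, grouping)
  groups <- unique(grouping)
  rows <- lapply(groups, function(grp) {
    sel <- which(grouping == grp)
    ho <- div$groups$H_O[div$groups$group == grp]
    if (length(sel) < min_n)
      return(data.frame(group = grp, n = length(sel), H_O = ho,
                        s = NA_real_, sd = NA_real_, p_value = NA_real_,
                        n_loci_used = NA_integer_))
    est <- estimate_selfing(gm, group = sel, max_loci = max_loci,
                            n_perm = n_perm, n_boot = n_boot)
    data.frame(group = grp, n = length(sel), H_O = ho, s = est$s_hat,
               sd = est$sd_s, p_value = est$p_value,
               n_loci_used = est$n_loci_used)
  })
  do.call(rbind, rows)
}
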
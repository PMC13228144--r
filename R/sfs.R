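#' Folded site-frequency spectrum
#'
#' Computes the folded SFS (distribution of minor-allele counts across loci)
#' for a subset of individuals, the input expected by multi-epoch demographic
#' inference. By default only complete-case loci (no missing call in the
#' subset) are used and counts are integers. With `projection_n` set, each
#' locus with at least `projection_n` called alleles is projected down to
#' `projection_n` alleles by the hypergeometric expectation (so loci with
#' moderate missingness still contribute, and counts become real-valued);
#' loci with fewer called alleles are dropped.
#'
#' @param gm A [genotype_matrix].
#' @param individuals Optional subset of individuals (indices, logical, or
#'   sample ids). Default: all.
#' @param projection_n Even number of alleles to project to, at most twice
#'   the subset size, or `NULL` (no projection).
#' @return Object of class `folded_sfs`: list with `counts` (named vector,
#'   minor-allele count 0 .. `n_alleles / 2`), `n_alleles`, `n_loci_used`.
#'   `sum(counts) == n_loci_used` always.
#' @examples
#' gm <- genotype_matrix(cbind(c(0, 0), c(1, 0), c(1, 1), c(2, 2)))
#' folded_sfs(gm)$counts  # 2 monomorphic, 1 singleton, 1 doubleton
#' @export
folded_sfs <- function(gm, individuals = NULL, projection_n = NULL) {
  if (!is.null(individuals)) gm <- gm[individuals, ]
  g <- gm$genotypes
  n <- nrow(g)
  if (n == 0L) stop("individual subset is empty")
  if (is.null(projection_n)) {
    n_alleles <- 2L * n
    complete <- colSums(is.na(g)) == 0L
    alt <- colSums(g[, complete, drop = FALSE])
    minor <- pmin(alt, n_alleles - alt)
    counts <- as.numeric(tabulate(minor + 1L, nbins = n + 1L))
    names(counts) <- 0:n
    return(structure(list(counts = counts, n_alleles = n_alleles,
                          n_loci_used = sum(complete)),
                     class = "folded_sfs"))
  }
  if (projection_n %% 2L != 0L) stop("projection_n must be even")
  if (projection_n > 2L * n || projection_n < 2L)
    stop("projection_n must be between 2 and twice the subset size")
  called <- 2L * colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  use <- called >= projection_n
  half <- projection_n %/% 2L
  counts <- numeric(half + 1L)
  for (l in which(use)) {
    pj <- stats::dhyper(0:projection_n, alt[l], called[l] - alt[l],
                        projection_n)
    fold <- pmin(0:projection_n, projection_n - (0:projection_n))
    counts <- counts + as.numeric(rowsum(pj, fold))
  }
  names(counts) <- 0:half
  structure(list(counts = counts, n_alleles = projection_n,
                 n_loci_used = sum(use)),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat("folded_sfs:", x$n_loci_used, "loci over", x$n_alleles, "alleles\n")
  print(round(x$counts, 3))
  invisible(x)
}
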
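#' Genotype matrix of unlinked biallelic SNPs
#'
#' Constructs the central data container of the package: an
#' individuals-by-loci matrix of diploid genotypes coded as the count of the
#' alternate (or second) allele, i.e. 0, 1 or 2, with `NA` for missing calls.
#' Sample identifiers, per-individual population labels and locus identifiers
#' travel with the matrix. All downstream statistics (heterozygosity, kinship,
#' identity disequilibrium, ancestry, SFS) consume this class.
#'
#' @param genotypes Integer (or numeric) matrix, individuals in rows, loci in
#'   columns. Non-missing entries must be 0, 1 or 2; missing calls are `NA`.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row. Defaults to existing rownames or `ind1..indN`.
#' @param populations Character vector of population labels, one per
#'   individual; non-empty strings. Defaults to `"pop1"` for all.
#' @param locus_ids Character vector of unique locus identifiers, one per
#'   column. Defaults to existing colnames or `locus1..locusL`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `genotypes`, `sample_ids`, `populations` and `locus_ids`.
#' @examples
#' g <- genotype_matrix(rbind(c(0, 1, 2), c(1, NA, 0)),
#'                      sample_ids = c("a", "b"),
#'                      populations = c("p1", "p1"))
#' g
#' @export
genotype_matrix <- function(genotypes, sample_ids = NULL, populations = NULL,
                            locus_ids = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  L <- ncol(genotypes)
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(genotypes))) rownames(genotypes)
      else sprintf("ind%d", seq_len(n))
  }
  if (is.null(populations)) populations <- rep("pop1", n)
  if (is.null(locus_ids)) {
    locus_ids <- if (!is.null(colnames(genotypes))) colnames(genotypes)
      else sprintf("locus%d", seq_len(L))
  }
  populations <- as.character(populations)
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  dimnames(genotypes) <- NULL
  gm <- structure(
    list(genotypes = genotypes, sample_ids = sample_ids,
         populations = populations, locus_ids = locus_ids),
    class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  g <- gm$genotypes
  n <- nrow(g); L <- ncol(g)
  if (length(gm$sample_ids) != n)
    stop("sample_ids length (", length(gm$sample_ids),
         ") does not match number of rows (", n, ")")
  if (length(gm$populations) != n)
    stop("populations length does not match number of individuals")
  if (length(gm$locus_ids) != L)
    stop("locus_ids length (", length(gm$locus_ids),
         ") does not match number of loci (", L, ")")
  if (anyDuplicated(gm$sample_ids))
    stop("sample_ids must be unique")
  if (anyDuplicated(gm$locus_ids))
    stop("locus_ids must be unique")
  if (any(!nzchar(gm$populations)) || anyNA(gm$populations))
    stop("populations must be non-empty strings")
  vals <- g[!is.na(g)]
  if (length(vals) && (any(vals < 0L) || any(vals > 2L)))
    stop("non-missing genotypes must be coded 0, 1 or 2")
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  g <- x$genotypes
  miss <- if (length(g)) mean(is.na(g)) else 0
  cat("genotype_matrix: ", nrow(g), " individuals x ", ncol(g),
      " loci (", sprintf("%.1f", 100 * miss), "% missing)\n", sep = "")
  pops <- table(x$populations)
  cat("populations:", length(pops), "--",
      paste0(utils::head(names(pops), 6), " (", utils::head(pops, 6), ")",
             collapse = ", "),
      if (length(pops) > 6) "..." else "", "\n")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' Standard `[` subsetting by individuals (`i`) and/or loci (`j`); metadata is
#' kept in sync.
#'
#' @param x A `genotype_matrix`.
#' @param i Individual index (integer, logical, or sample id character).
#' @param j Locus index (integer, logical, or locus id character).
#' @param ... Ignored.
#' @return A `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$locus_ids)
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$locus_ids)
  genotype_matrix(x$genotypes[i, j, drop = FALSE],
                  sample_ids = x$sample_ids[i],
                  populations = x$populations[i],
                  locus_ids = x$locus_ids[j])
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Per-locus alternate allele frequencies
#'
#' Frequencies of the alternate allele computed on non-missing calls only
#' (complete-case per locus). Loci with no called genotypes give `NaN`.
#'
#' @param gm A `genotype_matrix`.
#' @return Numeric vector of length `n_loci`, named by locus id.
#' @export
allele_frequencies <- function(gm) {
  g <- gm$genotypes
  called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * called)
  names(p) <- gm$locus_ids
  p
}

# 0/1 heterozygosity indicator matrix with NA at missing calls
het_indicator <- function(gm) {
  h <- gm$genotypes == 1L
  storage.mode(h) <- "integer"
  h
}

#' Filter loci on completeness and minor-allele frequency
#'
#' Retains loci whose missing fraction is at most `max_missing_frac` and whose
#' minor-allele frequency (computed on non-missing alleles) is at least
#' `min_maf`. Locus order is preserved; the result may have zero loci.
#'
#' @param gm A `genotype_matrix`.
#' @param max_missing_frac Maximum tolerated per-locus missing fraction, in
#'   `[0, 1]`. Default 1 (no completeness filter).
#' @param min_maf Minimum minor-allele frequency, in `[0, 0.5]`. Default 0.
#' @return The filtered `genotype_matrix`.
#' @examples
#' gm <- genotype_matrix(cbind(c(0, 0, 0, 1), c(1, 1, 0, 2)))
#' filter_loci(gm, min_maf = 0.2)$locus_ids
#' @export
filter_loci <- function(gm, max_missing_frac = 1, min_maf = 0) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1,
            min_maf >= 0, min_maf <= 0.5)
  g <- gm$genotypes
  miss <- colMeans(is.na(g))
  p <- allele_frequencies(gm)
  maf <- pmin(p, 1 - p)
  keep <- miss <= max_missing_frac & !is.nan(maf) & maf >= min_maf
  gm[, which(keep)]
}
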
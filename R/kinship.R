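#' KING-robust pairwise kinship
#'
#' Estimates the kinship coefficient phi between all pairs of individuals
#' with the allele-frequency-free KING-robust estimator. For a pair (i, j),
#' over the loci called in both,
#' \deqn{\phi = (N_{hetHet} - 2 N_{oppHom}) / (N_{het,i} + N_{het,j})}
#' where \eqn{N_{hetHet}} counts loci at which both are heterozygous,
#' \eqn{N_{oppHom}} loci with opposite homozygotes (0 vs 2), and
#' \eqn{N_{het,i}} the heterozygous loci of i among the shared called loci.
#' Duplicated genotypes (clones) give phi = 0.5 exactly; unrelated
#' individuals from the same gene pool give phi near 0. Pairs whose
#' denominator is zero (no heterozygous calls) are `NA`, never silently 0.
#'
#' Because the estimator is robust to allele frequencies only within a
#' homogeneous gene pool, kinship is computed within populations by default;
#' cross-population entries are then `NA`.
#'
#' @param gm A [genotype_matrix] with at least 2 individuals (per population
#'   when `within_population = TRUE`).
#' @param within_population Logical; compute pairs within each population
#'   separately (default `TRUE`).
#' @return An object of class `kinship_matrix`: list with `phi` (symmetric
#'   n x n matrix, `NA` diagonal), `n_loci` (loci used per pair),
#'   `sample_ids`, `populations`.
#' @export
king_kinship <- function(gm, within_population = TRUE) {
  g <- gm$genotypes
  n <- nrow(g)
  if (n < 2L) stop("need at least 2 individuals")
  phi <- matrix(NA_real_, n, n)
  nl <- matrix(NA_real_, n, n)
  blocks <- if (within_population) split(seq_len(n), gm$populations)
            else list(seq_len(n))
  for (idx in blocks) {
    if (length(idx) < 2L) next
    sub <- g[idx, , drop = FALSE]
    H <- (sub == 1L); H[is.na(H)] <- FALSE; storage.mode(H) <- "double"
    A0 <- (sub == 0L); A0[is.na(A0)] <- FALSE; storage.mode(A0) <- "double"
    A2 <- (sub == 2L); A2[is.na(A2)] <- FALSE; storage.mode(A2) <- "double"
    C <- !is.na(sub); storage.mode(C) <- "double"
    hethet <- tcrossprod(H)
    opp <- tcrossprod(A0, A2); opp <- opp + t(opp)
    hc <- tcrossprod(H, C)            # [i, j] = hets of i on loci called in j
    den <- hc + t(hc)
    ph <- (hethet - 2 * opp) / den
    ph[den == 0] <- NA_real_
    phi[idx, idx] <- ph
    nl[idx, idx] <- tcrossprod(C)
  }
  diag(phi) <- NA_real_
  structure(list(phi = phi, n_loci = nl, sample_ids = gm$sample_ids,
                 populations = gm$populations,
                 within_population = within_population),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  vals <- x$phi[upper.tri(x$phi)]
  cat("kinship_matrix:", length(x$sample_ids), "individuals;",
      sum(!is.na(vals)), "defined pairs\n")
  if (any(!is.na(vals)))
    cat("phi range:", sprintf("%.3f .. %.3f", min(vals, na.rm = TRUE),
                              max(vals, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Flag clones and close relatives from a kinship matrix
#'
#' Bins pairs by KING-robust phi: `phi > 0.45` is labelled
#' `"duplicate/clone"` (clones have phi of about 0.5), `0.354 < phi <= 0.45`
#' `"first-degree"`, and `0.177 < phi <= 0.354` `"close relative"`. Pairs at
#' or below 0.177 are not reported.
#'
#' @param kin A `kinship_matrix` from [king_kinship()].
#' @param clone_threshold Lower phi bound for the clone label (default 0.45).
#' @return Data frame with columns `id1`, `id2`, `population`, `phi`,
#'   `n_loci`, `label`; zero rows when nothing is flagged.
#' @export
kinship_flags <- function(kin, clone_threshold = 0.45) {
  ut <- which(upper.tri(kin$phi) & !is.na(kin$phi), arr.ind = TRUE)
  phi <- kin$phi[ut]
  keep <- phi > 0.177
  ut <- ut[keep, , drop = FALSE]; phi <- phi[keep]
  label <- ifelse(phi > clone_threshold, "duplicate/clone",
                  ifelse(phi > 0.354, "first-degree", "close relative"))
  data.frame(id1 = kin$sample_ids[ut[, 1]], id2 = kin$sample_ids[ut[, 2]],
             population = kin$populations[ut[, 1]],
             phi = phi, n_loci = kin$n_loci[ut], label = label,
             stringsAsFactors = FALSE)
}
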
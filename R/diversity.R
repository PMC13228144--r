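#' Observed and expected heterozygosity, and F_IS, per group
#'
#' Computes per-individual observed heterozygosity H_O (fraction of
#' heterozygous calls among non-missing loci) and, for each group, mean H_O,
#' expected heterozygosity H_E as Nei's unbiased gene diversity averaged over
#' loci, and the inbreeding coefficient `F_IS = 1 - mean(H_O) / mean(H_E)`.
#' All statistics are complete-case per locus; nothing is imputed.
#'
#' Nei's unbiased gene diversity at locus l is
#' `(2 n_l / (2 n_l - 1)) * (1 - p^2 - q^2)` with `n_l` the number of called
#' individuals at that locus, appropriate for the small per-population sample
#' sizes typical of field collections.
#'
#' @param gm A [genotype_matrix].
#' @param grouping Character vector of group labels, one per individual
#'   (e.g. population or lineage assignment). Defaults to `gm$populations`.
#' @return An object of class `diversity_summary`: a list with
#'   `individuals` (data frame: sample_id, group, n_called, H_O,
#'   missing_frac) and `groups` (data frame: group, n, H_O, H_E, F_IS).
#'   Individuals with zero called loci get `NA` H_O.
#' @examples
#' gm <- genotype_matrix(rbind(c(1, 1, 0, NA), c(0, 2, 0, 2)))
#' diversity_summary(gm)$individuals$H_O  # 2/3 and 0
#' @export
diversity_summary <- function(gm, grouping = NULL) {
  if (is.null(grouping)) grouping <- gm$populations
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == nrow(gm$genotypes))
  g <- gm$genotypes
  called <- rowSums(!is.na(g))
  nhet <- rowSums(g == 1L, na.rm = TRUE)
  ho <- ifelse(called > 0, nhet / called, NA_real_)
  ind <- data.frame(sample_id = gm$sample_ids, group = grouping,
                    n_called = called, H_O = ho,
                    missing_frac = 1 - called / max(1L, ncol(g)),
                    stringsAsFactors = FALSE)
  groups <- unique(grouping)
  gs <- lapply(groups, function(grp) {
    sub <- g[grouping == grp, , drop = FALSE]
    nl <- colSums(!is.na(sub))
    use <- nl > 0
    p <- colSums(sub, na.rm = TRUE)[use] / (2 * nl[use])
    he_l <- (2 * nl[use] / (2 * nl[use] - 1)) * (1 - p^2 - (1 - p)^2)
    # loci where every call is in one individual give 2n-1 = 1: still defined
    he <- if (any(use)) mean(he_l) else NA_real_
    ho_g <- mean(ho[grouping == grp], na.rm = TRUE)
    data.frame(group = grp, n = sum(grouping == grp), H_O = ho_g, H_E = he,
               F_IS = if (!is.na(he) && he > 0) 1 - ho_g / he else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(list(individuals = ind, groups = do.call(rbind, gs)),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("diversity_summary over", nrow(x$individuals), "individuals,",
      nrow(x$groups), "groups\n")
  print(x$groups, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Convert an inbreeding coefficient to a selfing rate
#'
#' Inverts the mixed-mating equilibrium relation `F = s / (2 - s)`, giving
#' `s = 2 F / (1 + F)`. Negative F maps to `s = 0` (with a `clipped`
#' attribute); results are clipped to `[0, 1]`.
#'
#' @param f Inbreeding coefficient(s) in `[-1, 1]`; `f = -1` is undefined.
#' @return Selfing rate(s) in `[0, 1]`, with attribute `clipped` marking
#'   inputs that were negative.
#' @examples
#' fis_to_selfing(1 / 3)  # 0.5
#' @export
fis_to_selfing <- function(f) {
  stopifnot(all(f >= -1 & f <= 1, na.rm = TRUE))
  if (any(f == -1, na.rm = TRUE)) stop("F = -1: selfing rate undefined")
  s <- 2 * f / (1 + f)
  clipped <- !is.na(f) & f < 0
  s[clipped] <- 0
  s <- pmin(pmax(s, 0), 1)
  attr(s, "clipped") <- clipped
  s
}
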
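#' Maximum-likelihood admixture-model ancestry inference (EM)
#'
#' Fits the standard admixture model to unlinked biallelic genotypes by
#' expectation-maximization: each individual's two alleles at each locus are
#' drawn from `K` cluster allele-frequency vectors according to membership
#' fractions `q`, maximizing
#' \deqn{\sum_{i,l} g_{il}\log\sum_k q_{ik} p_{kl} +
#'       (2-g_{il})\log\sum_k q_{ik}(1-p_{kl}).}
#' This is the deterministic maximum-likelihood counterpart of Bayesian
#' MCMC clustering: the same likelihood family, fit by EM from multiple
#' random restarts, keeping the best. Missing genotypes are skipped, with
#' per-individual normalization by called loci. Initialization: Q rows from
#' a symmetric Dirichlet(1), P from Uniform(0.05, 0.95); frequencies are
#' kept in `[1e-6, 1 - 1e-6]`.
#'
#' @param gm A [genotype_matrix].
#' @param K Number of clusters, `1 <= K <= n`.
#' @param n_restarts Random restarts (default 10); best final
#'   log-likelihood wins, ties broken by restart index.
#' @param tol Convergence tolerance on the log-likelihood increment
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations per restart (default 2000).
#' @param seed Integer seed, or `NULL`.
#' @return Object of class `ancestry_fit`: `Q` (n x K membership matrix,
#'   rows sum to 1), `P` (K x L cluster allele frequencies),
#'   `log_likelihood`, `ll_trace` (of the best restart), `K`, `n_restarts`,
#'   `converged`, `n_iter`, `seed`. The log-likelihood is non-decreasing
#'   along `ll_trace`.
#' @examples
#' freq <- rbind(rep(0.99, 50), rep(0.01, 50))
#' g <- rbind(matrix(rbinom(250, 2, 0.99), 5, byrow = TRUE),
#'            matrix(rbinom(250, 2, 0.01), 5, byrow = TRUE))
#' fit <- admixture_em(genotype_matrix(g), K = 2, n_restarts = 2, seed = 1)
#' round(fit$Q, 2)
#' @export
admixture_em <- function(gm, K, n_restarts = 10, tol = 1e-6,
                         max_iter = 2000, seed = NULL) {
  g <- gm$genotypes
  n <- nrow(g); L <- ncol(g)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of individuals (", n, ")")
  if (!is.null(seed)) set.seed(seed)
  M <- !is.na(g); storage.mode(M) <- "double"
  g0 <- g; g0[!M] <- 0L; storage.mode(g0) <- "double"
  g2c <- (2 - g0) * M
  called2 <- 2 * rowSums(M)
  eps <- 1e-6
  best <- NULL
  for (r in seq_len(n_restarts)) {
    Q <- matrix(stats::rexp(n * K), n, K)
    Q <- Q / rowSums(Q)
    P <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Fm <- Q %*% P
      U <- (g0 / Fm) * M
      V <- g2c / (1 - Fm)
      ll <- sum(M * (g0 * log(Fm) + (2 - g0) * log(1 - Fm)))
      ll_trace <- c(ll_trace, ll)
      Qn <- Q * (U %*% t(P) + V %*% t(1 - P)) / called2
      Qn <- Qn / rowSums(Qn)
      TU <- crossprod(U, Q)              # L x K
      TV <- crossprod(V, Q)
      Pn <- t(P) * TU
      Pn <- Pn / (Pn + t(1 - P) * TV)
      Pn[is.nan(Pn)] <- 0.5              # cluster weight vanished at locus
      P <- pmin(pmax(t(Pn), eps), 1 - eps)
      Q <- Qn
      if (it > 1 && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    Fm <- Q %*% P
    ll <- sum(M * (g0 * log(Fm) + (2 - g0) * log(1 - Fm)))
    ll_trace <- c(ll_trace, ll)
    if (is.null(best) || ll > best$log_likelihood) {
      best <- list(Q = Q, P = P, log_likelihood = ll, ll_trace = ll_trace,
                   converged = converged, n_iter = length(ll_trace) - 1L,
                   restart = r)
    }
  }
  rownames(best$Q) <- gm$sample_ids
  colnames(best$P) <- gm$locus_ids
  structure(c(best, list(K = K, n_restarts = n_restarts, seed = seed)),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("ancestry_fit: K =", x$K, "on", nrow(x$Q), "individuals,",
      ncol(x$P), "loci\n")
  cat("log-likelihood:", format(x$log_likelihood),
      if (x$converged) "(converged," else "(NOT converged,",
      x$n_iter, "EM iterations, best of", x$n_restarts, "restarts)\n")
  invisible(x)
}

#' @export
logLik.ancestry_fit <- function(object, ...) {
  ll <- object$log_likelihood
  attr(ll, "df") <- (nrow(object$Q) * (object$K - 1) +
                     object$K * ncol(object$P))
  class(ll) <- "logLik"
  ll
}

#' Supervised ancestry against two parental allele-frequency panels
#'
#' For each individual, maximizes the two-parental binomial likelihood with
#' per-locus allele frequency `f_l = q p_A,l + (1 - q) p_B,l` over the
#' single admixture coefficient `q` in `[0, 1]` by 1-D bounded
#' optimization. Parental frequencies are clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param gm A [genotype_matrix].
#' @param freqs_a,freqs_b Parental allele-frequency vectors on the same loci
#'   as `gm`.
#' @return Named numeric vector of `q` (ancestry fraction from panel A);
#'   `NA` for individuals with no called locus where both panels are
#'   defined.
#' @export
supervised_ancestry <- function(gm, freqs_a, freqs_b) {
  g <- gm$genotypes
  stopifnot(length(freqs_a) == ncol(g), length(freqs_b) == ncol(g))
  ok_l <- !is.na(freqs_a) & !is.na(freqs_b)
  pa <- pmin(pmax(freqs_a[ok_l], 1e-6), 1 - 1e-6)
  pb <- pmin(pmax(freqs_b[ok_l], 1e-6), 1 - 1e-6)
  q <- vapply(seq_len(nrow(g)), function(i) {
    gi <- g[i, ok_l]
    use <- !is.na(gi)
    if (!any(use)) return(NA_real_)
    gi <- gi[use]; a <- pa[use]; b <- pb[use]
    nll <- function(q) {
      f <- q * a + (1 - q) * b
      -sum(gi * log(f) + (2 - gi) * log(1 - f))
    }
    stats::optimize(nll, c(0, 1), tol = 1e-8)$minimum
  }, numeric(1))
  names(q) <- gm$sample_ids
  q
}

#' Evanno's delta-K from replicate log-likelihoods
#'
#' Computes the rate-of-change statistic used to choose the number of
#' clusters:
#' `deltaK(K) = mean_r |L_r(K+1) - 2 L_r(K) + L_r(K-1)| / sd_r(L_r(K))`,
#' with mean and SD over replicate runs. Defined only for interior K with
#' positive replicate SD; no K is auto-selected.
#'
#' @param ll Matrix of log-likelihoods: replicates in rows, consecutive K
#'   values in columns, with column names giving K (default `1..ncol`).
#'   At least 3 consecutive K values and 2 replicates are required.
#' @return Object of class `evanno_table` (data frame): K, `mean_ll`,
#'   `sd_ll`, `delta_k` (`NA` at the ends and where the SD is 0).
#' @examples
#' ll <- rbind(c(-100, -50, -45, -44), c(-100.1, -50.2, -45.1, -44.2))
#' evanno_delta_k(ll)
#' @export
evanno_delta_k <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2L)
    stop("need at least 2 replicate runs per K (SD undefined otherwise)")
  if (ncol(ll) < 3L) stop("need at least 3 consecutive K values")
  ks <- if (!is.null(colnames(ll))) as.integer(colnames(ll))
        else seq_len(ncol(ll))
  if (any(diff(ks) != 1L)) stop("K values must be consecutive")
  m <- colMeans(ll)
  s <- apply(ll, 2, stats::sd)
  dk <- rep(NA_real_, length(ks))
  for (j in 2:(length(ks) - 1L)) {
    if (s[j] > 0)
      dk[j] <- mean(abs(ll[, j + 1] - 2 * ll[, j] + ll[, j - 1])) / s[j]
  }
  out <- data.frame(K = ks, mean_ll = m, sd_ll = s, delta_k = dk)
  class(out) <- c("evanno_table", "data.frame")
  out
}

#' Per-individual degree of admixed ancestry
#'
#' Summarizes each row of a membership matrix Q as the population standard
#' deviation (divisor K) of its membership fractions: 0 for a uniformly
#' admixed row, maximal (`sqrt((K - 1)) / K`) for a pure row.
#'
#' @param Q Membership matrix (rows sum to 1), e.g. from [admixture_em()].
#' @return Numeric vector, one value per individual.
#' @examples
#' admixture_degree(rbind(c(0.5, 0.5), c(1, 0)))  # 0 and 0.5
#' @export
admixture_degree <- function(Q) {
  Q <- as.matrix(Q)
  apply(Q, 1, function(r) sqrt(mean((r - mean(r))^2)))
}

#' PCA of genotypes with mean imputation of missing calls
#'
#' Missing genotypes are imputed with the per-locus mean (twice the mean
#' allele frequency across all samples), columns are centered but not
#' scaled, and the covariance eigenstructure is obtained by SVD.
#' Deterministic up to the sign of each component.
#'
#' @param gm A [genotype_matrix] with at least 2 individuals.
#' @param n_components Number of components to return (default 2); at most
#'   `min(n, L)`.
#' @return Object of class `pca_result`: `scores` (n x d, rownames sample
#'   ids) and `explained_variance` (fractions, non-increasing).
#' @export
pca_mean_impute <- function(gm, n_components = 2) {
  g <- gm$genotypes
  n <- nrow(g)
  if (n < 2L) stop("need at least 2 individuals")
  if (n_components > min(dim(g)))
    stop("n_components exceeds min(individuals, loci)")
  x <- g
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- gm$sample_ids
  structure(list(scores = scores,
                 explained_variance = ev[seq_len(n_components)]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "individuals,",
      ncol(x$scores), "components; explained:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}
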
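#' Genomic relationship matrix and its transforms
#'
#' Computes the GCTA-default GRM from allele dosages,
#' \deqn{G_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}
#'   {2p_i(1-p_i)},}
#' with \eqn{p_i} the observed allele frequency in the current accession
#' set, plus its correlation form G* (via `cov2cor`) and the dissimilarity
#' matrix 1 - G* used for multidimensional scaling.
#'
#' @param genotypes a [genotype_matrix()]; all SNPs must be polymorphic and
#'   dosages complete.
#' @return object of class `relationship_set` with elements `G`, `G_star`,
#'   `D`, `accessions`, `n_snps`.
#' @export
compute_grm <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  X <- genotypes$dosage
  if (anyNA(X)) stop("missing dosages; filter first", call. = FALSE)
  p <- colMeans(X) / 2
  if (any(p <= 0 | p >= 1) ||
        any(apply(X, 2, function(v) length(unique(v))) < 2))
    stop("monomorphic SNP present; filter before computing the GRM",
         call. = FALSE)
  W <- sweep(X, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(W) / ncol(X)
  if (any(diag(G) <= 0)) stop("zero diagonal entry in G", call. = FALSE)
  G_star <- stats::cov2cor(G)
  D <- 1 - G_star
  diag(D) <- 0
  structure(list(G = G, G_star = G_star, D = D,
                 accessions = rownames(X), n_snps = ncol(X)),
            class = "relationship_set")
}

#' @export
print.relationship_set <- function(x, ...) {
  cat(sprintf("relationship_set: %d accessions from %d SNPs (mean diag G = %.3f)\n",
              length(x$accessions), x$n_snps, mean(diag(x$G))))
  invisible(x)
}

#' Classical multidimensional scaling of a dissimilarity matrix
#'
#' Double-centers the elementwise-squared dissimilarities,
#' \eqn{B = -\tfrac12 J D^{(2)} J}, and eigendecomposes B. Coordinates are
#' eigenvectors scaled by the square root of their (positive) eigenvalues;
#' the percentage of variance per axis is taken over positive eigenvalues
#' only. Each axis is oriented so its loading on the first accession is
#' non-negative.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes number of axes to return (default 2; capped at the number
#'   of positive eigenvalues).
#' @return object of class `mds_result` with `coordinates`, `eigenvalues`
#'   (all, sorted descending) and `pct_variance` (per returned axis).
#' @export
classical_mds <- function(D, n_axes = 2) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8 || max(abs(diag(D))) > 1e-8)
    stop("D must be symmetric with zero diagonal", call. = FALSE)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  ee <- eigen(B, symmetric = TRUE)
  lam <- ee$values
  pos <- which(lam > max(lam, 0) * 1e-10 & lam > 0)
  if (!length(pos)) {
    if (all(abs(D) < 1e-12)) {            # degenerate but well-defined: all points coincide
      k <- max(1, n_axes)
      return(structure(list(coordinates = matrix(0, n, min(k, n),
                                                 dimnames = list(rownames(D), NULL)),
                            eigenvalues = lam,
                            pct_variance = rep(0, min(k, n))),
                       class = "mds_result"))
    }
    stop("no positive eigenvalue: degenerate dissimilarity", call. = FALSE)
  }
  k <- min(n_axes, length(pos))
  coords <- ee$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(lam[pos[seq_len(k)]]), k)
  for (j in seq_len(k)) if (coords[1, j] < 0) coords[, j] <- -coords[, j]
  rownames(coords) <- rownames(D)
  structure(list(coordinates = coords, eigenvalues = lam,
                 pct_variance = 100 * lam[pos[seq_len(k)]] / sum(lam[pos])),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat("mds_result: axes explain",
      paste(sprintf("%.2f%%", x$pct_variance), collapse = ", "), "\n")
  invisible(x)
}
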
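#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bend a relationship matrix towards positive definiteness
#'
#' Adds a small ridge to the diagonal when the smallest eigenvalue falls
#' below a threshold, so that a Cholesky factor exists. The same rule is
#' used everywhere a relationship matrix enters a factorisation.
#'
#' @param G symmetric relationship matrix.
#' @param eps ridge added to the diagonal (default 1e-6).
#' @param tol smallest admissible eigenvalue before bending (default 1e-8).
#' @return the (possibly bent) matrix, with attribute `"bent"` TRUE/FALSE.
#' @export
bend_grm <- function(G, eps = 1e-6, tol = 1e-8) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  bent <- FALSE
  while (ev_min < tol) {
    G <- G + diag(eps, nrow(G))
    bent <- TRUE
    ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    eps <- eps * 10
  }
  attr(G, "bent") <- bent
  G
}

## multivariate normal draw with covariance s2 * G (G bent if needed)
draw_mvn_grm <- function(n_draws, G, s2) {
  q <- nrow(G)
  if (s2 <= 0) return(matrix(0, q, n_draws))
  L <- chol(bend_grm(G))             # upper triangular, G = t(L) %*% L
  crossprod(L, matrix(stats::rnorm(q * n_draws), q, n_draws)) * sqrt(s2)
}

## standardize a numeric vector; constant vectors map to zeros
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}
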
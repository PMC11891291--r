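#' Fit a gBLUP mixed model by EM-REML with one average-information step
#'
#' Fits \eqn{y = X\beta + Zg + e} with \eqn{g \sim N(0, \sigma_G^2 G)} and
#' \eqn{e \sim N(0, \sigma_e^2 I)} through the mixed-model equations.
#' Variance components are estimated by EM-REML iterations until the
#' restricted log-likelihood stabilises; a single average-information step
#' at the solution provides their standard errors. Fixed-effect standard
#' errors come from the inverse coefficient matrix; gBLUPs are the
#' converged random-effect solutions, including accessions carried only
#' through G (no phenotype rows).
#'
#' @param y numeric response vector.
#' @param X design matrix (columns aliased by rank deficiency are dropped
#'   with a message).
#' @param Z either a factor/character vector of length `length(y)` mapping
#'   observations to the rownames of `G`, or an incidence matrix with
#'   `ncol = nrow(G)`.
#' @param G relationship matrix (bent towards positive definiteness if
#'   required).
#' @param start optional `c(sigma2_g, sigma2_e)` starting values.
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-10).
#' @param par_tol convergence tolerance on the relative change of the
#'   variance components (default 1e-8).
#' @param max_iter iteration cap (default 2000).
#' @param bound lower bound for the variance components (default 1e-8);
#'   components pinned there flag the fit as `boundary`.
#' @return object of class `mixed_model_fit`: `beta` (estimate/SE table),
#'   `sigma2_g`, `sigma2_e` with SEs, `gblups`, `h2`, `loglik_trace`,
#'   `converged`, `boundary`, `n_obs`, `n_accessions`, `df_residual`,
#'   `vcov_beta` and bookkeeping for downstream tests.
#' @export
fit_emreml <- function(y, X, Z, G, start = NULL, tol = 1e-10,
                       par_tol = 1e-8, max_iter = 2000, bound = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  stopifnot(nrow(X) == n, is.matrix(G), nrow(G) == ncol(G))
  q <- nrow(G)
  if (is.matrix(Z)) {
    stopifnot(nrow(Z) == n, ncol(Z) == q)
    acc_idx <- max.col(Z)
    stopifnot(all(Z[cbind(seq_len(n), acc_idx)] == 1))
  } else {
    ids <- rownames(G) %||% as.character(seq_len(q))
    acc_idx <- match(as.character(Z), ids)
    if (anyNA(acc_idx))
      stop("observations map to accessions absent from G", call. = FALSE)
  }

  ## drop aliased fixed-effect columns by pivoted rank detection
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    message("dropping aliased fixed-effect column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
  }
  p <- ncol(X)

  Gb <- bend_grm(G)
  cholG <- chol(Gb)
  Ginv <- chol2inv(cholG)
  logdetG <- 2 * sum(log(diag(cholG)))

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  ZtZ_diag <- tabulate(acc_idx, nbins = q)
  zt_vec <- function(v) {   # Z'v, robust to accessions with no observations
    agg <- rowsum(v, acc_idx)
    out <- numeric(q)
    out[as.integer(rownames(agg))] <- agg
    out
  }
  Zty <- zt_vec(y)
  agg_X <- rowsum(X, acc_idx)
  XtZ <- matrix(0, p, q)
  XtZ[, as.integer(rownames(agg_X))] <- t(agg_X)

  solve_mme <- function(k, rhs_x, rhs_z) {
    M <- rbind(cbind(XtX, XtZ),
               cbind(t(XtZ), diag(ZtZ_diag, q) + k * Ginv))
    cholM <- chol(M)
    sol <- backsolve(cholM, forwardsolve(t(cholM), c(rhs_x, rhs_z)))
    list(beta = sol[seq_len(p)], u = sol[p + seq_len(q)], cholM = cholM)
  }

  if (is.null(start)) {
    v <- stats::var(y)
    start <- c(v / 2, v / 2)
  }
  s2g <- max(start[1], bound)
  s2e <- max(start[2], bound)
  trace <- numeric(0)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    k <- s2e / s2g
    sol <- solve_mme(k, Xty, Zty)
    logdetM <- 2 * sum(log(diag(sol$cholM)))
    resid_q <- yty - sum(sol$beta * Xty) - sum(sol$u * Zty)
    ll <- -0.5 * ((n - p) * log(s2e) + logdetG + q * log(s2g / s2e) +
                    logdetM + resid_q / s2e + (n - p) * log(2 * pi))
    trace <- c(trace, ll)
    C <- chol2inv(sol$cholM)
    Cuu <- C[p + seq_len(q), p + seq_len(q), drop = FALSE]
    s2g_new <- max((sum(sol$u * (Ginv %*% sol$u)) +
                      s2e * sum(Ginv * Cuu)) / q, bound)
    s2e_new <- max(resid_q / (n - p), bound)
    d_par <- max(abs(s2g_new - s2g) / max(s2g, 1e-12),
                 abs(s2e_new - s2e) / max(s2e, 1e-12))
    d_ll <- if (it > 1) abs(trace[it] - trace[it - 1]) else Inf
    s2g <- s2g_new; s2e <- s2e_new
    if (d_ll < tol && d_par < par_tol) { converged <- TRUE; break }
  }
  boundary <- s2g <= bound * (1 + 1e-6) || s2e <= bound * (1 + 1e-6)

  ## final solve and one AI step for variance-component standard errors
  k <- s2e / s2g
  sol <- solve_mme(k, Xty, Zty)
  C <- chol2inv(sol$cholM)
  Cbb <- C[seq_len(p), seq_len(p), drop = FALSE]
  e <- y - X %*% sol$beta - sol$u[acc_idx]
  Py <- as.vector(e) / s2e
  f_g <- (Gb %*% zt_vec(Py))[acc_idx]
  f_e <- Py
  Pf <- function(f) {
    f <- as.vector(f)
    s <- solve_mme(k, crossprod(X, f), zt_vec(f))
    as.vector(f - X %*% s$beta - s$u[acc_idx]) / s2e
  }
  se_vc <- c(NA_real_, NA_real_)
  AI <- NULL
  ai_try <- tryCatch({
    Pf_g <- Pf(f_g); Pf_e <- Pf(f_e)
    AI <- 0.5 * matrix(c(sum(f_g * Pf_g), sum(f_g * Pf_e),
                         sum(f_g * Pf_e), sum(f_e * Pf_e)), 2, 2)
    se_vc <- sqrt(diag(solve(AI)))
    TRUE
  }, error = function(e) FALSE)

  beta_se <- sqrt(pmax(diag(Cbb) * s2e, 0))
  h2 <- if (boundary && s2g <= bound * (1 + 1e-6) && s2e <= bound * (1 + 1e-6))
    NA_real_ else s2g / (s2g + s2e)
  gblups <- stats::setNames(sol$u, rownames(G))

  structure(list(
    beta = data.frame(term = colnames(X) %||% paste0("b", seq_len(p)),
                      estimate = sol$beta, se = beta_se,
                      stringsAsFactors = FALSE),
    sigma2_g = s2g, sigma2_e = s2e,
    se_sigma2_g = se_vc[1], se_sigma2_e = se_vc[2], ai_matrix = AI,
    gblups = gblups, h2 = h2, loglik = trace[length(trace)],
    loglik_trace = trace, converged = converged, boundary = boundary,
    n_obs = n, n_accessions = q, df_residual = n - p,
    vcov_beta = Cbb * s2e, acc_idx = acc_idx, X = X, y = y
  ), class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("mixed_model_fit: n=%d obs, %d accessions; sigma2_g=%.4g, sigma2_e=%.4g, h2=%.3f%s\n",
              x$n_obs, x$n_accessions, x$sigma2_g, x$sigma2_e, x$h2,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$beta, row.names = FALSE)
  invisible(x)
}

#' Extract per-accession gBLUPs from a fit
#'
#' One value per accession in the relationship matrix, including
#' accessions with no phenotype rows (predicted through G).
#'
#' @param fit a `mixed_model_fit`.
#' @return named numeric vector.
#' @export
extract_gblups <- function(fit) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  fit$gblups
}

#' Narrow-sense heritability of a fit
#'
#' Defined as \eqn{\sigma_G^2 / (\sigma_G^2 + \sigma_e^2)}.
#'
#' @param fit a `mixed_model_fit`.
#' @return value in [0, 1]; NA when both components sit at the lower bound.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  fit$h2
}

#' Wald Z-test of a fixed-effect term
#'
#' `z = estimate / SE` with a two-sided normal p-value, the large-sample
#' approximation to the t-test.
#'
#' @param fit a `mixed_model_fit` (or any object with a `beta` table).
#' @param term coefficient name (a column of the design matrix).
#' @return list with `estimate`, `se`, `z`, `p`.
#' @export
wald_z_test <- function(fit, term) {
  tab <- fit$beta
  i <- match(term, tab$term)
  if (is.na(i))
    stop("term not in fitted model (aliased or absent): ", term,
         call. = FALSE)
  z <- tab$estimate[i] / tab$se[i]
  list(estimate = tab$estimate[i], se = tab$se[i], z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Tukey HSD test over the levels of a fitted factor
#'
#' For each pair of levels, `q = |difference| / SE_mean` with
#' `SE_mean = SE(difference) / sqrt(2)`, and the p-value from the
#' studentized-range distribution with the residual degrees of freedom.
#'
#' @param fit a `mixed_model_fit` produced by [fit_gblup_model()] (the
#'   design bookkeeping is needed to locate the factor's columns).
#' @param factor_name name of a fitted factor with >= 2 levels.
#' @return data.frame with one row per level pair: `contrast`, `diff`,
#'   `se_diff`, `q`, `p`.
#' @export
tukey_hsd <- function(fit, factor_name) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  des <- attr(fit, "design")
  if (is.null(des) || is.null(des$xlevels[[factor_name]]))
    stop("factor not found in fit design: ", factor_name, call. = FALSE)
  levs <- des$xlevels[[factor_name]]
  k <- length(levs)
  if (k < 2) stop("factor has a single level", call. = FALSE)
  ## treatment coding: reference level has implicit coefficient 0
  coef_names <- paste0(factor_name, levs)
  tab <- fit$beta
  est <- stats::setNames(rep(0, k), levs)
  Cb <- fit$vcov_beta
  pos <- stats::setNames(rep(NA_integer_, k), levs)
  for (j in seq_len(k)) {
    i <- match(coef_names[j], tab$term)
    if (!is.na(i)) { est[j] <- tab$estimate[i]; pos[j] <- i }
  }
  out <- list()
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    d <- est[b] - est[a]
    v <- 0
    if (!is.na(pos[b])) v <- v + Cb[pos[b], pos[b]]
    if (!is.na(pos[a])) v <- v + Cb[pos[a], pos[a]]
    if (!is.na(pos[a]) && !is.na(pos[b])) v <- v - 2 * Cb[pos[a], pos[b]]
    se_d <- sqrt(v)
    qstat <- abs(d) / (se_d / sqrt(2))
    out[[length(out) + 1L]] <- data.frame(
      contrast = paste(levs[b], "-", levs[a]), diff = d, se_diff = se_d,
      q = qstat,
      p = stats::ptukey(qstat, nmeans = k, df = fit$df_residual,
                        lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
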
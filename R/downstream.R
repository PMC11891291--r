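#' Assemble per-accession summaries from cold and warm fits
#'
#' @param cold,warm named gBLUP vectors (cold and warm temperature) or
#'   `mixed_model_fit` objects.
#' @param meta data.frame with `accession` and optionally `species`,
#'   `type`, `country`, `latitude`.
#' @param emergence optional data.frame with `accession`, `emergence`.
#' @return data.frame (class `accession_summary`) with columns `accession`,
#'   metadata, `C`, `W`, and `E` where available. Accessions missing either
#'   gBLUP are excluded with a log entry.
#' @export
build_accession_summary <- function(cold, warm, meta, emergence = NULL) {
  if (inherits(cold, "mixed_model_fit")) cold <- extract_gblups(cold)
  if (inherits(warm, "mixed_model_fit")) warm <- extract_gblups(warm)
  acc <- union(names(cold), names(warm))
  out <- data.frame(accession = acc,
                    C = unname(cold[acc]), W = unname(warm[acc]),
                    stringsAsFactors = FALSE)
  bad <- is.na(out$C) | is.na(out$W)
  if (any(bad)) {
    message(sum(bad), " accession(s) missing a gBLUP excluded")
    out <- out[!bad, , drop = FALSE]
  }
  if (!is.null(meta)) {
    keep <- intersect(c("accession", "species", "type", "country",
                        "latitude"), names(meta))
    out <- merge(out, unique(meta[keep]), by = "accession", sort = TRUE)
  }
  if (!is.null(emergence))
    out <- merge(out, emergence[c("accession", "emergence")],
                 by = "accession", all.x = TRUE, sort = TRUE)
  class(out) <- c("accession_summary", "data.frame")
  out
}

#' Heat tolerance per accession
#'
#' Adds `H = W - C`, the warm-temperature gBLUP minus the cold-temperature
#' gBLUP.
#'
#' @param summaries an `accession_summary` (needs `W` and `C`).
#' @return the input with an `H` column.
#' @export
heat_tolerance <- function(summaries) {
  stopifnot(all(c("W", "C") %in% names(summaries)))
  bad <- is.na(summaries$W) | is.na(summaries$C)
  if (any(bad)) {
    message(sum(bad), " accession(s) without both gBLUPs excluded")
    summaries <- summaries[!bad, , drop = FALSE]
  }
  summaries$H <- summaries$W - summaries$C
  summaries
}

ols_fit <- function(y, X, offset = NULL) {
  if (!is.null(offset)) y <- y - offset
  fit <- stats::lm.fit(X, y)
  ok <- !is.na(fit$coefficients)   # aliased (e.g. constant) columns dropped
  X <- X[, ok, drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("too few observations for OLS", call. = FALSE)
  res <- fit$residuals
  sigma2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  est <- fit$coefficients[ok]
  z <- est / se
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  structure(list(
    coefficients = data.frame(term = colnames(X),
                              estimate = unname(est), se = se, z = unname(z),
                              p = unname(2 * stats::pnorm(-abs(z))),
                              stringsAsFactors = FALSE),
    n = n, r2 = r2,
    adj_r2 = adjusted_r2(r2, n, sum(colnames(X) != "(Intercept)")),
    sigma2 = sigma2, offset = offset,
    residuals = res), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear_fit: n=%d, R2=%.3f, adjusted R2=%.3f\n",
              x$n, x$r2, x$adj_r2))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Cross-temperature regression of warm on cold gBLUPs
#'
#' Ordinary least squares of `W` on `C` with intercept (the minimal-GxE
#' check: a slope near 1 with high adjusted R-squared means the accession
#' ranking is conserved across temperatures).
#'
#' @param summaries an `accession_summary` (>= 3 accessions).
#' @param by_type also return per-type fits (default TRUE when a `type`
#'   column is present).
#' @return a `linear_fit`; per-type fits in the `by_type` element.
#' @export
fit_cross_temperature <- function(summaries,
                                  by_type = "type" %in% names(summaries)) {
  stopifnot(nrow(summaries) >= 3)
  if (stats::sd(summaries$C) == 0)
    stop("zero variance in the cold gBLUP", call. = FALSE)
  X <- cbind("(Intercept)" = 1, C = summaries$C)
  fit <- ols_fit(summaries$W, X)
  if (isTRUE(by_type)) {
    fit$by_type <- lapply(split(summaries, summaries$type), function(d)
      if (nrow(d) >= 3 && stats::sd(d$C) > 0)
        ols_fit(d$W, cbind("(Intercept)" = 1, C = d$C)) else NULL)
  }
  fit
}

#' Latitude regression of heat tolerance
#'
#' OLS of `H` on the cold gBLUP `C` (baseline control) and latitude,
#' fitted separately for wild and landrace accessions (a joint fit pooling
#' types is returned as `joint`). The latitude coefficient quantifies
#' local adaptation of heat tolerance, in the spirit of a
#' Finlay-Wilkinson regression on an environmental index.
#'
#' @param summaries an `accession_summary` with `H` and `latitude`
#'   (>= 4 accessions per fit).
#' @param latitude_col column to use as latitude (default `"latitude"`).
#' @return named list of `linear_fit` per type, plus `joint`.
#' @export
fit_latitude_model <- function(summaries, latitude_col = "latitude") {
  stopifnot(all(c("H", "C") %in% names(summaries)))
  lat <- summaries[[latitude_col]]
  if (is.null(lat)) stop("latitude column missing", call. = FALSE)
  one_fit <- function(d) {
    if (nrow(d) < 4) return(NULL)
    l <- d[[latitude_col]]
    if (stats::sd(d$C) > 0 && stats::sd(l) > 0 &&
          abs(stats::cor(d$C, l)) > 0.999)
      stop("cold gBLUP and latitude are collinear", call. = FALSE)
    ols_fit(d$H, cbind("(Intercept)" = 1, C = d$C, latitude = l))
  }
  out <- if ("type" %in% names(summaries))
    lapply(split(summaries, summaries$type), one_fit) else list()
  out$joint <- one_fit(summaries)
  out
}

#' Emergence regression on the cold germination-rate gBLUP
#'
#' OLS of the field emergence rate `E` on the cold gBLUP `C`, with the
#' cold-model intercept `mu3` entered as a known offset (subtracted from E,
#' not re-estimated).
#'
#' @param summaries an `accession_summary` with `emergence`.
#' @param mu3 intercept of the corresponding cold-temperature
#'   germination-rate fit (required).
#' @return a `linear_fit` (its `offset` element records `mu3`).
#' @export
fit_emergence_model <- function(summaries, mu3) {
  if (missing(mu3) || is.null(mu3) || is.na(mu3))
    stop("mu3 (cold-model intercept) is required", call. = FALSE)
  d <- summaries[!is.na(summaries$emergence), , drop = FALSE]
  if (nrow(d) < 3) stop("too few accessions with emergence", call. = FALSE)
  if (stats::sd(d$C) == 0)
    stop("zero variance in the cold gBLUP", call. = FALSE)
  fit <- ols_fit(d$emergence, cbind("(Intercept)" = 1, C = d$C),
                 offset = rep(mu3, nrow(d)))
  fit$offset <- mu3
  fit
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)` for `p` model terms beyond the
#' intercept.
#'
#' @param r2 coefficient of determination.
#' @param n number of observations.
#' @param p_terms number of non-intercept model terms.
#' @return adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(r2, n, p_terms) {
  if (n <= p_terms + 1) stop("n must exceed p_terms + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p_terms - 1)
}
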
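#' Stage-one binomial-logit model of per-seed germination
#'
#' Fits the 0/1 germination outcome against the nuisance design (batch,
#' multiplication year, and the conservation-by-temperature interaction
#' with its main effects, hierarchical coding) by iteratively reweighted
#' least squares via [stats::glm()]. Complete separation is detected and
#' raised as an error naming the offending term.
#'
#' @param data phenotype data frame with `germinated`, `batch`, `year`,
#'   `conservation_days`, `temperature`.
#' @param formula optional model formula overriding the default
#'   `germinated ~ batch + year + conservation * temperature`.
#' @return object of class `glm_fit`: the underlying `glm` object,
#'   coefficient table, deviance, convergence flag.
#' @export
fit_binomial_logit <- function(data, formula = NULL) {
  d <- data
  d$germinated <- as.integer(d$germinated)
  if (length(unique(d$germinated)) < 2L)
    stop("complete separation: outcome is constant", call. = FALSE)
  if (is.null(formula)) {
    d$batch <- factor(d$batch)
    d$year <- factor(d$year)
    d$temperature <- factor(d$temperature)
    d$conservation <- standardize(d$conservation_days)
    terms <- c(if (nlevels(d$batch) > 1) "batch",
               if (nlevels(d$year) > 1) "year",
               if (stats::sd(d$conservation) > 0) "conservation",
               if (nlevels(d$temperature) > 1) "temperature",
               if (stats::sd(d$conservation) > 0 &&
                     nlevels(d$temperature) > 1) "conservation:temperature")
    if (!length(terms)) terms <- "1"
    formula <- stats::as.formula(
      paste("germinated ~", paste(terms, collapse = " + ")))
  }
  fit <- suppressWarnings(stats::glm(formula, family = stats::binomial(),
                                     data = d))
  mu <- stats::fitted(fit)
  if (any(abs(stats::coef(fit)[!is.na(stats::coef(fit))]) > 15) &&
        (any(mu < 1e-8) || any(mu > 1 - 1e-8))) {
    cf <- stats::coef(fit)
    bad <- names(cf)[which.max(abs(cf))]
    stop("complete separation detected at term: ", bad, call. = FALSE)
  }
  co <- summary(fit)$coefficients
  structure(list(glm = fit,
                 coefficients = data.frame(term = rownames(co),
                                           estimate = co[, 1], se = co[, 2],
                                           z = co[, 3], p = co[, 4],
                                           stringsAsFactors = FALSE,
                                           row.names = NULL),
                 deviance = stats::deviance(fit),
                 converged = fit$converged),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit (binomial logit): deviance %.2f, %s\n", x$deviance,
              if (x$converged) "converged" else "NOT converged"))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Latent-scale residuals of the stage-one germination model
#'
#' The default is the working residual on the linear-predictor scale,
#' \eqn{(y - \hat\mu) / (\hat\mu(1-\hat\mu))}, the convention of
#' GRAMMAR-family two-stage analyses; deviance and Pearson residuals are
#' selectable. Fitted probabilities are clipped away from 0/1 at 1e-8
#' (clips are counted and logged).
#'
#' @param fit a `glm_fit`.
#' @param type `"working"` (default), `"deviance"` or `"pearson"`.
#' @return numeric vector of per-seed residuals, with attributes
#'   `"residual_type"` and `"clipped"` (count).
#' @export
latent_residuals <- function(fit, type = c("working", "deviance", "pearson")) {
  stopifnot(inherits(fit, "glm_fit"))
  type <- match.arg(type)
  g <- fit$glm
  mu <- stats::fitted(g)
  clipped <- sum(mu < 1e-8 | mu > 1 - 1e-8)
  if (clipped) message(clipped, " fitted probabilit(ies) clipped at 1e-8")
  mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
  y <- g$y
  r <- switch(type,
    working = (y - mu) / (mu * (1 - mu)),
    deviance = stats::residuals(g, type = "deviance"),
    pearson = (y - mu) / sqrt(mu * (1 - mu)))
  attr(r, "residual_type") <- type
  attr(r, "clipped") <- clipped
  r
}

#' Append latent-scale germination-rate residuals (GRA) to a phenotype table
#'
#' Runs the stage-one binomial model per species and stores its
#' latent-scale residuals in a `GRA` column, the response of the
#' stage-two gBLUP models.
#'
#' @param data phenotype data frame.
#' @param type residual type; see [latent_residuals()].
#' @return `data` with a `GRA` column; attribute `"glm_fits"` holds the
#'   per-species stage-one fits.
#' @export
add_latent_residuals <- function(data, type = "working") {
  data$GRA <- NA_real_
  fits <- list()
  for (sp in unique(data$species)) {
    i <- data$species == sp
    f <- fit_binomial_logit(data[i, , drop = FALSE])
    data$GRA[i] <- as.numeric(latent_residuals(f, type))
    fits[[sp]] <- f
  }
  attr(data, "glm_fits") <- fits
  attr(data, "residual_type") <- type
  data
}
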
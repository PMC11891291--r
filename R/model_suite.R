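#' Fit a gBLUP model from a phenotype data frame
#'
#' Builds the fixed-effect design (treatment contrasts; `batch` and `year`
#' as factors; `conservation_days` standardized), drops terms that are
#' constant within the supplied subset with a log message, and calls
#' [fit_emreml()]. Design bookkeeping (factor levels, term labels) is
#' attached so that [tukey_hsd()] and [wald_z_test()] can address terms.
#'
#' @param data phenotype data frame (one row per seed) with a `response`
#'   column and the design covariates.
#' @param response response column name (e.g. `"gt_hours"` or `"GRA"`).
#' @param terms character vector of term labels among `"temperature"`,
#'   `"type"`, `"batch"`, `"year"`, `"conservation"`, `"country"`,
#'   `"temperature:country"` (per-country warm-treatment slopes). The
#'   intercept is always present.
#' @param relationship a `relationship_set` or a relationship matrix with
#'   accession rownames.
#' @param ... passed to [fit_emreml()].
#' @return a `mixed_model_fit` with a `"design"` attribute.
#' @export
fit_gblup_model <- function(data, response, terms, relationship, ...) {
  G <- if (inherits(relationship, "relationship_set"))
    relationship$G else relationship
  if (is.null(rownames(G))) stop("G needs accession rownames", call. = FALSE)
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  if (!nrow(data)) stop("no usable observations", call. = FALSE)
  if (!all(data$accession %in% rownames(G)))
    stop("phenotyped accessions missing from G", call. = FALSE)

  d <- data
  d$batch <- factor(d$batch)
  d$year <- factor(d$year)
  if ("type" %in% names(d)) d$type <- factor(d$type)
  if ("country" %in% names(d)) d$country <- factor(d$country)
  d$temperature <- factor(d$temperature, levels = c("cold", "warm"))
  d$conservation <- standardize(d$conservation_days)
  d$warm <- as.numeric(d$temperature == "warm")

  keep <- character(0)
  for (tm in terms) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    vars[vars == "conservation"] <- "conservation"
    const <- vapply(vars, function(v) {
      col <- if (v == "temperature") d$temperature else d[[v]]
      length(unique(col)) < 2L
    }, logical(1))
    if (any(const)) {
      message("dropping term constant in subset: ", tm)
    } else keep <- c(keep, tm)
  }
  rhs <- if (length(keep)) {
    paste(vapply(keep, function(tm) {
      if (tm == "temperature:country") "warm:country" else tm
    }, character(1)), collapse = " + ")
  } else "1"
  fml <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(fml, d)

  fit <- fit_emreml(d[[response]], X, Z = d$accession, G, ...)
  attr(fit, "design") <- list(
    formula = fml, terms = keep,
    xlevels = lapply(Filter(is.factor, d[c("temperature", "type", "batch",
                                           "year", "country")]),
                     levels),
    response = response)
  fit
}

#' Fit the per-species model suites for a trait
#'
#' Suites follow the analysis plan: a pooled model over both temperatures
#' and types (`"1"` for germination time, `"3"` for the latent-scale
#' germination-rate residual GRA), per-type fits (`"1b"`/`"3b"`), per
#' type x temperature fits (`"1c"`/`"3c"`, four fits), and a per-country
#' temperature-slope model (`"3d"`). Germination-time fits use germinated
#' seeds only (the time is undefined, i.e. censored, otherwise); GRA fits
#' use every seed. GR temperature contrasts are reported from the `3c`
#' family even where results prose labels them `1c`; the runner logs this
#' reading once.
#'
#' @param data phenotype data frame; for GRA suites it must carry a `GRA`
#'   column (see [add_latent_residuals()]).
#' @param species species label to subset on (column `species`).
#' @param trait `"GT"` or `"GRA"`.
#' @param suite one of `"1"`, `"1b"`, `"1c"`, `"3"`, `"3b"`, `"3c"`, `"3d"`.
#' @param relationship a `relationship_set` or relationship matrix.
#' @param ... passed to [fit_gblup_model()].
#' @return named list of `mixed_model_fit` objects (1, 2 or 4 fits; empty
#'   subsets are skipped with a log entry).
#' @export
fit_model_suite <- function(data, species, trait = c("GT", "GRA"),
                            suite = c("1", "1b", "1c", "3", "3b", "3c", "3d"),
                            relationship, ...) {
  trait <- match.arg(trait)
  suite <- match.arg(suite)
  d <- data[data$species == species, , drop = FALSE]
  if (trait == "GT") {
    d <- d[d$germinated == 1L & !is.na(d$gt_hours), , drop = FALSE]
    response <- "gt_hours"
    base_terms <- c("temperature", "type", "batch", "year", "conservation")
  } else {
    if (!"GRA" %in% names(d))
      stop("GRA column missing: run add_latent_residuals() first",
           call. = FALSE)
    response <- "GRA"
    base_terms <- c("temperature", "type")
  }
  if (trait == "GRA" && suite %in% c("1", "1b", "1c"))
    message("germination-rate suites are fitted as the (3) family")

  subsets <- switch(suite,
    "1" = , "3" = list(all = rep(TRUE, nrow(d))),
    "1b" = , "3b" = {
      s <- lapply(unique(d$type), function(t) d$type == t)
      names(s) <- unique(d$type); s
    },
    "1c" = , "3c" = {
      cells <- expand.grid(type = unique(d$type),
                           temperature = unique(d$temperature),
                           stringsAsFactors = FALSE)
      s <- lapply(seq_len(nrow(cells)), function(i)
        d$type == cells$type[i] & d$temperature == cells$temperature[i])
      names(s) <- paste(cells$type, cells$temperature, sep = "_"); s
    },
    "3d" = list(all = rep(TRUE, nrow(d))))

  terms <- switch(suite,
    "1" = base_terms,
    "1b" = setdiff(base_terms, "type"),
    "1c" = setdiff(base_terms, c("type", "temperature")),
    "3" = base_terms,
    "3b" = setdiff(base_terms, "type"),
    "3c" = setdiff(base_terms, c("type", "temperature")),
    "3d" = c("temperature:country", "type"))

  fits <- list()
  for (nm in names(subsets)) {
    di <- d[subsets[[nm]], , drop = FALSE]
    if (!nrow(di)) {
      message("empty subset skipped: ", nm)
      next
    }
    fits[[nm]] <- fit_gblup_model(di, response, terms, relationship, ...)
  }
  fits
}
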
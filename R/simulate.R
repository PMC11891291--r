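#' Configuration for the synthetic germination cohort
#'
#' Bundles every parameter of the generator: the Balding-Nichols genotype
#' model (K ancestral populations diverged by Fst, Dirichlet admixture),
#' the polygenic model for germination time (GT, hours) and the
#' latent-liability model for the 0/1 germination outcome (GR), the design
#' covariates (temperature treatment, accession type, batch, multiplication
#' year, conservation days), the cross-temperature genetic correlation, the
#' latitude effect on heat tolerance, and the field-emergence linkage.
#'
#' @param n_accessions number of accessions (>= 2).
#' @param n_snps number of SNPs (>= 1).
#' @param k_pops number of ancestral populations (>= 1).
#' @param fst divergence parameter in (0, 1).
#' @param admixture_concentration Dirichlet concentration; small values give
#'   near-discrete population membership.
#' @param seeds_per_cell seeds phenotyped per accession x temperature cell.
#' @param temperatures named numeric of length 2, `c(cold = , warm = )` in
#'   degrees C; the labels become the treatment factor levels.
#' @param fixed_effects named list of fixed-effect sizes; see
#'   [default_fixed_effects()] for names, units and defaults.
#' @param sigma2_g,sigma2_e additive and residual variance of GT (hours^2).
#' @param gr_sigma2_g additive variance on the GR liability scale (the
#'   logistic residual has variance pi^2/3, so 1.4 gives liability
#'   heritability of about 0.3).
#' @param ge_correlation cross-temperature genetic correlation rho in
#'   [-1, 1] (applies to both GT and GR genetic values).
#' @param latitude_slope effect of standardized latitude on the warm-minus-
#'   cold genetic value (heat tolerance), in trait units per latitude SD.
#' @param latitude_range sampling-site latitude range (degrees N).
#' @param censor_hours right-censoring threshold for GT (default 168 h).
#' @param gt_distribution `"gaussian"` (truncated below at 0.5 h) or
#'   `"lognormal"` for the germination-time residual scale.
#' @param n_batches number of experimental batches.
#' @param emergence_alpha,emergence_gamma,emergence_sd intercept, slope on
#'   the cold GR genetic value, and noise SD of the logit emergence rate.
#' @param rng_seed integer seed; identical configs reproduce identical
#'   cohorts byte for byte.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_accessions = 100,
                              n_snps = 1000,
                              k_pops = 3,
                              fst = 0.15,
                              admixture_concentration = 0.3,
                              seeds_per_cell = 50,
                              temperatures = c(cold = 20, warm = 35),
                              fixed_effects = default_fixed_effects(),
                              sigma2_g = 180,
                              sigma2_e = 640,
                              gr_sigma2_g = 1.4,
                              ge_correlation = 0.9,
                              latitude_slope = -0.01,
                              latitude_range = c(35, 50),
                              censor_hours = 168,
                              gt_distribution = c("gaussian", "lognormal"),
                              n_batches = 8,
                              emergence_alpha = 1.5,
                              emergence_gamma = 0.8,
                              emergence_sd = 0.3,
                              rng_seed = 1L) {
  gt_distribution <- match.arg(gt_distribution)
  if (k_pops < 1) stop("k_pops must be >= 1", call. = FALSE)
  if (!(fst > 0 && fst < 1)) stop("fst must lie in (0, 1)", call. = FALSE)
  if (abs(ge_correlation) > 1)
    stop("ge_correlation must lie in [-1, 1]", call. = FALSE)
  if (sigma2_g < 0 || sigma2_e < 0 || gr_sigma2_g < 0)
    stop("variance components must be non-negative", call. = FALSE)
  if (length(temperatures) != 2 || temperatures[1] == temperatures[2])
    stop("temperatures must be two distinct values", call. = FALSE)
  if (is.null(names(temperatures))) names(temperatures) <- c("cold", "warm")
  fe <- default_fixed_effects()
  fe[names(fixed_effects)] <- fixed_effects
  structure(list(
    n_accessions = as.integer(n_accessions), n_snps = as.integer(n_snps),
    k_pops = as.integer(k_pops), fst = fst,
    admixture_concentration = admixture_concentration,
    seeds_per_cell = as.integer(seeds_per_cell),
    temperatures = temperatures, fixed_effects = fe,
    sigma2_g = sigma2_g, sigma2_e = sigma2_e, gr_sigma2_g = gr_sigma2_g,
    ge_correlation = ge_correlation, latitude_slope = latitude_slope,
    latitude_range = latitude_range, censor_hours = censor_hours,
    gt_distribution = gt_distribution, n_batches = as.integer(n_batches),
    emergence_alpha = emergence_alpha, emergence_gamma = emergence_gamma,
    emergence_sd = emergence_sd, rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' Default fixed-effect sizes for the synthetic cohort
#'
#' GT effects are in hours (intercept near the landrace cold-condition mean,
#' warm-treatment contrast, wild-type penalty, batch SD, multiplication-year
#' contrast, conservation slope per day of storage); GR effects are on the
#' logit liability scale, including the conservation x temperature
#' interaction of the stage-one model.
#'
#' @return named list of effect sizes.
#' @export
default_fixed_effects <- function() {
  list(gt_intercept = 60, gt_temperature = -16, gt_type_wild = 26,
       gt_batch_sd = 3, gt_year = 2, gt_conservation = 0.01,
       gr_intercept = 2.5, gr_temperature = 0.8, gr_type_wild = -2,
       gr_batch_sd = 0.3, gr_year = -0.3, gr_conservation = -0.002,
       gr_conservation_warm = -0.001)
}

#' Construct a genotype matrix object
#'
#' @param dosage accessions x SNPs integer matrix of allele dosages
#'   (0/1/2); rownames are accession ids.
#' @param map data.frame with columns `chrom`, `pos`, `ref`, `alt` (one row
#'   per SNP).
#' @param populations optional integer vector of primary-population labels.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, map, populations = NULL) {
  stopifnot(is.matrix(dosage), nrow(map) == ncol(dosage))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("acc%03d", seq_len(nrow(dosage)))
  structure(list(dosage = dosage, map = map, populations = populations,
                 accessions = rownames(dosage)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d SNPs on %d scaffold(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate structured diploid genotypes (Balding-Nichols model)
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); each of the K
#' populations draws its frequency from Beta(p(1-F)/F, (1-p)(1-F)/F); each
#' accession mixes population frequencies with Dirichlet admixture weights
#' rotated so the largest weight falls on a round-robin primary population
#' (balanced, labelled clusters); dosages are Binomial(2, freq).
#' Monomorphic columns are re-drawn.
#'
#' @param cfg a [simulation_config()].
#' @return a [genotype_matrix()] with `populations` set to the primary
#'   population of each accession.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_snps < 1 || cfg$n_accessions < 2)
    stop("need n_snps >= 1 and n_accessions >= 2", call. = FALSE)
  set.seed(cfg$rng_seed)
  n <- cfg$n_accessions; m <- cfg$n_snps; K <- cfg$k_pops; F <- cfg$fst

  primary <- ((seq_len(n) - 1L) %% K) + 1L
  W <- do.call(rbind, lapply(seq_len(n), function(i) {
    w <- rdirichlet1(rep(cfg$admixture_concentration, K))
    idx <- order(w, decreasing = TRUE)
    out <- numeric(K)
    slots <- c(primary[i], setdiff(seq_len(K), primary[i]))
    out[slots] <- w[idx]
    out
  }))

  draw_cols <- function(mm) {
    p_anc <- stats::runif(mm, 0.05, 0.95)
    shape <- (1 - F) / F
    P <- matrix(stats::rbeta(mm * K, rep(p_anc, K) * shape,
                             rep(1 - p_anc, K) * shape), mm, K)
    fr <- W %*% t(P)                       # n x mm accession frequencies
    matrix(stats::rbinom(n * mm, 2L, pmin(pmax(as.vector(fr), 0), 1)), n, mm)
  }
  X <- draw_cols(m)
  for (round in 1:100) {
    mono <- which(apply(X, 2, function(v) length(unique(v)) == 1L))
    if (!length(mono)) break
    X[, mono] <- draw_cols(length(mono))
  }
  chroms <- sprintf("A%02d", ((seq_len(m) - 1L) %/% ceiling(m / 10)) + 1L)
  pos <- unlist(lapply(split(seq_len(m), chroms), function(ix)
    cumsum(sample(20:200, length(ix), replace = TRUE))), use.names = FALSE)
  map <- data.frame(chrom = sort(chroms), pos = pos,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  rownames(X) <- sprintf("acc%03d", seq_len(n))
  genotype_matrix(X, map, populations = primary)
}

#' Simulate phenotypes, latitude and emergence for a genotyped panel
#'
#' Cold-temperature genetic values are N(0, sigma2_g * G); warm values are
#' `rho * a_C + sqrt(1 - rho^2) * a_perp + latitude_slope * z(latitude)`,
#' so heat tolerance (warm minus cold) carries the latitude effect. Per-seed
#' germination time adds the design fixed effects and a residual, censored
#' at `censor_hours`; the binary germination outcome follows an independent
#' logistic liability with its own genetic values; the per-accession
#' emergence rate is a logistic function of the cold GR genetic value.
#'
#' @param cfg a [simulation_config()].
#' @param genotypes a [genotype_matrix()], typically from
#'   [simulate_genotypes()].
#' @return object of class `sim_cohort`: `genotypes`, `phenotypes` (one row
#'   per seed), `emergence`, `latitudes`, and a `truth` record of every
#'   drawn quantity (genetic values at both temperatures for GT and GR,
#'   batch/year effects, the per-degree latitude slope).
#' @export
simulate_phenotypes <- function(cfg, genotypes) {
  stopifnot(inherits(cfg, "sim_config"), inherits(genotypes, "genotype_matrix"))
  set.seed(cfg$rng_seed + 1L)
  acc <- genotypes$accessions
  q <- length(acc)
  G <- compute_grm(genotypes)$G
  fe <- cfg$fixed_effects
  rho <- cfg$ge_correlation

  lat <- stats::runif(q, cfg$latitude_range[1], cfg$latitude_range[2])
  zlat <- standardize(lat)

  draw_pair <- function(s2) {
    a_c <- drop(draw_mvn_grm(1, G, s2))
    a_p <- drop(draw_mvn_grm(1, G, s2))
    a_w <- rho * a_c + sqrt(max(0, 1 - rho^2)) * a_p
    list(cold = a_c, warm = a_w)
  }
  a_gt <- draw_pair(cfg$sigma2_g)
  a_gr <- draw_pair(cfg$gr_sigma2_g)
  a_gt$warm <- a_gt$warm + cfg$latitude_slope * zlat

  type <- ifelse(genotypes$populations %||% rep(1L, q) == 1L,
                 "landrace", "wild")
  countries <- c("France", "Algeria", "Italy", "Spain", "Slovenia", "Tunisia")
  country <- countries[((genotypes$populations %||% rep(1L, q)) - 1L) %%
                         length(countries) + 1L]
  year <- sample(c(2021L, 2022L), q, replace = TRUE)
  conservation <- round(stats::runif(q, 100, 600))
  batch_eff_gt <- stats::rnorm(cfg$n_batches, 0, fe$gt_batch_sd)
  batch_eff_gr <- stats::rnorm(cfg$n_batches, 0, fe$gr_batch_sd)

  temps <- names(cfg$temperatures)
  n_seed <- cfg$seeds_per_cell
  rows <- expand.grid(seed = seq_len(n_seed), temperature = temps,
                      accession = acc, stringsAsFactors = FALSE)
  i <- match(rows$accession, acc)
  warm <- rows$temperature == "warm"
  batch <- sample.int(cfg$n_batches, nrow(rows), replace = TRUE)

  mu_gt <- fe$gt_intercept + fe$gt_temperature * warm +
    fe$gt_type_wild * (type[i] == "wild") + batch_eff_gt[batch] +
    fe$gt_year * (year[i] == 2022L) + fe$gt_conservation * conservation[i] +
    ifelse(warm, a_gt$warm[i], a_gt$cold[i])
  e_gt <- stats::rnorm(nrow(rows), 0, sqrt(cfg$sigma2_e))
  gt <- if (cfg$gt_distribution == "lognormal") {
    exp(log(pmax(mu_gt, 1)) + e_gt / pmax(mu_gt, 1)) # residual scaled to hours
  } else pmax(mu_gt + e_gt, 0.5)

  eta <- fe$gr_intercept + fe$gr_temperature * warm +
    fe$gr_type_wild * (type[i] == "wild") + batch_eff_gr[batch] +
    fe$gr_year * (year[i] == 2022L) +
    (fe$gr_conservation + fe$gr_conservation_warm * warm) * conservation[i] +
    ifelse(warm, a_gr$warm[i], a_gr$cold[i])
  germ_latent <- stats::rbinom(nrow(rows), 1L, stats::plogis(eta))
  germinated <- germ_latent == 1L & gt < cfg$censor_hours

  phen <- data.frame(
    accession = rows$accession, species = "synthetica",
    type = type[i], country = country[i], latitude = lat[i],
    temperature = rows$temperature, batch = batch, year = year[i],
    conservation_days = conservation[i],
    germinated = as.integer(germinated),
    gt_hours = ifelse(germinated, round(gt, 2), NA_real_),
    stringsAsFactors = FALSE)

  emerg_noise <- stats::rnorm(q, 0, cfg$emergence_sd)
  emergence <- stats::plogis(cfg$emergence_alpha +
                               cfg$emergence_gamma * a_gr$cold + emerg_noise)

  structure(list(
    genotypes = genotypes, phenotypes = phen,
    emergence = data.frame(accession = acc, emergence = emergence,
                           stringsAsFactors = FALSE),
    latitudes = data.frame(accession = acc, latitude = lat,
                           latitude_std = zlat, type = type,
                           country = country, stringsAsFactors = FALSE),
    truth = list(
      config = cfg, grm = G,
      gblup_gt_cold = stats::setNames(a_gt$cold, acc),
      gblup_gt_warm = stats::setNames(a_gt$warm, acc),
      gblup_gr_cold = stats::setNames(a_gr$cold, acc),
      gblup_gr_warm = stats::setNames(a_gr$warm, acc),
      batch_eff_gt = batch_eff_gt, batch_eff_gr = batch_eff_gr,
      latitude_slope_std = cfg$latitude_slope,
      latitude_slope_per_degree =
        if (stats::sd(lat) > 0) cfg$latitude_slope / stats::sd(lat) else 0)
  ), class = "sim_cohort")
}

#' Simulate a complete cohort (genotypes + phenotypes)
#'
#' @param cfg a [simulation_config()].
#' @return a `sim_cohort`; see [simulate_phenotypes()].
#' @export
simulate_cohort <- function(cfg) {
  simulate_phenotypes(cfg, simulate_genotypes(cfg))
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d accessions, %d seeds (%.1f%% germinated)\n",
              nrow(x$latitudes), nrow(x$phenotypes),
              100 * mean(x$phenotypes$germinated)))
  invisible(x)
}
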
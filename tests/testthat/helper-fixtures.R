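# shared fixture builders; everything is generated in code at test time

small_config <- function(seed = 1L, n_accessions = 24, n_snps = 200,
                         seeds_per_cell = 10, ...) {
  simulation_config(n_accessions = n_accessions, n_snps = n_snps,
                    seeds_per_cell = seeds_per_cell, rng_seed = seed, ...)
}

# a variant_table built directly from components (bypassing VCF I/O)
make_tab <- function(chrom, pos, ref = "A", alt = "G", mq = 60,
                     dp, ad_ref = NULL, ad_alt = NULL, gt = NULL) {
  n_sites <- length(pos)
  if (is.null(dim(dp))) dp <- matrix(dp, n_sites, length(dp) / n_sites)
  n_acc <- ncol(dp)
  if (is.null(ad_ref)) ad_ref <- dp
  if (is.null(ad_alt)) ad_alt <- matrix(0, n_sites, n_acc)
  if (is.null(gt)) gt <- matrix(0, n_sites, n_acc)
  variant_table(
    data.frame(chrom = rep_len(chrom, n_sites), pos = pos,
               ref = rep_len(ref, n_sites), alt = rep_len(alt, n_sites),
               mq = rep_len(mq, n_sites), stringsAsFactors = FALSE),
    dp, ad_ref, ad_alt, gt, sprintf("s%02d", seq_len(n_acc)))
}

# mean silhouette of 1-d coordinates against two cluster labels
silhouette_1d <- function(x, labels) {
  d <- abs(outer(x, x, "-"))
  s <- vapply(seq_along(x), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(x) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# independent dense-matrix REML log-likelihood (oracle for the MME engine)
dense_reml_ll <- function(s2g, s2e, y, X, Zmat, G) {
  n <- length(y)
  V <- s2e * diag(n) + s2g * Zmat %*% G %*% t(Zmat)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
            t(r) %*% Vi %*% r + (n - ncol(X)) * log(2 * pi))[1]
}

incidence <- function(acc, ids) {
  Z <- matrix(0, length(acc), length(ids))
  Z[cbind(seq_along(acc), match(acc, ids))] <- 1
  Z
}

pool_typewise_gblups <- function(fits, acc_type, temp) {
  out <- numeric(0)
  for (ty in unique(acc_type)) {
    f <- fits[[paste(ty, temp, sep = "_")]]
    if (is.null(f)) next
    ids <- intersect(names(acc_type)[acc_type == ty], names(f$gblups))
    out <- c(out, f$gblups[ids])
  }
  out
}

# fitted heat-tolerance summaries for one simulated cohort
cohort_summaries <- function(cfg, trait = "GT") {
  co <- simulate_cohort(cfg)
  rel <- compute_grm(co$genotypes)
  suite <- if (trait == "GT") "1c" else "3c"
  phen <- co$phenotypes
  if (trait == "GRA") phen <- add_latent_residuals(phen)
  fits <- fit_model_suite(phen, "synthetica", trait, suite, rel)
  ty <- stats::setNames(co$latitudes$type, co$latitudes$accession)
  sm <- build_accession_summary(pool_typewise_gblups(fits, ty, "cold"),
                                pool_typewise_gblups(fits, ty, "warm"),
                                co$latitudes, co$emergence)
  list(cohort = co, rel = rel, fits = fits, summaries = heat_tolerance(sm))
}
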
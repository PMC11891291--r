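#' Summarise germination phenotypes by species, type and temperature
#'
#' Per cell: number of seeds, mean and sample SD of the 0/1 germination
#' indicator, and mean and sample SD of germination time over germinated
#' seeds only (the time is undefined for non-germinated seeds).
#'
#' @param phenotypes phenotype data frame.
#' @return data.frame with one row per species x type x temperature.
#' @export
summarize_phenotypes <- function(phenotypes) {
  req <- c("species", "type", "temperature", "germinated", "gt_hours")
  miss <- setdiff(req, names(phenotypes))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_type <- setdiff(unique(phenotypes$type), c("wild", "landrace"))
  if (length(bad_type))
    stop("unknown type level(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  cells <- split(phenotypes,
                 list(phenotypes$species, phenotypes$type,
                      phenotypes$temperature), drop = TRUE)
  out <- lapply(cells, function(d) {
    g <- d$gt_hours[d$germinated == 1L]
    data.frame(species = d$species[1], type = d$type[1],
               temperature = d$temperature[1], n_seeds = nrow(d),
               gr_mean = mean(d$germinated), gr_sd = stats::sd(d$germinated),
               n_germinated = sum(d$germinated),
               gt_mean = if (length(g)) mean(g) else NA_real_,
               gt_sd = if (length(g) > 1) stats::sd(g) else
                 if (length(g) == 1) 0 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$species, out$type, out$temperature), , drop = FALSE]
}

#' Pipeline configuration
#'
#' @param sim a [simulation_config()] describing the synthetic cohort (the
#'   offline input source).
#' @param plant_spec planted-violation counts for the contaminated VCF
#'   fixture; see [write_contaminated_vcf()].
#' @param filter a [filter_config()].
#' @param residual_type latent residual type for the stage-one GLM.
#' @param n_mds_axes MDS axes to report.
#' @param include_emergence fit the emergence model (default TRUE); when
#'   FALSE that stage is skipped and the rest of the report is unchanged.
#' @param out_dir output directory (tables written there when not NULL).
#' @return named list (class `pipeline_config`).
#' @export
pipeline_config <- function(sim = simulation_config(),
                            plant_spec = list(multiallelic = 7,
                                              near_indel = 5, low_mq = 6,
                                              depth_outlier = 6,
                                              low_allele_depth = 6,
                                              non_chromosome_scaffold = 4,
                                              low_depth_accession = 1),
                            filter = filter_config(),
                            residual_type = "working",
                            n_mds_axes = 2,
                            include_emergence = TRUE,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: simulate genotypes and phenotypes; write a contaminated VCF and
#' recover the panel through the variant-filter chain; genomic relationship
#' matrix and MDS; stage-one GLM and latent residuals; germination-time and
#' germination-rate model suites (pooled and per type x temperature);
#' cross-temperature, latitude and emergence regressions. Re-running with
#' an identical config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return object of class `report_bundle`: phenotype summary table,
#'   heritability table, fixed-effect table, downstream coefficient table,
#'   filter report, MDS result, and the underlying fits.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- simulate_cohort(config$sim)

  vcf_path <- tempfile(fileext = ".vcf")
  on.exit(unlink(vcf_path), add = TRUE)
  manifest <- write_contaminated_vcf(cohort$genotypes, config$plant_spec,
                                     vcf_path,
                                     rng_seed = config$sim$rng_seed + 7L)
  chain <- run_filter_chain(vcf_path, config$filter)

  rel <- compute_grm(chain$genotypes)
  mds <- classical_mds(rel$D, n_axes = config$n_mds_axes)

  phen <- cohort$phenotypes
  phen <- phen[phen$accession %in% rel$accessions, , drop = FALSE]
  phen <- add_latent_residuals(phen, type = config$residual_type)

  sp <- unique(phen$species)[1]
  fits_gt_1 <- fit_model_suite(phen, sp, "GT", "1", rel)
  fits_gt_1c <- fit_model_suite(phen, sp, "GT", "1c", rel)
  fits_gr_3 <- fit_model_suite(phen, sp, "GRA", "3", rel)
  fits_gr_3c <- fit_model_suite(phen, sp, "GRA", "3c", rel)

  h2_rows <- function(fits, trait) do.call(rbind, lapply(names(fits),
    function(nm) data.frame(trait = trait, subset = nm,
                            h2 = heritability(fits[[nm]]),
                            sigma2_g = fits[[nm]]$sigma2_g,
                            sigma2_e = fits[[nm]]$sigma2_e,
                            converged = fits[[nm]]$converged,
                            stringsAsFactors = FALSE)))
  h2_table <- rbind(h2_rows(fits_gt_1c, "GT"), h2_rows(fits_gr_3c, "GRA"))

  fe_rows <- function(fit, trait, model) {
    b <- fit$beta
    data.frame(trait = trait, model = model, term = b$term,
               estimate = b$estimate, se = b$se, z = b$estimate / b$se,
               p = 2 * stats::pnorm(-abs(b$estimate / b$se)),
               stringsAsFactors = FALSE)
  }
  fixed_table <- rbind(fe_rows(fits_gt_1$all, "GT", "1"),
                       fe_rows(fits_gr_3$all, "GRA", "3"))

  ## per-accession summaries from pooled per-temperature gBLUPs (average
  ## over the wild/landrace fits in which the accession was phenotyped)
  acc_type <- stats::setNames(cohort$latitudes$type,
                              cohort$latitudes$accession)
  pool_gblups <- function(fits, temp) {
    out <- numeric(0)
    for (ty in unique(acc_type)) {
      f <- fits[[paste(ty, temp, sep = "_")]]
      if (is.null(f)) next
      ids <- intersect(names(acc_type)[acc_type == ty], names(f$gblups))
      out <- c(out, f$gblups[ids])
    }
    out
  }
  summaries <- list()
  downstream_rows <- list()
  for (trait in c("GT", "GRA")) {
    fits <- if (trait == "GT") fits_gt_1c else fits_gr_3c
    cold <- pool_gblups(fits, "cold")
    warm <- pool_gblups(fits, "warm")
    sm <- build_accession_summary(cold, warm, cohort$latitudes,
                                  cohort$emergence)
    sm <- heat_tolerance(sm)
    summaries[[trait]] <- sm
    cross <- fit_cross_temperature(sm)
    lat <- fit_latitude_model(sm)
    downstream_rows[[trait]] <- rbind(
      data.frame(trait = trait, model = "cross_temperature",
                 subset = "all", term = cross$coefficients$term,
                 estimate = cross$coefficients$estimate,
                 se = cross$coefficients$se, p = cross$coefficients$p,
                 adj_r2 = cross$adj_r2, stringsAsFactors = FALSE),
      do.call(rbind, lapply(names(lat), function(nm) {
        f <- lat[[nm]]
        if (is.null(f)) return(NULL)
        data.frame(trait = trait, model = "latitude", subset = nm,
                   term = f$coefficients$term,
                   estimate = f$coefficients$estimate,
                   se = f$coefficients$se, p = f$coefficients$p,
                   adj_r2 = f$adj_r2, stringsAsFactors = FALSE)
      })))
  }
  emergence_fit <- NULL
  if (isTRUE(config$include_emergence) && !is.null(cohort$emergence)) {
    cold_fits <- fits_gr_3c[grepl("_cold$", names(fits_gr_3c))]
    mu3 <- mean(vapply(cold_fits, function(f)
      f$beta$estimate[f$beta$term == "(Intercept)"], numeric(1)))
    emergence_fit <- fit_emergence_model(summaries$GRA, mu3)
    downstream_rows$emergence <- data.frame(
      trait = "GRA", model = "emergence", subset = "all",
      term = emergence_fit$coefficients$term,
      estimate = emergence_fit$coefficients$estimate,
      se = emergence_fit$coefficients$se, p = emergence_fit$coefficients$p,
      adj_r2 = emergence_fit$adj_r2, stringsAsFactors = FALSE)
  } else message("no emergence data: emergence model skipped")

  bundle <- structure(list(
    summary_table = summarize_phenotypes(phen),
    h2_table = h2_table,
    fixed_table = fixed_table,
    downstream_table = do.call(rbind, downstream_rows),
    filter_report = chain$report,
    manifest = manifest,
    mds = mds,
    summaries = summaries,
    fits = list(gt_1 = fits_gt_1, gt_1c = fits_gt_1c,
                gr_3 = fits_gr_3, gr_3c = fits_gr_3c,
                emergence = emergence_fit),
    cohort = cohort,
    config = config
  ), class = "report_bundle")
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle's tables to a directory
#'
#' @param bundle a `report_bundle`.
#' @param out_dir directory (created if absent).
#' @return invisibly, the file paths written.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(
    wt(bundle$summary_table, "phenotype_summary.tsv"),
    wt(bundle$h2_table, "heritability.tsv"),
    wt(bundle$fixed_table, "fixed_effects.tsv"),
    wt(bundle$downstream_table, "downstream.tsv"),
    wt(bundle$filter_report$steps, "filter_report.tsv"),
    wt(data.frame(accession = rownames(bundle$mds$coordinates),
                  bundle$mds$coordinates), "mds_coordinates.tsv"))
  invisible(paths)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n== phenotype summary ==\n")
  print(x$summary_table, row.names = FALSE)
  cat("== heritability ==\n")
  print(x$h2_table, row.names = FALSE)
  cat(sprintf("MDS axis 1: %.2f%% of variance\n", x$mds$pct_variance[1]))
  invisible(x)
}

#' Write a relationship matrix in GCTA-style text format
#'
#' Lower-triangle `id1 id2 n_snps value` rows, plus a companion `.id` file.
#'
#' @param rel a `relationship_set`.
#' @param prefix output path prefix (writes `<prefix>.grm.txt` and
#'   `<prefix>.grm.id`).
#' @return invisibly, the paths written.
#' @export
write_grm_text <- function(rel, prefix) {
  stopifnot(inherits(rel, "relationship_set"))
  n <- length(rel$accessions)
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(i = i, j = seq_len(i), n_snps = rel$n_snps,
               value = rel$G[i, seq_len(i)])))
  grm_path <- paste0(prefix, ".grm.txt")
  id_path <- paste0(prefix, ".grm.id")
  utils::write.table(rows, grm_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(fid = rel$accessions, iid = rel$accessions),
                     id_path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(grm_path, id_path))
}
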
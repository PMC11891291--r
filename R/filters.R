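#' Drop accessions with low mean sequencing depth
#'
#' Retains accessions whose mean per-site total depth is strictly above the
#' threshold (depth "higher than" the cutoff, so a mean exactly at the
#' threshold is dropped).
#'
#' @param records a [variant_table()].
#' @param min_mean_depth depth threshold (default 20).
#' @return list with `records` (accessions dropped from every site) and
#'   `removed` (character vector of dropped accession ids).
#' @export
filter_accessions_by_depth <- function(records, min_mean_depth = 20) {
  stopifnot(inherits(records, "variant_table"))
  if (n_sites(records) == 0L)
    return(list(records = records, removed = character(0)))
  mean_depth <- colMeans(records$dp)
  keep <- mean_depth > min_mean_depth
  if (!any(keep)) stop("no accession passes the depth filter", call. = FALSE)
  list(records = subset_accessions(records, keep),
       removed = records$accessions[!keep])
}

#' Retain only biallelic SNPs
#'
#' Removes indel records (either allele longer than 1 bp) and sites with
#' more than one alternate allele.
#'
#' @param records a [variant_table()].
#' @return list with `records`, `removed_indel` and `removed_multiallelic`
#'   counts.
#' @export
filter_biallelic_snps <- function(records) {
  stopifnot(inherits(records, "variant_table"))
  indel <- records$sites$is_indel
  multi <- !indel & records$sites$n_alt != 1L
  list(records = subset_sites(records, !indel & !multi),
       removed_indel = sum(indel), removed_multiallelic = sum(multi))
}

#' Remove SNPs close to indels
#'
#' A SNP is removed iff an indel exists on the same scaffold strictly
#' closer than `min_distance_bp` (distance measured to the indel's anchor
#' position; a SNP exactly `min_distance_bp` away is retained).
#'
#' @param records a [variant_table()] (SNPs; any indel rows still present
#'   are used as indel positions but not themselves removed here).
#' @param min_distance_bp exclusion radius (default 5).
#' @param indel_positions optional data.frame (`chrom`, `pos`) of indel
#'   anchors recorded before indel records were dropped; defaults to the
#'   indels present in `records`.
#' @return list with `records` and `removed` count.
#' @export
filter_near_indel <- function(records, min_distance_bp = 5,
                              indel_positions = NULL) {
  stopifnot(inherits(records, "variant_table"))
  if (is.null(indel_positions)) {
    idx <- records$sites$is_indel
    indel_positions <- records$sites[idx, c("chrom", "pos")]
  }
  near <- rep(FALSE, n_sites(records))
  if (nrow(indel_positions)) {
    by_chrom <- split(indel_positions$pos, indel_positions$chrom)
    for (ch in names(by_chrom)) {
      on_ch <- which(records$sites$chrom == ch & !records$sites$is_indel)
      if (!length(on_ch)) next
      ip <- sort(by_chrom[[ch]])
      nearest <- findInterval(records$sites$pos[on_ch], ip)
      d_lo <- ifelse(nearest >= 1, records$sites$pos[on_ch] - ip[pmax(nearest, 1)], Inf)
      d_hi <- ifelse(nearest < length(ip), ip[pmin(nearest + 1, length(ip))] -
                       records$sites$pos[on_ch], Inf)
      near[on_ch] <- pmin(d_lo, d_hi) < min_distance_bp
    }
  }
  list(records = subset_sites(records, !near), removed = sum(near))
}

#' Retain sites with mean depth inside central percentiles
#'
#' Computes the per-site mean total depth over the current accessions, then
#' keeps sites whose mean lies in the closed interval between the `lo_pct`
#' and `hi_pct` percentiles of that distribution (linear interpolation
#' between order statistics, `stats::quantile` type 7 by default).
#'
#' @param records a [variant_table()].
#' @param lo_pct,hi_pct percentile bounds (default 5 and 95).
#' @param quantile_type passed to [stats::quantile()] (default 7).
#' @return list with `records` and `removed` count.
#' @export
filter_site_depth_percentiles <- function(records, lo_pct = 5, hi_pct = 95,
                                          quantile_type = 7) {
  stopifnot(inherits(records, "variant_table"))
  if (n_sites(records) < 20L) {
    warning("fewer than 20 sites: percentile depth filter skipped")
    return(list(records = records, removed = 0L))
  }
  md <- rowMeans(records$dp)
  qs <- stats::quantile(md, c(lo_pct, hi_pct) / 100, type = quantile_type,
                        names = FALSE)
  keep <- md >= qs[1] & md <= qs[2]
  list(records = subset_sites(records, keep), removed = sum(!keep))
}

#' Retain sites with mapping quality exceeding a threshold
#'
#' Strict inequality: a site at exactly `min_mq` is removed. Sites with a
#' missing MQ are treated as failing and counted separately.
#'
#' @param records a [variant_table()].
#' @param min_mq threshold (default 40).
#' @return list with `records`, `removed` count and `missing_mq` count.
#' @export
filter_mq <- function(records, min_mq = 40) {
  stopifnot(inherits(records, "variant_table"))
  mq <- records$sites$mq
  missing <- is.na(mq)
  if (any(missing))
    message(sum(missing), " site(s) with missing MQ treated as failing")
  keep <- !missing & mq > min_mq
  list(records = subset_sites(records, keep), removed = sum(!keep),
       missing_mq = sum(missing))
}

#' Remove sites where any accession has both allele depths below a cutoff
#'
#' A site is removed iff, in any retained accession, the reference depth
#' and the alternate depth are both strictly below `min_depth`. Missing
#' calls carry AD = (0, 0) and therefore also remove the site.
#'
#' @param records a [variant_table()].
#' @param min_depth per-allele depth cutoff (default 10).
#' @return list with `records` and `removed` count.
#' @export
filter_allele_depth <- function(records, min_depth = 10) {
  stopifnot(inherits(records, "variant_table"))
  bad <- (records$ad_ref < min_depth) & (records$ad_alt < min_depth)
  fail <- rowSums(bad) > 0
  list(records = subset_sites(records, !fail), removed = sum(fail))
}

#' Retain sites mapped on chromosome scaffolds
#'
#' @param records a [variant_table()].
#' @param chromosome_names non-empty character vector of chromosome
#'   scaffold names.
#' @return list with `records` and `removed` count.
#' @export
filter_chromosome_scaffolds <- function(records, chromosome_names) {
  stopifnot(inherits(records, "variant_table"))
  if (!length(chromosome_names))
    stop("chromosome name list is empty", call. = FALSE)
  keep <- records$sites$chrom %in% chromosome_names
  list(records = subset_sites(records, keep), removed = sum(!keep))
}

#' Greedy windowed LD pruning of a dosage matrix
#'
#' Scans each scaffold left to right, keeping a site unless its squared
#' Pearson correlation of dosages with any previously kept site within the
#' trailing window exceeds `r2_max`. Correlation against a monomorphic site
#' is defined as 0. Output order is preserved.
#'
#' @param genotypes a [genotype_matrix()].
#' @param r2_max squared-correlation threshold (default 0.2).
#' @param window trailing window size (default 1000).
#' @param window_units `"sites"` (the literal reading of a prune window of
#'   1000) or `"bp"`.
#' @return a pruned [genotype_matrix()].
#' @export
ld_prune <- function(genotypes, r2_max = 0.2, window = 1000,
                     window_units = c("sites", "bp")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  window_units <- match.arg(window_units)
  X <- genotypes$dosage
  map <- genotypes$map
  keep_all <- logical(ncol(X))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    kept <- integer(0)       # column indices kept so far on this scaffold
    kept_rank <- integer(0)  # their rank along the scaffold
    for (r in seq_along(idx)) {
      j <- idx[r]
      in_win <- if (window_units == "sites") {
        kept[r - kept_rank <= window]
      } else {
        kept[map$pos[j] - map$pos[kept] <= window]
      }
      ok <- TRUE
      xj <- X[, j]
      if (stats::sd(xj) > 0) {
        for (k in rev(in_win)) {
          xk <- X[, k]
          if (stats::sd(xk) == 0) next
          if (stats::cor(xj, xk)^2 > r2_max) { ok <- FALSE; break }
        }
      }
      if (ok) { kept <- c(kept, j); kept_rank <- c(kept_rank, r) }
    }
    keep_all[kept] <- TRUE
  }
  genotype_matrix(X[, keep_all, drop = FALSE],
                  map[keep_all, , drop = FALSE],
                  populations = genotypes$populations)
}

#' Run the full variant-filter chain on a VCF
#'
#' Applies, in order: accession mean-depth filter, non-SNP (indel) record
#' exclusion, biallelic filter, indel-proximity filter (using indel
#' positions recorded before their exclusion), site-depth percentile
#' filter, mapping-quality filter, chromosome-scaffold filter, allele-depth
#' filter, and windowed LD pruning. Deterministic for a given input.
#'
#' @param vcf_path path to the input VCF.
#' @param config list of thresholds; see [filter_config()].
#' @return list with `genotypes` (a pruned [genotype_matrix()]) and
#'   `report` (a `filter_report`).
#' @export
run_filter_chain <- function(vcf_path, config = filter_config()) {
  tab <- read_variant_table(vcf_path)
  steps <- list()
  add_step <- function(rule, before, removed) {
    steps[[length(steps) + 1L]] <<- data.frame(
      rule = rule, sites_before = before, sites_removed = removed,
      sites_after = before - removed, stringsAsFactors = FALSE)
  }

  acc <- filter_accessions_by_depth(tab, config$min_accession_depth)
  tab <- acc$records
  indel_pos <- tab$sites[tab$sites$is_indel, c("chrom", "pos")]

  b <- filter_biallelic_snps(tab)
  add_step("snp_only", n_sites(tab), b$removed_indel)
  add_step("biallelic", n_sites(tab) - b$removed_indel, b$removed_multiallelic)
  tab <- b$records

  s <- filter_near_indel(tab, config$min_indel_distance, indel_pos)
  add_step("near_indel", n_sites(tab), s$removed); tab <- s$records

  s <- filter_site_depth_percentiles(tab, config$depth_lo_pct,
                                     config$depth_hi_pct,
                                     config$quantile_type)
  add_step("site_depth", n_sites(tab), s$removed); tab <- s$records

  s <- filter_mq(tab, config$min_mq)
  add_step("mq", n_sites(tab), s$removed); tab <- s$records

  s <- filter_chromosome_scaffolds(tab, config$chromosome_names)
  add_step("chromosome", n_sites(tab), s$removed); tab <- s$records

  s <- filter_allele_depth(tab, config$min_allele_depth)
  add_step("allele_depth", n_sites(tab), s$removed); tab <- s$records

  geno <- genotype_matrix(
    t(tab$gt), tab$sites[, c("chrom", "pos", "ref", "alt")])
  rownames(geno$dosage) <- tab$accessions
  geno$accessions <- tab$accessions
  ## monomorphic or missing sites cannot enter the dosage matrix
  poly <- apply(geno$dosage, 2, function(v) !anyNA(v) && stats::sd(v) > 0)
  add_step("polymorphic", n_sites(tab), sum(!poly))
  geno <- genotype_matrix(geno$dosage[, poly, drop = FALSE],
                          geno$map[poly, , drop = FALSE])
  rownames(geno$dosage) <- tab$accessions
  geno$accessions <- tab$accessions

  pruned <- ld_prune(geno, config$ld_r2_max, config$ld_window,
                     config$ld_window_units)
  add_step("ld_prune", ncol(geno$dosage),
           ncol(geno$dosage) - ncol(pruned$dosage))

  report <- structure(list(steps = do.call(rbind, steps),
                           accessions_removed = acc$removed,
                           skipped_records = attr(tab, "skipped") %||% 0L),
                      class = "filter_report")
  list(genotypes = pruned, report = report)
}

#' Default thresholds for the variant-filter chain
#'
#' @param min_accession_depth accession mean-depth cutoff (strict >).
#' @param min_indel_distance indel exclusion radius in bp.
#' @param depth_lo_pct,depth_hi_pct site-depth percentile band.
#' @param quantile_type percentile convention (stats::quantile type).
#' @param min_mq mapping-quality cutoff (strict >).
#' @param min_allele_depth per-allele depth cutoff.
#' @param chromosome_names retained scaffolds.
#' @param ld_r2_max,ld_window,ld_window_units LD-pruning parameters.
#' @return named list.
#' @export
filter_config <- function(min_accession_depth = 20, min_indel_distance = 5,
                          depth_lo_pct = 5, depth_hi_pct = 95,
                          quantile_type = 7, min_mq = 40,
                          min_allele_depth = 10,
                          chromosome_names = sprintf("A%02d", 1:10),
                          ld_r2_max = 0.2, ld_window = 1000,
                          ld_window_units = "sites") {
  as.list(environment())
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  print(x$steps, row.names = FALSE)
  if (length(x$accessions_removed))
    cat("accessions removed:", paste(x$accessions_removed, collapse = ", "), "\n")
  invisible(x)
}
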
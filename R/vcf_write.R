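#' Write a VCF with planted filter violations
#'
#' Serialises a genotype panel as a VCF 4.2 file (FORMAT GT:AD:DP, INFO MQ
#' and DP) and inserts a requested number of records violating each site
#' filter: multiallelic sites, SNPs near indels (with their companion indel
#' records), low-MQ sites, site-depth outliers, sites with an accession
#' whose two allele depths are both below 10, and records on non-chromosome
#' scaffolds. Clean cells are written at constant depth so the site-depth
#' percentile band is degenerate and removes exactly the planted outliers.
#' Optionally one or more whole accessions are written at low depth.
#'
#' @param genotypes a [genotype_matrix()] supplying the clean records.
#' @param plant_spec named integer vector/list of violation counts; names
#'   among `multiallelic`, `near_indel`, `low_mq`, `depth_outlier`,
#'   `low_allele_depth`, `non_chromosome_scaffold`, `low_depth_accession`.
#' @param path output file path (plain-text `.vcf`).
#' @param clean_dp per-cell depth of clean records (default 50).
#' @param rng_seed seed for planted positions and genotypes.
#' @return invisibly, the planted-violation manifest: a data.frame with
#'   `chrom`, `pos`, `class` and `rule` (the filter-chain step expected to
#'   remove the record); attribute `"low_depth_accessions"` lists planted
#'   low-depth accession ids.
#' @export
write_contaminated_vcf <- function(genotypes, plant_spec = list(), path,
                                   clean_dp = 50, rng_seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  set.seed(rng_seed)
  spec <- list(multiallelic = 0L, near_indel = 0L, low_mq = 0L,
               depth_outlier = 0L, low_allele_depth = 0L,
               non_chromosome_scaffold = 0L, low_depth_accession = 0L)
  unknown <- setdiff(names(plant_spec), names(spec))
  if (length(unknown))
    stop("unknown violation class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  spec[names(plant_spec)] <- lapply(plant_spec, as.integer)
  X <- genotypes$dosage
  n_acc <- nrow(X)
  acc <- rownames(X)

  n_extra <- spec$multiallelic + 2L * spec$near_indel + spec$low_mq +
    spec$depth_outlier + spec$low_allele_depth
  n_clean <- ncol(X)
  n_slots <- n_clean + n_extra

  ## one position lattice per chromosome, spacing >= 20 bp so that an
  ## indel/SNP pair at distance 2 never grazes a neighbouring record
  chroms_main <- sprintf("A%02d", 1:10)
  slot_chrom <- sample(chroms_main, n_slots, replace = TRUE)
  slot_pos <- integer(n_slots)
  for (ch in chroms_main) {
    ix <- which(slot_chrom == ch)
    slot_pos[ix] <- cumsum(sample(20:200, length(ix), replace = TRUE))
  }
  o <- order(slot_chrom, slot_pos)
  slot_chrom <- slot_chrom[o]; slot_pos <- slot_pos[o]
  slot_class <- rep("clean", n_slots)
  extra_classes <- c(rep("multiallelic", spec$multiallelic),
                     rep("near_indel", spec$near_indel),
                     rep("low_mq", spec$low_mq),
                     rep("depth_outlier", spec$depth_outlier),
                     rep("low_allele_depth", spec$low_allele_depth))
  n_pair_extra <- spec$near_indel  # each near_indel consumes 2 slots
  slots_for_extra <- sample(n_slots, length(extra_classes) + n_pair_extra)
  pair_slots <- utils::head(slots_for_extra, n_pair_extra)
  single_slots <- utils::tail(slots_for_extra, length(extra_classes))
  slot_class[single_slots] <- extra_classes
  slot_class[pair_slots] <- "indel_companion"

  low_acc <- character(0)
  if (spec$low_depth_accession > 0) {
    if (spec$low_depth_accession >= n_acc)
      stop("cannot plant low depth in every accession", call. = FALSE)
    low_acc <- sample(acc, spec$low_depth_accession)
  }

  bases <- c("A", "C", "G", "T")
  random_dosages <- function() {
    p <- stats::runif(1, 0.2, 0.8)
    d <- stats::rbinom(n_acc, 2L, p)
    if (length(unique(d)) == 1L) d[1] <- (d[1] + 1L) %% 3L
    d
  }
  fmt_cell <- function(dos, dp, adr = NULL, ada = NULL) {
    gt <- c("0/0", "0/1", "1/1")[dos + 1L]
    if (is.null(adr)) {
      adr <- round(dp * (2 - dos) / 2); ada <- dp - adr
    }
    sprintf("%s:%d,%d:%d", gt, adr, ada, dp)
  }

  lines <- character(0)
  manifest <- list()
  clean_i <- 0L
  near_snp_done <- 0L
  emit <- function(chrom, pos, ref, alt, mq, dp_info, cells, class, rule) {
    lines[[length(lines) + 1L]] <<- paste(
      c(chrom, pos, ".", ref, alt, "100", "PASS",
        sprintf("DP=%d;MQ=%.1f", dp_info, mq), "GT:AD:DP", cells),
      collapse = "\t")
    if (class != "clean")
      manifest[[length(manifest) + 1L]] <<- data.frame(
        chrom = chrom, pos = pos, class = class, rule = rule,
        stringsAsFactors = FALSE)
  }

  for (s in seq_len(n_slots)) {
    ch <- slot_chrom[s]; pos <- slot_pos[s]
    cls <- slot_class[s]
    dp_cell <- rep(clean_dp, n_acc)
    dp_cell[acc %in% low_acc] <- 10L
    ra <- sample(bases, 2)
    if (cls == "clean") {
      clean_i <- clean_i + 1L
      dos <- X[, clean_i]
      emit(ch, pos, ra[1], ra[2], 60, sum(dp_cell),
           fmt_cell(dos, dp_cell), "clean", NA)
    } else if (cls == "multiallelic") {
      dos <- random_dosages()
      alt2 <- setdiff(bases, ra)[1]
      emit(ch, pos, ra[1], paste(ra[2], alt2, sep = ","), 60, sum(dp_cell),
           fmt_cell(dos, dp_cell), "multiallelic", "biallelic")
    } else if (cls == "indel_companion") {
      ## companion indel at pos, violating SNP 2 bp away
      near_snp_done <- near_snp_done + 1L
      dos <- random_dosages()
      emit(ch, pos, paste0(ra[1], "TTA"), ra[1], 60, sum(dp_cell),
           fmt_cell(dos, dp_cell), "indel_companion", "snp_only")
      dos2 <- random_dosages()
      emit(ch, pos + 2L, ra[1], ra[2], 60, sum(dp_cell),
           fmt_cell(dos2, dp_cell), "near_indel", "near_indel")
    } else if (cls == "low_mq") {
      dos <- random_dosages()
      emit(ch, pos, ra[1], ra[2], 35, sum(dp_cell),
           fmt_cell(dos, dp_cell), "low_mq", "mq")
    } else if (cls == "depth_outlier") {
      dp_out <- if (stats::runif(1) < 0.5) 500L else 30L
      dp_cell <- rep(dp_out, n_acc)
      dp_cell[acc %in% low_acc] <- 10L
      dos <- random_dosages()
      emit(ch, pos, ra[1], ra[2], 60, sum(dp_cell),
           fmt_cell(dos, dp_cell), "depth_outlier", "site_depth")
    } else if (cls == "low_allele_depth") {
      dos <- random_dosages()
      cells <- fmt_cell(dos, dp_cell)
      hit <- sample(setdiff(seq_len(n_acc), which(acc %in% low_acc)), 1)
      cells[hit] <- sprintf("%s:9,9:%d", c("0/0", "0/1", "1/1")[dos[hit] + 1L],
                            dp_cell[hit])
      emit(ch, pos, ra[1], ra[2], 60, sum(dp_cell), cells,
           "low_allele_depth", "allele_depth")
    }
  }
  ## non-chromosome scaffold records appended on their own contigs
  if (spec$non_chromosome_scaffold > 0) {
    for (k in seq_len(spec$non_chromosome_scaffold)) {
      ra <- sample(bases, 2)
      dp_cell <- rep(clean_dp, n_acc)
      dp_cell[acc %in% low_acc] <- 10L
      emit(sprintf("scaffold_%03d", 400L + k), 1000L + 17L * k,
           ra[1], ra[2], 60, sum(dp_cell),
           fmt_cell(random_dosages(), dp_cell),
           "non_chromosome_scaffold", "chromosome")
    }
  }

  contigs <- unique(c(chroms_main,
                      if (spec$non_chromosome_scaffold > 0)
                        sprintf("scaffold_%03d",
                                400L + seq_len(spec$non_chromosome_scaffold))))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=germtherm-synthetic",
    sprintf("##contig=<ID=%s>", contigs),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", acc), collapse = "\t"))
  writeLines(c(header, lines), path)
  man <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(chrom = character(0), pos = integer(0),
               class = character(0), rule = character(0))
  attr(man, "low_depth_accessions") <- low_acc
  attr(man, "n_clean") <- n_clean
  invisible(man)
}
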
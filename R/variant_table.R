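#' Construct a variant table
#'
#' In-memory representation of a multi-sample VCF slice carrying exactly the
#' attributes the site filters read: per-site chrom/pos/alleles/MQ and
#' per-accession total depth, ref/alt allele depths and genotype dosage.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated for multiallelic sites), `mq`.
#' @param dp,ad_ref,ad_alt sites x accessions numeric matrices of total
#'   depth and per-allele depths.
#' @param gt sites x accessions dosage matrix (0/1/2, NA for missing or
#'   non-biallelic calls).
#' @param accessions character vector of accession ids.
#' @return object of class `variant_table`.
#' @export
variant_table <- function(sites, dp, ad_ref, ad_alt, gt, accessions) {
  stopifnot(nrow(sites) == nrow(dp), all(dim(dp) == dim(ad_ref)),
            all(dim(dp) == dim(ad_alt)), all(dim(dp) == dim(gt)),
            ncol(dp) == length(accessions))
  alts <- strsplit(as.character(sites$alt), ",", fixed = TRUE)
  sites$n_alt <- lengths(alts)
  sites$is_indel <- nchar(sites$ref) > 1L |
    vapply(alts, function(a) any(nchar(a) > 1L), logical(1))
  structure(list(sites = sites, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
                 gt = gt, accessions = accessions),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d accessions\n",
              nrow(x$sites), length(x$accessions)))
  invisible(x)
}

n_sites <- function(tab) nrow(tab$sites)

subset_sites <- function(tab, keep) {
  tab$sites <- tab$sites[keep, , drop = FALSE]
  for (f in c("dp", "ad_ref", "ad_alt", "gt"))
    tab[[f]] <- tab[[f]][keep, , drop = FALSE]
  tab
}

subset_accessions <- function(tab, keep) {
  for (f in c("dp", "ad_ref", "ad_alt", "gt"))
    tab[[f]] <- tab[[f]][, keep, drop = FALSE]
  tab$accessions <- tab$accessions[keep]
  tab
}

#' Read a VCF into a variant table
#'
#' Parses a VCF 4.x file (FORMAT GT/AD/DP, INFO MQ) with `vcfR`. Records
#' with an unparsable position are logged and skipped.
#'
#' @param vcf_path path to a VCF (.vcf or .vcf.gz).
#' @return a [variant_table()]; attribute `"skipped"` counts malformed
#'   records.
#' @export
read_variant_table <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path, call. = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) {
    acc <- colnames(vcf@gt)[-1] %||% character(0)
    empty <- matrix(numeric(0), 0, length(acc))
    tab <- variant_table(
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), mq = numeric(0)),
      empty, empty, empty, empty, acc)
    attr(tab, "skipped") <- 0L
    return(tab)
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  ok <- !is.na(pos) & !is.na(fix$REF) & !is.na(fix$ALT)
  skipped <- sum(!ok)
  if (skipped) {
    message(skipped, " malformed VCF record(s) skipped")
    vcf <- vcf[ok, ]
    fix <- fix[ok, , drop = FALSE]
    pos <- pos[ok]
  }
  mq <- suppressWarnings(vcfR::extract.info(vcf, element = "MQ",
                                            as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                          as.numeric = TRUE))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  split_ad <- function(k) {
    v <- suppressWarnings(vapply(strsplit(ad, ",", fixed = TRUE),
                                 function(x) as.numeric(x[k]), numeric(1)))
    m <- matrix(v, nrow = nrow(ad))
    m[is.na(m)] <- 0
    m
  }
  ad_ref <- split_ad(1L)
  ad_alt <- split_ad(2L)
  dos <- matrix(NA_real_, nrow(gt_chr), ncol(gt_chr))
  gt_clean <- gsub("|", "/", gt_chr, fixed = TRUE)
  dos[gt_clean %in% c("0/0")] <- 0
  dos[gt_clean %in% c("0/1", "1/0")] <- 1
  dos[gt_clean %in% c("1/1")] <- 2
  dp[is.na(dp)] <- 0
  sites <- data.frame(chrom = fix$CHROM, pos = pos, ref = fix$REF,
                      alt = fix$ALT, mq = mq, stringsAsFactors = FALSE)
  tab <- variant_table(sites, dp, ad_ref, ad_alt, dos,
                       accessions = colnames(vcf@gt)[-1])
  attr(tab, "skipped") <- skipped
  tab
}
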
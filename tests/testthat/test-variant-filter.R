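test_that("accession depth filter is strict at the threshold", {
  tab <- make_tab("A01", c(100, 200), dp = cbind(c(19, 19), c(20, 20),
                                                 c(21, 21)))
  res <- filter_accessions_by_depth(tab, 20)
  expect_identical(res$records$accessions, "s03")
  expect_identical(res$removed, c("s01", "s02"))

  deep <- make_tab("A01", c(100, 200), dp = matrix(50, 2, 3))
  expect_length(filter_accessions_by_depth(deep, 20)$removed, 0)
  shallow <- make_tab("A01", 100, dp = matrix(5, 1, 2))
  expect_error(filter_accessions_by_depth(shallow, 20), "no accession")
})

test_that("biallelic filter removes multiallelic sites and indels", {
  tab <- make_tab("A01", c(10, 20, 30, 40),
                  ref = c("A", "A", "ATT", "C"),
                  alt = c("G", "A,T", "A", "T"),
                  dp = matrix(50, 4, 2))
  res <- filter_biallelic_snps(tab)
  expect_equal(res$removed_multiallelic, 1)
  expect_equal(res$removed_indel, 1)
  expect_equal(res$records$sites$pos, c(10, 40))
})

test_that("indel proximity removes strictly-closer SNPs only", {
  # indel at 103: SNP at 100 (distance 3) removed, SNP at 108 (distance 5) kept
  tab <- make_tab("A01", c(100, 103, 108), ref = c("A", "ATT", "G"),
                  alt = c("G", "A", "C"), dp = matrix(50, 3, 2))
  res <- filter_near_indel(tab, 5)
  expect_equal(res$removed, 1)
  expect_false(100 %in% res$records$sites$pos)
  expect_true(108 %in% res$records$sites$pos)
  # indels on another scaffold do not matter
  tab2 <- make_tab(c("A01", "A02"), c(100, 103), ref = c("A", "ATT"),
                   alt = c("G", "A"), dp = matrix(50, 2, 2))
  expect_equal(filter_near_indel(tab2, 5)$removed, 0)
})

test_that("site-depth percentile filter matches a sort-and-index oracle", {
  tab <- make_tab("A01", seq_len(100) * 10, dp = matrix(1:100, 100, 1))
  res <- filter_site_depth_percentiles(tab, 5, 95)
  qs <- stats::quantile(1:100, c(0.05, 0.95), type = 7)  # independent oracle
  keep_oracle <- which(1:100 >= qs[1] & 1:100 <= qs[2])
  expect_equal(rowMeans(res$records$dp), as.numeric(keep_oracle))
  # constant depth: nothing removed
  const <- make_tab("A01", seq_len(30) * 10, dp = matrix(50, 30, 2))
  expect_equal(filter_site_depth_percentiles(const)$removed, 0)
  # too few sites: warn, no-op
  few <- make_tab("A01", c(10, 20), dp = matrix(c(1, 100), 2, 1))
  expect_warning(out <- filter_site_depth_percentiles(few), "fewer than 20")
  expect_equal(out$removed, 0L)
})

test_that("MQ filter is strict and treats missing MQ as failing", {
  tab <- make_tab("A01", c(10, 20, 30), mq = c(40, 40.1, NA),
                  dp = matrix(50, 3, 1))
  expect_message(res <- filter_mq(tab, 40), "missing MQ")
  expect_equal(res$records$sites$pos, 20)
  expect_equal(res$removed, 2)
  expect_equal(res$missing_mq, 1)
})

test_that("allele-depth rule removes sites with a doubly-shallow accession", {
  both_low <- make_tab("A01", 10, dp = matrix(50, 1, 2),
                       ad_ref = matrix(c(9, 30), 1, 2),
                       ad_alt = matrix(c(9, 20), 1, 2))
  expect_equal(filter_allele_depth(both_low)$removed, 1)
  one_ok <- make_tab("A01", 10, dp = matrix(50, 1, 2),
                     ad_ref = matrix(9, 1, 2), ad_alt = matrix(30, 1, 2))
  expect_equal(filter_allele_depth(one_ok)$removed, 0)
  missing_call <- make_tab("A01", 10, dp = matrix(50, 1, 2),
                           ad_ref = matrix(c(0, 30), 1, 2),
                           ad_alt = matrix(c(0, 20), 1, 2))
  expect_equal(filter_allele_depth(missing_call)$removed, 1)
})

test_that("scaffold filter keeps chromosome-mapped records only", {
  tab <- make_tab(c("A01", "scaffold_441"), c(10, 20), dp = matrix(50, 2, 1))
  res <- filter_chromosome_scaffolds(tab, sprintf("A%02d", 1:10))
  expect_equal(res$records$sites$chrom, "A01")
  expect_equal(filter_chromosome_scaffolds(
    make_tab("A03", 10, dp = matrix(50, 1, 1)),
    sprintf("A%02d", 1:10))$removed, 0)
  expect_error(filter_chromosome_scaffolds(tab, character(0)), "empty")
})

test_that("LD pruning keeps the first of each correlated pair", {
  set.seed(42)
  x1 <- rbinom(100, 2, 0.5)
  x3 <- rbinom(100, 2, 0.5)
  g <- genotype_matrix(cbind(x1, x1, x3),
                       data.frame(chrom = "A01", pos = c(10, 20, 30),
                                  ref = "A", alt = "G"))
  pruned <- ld_prune(g, r2_max = 0.2)
  expect_equal(pruned$map$pos, c(10, 30))
  # exhaustive oracle: no retained pair exceeds the threshold
  r2 <- cor(pruned$dosage)^2
  expect_true(max(r2[upper.tri(r2)]) <= 0.2)

  dup5 <- genotype_matrix(matrix(rep(x1, 5), ncol = 5),
                          data.frame(chrom = "A01", pos = 1:5 * 10,
                                     ref = "A", alt = "G"))
  expect_equal(ncol(ld_prune(dup5)$dosage), 1)
})

test_that("LD pruning is the identity when all correlations are low", {
  set.seed(7)
  X <- sapply(1:12, function(i) rbinom(500, 2, 0.5))
  stopifnot(max(cor(X)[upper.tri(diag(12))]^2) < 0.2)
  g <- genotype_matrix(X, data.frame(chrom = "A01", pos = 1:12 * 10,
                                     ref = "A", alt = "G"))
  expect_identical(ld_prune(g)$dosage, g$dosage)
})

test_that("LD pruning respects the trailing window and monomorphic rule", {
  set.seed(3)
  x <- rbinom(80, 2, 0.5)
  mono <- rep(1, 80)
  # duplicate beyond the window is kept; monomorphic column never blocks
  g <- genotype_matrix(cbind(x, mono, x),
                       data.frame(chrom = "A01", pos = c(10, 20, 30),
                                  ref = "A", alt = "G"))
  expect_equal(ncol(ld_prune(g, r2_max = 0.2, window = 1)$dosage), 3)
  expect_equal(ncol(ld_prune(g, r2_max = 0.2, window = 2)$dosage), 2)
})

test_that("each site filter is idempotent", {
  set.seed(10)
  tab <- make_tab("A01", sort(sample(1:5000, 60)),
                  mq = sample(c(35, 60), 60, TRUE),
                  dp = matrix(sample(10:100, 120, TRUE), 60, 2),
                  ad_ref = matrix(sample(0:40, 120, TRUE), 60, 2),
                  ad_alt = matrix(sample(0:40, 120, TRUE), 60, 2))
  for (f in list(function(t) filter_biallelic_snps(t)$records,
                 function(t) filter_near_indel(t)$records,
                 function(t) filter_mq(t)$records,
                 function(t) filter_allele_depth(t)$records,
                 function(t) filter_chromosome_scaffolds(
                   t, sprintf("A%02d", 1:10))$records)) {
    once <- f(tab)
    expect_identical(f(once)$sites, once$sites)
  }
})

test_that("filter chain removals match the planted manifest exactly", {
  cfg <- simulation_config(n_accessions = 20, n_snps = 150, rng_seed = 31)
  geno <- simulate_genotypes(cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  spec <- list(multiallelic = 7, near_indel = 5, low_mq = 4,
               depth_outlier = 5, low_allele_depth = 3,
               non_chromosome_scaffold = 2, low_depth_accession = 1)
  man <- write_contaminated_vcf(geno, spec, vcf, rng_seed = 8)
  res <- run_filter_chain(vcf)
  steps <- res$report$steps
  got <- stats::setNames(steps$sites_removed, steps$rule)
  planted <- table(man$rule)
  for (rule in names(planted))
    expect_equal(unname(got[rule]), unname(planted[rule]), label = rule)
  expect_identical(res$report$accessions_removed,
                   attr(man, "low_depth_accessions"))
  # report bookkeeping invariant
  expect_true(all(steps$sites_after ==
                    steps$sites_before - steps$sites_removed))
})

test_that("round-trip: clean records come back with identical dosages", {
  cfg <- simulation_config(n_accessions = 12, n_snps = 80, rng_seed = 13)
  geno <- simulate_genotypes(cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_contaminated_vcf(geno, list(), vcf, rng_seed = 2)
  tab <- read_variant_table(vcf)
  expect_equal(unname(t(tab$gt)), unname(geno$dosage))
  expect_identical(tab$accessions, geno$accessions)
})

test_that("a clean VCF passes with removals only at LD pruning", {
  cfg <- simulation_config(n_accessions = 15, n_snps = 100, rng_seed = 17)
  geno <- simulate_genotypes(cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  man <- write_contaminated_vcf(geno, list(), vcf, rng_seed = 3)
  expect_equal(nrow(man), 0)
  res <- run_filter_chain(vcf)
  steps <- res$report$steps
  expect_true(all(steps$sites_removed[!steps$rule %in%
                                        c("ld_prune", "polymorphic")] == 0))
  expect_length(res$report$accessions_removed, 0)
})

test_that("an empty VCF yields an empty matrix and a zero report", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=A01>",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1", "s2"), collapse = "\t")), vcf)
  res <- suppressWarnings(run_filter_chain(vcf))
  expect_equal(ncol(res$genotypes$dosage), 0)
  expect_true(all(res$report$steps$sites_removed == 0))
})

test_that("byte-identical VCFs are written for identical seeds", {
  cfg <- simulation_config(n_accessions = 10, n_snps = 40, rng_seed = 23)
  geno <- simulate_genotypes(cfg)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_contaminated_vcf(geno, list(multiallelic = 3), f1, rng_seed = 4)
  write_contaminated_vcf(geno, list(multiallelic = 3), f2, rng_seed = 4)
  expect_identical(readLines(f1), readLines(f2))
})
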
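#!/usr/bin/env Rscript
# Stage 1 -- simulate the study cohort.
#
# Generates a structured diversity panel (3 ancestral populations, Fst 0.15)
# of 100 accessions typed at 800 SNPs, phenotypes 25 seeds per accession and
# temperature for germination time (censored at 168 h) and the 0/1
# germination outcome, draws sampling-site latitudes, and writes the raw
# inputs consumed by the later stages, including a contaminated VCF that
# carries planted violations of every site filter.

suppressPackageStartupMessages(library(germtherm))

out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- simulation_config(n_accessions = 100, n_snps = 800,
                         seeds_per_cell = 25, rng_seed = 20250901L)
cohort <- simulate_cohort(cfg)

write.csv(cohort$phenotypes, file.path(out, "phenotypes.csv"),
          row.names = FALSE)
write.csv(cohort$emergence, file.path(out, "emergence.csv"),
          row.names = FALSE)
write.csv(cohort$latitudes, file.path(out, "latitudes.csv"),
          row.names = FALSE)

man <- write_contaminated_vcf(
  cohort$genotypes,
  list(multiallelic = 7, near_indel = 5, low_mq = 6, depth_outlier = 6,
       low_allele_depth = 6, non_chromosome_scaffold = 4,
       low_depth_accession = 1),
  file.path(out, "cohort_raw.vcf"), rng_seed = cfg$rng_seed + 7L)
write.table(man, file.path(out, "planted_manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(cohort, file.path(out, "cohort.rds"))

cat(sprintf("simulated %d accessions x %d SNPs; %d seeds phenotyped (%.1f%% germinated)\n",
            length(cohort$genotypes$accessions), ncol(cohort$genotypes$dosage),
            nrow(cohort$phenotypes), 100 * mean(cohort$phenotypes$germinated)))
cat(sprintf("wrote raw VCF with %d planted violations and 1 low-depth accession\n",
            nrow(man)))
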
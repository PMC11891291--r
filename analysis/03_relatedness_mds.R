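#!/usr/bin/env Rscript
# Stage 3 -- genomic relationships and population structure.
#
# Computes the GCTA-style genomic relationship matrix from the filtered
# panel, its correlation form G* and dissimilarity 1 - G*, and a classical
# MDS of the dissimilarity; writes the GRM (text format) and the MDS
# coordinates with per-axis variance explained.

suppressPackageStartupMessages(library(germtherm))

out <- "results"
geno <- readRDS(file.path(out, "genotypes_filtered.rds"))
rel <- compute_grm(geno)
mds <- classical_mds(rel$D, n_axes = 4)

write_grm_text(rel, file.path(out, "panel"))
write.table(data.frame(accession = rownames(mds$coordinates),
                       mds$coordinates),
            file.path(out, "mds_coordinates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(rel, file.path(out, "relationship.rds"))

cat(sprintf("GRM from %d SNPs: mean diagonal %.3f\n", rel$n_snps,
            mean(diag(rel$G))))
cat(sprintf("MDS axes explain %s of the variance\n",
            paste(sprintf("%.2f%%", mds$pct_variance), collapse = ", ")))
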
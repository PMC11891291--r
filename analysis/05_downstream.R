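#!/usr/bin/env Rscript
# Stage 5 -- heat tolerance, latitude and emergence.
#
# Pools the per type x temperature gBLUPs into per-accession cold (C) and
# warm (W) genetic values, computes heat tolerance H = W - C, and fits the
# cross-temperature regression (W on C), the latitude regression of H
# (controlling for C), and the emergence regression of the field emergence
# rate on the cold germination-rate gBLUP with the cold-model intercept as
# a fixed offset.

suppressPackageStartupMessages(library(germtherm))

out <- "results"
cohort <- readRDS(file.path(out, "cohort.rds"))
mf <- readRDS(file.path(out, "model_fits.rds"))

acc_type <- setNames(cohort$latitudes$type, cohort$latitudes$accession)
pool <- function(fits, temp) {
  res <- numeric(0)
  for (ty in unique(acc_type)) {
    f <- fits[[paste(ty, temp, sep = "_")]]
    ids <- intersect(names(acc_type)[acc_type == ty], names(f$gblups))
    res <- c(res, f$gblups[ids])
  }
  res
}

rows <- list()
for (trait in c("GT", "GRA")) {
  fits <- if (trait == "GT") mf$fits$gt_1c else mf$fits$gr_3c
  sm <- heat_tolerance(build_accession_summary(
    pool(fits, "cold"), pool(fits, "warm"), cohort$latitudes,
    cohort$emergence))
  write.csv(sm, file.path(out, sprintf("summaries_%s.csv", trait)),
            row.names = FALSE)
  cross <- fit_cross_temperature(sm)
  lat <- fit_latitude_model(sm)$joint
  sl <- cross$coefficients[cross$coefficients$term == "C", ]
  lc <- lat$coefficients[lat$coefficients$term == "latitude", ]
  cat(sprintf("%s: W ~ C slope %.3f (p = %.2g, adj R2 = %.2f); latitude %.4f (p = %.2g)\n",
              trait, sl$estimate, sl$p, cross$adj_r2, lc$estimate, lc$p))
  rows[[trait]] <- data.frame(trait = trait, slope_WC = sl$estimate,
                              adj_r2_WC = cross$adj_r2,
                              latitude_coef = lc$estimate,
                              latitude_p = lc$p)
}

cold <- mf$fits$gr_3c[grepl("_cold$", names(mf$fits$gr_3c))]
mu3 <- mean(sapply(cold, function(f)
  f$beta$estimate[f$beta$term == "(Intercept)"]))
sm_gr <- read.csv(file.path(out, "summaries_GRA.csv"))
emf <- fit_emergence_model(sm_gr, mu3)
ec <- emf$coefficients[emf$coefficients$term == "C", ]
cat(sprintf("emergence ~ cold GR gBLUP: slope %.3f (p = %.2g, adj R2 = %.2f)\n",
            ec$estimate, ec$p, emf$adj_r2))

write.table(do.call(rbind, rows), file.path(out, "downstream_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
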
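#!/usr/bin/env Rscript
# Stage 3: per-individual genome-wide heterozygosity (folded two-class EM in
# 1 Mb windows), downsampling calibration of coverage bias on the
# highest-coverage contemporary individual, correction of all contemporary
# estimates, and the epoch comparison.

library(erosionkit)

data_dir <- "results/data"
pileup <- read_pileup_tsv(file.path(data_dir, "pileup.tsv"))
truth <- read.delim(file.path(data_dir, "truth.tsv"))
em <- error_model(0.001)

# all-sites heterozygosity is inflated in the damaged historic libraries;
# the transversion-only estimate removes C>T / G>A artifacts and is the
# basis of the epoch comparison (at the cost of assaying only transversion
# heterozygosity, about 2/3 of sites here)
est_all <- estimate_heterozygosity(pileup, em, window_size = 1e6)
est <- estimate_heterozygosity(pileup, em, window_size = 1e6,
                               transversions_only = TRUE)
ind <- est$individual
ind$het_all_sites <- est_all$individual$het_raw[match(ind$id,
                                                      est_all$individual$id)]
ind$epoch <- truth$epoch[match(ind$id, truth$id)]
inflation <- split(ind$het_all_sites / ind$het_raw, ind$epoch)
cat(sprintf(
  "damage check: all-sites/transversion het ratio %.1f (historic) vs %.1f (contemporary)\n",
  mean(inflation$historic), mean(inflation$contemporary)))

# calibration on the deepest contemporary genome
con <- ind[ind$epoch == "contemporary", ]
ref_id <- con$id[which.max(con$coverage)]
curve <- build_calibration_curve(pileup, ref_id, em, seed = 301L)
cat(sprintf("calibration on %s (%.1fx): %d support points, degree %d\n",
            ref_id, curve$reference_coverage, nrow(curve$support),
            curve$degree))
write.table(curve$support, "results/calibration_support.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ind$het_corrected <- ind$het_raw
ok <- ind$coverage >= 0.5 * min(curve$support$coverage) &
      ind$coverage <= 1.5 * curve$reference_coverage
ind$het_corrected[ok] <- apply_correction(ind$het_raw[ok], ind$coverage[ok],
                                          curve)
write.table(ind, "results/heterozygosity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

by_epoch <- split(ind$het_raw, ind$epoch)
kw <- kruskal_wallis(by_epoch)
cat(sprintf("mean transversion het: historic %.5f, contemporary %.5f (KW H = %.3f, p = %.3g)\n",
            mean(by_epoch$historic), mean(by_epoch$contemporary), kw$H,
            kw$p_value))
cat(sprintf("true means (all sites): historic %.5f, contemporary %.5f\n",
            mean(truth$true_het[truth$epoch == "historic"]),
            mean(truth$true_het[truth$epoch == "contemporary"])))
cat("wrote results/heterozygosity.tsv\n")
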
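#!/usr/bin/env Rscript
# Stage 2: error-rate estimation from a haploid reference, genotype
# likelihoods from the pileup, and ANGSD-style site filtering
# (MAF >= 0.05, SNP LRT p <= 1e-6, >= half the cohort with data,
# transversions only).

library(erosionkit)

data_dir <- "results/data"
out <- "results"
pileup <- read_pileup_tsv(file.path(data_dir, "pileup.tsv"))

# error rate from haploid (mitochondrial-style) reads: simulate reads off the
# first mt haplotype at the known per-base error and re-estimate it
mt <- read_labelled_fasta(file.path(data_dir, "mt_alignment.fasta"))
hap <- strsplit(unname(mt[1]), "")[[1]]
set.seed(201)
depth <- 40
ref <- rep(hap, depth)
bases <- ifelse(runif(length(ref)) < 0.001,
                vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), ""),
                ref)
em <- estimate_error_rate_from_haploid(bases, quals = rep(35, length(ref)),
                                       ref = ref, min_quality = 30)
cat(sprintf("estimated error rate from %d haploid bases: %.5f (tv-only %.5f)\n",
            em$n_bases, em$e, em$e_tv))

gl <- call_genotype_likelihoods(pileup, em)
gl <- estimate_maf_em(gl)
glf <- filter_sites(gl, min_maf = 0.05, snp_p = 1e-6,
                    min_ind = ceiling(nrow(pileup$individuals) / 2),
                    rm_transitions = TRUE)
cat(sprintf("site filters: %d of %d sites retained (transversion SNPs)\n",
            length(glf$pos), length(gl$pos)))
write_beagle_gl(glf, file.path(out, "filtered.beagle.tsv"))
cat("wrote", file.path(out, "filtered.beagle.tsv"), "\n")
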
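# erosionkit

Tools for quantifying **temporal genomic erosion** — the loss of genetic
diversity between a historic (museum) and a contemporary sampling epoch —
from low- to medium-coverage whole-genome resequencing data, as in temporal
studies of declining species such as the koala. It is written for
conservation and population genomicists who have mapped reads (or genotype
likelihood / VCF callsets) from two epochs and want the standard erosion
statistics with the artifacts of museum data handled explicitly.

Historic genomes confound real diversity loss with two artifacts: shallow
coverage (1–5x) and post-mortem deamination (C>T / G>A). The package
implements the analysis stack used in this field, each step testable
against synthetic data with known ground truth:

* **Genotype likelihoods** from pileups under the GATK-style model
  `L(a1,a2) = prod_j [P(b_j|a1) + P(b_j|a2)]/2`, `P(b|a) = 1-e` or `e/3`,
  with the error rate `e` estimated from mismatches to the haploid
  mitochondrial consensus; ANGSD-style site filters (MAF ≥ 0.05, SNP
  likelihood-ratio test p ≤ 1e-6, minimum individuals, transversions only).
* **Genome-wide heterozygosity** per individual by a folded two-class EM in
  1 Mb windows (tolerance 1e-8), with an optional transversion-only mode,
  and a **downsampling calibration** of coverage bias (5 fractions x 3
  replicates = 15 datasets per individual) fitted with an anchored
  polynomial and used to correct low-coverage estimates.
* **Runs of homozygosity** by a PLINK-style 50-SNP sliding window
  (`--homozyg-snp 50 --homozyg-kb 1000 --homozyg-gap 1000` semantics),
  `F_ROH` = summed ROH > 1 Mb over scaffolds > 10 Mb, five length classes,
  and the class-to-generation age mapping (`g = 100/(rL)` as conventionally
  applied; `g = 100/(2rL)` as stated in the literature — both available).
* **Mitochondrial haplotypes**: collapsing with missing-data masking,
  Nei's haplotype diversity `Hd = n/(n-1)(1 - sum p_i^2)`, a label
  permutation test for `delta Hd` between epochs, and Bandelt
  median-joining networks.
* **Population structure** from genotype likelihoods: PCAngsd-style
  covariance (`C_ij = mean_s (E_is - 2f_s)(E_js - 2f_s) / 2f_s(1-f_s)`)
  with PCA, and NGSadmix-model admixture EM (best of many random starts).
* **A synthetic-data generator** for all of it: two epochs with a
  calibrated bottleneck, Poisson coverage, sequencing error, strand-collapsed
  aDNA damage, planted autozygous tracts, and epoch-specific mitochondrial
  haplotype frequencies — every downstream number checkable against truth.

## Worked example

Simulate a two-epoch cohort at the published diversity scale (historic mean
heterozygosity 1.4e-3, contemporary reduced to 30%), compare epochs, and
date inbreeding from ROH lengths:

```r
library(erosionkit)

cfg <- sim_config(n_historic = 20, n_contemporary = 20, n_sites = 20000,
                  theta = 0.0014, bottleneck_factor = 0.3, seed = 11)
geno <- simulate_genotypes(cfg)
het <- split(geno$truth$het, geno$individuals$epoch)
kw <- kruskal_wallis(het)

mt <- simulate_mt_haplotypes(sim_config(n_historic = 31, n_contemporary = 31,
                                        seed = 11),
                             n_haplotypes = 5, seq_length = 400, drop_rare = 2)
tab <- call_haplotypes(mt$sequences)
a <- tab$assignments
hh <- a$haplotype[a$epoch == "historic"]
ch <- a$haplotype[a$epoch == "contemporary"]
permutation_test_hd(hh, ch, n_permutations = 10000, seed = 11)

roh_age(c(0.5, 1, 2, 5, 10))
```

Output:

```
true mean heterozygosity: historic 0.00121, contemporary 0.00024
Kruskal-Wallis H = 29.451, p = 5.74e-08
Hd historic = 0.768, Hd contemporary = 0.598
permutation test: observed delta Hd = 0.1699, p = 0.0046 (two-sided, 10000 permutations)
  length_mb generations years
1       0.5         200  1200
2       1.0         100   600
3       2.0          50   300
4       5.0          20   120
5      10.0          10    60
```

The heterozygosity decline between epochs is highly significant; the
contemporary epoch, having lost its two rarest mitochondrial matrilines,
shows significantly lower haplotype diversity; and a 10 Mb run of
homozygosity dates an inbreeding event to within the last ~10 koala
generations (~60 years).

## The analysis workflow

`analysis/01_simulate.R` … `06_population_structure.R` run the whole
pipeline as numbered stages over a simulated cohort (15 + 15 nuclear
genomes at 5x/12x with damage in the historic epoch; 31 + 31 mitogenomes),
writing tables under `results/`: the dataset and truth (01), filtered
genotype likelihoods in BEAGLE format (02), raw / transversion-only /
coverage-corrected heterozygosity with the calibration curve (03), ROH
segments, `F_ROH` and age classes on a SNP-dense callset (04), haplotype
diversity, the permutation test and the median-joining network (05), and
PCA plus admixture proportions (06). `run_pipeline()` performs the same
end-to-end run programmatically with a manifest recording every seed.

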
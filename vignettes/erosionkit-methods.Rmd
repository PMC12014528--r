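---
title: "Quantifying temporal genomic erosion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temporal genomic erosion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

erosionkit quantifies the loss of genetic diversity ("genomic erosion")
between two sampling epochs — historic museum specimens and contemporary
individuals — from low- to medium-coverage whole-genome resequencing data.
This vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design choices that were genuinely open.

## The measurement problem

Museum-era genomes differ from modern ones in three confounded ways: real
biology (diversity lost to drift, bottlenecks and inbreeding), sequencing
depth (historic libraries often reach only 1–5x against 10–17x for fresh
samples), and post-mortem chemistry (cytosine deamination read as C>T and,
strand-collapsed, G>A). Every estimator in this package exists to separate
the biology from the two artifacts:

* genotype likelihoods retain uncertainty instead of hard-calling genotypes
  at low depth;
* transversion-only modes remove deamination artifacts;
* an explicit downsampling calibration measures and corrects what depth does
  to heterozygosity estimates.

## Genotype likelihoods and site filters

For a site with reads `b_1..b_d` and error rate `e`, the likelihood of the
diploid genotype `(a1, a2)` is

    L(a1, a2) = prod_j [ P(b_j | a1) + P(b_j | a2) ] / 2,
    P(b | a) = 1 - e   if b = a,   e / 3 otherwise,

the standard GATK-style model. The error rate is estimated by counting
mismatches against a haploid sequence — the mitochondrial consensus — where
every disagreement above the quality threshold (default Q30) must be an
error; a transversion-only variant rescales the transversion mismatch rate
by 3/2 so it is robust to deamination.

The major and minor allele at a site are the two most frequent alleles over
all reads, ties broken in base order A < C < G < T (the tie-break is a
convention the upstream tools leave unspecified). Individuals without reads
carry flat likelihood triplets rather than being dropped, so the
"minimum individuals with data" filter counts individuals with at least one
read. Minor allele frequencies are estimated per site by an EM on the
marginal likelihood under Hardy–Weinberg priors, and sites are screened by
four filters applied in this order: transversion-only (after major/minor
inference — the upstream flag semantics are ambiguous, and this order means
the transversion test sees the final allele pair), minimum frequency
(default 0.05), a 1-df likelihood-ratio test against monomorphism (default
p <= 1e-6, with p = 1 at the f = 0 boundary rather than the chi-square
mixture refinement — conservative), and minimum individuals with data.

## Windowed heterozygosity and the folding convention

Per-individual genome-wide heterozygosity treats each site as a two-class
mixture: "homozygous" with likelihood `max(L_MM, L_mm)` and "heterozygous"
with likelihood `L_Mm`. An EM over the mixture weight runs in 1 Mb windows
to a tolerance of 1e-8 (initialized at (0.999, 0.001) because heterozygous
sites are rare; a flat initialization converges to the same answer, slower).
Windows with fewer than 10% informative sites are dropped, and the
per-individual value is the site-weighted mean over windows (window size is
the only documented upstream choice; the weighting is ours).

The `max()` folding convention matters. It is the documented design choice
here, but it makes the site likelihood an approximation rather than the
exact marginal: a heterozygous site at depth `d` whose reads happen to show
only one allele (probability `2^(1-d)`) is scored as a confident homozygote.
The resulting downward bias has magnitude roughly
`1 - E[1 - 2^(1-d)] / E[1 - 2^(-d)]` under Poisson depth — about 20% at 3x,
under 1% above 12x — and vanishing as depth grows. Sequencing errors push
the other way: an erroneous read at depth 2–4 makes the heterozygous class
much more likely, inflating estimates when true heterozygosity is small
relative to the error rate. Which effect wins depends on the ratio of
heterozygosity to error rate; for a high-diversity genome (around 0.02
per site at e = 0.001) the deficit dominates and estimates decrease
monotonically with falling coverage, which is the regime the calibration
demonstrations use. This estimator-level bias is precisely what the
downsampling calibration measures and removes; it is not patched inside the
estimator itself.

## Downsampling calibration

One high-coverage individual is downsampled to 25%, 40%, 50%, 60% and 80%
of its reads, three independent replicates each — 15 downsampled datasets —
and heterozygosity is re-estimated on each. Relative heterozygosity
(downsampled / full) against achieved coverage is fitted with a least-squares
polynomial (degree 3 for contemporary-style data, 2 for historic-style).
The fit is *anchored*: it uses the basis `(coverage^k - reference^k)` with
response `(relative - 1)`, so the prediction at the reference coverage is
exactly 1 and correction at full coverage is the identity. Corrections
divide the raw estimate by the predicted relative heterozygosity, with
predictions clipped below at 0.05 and an extrapolation guard refusing
coverages outside [0.5 x min fitted, 1.5 x reference].

Published correction polynomials for the original koala dataset are shipped
via `calibration_presets()` but never applied by default: evaluated at their
own reference coverage they do not return 1, so their normalization cannot
be reconstructed from the printed coefficients alone. A freshly fitted curve
is always the supported path.

## Runs of homozygosity and inbreeding ages

ROH are called PLINK-style: a 50-SNP window slides along each scaffold; a
window is homozygous if it has at most 1 heterozygous and at most 5 missing
calls; a SNP qualifies when at least 5% of windows covering it are
homozygous; qualifying SNPs join into segments unless separated by more than
1000 kb, and segments must hold at least 50 SNPs, span at least 1000 kb, and
average no more than 50 kb per SNP. Only the three parameters named in the
source protocol were specified; the rest are pinned to PLINK 1.9's
documented defaults, the only reproducible choice. Coordinates are 1-based
inclusive with length `end - start + 1` (the `.hom` convention).

FROH divides the summed length of segments exceeding 1 Mb on scaffolds
longer than 10 Mb by the total length of those scaffolds. Segments bin into
the classes [0.5, 1), [1, 2), [2, 5), [5, 10), [10, Inf) Mb —
lower-inclusive, since the conventional class labels overlap at their
boundaries and a convention had to be chosen.

Ages: with recombination rate `r` (cM/Mb) and length `L` (Mb), the
literature formula is `g = 100 / (2 r L)` generations. The conventional
class ages in this literature (200 generations at 0.5 Mb, 100 at 1 Mb, 50
at 2 Mb, 20 at 5 Mb, 10 at 10 Mb) instead satisfy `g = 100 / (r L)`. Both
conventions are implemented — `"stated"` and `"as_applied"` (default, which
reproduces the class ages) — and never silently blended. ROH scanning
requires a SNP-ascertained map: run it on segregating sites at realistic
density (the workflow uses ~5 kb spacing), not on an all-sites panel.

## Mitochondrial haplotypes

Aligned mitogenomes are collapsed to haplotypes after masking columns with
more than the tolerated fraction of gaps/Ns (default 0.2) and excluding
sequences still incomplete after masking. Haplotype diversity uses Nei's
corrected form `Hd = n/(n-1) (1 - sum p_i^2)` with `p_i` the haplotype
relative frequencies. The epoch comparison permutes epoch labels among
pooled individuals (the permutation unit is the individual, preserving group
sizes), recomputes `delta Hd` each time, and reports the add-one p-value
`(1 + #extreme) / (1 + permutations)`, two-sided by default with 10,000
permutations. None of these choices were specified upstream; all are
documented here. Note the test's power: with five haplotypes at frequencies
like (.40, .30, .15, .10, .05) and groups of 25–30, losing the two rarest
haplotypes shifts expected Hd by only ~0.09 while sample Hd varies by a
similar amount, so the two-sided test rejects in only about 20% of
replicates. Detecting subtle diversity loss needs larger samples or more
haplotypes; the test itself is exactly calibrated under the null (verified
by simulation against U(0,1)).

Median-joining networks follow Bandelt's algorithm at epsilon = 0: a minimum
spanning network (every edge participating in some minimum spanning tree
under Hamming distance) is augmented, one vector at a time, with the
column-majority median of connected node triplets whenever it shortens the
spanning tree, and unobserved nodes of degree < 3 are pruned. Median ties
resolve toward the first sequence of the triplet, deterministically. Larger
epsilon and quasi-median refinements are out of scope.

## Population structure from genotype likelihoods

The covariance between individuals is computed from posterior mean
minor-allele doses under Hardy–Weinberg priors at the estimated site
frequencies, standardized per site (`(E - 2f) / sqrt(2f(1-f))`), averaging
over sites with f in [0.05, 0.95]; PCA is its spectral decomposition with
scores scaled by the square root of the eigenvalue. Admixture proportions
use the NGSadmix model — dose frequency `h_is = sum_k q_ik f_ks`, binomial
genotype priors, GL-weighted EM updates of Q and F — with F clipped to
[1e-5, 1 - 1e-5] each update to avoid boundary absorption. "100 iterations"
in the source protocol is read as 100 independent random starts keeping the
highest-likelihood run (that is standard NGSadmix usage, and matches
"selected the highest log-likelihood run"); the workflow and tests use
10–20 starts, which suffice at their problem sizes. After subsetting
individuals, site filters are re-applied rather than reused.

## The synthetic-data generator

Every stage is validated against data with known truth. The generator
emulates:

* two epochs separated by a bottleneck: ancestral minor allele frequencies
  from a neutral-like 1/x density truncated to [1/2N, 1 - 1/2N] (2N = 100,
  avoiding zero-frequency sites), with a site polymorphic with the
  probability that makes expected per-site heterozygosity equal `theta`
  (default 0.00144, the published historic epoch mean); contemporary
  frequencies derived by binomial drift through an effective founder-copy
  number, randomized-rounded so expected heterozygosity is multiplied by
  `bottleneck_factor` exactly (default 0.3, the published
  contemporary/historic ratio);
* sequencing: Poisson depth (defaults 5x historic, 12x contemporary),
  uniform base error (default 0.001, the Q30 scale), and strand-collapsed
  constant-rate damage (C>T and G>A, default 0.02) in historic libraries
  only — constant along the read, not end-weighted, because every
  downstream filter acts on transitions regardless of position and the
  constant model keeps expectations analytic;
* inbreeding: non-overlapping autozygous tracts drawn from the standard
  length classes, planted to a target FROH with one haplotype allele per
  site drawn from local frequencies;
* mitochondria: haplotypes mutated along a random coalescent genealogy,
  epoch frequency vectors Dirichlet-distributed, with the contemporary
  epoch optionally dropping the rarest haplotypes.

It does **not** emulate linkage (sites are independent except planted
tracts), selection, end-weighted damage profiles, mapping artifacts,
reference bias, or disease-driven mortality. Passing tests therefore show
that the estimators are correct under their stated models at realistic
parameter values — not that real museum data meet those models.

## Numerical choices and problem sizes

EM tolerances: 1e-6 on allele frequencies, 1e-8 on heterozygosity (matching
the upstream tool's setting), 1e-4 on admixture log-likelihood. Error-free
models floor e at 1e-12 to keep log-likelihoods finite. Degenerate inputs:
zero-coverage pileups give flat triplets; all-flat windows return the
initialization with an `uninformative` flag; empty filter results warn
rather than error; a single haplotype yields a one-node network.

The test-suite and acceptance problem sizes — 2e4–1e5 sites, 2–40
individuals, 50 seeds for Monte-Carlo directionality, 1000 replicates for
permutation calibration — were chosen so each check resolves its expected
effect well above sampling noise on a single CPU in minutes; larger runs
change none of the conclusions, only the error bars.

## Known limitations

* The folded two-class estimator's bias curve is not monotone across the
  whole coverage range: above ~7x it sits within ±1% of 1 with a small
  error-driven bump, so fitted calibration curves are guaranteed monotone
  only over the region where they indicate a deficit.
* The downsampling correction transfers between individuals only insofar as
  their error and damage profiles match the calibration individual's.
* The admixture EM is a plain (unaccelerated) EM; for tens of thousands of
  sites and many starts it is slower than specialized native
  implementations, though identical in model.
* FROH from planted-truth simulations is recovered within ±0.02–0.03; real
  callsets add genotyping error the scan's window tolerances only partly
  absorb.
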
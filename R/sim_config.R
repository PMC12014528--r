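#' Simulation configuration for the two-epoch synthetic dataset
#'
#' Bundles and validates all parameters of the synthetic-data generator.
#' Defaults emulate the koala temporal study conditions: a historic (museum)
#' and a contemporary epoch separated by a diversity bottleneck, per-site
#' heterozygosity on the order of 1e-3 before the bottleneck, low-to-medium
#' sequencing coverage, sequencing error, and post-mortem C>T / G>A damage in
#' the historic epoch only.
#'
#' @param n_historic,n_contemporary Number of diploid individuals per epoch.
#' @param n_sites Number of assayed sites (variable and invariant) spread over
#'   the scaffolds.
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_length Length of each scaffold in bp.
#' @param theta Expected per-site heterozygosity before the bottleneck.
#' @param bottleneck_factor Multiplicative reduction of expected heterozygosity
#'   between epochs, in (0, 1]. 1 means no bottleneck.
#' @param coverage_historic,coverage_contemporary Mean sequencing depth per
#'   epoch (x).
#' @param error_rate Per-base sequencing error probability.
#' @param damage_rate Excess probability that a true C is read as T (and a true
#'   G as A; strand-collapsed), applied to historic libraries.
#' @param mu Per-site per-generation mutation rate (used for age scalings).
#' @param generation_time Generation time in years.
#' @param two_n SFS truncation parameter: allele frequencies are drawn from a
#'   1/x density truncated to \[1/two_n, 1 - 1/two_n\].
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_historic = 20,
                       n_contemporary = 20,
                       n_sites = 20000,
                       n_scaffolds = 2,
                       scaffold_length = 5e6,
                       theta = 0.00144,
                       bottleneck_factor = 0.3,
                       coverage_historic = 5,
                       coverage_contemporary = 12,
                       error_rate = 0.001,
                       damage_rate = 0.02,
                       mu = 1.905e-8,
                       generation_time = 6,
                       two_n = 100,
                       seed = 1L) {
  cfg <- list(
    n_historic = as.integer(n_historic),
    n_contemporary = as.integer(n_contemporary),
    n_sites = as.integer(n_sites),
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_length = as.numeric(scaffold_length),
    theta = as.numeric(theta),
    bottleneck_factor = as.numeric(bottleneck_factor),
    coverage_historic = as.numeric(coverage_historic),
    coverage_contemporary = as.numeric(coverage_contemporary),
    error_rate = as.numeric(error_rate),
    damage_rate = as.numeric(damage_rate),
    mu = as.numeric(mu),
    generation_time = as.numeric(generation_time),
    two_n = as.numeric(two_n),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_historic >= 1, cfg$n_contemporary >= 1,
    cfg$n_scaffolds >= 1, cfg$scaffold_length >= 1
  )
  if (cfg$n_sites < 1) stop("n_sites must be strictly positive")
  if (!(cfg$bottleneck_factor > 0 && cfg$bottleneck_factor <= 1)) {
    stop("bottleneck_factor must be in (0, 1]")
  }
  for (p in c("theta", "error_rate", "damage_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$coverage_historic < 0 || cfg$coverage_contemporary < 0) {
    stop("coverage must be non-negative")
  }
  if (cfg$n_sites > cfg$n_scaffolds * cfg$scaffold_length) {
    stop("n_sites exceeds total scaffold length")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_historic, "historic +", x$n_contemporary, "contemporary individuals,",
      x$n_sites, "sites on", x$n_scaffolds, "scaffold(s) of",
      format(x$scaffold_length, big.mark = ","), "bp\n")
  cat("  theta =", x$theta, " bottleneck_factor =", x$bottleneck_factor,
      " coverage =", x$coverage_historic, "/", x$coverage_contemporary, "x\n")
  cat("  error_rate =", x$error_rate, " damage_rate =", x$damage_rate,
      " seed =", x$seed, "\n")
  invisible(x)
}
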
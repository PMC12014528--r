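#' @export
print.erosion_pileup <- function(x, ...) {
  cat("erosion_pileup:", length(x$pos), "sites x", dim(x$counts)[2],
      "individuals, mean depth", signif(mean(pileup_depth(x)), 4),
      "x, base quality Q", round(x$qual), "\n")
  invisible(x)
}

#' Per-individual mean depth of a pileup
#' @param pileup An `erosion_pileup`.
#' @return Named numeric vector of mean depth per individual.
#' @export
pileup_coverage <- function(pileup) {
  colMeans(pileup_depth(pileup))
}

# sites x individuals depth matrix
pileup_depth <- function(pileup) {
  apply(pileup$counts, c(1, 2), sum)
}

#' Randomly thin a pileup to a fraction of its reads
#'
#' Each read is retained independently with probability `fraction`, emulating
#' samtools-style downsampling used to calibrate coverage bias.
#'
#' @param pileup An `erosion_pileup`.
#' @param fraction Retention probability in (0, 1]; 1 returns the input
#'   unchanged.
#' @param seed Integer seed.
#' @return The thinned `erosion_pileup`.
#' @export
downsample_pileup <- function(pileup, fraction, seed = 1L) {
  stopifnot(inherits(pileup, "erosion_pileup"))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(pileup)
  withr::with_seed(as.integer(seed), {
    k <- pileup$counts
    k[] <- stats::rbinom(length(k), as.vector(k), fraction)
    pileup$counts <- k
    pileup
  })
}

#' Extract a single-individual pileup
#' @param pileup An `erosion_pileup`.
#' @param individual Individual id or index.
#' @return An `erosion_pileup` with one individual.
#' @export
pileup_subset <- function(pileup, individual) {
  idx <- if (is.character(individual)) {
    match(individual, dimnames(pileup$counts)[[2]])
  } else individual
  if (anyNA(idx)) stop("unknown individual: ", individual)
  pileup$counts <- pileup$counts[, idx, , drop = FALSE]
  pileup$individuals <- pileup$individuals[idx, , drop = FALSE]
  pileup
}
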
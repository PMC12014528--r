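#' Estimate the per-base sequencing error rate from a haploid reference
#'
#' Every read base aligned to a haploid sequence (here: the mitochondrial
#' consensus) that disagrees with the consensus is an error, so the
#' mismatch fraction among bases passing the quality filter estimates the
#' per-base error rate directly. A transversion-only variant counts only
#' transversion mismatches and rescales by 3/2 (two of the three possible
#' erroneous bases are transversions) to a per-base rate robust to
#' post-mortem C>T / G>A damage.
#'
#' @param bases Character vector of observed read bases (A/C/G/T).
#' @param quals Numeric Phred qualities, same length.
#' @param ref Character vector of haploid consensus bases, same length.
#' @param min_quality Minimum base quality (default 30).
#' @return List of class `error_model` with elements `e` (error rate),
#'   `e_tv` (transversion-only estimate), `n_bases`, `min_quality`.
#' @export
estimate_error_rate_from_haploid <- function(bases, quals, ref,
                                             min_quality = 30) {
  stopifnot(length(bases) == length(quals), length(bases) == length(ref))
  keep <- quals >= min_quality
  if (!any(keep)) stop("no bases pass the quality filter")
  b <- bases[keep]; r <- ref[keep]
  mism <- b != r
  e <- mean(mism)
  tv <- mism & !is_transition(b, r)
  e_tv <- mean(tv) * 3 / 2
  error_model(e, e_tv = e_tv, n_bases = length(b), min_quality = min_quality)
}

#' Construct an error model
#' @param e Per-base error probability, in \[0, 0.75\].
#' @param e_tv Optional transversion-only error rate.
#' @param n_bases,min_quality Provenance of the estimate (optional).
#' @return List of class `error_model`.
#' @export
error_model <- function(e, e_tv = NULL, n_bases = NA_integer_,
                        min_quality = NA_real_) {
  if (e < 0 || e > 0.75) stop("error rate must be in [0, 0.75]")
  structure(list(e = e, e_tv = e_tv, n_bases = n_bases,
                 min_quality = min_quality), class = "error_model")
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Compute genotype likelihoods from a pileup
#'
#' For genotype (a1, a2) the likelihood is the product over reads of
#' \[P(b|a1) + P(b|a2)\]/2 with P(b|a) = 1 - e if b = a, else e/3. The major
#' and minor allele at each site are the two highest-count alleles across all
#' individuals, ties broken by base order A < C < G < T. Individuals with no
#' reads carry a flat triplet. Triplets are stored log-scaled and normalized
#' so the per-individual maximum is 1 on the linear scale.
#'
#' @param pileup An `erosion_pileup`.
#' @param error_model An [error_model()].
#' @return Object of class `erosion_gl`: site table (scaffold, pos, major,
#'   minor), `loglik` array (sites x individuals x 3 genotypes
#'   major/major, major/minor, minor/minor), `has_data` logical matrix,
#'   `maf` (NA until [estimate_maf_em()]).
#' @export
call_genotype_likelihoods <- function(pileup, error_model) {
  stopifnot(inherits(pileup, "erosion_pileup"),
            inherits(error_model, "error_model"))
  e <- error_model$e
  if (e >= 0.75) stop("error rate must be < 0.75")
  S <- dim(pileup$counts)[1]
  N <- dim(pileup$counts)[2]
  tot <- apply(pileup$counts, c(1, 3), sum)          # S x 4 allele counts
  major_i <- max.col(tot, ties.method = "first")
  tot2 <- tot
  tot2[cbind(seq_len(S), major_i)] <- -1L
  minor_i <- max.col(tot2, ties.method = "first")

  loglik <- gl_from_counts(pileup$counts, major_i, minor_i, e)
  has_data <- apply(pileup$counts, c(1, 2), sum) > 0L

  structure(list(
    scaffold = pileup$scaffold,
    pos = pileup$pos,
    major = BASES[major_i],
    minor = BASES[minor_i],
    loglik = loglik,
    has_data = has_data,
    maf = rep(NA_real_, S),
    individuals = pileup$individuals
  ), class = "erosion_gl")
}

# core GL kernel: counts S x N x 4, per-site allele index vectors
gl_from_counts <- function(counts, major_i, minor_i, e) {
  e <- max(e, 1e-12)      # keep log-likelihoods finite for error-free models
  S <- dim(counts)[1]; N <- dim(counts)[2]
  loglik <- array(0, c(S, N, 3))
  pmatch_ <- function(b_i, a_i) ifelse(b_i == a_i, 1 - e, e / 3)
  for (g in 1:3) {
    # per-site log emission prob of each of the 4 bases under genotype g
    lp <- matrix(0, S, 4)
    for (b in 1:4) {
      a1 <- if (g <= 2) major_i else minor_i
      a2 <- if (g >= 2) minor_i else major_i
      lp[, b] <- log((pmatch_(b, a1) + pmatch_(b, a2)) / 2)
    }
    acc <- matrix(0, S, N)
    for (b in 1:4) acc <- acc + counts[, , b] * lp[, b]   # column recycling
    loglik[, , g] <- acc
  }
  mx <- pmax(loglik[, , 1], loglik[, , 2], loglik[, , 3])
  for (g in 1:3) loglik[, , g] <- loglik[, , g] - mx
  dimnames(loglik) <- list(NULL, dimnames(counts)[[2]],
                           c("MM", "Mm", "mm"))
  loglik
}

# drop-safe extraction of one genotype layer as an S x N matrix
lin_slice <- function(A, g) matrix(A[, , g], dim(A)[1], dim(A)[2])

#' EM estimate of the per-site minor allele frequency from genotype likelihoods
#'
#' Maximizes the marginal likelihood sum_i log sum_g L_ig P(g|f) under
#' Hardy-Weinberg genotype priors by EM over all sites simultaneously.
#' Frequencies above 0.5 are folded (major/minor swapped in the returned
#' object) so f lies in \[0, 0.5\].
#'
#' @param gl An `erosion_gl`.
#' @param tol Convergence tolerance on max |delta f| (default 1e-6).
#' @param max_iter Maximum EM iterations.
#' @param trace If TRUE, attach the per-iteration total log-likelihood as
#'   attribute `ll_trace` (for diagnostics).
#' @return The `erosion_gl` with `maf` filled in (and major/minor re-polarized
#'   where folding was needed).
#' @export
estimate_maf_em <- function(gl, tol = 1e-6, max_iter = 200, trace = FALSE) {
  stopifnot(inherits(gl, "erosion_gl"))
  S <- dim(gl$loglik)[1]; N <- dim(gl$loglik)[2]
  L0 <- lin_slice(exp(gl$loglik), 1)
  L1 <- lin_slice(exp(gl$loglik), 2)
  L2 <- lin_slice(exp(gl$loglik), 3)
  f <- rep(0.2, S)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    P0 <- (1 - f)^2; P1 <- 2 * f * (1 - f); P2 <- f^2
    w0 <- L0 * P0; w1 <- L1 * P1; w2 <- L2 * P2
    den <- w0 + w1 + w2
    if (trace) ll_trace <- c(ll_trace, sum(log(pmax(den, 1e-300))))
    dose <- (w1 + 2 * w2) / pmax(den, 1e-300)
    f_new <- rowSums(dose) / (2 * N)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  # fold to minor allele frequency
  swap <- which(f > 0.5)
  if (length(swap)) {
    f[swap] <- 1 - f[swap]
    tmp <- gl$major[swap]
    gl$major[swap] <- gl$minor[swap]
    gl$minor[swap] <- tmp
    gl$loglik[swap, , ] <- gl$loglik[swap, , 3:1]
  }
  gl$maf <- f
  if (trace) attr(gl, "ll_trace") <- ll_trace
  gl
}

#' SNP likelihood-ratio test against monomorphism
#'
#' Tests f = 0 against the EM estimate with the statistic
#' 2\[l(f_hat) - l(0)\] referred to a 1-df chi-square upper tail. Sites with
#' f_hat = 0 get p = 1 (boundary convention).
#'
#' @param gl An `erosion_gl` with `maf` estimated.
#' @return Numeric vector of per-site p-values.
#' @export
snp_lrt <- function(gl) {
  stopifnot(inherits(gl, "erosion_gl"))
  if (anyNA(gl$maf)) stop("run estimate_maf_em first")
  L0 <- lin_slice(exp(gl$loglik), 1)
  L1 <- lin_slice(exp(gl$loglik), 2)
  L2 <- lin_slice(exp(gl$loglik), 3)
  ll_at <- function(f) {
    den <- L0 * (1 - f)^2 + L1 * 2 * f * (1 - f) + L2 * f^2
    rowSums(log(pmax(den, 1e-300)))
  }
  stat <- pmax(0, 2 * (ll_at(gl$maf) - ll_at(0)))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[gl$maf == 0] <- 1
  p
}

#' Apply the site filters used for structure analyses
#'
#' Retains sites with minor allele frequency >= `min_maf`, SNP
#' likelihood-ratio p <= `snp_p`, at least `min_ind` individuals with data
#' (>= 1 read), and - if `rm_transitions` - a major/minor pair that is not a
#' transition (A/G or C/T), guarding against post-mortem damage. The
#' transversion filter is applied after major/minor inference, before the
#' frequency thresholds. Site order is preserved.
#'
#' @param gl An `erosion_gl` (maf estimated with [estimate_maf_em()] if
#'   missing).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @param snp_p Maximum SNP LRT p-value (default 1e-6).
#' @param min_ind Minimum number of individuals with data (default half).
#' @param rm_transitions Drop transition sites (default TRUE).
#' @return The filtered `erosion_gl`; warns (not errors) when empty.
#' @export
filter_sites <- function(gl, min_maf = 0.05, snp_p = 1e-6,
                         min_ind = ceiling(dim(gl$loglik)[2] / 2),
                         rm_transitions = TRUE) {
  stopifnot(inherits(gl, "erosion_gl"))
  if (anyNA(gl$maf)) gl <- estimate_maf_em(gl)
  keep <- rep(TRUE, length(gl$pos))
  if (rm_transitions) keep <- keep & !is_transition(gl$major, gl$minor)
  keep <- keep & gl$maf >= min_maf
  p <- snp_lrt(gl)
  keep <- keep & p <= snp_p
  keep <- keep & rowSums(gl$has_data) >= min_ind
  if (!any(keep)) warning("no sites survive the filters")
  gl_subset_sites(gl, which(keep))
}

gl_subset_sites <- function(gl, idx) {
  gl$scaffold <- gl$scaffold[idx]
  gl$pos <- gl$pos[idx]
  gl$major <- gl$major[idx]
  gl$minor <- gl$minor[idx]
  gl$loglik <- gl$loglik[idx, , , drop = FALSE]
  gl$has_data <- gl$has_data[idx, , drop = FALSE]
  gl$maf <- gl$maf[idx]
  gl
}

#' @export
print.erosion_gl <- function(x, ...) {
  cat("erosion_gl:", length(x$pos), "sites x", dim(x$loglik)[2],
      "individuals;", sum(!is.na(x$maf)), "sites with MAF estimates\n")
  invisible(x)
}
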
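#' Fold a genotype-likelihood triplet into the two site classes
#'
#' The folded representation keeps only "homozygous" (the larger of the two
#' homozygote likelihoods) versus "heterozygous" (the major/minor
#' likelihood). This is what the per-individual windowed heterozygosity EM
#' consumes.
#'
#' @param triplet Numeric length-3 linear-scale likelihoods (MM, Mm, mm), or
#'   an S x 3 matrix.
#' @return Length-2 vector (hom, het), or S x 2 matrix.
#' @export
site_het_likelihood <- function(triplet) {
  if (is.matrix(triplet)) {
    cbind(hom = pmax(triplet[, 1], triplet[, 3]), het = triplet[, 2])
  } else {
    c(hom = max(triplet[1], triplet[3]), het = triplet[2])
  }
}

#' EM estimate of heterozygosity from folded two-class site likelihoods
#'
#' Fits the mixture proportion (p_hom, p_het) over sites by EM:
#' p_k <- (1/S) sum_s p_k L_sk / sum_j p_j L_sj, iterated until
#' max |delta p| < `tol`. The observed-data log-likelihood is non-decreasing.
#' Initialization is (0.999, 0.001) - heterozygous sites are rare.
#'
#' @param lik S x 2 matrix of (hom, het) linear-scale likelihoods.
#' @param tol Convergence tolerance (default 1e-8).
#' @param max_iter Maximum iterations (default 2000).
#' @param trace Attach per-iteration log-likelihood as attribute `ll_trace`.
#' @return The heterozygous proportion p_het, with attribute `uninformative`
#'   TRUE (returning the initialization) when every site is flat.
#' @export
estimate_heterozygosity_em <- function(lik, tol = 1e-8, max_iter = 2000,
                                       trace = FALSE) {
  stopifnot(is.matrix(lik), ncol(lik) == 2)
  if (nrow(lik) < 1) stop("need at least one site")
  # scale rows to max 1 for numerical stability (does not change the MLE)
  mx <- pmax(lik[, 1], lik[, 2])
  ok <- mx > 0
  lik <- lik[ok, , drop = FALSE] / mx[ok]
  init <- 0.001
  if (nrow(lik) == 0 || all(lik[, 1] == lik[, 2])) {
    out <- init
    attr(out, "uninformative") <- TRUE
    return(out)
  }
  p <- init
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    den <- (1 - p) * lik[, 1] + p * lik[, 2]
    if (trace) ll_trace <- c(ll_trace, sum(log(pmax(den, 1e-300))))
    w <- p * lik[, 2] / pmax(den, 1e-300)
    p_new <- mean(w)
    if (abs(p_new - p) < tol) { p <- p_new; break }
    p <- p_new
  }
  out <- p
  attr(out, "uninformative") <- FALSE
  if (trace) attr(out, "ll_trace") <- ll_trace
  out
}

# Per-site folded likelihoods for one individual directly from its pileup
# counts: the candidate allele pair is the individual's two highest-count
# bases (ties by base order); with a single observed base the pair is that
# base plus the first other base (the het likelihood does not depend on
# which, given the error model is base-symmetric). With transversions_only,
# sites whose allele pair is a transition (A/G, C/T) are flattened to
# (1, 1) - excluded as uninformative - which removes post-mortem C>T / G>A
# damage artifacts at the cost of assaying only transversion heterozygosity.
individual_fold_likelihoods <- function(pileup, individual, error_model,
                                        transversions_only = FALSE) {
  pu <- pileup_subset(pileup, individual)
  counts <- pu$counts[, 1, , drop = TRUE]
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 4)
  S <- nrow(counts)
  a1 <- max.col(counts, ties.method = "first")
  c2 <- counts
  c2[cbind(seq_len(S), a1)] <- -1L
  a2 <- max.col(c2, ties.method = "first")
  arr <- array(counts, c(S, 1, 4))
  ll <- matrix(gl_from_counts(arr, a1, a2, error_model$e), S, 3)
  fl <- site_het_likelihood(exp(ll))
  if (transversions_only) {
    ts <- is_transition(BASES[a1], BASES[a2])
    fl[ts, 1] <- 1
    fl[ts, 2] <- 1
  }
  fl
}

#' Windowed per-individual heterozygosity from a pileup
#'
#' Runs the folded two-class EM in non-overlapping windows along each
#' scaffold and aggregates to a per-individual genome-wide value as the
#' site-weighted mean over retained windows. Windows in which fewer than
#' `min_informative` of sites are informative (covered and not flat) are
#' dropped.
#'
#' @param pileup An `erosion_pileup`.
#' @param error_model An [error_model()].
#' @param window_size Window size in bp (default 1e6; `Inf` = one window per
#'   scaffold).
#' @param min_informative Minimum informative-site fraction per window
#'   (default 0.1).
#' @param transversions_only Assay only transversion heterozygosity
#'   (sites whose allele pair is a transition are treated as uninformative),
#'   guarding against post-mortem damage in historic libraries.
#' @param tol,max_iter Passed to [estimate_heterozygosity_em()].
#' @return List with `windows` (data frame: id, scaffold, start, end,
#'   n_sites, het, coverage) and `individual` (data frame: id, coverage,
#'   het_raw) where het_raw is the site-weighted mean.
#' @export
estimate_heterozygosity <- function(pileup, error_model, window_size = 1e6,
                                    min_informative = 0.1,
                                    transversions_only = FALSE,
                                    tol = 1e-8, max_iter = 2000) {
  stopifnot(inherits(pileup, "erosion_pileup"))
  ids <- pileup$individuals$id
  cov <- pileup_coverage(pileup)
  win_id <- paste(pileup$scaffold,
                  if (is.finite(window_size)) {
                    (pileup$pos - 1) %/% window_size
                  } else 0L)
  rows <- list()
  for (id in ids) {
    fl <- individual_fold_likelihoods(pileup, id, error_model,
                                      transversions_only = transversions_only)
    informative <- fl[, 1] != fl[, 2]
    for (w in unique(win_id)) {
      sel <- win_id == w
      if (mean(informative[sel]) < min_informative) next
      het <- estimate_heterozygosity_em(fl[sel, , drop = FALSE],
                                        tol = tol, max_iter = max_iter)
      rows[[length(rows) + 1]] <- data.frame(
        id = id,
        scaffold = pileup$scaffold[sel][1],
        start = min(pileup$pos[sel]),
        end = max(pileup$pos[sel]),
        n_sites = sum(sel),
        het = as.numeric(het),
        stringsAsFactors = FALSE
      )
    }
  }
  windows <- do.call(rbind, rows)
  if (is.null(windows)) {
    windows <- data.frame(id = character(), scaffold = character(),
                          start = numeric(), end = numeric(),
                          n_sites = integer(), het = numeric())
  }
  agg <- lapply(split(windows, windows$id), function(d) {
    data.frame(id = d$id[1],
               het_raw = sum(d$het * d$n_sites) / sum(d$n_sites))
  })
  individual <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  if (is.null(individual)) {
    individual <- data.frame(id = character(), het_raw = numeric())
  }
  individual$coverage <- cov[individual$id]
  list(windows = windows, individual = individual)
}

#' Build a coverage-bias calibration curve by downsampling
#'
#' Downsamples one high-coverage individual to each fraction, re-estimates
#' heterozygosity, records the relative heterozygosity (downsampled /
#' full-coverage estimate), and fits a least-squares polynomial of the given
#' degree to (achieved coverage, relative heterozygosity). The fit is
#' anchored so the prediction at the full (reference) coverage is exactly 1:
#' the polynomial is fitted without intercept on the basis
#' (coverage^k - reference^k) with response (relative - 1). With the default
#' design (5 fractions x 3 replicates) the curve is supported by 15
#' downsampled datasets per individual.
#'
#' @param pileup Single- or multi-individual `erosion_pileup`.
#' @param individual Which individual to calibrate on.
#' @param error_model An [error_model()].
#' @param fractions Downsampling fractions (default c(.25, .4, .5, .6, .8)).
#' @param replicates Independent replicates per fraction (default 3).
#' @param degree Polynomial degree (3 for contemporary-style, 2 for
#'   historic-style curves).
#' @param seed Integer seed.
#' @param window_size Passed to [estimate_heterozygosity()].
#' @return Object of class `calibration_curve`: `degree`, `coefficients`
#'   (highest order first, standard polynomial form), `reference_coverage`,
#'   `het_full`, and the `support` table (fraction, replicate, coverage,
#'   rel_het).
#' @export
build_calibration_curve <- function(pileup, individual, error_model,
                                    fractions = c(0.25, 0.4, 0.5, 0.6, 0.8),
                                    replicates = 3, degree = 3, seed = 1L,
                                    window_size = Inf) {
  stopifnot(inherits(pileup, "erosion_pileup"))
  if (length(fractions) < 2) stop("degenerate design: need >= 2 fractions")
  pu <- pileup_subset(pileup, individual)
  full <- estimate_heterozygosity(pu, error_model, window_size = window_size)
  het_full <- full$individual$het_raw[1]
  ref_cov <- full$individual$coverage[1]
  if (!is.finite(het_full) || het_full <= 0) {
    stop("full-coverage heterozygosity estimate is degenerate")
  }
  support <- expand.grid(fraction = fractions, replicate = seq_len(replicates))
  support$coverage <- NA_real_
  support$rel_het <- NA_real_
  for (j in seq_len(nrow(support))) {
    ds <- downsample_pileup(pu, support$fraction[j],
                            seed = as.integer(seed) * 1000L + j)
    est <- estimate_heterozygosity(ds, error_model, window_size = window_size)
    support$coverage[j] <- est$individual$coverage[1]
    support$rel_het[j] <- est$individual$het_raw[1] / het_full
  }
  # anchored polynomial fit: prediction at ref_cov is exactly 1
  X <- outer(support$coverage, seq_len(degree), `^`) -
       matrix(rep(ref_cov^seq_len(degree), each = nrow(support)),
              nrow(support), degree)
  beta <- stats::lm.fit(X, support$rel_het - 1)$coefficients
  beta[is.na(beta)] <- 0
  coef_std <- c(rev(beta), 1 - sum(beta * ref_cov^seq_len(degree)))
  structure(list(
    degree = degree,
    coefficients = unname(coef_std),     # highest order first
    reference_coverage = ref_cov,
    het_full = het_full,
    support = support,
    individual = individual
  ), class = "calibration_curve")
}

#' Predict relative heterozygosity at a coverage from a calibration curve
#' @param curve A `calibration_curve`.
#' @param coverage Coverage values (x).
#' @return Predicted relative heterozygosity (unclipped).
#' @export
predict_relative_het <- function(curve, coverage) {
  stopifnot(inherits(curve, "calibration_curve"))
  k <- rev(seq_along(curve$coefficients)) - 1
  colSums(curve$coefficients * t(outer(coverage, k, `^`)))
}

#' Correct a raw heterozygosity estimate for coverage bias
#'
#' Divides the raw estimate by the predicted relative heterozygosity at the
#' sample's coverage. Predictions are clipped below at 0.05 to avoid
#' explosion; coverage outside
#' \[0.5 x min fitted coverage, 1.5 x reference coverage\] is refused
#' (extrapolation guard).
#'
#' @param raw Raw heterozygosity.
#' @param coverage Coverage of the sample (x).
#' @param curve A `calibration_curve`.
#' @return Corrected heterozygosity.
#' @export
apply_correction <- function(raw, coverage, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  lo <- 0.5 * min(curve$support$coverage)
  hi <- 1.5 * curve$reference_coverage
  if (any(coverage < lo | coverage > hi)) {
    stop(sprintf("coverage outside the fitted range [%.3g, %.3g]x", lo, hi))
  }
  pred <- pmax(predict_relative_het(curve, coverage), 0.05)
  raw / pred
}

#' Published coverage-correction polynomial presets
#'
#' The correction formulas reported for the koala temporal dataset
#' (contemporary: cubic in coverage; historic: quadratic) are shipped verbatim
#' as opaque presets. Their coverage normalization is ambiguous (the
#' contemporary cubic does not evaluate to 1 at its own 12.3x reference
#' coverage), so they are never applied by default and no reference coverage
#' is attached; freshly fitted curves from [build_calibration_curve()] are
#' the supported path.
#'
#' @return Named list of coefficient vectors (highest order first).
#' @export
calibration_presets <- function() {
  list(
    contemporary = c(0.0008, -0.0265, 0.2998, 0.2191),
    historic = c(0.0063, -0.1399, 1.781)
  )
}

#' Kruskal-Wallis rank-sum comparison of per-individual heterozygosity
#'
#' Thin wrapper over [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-square approximation with groups - 1 df), the test used
#' for all epoch and population comparisons.
#'
#' @param groups List of numeric vectors (one per group).
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!vapply(groups, length, 1L))) stop("each group needs >= 1 value")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}
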
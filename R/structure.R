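#' Genotype-likelihood covariance matrix between individuals
#'
#' Expected minor-allele doses E\[g | GL, f\] are computed under
#' Hardy-Weinberg priors at the estimated site frequencies, standardized,
#' and averaged over sites:
#' C_ij = (1/L) sum_s (E_is - 2 f_s)(E_js - 2 f_s) / (2 f_s (1 - f_s)).
#' Sites with f outside \[0.05, 0.95\] are excluded.
#'
#' @param gl An `erosion_gl` with `maf` estimated (typically after
#'   [filter_sites()]).
#' @param min_maf Frequency bound for inclusion (default 0.05).
#' @return List of class `gl_covariance`: `C` (n x n), `n_sites` used.
#' @export
gl_covariance <- function(gl, min_maf = 0.05) {
  stopifnot(inherits(gl, "erosion_gl"))
  if (anyNA(gl$maf)) gl <- estimate_maf_em(gl)
  N <- dim(gl$loglik)[2]
  if (N < 2) stop("need at least 2 individuals")
  keep <- gl$maf >= min_maf & gl$maf <= 1 - min_maf
  gl <- gl_subset_sites(gl, which(keep))
  f <- gl$maf
  S <- length(f)
  if (!S) stop("no sites within the frequency bounds")
  L <- exp(gl$loglik)
  L0 <- matrix(L[, , 1], S, N); L1 <- matrix(L[, , 2], S, N)
  L2 <- matrix(L[, , 3], S, N)
  P0 <- (1 - f)^2; P1 <- 2 * f * (1 - f); P2 <- f^2
  w0 <- L0 * P0; w1 <- L1 * P1; w2 <- L2 * P2
  E <- (w1 + 2 * w2) / (w0 + w1 + w2)              # S x N expected dose
  Z <- (E - 2 * f) / sqrt(2 * f * (1 - f))
  C <- crossprod(Z) / S
  dimnames(C) <- list(dimnames(gl$loglik)[[2]], dimnames(gl$loglik)[[2]])
  structure(list(C = C, n_sites = S), class = "gl_covariance")
}

#' Principal component analysis of a covariance matrix
#'
#' Spectral decomposition with eigenvalues in descending order; PC scores
#' are eigenvectors scaled by the square root of their eigenvalue.
#'
#' @param cov A `gl_covariance` or plain symmetric matrix.
#' @return List with `values`, `vectors`, and `scores` (individuals x PCs).
#' @export
pca_covariance <- function(cov) {
  C <- if (inherits(cov, "gl_covariance")) cov$C else cov
  eg <- eigen(C, symmetric = TRUE)
  scores <- sweep(eg$vectors, 2, sqrt(pmax(eg$values, 0)), `*`)
  rownames(scores) <- rownames(C)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(values = eg$values, vectors = eg$vectors, scores = scores)
}

#' Admixture-proportion EM on genotype likelihoods (NGSadmix model)
#'
#' Model: the individual-site minor-allele dose is h_is = sum_k q_ik f_ks;
#' genotypes have binomial(2, h_is) priors and the data enter through the
#' GL triplets. Q (individual ancestry proportions) and F (cluster allele
#' frequencies) are updated by EM until the log-likelihood gain drops below
#' `tol`; the best of `n_starts` random initializations is returned. "100
#' iterations of NGSadmix per K" in the source protocol is read as 100
#' independent random starts, keeping the highest-likelihood run. F is
#' clipped to \[1e-5, 1 - 1e-5\] to avoid boundary absorption.
#'
#' @param gl An `erosion_gl` (filtered, maf estimated).
#' @param K Number of ancestral clusters (1 <= K <= individuals).
#' @param seed Integer seed.
#' @param n_starts Independent random starts (default 100).
#' @param tol Log-likelihood convergence tolerance (default 1e-4).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @return List of class `admixture_fit`: `K`, `Q` (n x K, rows sum to 1),
#'   `F` (K x L), `loglik`, `ll_trace` of the best start, `start_logliks`,
#'   `seed`.
#' @export
admixture_em <- function(gl, K, seed = 1L, n_starts = 100, tol = 1e-4,
                         max_iter = 500) {
  stopifnot(inherits(gl, "erosion_gl"))
  if (anyNA(gl$maf)) gl <- estimate_maf_em(gl)
  L <- exp(gl$loglik)
  S <- dim(L)[1]; N <- dim(L)[2]
  if (K < 1 || K > N) stop("K must be between 1 and the number of individuals")
  L0 <- t(matrix(L[, , 1], S, N))                           # N x S
  L1 <- t(matrix(L[, , 2], S, N))
  L2 <- t(matrix(L[, , 3], S, N))

  run_start <- function() {
    Q <- matrix(stats::rgamma(N * K, 1), N, K)
    Q <- Q / rowSums(Q)
    Fm <- matrix(stats::runif(K * S, 0.05, 0.95), K, S)
    ll_old <- -Inf
    ll_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      H <- Q %*% Fm                                   # N x S minor dose freq
      H <- pmin(pmax(H, 1e-9), 1 - 1e-9)
      pg0 <- (1 - H)^2; pg1 <- 2 * H * (1 - H); pg2 <- H^2
      w0 <- L0 * pg0; w1 <- L1 * pg1; w2 <- L2 * pg2
      den <- w0 + w1 + w2
      ll <- sum(log(pmax(den, 1e-300)))
      ll_trace <- c(ll_trace, ll)
      a <- (w1 + 2 * w2) / pmax(den, 1e-300)          # E[minor count], N x S
      b <- 2 - a                                      # E[major count]
      Am <- a / H                                     # N x S
      Bm <- b / (1 - H)
      Q_new <- matrix(0, N, K); F_num <- matrix(0, K, S); F_den <- matrix(0, K, S)
      for (k in seq_len(K)) {
        qk <- Q[, k]
        e_min <- Am * (qk * matrix(Fm[k, ], N, S, byrow = TRUE))
        e_maj <- Bm * (qk * matrix(1 - Fm[k, ], N, S, byrow = TRUE))
        Q_new[, k] <- rowSums(e_min + e_maj)
        F_num[k, ] <- colSums(e_min)
        F_den[k, ] <- colSums(e_min + e_maj)
      }
      Q <- Q_new / rowSums(Q_new)
      Fm <- pmin(pmax(F_num / pmax(F_den, 1e-300), 1e-5), 1 - 1e-5)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    list(Q = Q, F = Fm, loglik = ll_trace[length(ll_trace)],
         ll_trace = ll_trace)
  }

  withr::with_seed(as.integer(seed), {
    fits <- lapply(seq_len(n_starts), function(i) run_start())
  })
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  best <- fits[[which.max(lls)]]
  rownames(best$Q) <- dimnames(gl$loglik)[[2]]
  structure(list(K = K, Q = best$Q, F = best$F, loglik = best$loglik,
                 ll_trace = best$ll_trace, start_logliks = lls,
                 seed = as.integer(seed)), class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, " best log-likelihood =",
      format(x$loglik, digits = 8), "over", length(x$start_logliks),
      "starts\n")
  invisible(x)
}
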
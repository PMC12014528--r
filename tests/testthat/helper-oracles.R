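# Independent oracles and small fixture builders used across tests.
# Everything here is deliberately naive (loops, grids, enumeration) and
# independent of the package's own implementation paths.

# Build an erosion_gl object directly from a dose matrix with sharp
# (near-certain) likelihoods; ind x sites matrix, values 0/1/2.
make_sharp_gl <- function(dose, scaffold = "scaf001",
                          pos = seq_len(ncol(dose)),
                          major = rep("A", ncol(dose)),
                          minor = rep("C", ncol(dose)),
                          eps = 1e-9) {
  N <- nrow(dose); S <- ncol(dose)
  loglik <- array(log(eps), c(S, N, 3),
                  dimnames = list(NULL,
                                  rownames(dose) %||% sprintf("I%02d", 1:N),
                                  c("MM", "Mm", "mm")))
  for (i in seq_len(N)) {
    loglik[cbind(seq_len(S), i, dose[i, ] + 1L)] <- 0
  }
  structure(list(
    scaffold = rep(scaffold, S), pos = pos,
    major = major, minor = minor,
    loglik = loglik,
    has_data = matrix(TRUE, S, N),
    maf = rep(NA_real_, S),
    individuals = data.frame(id = dimnames(loglik)[[2]], epoch = NA)
  ), class = "erosion_gl")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Marginal per-site log-likelihood of an allele frequency under HW priors,
# written independently of the package internals.
naive_site_ll <- function(lik_triplets, f) {
  # lik_triplets: N x 3 linear likelihoods for one site
  sum(log(lik_triplets[, 1] * (1 - f)^2 +
          lik_triplets[, 2] * 2 * f * (1 - f) +
          lik_triplets[, 3] * f^2))
}

# Grid + golden-section MAF oracle for a single site
oracle_maf <- function(lik_triplets) {
  grid <- seq(0, 1, by = 1e-3)
  ll <- vapply(grid, function(f) naive_site_ll(lik_triplets, f), 0)
  f0 <- grid[which.max(ll)]
  opt <- stats::optimize(function(f) naive_site_ll(lik_triplets, f),
                         c(max(0, f0 - 2e-3), min(1, f0 + 2e-3)),
                         maximum = TRUE, tol = 1e-9)
  opt$maximum
}

# Exhaustive PLINK-style ROH oracle: explicit loops over windows and SNPs.
oracle_roh <- function(g, pos, prm = roh_params()) {
  n <- length(g)
  w <- prm$window_snp
  if (n < w) return(NULL)
  n_win <- n - w + 1
  hom_win <- logical(n_win)
  for (j in seq_len(n_win)) {
    win <- g[j:(j + w - 1)]
    hom_win[j] <- sum(win == 1, na.rm = TRUE) <= prm$window_het &&
                  sum(is.na(win)) <= prm$window_missing
  }
  qual <- logical(n)
  for (i in seq_len(n)) {
    js <- max(1, i - w + 1):min(i, n_win)
    js <- js[js >= 1 & js <= n_win]
    if (!length(js)) { qual[i] <- FALSE; next }
    qual[i] <- mean(hom_win[js]) >= prm$hit_threshold
  }
  idx <- which(qual)
  if (!length(idx)) return(NULL)
  segs <- list()
  cur <- idx[1]
  run <- c(cur)
  for (i in idx[-1]) {
    if (i == run[length(run)] + 1 &&
        pos[i] - pos[run[length(run)]] <= prm$max_gap_kb * 1000) {
      run <- c(run, i)
    } else {
      segs[[length(segs) + 1]] <- run
      run <- i
    }
  }
  segs[[length(segs) + 1]] <- run
  out <- do.call(rbind, lapply(segs, function(ii) {
    data.frame(start = pos[ii[1]], end = pos[ii[length(ii)]],
               n_snps = length(ii),
               length = pos[ii[length(ii)]] - pos[ii[1]] + 1)
  }))
  out <- out[out$n_snps >= w & out$length >= prm$min_kb * 1000 &
             (out$length / 1000) / out$n_snps <= prm$density_kb_per_snp, ,
             drop = FALSE]
  if (nrow(out)) out else NULL
}

# Tie-corrected Kruskal-Wallis H computed from first principles
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Hamming distance between two strings
str_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Total MST length over a set of sequences (igraph, independent of the
# package's internal Kruskal implementation)
oracle_mst_length <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(0)
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- str_hamming(seqs[i], seqs[j])
  }
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g))$weight)
}

# small standard simulated dataset reused by several tests
small_sim <- function(seed = 1, theta = 0.2, b = 0.9, n_sites = 3000,
                      n = 10, coverage = 6) {
  cfg <- sim_config(n_historic = n, n_contemporary = n, n_sites = n_sites,
                    n_scaffolds = 1, scaffold_length = 2e6, theta = theta,
                    bottleneck_factor = b, coverage_historic = coverage,
                    coverage_contemporary = coverage, damage_rate = 0,
                    seed = seed)
  g <- simulate_genotypes(cfg)
  pu <- simulate_reads(g, seed = seed + 1000L)
  list(cfg = cfg, geno = g, pileup = pu, em = error_model(cfg$error_rate))
}
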
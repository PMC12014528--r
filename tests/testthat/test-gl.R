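test_that("haploid-reference error estimation counts mismatches", {
  ref <- rep("A", 100)
  bases <- ref
  expect_identical(estimate_error_rate_from_haploid(bases, rep(35, 100), ref)$e, 0)

  bases[c(10, 20)] <- "C"
  em <- estimate_error_rate_from_haploid(bases, rep(35, 100), ref)
  expect_identical(em$e, 0.02)
  # both mismatches are transversions (A->C): scaled by 3/2
  expect_equal(em$e_tv, 0.03)

  # transitions are excluded from the transversion-only estimate
  bases[c(10, 20)] <- "G"
  em2 <- estimate_error_rate_from_haploid(bases, rep(35, 100), ref)
  expect_identical(em2$e, 0.02)
  expect_identical(em2$e_tv, 0)

  # quality filter applies before counting
  expect_error(estimate_error_rate_from_haploid(bases, rep(10, 100), ref),
               "quality")
  expect_error(error_model(0.8), "0.75")
})

test_that("genotype likelihood triplets match the closed-form model", {
  # single major read at error 0.01: triplet proportional to
  # (0.99, 0.496667, 0.003333)
  counts <- array(0L, c(1, 1, 4), dimnames = list(NULL, "I1", c("A", "C", "G", "T")))
  counts[1, 1, "A"] <- 1L
  pu <- structure(list(scaffold = "s", pos = 1L, counts = counts, qual = 20,
                       individuals = data.frame(id = "I1", epoch = NA)),
                  class = "erosion_pileup")
  gl <- call_genotype_likelihoods(pu, error_model(0.01))
  lin <- exp(gl$loglik[1, 1, ])
  expect_equal(unname(lin / lin[1]),
               c(0.99, 0.496667, 0.003333) / 0.99, tolerance = 1e-5)

  # no reads -> flat triplet
  counts[1, 1, "A"] <- 0L
  pu$counts <- counts
  gl0 <- call_genotype_likelihoods(pu, error_model(0.01))
  expect_equal(unname(exp(gl0$loglik[1, 1, ])), c(1, 1, 1))
  expect_false(gl0$has_data[1, 1])

  # one major + one minor read, tiny error -> heterozygote dominates
  counts[1, 1, c("A", "C")] <- 1L
  pu$counts <- counts
  gl2 <- call_genotype_likelihoods(pu, error_model(1e-6))
  lin2 <- exp(gl2$loglik[1, 1, ])
  expect_identical(unname(which.max(lin2)), 2L)
  expect_gt(lin2[2] / max(lin2[1], lin2[3]), 1e4)
})

test_that("major/minor polarization uses counts with base-order tie-breaks", {
  counts <- array(0L, c(2, 1, 4), dimnames = list(NULL, "I1", c("A", "C", "G", "T")))
  counts[1, 1, ] <- c(5L, 2L, 2L, 0L)   # tie C/G for minor -> C
  counts[2, 1, ] <- c(3L, 3L, 1L, 0L)   # tie A/C for major -> A, minor C
  pu <- structure(list(scaffold = c("s", "s"), pos = 1:2, counts = counts,
                       qual = 20, individuals = data.frame(id = "I1", epoch = NA)),
                  class = "erosion_pileup")
  gl <- call_genotype_likelihoods(pu, error_model(0.01))
  expect_identical(gl$major, c("A", "A"))
  expect_identical(gl$minor, c("C", "C"))
})

test_that("with no sequencing error, GL-based calls recover true genotypes", {
  s <- small_sim(seed = 21, theta = 0.3, b = 1, n_sites = 500, coverage = 15)
  pu <- simulate_reads(s$geno, error_rate = 0, damage_rate = 0, seed = 4)
  gl <- call_genotype_likelihoods(pu, error_model(0))
  called <- apply(exp(gl$loglik), c(1, 2), which.max) - 1L   # sites x ind
  # restrict to individuals with >= 8 reads at the site (unambiguous calls)
  depth <- apply(pu$counts, c(1, 2), sum)
  mask <- gl$has_data & depth >= 8
  # polarization: called dose is in minor-allele units; flip sites where the
  # simulated alt allele was inferred as major (monomorphic sites keep an
  # arbitrary zero-count minor, so they are not flipped)
  aligned <- s$geno$geno
  flip <- gl$major == s$geno$sites$alt
  aligned[, flip] <- 2L - aligned[, flip]
  expect_true(all(called[mask] == t(aligned)[mask]))
})

test_that("EM allele frequencies agree with a brute-force oracle", {
  # all confidently hom-major -> f ~ 0; all het -> f ~ 0.5
  gl_hom <- make_sharp_gl(matrix(0L, 10, 5))
  expect_lt(max(estimate_maf_em(gl_hom)$maf), 1e-4)
  gl_het <- make_sharp_gl(matrix(1L, 10, 5))
  expect_equal(estimate_maf_em(gl_het)$maf, rep(0.5, 5), tolerance = 1e-4)

  # 10 hom-major + 10 hom-minor -> f ~ 0.5
  gl_split <- make_sharp_gl(matrix(rep(c(0L, 2L), each = 10), 20, 4))
  expect_equal(estimate_maf_em(gl_split)$maf, rep(0.5, 4), tolerance = 1e-4)

  # random soft instances vs independent grid + golden-section oracle
  set.seed(31)
  s <- small_sim(seed = 31, theta = 0.3, b = 1, n_sites = 60, n = 8,
                 coverage = 4)
  gl <- call_genotype_likelihoods(s$pileup, s$em)
  gl <- estimate_maf_em(gl, tol = 1e-9, max_iter = 2000)
  for (site in sample(seq_along(gl$pos), 15)) {
    f_star <- oracle_maf(exp(gl$loglik[site, , ]))
    f_star <- min(f_star, 1 - f_star)
    expect_equal(gl$maf[site], f_star, tolerance = 1e-4)
  }
})

test_that("EM log-likelihood is non-decreasing", {
  s <- small_sim(seed = 33, theta = 0.3, b = 1, n_sites = 200, n = 6,
                 coverage = 3)
  gl <- call_genotype_likelihoods(s$pileup, s$em)
  gl <- estimate_maf_em(gl, trace = TRUE)
  expect_true(all(diff(attr(gl, "ll_trace")) > -1e-8))
})

test_that("SNP likelihood-ratio test matches direct evaluation", {
  # monomorphic -> p = 1
  gl_hom <- estimate_maf_em(make_sharp_gl(matrix(0L, 10, 3)))
  expect_identical(snp_lrt(gl_hom), rep(1, 3))

  # 20 sharp heterozygotes at f = 0.5 -> overwhelming evidence
  gl_het <- estimate_maf_em(make_sharp_gl(matrix(1L, 20, 2)))
  expect_true(all(snp_lrt(gl_het) < 1e-6))

  # statistic equals brute-force 2[max_f ll - ll(0)] on random instances
  s <- small_sim(seed = 35, theta = 0.3, b = 1, n_sites = 40, n = 10,
                 coverage = 5)
  gl <- call_genotype_likelihoods(s$pileup, s$em)
  gl <- estimate_maf_em(gl, tol = 1e-10, max_iter = 5000)
  p <- snp_lrt(gl)
  for (site in seq_along(gl$pos)) {
    trip <- exp(gl$loglik[site, , ])
    f_star <- oracle_maf(trip)
    stat_oracle <- max(0, 2 * (naive_site_ll(trip, f_star) -
                               naive_site_ll(trip, 0)))
    stat_pkg <- stats::qchisq(p[site], df = 1, lower.tail = FALSE)
    if (gl$maf[site] > 1e-6 && is.finite(stat_pkg)) {
      expect_equal(stat_pkg, stat_oracle, tolerance = 1e-6)
    }
  }
})

test_that("site filters mirror an independent per-site rule check", {
  s <- small_sim(seed = 37, theta = 0.25, b = 1, n_sites = 100, n = 12,
                 coverage = 4)
  gl <- estimate_maf_em(call_genotype_likelihoods(s$pileup, s$em))
  p <- snp_lrt(gl)
  min_ind <- 10
  glf <- filter_sites(gl, min_maf = 0.05, snp_p = 1e-6, min_ind = min_ind,
                      rm_transitions = TRUE)
  ts_pair <- paste(gl$major, gl$minor)
  naive_keep <- !(ts_pair %in% c("A G", "G A", "C T", "T C")) &
                gl$maf >= 0.05 & p <= 1e-6 &
                rowSums(gl$has_data) >= min_ind
  expect_identical(glf$pos, gl$pos[naive_keep])

  # transition sites are removed when rm_transitions is on
  if (any(ts_pair %in% c("A G", "G A", "C T", "T C"))) {
    expect_false(any(paste(glf$major, glf$minor) %in%
                     c("A G", "G A", "C T", "T C")))
  }
  # low-frequency sites are removed
  expect_true(all(glf$maf >= 0.05))
  # empty result warns rather than errors
  expect_warning(filter_sites(gl, min_maf = 0.6), "no sites")
})

test_that("likelihoods are invariant to the order reads are accumulated", {
  counts <- array(0L, c(1, 1, 4), dimnames = list(NULL, "I1", c("A", "C", "G", "T")))
  counts[1, 1, ] <- c(3L, 2L, 0L, 0L)
  pu <- structure(list(scaffold = "s", pos = 1L, counts = counts, qual = 20,
                       individuals = data.frame(id = "I1", epoch = NA)),
                  class = "erosion_pileup")
  gl_a <- call_genotype_likelihoods(pu, error_model(0.01))
  # same multiset of reads accumulated as two batches
  half <- pu
  half$counts[1, 1, ] <- c(1L, 1L, 0L, 0L)
  rest <- pu
  rest$counts[1, 1, ] <- c(2L, 1L, 0L, 0L)
  merged <- pu
  merged$counts[1, 1, ] <- half$counts[1, 1, ] + rest$counts[1, 1, ]
  gl_b <- call_genotype_likelihoods(merged, error_model(0.01))
  expect_identical(gl_a$loglik, gl_b$loglik)
})
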
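test_that("folded site likelihoods keep max homozygote and the het class", {
  expect_identical(unname(site_het_likelihood(c(1, 0, 0))), c(1, 0))
  expect_identical(unname(site_het_likelihood(c(0.2, 0.9, 0.1))), c(0.2, 0.9))
  expect_identical(unname(site_het_likelihood(c(1, 1, 1))), c(1, 1))
  m <- site_het_likelihood(rbind(c(0.1, 0.5, 0.7), c(1, 0, 0)))
  expect_equal(unname(m), rbind(c(0.7, 0.5), c(1, 0)))
})

test_that("two-class EM recovers sharp-likelihood counting and the grid MLE", {
  # all homozygous
  expect_lt(as.numeric(estimate_heterozygosity_em(cbind(rep(1, 50), 0))), 1e-9)

  # 90 hom + 10 het sharp sites -> 0.10
  lik <- rbind(matrix(c(1, 1e-9), 90, 2, byrow = TRUE),
               matrix(c(1e-9, 1), 10, 2, byrow = TRUE))
  expect_equal(as.numeric(estimate_heterozygosity_em(lik)), 0.1,
               tolerance = 1e-6)

  # flat input returns the initialization with a flag
  flat <- estimate_heterozygosity_em(cbind(rep(1, 5), rep(1, 5)))
  expect_true(attr(flat, "uninformative"))

  # soft random instances vs grid maximization of the mixture likelihood
  set.seed(41)
  for (rep in 1:5) {
    lik <- cbind(runif(50, 0.2, 1), runif(50, 0, 0.8))
    p_em <- as.numeric(estimate_heterozygosity_em(lik, tol = 1e-10))
    grid <- seq(0, 1, by = 1e-4)
    ll <- vapply(grid, function(p) {
      sum(log((1 - p) * lik[, 1] + p * lik[, 2]))
    }, 0)
    expect_equal(p_em, grid[which.max(ll)], tolerance = 2e-4)
  }

  # log-likelihood non-decreasing
  lik <- cbind(runif(100, 0.2, 1), runif(100, 0, 0.8))
  tr <- attr(estimate_heterozygosity_em(lik, trace = TRUE), "ll_trace")
  expect_true(all(diff(tr) > -1e-10))
})

test_that("downsampling thins reads binomially and validates its fraction", {
  s <- small_sim(seed = 43, n_sites = 2000, n = 2, coverage = 25)
  expect_error(downsample_pileup(s$pileup, 0), "fraction")
  expect_error(downsample_pileup(s$pileup, 1.5), "fraction")
  expect_identical(downsample_pileup(s$pileup, 1), s$pileup)

  n_reads <- sum(s$pileup$counts)
  expect_gt(n_reads, 1e5)
  ds <- downsample_pileup(s$pileup, 0.5, seed = 2)
  expect_lt(abs(sum(ds$counts) - 0.5 * n_reads), 3 * sqrt(0.25 * n_reads))
  # thinning never invents reads
  expect_true(all(ds$counts <= s$pileup$counts))
})

test_that("calibration uses 15 downsampled datasets and anchors at full coverage", {
  cfg <- sim_config(n_historic = 1, n_contemporary = 1, n_sites = 20000,
                    n_scaffolds = 1, scaffold_length = 2e6, theta = 0.02,
                    bottleneck_factor = 1, coverage_contemporary = 12,
                    damage_rate = 0, seed = 45)
  g <- simulate_genotypes(cfg)
  pu <- simulate_reads(g, coverage = c(HIS001 = 12, CON001 = 12), seed = 46)
  em <- error_model(cfg$error_rate)
  curve <- build_calibration_curve(pu, "CON001", em, seed = 47)
  expect_identical(nrow(curve$support), 15L)
  expect_identical(curve$degree, 3)
  # prediction at the reference coverage is exactly 1 (anchored fit)
  expect_equal(predict_relative_het(curve, curve$reference_coverage), 1,
               tolerance = 1e-12)
  expect_error(build_calibration_curve(pu, "CON001", em, fractions = 0.5),
               "degenerate")
})

test_that("fitted curves are monotone increasing over the deficit region", {
  monotone <- vapply(1:5, function(s) {
    cfg <- sim_config(n_historic = 1, n_contemporary = 1, n_sites = 40000,
                      n_scaffolds = 1, scaffold_length = 4e6, theta = 0.02,
                      bottleneck_factor = 1, coverage_contemporary = 12,
                      damage_rate = 0, error_rate = 0.001, seed = 100 + s)
    g <- simulate_genotypes(cfg)
    pu <- simulate_reads(g, coverage = c(HIS001 = 0.1, CON001 = 12),
                         seed = 200 + s)
    curve <- build_calibration_curve(pu, "CON001", error_model(0.001),
                                     seed = 300 + s)
    grid <- seq(min(curve$support$coverage), curve$reference_coverage,
                length.out = 100)
    pred <- predict_relative_het(curve, grid)
    # deficit region: from the lowest fitted coverage until the curve first
    # reaches 1
    deficit <- seq_len(max(which(pred < 1)[1], 2))
    all(diff(pred[seq_len(max(deficit))]) > 0) && pred[1] < 0.95
  }, logical(1))
  expect_gte(sum(monotone), 4)
})

test_that("correction divides by the predicted relative heterozygosity", {
  curve <- structure(list(
    degree = 1, coefficients = c(0.1, 0),  # rel het = 0.1 * coverage
    reference_coverage = 10, het_full = 0.001,
    support = data.frame(fraction = c(0.5, 0.8), replicate = 1,
                         coverage = c(5, 8), rel_het = c(0.5, 0.8)),
    individual = "X"), class = "calibration_curve")
  # prediction 1 at reference -> corrected equals raw
  expect_equal(apply_correction(0.0007, 10, curve), 0.0007)
  # prediction 0.5 -> corrected doubles
  expect_equal(apply_correction(0.0007, 5, curve), 0.0014)
  # extrapolation guard names the fitted range
  expect_error(apply_correction(0.0007, 30, curve), "fitted range")
  # predictions are clipped below at 0.05
  expect_equal(apply_correction(0.001, 2.6, curve), 0.001 / 0.26)
  curve$coefficients <- c(0.001, 0)
  expect_equal(apply_correction(0.001, 5, curve), 0.001 / 0.05)
})

test_that("published correction polynomials are shipped as opaque presets", {
  pre <- calibration_presets()
  expect_identical(pre$contemporary, c(0.0008, -0.0265, 0.2998, 0.2191))
  expect_identical(pre$historic, c(0.0063, -0.1399, 1.781))
  # deliberately not calibration_curve objects: they carry no reference
  # coverage and are never applied by default
  expect_false(inherits(pre$contemporary, "calibration_curve"))
})

test_that("Kruskal-Wallis wrapper matches a first-principles H", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(round(kw$H, 4), 3.8571)
  expect_identical(kw$df, 1L)

  ident <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_identical(ident$H, 0)
  expect_identical(ident$p_value, 1)

  set.seed(49)
  for (rep in 1:5) {
    groups <- list(sample(10, 4, TRUE), sample(10, 5, TRUE),
                   sample(10, 3, TRUE))
    expect_equal(kruskal_wallis(groups)$H, oracle_kw_h(groups),
                 tolerance = 1e-10)
  }
})

test_that("windowed EM recovers simulated heterozygosity at high coverage", {
  cfg <- sim_config(n_historic = 1, n_contemporary = 1, n_sites = 100000,
                    n_scaffolds = 1, scaffold_length = 3e6, theta = 0.0014,
                    bottleneck_factor = 1, damage_rate = 0, seed = 51)
  g <- simulate_genotypes(cfg)
  pu <- simulate_reads(g, coverage = 20, seed = 52)
  est <- estimate_heterozygosity(pu, error_model(cfg$error_rate),
                                 window_size = 1e6)
  truth <- g$truth$het[est$individual$id]
  expect_true(all(abs(est$individual$het_raw / truth - 1) < 0.05))
  # windows tile the scaffold and are site-weighted into the genome value
  expect_true(all(est$windows$n_sites > 0))
  one <- est$windows[est$windows$id == est$individual$id[1], ]
  expect_equal(sum(one$het * one$n_sites) / sum(one$n_sites),
               est$individual$het_raw[1])
})

test_that("transversion-only estimation removes damage-driven inflation", {
  cfg <- sim_config(n_historic = 1, n_contemporary = 1, n_sites = 40000,
                    n_scaffolds = 1, scaffold_length = 2e6, theta = 0.01,
                    bottleneck_factor = 1, coverage_historic = 10,
                    damage_rate = 0.02, seed = 95)
  g <- simulate_genotypes(cfg)
  pu <- simulate_reads(g, seed = 96)
  em <- error_model(cfg$error_rate)
  hist_pu <- pileup_subset(pu, "HIS001")
  all_sites <- estimate_heterozygosity(hist_pu, em, window_size = Inf)
  tv_only <- estimate_heterozygosity(hist_pu, em, window_size = Inf,
                                     transversions_only = TRUE)
  truth <- g$truth$het[["HIS001"]]
  # damage inflates the all-sites estimate severalfold ...
  expect_gt(all_sites$individual$het_raw / truth, 2)
  # ... while the transversion-only estimate tracks the transversion share
  # of true heterozygosity (2/3 under the uniform-alt simulator), with only
  # residual error-driven bias left
  tv_truth <- mean(g$geno["HIS001", ] == 1L &
                   !erosionkit:::is_transition(g$sites$ref, g$sites$alt))
  expect_lt(abs(tv_only$individual$het_raw / tv_truth - 1), 0.5)
  expect_lt(tv_only$individual$het_raw / truth,
            all_sites$individual$het_raw / truth / 3)
})

test_that("raw heterozygosity keeps the historic > contemporary ordering", {
  ok <- vapply(1:12, function(s) {
    sim <- small_sim(seed = 600 + s, theta = 0.01, b = 0.3, n_sites = 8000,
                     n = 6, coverage = 8)
    est <- estimate_heterozygosity(sim$pileup, sim$em, window_size = Inf)
    by_epoch <- split(est$individual$het_raw,
                      sim$geno$individuals$epoch[match(est$individual$id,
                                                       sim$geno$individuals$id)])
    truth <- split(sim$geno$truth$het, sim$geno$individuals$epoch)
    (mean(by_epoch$historic) > mean(by_epoch$contemporary)) ==
      (mean(truth$historic) > mean(truth$contemporary))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
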
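test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_sites = 0), "n_sites")
  expect_error(sim_config(bottleneck_factor = 0), "bottleneck_factor")
  expect_error(sim_config(bottleneck_factor = 1.2), "bottleneck_factor")
  expect_error(sim_config(error_rate = -0.1), "error_rate")
  expect_error(sim_config(n_sites = 1e9), "exceeds")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("simulation is bit-identical under a fixed seed and config", {
  cfg <- sim_config(n_sites = 2000, seed = 42)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  p1 <- simulate_reads(g1, seed = 7)
  p2 <- simulate_reads(g2, seed = 7)
  expect_identical(p1$counts, p2$counts)
  m1 <- simulate_mt_haplotypes(cfg, 4, 200)
  m2 <- simulate_mt_haplotypes(cfg, 4, 200)
  expect_identical(m1, m2)
})

test_that("theta = 0 gives fully homozygous-reference genotypes", {
  cfg <- sim_config(theta = 0, n_sites = 1000, seed = 3)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$geno == 0L))
  expect_true(all(g$truth$het == 0))
})

test_that("no bottleneck leaves the two epochs exchangeable in diversity", {
  cfg <- sim_config(n_historic = 25, n_contemporary = 25, n_sites = 20000,
                    theta = 0.05, bottleneck_factor = 1, seed = 9)
  g <- simulate_genotypes(cfg)
  het <- split(g$truth$het, g$individuals$epoch)
  # same allele frequencies in both epochs: means agree within sampling error
  expect_lt(abs(mean(het$historic) - mean(het$contemporary)) /
              mean(het$historic), 0.05)
  expect_identical(g$sites$p_historic, g$sites$p_contemporary)
})

test_that("a bottleneck lowers contemporary diversity in nearly all seeds", {
  hits <- vapply(1:50, function(s) {
    cfg <- sim_config(n_historic = 20, n_contemporary = 20, n_sites = 20000,
                      theta = 0.0014, bottleneck_factor = 0.3, seed = s)
    g <- simulate_genotypes(cfg)
    het <- split(g$truth$het, g$individuals$epoch)
    mean(het$contemporary) < mean(het$historic)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("expected bottleneck diversity reduction is calibrated", {
  # E[2p'(1-p')] = b * E[2p(1-p)] by construction of the drift resampling
  cfg <- sim_config(n_sites = 200000, theta = 0.01, bottleneck_factor = 0.6,
                    n_scaffolds = 1, scaffold_length = 1e7, seed = 5)
  g <- simulate_genotypes(cfg)
  div_h <- mean(2 * g$sites$p_historic * (1 - g$sites$p_historic))
  div_c <- mean(2 * g$sites$p_contemporary * (1 - g$sites$p_contemporary))
  expect_lt(abs(div_c / div_h - 0.6), 0.03)
})

test_that("planted ROH hit their FROH target and are internally homozygous", {
  cfg <- sim_config(n_historic = 1, n_contemporary = 1, n_sites = 20000,
                    n_scaffolds = 1, scaffold_length = 1e8, theta = 0.3,
                    bottleneck_factor = 1, seed = 11)
  g <- simulate_genotypes(cfg)
  g0 <- plant_roh(g, 0)
  expect_identical(g0$geno, g$geno)

  gp <- plant_roh(g, 0.5, seed = 2)
  tr <- gp$truth$tracts
  for (id in gp$individuals$id) {
    tot <- sum(tr$length[tr$id == id])
    expect_gte(tot, 45e6)
    expect_lte(tot, 55e6)
    # non-overlap within each individual
    ti <- tr[tr$id == id, ]
    ti <- ti[order(ti$start), ]
    if (nrow(ti) > 1) expect_true(all(diff(ti$start) > head(ti$length, -1)))
    # every site inside a tract is homozygous
    for (j in seq_len(nrow(ti))) {
      idx <- which(gp$sites$pos >= ti$start[j] & gp$sites$pos <= ti$end[j])
      expect_true(all(gp$geno[id, idx] != 1L))
    }
  }
  expect_equal(unname(gp$truth$froh),
               unname(c(tapply(tr$length, tr$id, sum)[gp$individuals$id])) / 1e8)
  expect_error(plant_roh(g, 0.95), "infeasible")
})

test_that("read simulation obeys depth, error-free and damage expectations", {
  cfg <- sim_config(n_historic = 1, n_contemporary = 1, n_sites = 100000,
                    n_scaffolds = 1, scaffold_length = 1e7, theta = 0,
                    damage_rate = 0, seed = 13)
  g <- simulate_genotypes(cfg)

  # coverage 0 -> empty pileup
  p0 <- simulate_reads(g, coverage = 0, seed = 1)
  expect_true(all(p0$counts == 0L))

  # error-free, damage-free hom-ref reads are all reference
  pe <- simulate_reads(g, coverage = 5, error_rate = 0, damage_rate = 0,
                       seed = 2)
  for (i in 1:2) {
    obs <- pe$counts[, i, ]
    ref_count <- obs[cbind(seq_len(nrow(obs)), match(g$sites$ref, c("A", "C", "G", "T")))]
    expect_identical(sum(obs), sum(ref_count))
  }

  # depth law: mean depth within 2% of nominal at 1e5 sites
  expect_lt(abs(mean(pileup_coverage(pe)) - 5) / 5, 0.02)

  # damage: hom-CC historic sites read as T at the damage rate
  g$sites$ref <- rep("C", nrow(g$sites))
  g$sites$alt <- rep("A", nrow(g$sites))
  pd <- simulate_reads(g, coverage = 10, error_rate = 0, damage_rate = 0.1,
                       seed = 3)
  hist_id <- g$individuals$id[g$individuals$epoch == "historic"]
  frac_t <- sum(pd$counts[, hist_id, "T"]) / sum(pd$counts[, hist_id, ])
  expect_lt(abs(frac_t - 0.1), 0.01)
  # contemporary libraries carry no damage
  con_id <- g$individuals$id[g$individuals$epoch == "contemporary"]
  expect_identical(sum(pd$counts[, con_id, "T"]), 0L)

  expect_error(simulate_reads(g, coverage = 5, error_rate = -1), "rates")
})

test_that("mitochondrial simulator produces labelled epochs with known truth", {
  cfg <- sim_config(n_historic = 15, n_contemporary = 12, seed = 17)
  expect_error(simulate_mt_haplotypes(cfg, 3, 0), "seq_length")

  one <- simulate_mt_haplotypes(cfg, 1, 100)
  expect_length(unique(unname(one$sequences)), 1)

  sim <- simulate_mt_haplotypes(cfg, 5, 300, drop_rare = 2)
  expect_length(sim$sequences, 27)
  expect_identical(as.integer(table(sim$assignments$epoch)[c("historic", "contemporary")]),
                   c(15L, 12L))
  expect_equal(sum(sim$truth$freq_historic), 1)
  expect_equal(sum(sim$truth$freq_contemporary), 1)
  expect_identical(sum(sim$truth$freq_contemporary == 0), 2L)
  # source haplotypes distinct
  expect_identical(anyDuplicated(sim$truth$haplotypes), 0L)
  # headers carry epoch tags
  expect_true(all(grepl("\\|epoch=(historic|contemporary)\\|pop=",
                        names(sim$sequences))))
})

test_that("losing rare haplotypes lowers contemporary diversity", {
  # population-level: renormalizing after dropping the rarest haplotypes
  # strictly lowers expected diversity in every seed
  hds <- t(vapply(1:40, function(s) {
    cfg <- sim_config(n_historic = 40, n_contemporary = 40, seed = s)
    sim <- simulate_mt_haplotypes(cfg, 6, 200, drop_rare = 2)
    a <- sim$assignments
    c(th = 1 - sum(sim$truth$freq_historic^2),
      tc = 1 - sum(sim$truth$freq_contemporary^2),
      h = haplotype_diversity(a$haplotype[a$epoch == "historic"]),
      c = haplotype_diversity(a$haplotype[a$epoch == "contemporary"]))
  }, c(th = 0, tc = 0, h = 0, c = 0)))
  expect_true(all(hds[, "tc"] < hds[, "th"]))
  # sample-level: the ordering carries through on average
  expect_gt(mean(hds[, "h"] > hds[, "c"]), 0.6)
  expect_gt(mean(hds[, "h"]) - mean(hds[, "c"]), 0.02)
})
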
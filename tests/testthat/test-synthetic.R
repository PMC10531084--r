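test_that("simulation is bit-identical under a fixed seed and validates config", {
  cfg <- sim_config(n = 30, m = 50, seed = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$genotypes$dosage, g2$genotypes$dosage)
  p1 <- simulate_phenotype(g1$genotypes, cfg)
  p2 <- simulate_phenotype(g2$genotypes, cfg)
  expect_identical(p1$phenotype$value, p2$phenotype$value)
  expect_error(sim_config(n = 30, m = 50), "seed")
  expect_error(sim_config(n = 30, m = 50, fst = 1, seed = 1))
  # generated matrices satisfy the container invariants by construction
  expect_s3_class(g1$genotypes, "genotype_matrix")
})

test_that("selfing forces homozygosity and fst controls subpop divergence", {
  g <- simulate_genotypes(sim_config(n = 50, m = 200, selfing = 1,
                                     missing_rate = 0, seed = 6))
  expect_false(any(g$genotypes$dosage == 1, na.rm = TRUE))
  g0 <- simulate_genotypes(sim_config(n = 20, m = 300, fst = 0, seed = 7))
  expect_lt(max(apply(g0$subpop_freq, 2, var)), 1e-20)
  # Balding-Nichols moment: Var(p_subpop) ~ fst * p(1-p)
  cfg <- sim_config(n = 20, m = 6000, fst = 0.1, n_subpops = 8, seed = 8)
  g1 <- simulate_genotypes(cfg)
  p_anc <- colMeans(g1$subpop_freq)
  v_emp <- apply(g1$subpop_freq, 2, var)
  ratio <- mean(v_emp) / mean(0.1 * p_anc * (1 - p_anc))
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("phenotype variance partition recovers h2 and the limits hold", {
  # h2 = 1: phenotype equals the genetic value exactly
  cfg1 <- sim_config(n = 80, m = 200, h2 = 1, outlier_rate = 0, seed = 9)
  g <- simulate_genotypes(cfg1)
  ph <- simulate_phenotype(g$genotypes, cfg1)
  hn <- ph$phenotype[ph$phenotype$treatment == "HN", ]
  expect_equal(cor(hn$value, unname(ph$genetic_values)), 1, tolerance = 1e-12)

  # h2 = 0: phenotype independent of the (raw) genetic signal
  cfg0 <- sim_config(n = 221, m = 200, h2 = 0, seed = 10)
  g0 <- simulate_genotypes(cfg0)
  ph0 <- simulate_phenotype(g0$genotypes, cfg0)
  hn0 <- ph0$phenotype[ph0$phenotype$treatment == "HN", ]
  W <- g0$genotypes$dosage[, match(ph0$qtl_ids, g0$genotypes$snp_meta$id)]
  W[is.na(W)] <- 0
  raw_gen <- drop(scale(W, scale = FALSE) %*% ph0$qtl_effects)
  expect_lt(abs(cor(hn0$value, raw_gen)), 0.2)

  # realized genetic variance fraction near h2 across seeds
  fr <- vapply(1:8, function(s) {
    cfg <- sim_config(n = 120, m = 500, h2 = 0.4, seed = 100 + s)
    gg <- simulate_genotypes(cfg)
    pp <- simulate_phenotype(gg$genotypes, cfg)
    hh <- pp$phenotype[pp$phenotype$treatment == "HN", ]
    var(pp$genetic_values) / var(hh$value)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.4), 0.1)
})

test_that("treatment shift and outlier injection behave as configured", {
  cfg <- sim_config(n = 200, m = 100, h2 = 0.2, treatment_shift = 500,
                    outlier_rate = 0, seed = 12)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g$genotypes, cfg)$phenotype
  d <- mean(ph$value[ph$treatment == "HN"]) -
    mean(ph$value[ph$treatment == "LN"])
  expect_equal(d, 500, tolerance = 3 * 145.16 / sqrt(100))
  cfg_o <- sim_config(n = 200, m = 100, h2 = 0, outlier_rate = 0.05,
                      seed = 13)
  ph_o <- simulate_phenotype(simulate_genotypes(cfg_o)$genotypes,
                             cfg_o)$phenotype
  hn <- ph_o$value[ph_o$treatment == "HN"]
  expect_gt(sum(detect_outliers(hn)), 0)
})

test_that("z-value mixture respects pi0, mu1 and the binomial signal count", {
  s0 <- simulate_zvalues(500, pi0 = 1, seed = 14)
  expect_true(all(s0$is_null))
  s <- simulate_zvalues(20000, pi0 = 0.9, mu1 = 2.5, sd1 = 1, seed = 15)
  expect_equal(mean(s$z[!s$is_null]), 2.5, tolerance = 0.05)
  k <- sum(!s$is_null)
  expect_lt(abs(k - 2000), 4 * sqrt(20000 * 0.1 * 0.9))
  expect_identical(simulate_zvalues(100, seed = 16)$z,
                   simulate_zvalues(100, seed = 16)$z)
})
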
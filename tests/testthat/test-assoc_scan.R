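test_that("scan with identity kinship and h2 = 0 reproduces OLS exactly", {
  set.seed(2)
  G <- simulate_genotypes(sim_config(n = 60, m = 30, fst = 0, selfing = 0,
                                     missing_rate = 0, seed = 2))$genotypes
  y <- rnorm(60)
  st <- single_locus_scan(y, G, K = NULL, h2 = 0)
  for (j in c(1, 7, 30)) {
    cf <- summary(lm(y ~ G$dosage[, j]))$coefficients
    expect_equal(st$effect[j], cf[2, 1], tolerance = 1e-10)
    expect_equal(st$se[j], cf[2, 2], tolerance = 1e-10)
    expect_equal(st$p[j], cf[2, 4], tolerance = 1e-10)
  }
})

test_that("scan is scale-equivariant and handles degenerate inputs", {
  set.seed(3)
  G <- simulate_genotypes(sim_config(n = 40, m = 20, missing_rate = 0,
                                     seed = 3))$genotypes
  y <- rnorm(40)
  K <- compute_grm(G)
  s1 <- single_locus_scan(y, G, K)
  s2 <- single_locus_scan(2 * y, G, K, h2 = attr(s1, "h2"))
  expect_equal(s2$effect, 2 * s1$effect, tolerance = 1e-8)
  expect_equal(s2$p, s1$p, tolerance = 1e-8)
  # monomorphic SNP: missing effect, p = 1
  Gm <- genotype_matrix(cbind(mono = rep(0, 40), poly = G$dosage[, 1]))
  sm <- single_locus_scan(y, Gm, K = NULL, h2 = 0)
  expect_true(is.na(sm$effect[1]))
  expect_equal(sm$p[1], 1)
  expect_error(single_locus_scan(y[1:2], genotype_matrix(G$dosage[1:2, ]),
                                 K = NULL), "at least 3")
  expect_error(single_locus_scan(y, G, K = NULL,
                                 covariates = cbind(rep(1, 40))),
               "rank deficient")
})

test_that("null scan p-values are uniform (KS calibration)", {
  set.seed(17)
  G <- simulate_genotypes(sim_config(n = 120, m = 2000, fst = 0, selfing = 0,
                                     missing_rate = 0, seed = 17))$genotypes
  y <- rnorm(120)   # pure noise, no structure, K = I
  st <- single_locus_scan(y, G, K = NULL, h2 = 0)
  expect_gt(ks.test(st$p, "punif")$p.value, 0.01)
})

test_that("p_to_z follows the signed two-sided convention with clamping", {
  expect_equal(p_to_z(1), 0)                             # one-sided boundary
  expect_equal(p_to_z(0.05), qnorm(0.95), tolerance = 1e-10)
  expect_equal(p_to_z(0.05, effect = -1), -qnorm(0.975), tolerance = 1e-10)
  expect_equal(p_to_z(1, effect = 1), 0)                 # two-sided boundary
  expect_true(is.finite(p_to_z(1e-300)))                 # clamped
  expect_error(p_to_z(0), "\\(0, 1\\]")
  expect_error(p_to_z(1.5), "\\(0, 1\\]")
  df <- data.frame(snp = c("a", "b"), p = c(0.5, 0.01), effect = c(1, -2))
  expect_equal(p_to_z(df)$z,
               c(qnorm(0.75), -qnorm(0.995)), tolerance = 1e-10)
})

test_that("summary statistics TSV round-trips and validates", {
  st <- data.frame(snp = c("a", "b"), chr = "1", pos = 1:2,
                   effect = c(0.5, -1), se = c(0.2, 0.3), p = c(0.5, 0.01),
                   z = NA_real_, maf = c(0.1, 0.3), callrate = 1,
                   model_tag = "x")
  f <- tempfile(fileext = ".tsv")
  write_summary_stats(st, f)
  st2 <- read_summary_stats(f)
  expect_equal(st2$p, st$p)
  expect_equal(st2$snp, st$snp)
  writeLines(c("snp\tp", "a\t0", "b\t0.5"), f)
  expect_error(read_summary_stats(f), "outside")
})
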
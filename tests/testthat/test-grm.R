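test_that("GRM matches the hand-evaluated VanRaden toy exactly", {
  G <- genotype_matrix(rbind(c(0, 2), c(2, 0)))
  K <- compute_grm(G)
  expect_equal(unname(K$K), rbind(c(2, -2), c(-2, 2)))
  expect_equal(K$denom, 1)
})

test_that("GRM is symmetric PSD, permutation- and label-swap-invariant", {
  set.seed(21)
  G <- simulate_genotypes(sim_config(n = 40, m = 120, seed = 21))$genotypes
  K <- compute_grm(G)$K
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # SNP column permutation
  perm <- sample(ncol(G$dosage))
  Gp <- genotype_matrix(G$dosage[, perm], snp_meta = G$snp_meta[perm, ],
                        sample_ids = G$sample_ids)
  expect_equal(compute_grm(Gp)$K, K, tolerance = 1e-12)
  # 0 <-> 2 allele label swap leaves K unchanged
  Gs <- genotype_matrix(2 - G$dosage, snp_meta = G$snp_meta,
                        sample_ids = G$sample_ids)
  expect_equal(compute_grm(Gs)$K, K, tolerance = 1e-12)
  # identical individuals get identical rows
  dup <- genotype_matrix(G$dosage[c(1, 1, 2:10), ],
                         snp_meta = G$snp_meta,
                         sample_ids = paste0("d", 1:11))
  Kd <- compute_grm(dup)$K
  expect_equal(unname(Kd[1, ]), unname(Kd[2, ]))
})

test_that("monomorphic-only input has no GRM", {
  G <- genotype_matrix(rbind(c(0, 2), c(0, 2), c(0, 2)))
  expect_error(compute_grm(G), "monomorphic")
})

test_that("mean GRM diagonal tracks 1 + inbreeding coefficient", {
  for (f in c(0, 0.5, 0.95)) {
    cfg <- sim_config(n = 120, m = 800, n_subpops = 1, fst = 0,
                      selfing = f, missing_rate = 0, seed = 31 + round(100 * f))
    K <- compute_grm(simulate_genotypes(cfg)$genotypes)$K
    expect_equal(mean(diag(K)), 1 + f, tolerance = 0.1)
  }
})

test_that("GBLUP matches a direct 2x2 solve and its shrinkage limits", {
  K <- structure(list(K = rbind(c(1, 0.5), c(0.5, 1)),
                      sample_ids = c("a", "b"), denom = 1),
                 class = "kinship_matrix")
  y <- c(3, 7)
  h2 <- 0.5
  res <- gblup_ebv(y, K, h2 = h2)
  # brute-force oracle: u = K (K + ((1-h2)/h2) I)^-1 (y - ybar)
  lam <- (1 - h2) / h2
  u_direct <- drop(K$K %*% solve(K$K + diag(lam, 2), y - mean(y)))
  expect_equal(unname(res$ebv), u_direct, tolerance = 1e-12)

  set.seed(4)
  n <- 30
  Ki <- structure(list(K = diag(n), sample_ids = paste0("s", 1:n), denom = 1),
                  class = "kinship_matrix")
  yy <- rnorm(n)
  # h2 -> 1: no shrinkage, EBVs -> centred y, r -> 1
  hi <- gblup_ebv(yy, Ki, h2 = 0.999)
  expect_equal(unname(hi$ebv), yy - mean(yy), tolerance = 0.01)
  expect_gt(hi$r, 0.999)
  # h2 -> 0: infinite ridge, EBVs -> 0
  lo <- gblup_ebv(yy, Ki, h2 = 0.001)
  expect_lt(max(abs(lo$ebv)), 0.01)
  expect_error(gblup_ebv(yy, Ki, h2 = 1.2), "h2")
})

test_that("GRM TSV round-trips through write_grm/read_grm", {
  G <- toy_genotypes()
  K <- compute_grm(G)
  f <- tempfile(fileext = ".tsv")
  write_grm(K, f)
  K2 <- read_grm(f)
  expect_equal(K2$K, K$K, tolerance = 1e-10)
  expect_equal(K2$sample_ids, K$sample_ids)
})
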
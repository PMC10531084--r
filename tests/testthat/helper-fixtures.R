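# shared fixtures and independent oracles for the test suite

toy_genotypes <- function() {
  # 6 individuals x 4 SNPs, hand-chosen dosages incl. a missing call and a
  # monomorphic column
  dos <- rbind(c(0, 2, 1, 0),
               c(1, 2, 0, 0),
               c(2, 0, NA, 0),
               c(0, 1, 2, 0),
               c(1, 0, 1, 0),
               c(2, 1, 0, 0))
  genotype_matrix(dos, sample_ids = paste0("s", 1:6))
}

# rank-based AUC of score for binary truth
auc_rank <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# independent Nelson-Aalen oracle: explicit risk-set enumeration
na_oracle <- function(time, event) {
  ts <- sort(unique(time[event]))
  H <- numeric(length(ts))
  acc <- 0
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(event & time == ts[i])
    acc <- acc + d / at_risk
    H[i] <- acc
  }
  data.frame(time = ts, H = H, S = exp(-H))
}

# analytic two-group posterior null probability for the z mixture
oracle_null_prob <- function(z, pi0, mu1, sd1) {
  pi0 * stats::dnorm(z) /
    (pi0 * stats::dnorm(z) + (1 - pi0) * stats::dnorm(z, mu1, sd1))
}
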
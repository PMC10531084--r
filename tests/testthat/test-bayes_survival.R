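test_that("event table ranks trait into pseudo-time with deterministic ties", {
  tab <- build_event_table(c(0, 0, 1, 2), c(10, 20, 30, 40))
  expect_equal(tab$time, 1:4)
  expect_equal(tab$allele_class,
               c("major_hom", "major_hom", "het", "minor_hom"))
  expect_equal(tab$event, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(tab$censored, !tab$event)
  # tied trait values break by sample id, stable under permutation
  y <- c(a = 5, b = 5, c = 5, d = 1)
  t1 <- build_event_table(c(0, 1, 0, 2), y, sample_ids = names(y))
  perm <- c(3, 1, 4, 2)
  t2 <- build_event_table(c(0, 1, 0, 2)[perm], y[perm],
                          sample_ids = names(y)[perm])
  expect_equal(t1$time[order(t1$sample_id)], t2$time[order(t2$sample_id)])
  # monomorphic column: zero events, flagged
  expect_warning(tm <- build_event_table(c(0, 0, 0, 0), 1:4), "no minor")
  expect_true(attr(tm, "monomorphic"))
  expect_equal(sum(tm$event), 0)
})

test_that("Nelson-Aalen matches the hand-derived all-event curve", {
  cv <- nelson_aalen(data.frame(time = 1:4, event = TRUE))
  expect_equal(cv$H, c(0.25, 7 / 12, 13 / 12, 25 / 12), tolerance = 1e-12)
  expect_equal(cv$S, exp(-cv$H))
  expect_equal(round(cv$S, 4), c(0.7788, 0.5580, 0.3385, 0.1245))
  expect_true(all(diff(cv$S) <= 0))
  # zero events: survival never drops
  empty <- nelson_aalen(data.frame(time = 1:3, event = FALSE))
  expect_equal(nrow(empty), 0L)
})

test_that("Nelson-Aalen equals the exhaustive risk-set oracle on small inputs", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    tab <- data.frame(time = sample(n), event = runif(n) < 0.6)
    if (sum(tab$event) == 0) tab$event[1] <- TRUE
    cv <- nelson_aalen(tab)
    oracle <- na_oracle(tab$time, tab$event)
    expect_equal(cv$time, oracle$time)
    expect_equal(cv$H, oracle$H, tolerance = 1e-12)
    expect_equal(cv$S, oracle$S, tolerance = 1e-12)
  }
})

test_that("class survival summaries flag survivors by count and floor", {
  tab <- build_event_table(c(0, 0, 1, 2), c(10, 20, 30, 40))
  sm <- summarize_survival(tab, min_count = 1)
  expect_setequal(sm$class, c("major_hom", "het", "minor_hom"))
  # the 4-event pooled curve: mean S over the grid
  pooled <- nelson_aalen(data.frame(time = 1:4, event = TRUE))
  expect_equal(mean(pooled$S), 0.45, tolerance = 2e-4)
  # class below min_count is not survived
  sm3 <- summarize_survival(tab, min_count = 3)
  expect_false(sm3$survived[sm3$class == "het"])
  # no-event curve with enough members: mean S 1, survived
  cv1 <- nelson_aalen(data.frame(time = 1:5, event = FALSE))
  attr(cv1, "n_members") <- 5
  smv <- summarize_survival(list(major_hom = cv1), min_count = 3)
  expect_equal(smv$mean_S, 1)
  expect_true(smv$survived)
})

test_that("exponential null fit matches the closed form, with AIC/BIC identities", {
  f <- fit_exponential_ph(data.frame(time = 1:4, event = TRUE,
                                     dosage = c(0, 0, 1, 1)))
  expect_equal(f$rate0, 0.4)                      # d / sum(t) = 4/10
  expect_equal(f$logL0, 4 * log(0.4) - 4, tolerance = 1e-12)
  expect_equal(round(f$AIC0, 4), 17.3303)
  expect_equal(round(f$BIC0, 4), 16.7166)
  expect_equal(f$AIC, 2 * 2 - 2 * f$logL, tolerance = 1e-12)
  expect_equal(f$BIC, 2 * log(f$n_events) - 2 * f$logL, tolerance = 1e-12)
  expect_gte(f$logL, f$logL0)                     # nested models
  # constant covariate: unidentifiable, null model returned
  fc <- fit_exponential_ph(data.frame(time = 1:4, event = TRUE,
                                      dosage = rep(1, 4)))
  expect_false(fc$identifiable)
  expect_equal(fc$logL, fc$logL0)
  expect_error(fit_exponential_ph(data.frame(time = 1:4, event = FALSE,
                                             dosage = 0:3)), "no events")
})

test_that("exponential PH beta agrees with survreg on censored data", {
  set.seed(23)
  n <- 80
  x <- rbinom(n, 2, 0.3)
  t_i <- rexp(n, rate = 0.5 * exp(0.6 * x))
  ev <- runif(n) < 0.8
  f <- fit_exponential_ph(data.frame(time = t_i, event = ev, dosage = x))
  sr <- survival::survreg(survival::Surv(t_i, ev) ~ x, dist = "exponential")
  # exponential AFT coefficient = -PH log-hazard coefficient
  expect_equal(f$beta, -unname(coef(sr)[2]), tolerance = 1e-5)
  expect_equal(log(f$lambda0), -unname(coef(sr)[1]), tolerance = 1e-5)
})

test_that("Bayes survived factor follows lambda0 * exp(beta)", {
  expect_equal(bayes_survived_factor(1, log(0.001)), 0.001)
  expect_equal(bayes_survived_factor(2, log(2)), 4)
  expect_equal(bayes_survived_factor(3, 0), 3)
  expect_error(bayes_survived_factor(0, 1), "positive")
})

test_that("MCMC posterior inclusion matches the closed-form two-group posterior", {
  tau2 <- 4
  pi1 <- 0.05
  z <- c(0, 1, 2, 3, 5, 10, -3)
  post <- mcmc_posterior_inclusion(z, lambda = 1, pi1_base = pi1,
                                   tau2 = tau2, iterations = 10000,
                                   burn_in = 1000, seed = 4)
  odds <- (pi1 / (1 - pi1)) *
    dnorm(z, 0, sqrt(1 + tau2)) / dnorm(z, 0, 1)
  analytic <- odds / (1 + odds)
  expect_lt(max(abs(post$P - analytic)), 0.02)
  expect_gt(post$P[z == 10], 0.99)
  # determinism
  post2 <- mcmc_posterior_inclusion(z, lambda = 1, pi1_base = pi1,
                                    tau2 = tau2, iterations = 10000,
                                    burn_in = 1000, seed = 4)
  expect_identical(post$P, post2$P)
  expect_error(mcmc_posterior_inclusion(z, iterations = 100, burn_in = 200),
               "exceed")
  # lambda tilts the prior odds proportionally
  p_tilt <- mcmc_posterior_inclusion(c(1, 1), lambda = c(4, 0.25),
                                     pi1_base = pi1, iterations = 8000,
                                     burn_in = 500, seed = 9)
  expect_gt(p_tilt$P[1], p_tilt$P[2])
})

test_that("bsFDR score is the printed ratio plus a companion Bayesian FDR", {
  expect_equal(bsfdr_score(0.8, 1, 1)$bsfdr_score, 0.8)
  expect_equal(bsfdr_score(c(1, 0), c(1, 1), c(1, 1))$bsfdr_score, 0.5)
  s <- bsfdr_score(c(0.9, 0.2), c(1, 1), c(2, 1), selection = 1)
  expect_equal(s$bayes_fdr, 0.1, tolerance = 1e-12)
  expect_error(bsfdr_score(c(0.5, 0.5), c(1, 1), c(0, 0)), "positive")
})

test_that("the MAF-indexed decision rule thresholds P at 1 - MAF", {
  # a posterior of 0.90 clears the bar at MAF 0.127 (threshold 0.873)
  expect_true(significance_decision(0.90, 0.127))
  expect_false(significance_decision(0.5, 0.05))
  expect_warning(flag0 <- significance_decision(0.999, 0), "never")
  expect_false(flag0)
  expect_error(significance_decision(0.5, 0.7), "0, 0.5")
})

test_that("bsfdr wrapper runs end-to-end and flags planted signal first", {
  cfg <- sim_config(n = 120, m = 300, n_qtl = 3, h2 = 0.6, qtl_frac = 1,
                    missing_rate = 0, seed = 41)
  gen <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(gen$genotypes, cfg)
  hn <- ph$phenotype[ph$phenotype$treatment == "HN", ]
  y <- hn$value
  names(y) <- hn$sample_id
  Gf <- suppressMessages(filter_snps(gen$genotypes))
  res <- bsfdr(Gf, y, iterations = 4000, burn_in = 500, seed = 41)
  expect_s3_class(res, "bsfdr_result")
  expect_true(all(res$posterior$P >= 0 & res$posterior$P <= 1))
  expect_true(all(res$posterior$lambda > 0))
  truth <- res$posterior$snp %in% ph$qtl_ids
  expect_gt(mean(res$posterior$P[truth]), mean(res$posterior$P[!truth]))
})
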
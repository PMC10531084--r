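#' Build the allele-event table for one SNP
#'
#' Casts a single SNP into survival form: each individual receives a
#' pseudo-time equal to the ascending rank of its trait value (ties broken
#' by sample id, lexicographically), so "time" runs from the lowest- to
#' the highest-yielding individual. Carriers of the minor allele
#' (heterozygotes and minor homozygotes) are events at their own
#' pseudo-time; major homozygotes (and missing calls) are censored at
#' theirs. Allele classes are taken directly from the dosage coding
#' (0 = major homozygote, 1 = heterozygote, 2 = minor homozygote).
#'
#' @param snp_dosage numeric vector in `{0, 1, 2, NA}` for one SNP.
#' @param y numeric trait vector (or phenotype data.frame) aligned to it.
#' @param sample_ids optional ids for tie-breaking; defaults to names of
#'   `y` or `ind1..n`.
#' @return data.frame of class `allele_event_table` with columns
#'   `sample_id`, `trait`, `time` (1..n permutation), `dosage`,
#'   `allele_class`, `event`, `censored`. A monomorphic column yields zero
#'   events and sets the attribute `monomorphic = TRUE` with a warning.
#' @export
build_event_table <- function(snp_dosage, y, sample_ids = NULL) {
  y <- pheno_values(y)
  n <- length(y)
  if (length(snp_dosage) != n) stop("dosage and trait lengths differ")
  if (n < 4L) stop("need at least 4 individuals")
  if (is.null(sample_ids)) {
    sample_ids <- names(y)
    if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(n))
  }
  ord <- order(y, sample_ids)
  time <- integer(n)
  time[ord] <- seq_len(n)
  cls <- rep("missing", n)
  cls[!is.na(snp_dosage) & snp_dosage == 0] <- "major_hom"
  cls[!is.na(snp_dosage) & snp_dosage == 1] <- "het"
  cls[!is.na(snp_dosage) & snp_dosage == 2] <- "minor_hom"
  event <- cls %in% c("het", "minor_hom")
  tab <- data.frame(sample_id = sample_ids, trait = unname(y), time = time,
                    dosage = as.numeric(snp_dosage), allele_class = cls,
                    event = event, censored = !event,
                    stringsAsFactors = FALSE)
  class(tab) <- c("allele_event_table", "data.frame")
  mono <- sum(event) == 0L
  attr(tab, "monomorphic") <- mono
  if (mono) warning("SNP column carries no minor alleles: zero events")
  tab
}

#' Nelson-Aalen cumulative hazard and survival curve
#'
#' Computes the Nelson-Aalen estimator `H(t) = sum_{t_i <= t} d_i / n_i`
#' over the event times of an allele-event table (via
#' [survival::survfit()]), and the survival curve `S(t) = exp(-H(t))`.
#'
#' @param tab an [build_event_table()] result, or any data.frame with
#'   `time` and `event` columns.
#' @return data.frame of class `survival_curve` with one row per event
#'   time: `time`, `n_risk`, `n_event`, `H`, `S`. Zero rows when there are
#'   no events (S identically 1).
#' @export
nelson_aalen <- function(tab) {
  stopifnot(all(c("time", "event") %in% names(tab)))
  if (sum(tab$event) == 0L) {
    out <- data.frame(time = numeric(0), n_risk = numeric(0),
                      n_event = numeric(0), H = numeric(0), S = numeric(0))
    class(out) <- c("survival_curve", "data.frame")
    return(out)
  }
  sf <- survival::survfit(survival::Surv(tab$time, tab$event) ~ 1)
  keep <- sf$n.event > 0
  H <- cumsum(sf$n.event / sf$n.risk)[keep]
  out <- data.frame(time = sf$time[keep], n_risk = sf$n.risk[keep],
                    n_event = sf$n.event[keep], H = H, S = exp(-H))
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Per-allele-class survival curves for one SNP
#'
#' Each allele class is followed along the phenotype-ranked pseudo-time as
#' its own cohort: within a class every member is an "event" at its own
#' pseudo-time (time of appearance along the trait ranking). A class whose
#' members concentrate among high-trait individuals loses its risk set
#' late and therefore survives longer; its mean `S` summarises where in
#' the trait distribution the class lives.
#'
#' @param tab an [build_event_table()] result.
#' @return named list of `survival_curve` objects, one per class present
#'   among `major_hom`, `het`, `minor_hom`, `missing`.
#' @export
class_survival_curves <- function(tab) {
  stopifnot(inherits(tab, "allele_event_table"))
  classes <- intersect(c("major_hom", "het", "minor_hom", "missing"),
                       unique(tab$allele_class))
  out <- lapply(classes, function(cl) {
    sub <- tab[tab$allele_class == cl, , drop = FALSE]
    cv <- nelson_aalen(data.frame(time = sub$time, event = TRUE))
    attr(cv, "n_members") <- nrow(sub)
    cv
  })
  names(out) <- classes
  out
}

#' Summarise per-class survival: mean S, SE and survived flags
#'
#' For each class curve, the mean and standard error of `S` over the
#' class's event grid are reported; a class is flagged "survived" when it
#' has at least `min_count` members and its mean survival is at least
#' `floor`.
#'
#' @param curves a named list of `survival_curve`s
#'   (from [class_survival_curves()]), or an `allele_event_table`.
#' @param min_count minimum class size to count as survived (default 3).
#' @param floor minimum mean S to count as survived (default 0.05).
#' @return data.frame with columns `class`, `n`, `mean_S`, `se_S`,
#'   `survived`. Classes with an empty grid report `mean_S = 1` (no
#'   events: survival never drops).
#' @export
summarize_survival <- function(curves, min_count = 3, floor = 0.05) {
  if (inherits(curves, "allele_event_table")) curves <- class_survival_curves(curves)
  if (length(curves) == 0L) stop("no allele classes present")
  rows <- lapply(names(curves), function(cl) {
    cv <- curves[[cl]]
    n_members <- attr(cv, "n_members")
    if (is.null(n_members)) n_members <- if (nrow(cv)) sum(cv$n_event) else 0L
    if (nrow(cv) == 0L) {
      mean_s <- 1; se_s <- 0
    } else {
      mean_s <- mean(cv$S)
      se_s <- stats::sd(cv$S) / sqrt(nrow(cv))
      if (is.na(se_s)) se_s <- 0
    }
    data.frame(class = cl, n = n_members, mean_S = mean_s, se_S = se_s,
               survived = n_members >= min_count && mean_s >= floor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exponential proportional-hazards fit of an allele-event table
#'
#' Fits the constant-hazard model `lambda(t | x) = lambda0 * exp(beta x)`
#' with `x` the SNP dosage, by profile Newton iteration on `beta`
#' (`lambda0` has the closed form `d / sum(exp(beta x_i) t_i)` at each
#' step; tolerance 1e-8, at most 100 iterations). Also returns the null
#' model (`beta = 0`), whose maximum-likelihood rate is
#' `events / total exposure`. Information criteria use the event count
#' `d` as the effective sample size: `AIC = 2k - 2 logL`,
#' `BIC = k log(d) - 2 logL`.
#'
#' @param tab an [build_event_table()] result (uses columns `time`,
#'   `event`, `dosage`), or any data.frame with those columns.
#' @param covariate optional replacement covariate vector (defaults to
#'   `tab$dosage`).
#' @return list of class `exp_ph_fit`: `rate0`, `logL0`, `AIC0`, `BIC0`
#'   (null model), `lambda0`, `beta`, `logL`, `AIC`, `BIC` (covariate
#'   model), `n_events`, `identifiable` (FALSE when the covariate is
#'   constant, in which case the covariate model mirrors the null fit).
#'   Errors when there are no events.
#' @export
fit_exponential_ph <- function(tab, covariate = NULL) {
  stopifnot(all(c("time", "event") %in% names(tab)))
  t_i <- as.numeric(tab$time)
  ev <- as.logical(tab$event)
  d <- sum(ev)
  if (d == 0L) stop("no events: exponential hazard is not estimable")
  x <- if (is.null(covariate)) tab$dosage else as.numeric(covariate)
  x[is.na(x)] <- 0

  exposure <- sum(t_i)
  rate0 <- d / exposure
  logL0 <- d * log(rate0) - rate0 * exposure
  k0 <- 1
  AIC0 <- 2 * k0 - 2 * logL0
  BIC0 <- k0 * log(d) - 2 * logL0

  identifiable <- stats::sd(x) > 0
  if (!identifiable) {
    out <- list(rate0 = rate0, logL0 = logL0, AIC0 = AIC0, BIC0 = BIC0,
                lambda0 = rate0, beta = 0, logL = logL0,
                AIC = AIC0, BIC = BIC0, n_events = d, identifiable = FALSE)
    class(out) <- "exp_ph_fit"
    return(out)
  }

  # profile log-likelihood in beta: lambda0(beta) = d / sum(e^{beta x} t)
  sx <- sum(x[ev])
  profile <- function(beta) {
    E <- sum(exp(beta * x) * t_i)
    d * log(d / E) + beta * sx - d
  }
  beta <- 0
  for (it in seq_len(100)) {
    e <- exp(beta * x) * t_i
    E <- sum(e); E1 <- sum(x * e); E2 <- sum(x^2 * e)
    grad <- sx - d * E1 / E
    hess <- -d * (E2 / E - (E1 / E)^2)
    if (abs(hess) < 1e-12) break
    step <- grad / hess
    # damped Newton: halve until the profile likelihood does not decrease
    ll_old <- profile(beta)
    new_beta <- beta - step
    half <- 0
    while (profile(new_beta) < ll_old - 1e-12 && half < 30) {
      step <- step / 2
      new_beta <- beta - step
      half <- half + 1
    }
    conv <- abs(new_beta - beta) < 1e-8
    beta <- new_beta
    if (conv) break
  }
  lambda0 <- d / sum(exp(beta * x) * t_i)
  logL <- sum(ev * (log(lambda0) + beta * x)) - lambda0 * sum(exp(beta * x) * t_i)
  k <- 2
  out <- list(rate0 = rate0, logL0 = logL0, AIC0 = AIC0, BIC0 = BIC0,
              lambda0 = lambda0, beta = beta, logL = logL,
              AIC = 2 * k - 2 * logL, BIC = k * log(d) - 2 * logL,
              n_events = d, identifiable = TRUE)
  class(out) <- "exp_ph_fit"
  out
}

#' Bayes survived factor
#'
#' The per-SNP hazard-scale weight `lambda_SNP = lambda0 * exp(beta_GY)`
#' that carries survival information into the spike-and-slab prior. With
#' the flat-prior convention `lambda0 = 1` and `exp(beta_GY) = 0.001`,
#' every SNP receives the same weight 0.001 and the prior is
#' uninformative.
#'
#' @param lambda0 baseline hazard factor (> 0).
#' @param beta_gy log hazard-scale regression coefficient of the trait
#'   vector (genome-wide or per-SNP).
#' @return `lambda0 * exp(beta_gy)`.
#' @examples
#' bayes_survived_factor(1, log(0.001))  # the flat prior: 0.001
#' @export
bayes_survived_factor <- function(lambda0, beta_gy) {
  if (any(lambda0 <= 0)) stop("lambda0 must be strictly positive")
  lambda0 * exp(beta_gy)
}

#' Posterior inclusion probabilities by binary-indicator MCMC
#'
#' Gibbs sampling over a two-group spike-and-slab model for the z-scores:
#' `z | gamma = 0 ~ N(0, 1)` (null) and `z | gamma = 1 ~ N(0, 1 + tau2)`
#' (signal). The per-SNP prior odds of inclusion are
#' `(pi1_base / (1 - pi1_base)) * lambda_j / mean(lambda)`, so the Bayes
#' survived factors tilt the prior while the average prior inclusion stays
#' at `pi1_base`. The posterior inclusion probability of each SNP is the
#' post-burn-in mean of its indicator.
#'
#' The published run length is 150,000 iterations with a burn-in of 2,000;
#' desk-scale analyses (and this package's tests) use 10,000 / 1,000,
#' which is ample because the indicators mix in one step.
#'
#' @param z numeric z-score vector.
#' @param lambda per-SNP Bayes survived factors (> 0); a scalar is
#'   recycled (flat prior).
#' @param pi1_base prior signal fraction in (0, 1) (default 0.05; a
#'   natural choice is `1 - pi0` from [fit_local_fdr()]).
#' @param tau2 slab variance inflation (default 4).
#' @param iterations,burn_in MCMC settings; defaults 150000 / 2000.
#' @param seed integer RNG seed.
#' @return data.frame of class `posterior_table`: `z`, `lambda`, `P`
#'   (posterior inclusion), plus attributes `settings` (iterations,
#'   burn-in, seed, tau2, pi1_base) and `analytic_P` (the closed-form
#'   per-SNP posterior, available here because the indicators are
#'   conditionally independent given the fixed prior odds).
#' @export
mcmc_posterior_inclusion <- function(z, lambda = 1, pi1_base = 0.05,
                                     tau2 = 4, iterations = 150000,
                                     burn_in = 2000, seed = 1L) {
  z <- as.numeric(z)
  if (any(!is.finite(z))) stop("z must be finite")
  m <- length(z)
  lambda <- rep_len(as.numeric(lambda), m)
  if (any(lambda <= 0)) stop("lambda factors must be strictly positive")
  if (pi1_base <= 0 || pi1_base >= 1) stop("pi1_base must lie in (0, 1)")
  if (iterations <= burn_in) stop("iterations must exceed burn_in")

  prior_odds <- (pi1_base / (1 - pi1_base)) * lambda / mean(lambda)
  lr <- stats::dnorm(z, 0, sqrt(1 + tau2)) / stats::dnorm(z, 0, 1)
  post_odds <- prior_odds * lr
  p_full <- post_odds / (1 + post_odds)
  p_full[is.na(p_full)] <- 1        # dnorm underflow at huge |z|: odds -> Inf

  set.seed(seed)
  keep <- iterations - burn_in
  acc <- numeric(m)
  for (it in seq_len(iterations)) {
    gamma <- stats::runif(m) < p_full
    if (it > burn_in) acc <- acc + gamma
  }
  out <- data.frame(z = z, lambda = lambda, P = acc / keep)
  class(out) <- c("posterior_table", "data.frame")
  attr(out, "settings") <- list(iterations = iterations, burn_in = burn_in,
                                seed = seed, tau2 = tau2,
                                pi1_base = pi1_base)
  attr(out, "analytic_P") <- p_full
  out
}

#' Bayesian survival FDR score
#'
#' The set-level score
#' \deqn{\mathrm{bsFDR} = \frac{\sum_j P(\theta_j \in \Theta_1 \mid
#'   \lambda_j \theta_j)}{\sum_j \lambda_j \hat\theta_j}}
#' with \eqn{\hat\theta_j = |z_j|} as the standardized effect magnitude.
#' Note this ratio is a model-comparison score, not a rate constrained to
#' `[0, 1]`; the companion `bayes_fdr` — the mean posterior null
#' probability `mean(1 - P)` over a selection — is the quantity with the
#' usual FDR interpretation.
#'
#' @param P posterior inclusion probabilities.
#' @param lambda Bayes survived factors, aligned to `P`.
#' @param theta_hat standardized effect magnitudes `|z|`, aligned to `P`.
#' @param selection optional index vector over which `bayes_fdr` is
#'   computed (default: all).
#' @return list with `bsfdr_score` and `bayes_fdr`.
#' @export
bsfdr_score <- function(P, lambda, theta_hat, selection = NULL) {
  P <- as.numeric(P)
  lambda <- rep_len(as.numeric(lambda), length(P))
  theta_hat <- as.numeric(theta_hat)
  if (length(theta_hat) != length(P)) stop("theta_hat not aligned to P")
  denom <- sum(lambda * theta_hat)
  if (denom <= 0) stop("sum(lambda * theta_hat) must be positive")
  if (is.null(selection)) selection <- seq_along(P)
  bayes_fdr <- if (length(selection)) mean(1 - P[selection]) else NA_real_
  list(bsfdr_score = sum(P) / denom, bayes_fdr = bayes_fdr)
}

#' MAF-indexed posterior significance rule
#'
#' A SNP is declared significant when its posterior inclusion probability
#' exceeds `1 - MAF`: rare alleles must clear a higher posterior bar, so
#' the nominal per-SNP level of the rule equals the SNP's MAF. A MAF of 0
#' makes the threshold 1 and the SNP can never be declared (a warning is
#' emitted).
#'
#' @param P posterior inclusion probabilities in `[0, 1]`.
#' @param maf per-SNP minor allele frequencies in `[0, 0.5]`.
#' @return logical significance flags.
#' @export
significance_decision <- function(P, maf) {
  P <- as.numeric(P); maf <- as.numeric(maf)
  if (length(P) != length(maf)) stop("P and maf must be aligned")
  if (any(P < 0 | P > 1, na.rm = TRUE)) stop("P must lie in [0, 1]")
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) stop("maf must lie in [0, 0.5]")
  if (any(maf == 0, na.rm = TRUE))
    warning("MAF 0 makes the threshold 1: such SNPs can never be significant")
  flags <- P > 1 - maf
  flags[is.na(flags)] <- FALSE
  flags
}

#' End-to-end Bayesian survival FDR for a genotype/phenotype pair
#'
#' Convenience wrapper: builds the pooled allele-event table per SNP, fits
#' the exponential proportional-hazards model to obtain per-SNP Bayes
#' survived factors `lambda0 * exp(beta_SNP)` (plus a genome-wide
#' `beta_GY` from the pooled table), runs the binary-indicator MCMC on the
#' z-scores, applies the MAF-indexed decision rule, and computes the
#' bsFDR score.
#'
#' @param G a filtered [genotype_matrix()].
#' @param y numeric trait vector (or phenotype data.frame) aligned to `G`.
#' @param stats optional `summary_stats` with a filled `z` column aligned
#'   to the SNPs of `G`; when `NULL` a [single_locus_scan()] +
#'   [p_to_z()] is run internally (with the GRM of `G`).
#' @param pi1_base prior signal fraction (default 0.05).
#' @param iterations,burn_in,seed MCMC settings (defaults 150000 / 2000 /
#'   1).
#' @param tau2 slab variance (default 4).
#' @return list of class `bsfdr_result`: `posterior` (per-SNP table with
#'   `snp`, `z`, `maf`, `lambda`, `beta`, `P`, `alpha`, `significant`),
#'   `beta_gy` (genome-wide coefficient from the pooled event table),
#'   `bsfdr_score`, `bayes_fdr` (over the significant set), `settings`.
#' @export
bsfdr <- function(G, y, stats = NULL, pi1_base = 0.05, iterations = 150000,
                  burn_in = 2000, tau2 = 4, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  yv <- pheno_values(y)
  if (is.null(stats)) {
    K <- compute_grm(G)
    stats <- p_to_z(single_locus_scan(yv, G, K))
  }
  if (!all(G$snp_meta$id %in% stats$snp))
    stop("summary statistics do not cover all SNPs in G")
  stats <- stats[match(G$snp_meta$id, stats$snp), , drop = FALSE]
  z <- stats$z
  if (any(is.na(z))) stop("summary statistics must carry z (run p_to_z)")

  m <- ncol(G$dosage)
  qc <- snp_qc_metrics(G)
  beta_snp <- numeric(m)
  lambda0_snp <- numeric(m)
  for (j in seq_len(m)) {
    tab <- suppressWarnings(build_event_table(G$dosage[, j], yv,
                                              sample_ids = G$sample_ids))
    if (attr(tab, "monomorphic")) {
      beta_snp[j] <- 0
      lambda0_snp[j] <- 1
      next
    }
    fit <- fit_exponential_ph(tab)
    beta_snp[j] <- fit$beta
    lambda0_snp[j] <- fit$lambda0
  }
  lambda <- bayes_survived_factor(lambda0_snp, beta_snp)

  # genome-wide beta: pooled event table over all SNPs (stacked)
  pooled <- do.call(rbind, lapply(seq_len(min(m, 500L)), function(j) {
    tab <- suppressWarnings(build_event_table(G$dosage[, j], yv,
                                              sample_ids = G$sample_ids))
    tab[, c("time", "event", "dosage")]
  }))
  beta_gy <- if (sum(pooled$event) > 0 && stats::sd(pooled$dosage, na.rm = TRUE) > 0)
    fit_exponential_ph(pooled)$beta else 0

  post <- mcmc_posterior_inclusion(z, lambda = lambda, pi1_base = pi1_base,
                                   tau2 = tau2, iterations = iterations,
                                   burn_in = burn_in, seed = seed)
  flags <- suppressWarnings(significance_decision(post$P, qc$maf))
  score <- bsfdr_score(post$P, lambda, abs(z),
                       selection = if (any(flags)) which(flags) else NULL)
  tabout <- data.frame(snp = G$snp_meta$id, z = z, maf = qc$maf,
                       lambda = lambda, beta = beta_snp, P = post$P,
                       alpha = qc$maf, significant = flags,
                       stringsAsFactors = FALSE)
  structure(list(posterior = tabout, beta_gy = beta_gy,
                 bsfdr_score = score$bsfdr_score,
                 bayes_fdr = score$bayes_fdr,
                 settings = attr(post, "settings")),
            class = "bsfdr_result")
}

#' @export
print.bsfdr_result <- function(x, ...) {
  cat(sprintf("Bayesian survival FDR: %d SNPs, %d significant (P > 1 - MAF)\n",
              nrow(x$posterior), sum(x$posterior$significant)))
  cat(sprintf("  bsFDR score %.4g; Bayesian FDR over selection %.4g; beta_GY %.4g\n",
              x$bsfdr_score, x$bayes_fdr, x$beta_gy))
  invisible(x)
}
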
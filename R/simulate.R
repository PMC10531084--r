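#' Simulation configuration for a structured selfing GWAS panel
#'
#' The defaults emulate a typical elite bread-wheat association panel: 221
#' genotypes in 3 subpopulations, strong selfing (inbreeding 0.95), mild
#' divergence (Fst 0.1), a MAF floor of 0.05 on ancestral frequencies, a
#' quantitative trait with a few moderate QTLs plus a polygenic
#' background, baseline mean 6400 and standard deviation 145.16 (grain
#' yield, g/m2) under the high-nitrogen condition, and a
#' low-nitrogen condition shifted down by `treatment_shift`.
#'
#' @param n individuals (default 221).
#' @param m SNPs (default 2000).
#' @param n_subpops subpopulation count (default 3).
#' @param fst Balding-Nichols divergence in `[0, 1)` (default 0.1).
#' @param selfing inbreeding coefficient in `[0, 1]` (default 0.95).
#' @param maf_floor lower bound of ancestral allele frequencies (default
#'   0.05).
#' @param missing_rate per-call missing probability (default 0.01).
#' @param n_qtl number of discrete QTLs (default 10).
#' @param h2 narrow-sense heritability of the trait in `[0, 1]` (default
#'   0.3).
#' @param qtl_frac fraction of the genetic variance carried by the
#'   discrete QTLs, the rest polygenic (default 0.7).
#' @param trait_mean,trait_sd phenotype location/scale (defaults 6400,
#'   145.16).
#' @param treatment_shift high-N minus low-N mean difference in trait
#'   units (default 500).
#' @param outlier_rate probability of a 5-sd phenotype shift (default 0).
#' @param seed integer RNG seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = 221, m = 2000, n_subpops = 3, fst = 0.1,
                       selfing = 0.95, maf_floor = 0.05,
                       missing_rate = 0.01, n_qtl = 10, h2 = 0.3,
                       qtl_frac = 0.7, trait_mean = 6400,
                       trait_sd = 145.16, treatment_shift = 500,
                       outlier_rate = 0, seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducible simulation")
  stopifnot(n >= 2, m >= 1, n_subpops >= 1, fst >= 0, fst < 1,
            selfing >= 0, selfing <= 1, maf_floor >= 0, maf_floor < 0.5,
            missing_rate >= 0, missing_rate < 1, n_qtl >= 0, n_qtl <= m,
            h2 >= 0, h2 <= 1, qtl_frac >= 0, qtl_frac <= 1, trait_sd > 0,
            outlier_rate >= 0, outlier_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate structured genotypes (Balding-Nichols with selfing)
#'
#' Ancestral allele frequencies are uniform on
#' `(maf_floor, 1 - maf_floor)`; each subpopulation draws its frequency
#' from `Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)` (identical to the ancestor
#' when `Fst = 0`); genotypes are drawn with an excess-homozygosity
#' inbreeding coefficient equal to the selfing rate, and calls are masked
#' at `missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @return list: `genotypes` (a [genotype_matrix()]), `subpop` (integer
#'   labels), `subpop_freq` (n_subpops x m frequency matrix).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n; m <- cfg$m; K <- cfg$n_subpops
  p_anc <- stats::runif(m, cfg$maf_floor, 1 - cfg$maf_floor)
  pf <- matrix(0, K, m)
  for (k in seq_len(K)) {
    pf[k, ] <- if (cfg$fst > 0) {
      a <- p_anc * (1 - cfg$fst) / cfg$fst
      b <- (1 - p_anc) * (1 - cfg$fst) / cfg$fst
      stats::rbeta(m, a, b)
    } else p_anc
  }
  subpop <- rep(seq_len(K), length.out = n)
  f <- cfg$selfing
  dos <- matrix(NA_real_, n, m)
  for (k in seq_len(K)) {
    idx <- which(subpop == k)
    p <- pf[k, ]
    # genotype probabilities with inbreeding F: excess homozygosity
    p_hom_alt <- rep(p^2 + f * p * (1 - p), each = length(idx))
    p_het <- rep(2 * p * (1 - p) * (1 - f), each = length(idx))
    u <- stats::runif(length(idx) * m)
    g <- ifelse(u < p_hom_alt, 2, ifelse(u < p_hom_alt + p_het, 1, 0))
    dos[idx, ] <- matrix(g, nrow = length(idx))
  }
  if (cfg$missing_rate > 0)
    dos[stats::runif(n * m) < cfg$missing_rate] <- NA_real_
  meta <- data.frame(id = sprintf("snp%05d", seq_len(m)),
                     chr = as.character(1 + (seq_len(m) - 1) %% 21),
                     pos = 1000 * seq_len(m), ref = "A", alt = "B",
                     stringsAsFactors = FALSE)
  G <- genotype_matrix(dos, snp_meta = meta,
                       sample_ids = sprintf("geno%04d", seq_len(n)))
  list(genotypes = G, subpop = subpop, subpop_freq = pf)
}

#' Simulate a quantitative trait on a genotype panel
#'
#' The genetic value is the sum of `n_qtl` discrete additive QTL effects
#' (drawn N(0,1) on centred dosages, then rescaled) and a polygenic term
#' drawn from `N(0, K)` with `K` the panel's genomic relationship matrix.
#' Components are empirically rescaled so the genetic fraction of the
#' phenotypic variance equals `h2` and the QTLs carry `qtl_frac` of it;
#' residual noise makes up the rest. Trait values are reported under both
#' treatments (`HN` at `trait_mean`, `LN` shifted down by
#' `treatment_shift`, with independent residuals). Outliers, when
#' requested, are symmetric 5-sd shifts.
#'
#' @param G a [genotype_matrix()] (typically from
#'   [simulate_genotypes()]).
#' @param cfg the [sim_config()] used (its `seed` offsets the genotype
#'   seed so genotype and phenotype draws are decoupled).
#' @return list: `phenotype` (data.frame `sample_id`, `value`,
#'   `treatment`, both treatments stacked), `qtl_ids`, `qtl_effects`,
#'   `genetic_values` (named, HN scale).
#' @export
simulate_phenotype <- function(G, cfg) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(G$dosage); m <- ncol(G$dosage)
  sd_p <- cfg$trait_sd

  qtl_idx <- if (cfg$n_qtl > 0) sort(sample.int(m, cfg$n_qtl)) else integer(0)
  g_qtl <- rep(0, n)
  eff <- numeric(0)
  if (length(qtl_idx)) {
    Wq <- G$dosage[, qtl_idx, drop = FALSE]
    Wq[is.na(Wq)] <- 0
    Wq <- scale(Wq, center = TRUE, scale = FALSE)
    eff <- stats::rnorm(length(qtl_idx))
    g_qtl <- drop(Wq %*% eff)
  }
  g_poly <- rep(0, n)
  if (cfg$h2 * (1 - cfg$qtl_frac) > 0) {
    Kmat <- compute_grm(G)$K
    ch <- chol(Kmat + diag(1e-6, n))
    g_poly <- drop(crossprod(ch, stats::rnorm(n)))
  }
  rescale <- function(x, target_var) {
    v <- stats::var(x)
    if (v <= 0 || target_var <= 0) return(rep(0, length(x)))
    x * sqrt(target_var / v)
  }
  g_qtl <- rescale(g_qtl, cfg$h2 * cfg$qtl_frac * sd_p^2)
  g_poly <- rescale(g_poly, cfg$h2 * (1 - cfg$qtl_frac) * sd_p^2)
  genetic <- g_qtl + g_poly
  noise_sd <- sqrt(max(0, (1 - cfg$h2)) * sd_p^2)

  make_values <- function(mu) {
    e <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
    v <- mu + genetic + e
    if (cfg$outlier_rate > 0) {
      hit <- stats::runif(n) < cfg$outlier_rate
      v[hit] <- v[hit] + sample(c(-5, 5), sum(hit), replace = TRUE) * sd_p
    }
    v
  }
  ph <- rbind(
    data.frame(sample_id = G$sample_ids, value = make_values(cfg$trait_mean),
               treatment = "HN", stringsAsFactors = FALSE),
    data.frame(sample_id = G$sample_ids,
               value = make_values(cfg$trait_mean - cfg$treatment_shift),
               treatment = "LN", stringsAsFactors = FALSE))
  names(genetic) <- G$sample_ids
  list(phenotype = ph, qtl_ids = G$snp_meta$id[qtl_idx],
       qtl_effects = eff, genetic_values = genetic)
}

#' Simulate z-values from a two-group mixture
#'
#' Each test is null with probability `pi0` (`z ~ N(0, 1)`) and signal
#' otherwise (`z ~ N(mu1, sd1^2)`); truth labels are returned so FDR
#' operating characteristics can be measured.
#'
#' @param m number of tests.
#' @param pi0 null fraction in `[0, 1]`.
#' @param mu1,sd1 signal component mean and sd.
#' @param seed integer RNG seed.
#' @return list: `z` (length m), `is_null` (logical).
#' @export
simulate_zvalues <- function(m, pi0 = 0.95, mu1 = 3, sd1 = 1, seed = 1L) {
  stopifnot(m >= 1, pi0 >= 0, pi0 <= 1, sd1 > 0)
  set.seed(seed)
  is_null <- stats::runif(m) < pi0
  z <- ifelse(is_null, stats::rnorm(m), stats::rnorm(m, mu1, sd1))
  list(z = z, is_null = is_null)
}
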
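#' Read a phenotype table
#'
#' Expects columns `sample_id`, `value` and optionally `treatment`
#' (e.g. nitrogen level LN/HN). Separator is sniffed from the extension
#' (`.tsv` tab, otherwise comma).
#'
#' @param path TSV/CSV file.
#' @param treatment optional label; when given, only rows with that
#'   treatment are returned.
#' @return data.frame with columns `sample_id`, `value`, `treatment`.
#' @export
read_phenotype <- function(path, treatment = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "value") %in% names(df)))
    stop("phenotype file must have columns sample_id and value")
  if (!"treatment" %in% names(df)) df$treatment <- "all"
  if (!is.null(treatment)) {
    df <- df[df$treatment == treatment, , drop = FALSE]
    if (nrow(df) == 0L) stop("no phenotype rows with treatment ", treatment)
  }
  df[, c("sample_id", "value", "treatment")]
}

# accept either a bare numeric vector or a phenotype data.frame
pheno_values <- function(y) {
  if (is.data.frame(y)) {
    if (!"value" %in% names(y)) stop("phenotype data.frame needs a 'value' column")
    v <- y$value
    names(v) <- y$sample_id
    v
  } else {
    as.numeric(y)
  }
}

#' Classical bootstrap of the trait mean
#'
#' Resamples the trait vector with replacement `B` times (B = 2000 by
#' default) and summarises the replicate means: bootstrap standard error,
#' percentile 95% confidence interval, and the Shapiro-Wilk normality
#' p-value of each replicate sample.
#'
#' @param y numeric trait vector (or phenotype data.frame).
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer RNG seed.
#' @return list of class `bootstrap_summary`: `B`, `replicate_means`,
#'   `boot_se`, `ci95`, `replicate_normality_p`, `mean`, `shapiro_p` (of
#'   the original vector, `NA` if degenerate), `method`, `seed`.
#' @export
bootstrap_mean <- function(y, B = 2000, seed = 1L) {
  y <- pheno_values(y)
  check_trait(y)
  if (B < 2) stop("B must be at least 2")
  set.seed(seed)
  n <- length(y)
  means <- numeric(B)
  norm_p <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    yb <- y[sample.int(n, n, replace = TRUE)]
    means[b] <- mean(yb)
    norm_p[b] <- safe_shapiro_p(yb)
  }
  boot_summary(y, means, norm_p, B, seed, method = "classical")
}

#' Bayesian bootstrap of the trait mean
#'
#' Replaces multinomial resampling with flat-Dirichlet observation weights
#' (Rubin's Bayesian bootstrap): each replicate draws
#' `w ~ Dirichlet(1, ..., 1)` and records the weighted mean. A summary
#' normality probability (`bayes_boot_p`) is the median Shapiro-Wilk
#' p-value over weighted resamples of size n, one per replicate.
#'
#' @inheritParams bootstrap_mean
#' @return a `bootstrap_summary` with the additional field `bayes_boot_p`.
#' @export
bayesian_bootstrap <- function(y, B = 2000, seed = 1L) {
  y <- pheno_values(y)
  check_trait(y)
  if (B < 2) stop("B must be at least 2")
  set.seed(seed)
  n <- length(y)
  means <- numeric(B)
  norm_p <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    w <- stats::rgamma(n, shape = 1)
    w <- w / sum(w)
    means[b] <- sum(w * y)
    yb <- sample(y, n, replace = TRUE, prob = w)
    norm_p[b] <- safe_shapiro_p(yb)
  }
  out <- boot_summary(y, means, norm_p, B, seed, method = "bayesian")
  out$bayes_boot_p <- stats::median(norm_p, na.rm = TRUE)
  out
}

check_trait <- function(y) {
  if (length(y) < 3L) stop("need at least 3 trait values")
  if (any(!is.finite(y))) stop("trait values must all be finite")
  invisible(TRUE)
}

safe_shapiro_p <- function(x) {
  if (length(unique(x)) < 3L) return(NA_real_)
  stats::shapiro.test(x)$p.value
}

boot_summary <- function(y, means, norm_p, B, seed, method) {
  ci <- unname(stats::quantile(means, c(0.025, 0.975), type = 7))
  structure(list(B = B,
                 replicate_means = means,
                 boot_se = stats::sd(means),
                 ci95 = ci,
                 replicate_normality_p = norm_p,
                 mean = mean(y),
                 shapiro_p = safe_shapiro_p(y),
                 method = method,
                 seed = seed),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("%s bootstrap (B = %d): mean %.4g, SE %.4g, 95%% CI [%.4g, %.4g]\n",
              x$method, x$B, x$mean, x$boot_se, x$ci95[1], x$ci95[2]))
  if (!is.null(x$bayes_boot_p))
    cat(sprintf("  Bayesian bootstrap normality p = %.4g\n", x$bayes_boot_p))
  invisible(x)
}

#' Shapiro-Wilk normality check of a trait vector
#'
#' @param y numeric trait vector (or phenotype data.frame), 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
normality_test <- function(y) {
  y <- pheno_values(y)
  if (length(y) < 3L || length(y) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (any(!is.finite(y))) stop("trait values must all be finite")
  st <- stats::shapiro.test(y)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Flag trait outliers by Tukey fences
#'
#' Values outside `[Q1 - k*IQR, Q3 + k*IQR]` are flagged. The default
#' policy is report-only: callers decide whether flagged observations are
#' removed (field records are often kept even when extreme).
#'
#' @param y numeric trait vector (or phenotype data.frame), n >= 4.
#' @param k fence multiplier (default 1.5; `Inf` flags nothing).
#' @return logical vector of flags, one per observation.
#' @export
detect_outliers <- function(y, k = 1.5) {
  y <- pheno_values(y)
  if (length(y) < 4L) stop("need at least 4 values to assess outliers")
  q <- stats::quantile(y, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  if (is.infinite(k)) return(rep(FALSE, length(y)))
  y < lo | y > hi
}
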
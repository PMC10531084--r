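#' Single-locus mixed-model association scan
#'
#' Fits the mixed linear model `y = X b + u + e` with `var(u) = K sigma_g^2`
#' and `var(e) = sigma_e^2 I`. The variance ratio is estimated once on the
#' null model by a one-dimensional restricted-likelihood grid over
#' heritability (99 points on 0.01..0.99, ties broken toward the lower
#' value) after a spectral decomposition of `K`; every SNP is then tested
#' by generalized least squares in the rotated coordinates, giving a Wald
#' effect, standard error and two-sided p-value on a t reference with
#' `n - rank(X) - 1` degrees of freedom.
#'
#' @param y numeric trait vector (or phenotype data.frame) aligned to `G`.
#' @param G a [genotype_matrix()].
#' @param K a `kinship_matrix` from [compute_grm()], or `NULL` for an
#'   identity kinship (plain regression with optional covariates).
#' @param covariates optional numeric matrix of extra fixed effects
#'   (intercept is always included).
#' @param h2 optional fixed heritability in `[0, 1)`; `h2 = 0` reduces the
#'   scan to ordinary least squares. `NULL` (default) estimates it.
#' @return data.frame of class `summary_stats` with one row per SNP:
#'   `snp`, `chr`, `pos`, `effect`, `se`, `p`, `z` (`NA` until
#'   [p_to_z()]), `maf`, `callrate`, `model_tag`. Monomorphic SNPs get a
#'   missing effect and `p = 1`. The chosen `h2` and variance components
#'   are attached as attributes.
#' @export
single_locus_scan <- function(y, G, K = NULL, covariates = NULL, h2 = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  y <- pheno_values(y)
  n <- length(y)
  if (n != nrow(G$dosage)) stop("phenotype length does not match genotypes")
  if (n < 3L) stop("need at least 3 individuals for the scan")
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  p_fixed <- ncol(X)
  if (n - p_fixed - 1L < 1L) stop("insufficient residual degrees of freedom")

  Kmat <- if (is.null(K)) diag(n) else K$K
  eig <- eigen(Kmat, symmetric = TRUE)
  if (is.null(h2)) {
    grid <- seq(0.01, 0.99, length.out = 99)
    ll <- vapply(grid, function(h) reml_loglik_X(y, X, h, eig), numeric(1))
    h2 <- grid[which.max(ll)]          # which.max returns the first (lowest h2) tie
  }
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  v <- h2 * d + (1 - h2)
  w <- 1 / sqrt(v)
  ys <- drop(crossprod(U, y)) * w
  Xs <- (crossprod(U, X)) * w

  dos <- G$dosage
  m <- ncol(dos)
  n_obs <- colSums(!is.na(dos))
  q <- colSums(dos, na.rm = TRUE) / (2 * pmax(n_obs, 1))
  maf <- pmin(q, 1 - q)
  maf[n_obs == 0] <- NA_real_

  eff <- se <- rep(NA_real_, m)
  pval <- rep(1, m)
  df <- n - p_fixed - 1L
  for (j in seq_len(m)) {
    g <- dos[, j]
    g[is.na(g)] <- 2 * q[j]            # mean impute for the test only
    if (stats::sd(g) == 0) next        # monomorphic: effect NA, p = 1
    gs <- drop(crossprod(U, g)) * w
    M <- cbind(Xs, gs)
    fit <- stats::lm.fit(M, ys)
    rss <- sum(fit$residuals^2)
    s2 <- rss / df
    XtXinv_gg <- chol2inv(chol(crossprod(M)))[p_fixed + 1L, p_fixed + 1L]
    eff[j] <- fit$coefficients[p_fixed + 1L]
    se[j] <- sqrt(s2 * XtXinv_gg)
    tt <- eff[j] / se[j]
    pval[j] <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  }
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)

  out <- data.frame(snp = G$snp_meta$id, chr = G$snp_meta$chr,
                    pos = G$snp_meta$pos, effect = eff, se = se, p = pval,
                    z = NA_real_, maf = maf, callrate = n_obs / n,
                    model_tag = "single_locus_mm", stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "h2") <- h2
  attr(out, "df") <- df
  out
}

# REML log-likelihood with an arbitrary fixed-effect design, in the
# eigenbasis of K (used for the scan's variance grid)
reml_loglik_X <- function(y, X, h2, eig) {
  n <- length(y)
  p <- ncol(X)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  v <- h2 * d + (1 - h2)
  w <- 1 / sqrt(v)
  ys <- drop(crossprod(U, y)) * w
  Xs <- crossprod(U, X) * w
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  rss <- sum((ys - Xs %*% beta)^2)
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * log(s2) + sum(log(v)) + determinant(XtX)$modulus[1] + (n - p))
}

#' Convert p-values to z-scores
#'
#' Fills the `z` column of a summary-statistics table:
#' `z = qnorm(1 - p/2) * sign(effect)` for the two-sided convention when an
#' effect estimate is present, else `z = qnorm(1 - p)` (one-sided, with
#' `p = 1` mapped to the null centre `z = 0`). P-values below `1e-15` are
#' clamped before inversion so z stays finite.
#'
#' @param stats a `summary_stats` data.frame (needs columns `p` and,
#'   optionally, `effect`), or a bare numeric p-value vector.
#' @param effect optional effect vector when `stats` is numeric.
#' @return the table with `z` filled (or a numeric z vector).
#' @export
p_to_z <- function(stats, effect = NULL) {
  if (is.data.frame(stats)) {
    z <- p_to_z(stats$p, effect = if ("effect" %in% names(stats)) stats$effect)
    stats$z <- z
    return(stats)
  }
  p <- as.numeric(stats)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p <- pmax(p, 1e-15)
  if (is.null(effect)) {
    # p = 1 carries no direction: mapped to the null centre z = 0 rather
    # than the one-sided limit -Inf
    ifelse(p == 1, 0, stats::qnorm(1 - p))
  } else {
    sgn <- sign(effect)
    sgn[is.na(sgn) | sgn == 0] <- 1
    stats::qnorm(1 - p / 2) * sgn
  }
}

#' Read / write GWAS summary statistics
#'
#' The TSV contract has fixed column names `snp, chr, pos, effect, se, p,
#' maf, callrate` (missing optional columns are tolerated and filled with
#' `NA`); any scan — internal or from an external GWAS package — enters
#' the FDR machinery through this table.
#'
#' @param path TSV file.
#' @return a `summary_stats` data.frame.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("snp", "p") %in% names(df)))
    stop("summary statistics need at least columns snp and p")
  for (col in c("chr", "pos", "effect", "se", "z", "maf", "callrate"))
    if (!col %in% names(df)) df[[col]] <- NA
  if (!"model_tag" %in% names(df)) df$model_tag <- "external"
  if (anyDuplicated(df$snp)) stop("duplicate SNP ids in summary statistics")
  bad <- !is.finite(df$p) | df$p <= 0 | df$p > 1
  if (any(bad)) stop(sum(bad), " p-values outside (0, 1]")
  df <- df[, c("snp", "chr", "pos", "effect", "se", "p", "z", "maf",
               "callrate", "model_tag")]
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' @rdname read_summary_stats
#' @param stats a `summary_stats` data.frame.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
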
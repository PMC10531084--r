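#' Per-SNP quality-control metrics
#'
#' Computes, for every SNP, the minor allele frequency (on non-missing
#' calls only), the call rate, and a Hardy-Weinberg equilibrium
#' goodness-of-fit p-value (1-df chi-square of observed genotype counts
#' against the expected p^2, 2pq, q^2 proportions, no continuity
#' correction). Note that in highly selfing species a heterozygote deficit
#' is expected, so the HWE filter is off by default downstream.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min,hwe_alpha,callrate_min thresholds used to set the `pass`
#'   flag (SNPs with `MAF <= maf_min` fail; `hwe_p < hwe_alpha` fails;
#'   `call_rate < callrate_min` fails). `hwe_alpha = 0` disables the HWE
#'   filter.
#' @return data.frame of class `snp_qc_report` with columns `id`, `maf`,
#'   `call_rate`, `hwe_chisq`, `hwe_p`, `pass`, `reason` (first failing
#'   filter among `callrate`, `maf`, `hwe`, else `kept`). All-missing SNPs
#'   get `NA` MAF/HWE and fail with reason `callrate`.
#' @examples
#' G <- genotype_matrix(cbind(s1 = c(0, 1, 2, NA)))
#' snp_qc_metrics(G)
#' @export
snp_qc_metrics <- function(G, maf_min = 0.05, hwe_alpha = 0,
                           callrate_min = 0.9) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosage
  n <- nrow(dos)
  n_obs <- colSums(!is.na(dos))
  call_rate <- n_obs / n
  q <- colSums(dos, na.rm = TRUE) / (2 * n_obs)   # alt-allele frequency
  q[n_obs == 0] <- NA_real_
  maf <- pmin(q, 1 - q)

  hwe <- vapply(seq_len(ncol(dos)), function(j) {
    x <- dos[, j]
    x <- x[!is.na(x)]
    nn <- length(x)
    if (nn == 0L) return(c(NA_real_, NA_real_))
    qj <- sum(x) / (2 * nn)
    if (qj <= 0 || qj >= 1) return(c(0, 1))      # monomorphic: nothing to test
    obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    expd <- nn * c((1 - qj)^2, 2 * qj * (1 - qj), qj^2)
    chisq <- sum((obs - expd)^2 / expd)
    c(chisq, stats::pchisq(chisq, df = 1, lower.tail = FALSE))
  }, numeric(2))

  hwe_chisq <- hwe[1, ]
  hwe_p <- hwe[2, ]

  fail_call <- call_rate < callrate_min | n_obs == 0
  fail_maf <- if (maf_min > 0) is.na(maf) | maf <= maf_min else rep(FALSE, ncol(dos))
  fail_hwe <- hwe_alpha > 0 & (is.na(hwe_p) | hwe_p < hwe_alpha)
  reason <- rep("kept", ncol(dos))
  reason[fail_hwe] <- "hwe"
  reason[fail_maf] <- "maf"
  reason[fail_call] <- "callrate"
  rep <- data.frame(id = G$snp_meta$id, maf = maf, call_rate = call_rate,
                    hwe_chisq = hwe_chisq, hwe_p = hwe_p,
                    pass = !(fail_call | fail_maf | fail_hwe),
                    reason = reason, stringsAsFactors = FALSE)
  class(rep) <- c("snp_qc_report", "data.frame")
  attr(rep, "thresholds") <- list(maf_min = maf_min, hwe_alpha = hwe_alpha,
                                  callrate_min = callrate_min)
  rep
}

#' Filter SNPs on MAF, HWE and call rate
#'
#' Keeps SNPs with `MAF > maf_min` (strict: a SNP at exactly the floor is
#' removed), `hwe_p >= hwe_alpha` and `call_rate >= callrate_min`. Column
#' order is preserved. The HWE filter is disabled by default
#' (`hwe_alpha = 0`) since the method targets selfing crops where
#' heterozygote deficits are expected; pass e.g. `1e-6` to enable it.
#'
#' @param G a [genotype_matrix()].
#' @param report optional [snp_qc_metrics()] output aligned to `G`;
#'   recomputed when `NULL`.
#' @param maf_min MAF floor (default 0.05).
#' @param hwe_alpha HWE p-value threshold (default 0 = off).
#' @param callrate_min minimum call rate (default 0.9).
#' @return a filtered [genotype_matrix()] with attribute `n_removed`.
#'   Errors if no SNP survives.
#' @export
filter_snps <- function(G, report = NULL, maf_min = 0.05, hwe_alpha = 0,
                        callrate_min = 0.9) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(report)) {
    report <- snp_qc_metrics(G, maf_min = maf_min, hwe_alpha = hwe_alpha,
                             callrate_min = callrate_min)
  } else {
    if (!identical(as.character(report$id), G$snp_meta$id))
      stop("QC report is not aligned to the genotype matrix")
    th <- attr(report, "thresholds")
    if (!is.null(th) && !identical(th, list(maf_min = maf_min,
                                            hwe_alpha = hwe_alpha,
                                            callrate_min = callrate_min))) {
      report <- snp_qc_metrics(G, maf_min = maf_min, hwe_alpha = hwe_alpha,
                               callrate_min = callrate_min)
    }
  }
  keep <- which(report$pass)
  if (length(keep) == 0L)
    stop("no SNPs survive QC (", ncol(G$dosage), " tested)")
  out <- genotype_matrix(G$dosage[, keep, drop = FALSE],
                         snp_meta = G$snp_meta[keep, , drop = FALSE],
                         sample_ids = G$sample_ids)
  attr(out, "n_removed") <- ncol(G$dosage) - length(keep)
  message(length(keep), " of ", ncol(G$dosage), " SNPs retained after QC")
  out
}

#' Write a SNP QC report as TSV
#' @param report a `snp_qc_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
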
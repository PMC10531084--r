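#' Construct a genotype matrix object
#'
#' Container for biallelic SNP dosages coded 0/1/2 (count of the alternate
#' allele) with `NA` marking missing calls, together with per-SNP metadata
#' and sample identifiers. All downstream QC, kinship and scan functions
#' consume this class.
#'
#' @param dosage numeric matrix, individuals in rows, SNPs in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param snp_meta data.frame with columns `id`, `chr`, `pos`, `ref`, `alt`.
#'   If `NULL`, metadata is synthesised from column names (or `snp1..m`).
#' @param sample_ids character vector of unique sample identifiers. If
#'   `NULL`, taken from row names (or `ind1..n`).
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosage`, `snp_meta`, `sample_ids`.
#' @examples
#' g <- genotype_matrix(rbind(c(0, 2), c(2, 0)))
#' dim(g$dosage)
#' @export
genotype_matrix <- function(dosage, snp_meta = NULL, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (n < 2L) stop("genotype matrix needs at least 2 individuals")
  if (m < 1L) stop("genotype matrix needs at least 1 SNP")
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- unique(dosage[!ok])
    stop("non-missing dosages must be 0, 1 or 2; found: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosage)
    if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids length must match nrow(dosage)")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (is.null(snp_meta)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- paste0("snp", seq_len(m))
    snp_meta <- data.frame(id = ids, chr = "1", pos = seq_len(m),
                           ref = "A", alt = "B", stringsAsFactors = FALSE)
  }
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  need <- c("id", "chr", "pos", "ref", "alt")
  miss <- setdiff(need, names(snp_meta))
  if (length(miss)) stop("snp_meta missing columns: ", paste(miss, collapse = ", "))
  if (nrow(snp_meta) != m) stop("snp_meta rows must match ncol(dosage)")
  if (anyDuplicated(snp_meta$id)) stop("SNP ids must be unique")
  if (any(snp_meta$pos < 1, na.rm = TRUE)) stop("positions must be >= 1 (1-based)")
  rownames(dosage) <- sample_ids
  colnames(dosage) <- snp_meta$id
  structure(list(dosage = dosage, snp_meta = snp_meta, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read genotypes from CSV, VCF or PLINK .raw
#'
#' Dispatches on file extension. CSV: rows are samples (first column the
#' sample id), remaining columns SNP ids, cells in `{0, 1, 2, NA}`. VCF:
#' biallelic SNPs only, the GT field is converted to an alternate-allele
#' dosage. PLINK `.raw` (additive export from `plink --recode A`): columns
#' FID IID PAT MAT SEX PHENOTYPE then one dosage column per SNP.
#'
#' @param path input file; format from extension (`.csv`, `.vcf`/`.vcf.gz`,
#'   `.raw`) unless overridden.
#' @param format one of `"auto"`, `"csv"`, `"vcf"`, `"raw"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
      else if (grepl("\\.raw$", path, ignore.case = TRUE)) "raw"
      else "csv"
  }
  switch(format,
    csv = read_genotypes_csv(path),
    vcf = read_genotypes_vcf(path),
    raw = read_genotypes_raw(path))
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  genotype_matrix(mat, sample_ids = ids)
}

read_genotypes_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  snp_cols <- setdiff(names(df), fixed)
  mat <- as.matrix(df[, snp_cols, drop = FALSE])
  storage.mode(mat) <- "double"
  # plink suffixes the counted allele onto the id (SNP_A); strip it
  ids <- sub("_[ACGT0-9]+$", "", snp_cols)
  meta <- data.frame(id = ids, chr = "NA", pos = seq_along(ids),
                     ref = "A", alt = "B", stringsAsFactors = FALSE)
  colnames(mat) <- ids
  genotype_matrix(mat, snp_meta = meta, sample_ids = as.character(df$IID))
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    stop(sum(multi), " non-biallelic-SNP records in ", path,
         " (multiallelic sites and indels are not supported)")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(x) {
    x[x %in% c(".", "./.", ".|.")] <- NA
    al <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(al, function(a) {
      if (anyNA(a) || any(a == ".")) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  }
  dos <- t(apply(gt, 1, count_alt))
  colnames(dos) <- colnames(gt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  meta <- data.frame(id = ids, chr = fix$CHROM, pos = as.numeric(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  mat <- t(dos)
  colnames(mat) <- ids
  genotype_matrix(mat, snp_meta = meta, sample_ids = colnames(gt))
}

#' Write a genotype matrix as CSV
#'
#' Inverse of the CSV reader: first column `sample_id`, one column per SNP.
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- data.frame(sample_id = G$sample_ids, G$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
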
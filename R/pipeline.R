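#' Pipeline configuration
#'
#' Validates and normalises the configuration for [run_pipeline()]. Either
#' file inputs (`genotypes`, `phenotype`) or a simulation block
#' (`simulate = TRUE` plus any [sim_config()] fields) must be given.
#'
#' @param genotypes,phenotype input paths (CSV/VCF/.raw and TSV/CSV); or
#'   `NULL` when simulating.
#' @param simulate logical; generate inputs with the synthetic module.
#' @param treatment phenotype treatment label to analyse (default `"HN"`;
#'   ignored when the phenotype table has no treatment column).
#' @param out_dir output directory (created if absent).
#' @param seed integer seed used for every stochastic stage.
#' @param maf_min,hwe_alpha,callrate_min SNP QC thresholds.
#' @param locfdr_threshold local FDR selection cut (default 0.05).
#' @param pi1_base,tau2,iterations,burn_in Bayesian survival FDR settings
#'   (`pi1_base = NULL` uses `1 - pi0` from the local FDR fit, floored at
#'   0.01).
#' @param sim extra [sim_config()] arguments as a named list (used when
#'   `simulate = TRUE`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, phenotype = NULL,
                            simulate = is.null(genotypes), treatment = "HN",
                            out_dir = "survfdr_out", seed = 1L,
                            maf_min = 0.05, hwe_alpha = 0,
                            callrate_min = 0.9, locfdr_threshold = 0.05,
                            pi1_base = NULL, tau2 = 4, iterations = 150000,
                            burn_in = 2000, sim = list()) {
  if (!simulate) {
    if (is.null(genotypes) || is.null(phenotype))
      stop("either supply genotype and phenotype files or set simulate = TRUE")
    if (!file.exists(genotypes)) stop("genotype file not found: ", genotypes)
    if (!file.exists(phenotype)) stop("phenotype file not found: ", phenotype)
  }
  cfg <- list(genotypes = genotypes, phenotype = phenotype,
              simulate = simulate, treatment = treatment, out_dir = out_dir,
              seed = as.integer(seed), maf_min = maf_min,
              hwe_alpha = hwe_alpha, callrate_min = callrate_min,
              locfdr_threshold = locfdr_threshold, pi1_base = pi1_base,
              tau2 = tau2, iterations = iterations, burn_in = burn_in,
              sim = sim)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # YAML 1.1 would resolve bare keys like `n` or `y` to booleans; keep
  # them as strings while still parsing true boolean values
  handlers <- list(
    "bool#yes" = function(x) if (toupper(x) %in% c("TRUE", "YES")) TRUE else x,
    "bool#no" = function(x) if (toupper(x) %in% c("FALSE", "NO")) FALSE else x)
  cfg <- yaml::yaml.load(paste(readLines(path), collapse = "\n"),
                         handlers = handlers)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (file readers or the synthetic
#' module), SNP QC and filtering, GRM construction, the single-locus
#' mixed-model scan, p-to-z conversion, the local FDR fit and selection,
#' and the Bayesian survival FDR. Per-stage TSV/JSON outputs and a run
#' manifest (seed, parameters, parameter hash, per-stage row counts,
#' collected warnings) are written under `cfg$out_dir`. Completed stage
#' outputs are left intact if a later stage fails.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `qc`, `stats`,
#'   `locfdr_fit`, `selection`, `bsfdr`, `manifest`, `files`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  files <- list()

  # --- inputs ---------------------------------------------------------
  if (cfg$simulate) {
    scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    gen <- simulate_genotypes(scfg)
    G <- gen$genotypes
    ph <- simulate_phenotype(G, scfg)
    pheno <- ph$phenotype
    files$truth <- file.path(cfg$out_dir, "truth.tsv")
    utils::write.table(data.frame(qtl = ph$qtl_ids, effect = ph$qtl_effects),
                       files$truth, sep = "\t", row.names = FALSE, quote = FALSE)
    files$genotypes <- file.path(cfg$out_dir, "genotypes.csv")
    write_genotypes(G, files$genotypes)
    files$phenotype <- file.path(cfg$out_dir, "phenotype.tsv")
    utils::write.table(pheno, files$phenotype, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    G <- read_genotypes(cfg$genotypes)
    pheno <- read_phenotype(cfg$phenotype)
  }
  if (cfg$treatment %in% pheno$treatment) {
    pheno <- pheno[pheno$treatment == cfg$treatment, , drop = FALSE]
  }
  keep <- match(G$sample_ids, pheno$sample_id)
  if (any(is.na(keep))) {
    miss <- sum(is.na(keep))
    if (miss == length(keep)) stop("no phenotyped samples match genotype ids")
    note(sprintf("%d genotyped samples lack phenotypes and were dropped", miss))
    G <- genotype_matrix(G$dosage[!is.na(keep), , drop = FALSE],
                         snp_meta = G$snp_meta,
                         sample_ids = G$sample_ids[!is.na(keep)])
    keep <- keep[!is.na(keep)]
  }
  y <- pheno$value[keep]
  names(y) <- pheno$sample_id[keep]

  # --- SNP QC ---------------------------------------------------------
  qc <- snp_qc_metrics(G, maf_min = cfg$maf_min, hwe_alpha = cfg$hwe_alpha,
                       callrate_min = cfg$callrate_min)
  files$qc <- file.path(cfg$out_dir, "snp_qc.tsv")
  write_qc_report(qc, files$qc)
  Gf <- suppressMessages(filter_snps(G, qc, maf_min = cfg$maf_min,
                                     hwe_alpha = cfg$hwe_alpha,
                                     callrate_min = cfg$callrate_min))
  if (attr(Gf, "n_removed") > 0)
    note(sprintf("%d SNPs removed by QC", attr(Gf, "n_removed")))

  # --- GRM + scan -----------------------------------------------------
  K <- compute_grm(Gf)
  files$grm <- file.path(cfg$out_dir, "grm.tsv")
  write_grm(K, files$grm)
  stats <- p_to_z(single_locus_scan(y, Gf, K))
  files$stats <- file.path(cfg$out_dir, "summary_stats.tsv")
  write_summary_stats(stats, files$stats)

  # --- local FDR ------------------------------------------------------
  fit <- fit_local_fdr(stats$z)
  sel <- locfdr_select(fit, threshold = cfg$locfdr_threshold)
  locfdr_tab <- data.frame(snp = stats$snp, z = stats$z,
                           locfdr = fit$locfdr,
                           selected = seq_along(stats$z) %in% sel$index)
  files$locfdr <- file.path(cfg$out_dir, "locfdr.tsv")
  utils::write.table(locfdr_tab, files$locfdr, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- Bayesian survival FDR ------------------------------------------
  pi1 <- cfg$pi1_base
  if (is.null(pi1)) pi1 <- min(0.5, max(0.01, 1 - fit$pi0_trunc))
  bs <- bsfdr(Gf, y, stats = stats, pi1_base = pi1, tau2 = cfg$tau2,
              iterations = cfg$iterations, burn_in = cfg$burn_in,
              seed = cfg$seed)
  files$posterior <- file.path(cfg$out_dir, "posterior.tsv")
  utils::write.table(bs$posterior, files$posterior, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- manifest -------------------------------------------------------
  par_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "sim")],
                               auto_unbox = TRUE, null = "null")
  tmp <- file.path(cfg$out_dir, "params.json")
  writeLines(par_json, tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("survfdr")),
    seed = cfg$seed,
    param_hash = unname(tools::md5sum(tmp)),
    n_samples = length(y),
    n_snps_input = ncol(G$dosage),
    n_snps_after_qc = ncol(Gf$dosage),
    n_locfdr_selected = length(sel$index),
    set_fdr = sel$set_fdr,
    locfdr_metrics = fit$metrics,
    n_significant_bsfdr = sum(bs$posterior$significant),
    bsfdr_score = bs$bsfdr_score,
    bayes_fdr = bs$bayes_fdr,
    beta_gy = bs$beta_gy,
    warnings = warnings_log)
  files$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  structure(list(qc = qc, stats = stats, locfdr_fit = fit, selection = sel,
                 bsfdr = bs, manifest = manifest, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("pipeline run (seed %d): %d samples, %d -> %d SNPs ",
                     "after QC\n  locFDR: %d selected (set FDR %.3g); ",
                     "bsFDR: %d significant, score %.3g\n"),
              m$seed, m$n_samples, m$n_snps_input, m$n_snps_after_qc,
              m$n_locfdr_selected, m$set_fdr, m$n_significant_bsfdr,
              m$bsfdr_score))
  invisible(x)
}
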
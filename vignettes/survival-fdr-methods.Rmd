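---
title: "Significance thresholds for GWAS: local FDR and the Bayesian survival FDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Significance thresholds for GWAS: local FDR and the Bayesian survival FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survfdr)
```

## The problem

A genome-wide association scan of a quantitative trait produces one test
statistic per SNP — tens of thousands of them. Deciding which associations
to believe is the hard part: Bonferroni-style family-wise control is so
conservative on dense marker panels that true moderate-effect loci are
routinely discarded, while a raw 0.05 cut drowns the analyst in false
positives. `survfdr` implements two complementary ways to set the
significance threshold for such scans, aimed at highly selfing crop panels
(a few hundred inbred genotypes, strong population structure, MAF-filtered
SNP chips):

1. an **empirical-Bayes local false discovery rate** with a fitted
   empirical null, which converts the full z-value distribution into a
   per-SNP posterior null probability; and
2. a **Bayesian survival FDR**, which converts each SNP's allele classes
   into survival curves along a phenotype-ranked pseudo-time, turns the
   fitted hazard into a per-SNP prior weight, and declares significance
   when the posterior inclusion probability clears a threshold indexed by
   the SNP's own minor allele frequency.

Everything else in the package — phenotype bootstrap QC, SNP filters, the
genomic relationship matrix, the mixed-model scan, the simulator, the
pipeline — exists to feed and test these two estimators.

## The two-groups model and the local FDR

Given m z-values, assume the mixture
$$f(z) = \pi_0 f_0(z) + (1 - \pi_0) f_1(z),$$
where $f_0$ is the density of null tests and $\pi_0$ their proportion.
The local FDR of an observation is the posterior null probability
$$\mathrm{locfdr}(z) = \frac{\pi_0 f_0(z)}{f(z)},$$
truncated into $[0,1]$. `fit_local_fdr()` estimates the pieces as
follows.

**Marginal density.** z-values are binned into 120 bins and the counts are
fitted by a Poisson regression on a natural spline of the bin midpoints
(Lindsey's method). The spline's degrees of freedom default to
$\max(5, \lceil 1.5 \log_{10} m \rceil + 4)$ — growing slowly with the
number of tests, so that heavier tails can be tracked in larger panels
without overfitting small ones.

**Empirical null.** Genome-wide scans rarely deliver exactly N(0,1) null
z-values: variance-component misspecification, residual structure and
correlation between tests move the null ensemble to some
$N(\delta, \sigma^2)$. We fit $(\delta, \sigma)$ by truncated maximum
likelihood on a central window of the z distribution, and then read
$\pi_0$ off the ratio of the observed central mass to the fitted null
mass in the window.

The window choice matters more than it looks. A symmetric window
$\text{median}(z) \pm b(m)\,\mathrm{mad}(z)$ with
$b(m) = 4.3\, e^{-0.26 \log_{10} m}$ (about $\pm 1.6$ standard deviations
at $m = 5000$, narrowing as $m$ grows) is used because:

- the window must reach the *shoulders* of the null component — on the
  middle 50% of a Gaussian the truncated likelihood is nearly flat and
  $(\delta, \sigma)$ are unidentified in practice (their sampling errors
  at $m = 5000$ are an order of magnitude worse than with the wider
  window); and
- the window's edges must be *robust* — mass quantiles (say the 5th to
  95th percentile of z) lean into whatever signal component is present
  and inflate $\hat\sigma$, which in turn inflates the local FDR exactly
  where decisions are made, around $|z| \approx 2\text{–}3$. The
  MAD-based half-width ignores the contaminated tail.

$\pi_0$ is reported raw (it may exceed 1 by estimation noise; values are
capped at 1.5) and truncated at 1 for use in the locfdr formula. The fit
also emits the model-comparison metrics used when the same trait has been
scanned by several GWAS models: `Delta` (null mean), `Sigma` (null sd),
and the null proportion in both conventions found in applied reports —
the mixture $\pi_0$ and the sigma/mean ratio — clearly labelled, since
the two do not agree and both appear in practice.

`locfdr_select()` applies the conventional 0.05 local FDR cut and reports
the realized set-level Bayesian FDR, i.e. the mean locfdr over the
selection, which is bounded by the threshold by construction.

## The Bayesian survival FDR

The second estimator treats each SNP's allele classes as cohorts followed
along a **pseudo-time**: individuals are ranked by trait value, and the
rank (1 = worst phenotype, n = best) is the "time" axis. The intuition:
for a SNP associated with the trait, carriers of the favourable allele
concentrate among late pseudo-times — the class "survives" longer.

**Event tables.** `build_event_table()` assigns each individual its trait
rank (ties broken by sample id so the construction is permutation-stable)
and classifies it by dosage: major homozygote, heterozygote, minor
homozygote, or missing. In the pooled table used for hazard regression,
minor-allele carriers (dosage 1 or 2) are events at their own pseudo-time
and major homozygotes are censored — the minor allele "relapses" wherever
it appears along the ranking.

**Survival curves.** `nelson_aalen()` computes the cumulative hazard
$H(t) = \sum_{t_i \le t} d_i / n_i$ and $S(t) = e^{-H(t)}$. For the
per-class curves of `class_survival_curves()`, each class is its own risk
set and every member is an event at its pseudo-time; the mean of $S$ over
the class's event grid then summarises where in the trait distribution
the class lives (a class spread uniformly over ranks has mean S ≈ 0.45
at n = 4, higher when it concentrates late). A class "survives" when it
has at least 3 members and mean S ≥ 0.05; these per-class summaries, with
their standard errors, are the model-comparison output for competing
scans of the same trait.

**Hazard model and the Bayes survived factor.** `fit_exponential_ph()`
fits the constant-hazard proportional-hazards model
$\lambda(t \mid x) = \lambda_0 e^{\beta x}$ with dosage as covariate, by
profile Newton iteration on $\beta$ (the baseline has a closed form at
each step; tolerance 1e-8). The per-SNP **Bayes survived factor** is
$$\lambda_{\mathrm{SNP}} = \lambda_0 \, e^{\beta},$$
and with $\lambda_0 = 1$, $e^{\beta} = 0.001$ the prior is flat — the
convention used when no survival information should be injected. The
exponential model (rather than a Cox partial likelihood) keeps the
factor interpretable as an absolute rate and the likelihood closed-form;
AIC/BIC use the event count as the effective sample size, which is the
standard survival-analysis convention.

**Posterior inclusion.** `mcmc_posterior_inclusion()` runs a
binary-indicator Gibbs sampler over the two-group model
$z \mid \gamma = 0 \sim N(0,1)$, $z \mid \gamma = 1 \sim N(0, 1+\tau^2)$
($\tau^2 = 4$ by default, i.e. signal z-scores of typical size 2–3). The
per-SNP prior odds are tilted by the survived factors,
$$\mathrm{odds}_j = \frac{\pi_1}{1-\pi_1}\cdot
  \frac{\lambda_j}{\bar\lambda},$$
normalised by the mean factor so the average prior inclusion stays at
$\pi_1$ (taken from $1 - \hat\pi_0$ of the local FDR fit when available,
else 0.05). Because the prior odds are fixed, the indicators are
conditionally independent and the sampler mixes in a single step; the
closed-form posterior is therefore available as an exact oracle and is
attached to the output for verification. The published run length of
150,000 iterations with 2,000 burn-in is the default; tests and the
examples use 10,000/1,000, which is already far beyond what the one-step
mixing requires.

**Decision rule and scores.** `significance_decision()` flags SNP j when
$P_j > 1 - \mathrm{MAF}_j$: rare alleles must clear a higher posterior
bar, making the rule's nominal per-SNP level equal to the MAF itself
(a MAF of 0 can never be declared, and says so). Two set-level numbers
are reported: the **bsFDR score**
$\sum_j P_j \big/ \sum_j \lambda_j |z_j|$ — a model-comparison ratio, not
a rate, and deliberately labelled as a score — and the companion Bayesian
FDR $\mathrm{mean}(1 - P_j)$ over the selected set, which has the usual
FDR interpretation.

## Supporting machinery

**Phenotype QC.** `bootstrap_mean()` (B = 2000 by default) and
`bayesian_bootstrap()` (flat-Dirichlet weights) summarise the stability
of the trait mean; the Bayesian variant's replicate means have variance
$\hat\sigma^2/(n+1)$ against the classical $\hat\sigma^2/n$, a difference
that only matters at small n but makes the weighted scheme strictly less
outlier-volatile. No closed definition of a "Bayesian bootstrap
normality p-value" exists in common use; the package pins it as the
median Shapiro–Wilk p over one weighted resample per replicate —
reproducible and monotone in non-normality. Outlier handling is
report-only (Tukey fences via `detect_outliers()`): field records are
often kept even when extreme, so removal is the caller's explicit
decision.

**SNP QC.** MAF is computed on non-missing calls; SNPs with
MAF ≤ 0.05 are removed by default (the floor is strict, so a SNP at
exactly 0.05 goes; a floor of 0 disables the filter entirely). The HWE
goodness-of-fit test (1-df chi-square against $p^2, 2pq, q^2$) is
computed but **off by default**: in a selfing crop the heterozygote
deficit is real biology, not genotyping error, and an HWE filter at any
conventional alpha would discard the genome. Call-rate threshold 0.9.

**Kinship and scan.** `compute_grm()` is VanRaden method 1,
$K = WW^\top / \sum_k 2p_k(1-p_k)$ with $W$ the centred dosages and
missing values mean-imputed only inside this computation.
`single_locus_scan()` fits $y = X\beta + u + e$, $\mathrm{var}(u) =
K\sigma_g^2$, with the variance ratio estimated once on the null model by
a 99-point restricted-likelihood grid on heritability after a spectral
decomposition of K (ties toward lower h2), then tests every SNP by GLS in
the rotated coordinates. With $K = I$ and $h^2 = 0$ the scan reduces
exactly to OLS, which the tests assert. External GWAS results enter the
FDR machinery through the fixed-column summary-statistics TSV and
`p_to_z()` (two-sided, sign from the effect, p clamped at 1e-15).

## The synthetic panel

`sim_config()` defaults describe the kind of data the method targets and
are fixed study conditions, not tuning knobs: 221 genotypes in 3
subpopulations (Balding–Nichols divergence Fst = 0.1), selfing/inbreeding
0.95, ancestral MAF floor 0.05, 1% missing calls, and a trait with mean
6400 and sd 145.16 (grain yield in g/m², high-nitrogen condition; the
low-nitrogen condition sits 500 g/m² lower — a typical nitrogen response
for elite wheat — with independent residuals). The genetic architecture
is 10 QTLs with N(0,1) effects plus a polygenic term drawn from
$N(0, K)$; by default the QTLs carry 70% of the genetic variance
(`qtl_frac`), the polygenic background the rest, at total $h^2 = 0.3$.
Components are empirically rescaled so realized variance fractions match
the configuration.

What the simulator does *not* emulate: linkage disequilibrium between
markers (adjacent-SNP correlation in real chips is strong), multi-year
G×E structure, and genotyping-error patterns. Passing tests therefore
show the estimators' calibration and ranking behaviour under clean
structured data, not performance on a real chip, where LD both helps
(signal is replicated across neighbours) and hurts (the effective number
of tests is smaller than m).

One property of this architecture is worth knowing when reading test
output: N(0,1) effect draws give chi-square(1)-skewed variance shares, so
a few of the 10 QTLs are typically statistically invisible at n = 221
(|z| < 1). The expected AUC of *any* ranking, even an oracle scan, is
about 0.79 (SD 0.08 across seeds) under these conditions; the package's
posterior-P ranking sits at that ceiling, and the signal-recovery check
in the test suite is accordingly strict — it can fail on seeds where the
draw is unlucky even though the ranking is optimal for the data.

## Numerical choices and degenerate inputs

- Empirical-null optimizer: BFGS on $(\delta, \log\sigma)$, relative
  tolerance 1e-8; histogram end bins padded to cover the range.
- Fewer than 200 z-values: the empirical null is refused (use the
  theoretical null); constant z is an error.
- Monomorphic SNPs: scan records effect `NA`, p = 1; event tables carry a
  warning flag and zero events; the GRM errors only when *every* SNP is
  monomorphic (zero denominator).
- Exponential fit with a constant covariate: flagged unidentifiable and
  the null fit is returned rather than a spurious coefficient.
- Ties in trait values: broken by sample id, so pseudo-times are a
  deterministic permutation of 1..n under any input ordering.
- All randomness flows from explicit integer seeds; equal seeds give
  byte-identical outputs end to end, including the pipeline's files.
- Pipeline problem sizes in the tests (n = 60–221, m = 300–2000,
  MCMC 2,000–10,000 iterations) were chosen as the smallest sizes at
  which the statistical properties under test are stable.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(simulate = TRUE, out_dir = "demo_run", seed = 42,
                       iterations = 10000, burn_in = 1000,
                       sim = list(n = 221, m = 2000, n_qtl = 10, h2 = 0.3))
res <- run_pipeline(cfg)
res
res$locfdr_fit
head(res$bsfdr$posterior[order(-res$bsfdr$posterior$P), ])
```

## Known limitations

- The bsFDR score is a ratio of posterior mass to survival-weighted
  effect magnitude; it ranks models usefully but has no frequency
  calibration, which is why the companion mean(1 − P) is always reported
  beside it.
- The MAF-indexed decision rule is extremely conservative for rare
  alleles by design; panels dominated by low-MAF markers will flag
  little.
- The scan estimates the variance ratio once on the null model
  (population-parameters-previously-determined style); per-SNP REML
  would be slower and change little at these panel sizes.
- Heritability for `gblup_ebv()` is profiled on a coarse grid
  (0.05–0.95 by 0.05); it is a QC summary, not a variance-component
  estimator.
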
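---
title: "Methods: SNP regulation of miRNA expression in paired tumor/non-tumor tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP regulation of miRNA expression in paired tumor/non-tumor tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mireqtl)
```

# Scientific setting

`mireqtl` implements a miRNA-eQTL screen: given SNP genotypes and miRNA
expression measured in paired tumor and non-tumor colon tissue from the
same individuals, it asks which SNPs regulate miRNA expression
(expression quantitative trait loci), whether that regulation differs
between tumor and non-tumor tissue, and whether the implicated SNPs are
in turn associated with cancer risk in a case-control comparison.

The analysis is a fixed pipeline:

1. **Normalize** raw expression signal per tissue by stratified
   75th-percentile scaling.
2. **Expand and filter** a curated catalog of candidate SNP-miRNA pairs
   through a quality cascade.
3. **Associate** genotype with log2 expression (non-tumor) and with the
   paired tumor-minus-non-tumor difference (differential), using a
   linear trend model with bootstrap p-values, followed by
   Benjamini-Hochberg FDR control.
4. **Risk-model** the surviving SNPs against case-control status with
   genotype-class logistic regression and crude odds ratios.

# Normalization

Each tissue's signal matrix (miRNAs x samples, non-negative) is scaled
within strata. For sample $j$ in stratum $s$, with $q_j$ the 75th
percentile of the sample's signal (quantile type 7, R's default), the
scaling factor is

$$f_j = \frac{\operatorname{median}_{k \in s}(q_k)}{q_j},$$

and the normalized signal is $f_j \, x_{ij}$. After scaling, every
sample's 75th percentile equals the stratum median of the pre-scaling
percentiles — the procedure's fixed point — and rerunning it is the
identity (factors all 1). The factors are invariant to multiplying a
stratum by a constant $c > 0$, so the normalized values are
scale-equivariant (they scale by $c$).

Strata: `strata_mode = "tissue_site"` (the default in `run_config()`)
crosses tissue with anatomic site (proximal/distal), so tumor and
non-tumor matrices are each normalized within site; `"site"` uses site
alone. Samples with a zero 75th percentile have no defined factor and
are reported by name as errors rather than silently dropped.

Downstream modelling uses `log2(x + offset)` with `log2_offset = 1`.
An offset is required whenever zeros are present; 1 keeps zero signal
at zero on the log scale and makes `log2(x + 1)` invertible for the
synthetic generator's latent scale (see below).

# Pair expansion and the filtering cascade

Candidate pairs name a SNP and a miRNA, but catalog names are often
family-level (`hsa-miR-605`) while the expression matrix indexes mature
arms (`hsa-miR-605-5p`). `expand_pairs()` parses names into prefix,
class, family number, letter suffix, locus-of-origin, and arm, then
matches a catalog row when the family number agrees and every component
present in the query (letter, locus, arm) also agrees. A query that is
itself an exact catalog entry matches only itself — specific names are
never broadened. Unmatched queries are retained with `matched = FALSE`
so nothing disappears silently.

Expanded pairs then pass through a four-stage cascade
(`apply_cascade()`), with each dropped record attributed to the *first*
stage it fails:

1. `expressed_anywhere` — the miRNA shows non-zero signal in at least
   one sample (default scope `expressed_in = "any"` spans both tissues;
   `"normal"` restricts to non-tumor). "Any" is the permissive default:
   a miRNA expressed only in tumors is still informative for the
   differential analysis.
2. `genotype_available` — the SNP is present in the genotype matrix and
   not on the `exclusions` list.
3. `polymorphic` — at least `min_minor_carriers = 2` minor-allele
   carriers *and* an exact Hardy-Weinberg test p-value of at least
   `hwe_alpha = 1e-4`. The HWE test enumerates all heterozygote counts
   compatible with the observed allele counts and sums the
   probabilities no larger than the observed configuration's. It is
   computed on all genotyped samples for the pair; with paired tissue
   there is one genotype per individual, so no tissue subsetting
   arises.
4. `prevalent` — non-zero non-tumor expression in at least
   `min_expression_prevalence = 5%` of samples, so trend models are not
   fit to essentially unexpressed miRNAs.

The `cascade_report` records in/out/dropped counts per stage plus the
per-record first-failure reason, and is written with the pipeline
outputs.

# Association testing

For each surviving pair, expression is modelled as a linear trend in
allele count (additive coding 0/1/2) with optional covariates:
stage 1 uses non-tumor `log2(signal + 1)`, stage 2 the paired
tumor-minus-non-tumor difference (individuals missing either tissue
are dropped with a message). Coefficients come from ordinary least
squares; the p-value for the genotype coefficient comes from a case
bootstrap (`bootstrap_spec()`, default `n_boot = 10000`): rows are
resampled with replacement, the model refit, and

$$p = \min\!\left(1,\; 2\,\frac{\min(\#\{\beta^* \le 0\},
\#\{\beta^* \ge 0\}) + 1}{B + 1}\right).$$

The $+1$ smoothing keeps $p \ge 2/(B+1)$ and avoids zero p-values.
Resamples in which the genotype becomes constant are redrawn; if more
than half of the draws degenerate the test aborts with an error rather
than report an untrustworthy p. A residual-bootstrap variant is
available via `bootstrap_spec(method = "residuals")`.

Per-miRNA tumor vs non-tumor shifts use a paired bootstrap t-test
(`paired_bootstrap_ttest()`): differences are mean-centered, resampled,
and the observed $|t|$ compared to the bootstrap distribution with the
same $+1$ smoothing.

FDR control uses Benjamini-Hochberg (`bh_fdr()`, a validated wrapper
around `stats::p.adjust`). Each analysis (non-tumor, differential) is
adjusted as its own family: the two stages answer different questions
and pooling them would let one family's signal density dilute or
inflate the other's threshold.

# Risk modelling

SNPs with a raw trend p-value below `alpha` in either analysis are
carried to case-control risk models. `fit_genotype_logistic()` codes
genotype as indicator contrasts against the common-homozygote reference
(heterozygote, rare homozygote), fitting
`stats::glm(binomial)` with a tightened convergence tolerance
(`epsilon = 1e-8`, `maxit = 50`) and Wald confidence intervals; an
absent genotype class is dropped from the design, and detected
separation blanks the intervals rather than report meaningless ones. A
per-allele trend coding is available. `crude_or()` gives the matching
2x2 odds ratios with Woolf intervals, adding the Haldane-Anscombe 0.5
correction only when a cell is zero, and flags the OR as undefined when
an entire comparison group is empty.

Published genotype-class counts for 41 risk-screened SNPs ship in
`system.file("extdata", "table5_genotype_counts.tsv", package =
"mireqtl")` and serve as worked-example inputs:

```{r}
t5 <- read.delim(system.file("extdata", "table5_genotype_counts.tsv",
                             package = "mireqtl"))
cc <- t5[t5$snp_id == "rs8905", ]
crude_or(cc$controls_0, cc$cases_0, cc$controls_2, cc$cases_2)
```

# Synthetic cohort generator

`generate_cohort(cohort_config())` produces a complete paired-tissue
cohort for testing and power studies. Genotypes are drawn in
Hardy-Weinberg proportions with minor allele frequencies uniform on
`maf_range = c(0.1, 0.4)` — common variants, where the trend test is
well behaved. Latent log2 expression for miRNA $k$ in individual $i$ is

$$y_{ik} = \mu_k + \beta_g g_{ik} + \delta_T T + \gamma_{g \times T}\, g_{ik} T
+ \text{covariate terms} + \varepsilon,\quad \varepsilon \sim N(0, \sigma^2),$$

and the observed signal is $\max(2^{y} - 1, 0)$ with an additional
hurdle that zeroes a fraction `pi_zero` of entries. Because
`log2(x + 1)` inverts the signal map exactly whenever $y > 0$, the
analysis recovers the planted coefficients without transformation bias,
which makes the generator usable as a ground-truth oracle in tests.
Case-control status follows a logistic model with `risk_or_per_allele`
per minor allele of the designated risk SNP, centered so that roughly
half the cohort are cases. Age is truncated normal (mean 65, SD 9.5,
range 30-79) and site is proximal/distal, mirroring a realistic
colon-tissue cohort.

Defaults (`n_individuals = 344`, `beta_g = 0.5` log2 per allele,
`delta_tumor = 1.0`, `gamma_gxt = 0`, `pi_zero = 0.1`, `sigma = 1.0`)
were chosen once, before any testing, to represent a moderately powered
study of realistic size; they were not tuned afterwards. The generator
deliberately omits library-size artifacts, batch effects, correlated
miRNA families, and linkage disequilibrium between SNPs — it validates
the statistical machinery, not platform-specific noise.

# Pipeline and reproducibility

`run_pipeline(run_config(...))` runs the full analysis from either an
in-memory synthetic cohort or five input files (tumor expression,
non-tumor expression, genotypes, covariates, pairs). `set.seed(seed)`
at entry makes runs bit-identical; every output TSV carries a header
line `# mireqtl config_hash=<md5> seed=<n>` and a `manifest.yaml`
records the hash, seed, stage counts, and file list. A thin
command-line front end with subcommands (`simulate`, `normalize`,
`filter`, `associate`, `risk`, `report`, `run-all` over a YAML config)
is installed at `system.file("exec", "mireqtl", package = "mireqtl")`.

```{r, eval = FALSE}
co <- generate_cohort(cohort_config(seed = 1))
run <- run_pipeline(run_config(cohort = co, seed = 1))
run$summary$pct_snps_significant
```

Problem sizes used throughout the package's own checks — cohorts of a
few hundred individuals, bootstrap sizes of 500-10000, simulation
suites of 100-1000 replicates — are the package's own choices,
balancing statistical resolution against runtime.
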
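#' Draw additive genotype codes under Hardy-Weinberg equilibrium
#'
#' Each individual is drawn independently with genotype probabilities
#' \eqn{((1-q)^2,\; 2q(1-q),\; q^2)} for codes 0/1/2, where `maf` is the
#' minor-allele frequency \eqn{q}.
#'
#' @param n number of individuals.
#' @param maf minor-allele frequency, in (0, 0.5].
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of 0/1/2 codes of length `n`.
#' @examples
#' table(generate_genotypes(1000, maf = 0.25, seed = 1))
#' @export
generate_genotypes <- function(n, maf, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5) {
    stop("maf must lie in (0, 0.5]")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  sample.int(3L, size = n, replace = TRUE, prob = p) - 1L
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model: per-SNP genotypes drawn under
#' Hardy-Weinberg equilibrium at MAFs uniform in `maf_range`; latent
#' log2 expression of miRNA j in individual i and tissue t (t = 1 tumor)
#' \deqn{y = \mu_j + \beta_g g + \delta t + \gamma g t + \text{covariates} + N(0, \sigma)}
#' for the SNP paired with miRNA j; observed signal
#' \eqn{\max(2^y - 1,\, 0)}, with zeros additionally injected as an
#' independent hurdle with probability `pi_zero`; and case status from a
#' logistic model with per-minor-allele odds ratio `risk_or_per_allele`
#' on the designated risk SNP.
#'
#' @param n_individuals cohort size (default 344, a paired-tissue cohort
#'   scale typical of molecular-epidemiology studies).
#' @param n_snps,n_mirnas numbers of SNPs and miRNAs; pair k links SNP k
#'   to miRNA k, so `n_snps` must equal `n_mirnas`.
#' @param maf_range length-2 numeric in (0, 0.5], MAF bounds.
#' @param beta_g log2-expression change per minor allele (recycled per
#'   pair; default 0.5).
#' @param delta_tumor log2 tumor shift (default 1.0).
#' @param gamma_gxt genotype-by-tumor interaction on the log2 scale
#'   (recycled per pair; default 0).
#' @param pi_zero baseline probability that a measurement is zeroed,
#'   independent of the latent value (default 0.1).
#' @param covariate_effects named list of log2 slopes: `age` (per year,
#'   centered at 65), `sex` (male vs female), `center` (per contrast vs
#'   reference center); defaults 0.
#' @param risk_or_per_allele odds ratio per minor allele of the risk SNP
#'   for case status (default 1.5).
#' @param risk_snp index of the SNP driving case status (default 1).
#' @param sigma residual SD on the log2 scale (> 0; default 1).
#' @param mu_range range of per-miRNA baseline log2 intercepts.
#' @param seed integer seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 344, n_snps = 10, n_mirnas = 10,
                          maf_range = c(0.1, 0.4), beta_g = 0.5,
                          delta_tumor = 1.0, gamma_gxt = 0, pi_zero = 0.1,
                          covariate_effects = list(age = 0, sex = 0, center = 0),
                          risk_or_per_allele = 1.5, risk_snp = 1L,
                          sigma = 1.0, mu_range = c(2, 8), seed = 1L) {
  stopifnot(n_individuals >= 1, n_snps >= 1, n_mirnas >= 1)
  if (n_snps != n_mirnas) stop("n_snps must equal n_mirnas (pair k links SNP k to miRNA k)")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (pi_zero < 0 || pi_zero >= 1) stop("pi_zero must lie in [0, 1)")
  if (sigma <= 0) stop("sigma must be positive")
  if (risk_or_per_allele <= 0) stop("risk_or_per_allele must be positive")
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_snps = as.integer(n_snps), n_mirnas = as.integer(n_mirnas),
              maf_range = as.numeric(maf_range),
              beta_g = rep_len(beta_g, n_snps),
              delta_tumor = delta_tumor,
              gamma_gxt = rep_len(gamma_gxt, n_snps),
              pi_zero = pi_zero,
              covariate_effects = utils::modifyList(
                list(age = 0, sex = 0, center = 0), covariate_effects),
              risk_or_per_allele = risk_or_per_allele,
              risk_snp = as.integer(risk_snp),
              sigma = sigma, mu_range = as.numeric(mu_range),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic paired tumor/non-tumor cohort
#'
#' Draws genotypes, covariates (age ~ Normal(65, 9.5) truncated to
#' 30-79 years; sex; two study centers; one proximal/distal tumor-site
#' label per individual), paired tumor and non-tumor signal matrices on
#' the non-negative signal scale, and case/control status, under the
#' model described in [cohort_config()]. The generating effect sizes are
#' returned per pair in `$truth` so recovery can be audited.
#'
#' @param config a `cohort_config`.
#' @return object of class `synthetic_cohort`: list with `genotypes`
#'   (SNP x individual integer matrix), `covariates` (data.frame with
#'   sample_id, age, sex, center, site, status), `expression_tumor` and
#'   `expression_normal` (miRNA x individual signal matrices, identical
#'   individual order), `pairs` (the SNP-miRNA pair catalog), `truth`
#'   (per-pair generating parameters), and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_individuals = 50, seed = 7))
#' dim(cohort$expression_tumor)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  ids <- sprintf("ind%04d", seq_len(n))

  # covariates
  age <- stats::rnorm(n, 65, 9.5)
  while (any(bad <- age < 30 | age > 79)) age[bad] <- stats::rnorm(sum(bad), 65, 9.5)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  center <- sample(c("centerA", "centerB"), n, replace = TRUE)
  site <- sample(c("proximal", "distal"), n, replace = TRUE)

  # genotypes under HWE
  mafs <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  geno <- t(vapply(mafs, function(q) generate_genotypes(n, q), integer(n)))
  rownames(geno) <- sprintf("rs%05d", seq_len(config$n_snps))
  colnames(geno) <- ids

  mirnas <- sprintf("hsa-miR-%d-5p", 1000L + seq_len(config$n_mirnas))
  mus <- stats::runif(config$n_mirnas, config$mu_range[1], config$mu_range[2])

  ce <- config$covariate_effects
  covar_term <- ce$age * (age - 65) + ce$sex * (sex == "male") +
    ce$center * (center == "centerB")

  latent <- function(j, tumor) {
    g <- geno[j, ]
    t_ind <- as.numeric(tumor)
    mus[j] + config$beta_g[j] * g + config$delta_tumor * t_ind +
      config$gamma_gxt[j] * g * t_ind + covar_term +
      stats::rnorm(n, 0, config$sigma)
  }
  to_signal <- function(y) {
    s <- pmax(2^y - 1, 0)
    s[stats::runif(length(s)) < config$pi_zero] <- 0
    s
  }
  expr_n <- t(vapply(seq_len(config$n_mirnas), function(j) to_signal(latent(j, FALSE)),
                     numeric(n)))
  expr_t <- t(vapply(seq_len(config$n_mirnas), function(j) to_signal(latent(j, TRUE)),
                     numeric(n)))
  dimnames(expr_n) <- dimnames(expr_t) <- list(mirnas, ids)

  # case status: logistic in the risk SNP's allele count
  g_risk <- geno[config$risk_snp, ]
  lo <- log(config$risk_or_per_allele) * g_risk
  lo <- lo - mean(lo)           # balance cases and controls around 50%
  status <- stats::rbinom(n, 1L, stats::plogis(lo))

  covariates <- data.frame(sample_id = ids, age = age, sex = sex,
                           center = center, site = site, status = status,
                           stringsAsFactors = FALSE)
  pairs <- data.frame(snp_id = rownames(geno), gene_labels = "synthetic",
                      mirna_name = mirnas, stringsAsFactors = FALSE)
  truth <- data.frame(snp_id = rownames(geno), mirna_name = mirnas,
                      maf = mafs, mu = mus, beta_g = config$beta_g,
                      gamma_gxt = config$gamma_gxt,
                      delta_tumor = config$delta_tumor,
                      risk_or_per_allele = ifelse(
                        seq_len(config$n_snps) == config$risk_snp,
                        config$risk_or_per_allele, 1),
                      stringsAsFactors = FALSE)
  out <- list(genotypes = geno, covariates = covariates,
              expression_tumor = expr_t, expression_normal = expr_n,
              pairs = pairs, truth = truth, config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic paired tumor/non-tumor cohort\n")
  cat("  individuals:", x$config$n_individuals,
      " cases:", sum(x$covariates$status), "\n")
  cat("  SNPs:", nrow(x$genotypes), "  miRNAs:", nrow(x$expression_tumor), "\n")
  cat("  beta_g:", paste(unique(signif(x$config$beta_g, 3)), collapse = ", "),
      " delta_tumor:", x$config$delta_tumor,
      " risk OR/allele:", x$config$risk_or_per_allele, "\n")
  invisible(x)
}

#' Write a synthetic cohort to the pipeline's file dialects
#'
#' Emits the same TSV/CSV formats the readers accept, so synthetic
#' fixtures exercise the parsers end to end.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return named list of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expression_tumor = file.path(dir, "expression_tumor.tsv"),
    expression_normal = file.path(dir, "expression_normal.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    pairs = file.path(dir, "pairs.csv"))
  write_expression(cohort$expression_tumor, paths$expression_tumor)
  write_expression(cohort$expression_normal, paths$expression_normal)
  write_genotypes(cohort$genotypes, paths$genotypes)
  write_covariates(cohort$covariates, paths$covariates)
  write_pairs(cohort$pairs, paths$pairs)
  paths
}
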
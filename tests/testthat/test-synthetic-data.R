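test_that("genotype generator respects HWE frequencies and seeding", {
  # degenerate frequency: essentially no minor alleles
  expect_true(all(generate_genotypes(100, 1e-9, seed = 1) == 0))
  expect_error(generate_genotypes(100, 0), "\\(0, 0.5\\]")
  expect_error(generate_genotypes(100, 0.6), "\\(0, 0.5\\]")

  # observed class frequencies within 4 binomial SDs of HWE expectations
  n <- 10000; maf <- 0.25
  g <- generate_genotypes(n, maf, seed = 7)
  p_exp <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  obs <- tabulate(g + 1L, 3L) / n
  sd_bin <- sqrt(p_exp * (1 - p_exp) / n)
  expect_true(all(abs(obs - p_exp) <= 4 * sd_bin))

  expect_identical(generate_genotypes(500, 0.3, seed = 5),
                   generate_genotypes(500, 0.3, seed = 5))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(cohort_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(cohort_config(pi_zero = 1), "pi_zero")
  expect_error(cohort_config(sigma = 0), "sigma")
  expect_error(cohort_config(n_snps = 3, n_mirnas = 4), "n_snps")
})

test_that("cohort generation is reproducible and structurally sound", {
  cfg <- cohort_config(n_individuals = 80, n_snps = 3, n_mirnas = 3, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression_tumor, b$expression_tumor)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(colnames(a$expression_tumor), colnames(a$expression_normal))
  expect_true(all(a$expression_tumor >= 0))
  expect_true(all(a$expression_normal >= 0))
  expect_equal(nrow(a$truth), nrow(a$pairs))
  expect_true(all(a$covariates$age >= 30 & a$covariates$age <= 79))
})

test_that("tumor shift is recovered on the log2 scale when noise is small", {
  co <- generate_cohort(cohort_config(n_individuals = 400, n_snps = 2,
                                      n_mirnas = 2, beta_g = 0,
                                      delta_tumor = 1.0, sigma = 0.05,
                                      pi_zero = 0, seed = 13))
  d <- rowMeans(log2(co$expression_tumor + 1)) -
    rowMeans(log2(co$expression_normal + 1))
  expect_true(all(abs(d - 1.0) < 0.05))
})

test_that("per-allele risk odds ratio is recovered within its CI", {
  co <- generate_cohort(cohort_config(n_individuals = 5000, n_snps = 1,
                                      n_mirnas = 1, risk_or_per_allele = 2.0,
                                      seed = 31))
  fit <- fit_genotype_logistic(co$covariates$status, co$genotypes[1, ],
                               coding = "trend")
  cf <- summary(fit$glm)$coefficients["per_allele", ]
  ci <- exp(cf["Estimate"] + c(-1.96, 1.96) * cf["Std. Error"])
  expect_true(ci[1] <= 2.0 && 2.0 <= ci[2])
})

test_that("zero-inflation rate matches pi_zero in an otherwise high-signal cohort", {
  co <- generate_cohort(cohort_config(n_individuals = 500, n_snps = 2,
                                      n_mirnas = 2, pi_zero = 0.3,
                                      mu_range = c(8, 10), sigma = 0.3,
                                      seed = 17))
  # with mu >= 8 the latent signal never reaches 0, so zeros are hurdle-only
  frac0 <- mean(co$expression_normal == 0)
  expect_lt(abs(frac0 - 0.3), 4 * sqrt(0.3 * 0.7 / length(co$expression_normal)))
})
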
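test_that("crude odds ratios reproduce hand-computed values and symmetries", {
  # published case-control genotype counts as worked examples
  expect_equal(crude_or(928, 836, 11, 23)$or, (23 * 928) / (11 * 836),
               tolerance = 1e-12)
  expect_equal(round(crude_or(928, 836, 11, 23)$or, 1), 2.3)
  expect_equal(round(crude_or(560, 484, 109, 127)$or, 1), 1.3)

  # balanced groups give OR exactly 1
  expect_equal(crude_or(40, 40, 7, 7)$or, 1)

  # swapping referent and comparison groups inverts the OR
  a <- crude_or(100, 80, 30, 45)
  b <- crude_or(30, 45, 100, 80)
  expect_equal(b$or, 1 / a$or)
  expect_equal(sort(b$ci), sort(1 / a$ci))

  # CI brackets the OR
  expect_true(a$ci[1] < a$or && a$or < a$ci[2])

  # zero cells: Haldane-Anscombe correction, and undefined groups flagged
  z <- crude_or(50, 40, 10, 0)
  expect_equal(z$or, (0.5 * 50.5) / (10.5 * 40.5))
  u <- crude_or(50, 40, 0, 0)
  expect_true(u$undefined)
  expect_error(crude_or(-1, 2, 3, 4), "non-negative")
})

test_that("logistic model without covariates matches crude 2x2 odds ratios", {
  set.seed(70)
  g <- generate_genotypes(600, 0.3)
  status <- rbinom(600, 1, plogis(-0.2 + 0.4 * (g == 1) + 0.9 * (g == 2)))
  fit <- fit_genotype_logistic(status, g)
  cnt <- fit$counts
  for (term in c("het", "hom_rare")) {
    k <- if (term == "het") "1" else "2"
    oracle <- crude_or(cnt["0", "controls"], cnt["0", "cases"],
                       cnt[k, "controls"], cnt[k, "cases"])$or
    i <- match(term, fit$or_table$term)
    # saturated-model equivalence: MLE equals the empirical odds ratio
    expect_equal(fit$or_table$or[i], oracle, tolerance = 1e-6)
  }
  expect_true(all(fit$or_table$ci_lower < fit$or_table$or &
                    fit$or_table$or < fit$or_table$ci_upper))
})

test_that("covariates independent of genotype leave the OR nearly collapsible", {
  co <- generate_cohort(cohort_config(n_individuals = 3000, n_snps = 1,
                                      n_mirnas = 1, risk_or_per_allele = 1.8,
                                      seed = 71))
  g <- co$genotypes[1, ]; st <- co$covariates$status
  X <- co$covariates[, c("age", "sex", "center")]
  adj <- fit_genotype_logistic(st, g, X)
  crude <- fit_genotype_logistic(st, g)
  expect_equal(adj$or_table$or, crude$or_table$or, tolerance = 0.1)
})

test_that("IRLS deviance decreases monotonically across iterations", {
  set.seed(72)
  g <- generate_genotypes(300, 0.25)
  status <- rbinom(300, 1, plogis(0.5 * g))
  dev_trace <- capture.output(
    glm(status ~ factor(g), family = binomial(),
        control = glm.control(trace = TRUE, epsilon = 1e-8, maxit = 50)))
  devs <- as.numeric(sub("^Deviance = ([0-9.eE+-]+) Iterations.*", "\\1",
                         dev_trace[grepl("^Deviance = ", dev_trace)]))
  expect_gte(length(devs), 2)
  expect_true(all(diff(devs) <= 1e-8))
})

test_that("separation is detected and intervals suppressed", {
  g <- rep(c(0L, 1L, 2L), each = 30)
  status <- as.integer(g == 2)      # rare homozygotes perfectly predict cases
  fit <- suppressWarnings(fit_genotype_logistic(status, g))
  expect_true(fit$separation)
  expect_true(all(is.na(fit$or_table$ci_lower)))
  expect_error(fit_genotype_logistic(rep(1, 90), g), "both outcome classes")
})

test_that("Wald test size is near nominal when the genotype is null", {
  set.seed(73)
  n_sim <- 300; rej <- 0L
  for (s in seq_len(n_sim)) {
    g <- generate_genotypes(250, 0.3)
    status <- rbinom(250, 1, 0.5)
    fit <- fit_genotype_logistic(status, g, coding = "trend")
    rej <- rej + (fit$or_table$p < 0.05)
  }
  rate <- rej / n_sim
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
})
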
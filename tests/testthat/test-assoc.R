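test_that("trend fit matches an independent normal-equations solve", {
  set.seed(60)
  n <- 50
  g <- sample(0:2, n, replace = TRUE)
  X <- data.frame(age = rnorm(n, 65, 9), sex = sample(c("m", "f"), n, TRUE),
                  center = sample(c("A", "B"), n, TRUE))
  y <- 0.4 * g + 0.02 * X$age + rnorm(n)
  fit <- fit_trend(y, g, X)
  mm <- model.matrix(~ genotype + age + sex + center,
                     data = cbind(data.frame(genotype = g), X))
  beta_oracle <- solve(t(mm) %*% mm, t(mm) %*% y)
  expect_equal(unname(fit$coefficients), c(beta_oracle), tolerance = 1e-10)

  # constant outcome: genotype coefficient exactly 0
  expect_equal(fit_trend(rep(2, n), g)$beta, 0)

  # noiseless limit recovers the generating slope
  y0 <- 0.7 * g + rnorm(n, sd = 1e-10)
  expect_equal(fit_trend(y0, g)$beta, 0.7, tolerance = 1e-6)

  # rank-deficient design names the collinear column
  X2 <- data.frame(age = X$age, age_copy = X$age)
  expect_error(fit_trend(y, g, X2), "collinear.*age_copy")
  expect_error(fit_trend(y, rep(1, n)), "2 distinct")
})

test_that("bootstrap trend p-values are seeded, bounded away from 0 and signal-sensitive", {
  set.seed(61)
  n <- 200
  g <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  y_strong <- 2 * g + rnorm(n, sd = 0.1)
  spec <- fast_spec(n_boot = 400)
  res <- bootstrap_trend_p(y_strong, g, spec = spec)
  # strong signal: every resampled beta on one side, p at the attainable floor
  expect_equal(res$p, 2 / (spec$n_boot + 1))
  expect_gt(res$p, 0)

  res2 <- bootstrap_trend_p(y_strong, g, spec = spec)
  expect_identical(res, res2)

  # residual bootstrap agrees on the strong signal
  res_r <- bootstrap_trend_p(y_strong, g,
                             spec = fast_spec(n_boot = 400, method = "residuals"))
  expect_equal(res_r$p, 2 / 401)
})

test_that("bootstrap and classical OLS p agree on Gaussian data", {
  set.seed(62)
  n <- 500
  g <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  y <- 0.12 * g + rnorm(n)
  fit <- fit_trend(y, g)
  res <- bootstrap_trend_p(y, g, spec = fast_spec(n_boot = 2000))
  # asymptotically equivalent; allow Monte-Carlo error ~ 1/sqrt(n_boot)
  expect_lt(abs(res$p - fit$t_p), 4 * sqrt(0.25 / 2000) + 0.02)
})

test_that("differential trend recovers the interaction and is sign-symmetric", {
  co <- generate_cohort(cohort_config(n_individuals = 300, n_snps = 1,
                                      n_mirnas = 1, beta_g = 0,
                                      gamma_gxt = 0.5, sigma = 0.4,
                                      pi_zero = 0, mu_range = c(6, 7),
                                      seed = 63))
  yt <- log2(co$expression_tumor[1, ] + 1)
  yn <- log2(co$expression_normal[1, ] + 1)
  g <- co$genotypes[1, ]
  res <- differential_trend(yt, yn, g, spec = fast_spec(n_boot = 300))
  # recovery within a generous CI of the generating interaction
  expect_lt(abs(res$beta - 0.5), 4 * res$boot_sd)

  # tumor == normal: beta 0, p near 1
  res0 <- differential_trend(yn, yn, g, spec = fast_spec(n_boot = 300))
  expect_equal(res0$beta, 0)
  expect_gt(res0$p, 0.9)

  # flipping all differences flips beta, leaves p unchanged
  res_pos <- bootstrap_trend_p(yt - yn, g, spec = fast_spec(n_boot = 300))
  res_neg <- bootstrap_trend_p(yn - yt, g, spec = fast_spec(n_boot = 300))
  expect_equal(res_neg$beta, -res_pos$beta)
  expect_equal(res_neg$p, res_pos$p)
})

test_that("paired bootstrap t-test behaves at the extremes", {
  set.seed(64)
  x <- rnorm(50)
  same <- paired_bootstrap_ttest(x, x, fast_spec(n_boot = 200))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  # large shift: p at the attainable minimum
  tumor <- x + 1; spec <- fast_spec(n_boot = 500)
  res <- paired_bootstrap_ttest(tumor + rnorm(50, sd = 0.3), x, spec)
  expect_equal(res$p, 1 / (spec$n_boot + 1))
  expect_error(paired_bootstrap_ttest(1:2, 2:3, spec), "at least 3")
})

test_that("trend test size is near nominal under the null", {
  # Monte-Carlo size study, scaled for the routine suite
  set.seed(65)
  n_sim <- 200; n <- 120; B <- 150
  rej <- 0L
  for (s in seq_len(n_sim)) {
    g <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
    y <- rnorm(n)
    p <- bootstrap_trend_p(y, g, spec = bootstrap_spec(n_boot = B))$p
    rej <- rej + (p < 0.05)
  }
  rate <- rej / n_sim
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(66)
  for (len in c(2, 3, 5, 7, 10)) {
    p <- round(runif(len), 3)
    expect_equal(bh_fdr(p), bh_oracle(p), info = paste("len", len))
    # adjusted >= raw, order preserved, monotone in rank
    q <- bh_fdr(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  # ties and duplicated values
  p_t <- c(0.02, 0.02, 0.5, 0.5, 0.001)
  expect_equal(bh_fdr(p_t), bh_oracle(p_t))
})
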
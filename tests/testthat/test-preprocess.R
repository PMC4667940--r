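# build a matrix whose per-sample (type-7) 75th percentiles are exactly `q75s`
mat_with_q75 <- function(q75s) {
  m <- vapply(q75s, function(q) c(q / 4, q / 2, q, q), numeric(4))
  colnames(m) <- paste0("s", seq_along(q75s))
  rownames(m) <- paste0("m", 1:4)
  m
}

test_that("scaling factors follow the stratified median-q75 formula", {
  m <- mat_with_q75(c(10, 20, 40))
  q75 <- apply(m, 2, quantile, probs = 0.75, names = FALSE)
  f <- compute_scaling_factors(m, strata = rep("one", 3))
  expect_equal(unname(f), unname(median(q75) / q75))

  # hand evaluation on exact q75 values (10, 20, 40) -> (2, 1, 0.5)
  m2 <- rbind(a = c(10, 20, 40), b = c(10, 20, 40), c = c(10, 20, 40),
              d = c(10, 20, 40))
  colnames(m2) <- c("s1", "s2", "s3")
  f2 <- compute_scaling_factors(m2, rep("one", 3))
  expect_equal(unname(f2), c(2, 1, 0.5))

  # single-sample stratum: median over one value, factor exactly 1
  f3 <- compute_scaling_factors(m2[, 1, drop = FALSE], "solo")
  expect_equal(unname(f3), 1)

  # stratum independence: two strata jointly = each alone
  m4 <- cbind(m2, m2 * 3)
  colnames(m4) <- paste0("s", 1:6)
  strata <- rep(c("A", "B"), each = 3)
  joint <- compute_scaling_factors(m4, strata)
  alone_a <- compute_scaling_factors(m4[, 1:3], rep("A", 3))
  alone_b <- compute_scaling_factors(m4[, 4:6], rep("B", 3))
  expect_equal(unname(joint), unname(c(alone_a, alone_b)))

  # q75 of zero is an error naming the sample
  m5 <- m2; m5[, 2] <- 0
  expect_error(compute_scaling_factors(m5, rep("one", 3)), "s2")
})

test_that("normalization reaches its fixed point and is idempotent", {
  co <- small_cohort(n = 60, n_snps = 8, seed = 8, pi_zero = 0.05,
                     mu_range = c(4, 8))
  sig <- co$expression_normal
  strata <- co$covariates$site
  norm <- normalize_expression(sig, strata)

  q75_before <- apply(sig, 2, quantile, probs = 0.75, names = FALSE)
  q75_after <- apply(norm$values, 2, quantile, probs = 0.75, names = FALSE)
  for (s in unique(strata)) {
    target <- median(q75_before[strata == s])
    expect_equal(unname(q75_after[strata == s]),
                 rep(target, sum(strata == s)), tolerance = 1e-9)
  }

  # idempotence: second-pass factors are all 1
  f2 <- compute_scaling_factors(norm$values, strata)
  expect_equal(unname(f2), rep(1, length(f2)), tolerance = 1e-12)

  # scale equivariance: scaling a stratum's raw signal by c leaves the
  # factors unchanged and scales that stratum's normalized values by c
  sig2 <- sig
  in_s1 <- strata == strata[1]
  sig2[, in_s1] <- sig2[, in_s1] * 7
  norm2 <- normalize_expression(sig2, strata)
  expect_equal(norm2$scaling_factors, norm$scaling_factors, tolerance = 1e-12)
  expect_equal(norm2$values[, in_s1], norm$values[, in_s1] * 7, tolerance = 1e-12)
  expect_equal(norm2$values[, !in_s1], norm$values[, !in_s1], tolerance = 1e-12)
})

test_that("apply_normalization validates alignment and identity factors", {
  m <- matrix(1:6, 2, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  id <- apply_normalization(m, setNames(c(1, 1, 1), colnames(m)))
  expect_equal(id$values, m)
  expect_error(apply_normalization(m, setNames(c(1, 1, 1), c("s1", "s2", "s9"))),
               "misaligned")
  expect_error(apply_normalization(m, c(1, -1, 1)), "positive")
})

test_that("log2 transform applies the recorded offset", {
  m <- matrix(c(0, 3, 1, 7), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  out <- log2_transform(m, offset = 1)
  expect_equal(out["a", "s1"], 0)
  expect_equal(out["b", "s2"], 3)           # log2(7 + 1)
  expect_equal(out["a", "s2"], 1)           # log2(1 + 1)
  expect_equal(attr(out, "log2_offset"), 1)
  expect_error(log2_transform(m, offset = 0), "offset")
  # inverse transform recovers the signal scale used for reporting
  expect_equal(2^out - 1, m, ignore_attr = TRUE)
})

test_that("expression prevalence counts strictly positive signal", {
  m <- rbind(allzero = c(0, 0, 0, 0), some = c(0, 1, 2, 0), all = c(1, 1, 1, 1))
  colnames(m) <- paste0("s", 1:4)
  prev <- expression_prevalence(m)
  expect_equal(unname(prev), c(0, 0.5, 1))

  # boundary arithmetic: 16 of 320 samples is exactly 5%
  m2 <- matrix(c(rep(1, 16), rep(0, 304)), nrow = 1,
               dimnames = list("m", paste0("s", 1:320)))
  expect_equal(unname(expression_prevalence(m2)), 0.05)

  # generator truth: pi_zero = 0.9 leaves ~10% prevalence
  co <- generate_cohort(cohort_config(n_individuals = 400, n_snps = 2,
                                      n_mirnas = 2, pi_zero = 0.9,
                                      mu_range = c(8, 10), seed = 3))
  prev3 <- mean(expression_prevalence(co$expression_normal))
  expect_lt(abs(prev3 - 0.1), 4 * sqrt(0.1 * 0.9 / 800))
})
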
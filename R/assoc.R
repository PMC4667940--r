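#' Bootstrap settings for the association tests
#'
#' @param n_boot number of bootstrap resamples (>= 100; default 10000).
#' @param seed optional integer seed.
#' @param two_sided logical; two-sided p-values (default TRUE).
#' @param method `"cases"` (nonparametric resampling of individuals,
#'   the default) or `"residuals"` (residual bootstrap, offered for
#'   sensitivity analysis).
#' @return validated list of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_boot = 10000, seed = NULL, two_sided = TRUE,
                           method = c("cases", "residuals")) {
  stopifnot(is.numeric(n_boot), length(n_boot) == 1L)
  if (n_boot < 100) stop("n_boot must be at least 100")
  out <- list(n_boot = as.integer(n_boot), seed = seed,
              two_sided = isTRUE(two_sided), method = match.arg(method))
  class(out) <- "bootstrap_spec"
  out
}

# Build the trend-model design matrix: intercept, numeric genotype code,
# then covariates (factors one-hot against a reference level).
.trend_design <- function(g, X, n) {
  if (is.null(X)) {
    mm <- cbind(`(Intercept)` = 1, genotype = g)
  } else {
    X <- as.data.frame(X)
    stopifnot(nrow(X) == n)
    mm <- stats::model.matrix(~ ., data = cbind(data.frame(genotype = g), X))
  }
  mm
}

#' Fit the genotype linear-trend model by ordinary least squares
#'
#' Regresses log2 expression on the additive genotype code (0/1/2,
#' treated as numeric so the test is for linear trend across genotypes)
#' with optional covariate adjustment (age, sex, study center in the
#' canonical analysis). When a genotype class is absent the fit proceeds
#' on the remaining codes.
#'
#' @param y numeric outcome per individual (log2 expression).
#' @param g additive genotype codes 0/1/2.
#' @param X optional data.frame of covariates; factors are expanded
#'   against a reference level.
#' @return object of class `trend_fit`: list with `beta` (the genotype
#'   coefficient), `coefficients`, `se`, `t_p` (classical t-test p for
#'   the genotype coefficient), `n`, `df_residual`, and the design/
#'   outcome needed for bootstrapping.
#' @examples
#' g <- rep(0:2, each = 20)
#' y <- 0.7 * g + rnorm(60, sd = 0.2)
#' coef(fit_trend(y, g))
#' @export
fit_trend <- function(y, g, X = NULL) {
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  if (!is.null(X)) X <- as.data.frame(X)[keep, , drop = FALSE]
  n <- length(y)
  if (length(unique(g)) < 2L) stop("genotype must take at least 2 distinct values")
  mm <- .trend_design(g, X, n)
  if (n <= ncol(mm)) stop("more coefficients than observations")
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(mm, y)
  res <- fit$residuals
  sigma2 <- sum(res^2) / fit$df.residual
  xtx_inv <- chol2inv(chol(crossprod(mm)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  names(se) <- colnames(mm)
  tval <- fit$coefficients / se
  t_p <- 2 * stats::pt(abs(tval), fit$df.residual, lower.tail = FALSE)
  out <- list(beta = unname(fit$coefficients["genotype"]),
              coefficients = fit$coefficients, se = se,
              t_p = unname(t_p["genotype"]),
              n = n, df_residual = fit$df.residual,
              design = mm, y = y, fitted = fit$fitted.values,
              residuals = res)
  class(out) <- "trend_fit"
  out
}

#' @export
coef.trend_fit <- function(object, ...) object$coefficients

#' @export
print.trend_fit <- function(x, ...) {
  cat("Genotype linear-trend fit (n =", x$n, ")\n")
  cat("  beta per minor allele:", signif(x$beta, 4),
      " SE:", signif(x$se["genotype"], 4),
      " t-test p:", signif(x$t_p, 3), "\n")
  invisible(x)
}

#' Bootstrap p-value for the genotype trend coefficient
#'
#' Builds the empirical distribution of the genotype coefficient by
#' refitting the trend model on `n_boot` resamples and evaluates
#' H0: beta = 0 against H1: beta != 0. With case resampling, rows
#' (outcome, genotype, covariates together) are drawn with replacement;
#' resamples in which the genotype is degenerate (a single distinct
#' value) are redrawn, with a guard that aborts if more than half of
#' all draws are degenerate. The two-sided p-value is
#' \deqn{p = \min\left(1,\; 2\,\frac{\min(\#\{\beta^* \le 0\},\, \#\{\beta^* \ge 0\}) + 1}{B + 1}\right)}
#' so p is never exactly zero at finite B.
#'
#' @inheritParams fit_trend
#' @param spec a [bootstrap_spec()].
#' @return list with `p`, `beta` (observed), `boot_mean`, `boot_sd`,
#'   `boot_quantiles` (2.5/25/50/75/97.5%), `n_boot`, `n_degenerate`.
#' @export
bootstrap_trend_p <- function(y, g, X = NULL, spec = bootstrap_spec()) {
  stopifnot(inherits(spec, "bootstrap_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  obs <- fit_trend(y, g, X)
  n <- obs$n
  B <- spec$n_boot
  j <- match("genotype", colnames(obs$design))
  betas <- numeric(B)
  n_degen <- 0L
  if (spec$method == "cases") {
    yy <- obs$y
    mm <- obs$design
    gcol <- mm[, j]
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(gcol[idx])) >= 2L) break
        n_degen <- n_degen + 1L
        if (n_degen > B / 2) {
          stop("more than half of bootstrap resamples had a degenerate ",
               "genotype; increase the sample size or apply the ",
               "monomorphic-SNP filter first")
        }
      }
      betas[b] <- stats::lm.fit(mm[idx, , drop = FALSE], yy[idx])$coefficients[j]
    }
  } else {
    mm <- obs$design
    fitted <- obs$fitted
    res <- obs$residuals
    for (b in seq_len(B)) {
      ystar <- fitted + sample(res, n, replace = TRUE)
      betas[b] <- stats::lm.fit(mm, ystar)$coefficients[j]
    }
  }
  n_le <- sum(betas <= 0) + 1L
  n_ge <- sum(betas >= 0) + 1L
  p <- if (spec$two_sided) {
    min(1, 2 * min(n_le, n_ge) / (B + 1))
  } else {
    min(n_le, n_ge) / (B + 1)
  }
  list(p = p, beta = obs$beta,
       boot_mean = mean(betas), boot_sd = stats::sd(betas),
       boot_quantiles = stats::quantile(betas, c(0.025, 0.25, 0.5, 0.75, 0.975)),
       n_boot = B, n_degenerate = n_degen)
}

#' Genotype trend on paired tumor-minus-normal differences
#'
#' Computes per-individual differences d = log2(tumor) - log2(normal)
#' and runs [fit_trend()] plus [bootstrap_trend_p()] on d, testing
#' whether the tumor/non-tumor expression change varies across
#' genotypes. Individuals with a missing value in either tissue are
#' dropped with a message.
#'
#' @param y_tumor,y_normal per-individual log2 values, paired by
#'   position.
#' @inheritParams bootstrap_trend_p
#' @return as [bootstrap_trend_p()], plus `n_dropped`.
#' @export
differential_trend <- function(y_tumor, y_normal, g, X = NULL,
                               spec = bootstrap_spec()) {
  stopifnot(length(y_tumor) == length(y_normal))
  d <- y_tumor - y_normal
  dropped <- sum(is.na(d) & !(is.na(y_tumor) & is.na(y_normal)))
  if (dropped > 0) message(dropped, " unpaired individuals dropped")
  out <- bootstrap_trend_p(d, g, X, spec)
  out$n_dropped <- dropped
  out
}

#' Paired bootstrap t-test of tumor versus non-tumor expression
#'
#' The observed statistic is the paired t on the differences
#' d = tumor - normal. The null distribution is built by resampling the
#' mean-centered differences with replacement and recomputing t, so the
#' resampling world satisfies H0 by construction;
#' p = (#\{|t*| >= |t_obs|\} + 1) / (B + 1).
#'
#' @param tumor,normal per-individual log2 values, paired by position.
#' @param spec a [bootstrap_spec()].
#' @return list with `t` (observed statistic), `p`, `mean_diff`, `n`,
#'   `n_boot`, and `degenerate` (TRUE when the differences have zero
#'   variance, in which case p = 1).
#' @export
paired_bootstrap_ttest <- function(tumor, normal, spec = bootstrap_spec()) {
  stopifnot(inherits(spec, "bootstrap_spec"), length(tumor) == length(normal))
  keep <- !is.na(tumor) & !is.na(normal)
  d <- tumor[keep] - normal[keep]
  n <- length(d)
  if (n < 3) stop("paired t-test needs at least 3 complete pairs")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = 0, p = 1, mean_diff = mean(d), n = n,
                n_boot = spec$n_boot, degenerate = TRUE))
  }
  t_obs <- mean(d) / (s / sqrt(n))
  dc <- d - mean(d)
  B <- spec$n_boot
  tstar <- numeric(B)
  for (b in seq_len(B)) {
    db <- sample(dc, n, replace = TRUE)
    sb <- stats::sd(db)
    tstar[b] <- if (sb == 0) {
      if (db[1] == 0) 0 else Inf
    } else {
      mean(db) / (sb / sqrt(n))
    }
  }
  p <- (sum(abs(tstar) >= abs(t_obs)) + 1) / (B + 1)
  list(t = t_obs, p = p, mean_diff = mean(d), n = n, n_boot = B,
       degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values over the family of all tests in the run:
#' the i-th smallest p becomes `min_{j >= i} p_(j) * m / j`, capped at
#' 1, returned in the input order.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  stopifnot(is.numeric(p))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Genotype-stratified descriptive summary
#'
#' Per genotype class: N, mean signal on the normalized (non-log2)
#' scale, and the percent of individuals with zero signal — the
#' descriptive companions to the trend test.
#'
#' @param signal per-individual normalized signal values (non-log2).
#' @param g additive genotype codes 0/1/2.
#' @return data.frame with one row per genotype code 0, 1, 2.
#' @export
genotype_strata_summary <- function(signal, g) {
  stopifnot(length(signal) == length(g))
  out <- lapply(0:2, function(k) {
    v <- signal[!is.na(g) & g == k]
    data.frame(genotype = k, n = length(v),
               mean_signal = if (length(v)) mean(v) else NA_real_,
               pct_zero = if (length(v)) 100 * mean(v == 0) else NA_real_)
  })
  do.call(rbind, out)
}
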
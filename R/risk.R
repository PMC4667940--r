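#' Crude odds ratio from a 2x2 genotype-class table
#'
#' OR = (cases_alt * controls_ref) / (controls_alt * cases_ref), with a
#' Woolf (log-scale normal) 95% confidence interval
#' exp(log OR +/- 1.96 * sqrt(sum of reciprocal cells)). When any cell
#' is zero the Haldane-Anscombe correction adds 0.5 to every cell; when
#' both cells of a genotype group are zero the OR is undefined and the
#' result is flagged.
#'
#' @param controls_ref,cases_ref counts in the referent genotype class
#'   (common homozygote).
#' @param controls_alt,cases_alt counts in the comparison class
#'   (heterozygote or rare homozygote).
#' @return list with `or`, `ci` (length-2), and `undefined`.
#' @examples
#' crude_or(928, 836, 11, 23)   # rare-homozygote class of a risk SNP
#' @export
crude_or <- function(controls_ref, cases_ref, controls_alt, cases_alt) {
  cells <- c(controls_ref, cases_ref, controls_alt, cases_alt)
  if (any(cells < 0)) stop("counts must be non-negative")
  if ((controls_ref == 0 && cases_ref == 0) ||
      (controls_alt == 0 && cases_alt == 0)) {
    return(list(or = NA_real_, ci = c(NA_real_, NA_real_), undefined = TRUE))
  }
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[4] * cells[1]) / (cells[3] * cells[2])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  list(or = or, ci = ci, undefined = FALSE)
}

#' Genotype-class logistic regression for case-control risk
#'
#' Fits case/control status on heterozygote and rare-homozygote
#' indicators (referent: common homozygote) with optional covariate
#' adjustment (age, sex, study center in the canonical analysis), by
#' maximum likelihood (iteratively reweighted least squares; relative
#' deviance convergence 1e-8, at most 50 iterations). Reports odds
#' ratios with Wald 95% confidence intervals. A per-allele trend coding
#' is available instead of indicators.
#'
#' @param status 0/1 case-control outcome.
#' @param g additive genotype codes 0/1/2.
#' @param X optional covariate data.frame.
#' @param coding `"indicator"` (default: het and rare-hom vs common-hom)
#'   or `"trend"` (single per-allele term).
#' @return object of class `risk_fit`: per-genotype control/case counts,
#'   data.frame `or_table` with term, OR, CI bounds and p, the glm fit,
#'   and `separation` (TRUE when quasi-separation was detected, in
#'   which case intervals are suppressed).
#' @examples
#' g <- generate_genotypes(400, 0.3, seed = 2)
#' status <- rbinom(400, 1, plogis(0.3 * g))
#' fit_genotype_logistic(status, g)
#' @export
fit_genotype_logistic <- function(status, g, X = NULL,
                                  coding = c("indicator", "trend")) {
  coding <- match.arg(coding)
  keep <- !is.na(status) & !is.na(g)
  status <- status[keep]; g <- g[keep]
  if (!is.null(X)) X <- as.data.frame(X)[keep, , drop = FALSE]
  if (length(unique(status)) < 2L) stop("both outcome classes must be present")
  df <- if (coding == "indicator") {
    d <- data.frame(status = status,
                    het = as.integer(g == 1), hom_rare = as.integer(g == 2))
    # an absent genotype class contributes no indicator
    d[, c(TRUE, any(g == 1), any(g == 2)), drop = FALSE]
  } else {
    data.frame(status = status, per_allele = g)
  }
  if (!is.null(X)) df <- cbind(df, X)
  mm <- stats::model.matrix(stats::reformulate(setdiff(names(df), "status")),
                            data = df)
  if (qr(mm)$rank < ncol(mm)) stop("design matrix is not full rank")
  fit <- stats::glm(status ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  cf <- summary(fit)$coefficients
  terms <- setdiff(rownames(cf), "(Intercept)")
  gt <- if (coding == "indicator") intersect(c("het", "hom_rare"), terms) else "per_allele"
  separation <- !fit$converged ||
    (any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8) &&
       any(abs(cf[gt, "Estimate"]) > 10))
  or_table <- data.frame(
    term = gt,
    or = exp(cf[gt, "Estimate"]),
    ci_lower = if (separation) NA_real_ else exp(cf[gt, "Estimate"] - 1.96 * cf[gt, "Std. Error"]),
    ci_upper = if (separation) NA_real_ else exp(cf[gt, "Estimate"] + 1.96 * cf[gt, "Std. Error"]),
    p = cf[gt, "Pr(>|z|)"],
    stringsAsFactors = FALSE)
  rownames(or_table) <- NULL
  counts <- table(factor(g, levels = 0:2),
                  factor(status, levels = 0:1, labels = c("controls", "cases")))
  out <- list(counts = counts, or_table = or_table, glm = fit,
              coding = coding, separation = separation)
  class(out) <- "risk_fit"
  out
}

#' @export
print.risk_fit <- function(x, ...) {
  cat("Genotype-class logistic risk model (", x$coding, " coding)\n", sep = "")
  print(x$counts)
  tab <- x$or_table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-10s OR %.2f (95%% CI %.2f, %.2f)  p = %.3g\n",
                tab$term[i], tab$or[i], tab$ci_lower[i], tab$ci_upper[i],
                tab$p[i]))
  }
  if (x$separation) cat("  [separation detected: intervals suppressed]\n")
  invisible(x)
}

#' @export
coef.risk_fit <- function(object, ...) stats::coef(object$glm)
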
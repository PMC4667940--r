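#' Per-sample 75th-percentile scaling factors, stratified
#'
#' For sample j in stratum s, the factor is
#' \deqn{f_j = \mathrm{median}_{k \in s}(q75_k)\, /\, q75_j}
#' where q75 is the sample's 75th percentile of signal. Multiplying each
#' sample by its factor equalizes the 75th percentiles within a stratum
#' at the stratum's median, removing array-to-array intensity
#' differences while preserving relative signal within a sample.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param signal miRNA x sample signal matrix (non-negative).
#' @param strata per-sample stratum labels (e.g. tumor site), aligned to
#'   the columns of `signal`.
#' @return named numeric vector of per-sample factors (> 0).
#' @examples
#' m <- rbind(a = c(10, 20, 40), b = c(5, 10, 20), c = c(1, 2, 4), d = c(0, 0, 0))
#' colnames(m) <- c("s1", "s2", "s3")
#' compute_scaling_factors(m, strata = rep("one", 3))
#' @export
compute_scaling_factors <- function(signal, strata) {
  stopifnot(is.matrix(signal))
  if (length(strata) != ncol(signal)) {
    stop("strata must supply one label per sample (",
         length(strata), " labels for ", ncol(signal), " samples)")
  }
  if (anyNA(strata)) stop("every sample needs a stratum label")
  q75 <- apply(signal, 2, stats::quantile, probs = 0.75, names = FALSE, type = 7)
  if (any(q75 <= 0)) {
    stop("cannot normalize samples with 75th percentile of 0: ",
         paste(colnames(signal)[q75 <= 0], collapse = ", "))
  }
  factors <- numeric(ncol(signal))
  for (s in unique(strata)) {
    in_s <- strata == s
    factors[in_s] <- stats::median(q75[in_s]) / q75[in_s]
  }
  names(factors) <- colnames(signal)
  factors
}

#' Apply per-sample scaling factors
#'
#' @param signal miRNA x sample signal matrix.
#' @param factors per-sample positive multipliers; if named, they must
#'   cover exactly the matrix's samples.
#' @param strata optional per-sample stratum labels, recorded in the result.
#' @return object of class `normalized_matrix`: list with `values`
#'   (scaled matrix), `scaling_factors`, `strata`, and `log2_offset`
#'   (NA until [log2_transform()] is applied).
#' @export
apply_normalization <- function(signal, factors, strata = NULL) {
  stopifnot(is.matrix(signal))
  if (!is.null(names(factors)) && !is.null(colnames(signal))) {
    missing_f <- setdiff(colnames(signal), names(factors))
    extra_f <- setdiff(names(factors), colnames(signal))
    if (length(missing_f) || length(extra_f)) {
      stop("factors misaligned with samples; missing: [",
           paste(missing_f, collapse = ", "), "] extra: [",
           paste(extra_f, collapse = ", "), "]")
    }
    factors <- factors[colnames(signal)]
  } else if (length(factors) != ncol(signal)) {
    stop("need one factor per sample")
  }
  if (any(factors <= 0)) stop("scaling factors must be positive")
  out <- list(values = sweep(signal, 2, factors, `*`),
              scaling_factors = factors,
              strata = strata,
              log2_offset = NA_real_)
  class(out) <- "normalized_matrix"
  out
}

#' Stratified 75th-percentile normalization in one step
#'
#' Convenience wrapper: [compute_scaling_factors()] then
#' [apply_normalization()].
#'
#' @inheritParams compute_scaling_factors
#' @return a `normalized_matrix`.
#' @export
normalize_expression <- function(signal, strata) {
  f <- compute_scaling_factors(signal, strata)
  apply_normalization(signal, f, strata = strata)
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("Normalized expression matrix:", nrow(x$values), "miRNAs x",
      ncol(x$values), "samples\n")
  cat("  scaling factors in [", signif(min(x$scaling_factors), 4), ", ",
      signif(max(x$scaling_factors), 4), "]\n", sep = "")
  if (!is.null(x$strata)) cat("  strata:", paste(unique(x$strata), collapse = ", "), "\n")
  invisible(x)
}

#' Log2-transform normalized signal
#'
#' Computes `log2(x + offset)`. Zero signal values require a positive
#' offset; the offset is recorded so reported means can be mapped back
#' to the signal scale.
#'
#' @param x a `normalized_matrix` or plain numeric matrix.
#' @param offset non-negative constant added before taking logs
#'   (default 1, so zero signal maps to 0).
#' @return numeric matrix of log2 values, with the offset in
#'   `attr(, "log2_offset")`; for `normalized_matrix` input the offset
#'   is also recorded in the object's metadata slot of the returned
#'   attribute copy.
#' @export
log2_transform <- function(x, offset = 1) {
  vals <- if (inherits(x, "normalized_matrix")) x$values else x
  stopifnot(is.numeric(vals), offset >= 0)
  if (offset == 0 && any(vals == 0)) {
    stop("zero signal values present: log2 transform needs a positive offset")
  }
  out <- log2(vals + offset)
  attr(out, "log2_offset") <- offset
  out
}

#' Per-miRNA expression prevalence
#'
#' Proportion of samples in which each miRNA has signal strictly above
#' zero. `1 - prevalence` is the "% zero expression" descriptor used in
#' genotype-stratified reporting, and prevalence in non-tumor tissue
#' feeds the cascade's >= 5% expression filter.
#'
#' @param x a `normalized_matrix` or numeric matrix.
#' @return named numeric vector of proportions in [0, 1].
#' @export
expression_prevalence <- function(x) {
  vals <- if (inherits(x, "normalized_matrix")) x$values else x
  stopifnot(is.numeric(vals))
  rowMeans(vals > 0)
}

#' Per-sample normalization report
#'
#' @param signal the raw signal matrix that was normalized.
#' @param norm the `normalized_matrix` produced from it.
#' @return data.frame with sample, stratum, q75 before and after
#'   scaling, and the factor; writable as TSV.
#' @export
normalization_report <- function(signal, norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  q75_before <- apply(signal, 2, stats::quantile, probs = 0.75, names = FALSE)
  q75_after <- apply(norm$values, 2, stats::quantile, probs = 0.75, names = FALSE)
  data.frame(sample = colnames(signal),
             stratum = if (is.null(norm$strata)) NA else norm$strata,
             q75_before = q75_before, q75_after = q75_after,
             factor = unname(norm$scaling_factors),
             stringsAsFactors = FALSE)
}
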
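#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: all
#' heterozygote counts compatible with the allele counts (same parity,
#' within bounds) are enumerated, each configuration's probability under
#' random mating is computed from the hypergeometric-form expression,
#' and the p-value is the sum of probabilities no greater than that of
#' the observed configuration. A monomorphic marker admits a single
#' configuration and returns p = 1.
#'
#' @param n_AA,n_AB,n_BB genotype counts (common homozygote,
#'   heterozygote, rare homozygote).
#' @return exact two-sided p-value in [0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(50, 0, 50)   # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  counts <- c(n_AA, n_AB, n_BB)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  if (any(counts != round(counts))) stop("genotype counts must be integers")
  n <- sum(counts)
  if (n < 1) stop("need at least one genotyped individual")
  n_a <- 2 * min(n_AA, n_BB) + n_AB      # minor allele count
  if (n_AA < n_BB) {                     # orient so 'rare' is the minor allele
    tmp <- n_AA; n_AA <- n_BB; n_BB <- tmp
  }
  n_b <- 2 * n - n_a
  if (n_a == 0) return(1)
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(n_a %% 2, n_a, by = 2)
  # log P(n_AB = h | n, n_a) up to a constant:
  #   n! / (nAA! nAB! nBB!) * 2^nAB with nBB = (n_a - h)/2, nAA = n - nBB - h
  logp <- vapply(hets, function(h) {
    hom_rare <- (n_a - h) / 2
    hom_common <- n - hom_rare - h
    h * log(2) - lfactorial(hom_common) - lfactorial(h) - lfactorial(hom_rare)
  }, numeric(1))
  p_cfg <- exp(logp - max(logp))
  p_cfg <- p_cfg / sum(p_cfg)
  p_obs <- p_cfg[match(n_AB, hets)]
  min(1, sum(p_cfg[p_cfg <= p_obs * (1 + 1e-10)]))
}

#' Filtering thresholds for the SNP-miRNA pair cascade
#'
#' @param min_expression_prevalence minimum proportion of individuals
#'   with non-tumor expression (default 0.05).
#' @param min_minor_carriers minimum number of individuals carrying the
#'   minor allele for a SNP to count as polymorphic (default 2).
#' @param hwe_alpha exact Hardy-Weinberg test threshold; SNPs with
#'   p below it are excluded (default 1e-4).
#' @param expressed_in tissue scope of the any-expression stage:
#'   `"any"` (either tissue, the default) or `"normal"`.
#' @param exclusions optional character vector of SNP ids failing
#'   upstream array QC (supplied externally; treated as lacking usable
#'   genotype data).
#' @return validated list of class `filter_params`.
#' @export
filter_params <- function(min_expression_prevalence = 0.05,
                          min_minor_carriers = 2,
                          hwe_alpha = 1e-4,
                          expressed_in = c("any", "normal"),
                          exclusions = character(0)) {
  stopifnot(min_expression_prevalence >= 0, min_expression_prevalence <= 1,
            min_minor_carriers >= 0,
            hwe_alpha > 0, hwe_alpha < 1)
  out <- list(min_expression_prevalence = min_expression_prevalence,
              min_minor_carriers = min_minor_carriers,
              hwe_alpha = hwe_alpha,
              expressed_in = match.arg(expressed_in),
              exclusions = exclusions)
  class(out) <- "filter_params"
  out
}

.minor_carriers <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) return(0L)
  q2 <- (sum(g == 1) + 2 * sum(g == 2)) / (2 * length(g))  # freq of '2' allele
  if (q2 <= 0.5) sum(g >= 1) else sum(g <= 1)
}

#' Apply the staged SNP-miRNA pair filtering cascade
#'
#' Stages, applied in order with first-failure attribution:
#' \enumerate{
#'   \item \strong{expressed_anywhere}: drop pairs whose miRNA is absent
#'     from the platform (unmatched expansion records) or has zero
#'     signal in every sample of the chosen tissue scope;
#'   \item \strong{genotype_available}: drop pairs whose SNP has no
#'     genotype data (absent, all-missing, or on the QC exclusion list);
#'   \item \strong{polymorphic}: drop SNPs with fewer than
#'     `min_minor_carriers` minor-allele carriers or failing the exact
#'     Hardy-Weinberg test at `hwe_alpha`;
#'   \item \strong{prevalent}: drop pairs whose miRNA is expressed in
#'     fewer than `min_expression_prevalence` of non-tumor samples.
#' }
#'
#' @param pairs expanded pair catalog (see [expand_pairs()]); a
#'   `matched` column, if present, marks platform-matched records.
#' @param expr_normal,expr_tumor signal matrices (miRNA x sample); raw
#'   or normalized scale — only zero/non-zero status is used.
#' @param genotypes SNP x individual matrix of 0/1/2/NA codes.
#' @param params a `filter_params`.
#' @return list with `pairs` (surviving records, with per-stage logical
#'   flag columns) and `report` (a `cascade_report`: per-stage in/out
#'   counts plus a per-record `drop_reason` attribute).
#' @export
apply_cascade <- function(pairs, expr_normal, expr_tumor, genotypes,
                          params = filter_params()) {
  stopifnot(is.data.frame(pairs), inherits(params, "filter_params"))
  en <- if (inherits(expr_normal, "normalized_matrix")) expr_normal$values else expr_normal
  et <- if (inherits(expr_tumor, "normalized_matrix")) expr_tumor$values else expr_tumor
  common <- intersect(colnames(en), colnames(genotypes))
  if (length(common) == 0L) {
    stop("expression and genotype sample sets are disjoint")
  }

  n0 <- nrow(pairs)
  reason <- rep(NA_character_, n0)

  # stage 1: expressed in at least one sample (platform + any-expression)
  expressed <- expression_prevalence(en) > 0
  if (params$expressed_in == "any") {
    expressed <- expressed | expression_prevalence(et)[rownames(en)] > 0
  }
  on_platform <- pairs$mirna_name %in% rownames(en)
  if ("matched" %in% names(pairs)) on_platform <- on_platform & pairs$matched
  s1 <- on_platform & expressed[match(pairs$mirna_name, rownames(en))]
  s1[is.na(s1)] <- FALSE
  reason[!s1] <- "not_expressed"

  # stage 2: genotype data available
  has_geno <- pairs$snp_id %in% rownames(genotypes) &
    !(pairs$snp_id %in% params$exclusions)
  any_call <- rep(FALSE, n0)
  idx <- match(pairs$snp_id, rownames(genotypes))
  any_call[!is.na(idx)] <- rowSums(!is.na(genotypes[idx[!is.na(idx)], common,
                                                    drop = FALSE])) > 0
  s2 <- has_geno & any_call
  reason[is.na(reason) & !s2] <- "no_genotype"

  # stage 3: variation and Hardy-Weinberg equilibrium
  s3 <- rep(FALSE, n0)
  for (i in which(s1 & s2)) {
    g <- genotypes[pairs$snp_id[i], common]
    carriers_ok <- .minor_carriers(g) >= params$min_minor_carriers
    gg <- g[!is.na(g)]
    hwe_p <- hwe_exact_test(sum(gg == 0), sum(gg == 1), sum(gg == 2))
    s3[i] <- carriers_ok && hwe_p >= params$hwe_alpha
  }
  reason[is.na(reason) & s1 & s2 & !s3] <- "no_variation_or_hwe"

  # stage 4: non-tumor expression prevalence
  prev <- expression_prevalence(en)
  s4 <- rep(FALSE, n0)
  ok123 <- s1 & s2 & s3
  s4[ok123] <- prev[pairs$mirna_name[ok123]] >= params$min_expression_prevalence
  reason[is.na(reason) & ok123 & !s4] <- "low_prevalence"

  keep <- s1 & s2 & s3 & s4
  stages <- data.frame(
    stage = c("expanded", "expressed_anywhere", "genotype_available",
              "polymorphic", "prevalent"),
    description = c("expanded pair catalog",
                    "miRNA expressed in at least one sample",
                    "SNP genotype data available",
                    "SNP polymorphic and in Hardy-Weinberg equilibrium",
                    paste0("non-tumor expression in >= ",
                           params$min_expression_prevalence * 100, "% of samples")),
    n_in = c(n0, n0, sum(s1), sum(s1 & s2), sum(ok123)),
    n_out = c(n0, sum(s1), sum(s1 & s2), sum(ok123), sum(keep)),
    stringsAsFactors = FALSE)
  stages$n_dropped <- stages$n_in - stages$n_out
  attr(stages, "drop_reason") <- data.frame(
    snp_id = pairs$snp_id, mirna_name = pairs$mirna_name,
    drop_reason = reason, stringsAsFactors = FALSE)
  class(stages) <- c("cascade_report", "data.frame")

  out_pairs <- pairs
  out_pairs$expressed_anywhere <- s1
  out_pairs$genotype_available <- s1 & s2
  out_pairs$polymorphic <- ok123
  out_pairs$prevalent <- keep
  list(pairs = out_pairs[keep, , drop = FALSE], report = stages)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("SNP-miRNA pair filtering cascade\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%-19s] %4d -> %4d   %s\n", x$stage[i], x$n_in[i],
                x$n_out[i], x$description[i]))
  }
  invisible(x)
}

#' Serialize a cascade report as TSV
#' @param report a `cascade_report`.
#' @param path output file path.
#' @export
write_cascade_report <- function(report, path) {
  stopifnot(inherits(report, "cascade_report"))
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
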
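#' Configuration for an end-to-end pipeline run
#'
#' Inputs are supplied either as a [generate_cohort()] object or as file
#' paths in the dialects of the I/O readers; file paths are validated at
#' configuration time.
#'
#' @param cohort optional `synthetic_cohort`; when given, file paths are
#'   ignored.
#' @param expression_tumor,expression_normal,genotypes,covariates,pairs
#'   input file paths (see [read_expression()], [read_genotypes()],
#'   [read_covariates()], [read_pairs()]).
#' @param filter a [filter_params()].
#' @param bootstrap a [bootstrap_spec()].
#' @param log2_offset offset added before the log2 transform (default 1).
#' @param strata_mode `"tissue_site"` (default: site strata computed
#'   separately within the tumor and the non-tumor sample sets) or
#'   `"site"` (tumor and non-tumor samples pooled per site when the
#'   stratum median is taken).
#' @param alpha raw significance threshold used when selecting SNPs for
#'   the risk stage and in the summary (default 0.05).
#' @param out_dir output directory for the stage tables and manifest.
#' @param seed integer seed governing all randomness in the run.
#' @param verbose print per-stage record counts (default TRUE).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(cohort = NULL, expression_tumor = NULL,
                       expression_normal = NULL, genotypes = NULL,
                       covariates = NULL, pairs = NULL,
                       filter = filter_params(),
                       bootstrap = bootstrap_spec(),
                       log2_offset = 1, strata_mode = c("tissue_site", "site"),
                       alpha = 0.05, out_dir = tempfile("mireqtl_run_"),
                       seed = 1L, verbose = TRUE) {
  strata_mode <- match.arg(strata_mode)
  if (is.null(cohort)) {
    paths <- c(expression_tumor = expression_tumor,
               expression_normal = expression_normal,
               genotypes = genotypes, covariates = covariates, pairs = pairs)
    if (length(paths) < 5L) stop("supply either a cohort or all five input paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input files not found: ", paste(missing, collapse = ", "))
    }
  } else {
    stopifnot(inherits(cohort, "synthetic_cohort"))
  }
  cfg <- list(cohort = cohort, expression_tumor = expression_tumor,
              expression_normal = expression_normal, genotypes = genotypes,
              covariates = covariates, pairs = pairs, filter = filter,
              bootstrap = bootstrap, log2_offset = log2_offset,
              strata_mode = strata_mode, alpha = alpha, out_dir = out_dir,
              seed = as.integer(seed), verbose = isTRUE(verbose))
  class(cfg) <- "run_config"
  cfg
}

.log_stage <- function(verbose, ...) if (verbose) message("[mireqtl] ", ...)

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  stripped <- config[setdiff(names(config), c("cohort", "verbose", "out_dir"))]
  writeLines(deparse(stripped), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full association pipeline
#'
#' Executes the stages in order: stratified 75th-percentile
#' normalization and log2 transform of both tissues; pair-list
#' expansion against the platform catalog (the measured miRNAs);
#' the filtering cascade; stage 1, genotype-trend tests with bootstrap
#' p-values on non-tumor log2 expression adjusted for age, sex and
#' center, with FDR over all tested pairs; stage 2, the same trend on
#' paired tumor-minus-normal differences, plus paired bootstrap t-tests
#' of tumor vs non-tumor expression per miRNA; stage 3, genotype-class
#' logistic risk models for SNPs significant (raw p < alpha) in stage 1
#' or 2. All result tables are written as TSV to `config$out_dir`
#' together with a manifest (config hash, seed, per-stage outputs), and
#' a rerun with the same config is bit-identical.
#'
#' @param config a [run_config()].
#' @return object of class `pipeline_run`: list with `cascade`
#'   (the `cascade_report`), `nontumor` (stage-1 table), `differential`
#'   (stage-2 trend table), `paired` (per-miRNA paired-test table),
#'   `risk` (stage-3 table), `summary` (see
#'   [summarize_significance()]), `manifest`, and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  v <- config$verbose
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- load
  if (!is.null(config$cohort)) {
    co <- config$cohort
    expr_t <- co$expression_tumor; expr_n <- co$expression_normal
    geno <- co$genotypes; covar <- co$covariates; pairs <- co$pairs
  } else {
    expr_t <- read_expression(config$expression_tumor)
    expr_n <- read_expression(config$expression_normal)
    geno <- read_genotypes(config$genotypes)
    covar <- read_covariates(config$covariates)
    pairs <- read_pairs(config$pairs)
  }
  ids <- covar$sample_id
  stopifnot(all(ids %in% colnames(expr_t)), all(ids %in% colnames(expr_n)))
  expr_t <- expr_t[, ids, drop = FALSE]
  expr_n <- expr_n[, ids, drop = FALSE]
  site <- covar$site
  .log_stage(v, "loaded ", length(ids), " individuals, ", nrow(geno),
             " SNPs, ", nrow(expr_n), " miRNAs, ", nrow(pairs), " pairs")

  # ---- normalize
  if (config$strata_mode == "tissue_site") {
    norm_t <- normalize_expression(expr_t, site)
    norm_n <- normalize_expression(expr_n, site)
  } else {
    pooled <- cbind(expr_t, expr_n)
    colnames(pooled) <- c(paste0(ids, ".T"), paste0(ids, ".N"))
    f <- compute_scaling_factors(pooled, rep(site, 2))
    norm_t <- apply_normalization(expr_t, stats::setNames(f[seq_along(ids)], ids),
                                  strata = site)
    norm_n <- apply_normalization(expr_n,
                                  stats::setNames(f[length(ids) + seq_along(ids)], ids),
                                  strata = site)
  }
  log2_t <- log2_transform(norm_t, config$log2_offset)
  log2_n <- log2_transform(norm_n, config$log2_offset)
  .log_stage(v, "normalized (strata: ", config$strata_mode, ")")

  # ---- expand + cascade
  expanded <- expand_pairs(pairs, rownames(expr_n))
  casc <- apply_cascade(expanded, norm_n, norm_t, geno, config$filter)
  tested <- casc$pairs
  .log_stage(v, "cascade: ", paste(casc$report$n_out, collapse = " -> "))
  if (nrow(tested) == 0L) stop("no pairs survive the filtering cascade")

  X <- covar[, intersect(c("age", "sex", "center"), names(covar)), drop = FALSE]
  spec <- config$bootstrap

  # ---- stage 1: non-tumor trend
  stage1 <- .trend_table(tested, log2_n, norm_n$values,
                         list(zero = norm_n$values), geno, X, spec)
  stage1$analysis <- "nontumor"
  .log_stage(v, "stage 1: ", nrow(stage1), " non-tumor trend tests")

  # ---- stage 2: tumor-minus-normal differential trend
  stage2 <- .trend_table(tested, log2_t - log2_n, norm_t$values - norm_n$values,
                         list(zero_tumor = norm_t$values,
                              zero_normal = norm_n$values), geno, X, spec)
  stage2$analysis <- "differential"
  .log_stage(v, "stage 2: ", nrow(stage2), " differential trend tests")

  # FDR family: all pairs tested in the run, per analysis
  stage1$q_fdr <- bh_fdr(stage1$p_raw)
  stage2$q_fdr <- bh_fdr(stage2$p_raw)

  # ---- paired tumor vs non-tumor tests per unique miRNA
  mirnas <- unique(tested$mirna_name)
  paired <- do.call(rbind, lapply(mirnas, function(m) {
    res <- paired_bootstrap_ttest(log2_t[m, ], log2_n[m, ], spec)
    data.frame(mirna_name = m,
               mean_tumor = mean(norm_t$values[m, ]),
               pct_zero_tumor = 100 * mean(norm_t$values[m, ] == 0),
               mean_normal = mean(norm_n$values[m, ]),
               pct_zero_normal = 100 * mean(norm_n$values[m, ] == 0),
               t = res$t, p = res$p, stringsAsFactors = FALSE)
  }))
  .log_stage(v, "paired tests: ", nrow(paired), " miRNAs")

  # ---- stage 3: risk models for SNPs significant in stage 1 or 2
  sig_snps <- unique(c(stage1$snp_id[stage1$p_raw < config$alpha],
                       stage2$snp_id[stage2$p_raw < config$alpha]))
  risk <- NULL
  if (length(sig_snps) && "status" %in% names(covar) &&
      length(unique(covar$status)) == 2L) {
    risk <- do.call(rbind, lapply(sig_snps, function(s) {
      g <- geno[s, ids]
      fit <- fit_genotype_logistic(covar$status, g, X)
      tab <- fit$or_table
      cnt <- fit$counts
      row <- data.frame(snp_id = s,
                        controls_0 = cnt["0", "controls"], cases_0 = cnt["0", "cases"],
                        controls_1 = cnt["1", "controls"], cases_1 = cnt["1", "cases"],
                        controls_2 = cnt["2", "controls"], cases_2 = cnt["2", "cases"],
                        stringsAsFactors = FALSE)
      for (term in c("het", "hom_rare")) {
        i <- match(term, tab$term)
        row[[paste0("or_", term)]] <- if (is.na(i)) NA_real_ else tab$or[i]
        row[[paste0("ci_lower_", term)]] <- if (is.na(i)) NA_real_ else tab$ci_lower[i]
        row[[paste0("ci_upper_", term)]] <- if (is.na(i)) NA_real_ else tab$ci_upper[i]
      }
      row
    }))
  }
  .log_stage(v, "stage 3: ", length(sig_snps), " SNPs carried to risk models")

  keep_cols <- c("snp_id", "mirna_name", "p_raw", "q_fdr", "analysis")
  summary <- summarize_significance(rbind(stage1[keep_cols], stage2[keep_cols]),
                                    n_pairs = nrow(tested),
                                    alpha = config$alpha)

  # ---- write outputs
  paths <- list(
    normalization_report = file.path(config$out_dir, "normalization_report.tsv"),
    cascade_report = file.path(config$out_dir, "cascade_report.tsv"),
    nontumor_trend = file.path(config$out_dir, "nontumor_trend.tsv"),
    differential_trend = file.path(config$out_dir, "differential_trend.tsv"),
    paired_diff = file.path(config$out_dir, "paired_diff.tsv"),
    risk = file.path(config$out_dir, "risk.tsv"),
    manifest = file.path(config$out_dir, "manifest.yaml"))
  hash <- .config_hash(config)
  wr <- function(df, path) {
    con <- file(path, "w")
    writeLines(paste0("# mireqtl config_hash=", hash, " seed=", config$seed), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wr(normalization_report(expr_n, norm_n), paths$normalization_report)
  wr(as.data.frame(casc$report), paths$cascade_report)
  wr(stage1, paths$nontumor_trend)
  wr(stage2, paths$differential_trend)
  wr(paired, paths$paired_diff)
  if (!is.null(risk)) wr(risk, paths$risk) else paths$risk <- NULL
  manifest <- list(config_hash = hash, seed = config$seed,
                   n_pairs_tested = nrow(tested),
                   cascade_counts = casc$report$n_out,
                   outputs = lapply(paths[setdiff(names(paths), "manifest")],
                                    basename),
                   summary = summary[c("n_significant_raw", "n_unique_snps_raw",
                                       "pct_snps_significant")])
  yaml::write_yaml(manifest, paths$manifest)

  out <- list(cascade = casc$report, nontumor = stage1, differential = stage2,
              paired = paired, risk = risk, summary = summary,
              manifest = manifest, paths = paths)
  class(out) <- "pipeline_run"
  out
}

# Stage-1/2 workhorse: per tested pair, trend fit + bootstrap p +
# genotype-stratified descriptives. Means are reported on `mean_mat`'s
# scale (normalized signal, or tumor-minus-normal signal difference);
# percent-zero columns come from each matrix in `zero_mats`.
.trend_table <- function(tested, y_mat, mean_mat, zero_mats, geno, X, spec) {
  ids <- colnames(y_mat)
  do.call(rbind, lapply(seq_len(nrow(tested)), function(i) {
    m <- tested$mirna_name[i]; s <- tested$snp_id[i]
    g <- geno[s, ids]
    res <- bootstrap_trend_p(y_mat[m, ], g, X, spec)
    strat <- genotype_strata_summary(mean_mat[m, ], g)
    row <- data.frame(snp_id = s, mirna_name = m, beta = res$beta,
                      p_raw = res$p, boot_sd = res$boot_sd,
                      stringsAsFactors = FALSE)
    for (k in 0:2) {
      row[[paste0("n_", k)]] <- strat$n[k + 1]
      row[[paste0("mean_", k)]] <- strat$mean_signal[k + 1]
      for (zn in names(zero_mats)) {
        v <- zero_mats[[zn]][m, !is.na(g) & g == k]
        row[[paste0("pct_", zn, "_", k)]] <-
          if (length(v)) 100 * mean(v == 0) else NA_real_
      }
    }
    row
  }))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("mireqtl pipeline run (seed ", x$manifest$seed, ", config ",
      substr(x$manifest$config_hash, 1, 8), ")\n", sep = "")
  print(x$cascade)
  s <- x$summary
  cat(sprintf("  significant pairs at alpha: %d raw (%d non-tumor, %d differential), %d after FDR\n",
              s$n_significant_raw, s$n_nontumor_raw, s$n_differential_raw,
              s$n_significant_fdr))
  cat(sprintf("  unique significant SNPs: %d of %d tested pairs (%.1f%%)\n",
              s$n_unique_snps_raw, s$n_pairs, s$pct_snps_significant))
  invisible(x)
}

#' Summarize significance over the association results
#'
#' Counts pairs significant at `alpha` before and after FDR adjustment,
#' per analysis and as a union, and reports the percentage of unique
#' significant SNPs among all tested pairs.
#'
#' @param results data.frame with columns `snp_id`, `p_raw`, `analysis`
#'   and optionally `q_fdr` — typically `rbind` of the stage-1 and
#'   stage-2 tables.
#' @param n_pairs number of pairs tested (the FDR family size).
#' @param alpha significance threshold (default 0.05).
#' @return list with `n_pairs`, per-analysis raw counts, union counts
#'   raw and FDR-adjusted, `n_unique_snps_raw`, and
#'   `pct_snps_significant` (= 100 * unique significant SNPs / tested
#'   pairs).
#' @export
summarize_significance <- function(results, n_pairs, alpha = 0.05) {
  stopifnot(is.data.frame(results), nrow(results) > 0,
            all(c("snp_id", "p_raw", "analysis") %in% names(results)))
  sig <- results$p_raw < alpha
  by_analysis <- tapply(sig, results$analysis, sum)
  n_fdr <- if ("q_fdr" %in% names(results)) sum(results$q_fdr < alpha) else NA_integer_
  uniq <- unique(results$snp_id[sig])
  list(n_pairs = n_pairs,
       n_nontumor_raw = unname(by_analysis["nontumor"] %||% 0L),
       n_differential_raw = unname(by_analysis["differential"] %||% 0L),
       n_significant_raw = sum(sig),
       n_significant_fdr = n_fdr,
       n_unique_snps_raw = length(uniq),
       pct_snps_significant = 100 * length(uniq) / n_pairs)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
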
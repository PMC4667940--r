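#' @title Tabular input/output
#' @description Readers and writers for the pipeline's file dialects:
#'   expression TSV (miRNA rows by sample columns), genotype TSV (SNP rows
#'   by individual columns, additive codes 0/1/2 with NA for missing), a
#'   minimal VCF dialect (GT subfield only), covariate TSV, and the
#'   curated pair-list CSV. All readers reject ragged tables and
#'   duplicated identifiers; all writers emit tables their readers accept.
#' @name io
NULL

.check_ids <- function(ids, what, path) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("missing ", what, " identifier in ", path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicated ", what, " identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
}

.read_tsv_matrix <- function(path, id_what, value_what) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file ", path, " has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged table in ", path, ": row ", bad, " has ", widths[bad],
         " fields, header has ", widths[1L])
  }
  header <- fields[[1L]]
  samples <- header[-1L]
  .check_ids(samples, "sample", path)
  body <- fields[-1L]
  ids <- vapply(body, `[[`, character(1), 1L)
  .check_ids(ids, id_what, path)
  vals <- t(vapply(body, function(f) {
    v <- f[-1L]
    v[v %in% c("NA", "")] <- NA
    suppressWarnings(as.numeric(v))
  }, numeric(length(samples))))
  if (length(samples) == 1L) vals <- matrix(vals, ncol = 1L)
  for (i in seq_along(body)) {
    raw <- body[[i]][-1L]
    bad <- which(is.na(vals[i, ]) & !(raw %in% c("NA", "")))
    if (length(bad)) {
      stop("non-numeric ", value_what, " in ", path, ", row ", ids[i],
           ", column ", samples[bad[1L]], ": '", raw[bad[1L]], "'")
    }
  }
  dimnames(vals) <- list(ids, samples)
  vals
}

#' Read an expression signal matrix
#'
#' TSV dialect: first column miRNA name, remaining columns one per
#' sample; values are non-negative signal intensities.
#'
#' @param path file path.
#' @return numeric matrix, miRNAs in rows, samples in columns.
#' @export
read_expression <- function(path) {
  m <- .read_tsv_matrix(path, "miRNA", "signal")
  if (anyNA(m)) stop("missing signal values in ", path)
  if (any(m < 0)) stop("negative signal values in ", path)
  m
}

#' Write an expression signal matrix
#'
#' @param matrix numeric matrix with miRNA rownames and sample colnames.
#' @param path output file path.
#' @export
write_expression <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  df <- data.frame(mirna = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix (TSV dialect)
#'
#' SNP rows by individual columns; additive codes 0 (common homozygote),
#' 1 (heterozygote), 2 (rare homozygote); `NA` for missing calls.
#' Missing entries are preserved as `NA`, never coerced to 0.
#'
#' @param path file path.
#' @return integer matrix, SNPs in rows, individuals in columns.
#' @export
read_genotypes <- function(path) {
  m <- .read_tsv_matrix(path, "SNP", "genotype code")
  ok <- is.na(m) | m %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("invalid genotype code in ", path, ", row ", rownames(m)[bad[1L]],
         ", column ", colnames(m)[bad[2L]], " (expected 0/1/2/NA)")
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a genotype matrix
#' @param matrix integer matrix of 0/1/2/NA codes with dimnames.
#' @param path output file path.
#' @export
write_genotypes <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  df <- data.frame(snp_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a minimal VCF
#'
#' Only the GT subfield is interpreted: the additive code is the count
#' of non-reference alleles, so `0/0` maps to 0, `0/1` to 1 and `1/1`
#' to 2; phased separators (`|`) are accepted; `./.` maps to `NA`.
#' SNPs are keyed by the ID column.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return integer matrix, SNPs in rows, individuals in columns.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  codes <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  })
  storage.mode(codes) <- "integer"
  codes
}

#' Read per-individual covariates
#'
#' TSV with a `sample_id` column plus covariates; expected columns where
#' present are `age` (years), `sex`, `center`, `site`
#' (proximal/distal), and `status` (0 control / 1 case).
#'
#' @param path file path.
#' @return data.frame with one row per individual.
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("covariate file ", path, " lacks a sample_id column")
  .check_ids(df$sample_id, "sample", path)
  df
}

#' Write per-individual covariates
#' @param covariates data.frame with a `sample_id` column.
#' @param path output file path.
#' @export
write_covariates <- function(covariates, path) {
  stopifnot(is.data.frame(covariates), "sample_id" %in% names(covariates))
  utils::write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a curated SNP-miRNA pair list
#'
#' CSV with columns `snp_id`, `gene_labels`, `mirna_name`.
#'
#' @param path file path.
#' @return data.frame of pairs.
#' @export
read_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "gene_labels", "mirna_name")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pair file ", path, " lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' Write a SNP-miRNA pair list
#' @param pairs data.frame with `snp_id`, `gene_labels`, `mirna_name`.
#' @param path output file path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
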
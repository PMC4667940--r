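#' Parse a mature miRNA name into its structural components
#'
#' Mature miRNA names follow the miRBase convention: a three-letter
#' organism prefix (`hsa` for human), the class token (`miR` or `let`),
#' a family number, an optional lowercase letter suffix marking closely
#' related sequences (`let-7a`), an optional dash-number marking distinct
#' genomic loci coding the same mature sequence (`miR-30c-2`), and an
#' optional arm designator (`-5p`, `-3p`, or a trailing `*` for the minor
#' product of a precursor).
#'
#' @param text character vector of miRNA names.
#' @return A data.frame of class `mirna_name` with one row per input and
#'   columns `raw`, `prefix`, `class`, `number`, `letter`, `locus`, `arm`
#'   (one of `"5p"`, `"3p"`, `"star"`, `"none"`), `family` (class token +
#'   number, e.g. `"miR-143"`), and `valid`. Unparseable tokens are
#'   flagged `valid = FALSE` rather than raising an error, so malformed
#'   records in bulk input can be reported downstream.
#' @examples
#' parse_mirna_name(c("hsa-miR-143-5p", "hsa-let-7a-3p", "let-7"))
#' @export
parse_mirna_name <- function(text) {
  stopifnot(is.character(text))
  if (any(!nzchar(trimws(text)))) {
    stop("empty miRNA name token")
  }
  pat <- "^(?:([A-Za-z]{3})-)?(miR|mir|let|lin)-?([0-9]+)([a-z]+)?(?:-([0-9]+))?(?:-(5p|3p))?(\\*)?$"
  m <- regmatches(text, regexec(pat, text))
  one <- function(raw, mm) {
    if (length(mm) == 0L) {
      return(data.frame(raw = raw, prefix = NA_character_, class = NA_character_,
                        number = NA_integer_, letter = NA_character_,
                        locus = NA_integer_, arm = NA_character_,
                        family = NA_character_, valid = FALSE,
                        stringsAsFactors = FALSE))
    }
    prefix <- if (nzchar(mm[2])) mm[2] else NA_character_
    cls <- mm[3]
    number <- as.integer(mm[4])
    letter <- if (nzchar(mm[5])) mm[5] else NA_character_
    locus <- if (nzchar(mm[6])) as.integer(mm[6]) else NA_integer_
    arm <- if (nzchar(mm[7])) mm[7] else if (nzchar(mm[8])) "star" else "none"
    data.frame(raw = raw, prefix = prefix, class = cls, number = number,
               letter = letter, locus = locus, arm = arm,
               family = paste0(cls, "-", number), valid = TRUE,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(one, text, m))
  rownames(out) <- NULL
  class(out) <- c("mirna_name", "data.frame")
  out
}

#' Format parsed miRNA names back to text
#'
#' Inverse of [parse_mirna_name()]: valid parses round-trip unchanged.
#'
#' @param x a `mirna_name` data.frame.
#' @return character vector of names; invalid rows return their raw text.
#' @export
format_mirna_name <- function(x) {
  stopifnot(inherits(x, "mirna_name"))
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    if (!x$valid[i]) {
      out[i] <- x$raw[i]
      next
    }
    s <- paste0(x$class[i], "-", x$number[i])
    if (!is.na(x$prefix[i])) s <- paste0(x$prefix[i], "-", s)
    if (!is.na(x$letter[i])) s <- paste0(s, x$letter[i])
    if (!is.na(x$locus[i])) s <- paste0(s, "-", x$locus[i])
    if (x$arm[i] %in% c("5p", "3p")) s <- paste0(s, "-", x$arm[i])
    if (x$arm[i] == "star") s <- paste0(s, "*")
    out[i] <- s
  }
  out
}

#' Expand a curated SNP-miRNA pair list against a platform catalog
#'
#' Literature-curated pair lists often name miRNAs generically
#' (`let-7`), whereas expression platforms measure specific mature
#' sequences (`let-7a-3p`, `let-7a-5p`, ...). Each pair is expanded to
#' every catalog name it is compatible with: the family token (class +
#' number) must match; a letter variant in the input restricts matches
#' to that letter; a locus number or an arm in the input must match
#' exactly. Organism prefixes are compared case-insensitively, and a
#' catalog prefix is allowed to satisfy an input that omits one.
#' Already-specific names therefore map to themselves.
#'
#' @param pairs data.frame with at least columns `snp_id` and
#'   `mirna_name`; other columns (e.g. `gene_labels`) are carried along.
#' @param catalog character vector of platform miRNA names (the
#'   measurable mature sequences).
#' @return data.frame with one row per expanded pair: the original
#'   columns, `mirna_name` replaced by the matched catalog name,
#'   `source_name` recording the pre-expansion name, and `matched`
#'   (FALSE for pairs with no catalog match, which are retained so the
#'   expression-stage filter can drop and count them). Duplicate
#'   (SNP, miRNA) records are removed.
#' @examples
#' pairs <- data.frame(snp_id = "rs1", mirna_name = "let-7")
#' expand_pairs(pairs, c("hsa-let-7a-3p", "hsa-let-7a-5p", "hsa-let-7b-3p"))
#' @export
expand_pairs <- function(pairs, catalog) {
  stopifnot(is.data.frame(pairs), all(c("snp_id", "mirna_name") %in% names(pairs)))
  if (length(catalog) == 0L) stop("platform catalog is empty")
  cat_parsed <- parse_mirna_name(catalog)
  if (any(!cat_parsed$valid)) {
    stop("unparseable catalog names: ",
         paste(cat_parsed$raw[!cat_parsed$valid], collapse = ", "))
  }
  in_parsed <- parse_mirna_name(pairs$mirna_name)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p <- in_parsed[i, ]
    exact <- which(tolower(catalog) == tolower(pairs$mirna_name[i]))
    if (length(exact)) {
      # already-specific name present on the platform: maps to itself only
      hit <- exact[1L]
    } else if (!p$valid) {
      hit <- integer(0)
    } else {
      ok <- tolower(cat_parsed$family) == tolower(p$family)
      if (!is.na(p$letter)) ok <- ok & !is.na(cat_parsed$letter) & cat_parsed$letter == p$letter
      if (!is.na(p$locus)) ok <- ok & !is.na(cat_parsed$locus) & cat_parsed$locus == p$locus
      if (p$arm != "none") ok <- ok & cat_parsed$arm == p$arm
      if (!is.na(p$prefix)) ok <- ok & !is.na(cat_parsed$prefix) &
          tolower(cat_parsed$prefix) == tolower(p$prefix)
      hit <- which(ok)
    }
    base <- pairs[i, , drop = FALSE]
    if (length(hit) == 0L) {
      r <- base
      r$source_name <- base$mirna_name
      r$matched <- FALSE
      rows[[i]] <- r
    } else {
      r <- base[rep(1L, length(hit)), , drop = FALSE]
      r$mirna_name <- catalog[hit]
      r$source_name <- base$mirna_name
      r$matched <- TRUE
      rows[[i]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[!duplicated(out[, c("snp_id", "mirna_name")]), , drop = FALSE]
}
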
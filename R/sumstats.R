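#' @keywords internal
"_PACKAGE"

VALID_ALLELES <- c("A", "C", "G", "T")

SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

# Fixed column order for serialized harmonized instrument tables.
HARMONIZED_COLS <- c("snp_id", "effect_allele", "other_allele", "eaf_exposure",
                     "beta_exposure", "se_exposure", "pvalue_exposure",
                     "beta_outcome", "se_outcome", "pvalue_outcome")

mr_log <- function(...) {
  if (isTRUE(getOption("mrkit.verbose", FALSE))) message(...)
  invisible(NULL)
}

#' Column-name dialect for a summary-statistics file
#'
#' Maps the canonical field names used throughout the package onto the header
#' names of a particular source file. The default is the generic
#' SNP/CHR/BP/EA/OA/EAF/BETA/SE/P/N layout; consortium files with different
#' headers are adapted by overriding individual entries. `eaf`, `pvalue` and
#' `n` may be set to `NA` when the source lacks the column; a missing p-value
#' column is reconstructed from beta/SE via [pvalue_from_z()].
#'
#' @param snp_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pvalue,n
#'   Header names in the source file.
#' @return Named character vector of class `sumstats_dialect`.
#' @export
#' @examples
#' sumstats_dialect(pvalue = "P_BOLT", n = NA)
sumstats_dialect <- function(snp_id = "SNP", chrom = "CHR", pos = "BP",
                             effect_allele = "EA", other_allele = "OA",
                             eaf = "EAF", beta = "BETA", se = "SE",
                             pvalue = "P", n = "N") {
  d <- c(snp_id = snp_id, chrom = chrom, pos = pos,
         effect_allele = effect_allele, other_allele = other_allele,
         eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n)
  class(d) <- "sumstats_dialect"
  d
}

#' Construct a validated summary-statistics table
#'
#' Validates per-record invariants (distinct A/C/G/T alleles, positive SE,
#' p-value in (0,1], allele frequency in \[0,1\]), drops offending rows with a
#' reason, floors p-values of exactly zero at the smallest positive double,
#' and deduplicates shared rsIDs keeping the smallest p-value. The drop log is
#' attached as attribute `"dropped"` (a data.frame of snp_id and reason).
#'
#' @param records data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`
#'   (missing `eaf`/`n`/`pvalue` columns are added as `NA`; a missing p-value
#'   is computed from beta/SE).
#' @param trait_label Character label for the trait.
#' @param trait_type `"quantitative"` (effects in SD units) or `"binary"`
#'   (log-odds scale).
#' @return A `sumstats` data.frame (canonical columns, attributes
#'   `trait_label`, `trait_type`, `dropped`).
#' @export
sumstats_table <- function(records, trait_label = "trait",
                           trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  for (col in c("eaf", "n", "pvalue")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  missing_cols <- setdiff(setdiff(SUMSTATS_COLS, c("eaf", "n")), names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[SUMSTATS_COLS]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  records$n <- as.integer(records$n)

  # Reconstruct absent p-values from the z statistic before validating.
  needs_p <- is.na(records$pvalue) & !is.na(records$beta) &
    !is.na(records$se) & records$se > 0
  if (any(needs_p)) {
    records$pvalue[needs_p] <-
      pvalue_from_z(records$beta[needs_p], records$se[needs_p])
  }
  zero_p <- !is.na(records$pvalue) & records$pvalue == 0
  if (any(zero_p)) {
    records$pvalue[zero_p] <- .Machine$double.xmin
    mr_log(sum(zero_p), " zero p-value(s) floored at the smallest positive double")
  }

  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(is.na(records$snp_id) | records$snp_id == "", "missing snp_id")
  flag(!records$effect_allele %in% VALID_ALLELES |
         !records$other_allele %in% VALID_ALLELES, "invalid allele")
  flag(records$effect_allele == records$other_allele, "identical alleles")
  flag(is.na(records$beta), "missing beta")
  flag(is.na(records$se) | records$se <= 0, "nonpositive SE")
  flag(is.na(records$pvalue) | records$pvalue <= 0 | records$pvalue > 1,
       "p-value outside (0,1]")
  flag(!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1),
       "eaf outside [0,1]")
  flag(is.na(records$pos), "missing position")

  dropped <- data.frame(snp_id = records$snp_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  kept <- records[is.na(reason), , drop = FALSE]

  # Duplicate rsIDs: keep the row with the smallest p-value.
  if (anyDuplicated(kept$snp_id)) {
    ord <- order(kept$pvalue, kept$chrom, kept$pos)
    first <- !duplicated(kept$snp_id[ord])
    dup_ids <- kept$snp_id[ord][!first]
    dropped <- rbind(dropped, data.frame(
      snp_id = dup_ids, reason = rep("duplicate snp_id (larger p)", length(dup_ids)),
      stringsAsFactors = FALSE))
    keep_idx <- sort(ord[first])
    kept <- kept[keep_idx, , drop = FALSE]
  }
  rownames(kept) <- NULL
  if (nrow(dropped) > 0) {
    mr_log("dropped ", nrow(dropped), " row(s): ",
           paste(sprintf("%s (%s)", dropped$snp_id, dropped$reason), collapse = "; "))
  }
  structure(kept, trait_label = trait_label, trait_type = trait_type,
            dropped = dropped, class = c("sumstats", "data.frame"))
}

# Row subset that preserves sumstats attributes.
restrict_sumstats <- function(tbl, keep, dropped_reason = NULL) {
  out <- as.data.frame(tbl)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_label = attr(tbl, "trait_label"),
            trait_type = attr(tbl, "trait_type"),
            dropped = attr(tbl, "dropped"),
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s (%s), %d SNP(s)\n",
              attr(x, "trait_label"), attr(x, "trait_type"), nrow(x)))
  print(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab-separated file with a header row (gzip handled transparently),
#' renames columns through `dialect`, and validates every row via
#' [sumstats_table()]; rows failing validation are dropped with a logged
#' reason. `"NA"` denotes missing values.
#'
#' @param path File path (plain or `.gz`).
#' @param dialect A [sumstats_dialect()] mapping canonical fields to the
#'   file's header names.
#' @param trait_label,trait_type Passed to [sumstats_table()].
#' @return A `sumstats` table.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_label = basename(path),
                          trait_type = c("quantitative", "binary")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = "NA", colClasses = "character",
                           check.names = FALSE, quote = "", comment.char = "")
  optional <- c("eaf", "n", "pvalue")
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in SUMSTATS_COLS) {
    src <- unname(dialect[[field]])
    if (is.na(src) || !nzchar(src)) {
      if (field %in% optional) { out[[field]] <- NA; next }
      stop("dialect maps no column for mandatory field '", field, "'")
    }
    if (!src %in% names(raw)) {
      if (field %in% optional) { out[[field]] <- NA; next }
      stop("missing mandatory column '", src, "' (field '", field,
           "') in ", path)
    }
    out[[field]] <- raw[[src]]
  }
  tbl <- sumstats_table(out, trait_label = trait_label,
                        trait_type = match.arg(trait_type))
  if (nrow(tbl) == 0) stop("no valid rows in ", path)
  tbl
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a summary-statistics table
#'
#' Serializes with the generic SNP/CHR/BP/EA/OA/EAF/BETA/SE/P/N header,
#' tab-separated, `"NA"` for missing, floating-point values at full
#' round-trip precision, so `read_sumstats(write_sumstats(t))` reproduces `t`
#' field for field.
#'
#' @param table A `sumstats` table.
#' @param path Output path (`.gz` suffix writes gzip).
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  df <- as.data.frame(table)
  out <- data.frame(SNP = df$snp_id, CHR = df$chrom, BP = df$pos,
                    EA = df$effect_allele, OA = df$other_allele,
                    EAF = fmt_num(df$eaf), BETA = fmt_num(df$beta),
                    SE = fmt_num(df$se), P = fmt_num(df$pvalue),
                    N = ifelse(is.na(df$n), "NA", as.character(df$n)),
                    stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Two-sided normal p-value from an effect estimate and its standard error
#'
#' Returns `2 * (1 - pnorm(|beta/se|))`, computed on the log scale for
#' numerical accuracy in the far tail; symmetric in the sign of `beta`.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return p-value(s) in (0, 1].
#' @export
#' @examples
#' pvalue_from_z(1.959964, 1) # ~0.05
pvalue_from_z <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) stop("se must be positive")
  p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)
}

#' Write a harmonized instrument table
#'
#' Fixed column order: snp_id, effect_allele, other_allele, eaf_exposure,
#' beta_exposure, se_exposure, pvalue_exposure, beta_outcome, se_outcome,
#' pvalue_outcome. Tab-separated, full float precision.
#'
#' @param harmonized data.frame of harmonized instruments (see [harmonize()]).
#' @param path Output path.
#' @export
write_harmonized <- function(harmonized, path) {
  stopifnot(all(HARMONIZED_COLS %in% names(harmonized)))
  df <- harmonized[HARMONIZED_COLS]
  for (col in setdiff(HARMONIZED_COLS, c("snp_id", "effect_allele", "other_allele"))) {
    df[[col]] <- fmt_num(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a harmonized instrument table written by [write_harmonized()]
#' @param path File path.
#' @return data.frame with the fixed harmonized column layout.
#' @export
read_harmonized <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(HARMONIZED_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing harmonized column(s): ", paste(missing_cols, collapse = ", "))
  }
  df[HARMONIZED_COLS]
}
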
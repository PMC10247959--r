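#' Pairwise LD (r-squared) matrix for a set of SNPs
#'
#' Container used by [ld_clump()]: SNP identifiers with genomic positions and
#' a symmetric r-squared matrix with unit diagonal.
#'
#' @param snp_ids Character vector of SNP identifiers (unique).
#' @param chrom Chromosome label per SNP.
#' @param pos 1-based base-pair position per SNP.
#' @param r2 Square symmetric matrix of r-squared values in \[0,1\], unit
#'   diagonal, rows/columns ordered as `snp_ids`.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(snp_ids, chrom, pos, r2) {
  snp_ids <- as.character(snp_ids)
  stopifnot(!anyDuplicated(snp_ids),
            length(chrom) == length(snp_ids),
            length(pos) == length(snp_ids),
            is.matrix(r2),
            nrow(r2) == length(snp_ids), ncol(r2) == length(snp_ids))
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0,1]")
  if (max(abs(r2 - t(r2))) > 1e-12) stop("r2 matrix must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-12)) stop("r2 diagonal must be 1")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, chrom = as.character(chrom),
                 pos = as.integer(pos), r2 = r2),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d SNP(s) on chromosome(s) %s\n",
              length(x$snp_ids), paste(unique(x$chrom), collapse = ",")))
  invisible(x)
}

#' Write / read an LD matrix as a SNP-info TSV plus a square matrix TSV
#'
#' `info_path` holds snp_id, chrom, pos (one row per SNP); `matrix_path`
#' holds the square r-squared matrix with snp_id row and column headers in
#' matching order.
#'
#' @param ld An `ld_matrix`.
#' @param info_path,matrix_path Output/input paths.
#' @return `read_ld_matrix` returns an `ld_matrix`.
#' @export
write_ld_matrix <- function(ld, info_path, matrix_path) {
  stopifnot(inherits(ld, "ld_matrix"))
  utils::write.table(
    data.frame(snp_id = ld$snp_ids, chrom = ld$chrom, pos = ld$pos),
    info_path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- ld$r2
  utils::write.table(
    cbind(data.frame(snp_id = ld$snp_ids), as.data.frame(m)),
    matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(info_path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(info_path, matrix_path) {
  info <- utils::read.table(info_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  m <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(m$snp_id)
  m <- as.matrix(m[setdiff(names(m), "snp_id")])
  if (!identical(ids, info$snp_id) || !identical(colnames(m), info$snp_id)) {
    stop("SNP order mismatch between info and matrix files")
  }
  ld_matrix(info$snp_id, info$chrom, info$pos, m)
}

#' Instrument-selection thresholds
#'
#' Defaults follow common practice for a large single-trait GWAS exposure:
#' genome-wide significance tightened to 5e-9, clumping at r-squared < 0.001
#' within 1,000 kb, F > 10, and exclusion of instruments with outcome
#' association p < 1e-5. For small exposure GWASs (e.g. flow-cytometry
#' lymphocyte panels) use `selection_config(p_threshold = 5e-8,
#' clump_r2 = 0.1, clump_window_kb = 500)`.
#'
#' @param p_threshold Exposure significance threshold (strict `<`).
#' @param clump_r2 LD pruning threshold; pairs at or above it are clumped.
#' @param clump_window_kb Clumping window, inclusive center-to-center kb.
#' @param f_min Minimum instrument F statistic (strict `>`).
#' @param outcome_p_exclude Outcome-association exclusion threshold; `0`
#'   disables the screen (the strict `p < 0` test removes nothing).
#' @return List of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 5e-9, clump_r2 = 0.001,
                             clump_window_kb = 1000, f_min = 10,
                             outcome_p_exclude = 1e-5) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 > 0, clump_r2 < 1,
            clump_window_kb > 0, f_min > 0,
            outcome_p_exclude >= 0, outcome_p_exclude < 1)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = as.integer(clump_window_kb),
                 f_min = f_min, outcome_p_exclude = outcome_p_exclude),
            class = "selection_config")
}

#' Keep records passing a significance threshold
#'
#' @param table A `sumstats` table.
#' @param p_threshold Strict upper bound on the p-value, in (0,1).
#' @return The filtered table, input order preserved.
#' @export
filter_significant <- function(table, p_threshold) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  keep <- table$pvalue < p_threshold
  mr_log("significance filter p < ", p_threshold, ": kept ", sum(keep),
         " of ", nrow(table))
  restrict_sumstats(table, keep)
}

#' Per-SNP instrument-strength F statistic
#'
#' Single-SNP summary-statistics approximation `(beta/se)^2`; instruments
#' with F > 10 are conventionally considered strong.
#'
#' @param beta,se Effect estimate(s) and standard error(s) (se > 0).
#' @return Nonnegative F value(s).
#' @export
f_statistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

#' Keep strong instruments (F statistic above a floor)
#'
#' @param table A `sumstats` table.
#' @param f_min Strict lower bound on `f_statistic(beta, se)`.
#' @return The filtered table.
#' @export
filter_strong <- function(table, f_min = 10) {
  stopifnot(f_min > 0)
  if (nrow(table) == 0) return(table)
  keep <- f_statistic(table$beta, table$se) > f_min
  mr_log("F-statistic filter > ", f_min, ": kept ", sum(keep), " of ",
         nrow(table))
  restrict_sumstats(table, keep)
}

# Deterministic candidate ordering for clumping: p ascending, then
# (chrom, pos, snp_id) to break exact p ties identically across platforms.
clump_order <- function(tbl) {
  order(tbl$pvalue, tbl$chrom, tbl$pos, tbl$snp_id)
}

#' Greedy LD clumping to independent index SNPs
#'
#' Repeatedly takes the remaining record with the smallest p-value as an
#' index SNP and removes all remaining records on the same chromosome within
#' `window_kb` (inclusive, center-to-center) whose r-squared with the index
#' is at or above `r2_threshold`. Exact p-value ties are broken by
#' (chrom, pos, snp_id) ascending. Every clumped pair in the output is
#' therefore "independent": same-chromosome pairs within the window have
#' r-squared below the threshold.
#'
#' @param table A `sumstats` table; every SNP must be present in `ld`.
#' @param ld An [ld_matrix()] covering the table's SNPs.
#' @param r2_threshold Pruning threshold in (0,1); pairs with r2 >=
#'   threshold are clumped.
#' @param window_kb Window in kb within which LD is considered.
#' @return Index SNPs only, sorted by p-value ascending. The removal log
#'   (removed snp_id, responsible index snp_id) is attached as attribute
#'   `"clump_log"`.
#' @export
ld_clump <- function(table, ld, r2_threshold = 0.001, window_kb = 1000) {
  stopifnot(inherits(ld, "ld_matrix"), r2_threshold > 0, r2_threshold < 1,
            window_kb > 0)
  if (nrow(table) == 0) return(table)
  missing_snp <- setdiff(table$snp_id, ld$snp_ids)
  if (length(missing_snp) > 0) {
    stop("SNP(s) absent from LD matrix: ",
         paste(utils::head(missing_snp, 5), collapse = ", "))
  }
  df <- as.data.frame(table)
  idx <- clump_order(df)
  window_bp <- window_kb * 1000
  kept <- integer(0)
  removed_by <- character(0)
  removed_id <- character(0)
  remaining <- idx
  while (length(remaining) > 0) {
    i <- remaining[1]
    kept <- c(kept, i)
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      same_chr <- df$chrom[remaining] == df$chrom[i]
      in_window <- abs(df$pos[remaining] - df$pos[i]) <= window_bp
      r2 <- ld$r2[df$snp_id[i], df$snp_id[remaining]]
      clumped <- same_chr & in_window & (r2 >= r2_threshold)
      if (any(clumped)) {
        removed_id <- c(removed_id, df$snp_id[remaining[clumped]])
        removed_by <- c(removed_by, rep(df$snp_id[i], sum(clumped)))
        remaining <- remaining[!clumped]
      }
    }
  }
  mr_log("clumping r2 >= ", r2_threshold, " within ", window_kb,
         " kb: kept ", length(kept), " index SNP(s), removed ",
         length(removed_id))
  out <- restrict_sumstats(table, kept)
  attr(out, "clump_log") <- data.frame(removed = removed_id,
                                       index_snp = removed_by,
                                       stringsAsFactors = FALSE)
  out
}

#' Drop instruments with evidence of direct outcome association
#'
#' Removes any instrument whose record in the outcome table has
#' `pvalue < p_exclude` (potential direct/pleiotropic effect on the outcome).
#' Instruments absent from the outcome table are removed too, logged with
#' reason "not found in outcome" (no LD-proxy search is attempted).
#'
#' @param instruments,outcome `sumstats` tables.
#' @param p_exclude Strict exclusion threshold in (0,1).
#' @return Filtered instrument table; attribute `"outcome_drop_log"` records
#'   each removal and its reason.
#' @export
drop_outcome_associated <- function(instruments, outcome, p_exclude = 1e-5) {
  stopifnot(p_exclude >= 0, p_exclude < 1)
  m <- match(instruments$snp_id, outcome$snp_id)
  not_found <- is.na(m)
  assoc <- !not_found & outcome$pvalue[m] < p_exclude
  reason <- rep(NA_character_, nrow(instruments))
  reason[not_found] <- "not found in outcome"
  reason[assoc] <- "outcome-associated"
  drop_log <- data.frame(snp_id = instruments$snp_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  mr_log("outcome screen p < ", p_exclude, ": removed ", sum(assoc),
         " associated, ", sum(not_found), " not found in outcome")
  out <- restrict_sumstats(instruments, !(not_found | assoc))
  attr(out, "outcome_drop_log") <- drop_log
  out
}

#' Drop instruments on a user-supplied exclusion list
#'
#' Used for confounder-associated SNPs identified externally (e.g. by a
#' phenome-wide lookup against known risk factors). Unknown identifiers in
#' the list are ignored with a log note.
#'
#' @param instruments A `sumstats` table.
#' @param exclusion_ids Character vector of snp_ids to remove.
#' @param label Log label describing the list.
#' @return Filtered table.
#' @export
drop_listed <- function(instruments, exclusion_ids, label = "exclusion list") {
  exclusion_ids <- unique(as.character(exclusion_ids))
  hit <- instruments$snp_id %in% exclusion_ids
  unknown <- setdiff(exclusion_ids, instruments$snp_id)
  if (length(unknown) > 0) {
    mr_log(label, ": ", length(unknown), " listed id(s) not in table, ignored")
  }
  mr_log(label, ": removed ", sum(hit), " of ", nrow(instruments))
  restrict_sumstats(instruments, !hit)
}

#' Read a one-id-per-line SNP exclusion list
#' @param path Plain-text file, one snp_id per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of snp_ids.
#' @export
read_exclusion_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Select instruments from an exposure table
#'
#' Applies the full selection cascade: significance filter, greedy LD
#' clumping, F-statistic screen, and outcome-overlap exclusion.
#'
#' @param exposure,outcome `sumstats` tables.
#' @param ld An [ld_matrix()] covering the significant exposure SNPs.
#' @param config A [selection_config()].
#' @return Selected instrument table.
#' @export
select_instruments <- function(exposure, outcome, ld,
                               config = selection_config()) {
  tbl <- filter_significant(exposure, config$p_threshold)
  if (nrow(tbl) > 0) {
    tbl <- ld_clump(tbl, ld, config$clump_r2, config$clump_window_kb)
  }
  tbl <- filter_strong(tbl, config$f_min)
  drop_outcome_associated(tbl, outcome, config$outcome_p_exclude)
}
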
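ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is a SNP palindromic (strand-ambiguous)?
#'
#' A/T and C/G variants read identically on both strands, so their
#' orientation across studies cannot be resolved from allele letters alone.
#'
#' @param a1,a2 Allele characters over A/C/G/T (vectorized).
#' @return Logical: `TRUE` iff \{a1, a2\} is \{A,T\} or \{C,G\}.
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  if (any(!a1 %in% VALID_ALLELES) || any(!a2 %in% VALID_ALLELES)) {
    stop("alleles must be one of A, C, G, T")
  }
  unname(ALLELE_COMPLEMENT[a1] == a2)
}

#' Harmonization settings
#'
#' @param palindromic_eaf_low,palindromic_eaf_high Bounds of the symmetric
#'   allele-frequency ambiguity window: palindromic SNPs whose exposure EAF
#'   lies strictly inside (low, high) are dropped as unresolvable. Defaults
#'   (0.42, 0.58) drop palindromes with intermediate frequencies while
#'   retaining those whose frequency clearly identifies the strand.
#' @param drop_all_palindromic If `TRUE`, every palindromic SNP is dropped
#'   regardless of frequency (the conservative alternative).
#' @return List of class `harmonize_config`.
#' @export
harmonize_config <- function(palindromic_eaf_low = 0.42,
                             palindromic_eaf_high = 0.58,
                             drop_all_palindromic = FALSE) {
  stopifnot(palindromic_eaf_low > 0, palindromic_eaf_high < 1,
            palindromic_eaf_low < palindromic_eaf_high,
            abs(palindromic_eaf_low + palindromic_eaf_high - 1) < 1e-12)
  structure(list(palindromic_eaf_low = palindromic_eaf_low,
                 palindromic_eaf_high = palindromic_eaf_high,
                 drop_all_palindromic = isTRUE(drop_all_palindromic)),
            class = "harmonize_config")
}

#' Align exposure and outcome effects onto a shared effect allele
#'
#' For every exposure SNP found in the outcome table, decides how the two
#' studies' allele encodings relate and emits one harmonized instrument per
#' resolvable SNP:
#'
#' * same orientation (or strand-complement of it) — outcome effect copied;
#' * swapped alleles (or complement-swapped) — outcome beta negated and its
#'   EAF flipped;
#' * different allele sets — dropped as incompatible;
#' * palindromic with missing exposure EAF, or with exposure EAF strictly
#'   inside the ambiguity window — dropped as ambiguous. Palindromic SNPs
#'   outside the window are oriented by frequency agreement when the outcome
#'   EAF is present (disagreeing frequency quadrants imply opposite strand
#'   reference, so the outcome beta is negated), else kept as-is.
#'
#' The report accounts for every input SNP exactly once.
#'
#' @param exposure,outcome `sumstats` tables.
#' @param cfg A [harmonize_config()].
#' @return List with `instruments` (data.frame in the fixed harmonized
#'   column order) and `report` (counts `n_kept`, `n_flipped`,
#'   `n_dropped_palindromic`, `n_dropped_incompatible`, `n_dropped_missing`,
#'   plus a per-SNP `actions` data.frame of snp_id, action, reason).
#' @export
harmonize <- function(exposure, outcome, cfg = harmonize_config()) {
  stopifnot(inherits(cfg, "harmonize_config"))
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)
  m <- match(ex$snp_id, ou$snp_id)

  n <- nrow(ex)
  action <- character(n)
  reason <- rep(NA_character_, n)
  rows <- vector("list", n)

  for (i in seq_len(n)) {
    j <- m[i]
    if (is.na(j)) {
      action[i] <- "dropped"; reason[i] <- "missing from outcome"
      next
    }
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[j]; oa_y <- ou$other_allele[j]
    pal <- is_palindromic(ea_x, oa_x)

    if (pal) {
      # Letters cannot distinguish strand for palindromes; allele set must
      # still match (e.g. exposure A/T vs outcome C/G is incompatible).
      if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        action[i] <- "dropped"; reason[i] <- "incompatible alleles"
        next
      }
      if (cfg$drop_all_palindromic || is.na(ex$eaf[i]) ||
          (ex$eaf[i] > cfg$palindromic_eaf_low &&
           ex$eaf[i] < cfg$palindromic_eaf_high)) {
        action[i] <- "dropped"
        reason[i] <- if (cfg$drop_all_palindromic) "palindromic" else
          if (is.na(ex$eaf[i])) "palindromic, missing eaf" else
            "palindromic, intermediate eaf"
        next
      }
      # Orient by frequency: the exposure effect allele is the one whose
      # frequency sits on the same side of 0.5 in the outcome study.
      eaf_y <- ou$eaf[j]
      # Outcome file may list alleles swapped relative to exposure even
      # before strand is considered; put its beta/eaf on the exposure's
      # effect allele first, by letter.
      beta_y <- ou$beta[j]
      if (ea_y == oa_x && oa_y == ea_x && !is.na(eaf_y)) {
        beta_y <- -beta_y; eaf_y <- 1 - eaf_y
      } else if (ea_y == oa_x && oa_y == ea_x) {
        beta_y <- -beta_y
      }
      flipped <- FALSE
      if (!is.na(eaf_y) && (ex$eaf[i] - 0.5) * (eaf_y - 0.5) < 0) {
        beta_y <- -beta_y
        flipped <- TRUE
      }
      action[i] <- if (flipped || beta_y != ou$beta[j]) "flipped" else "kept"
      rows[[i]] <- data.frame(
        snp_id = ex$snp_id[i], effect_allele = ea_x, other_allele = oa_x,
        eaf_exposure = ex$eaf[i], beta_exposure = ex$beta[i],
        se_exposure = ex$se[i], pvalue_exposure = ex$pvalue[i],
        beta_outcome = beta_y, se_outcome = ou$se[j],
        pvalue_outcome = ou$pvalue[j], stringsAsFactors = FALSE)
      next
    }

    comp_ea_y <- unname(ALLELE_COMPLEMENT[ea_y])
    comp_oa_y <- unname(ALLELE_COMPLEMENT[oa_y])
    if ((ea_y == ea_x && oa_y == oa_x) ||
        (comp_ea_y == ea_x && comp_oa_y == oa_x)) {
      sign_flip <- FALSE
    } else if ((ea_y == oa_x && oa_y == ea_x) ||
               (comp_ea_y == oa_x && comp_oa_y == ea_x)) {
      sign_flip <- TRUE
    } else {
      action[i] <- "dropped"; reason[i] <- "incompatible alleles"
      next
    }
    action[i] <- if (sign_flip) "flipped" else "kept"
    rows[[i]] <- data.frame(
      snp_id = ex$snp_id[i], effect_allele = ea_x, other_allele = oa_x,
      eaf_exposure = ex$eaf[i], beta_exposure = ex$beta[i],
      se_exposure = ex$se[i], pvalue_exposure = ex$pvalue[i],
      beta_outcome = if (sign_flip) -ou$beta[j] else ou$beta[j],
      se_outcome = ou$se[j], pvalue_outcome = ou$pvalue[j],
      stringsAsFactors = FALSE)
  }

  keep <- !vapply(rows, is.null, logical(1))
  instruments <- if (any(keep)) do.call(rbind, rows[keep]) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(HARMONIZED_COLS))),
                    HARMONIZED_COLS)
  rownames(instruments) <- NULL
  actions <- data.frame(snp_id = ex$snp_id, action = action, reason = reason,
                        stringsAsFactors = FALSE)
  report <- list(
    n_kept = sum(action %in% c("kept", "flipped")),
    n_flipped = sum(action == "flipped"),
    n_dropped_palindromic = sum(!is.na(reason) & startsWith(reason, "palindromic")),
    n_dropped_incompatible = sum(!is.na(reason) & reason == "incompatible alleles"),
    n_dropped_missing = sum(!is.na(reason) & reason == "missing from outcome"),
    actions = actions)
  mr_log("harmonized: kept ", report$n_kept, " (", report$n_flipped,
         " flipped), dropped ", report$n_dropped_palindromic,
         " palindromic, ", report$n_dropped_incompatible, " incompatible, ",
         report$n_dropped_missing, " missing from outcome")
  list(instruments = instruments, report = report)
}

#' Write a harmonization action log as TSV
#' @param report The `report` element returned by [harmonize()].
#' @param path Output path.
#' @export
write_harmonize_report <- function(report, path) {
  utils::write.table(report$actions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
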
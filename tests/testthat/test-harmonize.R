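make_pair_tables <- function(ex_df, ou_df) {
  list(exposure = sumstats_table(ex_df, trait_label = "exposure"),
       outcome = sumstats_table(ou_df, trait_label = "outcome",
                                trait_type = "binary"))
}

base_row <- function(snp_id, ea, oa, eaf, beta, se = 0.01, pos = 1000L,
                     chrom = "1") {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = pvalue_from_z(beta, se),
             n = NA_integer_, stringsAsFactors = FALSE)
}

test_that("palindrome detection follows the A/T, C/G definition", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
  expect_error(is_palindromic("A", "N"), "alleles")
})

test_that("swapped outcome alleles flip the outcome beta onto the exposure effect allele", {
  p <- make_pair_tables(base_row("rs1", "A", "G", 0.3, 0.10),
                        base_row("rs1", "G", "A", 0.7, -0.05))
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(nrow(h$instruments), 1L)
  expect_equal(h$instruments$effect_allele, "A")
  expect_equal(h$instruments$beta_outcome, 0.05)
  expect_equal(h$report$n_flipped, 1L)

  # same orientation copies through untouched
  p2 <- make_pair_tables(base_row("rs1", "A", "G", 0.3, 0.10),
                         base_row("rs1", "A", "G", 0.3, -0.05))
  h2 <- harmonize(p2$exposure, p2$outcome)
  expect_equal(h2$instruments$beta_outcome, -0.05)
  expect_equal(h2$report$n_flipped, 0L)
})

test_that("strand-complement encodings align for non-palindromic SNPs", {
  # outcome reports the same variant on the other strand: A/G vs T/C
  p <- make_pair_tables(base_row("rs1", "A", "G", 0.3, 0.10),
                        base_row("rs1", "T", "C", 0.3, 0.04))
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$instruments$beta_outcome, 0.04)
  # complement AND swapped: C/T vs A/G
  p2 <- make_pair_tables(base_row("rs1", "G", "A", 0.3, 0.10),
                         base_row("rs1", "T", "C", 0.7, 0.04))
  h2 <- harmonize(p2$exposure, p2$outcome)
  expect_equal(h2$instruments$beta_outcome, -0.04)
})

test_that("incompatible allele sets are dropped with a reason", {
  p <- make_pair_tables(base_row("rs1", "A", "G", 0.3, 0.10),
                        base_row("rs1", "A", "C", 0.3, 0.04))
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(nrow(h$instruments), 0L)
  expect_equal(h$report$n_dropped_incompatible, 1L)
  expect_equal(h$report$actions$reason, "incompatible alleles")
})

test_that("palindromic SNPs inside the frequency ambiguity window are dropped, outside are oriented", {
  ex <- rbind(base_row("rs_mid", "A", "T", 0.50, 0.10),
              base_row("rs_edge", "A", "T", 0.45, 0.10, pos = 2000L),
              base_row("rs_low", "C", "G", 0.10, 0.10, pos = 3000L),
              base_row("rs_na", "A", "T", NA, 0.10, pos = 4000L))
  ou <- rbind(base_row("rs_mid", "A", "T", 0.50, 0.04),
              base_row("rs_edge", "A", "T", 0.45, 0.04, pos = 2000L),
              # outcome eaf on the other side of 0.5: opposite strand read
              base_row("rs_low", "C", "G", 0.92, 0.04, pos = 3000L),
              base_row("rs_na", "A", "T", 0.30, 0.04, pos = 4000L))
  p <- make_pair_tables(ex, ou)
  h <- harmonize(p$exposure, p$outcome)
  acts <- h$report$actions
  expect_equal(acts$action[acts$snp_id == "rs_mid"], "dropped")
  expect_equal(acts$reason[acts$snp_id == "rs_mid"],
               "palindromic, intermediate eaf")
  expect_equal(acts$reason[acts$snp_id == "rs_na"],
               "palindromic, missing eaf")
  # 0.45 is inside (0.42, 0.58): dropped too
  expect_equal(acts$action[acts$snp_id == "rs_edge"], "dropped")
  # clearly low-frequency palindrome with disagreeing outcome frequency:
  # orientation resolved by flipping the outcome effect
  expect_equal(h$instruments$snp_id, "rs_low")
  expect_equal(h$instruments$beta_outcome, -0.04)

  # conservative switch drops every palindrome
  h_all <- harmonize(p$exposure, p$outcome,
                     harmonize_config(drop_all_palindromic = TRUE))
  expect_equal(nrow(h_all$instruments), 0L)
  expect_equal(h_all$report$n_dropped_palindromic, 4L)
})

test_that("harmonization is a fixed point on already-aligned tables", {
  ex <- rbind(base_row("rs1", "A", "G", 0.3, 0.10),
              base_row("rs2", "C", "T", 0.6, -0.05, pos = 2000L),
              base_row("rs3", "C", "G", 0.10, 0.04, pos = 3000L))
  ou <- ex
  ou$beta <- c(0.05, -0.02, 0.01)
  ou$pvalue <- pvalue_from_z(ou$beta, ou$se)
  p <- make_pair_tables(ex, ou)
  h1 <- harmonize(p$exposure, p$outcome)
  expect_equal(h1$report$n_flipped, 0L)
  # rebuild tables from the harmonized output and harmonize again
  ex2 <- ex; ex2$beta <- h1$instruments$beta_exposure
  ou2 <- ou; ou2$beta <- h1$instruments$beta_outcome
  p2 <- make_pair_tables(ex2, ou2)
  h2 <- harmonize(p2$exposure, p2$outcome)
  expect_equal(h2$instruments, h1$instruments)
})

test_that("swapping outcome alleles while negating betas and flipping eaf changes nothing", {
  set.seed(31)
  n <- 20
  tbl <- make_sumstats(n, seed = 31)
  outcome <- as.data.frame(tbl)
  outcome$beta <- rnorm(n, 0, 0.02)
  outcome$pvalue <- pvalue_from_z(outcome$beta, outcome$se)
  p <- make_pair_tables(as.data.frame(tbl), outcome)
  h_ref <- harmonize(p$exposure, p$outcome)

  flipped <- outcome
  flipped$effect_allele <- outcome$other_allele
  flipped$other_allele <- outcome$effect_allele
  flipped$beta <- -outcome$beta
  flipped$eaf <- 1 - outcome$eaf
  p_flip <- make_pair_tables(as.data.frame(tbl), flipped)
  h_flip <- harmonize(p_flip$exposure, p_flip$outcome)
  expect_equal(h_flip$instruments, h_ref$instruments)

  # downstream estimates are identical too
  if (nrow(h_ref$instruments) >= 3) {
    expect_equal(ivw(h_flip$instruments)$estimate$beta,
                 ivw(h_ref$instruments)$estimate$beta)
  }
})

test_that("the action log accounts for every input SNP exactly once and counts sum", {
  ex <- rbind(base_row("rs1", "A", "G", 0.3, 0.10),
              base_row("rs2", "A", "T", 0.50, 0.05, pos = 2000L),
              base_row("rs3", "A", "C", 0.2, 0.02, pos = 3000L),
              base_row("rs4", "C", "T", 0.6, 0.03, pos = 4000L))
  ou <- rbind(base_row("rs1", "G", "A", 0.7, 0.04),
              base_row("rs2", "A", "T", 0.50, 0.01, pos = 2000L),
              base_row("rs3", "A", "G", 0.2, 0.01, pos = 3000L))
  p <- make_pair_tables(ex, ou)
  h <- harmonize(p$exposure, p$outcome)
  r <- h$report
  expect_setequal(r$actions$snp_id, ex$snp_id)
  expect_equal(anyDuplicated(r$actions$snp_id), 0L)
  expect_equal(r$n_kept + r$n_dropped_palindromic +
                 r$n_dropped_incompatible + r$n_dropped_missing, nrow(ex))
  expect_equal(r$n_kept, 1L)       # rs1 (flipped)
  expect_equal(r$n_flipped, 1L)
  expect_equal(r$n_dropped_palindromic, 1L)  # rs2
  expect_equal(r$n_dropped_incompatible, 1L) # rs3
  expect_equal(r$n_dropped_missing, 1L)      # rs4

  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonize_report(h$report, path)
  expect_equal(nrow(read.delim(path)), 4L)
})
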
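make_pair_tables <- function(ea_x, oa_x, ea_y, oa_y, eaf_x = 0.25,
                             eaf_y = 0.3, beta_y = 0.03) {
  ex <- data.frame(snp_id = "rs1", chrom = "1", pos = 1000,
                   effect_allele = ea_x, other_allele = oa_x,
                   eaf = eaf_x, beta = 0.1, se = 0.01, pval = 1e-9,
                   n = 50000, stringsAsFactors = FALSE)
  ou <- ex
  ou$effect_allele <- ea_y; ou$other_allele <- oa_y
  ou$eaf <- eaf_y; ou$beta <- beta_y; ou$se <- 0.012
  list(exposure = sumstats(ex, "X", "continuous"),
       outcome = sumstats(ou, "Y", "continuous"))
}

test_that("matching, swapped and strand-flipped alleles are aligned as
          the definitions force", {
  # identical alleles: copied unchanged
  p <- make_pair_tables("A", "G", "A", "G")
  h <- harmonize_pair(p$exposure, p$outcome)
  expect_equal(h$beta_outcome, 0.03)
  expect_equal(h$flag, "unchanged")
  # swapped alleles: beta negated, eaf reflected
  p <- make_pair_tables("A", "G", "G", "A", eaf_y = 0.7)
  h <- harmonize_pair(p$exposure, p$outcome)
  expect_equal(h$beta_outcome, -0.03)
  expect_equal(h$eaf_outcome, 0.3)
  expect_equal(h$flag, "allele_swapped")
  # complement (opposite strand report): beta unchanged
  p <- make_pair_tables("A", "G", "T", "C")
  h <- harmonize_pair(p$exposure, p$outcome)
  expect_equal(h$beta_outcome, 0.03)
  expect_equal(h$flag, "strand_flipped")
  # irreconcilable allele sets: dropped and counted
  p <- make_pair_tables("A", "G", "A", "C")
  expect_error(harmonize_pair(p$exposure, p$outcome), "retained no SNPs")
})

test_that("palindromic SNPs follow the ambiguity band and EAF
          concordance rules", {
  # eaf = 0.5 in both: inside any sensible band, dropped
  p <- make_pair_tables("A", "T", "A", "T", eaf_x = 0.5, eaf_y = 0.5)
  expect_error(harmonize_pair(p$exposure, p$outcome), "retained no SNPs")
  # clearly informative frequencies, concordant: kept as printed
  p <- make_pair_tables("A", "T", "A", "T", eaf_x = 0.2, eaf_y = 0.22)
  h <- harmonize_pair(p$exposure, p$outcome)
  expect_equal(h$beta_outcome, 0.03)
  # printed swapped with the reflected frequency: equivalent row, swap
  p <- make_pair_tables("A", "T", "T", "A", eaf_x = 0.2, eaf_y = 0.78)
  h <- harmonize_pair(p$exposure, p$outcome)
  expect_equal(h$beta_outcome, -0.03)
  expect_equal(h$eaf_outcome, 1 - 0.78)
  # discordant frequencies under the same letters imply a strand flip
  p <- make_pair_tables("A", "T", "A", "T", eaf_x = 0.2, eaf_y = 0.81)
  h <- harmonize_pair(p$exposure, p$outcome)
  expect_equal(h$beta_outcome, -0.03)
  # infer_by_eaf with missing EAF is a hard error naming the SNP
  p <- make_pair_tables("A", "T", "A", "T", eaf_x = 0.2)
  pe <- p$exposure; pe$eaf <- NA
  expect_error(harmonize_pair(pe, p$outcome,
                              palindrome_policy = "infer_by_eaf"),
               "rs1")
})

test_that("alignment matches an independent rule-table oracle on the
          exhaustive enumeration of biallelic configurations", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ea = bases, oa = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  eaf_x <- 0.2
  eaf_grid <- c(0.25, 0.75)  # outside the band, both sides of 0.5
  n_checked <- 0
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(nrow(pairs))) {
      for (eaf_y in eaf_grid) {
        expected <- align_oracle(pairs$ea[i], pairs$oa[i],
                                 pairs$ea[j], pairs$oa[j],
                                 eaf_x, eaf_y)
        p <- make_pair_tables(pairs$ea[i], pairs$oa[i],
                              pairs$ea[j], pairs$oa[j],
                              eaf_x = eaf_x, eaf_y = eaf_y)
        h <- tryCatch(harmonize_pair(p$exposure, p$outcome),
                      error = function(e) NULL)
        if (expected %in% c("drop_palindromic", "drop_incompatible")) {
          expect_null(h, label = paste("dropped", i, j, eaf_y))
        } else {
          expect_false(is.null(h), label = paste("kept", i, j, eaf_y))
          # the observable contract: sign of the harmonized outcome beta
          # and the provenance flag family
          ora_beta <- if (expected %in% c("swap", "flip_swap")) -0.03
                      else 0.03
          expect_equal(h$beta_outcome, ora_beta,
                       label = paste("beta", i, j, eaf_y))
          ora_flag <- switch(expected,
                             keep = "unchanged",
                             swap = "allele_swapped",
                             flip = "strand_flipped",
                             flip_swap = "strand_flipped")
          expect_equal(h$flag, ora_flag,
                       label = paste("flag", i, j, eaf_y))
        }
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, 12 * 12 * 2)
})

test_that("row conservation holds: retained + dropped +
          missing-from-outcome equals the instrument count", {
  ex <- toy_sumstats_df(6)
  ex$effect_allele <- c("A", "A", "C", "A", "G", "C")
  ex$other_allele  <- c("G", "T", "G", "C", "T", "T")
  ou <- ex
  # rs1 match, rs2 palindromic ambiguous, rs3 swapped, rs4 incompatible,
  # rs5 strand flipped, rs6 missing from outcome
  ou$eaf[2] <- 0.5
  ex$eaf[2] <- 0.5
  ou[3, c("effect_allele", "other_allele")] <- c("G", "C")
  ou[4, c("effect_allele", "other_allele")] <- c("A", "T")
  ou[5, c("effect_allele", "other_allele")] <- c("C", "A")
  ou <- ou[-6, ]
  h <- harmonize_pair(sumstats(ex, "X", "continuous"),
                      sumstats(ou, "Y", "continuous"))
  cts <- attr(h, "counts")
  expect_equal(cts[["exposure_instruments"]], 6)
  expect_equal(cts[["missing_from_outcome"]], 1)
  expect_equal(cts[["retained"]] + cts[["dropped_palindromic"]] +
                 cts[["dropped_incompatible"]] +
                 cts[["missing_from_outcome"]], 6)
  expect_equal(nrow(h), cts[["retained"]])
  expect_setequal(h$snp_id, c("rs1", "rs3", "rs5"))
  expect_true(all(!startsWith(h$flag, "dropped")))
  # every retained row ends up on the exposure's effect allele
  expect_equal(h$effect_allele,
               ex$effect_allele[match(h$snp_id, ex$snp_id)])
})

test_that("allele-swap correction is involutive: a doubly-swapped outcome
          table harmonizes to the identical dataset", {
  ex <- toy_sumstats(5, trait = "X")
  ou_df <- toy_sumstats_df(5)
  ou_df$beta <- ou_df$beta * 0.5
  ou <- sumstats(ou_df, "Y", "continuous")
  h_direct <- harmonize_pair(ex, ou)
  swapped <- ou_df
  swapped[, c("effect_allele", "other_allele")] <-
    swapped[, c("other_allele", "effect_allele")]
  swapped$beta <- -swapped$beta
  swapped$eaf <- 1 - swapped$eaf
  h_swapped <- harmonize_pair(ex, sumstats(swapped, "Y", "continuous"))
  expect_equal(h_swapped$beta_outcome, h_direct$beta_outcome)
  expect_equal(h_swapped$eaf_outcome, h_direct$eaf_outcome)
  expect_true(all(h_swapped$flag == "allele_swapped"))
})

test_that("exclude_overlap removes shared instruments from both tables", {
  a <- toy_sumstats(4, trait = "education")
  b_df <- toy_sumstats_df(6)
  b_df$snp_id <- c("rs3", "rs4", "rs10", "rs11", "rs12", "rs13")
  b <- sumstats(b_df, "intelligence", "continuous")
  res <- exclude_overlap(a, b)
  expect_setequal(res$overlap, c("rs3", "rs4"))
  expect_equal(nrow(res$a), 2)
  expect_equal(nrow(res$b), 4)
  expect_false(any(res$overlap %in% res$a$snp_id))
  expect_false(any(res$overlap %in% res$b$snp_id))
  # disjoint tables come back unchanged
  res2 <- exclude_overlap(res$a, res$b)
  expect_length(res2$overlap, 0)
  expect_equal(as.data.frame(res2$a), as.data.frame(res$a))
})

test_that("greedy clumping reproduces a direct enumeration oracle and
          honours window and tie-break rules", {
  # hand case: two SNPs 1 kb apart, r2 = 0.9 -> smaller p wins
  df <- toy_sumstats_df(2)
  df$chrom <- "1"; df$pos <- c(10000, 11000)
  df$pval <- c(1e-10, 1e-8)
  r2m <- matrix(c(1, 0.9, 0.9, 1), 2,
                dimnames = list(df$snp_id, df$snp_id))
  tab <- sumstats(df, "X", "continuous")
  out <- greedy_clump(tab, ld_info(r2m))
  expect_equal(out$snp_id, "rs1")
  # same pair but 20 Mb apart: window rule keeps both
  df2 <- df; df2$pos <- c(1e6, 21e6)
  out2 <- greedy_clump(sumstats(df2, "X", "continuous"), ld_info(r2m))
  expect_equal(nrow(out2), 2)
  # no LD supplied: pre-clumped pass-through with a notice
  expect_message(out3 <- greedy_clump(tab, NULL), "pre-clumped")
  expect_equal(as.data.frame(out3), as.data.frame(tab))
  # randomized small instances against the rescanning oracle
  set.seed(99)
  for (rep in 1:25) {
    k <- sample(3:5, 1)
    df <- toy_sumstats_df(k)
    df$chrom <- sample(c("1", "2"), k, replace = TRUE)
    df$pos <- sample(1:20, k) * 1e6
    df$pval <- 10^-runif(k, 4, 12)
    r2m <- matrix(runif(k * k), k)
    r2m <- (r2m + t(r2m)) / 2
    r2m[r2m > 0.5] <- 0.9  # make some pairs clearly dependent
    diag(r2m) <- 1
    dimnames(r2m) <- list(df$snp_id, df$snp_id)
    expected <- clump_oracle(df, r2m, r2_threshold = 0.1)
    got <- greedy_clump(sumstats(df, "X", "continuous"),
                        ld_info(r2m), r2_threshold = 0.1)
    expect_setequal(got$snp_id, expected)
    # row-order invariance
    perm <- sample(k)
    got_perm <- greedy_clump(sumstats(df[perm, ], "X", "continuous"),
                             ld_info(r2m), r2_threshold = 0.1)
    expect_setequal(got_perm$snp_id, expected)
  }
})

test_that("clumping with an incomplete pair list fails rather than
          assuming independence", {
  df <- toy_sumstats_df(3)
  df$chrom <- "1"; df$pos <- c(1e6, 2e6, 3e6)
  pairs <- data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5)
  expect_error(greedy_clump(sumstats(df, "X", "continuous"),
                            ld_info(pairs), r2_threshold = 0.01),
               "missing")
})

test_that("LD info validates its values and reads both pair-list and
          matrix layouts", {
  expect_error(ld_info(data.frame(snp_a = "a", snp_b = "b", r2 = 1.4)),
               "\\[0, 1\\]")
  pairs_path <- tempfile(fileext = ".tsv")
  data.table::fwrite(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.31),
                     pairs_path, sep = "\t")
  ld1 <- read_ld(pairs_path)
  m <- matrix(c(1, 0.31, 0.31, 1), 2,
              dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  mat_path <- tempfile(fileext = ".tsv")
  data.table::fwrite(data.frame(snp_id = rownames(m), m), mat_path,
                     sep = "\t")
  ld2 <- read_ld(mat_path)
  expect_equal(mrpath:::.ld_r2(ld1, "rs2", "rs1"), 0.31)
  expect_equal(mrpath:::.ld_r2(ld2, "rs1", "rs2"), 0.31)
})

test_that("the multivariable dataset assembles the clumped union with
          both exposures' betas and full provenance counts", {
  # toy: 3 + 2 instruments with one duplicate -> 4 unique
  e1_df <- toy_sumstats_df(3)
  e2_df <- toy_sumstats_df(4)[3:4, ]
  e2_df$beta <- c(0.2, 0.3)
  full1 <- toy_sumstats_df(4); full1$beta <- c(0.1, 0.12, 0.14, 0.05)
  full2 <- toy_sumstats_df(4); full2$beta <- c(0.01, 0.02, 0.2, 0.3)
  e1 <- sumstats(e1_df, "education", "continuous")
  e2 <- sumstats(e2_df, "intelligence", "continuous")
  out_df <- toy_sumstats_df(4); out_df$beta <- out_df$beta / 10
  outc <- sumstats(out_df, "AD", "binary")
  mv <- suppressMessages(build_mvmr_dataset(
    e1, e2,
    cross_assoc = list(
      education = sumstats(full1, "education", "continuous"),
      intelligence = sumstats(full2, "intelligence", "continuous")),
    outcome = outc))
  expect_equal(nrow(mv), 4)
  cts <- attr(mv, "counts")
  expect_equal(cts[["instruments_exposure1"]], 3)
  expect_equal(cts[["instruments_exposure2"]], 2)
  expect_equal(cts[["instrument_overlap"]], 1)
  expect_equal(cts[["union"]], 4)
  expect_equal(mv$beta_exposure1,
               full1$beta[match(mv$snp_id, full1$snp_id)])
  expect_equal(mv$beta_exposure2,
               full2$beta[match(mv$snp_id, full2$snp_id)])
  # SNPs lacking a cross association are dropped and counted
  mv2 <- suppressMessages(build_mvmr_dataset(
    e1, e2,
    cross_assoc = list(
      education = sumstats(full1, "education", "continuous"),
      intelligence = sumstats(full2[-1, ], "intelligence",
                              "continuous")),
    outcome = outc))
  expect_equal(nrow(mv2), 3)
  expect_equal(attr(mv2, "counts")[["missing_cross_association"]], 1)
})

test_that("an empty second instrument list reduces the multivariable
          dataset to the univariable harmonization of exposure 1", {
  e1 <- toy_sumstats(4, trait = "education")
  e2 <- sumstats(toy_sumstats_df(1)[0, ], "intelligence", "continuous",
                 allow_empty = TRUE)
  full2 <- toy_sumstats_df(4); full2$beta <- 0
  out_df <- toy_sumstats_df(4); out_df$beta <- out_df$beta / 10
  outc <- sumstats(out_df, "AD", "binary")
  mv <- suppressMessages(build_mvmr_dataset(
    e1, e2,
    cross_assoc = list(
      education = e1,
      intelligence = suppressMessages(
        sumstats(full2, "intelligence", "continuous"))),
    outcome = outc))
  uni <- harmonize_pair(e1, outc)
  expect_equal(mv$snp_id, uni$snp_id)
  expect_equal(mv$beta_exposure1, uni$beta_exposure)
  expect_equal(mv$beta_outcome, uni$beta_outcome)
  expect_true(all(mv$beta_exposure2 == 0))
})
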
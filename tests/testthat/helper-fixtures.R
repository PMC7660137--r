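# Fixtures and independent oracles shared across the test files.
# Oracles are deliberately implemented differently from the package code
# (lm() fits, set arithmetic, direct enumeration) so agreement is evidence,
# not tautology.

toy_sumstats_df <- function(n = 3, seed = NULL, trait = "exposure",
                            palindromic = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  alleles <- if (palindromic) {
    cbind(rep("A", n), rep("T", n))
  } else {
    cbind(rep(c("A", "C", "G"), length.out = n),
          rep(c("G", "T", "A"), length.out = n))
  }
  data.frame(
    snp_id = sprintf("rs%d", seq_len(n)),
    chrom = as.character(rep_len(1:22, n)),
    pos = seq_len(n) * 1000 + 500,
    effect_allele = alleles[, 1],
    other_allele = alleles[, 2],
    eaf = round(seq(0.15, 0.45, length.out = n), 3),
    beta = round(seq(0.02, 0.1, length.out = n), 4),
    se = round(seq(0.01, 0.02, length.out = n), 4),
    pval = 10^(-seq(8, 10, length.out = n)),
    n = 10000,
    stringsAsFactors = FALSE)
}

toy_sumstats <- function(n = 3, trait = "exposure",
                         trait_type = "continuous", ...) {
  sumstats(toy_sumstats_df(n, ...), trait_name = trait,
           trait_type = trait_type)
}

write_sumstats_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  path
}

# Hand-built harmonized dataset, bypassing harmonize_pair, for estimator
# unit tests.
toy_dataset <- function(bx, by, sey, sex = 0.01, eaf = 0.3,
                        nx = 1e5, ny = 1e5,
                        outcome_type = "continuous",
                        exposure = "X", outcome = "Y") {
  k <- length(bx)
  structure(
    data.frame(snp_id = sprintf("rs%d", seq_len(k)),
               chrom = "1", pos = seq_len(k) * 1e6,
               effect_allele = "A", other_allele = "G",
               beta_exposure = bx, se_exposure = rep_len(sex, k),
               eaf_exposure = rep_len(eaf, k),
               eaf_outcome = rep_len(eaf, k),
               beta_outcome = by, se_outcome = rep_len(sey, k),
               pval_exposure = 1e-8, pval_outcome = 0.5,
               n_exposure = rep_len(nx, k), n_outcome = rep_len(ny, k),
               flag = "unchanged", stringsAsFactors = FALSE),
    class = c("mr_dataset", "data.frame"),
    exposure_names = exposure, exposure_types = "continuous",
    outcome_name = outcome, outcome_type = outcome_type)
}

toy_mvmr_dataset <- function(bx1, bx2, by, sey,
                             exposures = c("X1", "X2"),
                             outcome_type = "continuous") {
  k <- length(by)
  structure(
    data.frame(snp_id = sprintf("rs%d", seq_len(k)),
               beta_exposure1 = bx1, se_exposure1 = 0.01,
               beta_exposure2 = bx2, se_exposure2 = 0.01,
               eaf_exposure = 0.3,
               beta_outcome = by, se_outcome = rep_len(sey, k),
               n_exposure1 = 1e5, n_exposure2 = 1e5, n_outcome = 1e5,
               flag = "unchanged", stringsAsFactors = FALSE),
    class = c("mr_dataset", "data.frame"),
    exposure_names = exposures,
    exposure_types = c("continuous", "continuous"),
    outcome_name = "Y", outcome_type = outcome_type)
}

# Inverse-variance meta-analysis of per-SNP Wald ratios: the classical
# fixed-effect pooling formula, written independently of mr_ivw().
ivw_meta_oracle <- function(bx, by, sey) {
  b <- by / bx
  se <- sey / abs(bx)
  w <- 1 / se^2
  list(beta = sum(w * b) / sum(w), se = sqrt(1 / sum(w)))
}

# Weighted regression oracle through lm(), used against the closed-form
# normal-equation fits in the package.
wls_oracle <- function(y, X, w, intercept = FALSE) {
  df <- as.data.frame(X)
  form <- if (intercept) y ~ . else y ~ . - 1
  fit <- stats::lm(form, data = cbind(y = y, df), weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  se_fixed <- unname(sm$coefficients[, 2] / sigma)
  list(coef = unname(stats::coef(fit)),
       se_fixed = se_fixed,
       se_scaled = se_fixed * max(1, sigma),
       sigma = sigma)
}

# Independent rule-table oracle for allele alignment, written with
# set/complement logic rather than the package's branch order.
align_oracle <- function(ea_x, oa_x, ea_y, oa_y, eaf_x, eaf_y,
                         band = c(0.42, 0.58)) {
  comp <- function(a) c(A = "T", T = "A", C = "G", G = "C")[[a]]
  pal <- identical(sort(c(ea_x, oa_x)), sort(c(comp(ea_x), comp(oa_x))))
  if (pal) {
    if (!setequal(c(ea_x, oa_x), c(ea_y, oa_y))) return("drop_incompatible")
    if (is.na(eaf_x) || is.na(eaf_y)) return("drop_palindromic")
    if ((eaf_x > band[1] && eaf_x < band[2]) ||
        (eaf_y > band[1] && eaf_y < band[2])) return("drop_palindromic")
    f_face_value <- if (ea_y == ea_x) eaf_y else 1 - eaf_y
    face_value_ok <- (f_face_value < 0.5) == (eaf_x < 0.5)
    keep <- (ea_y == ea_x) == face_value_ok
    return(if (keep) "keep" else "swap")
  }
  if (identical(c(ea_y, oa_y), c(ea_x, oa_x))) return("keep")
  if (identical(c(ea_y, oa_y), c(oa_x, ea_x))) return("swap")
  if (identical(c(comp(ea_y), comp(oa_y)), c(ea_x, oa_x))) return("flip")
  if (identical(c(comp(ea_y), comp(oa_y)), c(oa_x, ea_x)))
    return("flip_swap")
  "drop_incompatible"
}

# Direct greedy-clumping enumeration for tiny instances: rescan the table
# from scratch at every step instead of maintaining state.
clump_oracle <- function(df, r2m, r2_threshold = 0.01, window_bp = 1e7) {
  remaining <- df
  kept <- character()
  while (nrow(remaining) > 0) {
    o <- order(remaining$pval, remaining$chrom, remaining$pos)
    lead <- remaining[o[1], ]
    kept <- c(kept, lead$snp_id)
    drop <- vapply(seq_len(nrow(remaining)), function(i) {
      r <- remaining[i, ]
      if (r$snp_id == lead$snp_id) return(TRUE)
      r$chrom == lead$chrom &&
        abs(r$pos - lead$pos) <= window_bp &&
        r2m[lead$snp_id, r$snp_id] >= r2_threshold
    }, logical(1))
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# One small simulated study reused by several pipeline tests (cached per
# session; strong instruments so selection noise is negligible).
strong_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_config("h", n_sample_exposure = 50000,
                             n_sample_outcome = 50000, seed = 424242)
      cache <<- suppressMessages(make_two_sample_study(cfg))
    }
    cache
  }
})
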
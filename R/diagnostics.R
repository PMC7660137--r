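#' Per-SNP variance explained
#'
#' Two interchangeable r-squared formulations for a SNP-trait association:
#'
#' * `"eaf_beta"`: `2 * eaf * (1 - eaf) * beta^2`, valid when the trait is
#'   continuous in SD units and EAF is available (the genotype variance
#'   times the squared standardized effect);
#' * `"t_stat"`: with `t = beta / se`, `t^2 / (t^2 + n - 2)`, which needs
#'   only the per-SNP sample size.
#'
#' Both are small-effect approximations to the squared genotype-phenotype
#' correlation and agree closely where both are valid.
#'
#' @param beta,se,eaf,n vectors of per-SNP association statistics.
#' @param method `"eaf_beta"` or `"t_stat"`.
#' @return numeric vector of per-SNP r-squared values.
#' @export
snp_r2 <- function(beta, se = NULL, eaf = NULL, n = NULL,
                   method = c("eaf_beta", "t_stat")) {
  method <- match.arg(method)
  if (method == "eaf_beta") {
    if (is.null(eaf) || anyNA(eaf)) {
      stop("r2 method 'eaf_beta' requires EAF for every SNP", call. = FALSE)
    }
    return(2 * eaf * (1 - eaf) * beta^2)
  }
  if (is.null(n) || anyNA(n) || is.null(se)) {
    stop("r2 method 't_stat' requires se and n for every SNP",
         call. = FALSE)
  }
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Steiger directionality filtering
#'
#' For each instrument, compares the variance it explains in the exposure
#' with the variance it explains in the outcome. An instrument consistent
#' with the hypothesized exposure-to-outcome direction should explain more
#' variance in the exposure; rows failing that plain comparison are removed
#' (no significance threshold is applied to the filter itself). The
#' Steiger z test comparing the two dependent correlations (Fisher
#' z-transformed, with the two GWAS sample sizes) is also computed for
#' reporting.
#'
#' @param dataset single-exposure `mr_dataset`.
#' @param r2_method passed to [snp_r2()]; `"eaf_beta"` (default) uses the
#'   harmonized EAF for both traits, `"t_stat"` uses per-trait sample
#'   sizes.
#' @return list with `records` (per-SNP `snp_id`, `r2_exposure`,
#'   `r2_outcome`, `direction_ok`, `z_steiger`, `steiger_pval`) and
#'   `dataset` (the filtered `mr_dataset` containing only
#'   direction-consistent rows).
#' @export
steiger_filter <- function(dataset, r2_method = c("eaf_beta", "t_stat")) {
  r2_method <- match.arg(r2_method)
  if (r2_method == "eaf_beta") {
    eaf <- dataset$eaf_exposure
    if (anyNA(eaf)) {
      stop("Steiger r2 undefined (missing EAF) for SNP(s) ",
           paste(utils::head(dataset$snp_id[is.na(eaf)], 5L),
                 collapse = ", "), call. = FALSE)
    }
    r2_exp <- snp_r2(dataset$beta_exposure, eaf = eaf, method = "eaf_beta")
    r2_out <- snp_r2(dataset$beta_outcome, eaf = eaf, method = "eaf_beta")
  } else {
    r2_exp <- snp_r2(dataset$beta_exposure, dataset$se_exposure,
                     n = dataset$n_exposure, method = "t_stat")
    r2_out <- snp_r2(dataset$beta_outcome, dataset$se_outcome,
                     n = dataset$n_outcome, method = "t_stat")
  }
  bad <- !is.finite(r2_exp) | !is.finite(r2_out) | r2_exp >= 1 | r2_out >= 1
  if (any(bad)) {
    stop("Steiger r2 undefined for SNP(s) ",
         paste(utils::head(dataset$snp_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (dataset$n_exposure - 3) + 1 / (dataset$n_outcome - 3))
  records <- data.frame(
    snp_id = dataset$snp_id,
    r2_exposure = r2_exp,
    r2_outcome = r2_out,
    direction_ok = r2_exp > r2_out,
    z_steiger = z,
    steiger_pval = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE)
  filtered <- dataset[records$direction_ok, , drop = FALSE]
  rownames(filtered) <- NULL
  attrs <- attributes(dataset)
  attributes(filtered)[c("class", "exposure_names", "exposure_types",
                         "outcome_name", "outcome_type")] <-
    attrs[c("class", "exposure_names", "exposure_types", "outcome_name",
            "outcome_type")]
  if (nrow(filtered) == 0L) {
    warning("Steiger filtering removed every SNP")
  }
  list(records = records, dataset = filtered)
}

#' Instrument-strength F statistic
#'
#' `F = (r2 / (1 - r2)) * ((n - 1 - k) / k)` for a set of `k` instruments
#' jointly explaining a fraction `r2_total` of the exposure variance in a
#' GWAS of `n` individuals. F > 10 is the conventional bar above which weak
#' instrument bias is considered unlikely.
#'
#' @param r2_total summed variance explained, in \[0, 1).
#' @param n GWAS sample size, must exceed `k + 1`.
#' @param k number of instruments, >= 1.
#' @return list of class `instrument_strength`: `r2_total`, `n`, `k`, `F`,
#'   `weak` (logical, `F <= 10`).
#' @export
f_statistic <- function(r2_total, n, k) {
  if (r2_total < 0 || r2_total >= 1) {
    stop("r2_total must lie in [0, 1)", call. = FALSE)
  }
  if (k < 1 || n <= k + 1) {
    stop("need n > k + 1 >= 2 (got n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  F <- (r2_total / (1 - r2_total)) * ((n - 1 - k) / k)
  structure(list(r2_total = r2_total, n = n, k = k, F = F, weak = F <= 10),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("F = %.2f (r2 = %.4g, n = %d, k = %d)%s\n", x$F, x$r2_total,
              as.integer(x$n), as.integer(x$k),
              if (x$weak) " [weak: F <= 10]" else ""))
  invisible(x)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (b_j - beta)^2` over per-SNP Wald ratios `b_j`, with
#' first-order inverse-variance weights `w_j = beta_exposure_j^2 /
#' se_outcome_j^2` (the same dialect as the IVW weighting: exposure-side
#' uncertainty ignored) and `beta` the IVW estimate. Referred to the
#' chi-square distribution with `n_snps - 1` degrees of freedom; excess
#' heterogeneity suggests that not all instruments estimate the same
#' causal quantity.
#'
#' @param dataset single-exposure `mr_dataset`, at least 2 SNPs.
#' @param est optional `mr_estimate` whose `beta` centres the sum; the
#'   fixed-effect IVW estimate is used when omitted (the weighted mean of
#'   the Wald ratios, which minimizes Q).
#' @return list of class `q_result`: `Q`, `df`, `pval`.
#' @export
cochrans_q <- function(dataset, est = NULL) {
  k <- nrow(dataset)
  if (k < 2L) {
    stop("Cochran's Q needs at least 2 SNPs, got ", k, call. = FALSE)
  }
  wr <- wald_ratio(dataset)
  beta <- if (is.null(est)) {
    mr_ivw(dataset, weights_model = "fixed")$beta
  } else {
    est$beta
  }
  w <- 1 / wr$se_wald^2
  Q <- sum(w * (wr$wald_ratio - beta)^2)
  structure(list(Q = Q, df = k - 1L,
                 pval = stats::pchisq(Q, df = k - 1L, lower.tail = FALSE)),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %.3g\n", x$Q, x$df, x$pval))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW estimate with each SNP removed in turn, using the same
#' weights model as the main fit. Omissions that change the sign of the
#' estimate or move it by more than `influence_se_multiple` full-sample
#' standard errors are flagged as influential — a reproducible numeric
#' proxy for the visual distortion check.
#'
#' @param dataset single-exposure `mr_dataset`, at least 3 SNPs.
#' @param weights_model see [mr_ivw()].
#' @param influence_se_multiple shift threshold in units of the full-sample
#'   SE (default 1).
#' @return data frame with one row per omitted SNP: `omitted`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pval`, `shift_se` (shift from the full
#'   estimate in full-sample SEs), `influential`.
#' @export
leave_one_out <- function(dataset,
                          weights_model = c("multiplicative_random",
                                            "fixed"),
                          influence_se_multiple = 1) {
  weights_model <- match.arg(weights_model)
  k <- nrow(dataset)
  if (k < 3L) {
    stop("leave-one-out needs at least 3 SNPs, got ", k, call. = FALSE)
  }
  full <- mr_ivw(dataset, weights_model = weights_model)
  rows <- lapply(seq_len(k), function(i) {
    est <- mr_ivw(dataset[-i, , drop = FALSE], weights_model = weights_model)
    data.frame(omitted = dataset$snp_id[i], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pval = est$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$shift_se <- (out$beta - full$beta) / full$se
  out$influential <- abs(out$shift_se) > influence_se_multiple |
    (sign(out$beta) != sign(full$beta) & out$beta != 0 & full$beta != 0)
  attr(out, "full_estimate") <- full
  out
}

#' Funnel-plot data and asymmetry summary
#'
#' Per-SNP Wald ratios against their precisions (`1/se_wald`). Under
#' balanced pleiotropy the scatter is symmetric about the causal estimate
#' at every precision; directional pleiotropy shows up as asymmetry, here
#' summarized by the precision-weighted regression of the estimate on
#' precision (slope near zero indicates symmetry). With a single SNP the
#' asymmetry summary is undefined and reported as `NA`.
#'
#' @param dataset single-exposure `mr_dataset`.
#' @return list with `data` (per-SNP `snp_id`, `wald_ratio`, `precision`)
#'   and `asymmetry` (`slope`, `se`, `pval`, all `NA` when fewer than 3
#'   SNPs).
#' @export
funnel_data <- function(dataset) {
  wr <- wald_ratio(dataset)
  df <- data.frame(snp_id = wr$snp_id, wald_ratio = wr$wald_ratio,
                   precision = 1 / wr$se_wald, stringsAsFactors = FALSE)
  asym <- list(slope = NA_real_, se = NA_real_, pval = NA_real_)
  if (nrow(df) >= 3L) {
    fit <- .wls(cbind(1, df$precision), df$wald_ratio, df$precision)
    asym <- list(slope = fit$coef[2L],
                 se = sqrt(fit$vcov[2L, 2L]),
                 pval = 2 * stats::pnorm(
                   -abs(fit$coef[2L] / sqrt(fit$vcov[2L, 2L]))))
  }
  list(data = df, asymmetry = asym)
}
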
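#' @section Estimation model:
#' All estimators operate on harmonized per-SNP summary statistics. With
#' per-SNP exposure associations `bx_j` (SD units) and outcome associations
#' `by_j` (SD units, or log odds ratios for a binary outcome), the IVW
#' estimate is the weighted regression of `by` on `bx` through the origin
#' with weights `1/se_by^2`; MR-Egger frees the intercept; multivariable
#' IVW regresses `by` on both exposures' `bx` columns jointly. 95%
#' confidence intervals use the normal quantile 1.96 throughout and
#' p-values are two-sided normal, so reported numbers are exactly
#' reproducible from beta and se.
#' @keywords internal
#' @name mrpath-estimation
NULL

.Z95 <- qnorm(0.975)

.mr_estimate <- function(method, exposure, outcome, outcome_type,
                         beta, se, n_snps, weights_model = NA_character_) {
  z <- beta / se
  structure(data.frame(
    method = method,
    exposure = exposure,
    outcome = outcome,
    outcome_type = outcome_type,
    n_snps = as.integer(n_snps),
    beta = beta,
    se = se,
    ci_low = beta - .Z95 * se,
    ci_high = beta + .Z95 * se,
    pval = 2 * stats::pnorm(-abs(z)),
    weights_model = weights_model,
    stringsAsFactors = FALSE),
    class = c("mr_estimate", "data.frame"))
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-SNP Wald ratio
#'
#' The causal estimate contributed by a single instrument:
#' `beta_outcome / beta_exposure`, with the first-order delta-method
#' standard error `se_outcome / |beta_exposure|` (uncertainty in the
#' exposure association is ignored, the standard two-sample convention that
#' also underlies the IVW weights).
#'
#' @param dataset a single-exposure `mr_dataset`, or any data frame with
#'   columns `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`.
#' @return data frame with one row per SNP: `snp_id`, `wald_ratio`,
#'   `se_wald`.
#' @export
wald_ratio <- function(dataset) {
  if (any(dataset$beta_exposure == 0)) {
    stop("Wald ratio undefined: beta_exposure is zero for SNP(s) ",
         paste(utils::head(dataset$snp_id[dataset$beta_exposure == 0], 5L),
               collapse = ", "), call. = FALSE)
  }
  data.frame(snp_id = if (!is.null(dataset$snp_id)) dataset$snp_id
                      else seq_len(nrow(dataset)),
             wald_ratio = dataset$beta_outcome / dataset$beta_exposure,
             se_wald = dataset$se_outcome / abs(dataset$beta_exposure),
             stringsAsFactors = FALSE)
}

# Weighted least squares by explicit normal equations. X: n x p, w: weights.
# Returns coefficients, their covariance with residual scaling
# max(1, sigma), sigma2, and the fixed (unscaled) covariance.
.wls <- function(X, y, w, floor_sigma = TRUE) {
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  cn <- kappa(XtWX, exact = TRUE)
  if (!is.finite(cn) || cn > 1e10) {
    stop("design is rank deficient or near-singular (condition number ",
         format(cn, digits = 4), ")", call. = FALSE)
  }
  V <- solve(XtWX)
  coef <- drop(V %*% (XtW %*% y))
  resid <- y - drop(X %*% coef)
  df <- nrow(X) - ncol(X)
  sigma2 <- if (df > 0) sum(w * resid^2) / df else NA_real_
  scale <- if (floor_sigma && !is.na(sigma2)) max(1, sigma2) else 1
  list(coef = coef, vcov_fixed = V, vcov = V * scale, sigma2 = sigma2,
       df = df, condition_number = cn)
}

#' Inverse-variance-weighted causal estimate
#'
#' Averages per-SNP Wald ratios with inverse-variance weights, equivalently
#' the weighted regression of outcome betas on exposure betas with the
#' intercept constrained to zero (weights `1/se_outcome^2`). Under
#' `"fixed"` weighting the standard error is `(sum w bx^2)^(-1/2)`; under
#' `"multiplicative_random"` (the default) it is scaled by the residual
#' standard deviation of the weighted regression, floored at 1 so
#' underdispersion never shrinks the interval. Point estimates are
#' identical under both weightings.
#'
#' @param dataset single-exposure `mr_dataset` (from [harmonize_pair()]).
#' @param weights_model `"multiplicative_random"` or `"fixed"`.
#' @return one-row `mr_estimate` data frame.
#' @export
mr_ivw <- function(dataset,
                   weights_model = c("multiplicative_random", "fixed")) {
  weights_model <- match.arg(weights_model)
  k <- nrow(dataset)
  if (k < 1L) stop("no SNPs in dataset", call. = FALSE)
  if (weights_model == "multiplicative_random" && k < 2L) {
    stop("multiplicative random-effects IVW needs at least 2 SNPs",
         call. = FALSE)
  }
  bx <- dataset$beta_exposure
  by <- dataset$beta_outcome
  if (all(bx == 0)) {
    stop("degenerate design: all exposure betas are zero", call. = FALSE)
  }
  w <- 1 / dataset$se_outcome^2
  sw_bxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sw_bxx
  se_fixed <- sqrt(1 / sw_bxx)
  se <- se_fixed
  if (weights_model == "multiplicative_random" && k >= 2L) {
    sigma2 <- sum(w * (by - beta * bx)^2) / (k - 1)
    se <- se_fixed * sqrt(max(1, sigma2))
  }
  .mr_estimate("ivw", paste(attr(dataset, "exposure_names"),
                            collapse = "+"),
               attr(dataset, "outcome_name") %||% "outcome",
               attr(dataset, "outcome_type") %||% NA_character_,
               beta, se, k, weights_model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept (weights `1/se_outcome^2`). The intercept estimates the
#' average directional pleiotropic effect per SNP; the slope is a causal
#' estimate adjusted for it. Exposure betas are oriented non-negative
#' before fitting (flipping the paired outcome beta's sign), the standard
#' convention that fixes Egger's orientation-dependent estimand; slope and
#' intercept are invariant to any further sign flips. Standard errors carry
#' the multiplicative residual scaling floored at 1.
#'
#' @param dataset single-exposure `mr_dataset` with at least 3 SNPs.
#' @return An `mr_egger_result`: list with `slope` (an `mr_estimate`),
#'   `intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(dataset) {
  k <- nrow(dataset)
  if (k < 3L) {
    stop("MR-Egger needs at least 3 SNPs, got ", k, call. = FALSE)
  }
  s <- ifelse(dataset$beta_exposure < 0, -1, 1)
  bx <- s * dataset$beta_exposure
  by <- s * dataset$beta_outcome
  w <- 1 / dataset$se_outcome^2
  fit <- .wls(cbind(intercept = 1, slope = bx), by, w)
  ses <- sqrt(diag(fit$vcov))
  slope <- .mr_estimate("egger_slope",
                        paste(attr(dataset, "exposure_names"),
                              collapse = "+"),
                        attr(dataset, "outcome_name") %||% "outcome",
                        attr(dataset, "outcome_type") %||% NA_character_,
                        fit$coef[["slope"]], ses[["slope"]], k,
                        "multiplicative_random")
  structure(list(slope = slope,
                 intercept = fit$coef[["intercept"]],
                 intercept_se = ses[["intercept"]],
                 intercept_pval = 2 * stats::pnorm(
                   -abs(fit$coef[["intercept"]] / ses[["intercept"]])),
                 sigma2 = fit$sigma2),
            class = "mr_egger_result")
}

#' @export
print.mr_egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept (avg pleiotropy/SNP): %.4g (se %.3g, p %.3g)\n",
              x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

#' Multivariable IVW: direct effects of two exposures
#'
#' Weighted least squares of outcome betas on both exposures' betas jointly,
#' no intercept, weights `1/se_outcome^2`. Each coefficient is that
#' exposure's direct effect conditional on the other. An exposure whose
#' beta column is identically zero is dropped from the fit (its estimate is
#' reported as `NA`, and the other coefficient reduces exactly to the
#' univariable IVW); non-trivially collinear exposure columns raise a
#' rank-deficiency error reporting the condition number.
#'
#' @param dataset two-exposure `mr_dataset` from [build_mvmr_dataset()],
#'   at least 3 SNPs.
#' @return `mr_estimate` data frame with one row per exposure
#'   (method `"mvmr_ivw"`).
#' @export
mr_mvmr_ivw <- function(dataset) {
  k <- nrow(dataset)
  if (k < 3L) {
    stop("multivariable IVW needs at least 3 SNPs, got ", k, call. = FALSE)
  }
  exposures <- attr(dataset, "exposure_names")
  X <- cbind(dataset$beta_exposure1, dataset$beta_exposure2)
  colnames(X) <- exposures
  w <- 1 / dataset$se_outcome^2
  nonzero <- colSums(X != 0) > 0
  if (!any(nonzero)) {
    stop("degenerate design: all exposure betas are zero", call. = FALSE)
  }
  if (!all(nonzero)) {
    warning("exposure '", exposures[!nonzero],
            "' has all-zero betas; dropped from the multivariable fit")
  }
  fit <- .wls(X[, nonzero, drop = FALSE], dataset$beta_outcome, w)
  beta <- se <- rep(NA_real_, 2L)
  beta[nonzero] <- fit$coef
  se[nonzero] <- sqrt(diag(fit$vcov))
  out <- .mr_estimate("mvmr_ivw", exposures,
                      attr(dataset, "outcome_name") %||% "outcome",
                      attr(dataset, "outcome_type") %||% NA_character_,
                      beta, se, k, "multiplicative_random")
  attr(out, "condition_number") <- fit$condition_number
  out
}

#' Convert a log-odds-scale estimate to the odds-ratio scale
#'
#' Exponentiates the estimate and its confidence bounds and derives the
#' percent change in odds, reported as "x% lower" when OR < 1. Only valid
#' for binary outcomes; applying it to a continuous-outcome estimate is an
#' error.
#'
#' @param est `mr_estimate` rows with `outcome_type == "binary"`.
#' @return data frame with the original columns plus `or`, `or_ci_low`,
#'   `or_ci_high`, `percent_change` (positive = lower odds) and
#'   `percent_text` (nearest-integer wording; underlying columns keep full
#'   precision).
#' @export
to_odds_scale <- function(est) {
  est <- as.data.frame(est)
  if (any(is.na(est$outcome_type)) || any(est$outcome_type != "binary")) {
    stop("odds-scale conversion requires a binary outcome (log-OR betas)",
         call. = FALSE)
  }
  est$or <- exp(est$beta)
  est$or_ci_low <- exp(est$ci_low)
  est$or_ci_high <- exp(est$ci_high)
  est$percent_change <- (1 - est$or) * 100
  est$percent_text <- ifelse(
    est$or < 1,
    sprintf("%.0f%% lower odds", (1 - est$or) * 100),
    sprintf("%.0f%% higher odds", (est$or - 1) * 100))
  est
}
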
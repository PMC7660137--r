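#' Configure a causal scenario for GWAS simulation
#'
#' Defines the generative model for a two-sample MR study of two correlated
#' continuous exposures in SD units (education-like `ea`, intelligence-like
#' `iq`) and a binary outcome (`ad`) on the log-odds scale. The scenario
#' letters realize the classic causal structures that make univariable MR
#' ambiguous:
#'
#' * `"a"`: instruments act on IQ; IQ causes EA and AD (EA-AD association
#'   is pure confounding by IQ).
#' * `"b"`: mirror of (a) through EA.
#' * `"c"`: instruments act on EA; EA causes IQ; IQ causes AD (the EA
#'   effect on AD is entirely mediated by IQ).
#' * `"d"`: mirror of (c) through EA.
#' * `"e"`: EA instruments also act on IQ directly (horizontal pleiotropy
#'   through IQ); IQ causes AD.
#' * `"f"`: mirror of (e) through EA.
#' * `"g"`: instruments act directly on their exposure *and* on AD
#'   (balanced horizontal pleiotropy); no trait affects any other.
#' * `"h"`: joint independent effects of EA and IQ on AD, with IQ causing
#'   EA.
#' * `"custom"`: all path coefficients taken from the arguments.
#'
#' Bidirectional EA/IQ arrows are realized as a two-stage structural
#' assignment with documented order (the scenario fixes which trait is
#' assigned first); a simultaneous loop is never simulated. Exposure
#' variances are normalized to 1 (genetic + upstream + confounder +
#' residual), so all betas are in SD units; a budget exceeding 1 is a
#' configuration error listing the contributions. The disease is generated
#' from a logistic model: `logit P(AD) = qlogis(ad_base_prevalence) +
#' theta_ea_ad * EA + theta_iq_ad * IQ + sum(pleiotropic SNP effects) +
#' confounder term`.
#'
#' Default scale (100 candidate SNPs per exposure, 20 000 individuals per
#' sample, selection threshold 1e-4) is a scaled-down analogue of a
#' consortium GWAS (where selection would use 5e-8); path-coefficient
#' defaults mirror the magnitudes reported for education/intelligence/AD
#' (IQ-to-EA about 0.5 SD/SD, protective direct effects of -0.2 and -0.3
#' log-odds per SD).
#'
#' @param scenario one of `"a"` to `"h"` or `"custom"`.
#' @param n_snps_ea,n_snps_iq candidate instrument counts per exposure.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param h2_ea,h2_iq variance of each exposure explained by its own
#'   candidate SNPs.
#' @param cross_h2 variance of the *other* exposure explained by a set's
#'   direct cross effects (scenarios e/f).
#' @param theta_ea_iq,theta_iq_ea,theta_ea_ad,theta_iq_ad path
#'   coefficients (SD/SD for trait-trait, log-odds per SD for trait-AD);
#'   `NULL` takes the scenario default.
#' @param pleiotropy_mean,pleiotropy_sd distribution of direct SNP-to-AD
#'   log-odds effects applied to every SNP; `NULL` takes the scenario
#'   default (0 everywhere except `"g"`, which uses sd 0.05).
#' @param confounder_ea,confounder_iq,confounder_ad loadings of a shared
#'   standard-normal latent confounder.
#' @param n_sample_exposure,n_sample_outcome individuals per
#'   (non-overlapping) sample.
#' @param ad_base_prevalence baseline disease probability, in (0, 1).
#' @param p_threshold instrument selection p-value threshold in the
#'   exposure sample.
#' @param seed integer seed; every stochastic operation in this module is
#'   reproducible under it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("h", "a", "b", "c", "d", "e", "f",
                                         "g", "custom"),
                            n_snps_ea = 100, n_snps_iq = 100,
                            maf_range = c(0.05, 0.5),
                            h2_ea = 0.1, h2_iq = 0.1, cross_h2 = 0.05,
                            theta_ea_iq = NULL, theta_iq_ea = NULL,
                            theta_ea_ad = NULL, theta_iq_ad = NULL,
                            pleiotropy_mean = NULL, pleiotropy_sd = NULL,
                            confounder_ea = 0, confounder_iq = 0,
                            confounder_ad = 0,
                            n_sample_exposure = 20000,
                            n_sample_outcome = 20000,
                            ad_base_prevalence = 0.15,
                            p_threshold = 1e-4,
                            seed = 20200131) {
  scenario <- match.arg(scenario)
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_sample_exposure > 0, n_sample_outcome > 0,
            ad_base_prevalence > 0, ad_base_prevalence < 1,
            n_snps_ea >= 1, n_snps_iq >= 1)
  d <- .scenario_defaults(scenario)
  cfg <- list(
    scenario = scenario,
    n_snps_ea = as.integer(n_snps_ea), n_snps_iq = as.integer(n_snps_iq),
    maf_range = maf_range, h2_ea = h2_ea, h2_iq = h2_iq,
    cross_h2 = cross_h2,
    theta_ea_iq = theta_ea_iq %||% d$theta[["ea_iq"]],
    theta_iq_ea = theta_iq_ea %||% d$theta[["iq_ea"]],
    theta_ea_ad = theta_ea_ad %||% d$theta[["ea_ad"]],
    theta_iq_ad = theta_iq_ad %||% d$theta[["iq_ad"]],
    pleiotropy_mean = pleiotropy_mean %||% d$pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd %||% d$pleiotropy_sd,
    confounder_ea = confounder_ea, confounder_iq = confounder_iq,
    confounder_ad = confounder_ad,
    n_sample_exposure = as.integer(n_sample_exposure),
    n_sample_outcome = as.integer(n_sample_outcome),
    ad_base_prevalence = ad_base_prevalence,
    p_threshold = p_threshold,
    order = d$order,
    seed = seed)
  if (scenario == "custom") {
    # a custom IQ->EA path needs IQ assigned first
    cfg$order <- if (cfg$theta_iq_ea != 0) "iq_first" else "ea_first"
  }
  class(cfg) <- "scenario_config"
  cfg
}

# Scenario letter -> assignment order and default path coefficients.
.scenario_defaults <- function(scenario) {
  theta <- c(ea_iq = 0, iq_ea = 0, ea_ad = 0, iq_ad = 0)
  pm <- 0; ps <- 0; order <- "ea_first"
  switch(scenario,
    a = { theta[c("iq_ea", "iq_ad")] <- c(0.5, -0.3); order <- "iq_first" },
    b = { theta[c("ea_iq", "ea_ad")] <- c(0.5, -0.2) },
    c = { theta[c("ea_iq", "iq_ad")] <- c(0.5, -0.4) },
    d = { theta[c("iq_ea", "ea_ad")] <- c(0.5, -0.3); order <- "iq_first" },
    e = { theta[["iq_ad"]] <- -0.3 },
    f = { theta[["ea_ad"]] <- -0.2 },
    g = { ps <- 0.05 },
    h = { theta[c("iq_ea", "ea_ad", "iq_ad")] <- c(0.5, -0.2, -0.3)
          order <- "iq_first" },
    custom = NULL)
  list(theta = theta, pleiotropy_mean = pm, pleiotropy_sd = ps,
       order = order)
}

#' Read a scenario configuration from YAML or JSON
#'
#' @param path file whose keys are [scenario_config()] arguments.
#' @export
read_scenario_config <- function(path) {
  args <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(scenario_config, args)
}

# Draw the per-SNP genetic architecture implied by the scenario: MAFs,
# allele labels, map positions and direct per-allele effects on EA, IQ and
# the AD log-odds. Uses the current RNG stream.
.draw_architecture <- function(cfg) {
  m <- cfg$n_snps_ea + cfg$n_snps_iq
  set <- rep(c("ea", "iq"), c(cfg$n_snps_ea, cfg$n_snps_iq))
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  # non-palindromic allele pairs: palindrome handling is exercised by its
  # own harmonization tests, simulated instruments stay alignable
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                 c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  pick <- sample.int(nrow(pairs), m, replace = TRUE)
  info <- data.frame(
    snp_id = sprintf("rs%05d", seq_len(m)),
    chrom = as.character(rep_len(1:22, m)),
    pos = as.numeric(1e6 + 2e7 * (seq_len(m) - 1) %/% 22),
    effect_allele = pairs[pick, 1L],
    other_allele = pairs[pick, 2L],
    maf = maf, set = set, stringsAsFactors = FALSE)

  v <- 2 * maf * (1 - maf)  # per-SNP genotype variance
  draw <- function(idx, h2) {
    # per-allele effects scaled so the set explains h2 in expectation,
    # each SNP contributing equally in expectation
    out <- numeric(m)
    out[idx] <- stats::rnorm(sum(idx)) * sqrt(h2 / (sum(idx) * v[idx]))
    out
  }
  is_ea <- set == "ea"; is_iq <- set == "iq"
  delta_ea <- delta_iq <- numeric(m)
  kappa <- NA_real_
  sc <- cfg$scenario
  if (sc == "a") {                 # both sets act on IQ only
    delta_iq <- draw(is_ea, cfg$h2_ea) + draw(is_iq, cfg$h2_iq)
  } else if (sc == "b") {          # both sets act on EA only
    delta_ea <- draw(is_ea, cfg$h2_ea) + draw(is_iq, cfg$h2_iq)
  } else if (sc == "e") {          # EA set also hits IQ, proportionally
    delta_ea <- draw(is_ea, cfg$h2_ea)
    kappa <- sqrt(cfg$cross_h2 / cfg$h2_ea)
    delta_iq <- kappa * delta_ea + draw(is_iq, cfg$h2_iq)
  } else if (sc == "f") {          # IQ set also hits EA, proportionally
    delta_iq <- draw(is_iq, cfg$h2_iq)
    kappa <- sqrt(cfg$cross_h2 / cfg$h2_iq)
    delta_ea <- kappa * delta_iq + draw(is_ea, cfg$h2_ea)
  } else {                         # c, d, g, h, custom: own-trait effects
    delta_ea <- draw(is_ea, cfg$h2_ea)
    delta_iq <- draw(is_iq, cfg$h2_iq)
  }
  alpha <- if (cfg$pleiotropy_sd > 0 || cfg$pleiotropy_mean != 0) {
    # directional pleiotropy is defined relative to the exposure-raising
    # allele (a mean direct effect attached to random allele labels would
    # cancel under orientation and be undetectable by construction)
    orient <- sign(ifelse(delta_ea != 0, delta_ea, delta_iq))
    orient[orient == 0] <- 1
    orient * cfg$pleiotropy_mean + stats::rnorm(m, 0, cfg$pleiotropy_sd)
  } else numeric(m)
  info$delta_ea <- delta_ea
  info$delta_iq <- delta_iq
  info$alpha_ad <- alpha
  list(info = info, kappa = kappa)
}

# Simulate one sample of n individuals under the architecture; traits are
# built in the scenario's assignment order with unit marginal variance.
.simulate_sample <- function(arch, cfg, n) {
  info <- arch$info
  m <- nrow(info)
  # Binomial(2, maf) via one uniform draw per genotype: g = [u > (1-p)^2]
  # + [u > (1-p)^2 + 2p(1-p)]; same distribution as rbinom, materially
  # faster at GWAS scale
  p0 <- rep((1 - info$maf)^2, each = n)
  p01 <- p0 + rep(2 * info$maf * (1 - info$maf), each = n)
  u <- stats::runif(n * m)
  G <- (u > p0) + (u > p01)
  dim(G) <- c(n, m)
  colnames(G) <- info$snp_id
  U <- stats::rnorm(n)
  v <- 2 * info$maf * (1 - info$maf)
  # centered genetic score without materializing a centered matrix
  gscore <- function(delta) {
    nz <- delta != 0
    if (!any(nz)) return(numeric(n))
    drop(G[, nz, drop = FALSE] %*% delta[nz]) -
      sum(2 * info$maf[nz] * delta[nz])
  }

  build_first <- function(delta, conf) {
    vg <- sum(v * delta^2)
    resid2 <- 1 - vg - conf^2
    if (resid2 < 0) {
      stop("variance budget exceeds 1 for an exposure: genetic = ",
           format(vg, digits = 4), ", confounder^2 = ",
           format(conf^2, digits = 4), call. = FALSE)
    }
    gscore(delta) + conf * U + stats::rnorm(n, sd = sqrt(resid2))
  }
  build_second <- function(delta, conf, theta, first, first_delta,
                           first_conf) {
    total_delta <- delta + theta * first_delta
    vg <- sum(v * total_delta^2)
    conf_total <- conf + theta * first_conf
    # var(theta * first) already counted through its genetic/confounder
    # parts; the remaining piece is theta^2 * residual variance of `first`
    resid_first2 <- 1 - sum(v * first_delta^2) - first_conf^2
    known <- vg + conf_total^2 + theta^2 * resid_first2
    if (known > 1) {
      stop("variance budget exceeds 1 for an exposure: genetic = ",
           format(vg, digits = 4), ", confounder^2 = ",
           format(conf_total^2, digits = 4), ", upstream = ",
           format(theta^2 * resid_first2, digits = 4), call. = FALSE)
    }
    theta * first + gscore(delta) + conf * U +
      stats::rnorm(n, sd = sqrt(1 - known))
  }

  # Bidirectional arrows are realized as a two-stage assignment: the
  # first trait is drawn as a baseline, the second depends on it, and a
  # non-zero feedback coefficient adds the second trait back onto the
  # baseline, rescaled to unit variance. No simultaneous loop is solved.
  if (cfg$order == "iq_first") {
    iq <- build_first(info$delta_iq, cfg$confounder_iq)
    ea <- build_second(info$delta_ea, cfg$confounder_ea, cfg$theta_iq_ea,
                       iq, info$delta_iq, cfg$confounder_iq)
    fb <- cfg$theta_ea_iq
    if (fb != 0) {
      s <- sqrt(1 + fb^2 + 2 * fb * cfg$theta_iq_ea)
      iq <- (iq + fb * ea) / s
    }
  } else {
    ea <- build_first(info$delta_ea, cfg$confounder_ea)
    iq <- build_second(info$delta_iq, cfg$confounder_iq, cfg$theta_ea_iq,
                       ea, info$delta_ea, cfg$confounder_ea)
    fb <- cfg$theta_iq_ea
    if (fb != 0) {
      s <- sqrt(1 + fb^2 + 2 * fb * cfg$theta_ea_iq)
      ea <- (ea + fb * iq) / s
    }
  }
  lp <- stats::qlogis(cfg$ad_base_prevalence) +
    cfg$theta_ea_ad * ea + cfg$theta_iq_ad * iq +
    cfg$confounder_ad * U
  if (any(info$alpha_ad != 0)) lp <- lp + gscore(info$alpha_ad)
  ad <- stats::rbinom(n, 1L, stats::plogis(lp))
  list(genotypes = G, ea = ea, iq = iq, ad = ad, confounder = U)
}

#' Simulate individual-level data under a causal scenario
#'
#' Genotypes are independent `Binomial(2, maf)` across SNPs (instruments
#' are independent by construction, matching the post-clumping setting);
#' exposures are linear structural equations in SD units with residuals
#' scaled to unit marginal variance; disease status is Bernoulli from the
#' logistic model described in [scenario_config()].
#'
#' @param config a [scenario_config()].
#' @param n number of individuals (default `config$n_sample_exposure`).
#' @return list with `genotypes` (n x m matrix of effect-allele counts),
#'   `ea`, `iq` (numeric), `ad` (0/1), `confounder`, and `truth` (a
#'   `ground_truth` object, see [ground_truth()]).
#' @export
simulate_individuals <- function(config, n = config$n_sample_exposure) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  arch <- .draw_architecture(config)
  s <- .simulate_sample(arch, config, n)
  s$truth <- ground_truth(config, arch)
  s
}

#' Ground truth implied by a scenario's path coefficients
#'
#' Records the realized per-SNP effects and all path coefficients, the
#' path-traced total causal effects, the multivariable direct effects, and
#' the values that univariable IVW converges to with each designed
#' instrument set (which differ from the causal totals in the confounded
#' and pleiotropic scenarios — that divergence is the point of the
#' scenarios). Logistic non-collapsibility attenuates realized disease
#' log-odds slightly relative to these structural values; at the default
#' effect sizes the attenuation is below 5%.
#'
#' @param config a [scenario_config()].
#' @param arch internal architecture (per-SNP effects); drawn fresh under
#'   the config seed when omitted.
#' @return A `ground_truth` list: `theta`, `totals` (path-traced causal
#'   effects `ea_iq`, `iq_ea`, `ea_ad`, `iq_ad`), `mvmr_direct`,
#'   `ivw_estimands` (per instrument set), `snps` (per-SNP effects).
#' @export
ground_truth <- function(config, arch = NULL) {
  if (is.null(arch)) {
    if (!is.null(config$seed)) set.seed(config$seed)
    arch <- .draw_architecture(config)
  }
  th <- c(ea_iq = config$theta_ea_iq, iq_ea = config$theta_iq_ea,
          ea_ad = config$theta_ea_ad, iq_ad = config$theta_iq_ad)
  # Path-traced totals under the two-stage assignment (feedback term
  # rescaled to unit variance, see .simulate_sample); with a single
  # non-zero trait-trait path these reduce to the usual products.
  if (config$order == "iq_first") {
    fwd <- th[["iq_ea"]]; fb <- th[["ea_iq"]]
    s <- sqrt(1 + fb^2 + 2 * fb * fwd)
    iq_ea_tot <- fwd * s / (1 + fb * fwd)
    ea_iq_tot <- fb / s
  } else {
    fwd <- th[["ea_iq"]]; fb <- th[["iq_ea"]]
    s <- sqrt(1 + fb^2 + 2 * fb * fwd)
    ea_iq_tot <- fwd * s / (1 + fb * fwd)
    iq_ea_tot <- fb / s
  }
  totals <- c(
    ea_iq = ea_iq_tot,
    iq_ea = iq_ea_tot,
    ea_ad = th[["ea_ad"]] + ea_iq_tot * th[["iq_ad"]],
    iq_ad = th[["iq_ad"]] + iq_ea_tot * th[["ea_ad"]])
  k <- arch$kappa
  est <- switch(config$scenario,
    a = c(ea_ad = th[["iq_ad"]] / th[["iq_ea"]], iq_ad = th[["iq_ad"]],
          ea_iq = 1 / th[["iq_ea"]], iq_ea = th[["iq_ea"]]),
    b = c(ea_ad = th[["ea_ad"]], iq_ad = th[["ea_ad"]] / th[["ea_iq"]],
          ea_iq = th[["ea_iq"]], iq_ea = 1 / th[["ea_iq"]]),
    e = c(ea_ad = k * th[["iq_ad"]], iq_ad = th[["iq_ad"]],
          ea_iq = k, iq_ea = 0),
    f = c(ea_ad = th[["ea_ad"]], iq_ad = k * th[["ea_ad"]],
          ea_iq = 0, iq_ea = k),
    g = c(ea_ad = 0, iq_ad = 0, ea_iq = 0, iq_ea = 0),
    c(ea_ad = totals[["ea_ad"]], iq_ad = totals[["iq_ad"]],
      ea_iq = totals[["ea_iq"]], iq_ea = totals[["iq_ea"]]))
  structure(list(scenario = config$scenario, theta = th, totals = totals,
                 mvmr_direct = c(ea = th[["ea_ad"]], iq = th[["iq_ad"]]),
                 ivw_estimands = est, kappa = k, snps = arch$info),
            class = "ground_truth")
}

#' Per-SNP GWAS on simulated individual-level data
#'
#' Continuous traits: closed-form simple linear regression per SNP (beta,
#' SE, two-sided t-test p, EAF, n). Binary traits: per-SNP log odds ratio
#' by the one-step score estimator (`beta = U/I`, `se = 1/sqrt(I)` with `U`
#' the null score and `I` the null information; equivalent to one Newton
#' step of the logistic likelihood from zero and accurate to third order in
#' the effect — the default, `method = "score"`) or by full per-SNP
#' logistic regression (`method = "logistic"`). Monomorphic SNPs cannot be
#' tested; they are logged in the `flagged` attribute and never reach
#' instrument selection. Underflowing p-values are floored at 1e-300 to
#' keep them in (0, 1].
#'
#' @param genotypes n x m matrix of effect-allele counts (0/1/2), columns
#'   named by snp_id.
#' @param phenotype numeric (continuous) or 0/1 (binary) vector, length n.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param trait_name trait label for the output table.
#' @param snp_info optional data frame (`snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`) giving map/allele metadata; defaults
#'   are generated when omitted.
#' @param method binary-trait estimator, `"score"` or `"logistic"`.
#' @return A [sumstats] table; monomorphic SNPs in `attr(, "flagged")`.
#' @export
gwas_summary <- function(genotypes, phenotype,
                         trait_type = c("continuous", "binary"),
                         trait_name = "trait", snp_info = NULL,
                         method = c("score", "logistic")) {
  trait_type <- match.arg(trait_type)
  method <- match.arg(method)
  n <- length(phenotype)
  if (nrow(genotypes) != n) {
    stop("phenotype length does not match genotype rows", call. = FALSE)
  }
  m <- ncol(genotypes)
  ids <- colnames(genotypes) %||% sprintf("rs%05d", seq_len(m))
  if (is.null(snp_info)) {
    snp_info <- data.frame(snp_id = ids, chrom = "1",
                           pos = seq_len(m) * 1e6,
                           effect_allele = "A", other_allele = "G",
                           stringsAsFactors = FALSE)
  }
  eaf <- colMeans(genotypes) / 2
  # centered cross-products without materializing a centered matrix:
  # sum((g - gbar)^2) = sum(g^2) - n gbar^2, and for centered y,
  # sum((g - gbar) y) = sum(g y)
  sgg <- colSums(genotypes^2) - n * (2 * eaf)^2
  mono <- sgg <= 0
  sgg[mono] <- NA_real_
  beta <- se <- pval <- rep(NA_real_, m)

  if (trait_type == "continuous") {
    yc <- phenotype - mean(phenotype)
    syy <- sum(yc^2)
    sgy <- drop(crossprod(genotypes, yc))
    beta[!mono] <- sgy[!mono] / sgg[!mono]
    rss <- pmax(syy - sgy^2 / sgg, 0)
    se[!mono] <- sqrt((rss[!mono] / (n - 2)) / sgg[!mono])
    tval <- beta / se
    pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  } else if (method == "score") {
    pbar <- mean(phenotype)
    if (pbar <= 0 || pbar >= 1) {
      stop("binary phenotype has no variation", call. = FALSE)
    }
    U <- drop(crossprod(genotypes, phenotype - pbar))
    I <- pbar * (1 - pbar) * sgg
    beta[!mono] <- U[!mono] / I[!mono]
    se[!mono] <- 1 / sqrt(I[!mono])
    pval <- 2 * stats::pnorm(-abs(beta / se))
  } else {
    for (j in which(!mono)) {
      fit <- stats::glm.fit(cbind(1, genotypes[, j]), phenotype,
                            family = stats::binomial())
      sm <- chol2inv(chol(crossprod(
        sqrt(fit$weights) * cbind(1, genotypes[, j]))))
      beta[j] <- fit$coefficients[2L]
      se[j] <- sqrt(sm[2L, 2L])
    }
    pval <- 2 * stats::pnorm(-abs(beta / se))
  }
  # deterministic fits give rss = 0; keep se/p inside their open domains
  se <- pmax(se, 1e-300)
  pval <- pmax(pval, 1e-300)

  tab <- data.frame(snp_id = ids,
                    chrom = snp_info$chrom[match(ids, snp_info$snp_id)],
                    pos = snp_info$pos[match(ids, snp_info$snp_id)],
                    effect_allele =
                      snp_info$effect_allele[match(ids, snp_info$snp_id)],
                    other_allele =
                      snp_info$other_allele[match(ids, snp_info$snp_id)],
                    eaf = eaf, beta = beta, se = se, pval = pval, n = n,
                    stringsAsFactors = FALSE)
  flagged <- data.frame(snp_id = ids[mono],
                        reason = rep("monomorphic", sum(mono)),
                        stringsAsFactors = FALSE)
  out <- sumstats(tab[!mono, , drop = FALSE], trait_name = trait_name,
                  trait_type = trait_type, allow_empty = TRUE)
  attr(out, "flagged") <- flagged
  if (nrow(flagged) > 0L) {
    message(nrow(flagged), " monomorphic SNP(s) flagged and excluded for '",
            trait_name, "'")
  }
  out
}

#' Generate a complete two-sample GWAS study with known ground truth
#'
#' Simulates disjoint samples from the same generative law: each
#' exposure's GWAS runs in its own sample (as in separate consortium GWAS;
#' estimation errors across traits are therefore independent) and the
#' disease GWAS runs in a further sample. Instruments are the SNPs passing
#' `p_threshold` for each exposure in its discovery sample, so instrument
#' lists can overlap exactly as published lead-SNP lists do, and selected
#' effect sizes carry realistic winner's curse.
#'
#' @param config a [scenario_config()].
#' @param include_replication also simulate an independent third sample and
#'   re-estimate the exposure GWAS in it (for winner's-curse checks).
#' @return An `mr_study` list: `exposure_gwas` (named list of [sumstats]
#'   for `education` and `intelligence`, all SNPs), `outcome_gwas`
#'   ([sumstats] for `AD`), `instruments` (named list of snp_id vectors),
#'   `truth` (a `ground_truth`), `config`, and optionally
#'   `replication_gwas`.
#' @export
make_two_sample_study <- function(config, include_replication = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  arch <- .draw_architecture(config)
  info <- arch$info

  s1a <- .simulate_sample(arch, config, config$n_sample_exposure)
  ea_gwas <- gwas_summary(s1a$genotypes, s1a$ea, "continuous",
                          trait_name = "education", snp_info = info)
  s1b <- .simulate_sample(arch, config, config$n_sample_exposure)
  iq_gwas <- gwas_summary(s1b$genotypes, s1b$iq, "continuous",
                          trait_name = "intelligence", snp_info = info)
  s2 <- .simulate_sample(arch, config, config$n_sample_outcome)
  ad_gwas <- gwas_summary(s2$genotypes, s2$ad, "binary",
                          trait_name = "AD", snp_info = info)

  instruments <- list(
    education = ea_gwas$snp_id[ea_gwas$pval < config$p_threshold],
    intelligence = iq_gwas$snp_id[iq_gwas$pval < config$p_threshold])
  if (all(lengths(instruments) == 0L)) {
    stop("no instruments passed the selection threshold (",
         format(config$p_threshold), "): increase n_sample_exposure, ",
         "h2, or the threshold", call. = FALSE)
  }
  study <- list(exposure_gwas = list(education = ea_gwas,
                                     intelligence = iq_gwas),
                outcome_gwas = ad_gwas,
                instruments = instruments,
                truth = ground_truth(config, arch),
                config = config)
  if (include_replication) {
    s3 <- .simulate_sample(arch, config, config$n_sample_exposure)
    study$replication_gwas <- list(
      education = gwas_summary(s3$genotypes, s3$ea, "continuous",
                               trait_name = "education", snp_info = info),
      intelligence = gwas_summary(s3$genotypes, s3$iq, "continuous",
                                  trait_name = "intelligence",
                                  snp_info = info))
  }
  class(study) <- "mr_study"
  study
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf(
    "<mr_study> scenario %s: %d candidate SNPs, %d + %d instruments\n",
    x$config$scenario, nrow(x$truth$snps),
    length(x$instruments$education), length(x$instruments$intelligence)))
  invisible(x)
}
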
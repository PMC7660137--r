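test_that("scenario configuration validates its domain and applies
          scenario defaults", {
  cfg <- scenario_config("h")
  expect_equal(cfg$theta_iq_ea, 0.5)
  expect_equal(cfg$theta_ea_ad, -0.2)
  expect_equal(cfg$order, "iq_first")
  cfg_c <- scenario_config("c")
  expect_equal(cfg_c$theta_ea_iq, 0.5)
  expect_equal(cfg_c$order, "ea_first")
  # explicit arguments override scenario defaults
  expect_equal(scenario_config("h", theta_iq_ad = -0.1)$theta_iq_ad, -0.1)
  expect_error(scenario_config("h", maf_range = c(0, 0.5)))
  expect_error(scenario_config("h", ad_base_prevalence = 1.5))
  # a custom IQ->EA path flips the assignment order
  expect_equal(scenario_config("custom", theta_iq_ea = 0.3)$order,
               "iq_first")
})

test_that("an over-committed variance budget is a configuration error
          listing contributions", {
  cfg <- scenario_config("custom", h2_ea = 0.5, confounder_ea = 0.8,
                         n_sample_exposure = 200)
  expect_error(simulate_individuals(cfg), "variance budget")
  cfg2 <- scenario_config("h", theta_iq_ea = 0.9, h2_ea = 0.3,
                          n_sample_exposure = 200)
  expect_error(simulate_individuals(cfg2), "variance budget")
})

test_that("the null scenario yields mutually independent traits with
          unit-variance exposures", {
  cfg <- scenario_config("custom", n_sample_exposure = 8000, seed = 314)
  s <- simulate_individuals(cfg)
  n <- cfg$n_sample_exposure
  expect_lt(abs(cor(s$ea, s$iq)), 3 / sqrt(n))
  expect_lt(abs(cor(s$ea, s$ad)), 3 / sqrt(n))
  expect_lt(abs(cor(s$iq, s$ad)), 3 / sqrt(n))
  expect_equal(var(s$ea), 1, tolerance = 0.1)
  expect_equal(var(s$iq), 1, tolerance = 0.1)
  expect_equal(mean(s$ad), cfg$ad_base_prevalence, tolerance = 0.03)
})

test_that("structural paths reproduce their configured coefficients in
          the individual-level data", {
  cfg <- scenario_config("h", n_sample_exposure = 20000, seed = 11)
  s <- simulate_individuals(cfg)
  # EA = 0.5 IQ + rest: regression of EA on IQ recovers theta_iq_ea
  expect_equal(unname(coef(lm(s$ea ~ s$iq))[2]), 0.5, tolerance = 0.05)
  # genetic variance close to its h2 share
  gt <- s$truth
  v <- 2 * gt$snps$maf * (1 - gt$snps$maf)
  expect_equal(sum(v * gt$snps$delta_iq^2), cfg$h2_iq, tolerance = 0.35)
  # path-traced totals follow the two-stage assignment
  expect_equal(unname(gt$totals["iq_ad"]), -0.3 + 0.5 * -0.2)
  expect_equal(unname(gt$totals["ea_ad"]), -0.2)
  expect_equal(unname(gt$mvmr_direct), c(-0.2, -0.3))
})

test_that("per-SNP GWAS matches independently coded least-squares and
          Newton-logistic oracles", {
  set.seed(8)
  n <- 800
  G <- sapply(c(0.2, 0.4, 0.3), function(p) rbinom(n, 2, p))
  colnames(G) <- paste0("rs", 1:3)
  y <- 0.2 * G[, 1] + rnorm(n)
  tab <- gwas_summary(G, y, "continuous")
  for (j in 1:3) {
    fit <- lm(y ~ G[, j])
    expect_equal(tab$beta[j], unname(coef(fit)[2]), tolerance = 1e-8)
    expect_equal(tab$se[j], unname(summary(fit)$coefficients[2, 2]),
                 tolerance = 1e-8)
    expect_equal(tab$pval[j], summary(fit)$coefficients[2, 4],
                 tolerance = 1e-6)
  }
  expect_equal(tab$eaf, unname(colMeans(G) / 2))
  yb <- rbinom(n, 1, plogis(-1 + 0.3 * G[, 2]))
  tb <- gwas_summary(G, yb, "binary", method = "logistic")
  for (j in 1:3) {
    fit <- glm(yb ~ G[, j], family = binomial())
    expect_equal(tb$beta[j], unname(coef(fit)[2]), tolerance = 1e-6)
    expect_equal(tb$se[j], unname(summary(fit)$coefficients[2, 2]),
                 tolerance = 1e-4)
  }
  # the one-step score estimator agrees with the MLE at small effects
  tscore <- gwas_summary(G, yb, "binary", method = "score")
  expect_equal(tscore$beta, tb$beta, tolerance = 0.05)
})

test_that("a deterministic phenotype gives beta 1 with vanishing SE, and
          monomorphic SNPs are flagged out", {
  set.seed(12)
  G <- cbind(rs1 = rbinom(300, 2, 0.3), rs2 = 0)
  y <- G[, 1]
  expect_message(tab <- gwas_summary(G, y, "continuous"), "monomorphic")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$beta[1], 1, tolerance = 1e-12)
  expect_lt(tab$se[1], 1e-6)
  expect_equal(attr(tab, "flagged")$snp_id, "rs2")
})

test_that("null-GWAS p-values are calibrated at the 5% level", {
  set.seed(55)
  n <- 600
  m <- 1000
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(NULL, sprintf("s%d", 1:m)))
  y <- rnorm(n)
  tab <- gwas_summary(G, y, "continuous")
  rate <- mean(tab$pval < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / m))
})

test_that("the two-sample study is byte-identical under a repeated seed
          and exposes selected instruments with ground truth", {
  cfg <- scenario_config("c", n_sample_exposure = 3000,
                         n_sample_outcome = 3000, n_snps_ea = 30,
                         n_snps_iq = 30, p_threshold = 1e-3, seed = 99)
  s1 <- suppressMessages(make_two_sample_study(cfg))
  s2 <- suppressMessages(make_two_sample_study(cfg))
  expect_identical(s1$exposure_gwas$education$beta,
                   s2$exposure_gwas$education$beta)
  expect_identical(s1$outcome_gwas$beta, s2$outcome_gwas$beta)
  expect_identical(s1$instruments, s2$instruments)
  expect_true(all(s1$instruments$education %in%
                    s1$exposure_gwas$education$snp_id))
  expect_s3_class(s1$exposure_gwas$education, "sumstats")
  expect_equal(attr(s1$outcome_gwas, "trait_type"), "binary")
  # selection error is explicit when nothing passes
  cfg_bad <- scenario_config("custom", h2_ea = 1e-6, h2_iq = 1e-6,
                             n_sample_exposure = 500,
                             n_sample_outcome = 500,
                             p_threshold = 1e-12, seed = 1)
  expect_error(suppressMessages(make_two_sample_study(cfg_bad)),
               "threshold")
})

test_that("simulated summary statistics round-trip through the delimited
          reader", {
  cfg <- scenario_config("h", n_sample_exposure = 2000,
                         n_sample_outcome = 2000, n_snps_ea = 20,
                         n_snps_iq = 20, seed = 5)
  st <- suppressMessages(make_two_sample_study(cfg))
  path <- tempfile(fileext = ".tsv")
  data.table::fwrite(as.data.frame(st$outcome_gwas), path, sep = "\t")
  back <- read_sumstats(path, trait_name = "AD", trait_type = "binary")
  expect_equal(back$beta, st$outcome_gwas$beta, tolerance = 1e-10)
  expect_equal(back$snp_id, st$outcome_gwas$snp_id)
})

test_that("selected instruments carry winner's curse: discovery effects
          exceed replication effects on average", {
  set.seed(2024)
  diffs <- numeric(120)
  for (r in seq_len(120)) {
    cfg <- scenario_config("custom", h2_ea = 0.05, n_snps_ea = 40,
                           n_snps_iq = 2, n_sample_exposure = 2500,
                           n_sample_outcome = 500, p_threshold = 1e-3,
                           seed = 5000 + r)
    st <- suppressMessages(make_two_sample_study(cfg,
                                                 include_replication = TRUE))
    sel <- st$instruments$education
    if (length(sel) == 0) next
    disc <- st$exposure_gwas$education
    repl <- st$replication_gwas$education
    diffs[r] <- mean(abs(disc$beta[match(sel, disc$snp_id)])) -
      mean(abs(repl$beta[match(sel, repl$snp_id)]))
  }
  # mean discovery |beta| exceeds replication |beta| by more than 3 MC SEs
  expect_gt(mean(diffs), 3 * sd(diffs) / sqrt(length(diffs)))
  expect_gt(mean(diffs > 0), 0.7)
})

test_that("balanced vs directional pleiotropy is recovered by the Egger
          intercept on simulated studies", {
  # directional pleiotropy: intercept recovers the mean SNP effect
  cfg_dir <- scenario_config("custom", pleiotropy_mean = 0.04,
                             pleiotropy_sd = 0.01, h2_ea = 0.15,
                             n_sample_exposure = 30000,
                             n_sample_outcome = 30000, seed = 909)
  st <- suppressMessages(make_two_sample_study(cfg_dir))
  h <- harmonize_pair(
    mrpath:::.instrument_table(st, "education"), st$outcome_gwas)
  eg <- mr_egger(h)
  expect_lt(abs(eg$intercept - 0.04), 3 * eg$intercept_se)
  expect_gt(eg$intercept, 0.01)
  # balanced pleiotropy: intercept within 3 MC SEs of zero
  cfg_bal <- scenario_config("custom", pleiotropy_mean = 0,
                             pleiotropy_sd = 0.04, h2_ea = 0.15,
                             n_sample_exposure = 30000,
                             n_sample_outcome = 30000, seed = 910)
  st2 <- suppressMessages(make_two_sample_study(cfg_bal))
  h2 <- harmonize_pair(
    mrpath:::.instrument_table(st2, "education"), st2$outcome_gwas)
  eg2 <- mr_egger(h2)
  expect_lt(abs(eg2$intercept), 3 * eg2$intercept_se)
})

test_that("scenario configurations load from YAML and JSON", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("scenario: c", "n_snps_ea: 10", "seed: 3"), y)
  cfg <- read_scenario_config(y)
  expect_equal(cfg$scenario, "c")
  expect_equal(cfg$n_snps_ea, 10L)
  j <- tempfile(fileext = ".json")
  jsonlite::write_json(list(scenario = "a", seed = 4), j,
                       auto_unbox = TRUE)
  expect_equal(read_scenario_config(j)$scenario, "a")
})
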
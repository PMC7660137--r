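# mrpath

Two-sample and multivariable Mendelian randomization (MR) from GWAS
summary statistics, with a built-in structural GWAS simulator so every
estimator can be validated by parameter recovery against known ground
truth.

The package is aimed at epidemiologists disentangling the effects of two
strongly correlated exposures — the motivating application is education
and intelligence as determinants of Alzheimer's disease risk — where
univariable MR is ambiguous: confounding of one exposure by the other,
mediation, and horizontal pleiotropy all produce the same univariable
signal. It implements:

* **IO and harmonization**: validated summary-statistic tables with
  explicit column maps (`read_sumstats()`), allele harmonization with
  palindrome handling (`harmonize_pair()`), instrument-overlap exclusion,
  greedy LD clumping (`greedy_clump()`), and assembly of two-exposure
  datasets (`build_mvmr_dataset()`).
* **Estimation**: per-SNP Wald ratios; inverse-variance-weighted (IVW)
  regression through the origin
  `beta = sum(w_j bx_j by_j) / sum(w_j bx_j^2)`, `w_j = 1/se_yj^2`, with
  fixed or multiplicative random-effects standard errors (floored at the
  fixed-effect SE); MR-Egger regression, whose free intercept estimates
  average directional pleiotropy; multivariable IVW for direct effects of
  each exposure conditional on the other; odds-scale reporting for binary
  outcomes.
* **Diagnostics**: Steiger directionality filtering on per-SNP variance
  explained, instrument F statistics, Cochran's Q heterogeneity,
  leave-one-out influence, funnel-plot data with an asymmetry summary.
* **Simulation**: `scenario_config()` / `make_two_sample_study()`
  generate two-sample GWAS summary statistics under explicit causal
  structures (confounding, mediation, pleiotropy, bidirectional and
  joint effects) with instrument selection, winner's curse, and full
  ground truth attached.
* **Orchestration**: `run_bidirectional()`, `run_ad_analysis()` and the
  config-driven `mr_run()` produce estimate tables, per-stage SNP
  attrition counts, a sensitivity suite and a JSON run manifest; a thin
  command-line front end lives at `exec/mr`.

See the methods vignette (`vignettes/mr-methods.Rmd`) for the model,
its assumptions, and every numerical convention.

## Worked example

Simulate a study in which intelligence raises educational attainment
(0.5 SD/SD) and both traits lower disease odds directly (log-odds -0.2
and -0.3 per SD), then run the full analysis:

```r
library(mrpath)

cfg   <- scenario_config("h", seed = 1)   # joint-effects scenario
study <- make_two_sample_study(cfg)
run_ad_analysis(study)
#> <mr_report>
#>                    analysis   method n_snps    beta     se ci_low ci_high
#>       univariable_education      ivw     53 -0.1910 0.0689 -0.326 -0.0563
#>    univariable_intelligence      ivw     41 -0.3940 0.0737 -0.539 -0.2500
#>     multivariable_education mvmr_ivw     81 -0.0937 0.0685 -0.228  0.0406
#>  multivariable_intelligence mvmr_ivw     81 -0.3550 0.0780 -0.508 -0.2020
#>      pval    or or_ci_low or_ci_high
#>  5.47e-03 0.826     0.721      0.945
#>  8.83e-08 0.674     0.584      0.779
#>  1.71e-01 0.911     0.796      1.040
#>  5.37e-06 0.701     0.602      0.817
```

Reading the output: 53 and 41 SNPs passed selection as instruments for
education and intelligence, and the multivariable analysis uses their
81-SNP clumped union. The univariable rows are *total* effects —
education's -0.19 log-odds (OR 0.83) mixes its direct effect with the
signal flowing through intelligence — while the multivariable rows
condition each exposure on the other and track the true direct effects
of -0.2 and -0.3 (here -0.09 with a CI spanning zero, and -0.36; any
single replicate scatters around the truth within its interval). The
same study object feeds
`run_bidirectional(study)`, which excludes overlapping instruments,
estimates both exposure-on-exposure directions and re-estimates after
Steiger filtering.

With real data, build the study from delimited GWAS exports instead:

```r
ed <- read_sumstats("education.tsv",
                    column_map = c(snp_id = "MarkerName", beta = "Beta"),
                    trait_name = "education", trait_type = "continuous")
iq <- read_sumstats("intelligence.tsv", trait_name = "intelligence")
ad <- read_sumstats("ad.tsv", trait_name = "AD", trait_type = "binary")
study <- mr_study(list(education = ed, intelligence = iq), ad,
                  instruments = list(education = ed_lead_snps,
                                     intelligence = iq_lead_snps))
run_ad_analysis(study)
```

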
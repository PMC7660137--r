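#' Assemble an MR study from real summary-statistic tables
#'
#' The container consumed by [run_bidirectional()] and [run_ad_analysis()].
#' Simulated studies come from [make_two_sample_study()]; real-data studies
#' are assembled here from tables read with [read_sumstats()]. Each
#' exposure table must hold the associations of *all* candidate SNPs (both
#' exposures' instruments) with that trait, so cross-exposure associations
#' can be looked up; the instrument lists say which SNPs instrument which
#' exposure.
#'
#' @param exposure_gwas named list of two [sumstats] tables (one per
#'   exposure trait).
#' @param outcome_gwas [sumstats] table for the outcome.
#' @param instruments named list (same names) of instrument snp_id vectors;
#'   defaults to each full table's SNPs.
#' @return An `mr_study` object.
#' @export
mr_study <- function(exposure_gwas, outcome_gwas, instruments = NULL) {
  stopifnot(length(exposure_gwas) == 2L, !is.null(names(exposure_gwas)))
  if (is.null(instruments)) {
    instruments <- lapply(exposure_gwas, function(x) x$snp_id)
  }
  stopifnot(setequal(names(instruments), names(exposure_gwas)))
  structure(list(exposure_gwas = exposure_gwas,
                 outcome_gwas = outcome_gwas,
                 instruments = instruments[names(exposure_gwas)],
                 truth = NULL, config = NULL),
            class = "mr_study")
}

.instrument_table <- function(study, trait) {
  tab <- study$exposure_gwas[[trait]]
  .subset_sumstats(tab, tab$snp_id %in% study$instruments[[trait]])
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Bidirectional univariable MR between the two exposures
#'
#' Runs the exposure-on-exposure analysis in both directions: excludes
#' instruments shared between the two GWAS, harmonizes each instrument set
#' against the other trait's associations, estimates both IVW effects,
#' then Steiger-filters each direction (removing instruments explaining
#' more variance in the outcome trait than in their own) and re-estimates.
#'
#' @param study an `mr_study`.
#' @param weights_model,palindrome_policy,r2_method passed through to
#'   [mr_ivw()], [harmonize_pair()] and [steiger_filter()].
#' @return list of class `mr_report`: `estimates` (rows for each direction,
#'   unfiltered and Steiger-filtered), `steiger` (per-direction records),
#'   `attrition` (per-stage SNP counts), `overlap` (excluded snp_ids).
#' @export
run_bidirectional <- function(study,
                              weights_model = "multiplicative_random",
                              palindrome_policy = "drop_ambiguous",
                              r2_method = "eaf_beta") {
  traits <- names(study$exposure_gwas)
  ins <- lapply(traits, function(tr) .instrument_table(study, tr))
  names(ins) <- traits
  ov <- .stage("overlap_exclusion", exclude_overlap(ins[[1]], ins[[2]]))
  ins_clean <- list(ov$a, ov$b)
  names(ins_clean) <- traits

  estimates <- list()
  steiger <- list()
  attrition <- list()
  for (i in 1:2) {
    exp_tr <- traits[i]; out_tr <- traits[3 - i]
    dir_tag <- paste0(exp_tr, "_on_", out_tr)
    h <- .stage(paste0("harmonize_", dir_tag),
                harmonize_pair(ins_clean[[exp_tr]],
                               study$exposure_gwas[[out_tr]],
                               palindrome_policy = palindrome_policy))
    est <- .stage(paste0("ivw_", dir_tag),
                  mr_ivw(h, weights_model = weights_model))
    est$analysis <- dir_tag
    sf <- .stage(paste0("steiger_", dir_tag),
                 steiger_filter(h, r2_method = r2_method))
    est_f <- .stage(paste0("ivw_filtered_", dir_tag),
                    mr_ivw(sf$dataset, weights_model = weights_model))
    est_f$analysis <- paste0(dir_tag, "_steiger_filtered")
    estimates[[dir_tag]] <- rbind(est, est_f)
    steiger[[dir_tag]] <- sf$records
    attrition[[dir_tag]] <- data.frame(
      analysis = dir_tag,
      instruments = nrow(ins[[exp_tr]]),
      after_overlap_exclusion = nrow(ins_clean[[exp_tr]]),
      retained_after_harmonization = attr(h, "counts")[["retained"]],
      steiger_flagged = sum(!sf$records$direction_ok),
      steiger_retained = sum(sf$records$direction_ok))
  }
  structure(list(estimates = do.call(rbind, unname(estimates)),
                 steiger = steiger,
                 attrition = do.call(rbind, unname(attrition)),
                 overlap = ov$overlap),
            class = "mr_report")
}

#' Total and independent effects of both exposures on the disease outcome
#'
#' Univariable IVW of each exposure on the outcome — instruments shared
#' between the two exposure GWAS are deliberately retained, since the point
#' of the univariable analyses is to show the estimates a typical single-
#' exposure analysis would report — followed by multivariable IVW on the
#' merged, clumped instrument union (direct effects conditional on the
#' other exposure), odds-scale conversion, and the sensitivity suite:
#' MR-Egger, Cochran's Q, leave-one-out and funnel data per univariable
#' analysis.
#'
#' @param study an `mr_study` whose outcome is binary.
#' @param weights_model,palindrome_policy passed through.
#' @param ld optional [ld_info()] for clumping the multivariable union.
#' @param sensitivity run the sensitivity suite (default TRUE).
#' @return list of class `mr_report`: `estimates` (univariable and
#'   multivariable rows on both log-odds and odds scales), `sensitivity`
#'   (per-exposure `egger`, `q`, `loo`, `funnel`), `attrition`, and
#'   `mvmr_counts` (instrument provenance of the multivariable set).
#' @export
run_ad_analysis <- function(study,
                            weights_model = "multiplicative_random",
                            palindrome_policy = "drop_ambiguous",
                            ld = NULL, sensitivity = TRUE) {
  traits <- names(study$exposure_gwas)
  outcome <- study$outcome_gwas
  estimates <- list()
  sens <- list()
  attrition <- list()
  for (tr in traits) {
    instab <- .instrument_table(study, tr)
    h <- .stage(paste0("harmonize_", tr),
                harmonize_pair(instab, outcome,
                               palindrome_policy = palindrome_policy))
    est <- .stage(paste0("ivw_", tr), mr_ivw(h, weights_model))
    est$analysis <- paste0("univariable_", tr)
    estimates[[tr]] <- est
    attrition[[tr]] <- data.frame(
      analysis = paste0("univariable_", tr),
      instruments = nrow(instab),
      retained_after_harmonization = attr(h, "counts")[["retained"]])
    if (sensitivity) {
      sens[[tr]] <- list(
        egger = .stage(paste0("egger_", tr), mr_egger(h)),
        q = .stage(paste0("cochrans_q_", tr), cochrans_q(h)),
        loo = .stage(paste0("leave_one_out_", tr), leave_one_out(h)),
        funnel = .stage(paste0("funnel_", tr), funnel_data(h)))
    }
  }
  mv <- .stage("build_mvmr",
               build_mvmr_dataset(.instrument_table(study, traits[1]),
                                  .instrument_table(study, traits[2]),
                                  cross_assoc = study$exposure_gwas,
                                  outcome = outcome, ld = ld,
                                  palindrome_policy = palindrome_policy))
  mv_est <- .stage("mvmr_ivw", mr_mvmr_ivw(mv))
  mv_est$analysis <- paste0("multivariable_", mv_est$exposure)
  estimates$mvmr <- mv_est

  all_est <- do.call(rbind, unname(estimates))
  all_est <- .stage("odds_scale", to_odds_scale(all_est))
  structure(list(estimates = all_est,
                 sensitivity = sens,
                 attrition = do.call(rbind, unname(attrition)),
                 mvmr_counts = attr(mv, "counts")),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, digits = 3, ...) {
  cat("<mr_report>\n")
  df <- x$estimates
  keep <- intersect(c("analysis", "method", "n_snps", "beta", "se",
                      "ci_low", "ci_high", "pval", "or", "or_ci_low",
                      "or_ci_high"), names(df))
  df <- df[, keep]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  if (!is.null(x$attrition)) {
    cat("\nSNP attrition by stage:\n")
    print(x$attrition, row.names = FALSE)
  }
  invisible(x)
}

#' Run a full configured analysis and write a reproducible run directory
#'
#' Accepts a YAML (or JSON) configuration describing either a simulation
#' scenario (`scenario:` block of [scenario_config()] arguments) or real
#' input tables (`data:` block with per-table `path`, `column_map`, trait
#' metadata and instrument lists), runs the bidirectional and/or
#' disease analyses, and writes a deterministic directory layout:
#' `tables/` (estimates), `diagnostics/` (Steiger, Q, leave-one-out,
#' funnel TSVs), `manifest.json` and `log.txt`.
#'
#' @param config path to a config file, or an equivalent list.
#' @param out output directory (config key `output_dir` used when absent).
#' @param seed overrides the config seed when supplied.
#' @return Invisibly, a list with the reports and the output directory.
#' @export
mr_run <- function(config, out = NULL, seed = NULL) {
  cfg <- if (is.character(config)) .read_analysis_config(config)
         else config
  out <- out %||% cfg$output_dir
  if (is.null(out)) {
    stop("no output directory: supply `out` or config key `output_dir`",
         call. = FALSE)
  }
  if (!is.null(cfg$scenario) && !is.null(cfg$data)) {
    stop("config must provide exactly one of 'scenario' or 'data'",
         call. = FALSE)
  }
  dir.create(file.path(out, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out, "diagnostics"), showWarnings = FALSE)
  log_lines <- character()
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  if (!is.null(cfg$scenario)) {
    sc_args <- cfg$scenario
    if (!is.null(seed)) sc_args$seed <- seed
    scfg <- do.call(scenario_config, sc_args)
    log("simulating scenario ", scfg$scenario, " (seed ", scfg$seed, ")")
    study <- make_two_sample_study(scfg)
    used_seed <- scfg$seed
  } else {
    if (is.null(cfg$data)) {
      stop("config must provide a 'scenario' or 'data' block",
           call. = FALSE)
    }
    study <- .study_from_paths(cfg$data)
    used_seed <- seed
  }
  log("instruments: ",
      paste(names(study$instruments), lengths(study$instruments),
            sep = "=", collapse = ", "))

  reports <- list()
  run_bidir <- cfg$run_bidirectional %||% TRUE
  run_ad <- cfg$run_outcome %||%
    (attr(study$outcome_gwas, "trait_type") == "binary")
  weights <- cfg$weights_model %||% "multiplicative_random"
  if (isTRUE(run_bidir)) {
    log("bidirectional exposure analysis")
    reports$bidirectional <- run_bidirectional(study,
                                               weights_model = weights)
    write_report(reports$bidirectional$estimates,
                 file.path(out, "tables", "bidirectional.tsv"),
                 config = cfg, seed = used_seed)
    for (nm in names(reports$bidirectional$steiger)) {
      data.table::fwrite(reports$bidirectional$steiger[[nm]],
                         file.path(out, "diagnostics",
                                   paste0("steiger_", nm, ".tsv")),
                         sep = "\t")
    }
  }
  if (isTRUE(run_ad)) {
    log("outcome analysis (univariable + multivariable)")
    reports$outcome <- run_ad_analysis(
      study, weights_model = weights,
      sensitivity = !isTRUE(cfg$skip_sensitivity))
    write_report(reports$outcome$estimates,
                 file.path(out, "tables", "outcome.tsv"),
                 config = cfg, seed = used_seed)
    for (tr in names(reports$outcome$sensitivity)) {
      s <- reports$outcome$sensitivity[[tr]]
      data.table::fwrite(s$loo,
                         file.path(out, "diagnostics",
                                   paste0("loo_", tr, ".tsv")), sep = "\t")
      data.table::fwrite(s$funnel$data,
                         file.path(out, "diagnostics",
                                   paste0("funnel_", tr, ".tsv")),
                         sep = "\t")
      data.table::fwrite(
        data.frame(trait = tr, Q = s$q$Q, df = s$q$df, pval = s$q$pval,
                   egger_intercept = s$egger$intercept,
                   egger_intercept_pval = s$egger$intercept_pval),
        file.path(out, "diagnostics", paste0("q_egger_", tr, ".tsv")),
        sep = "\t")
    }
  }
  manifest <- list(config = cfg, seed = used_seed,
                   instruments = lapply(study$instruments, length),
                   versions = list(
                     mrpath = as.character(utils::packageVersion("mrpath")),
                     R = paste(R.version$major, R.version$minor,
                               sep = ".")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("done")
  writeLines(log_lines, file.path(out, "log.txt"))
  invisible(list(reports = reports, out = out))
}

.read_analysis_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

.study_from_paths <- function(data_cfg) {
  need <- c("exposure1", "exposure2", "outcome")
  missing_keys <- setdiff(need, names(data_cfg))
  if (length(missing_keys) > 0L) {
    stop("config 'data' block missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  read_one <- function(blk) {
    if (is.null(blk$path) || !file.exists(blk$path)) {
      stop("input table not found: ", blk$path %||% "<missing path>",
           call. = FALSE)
    }
    read_sumstats(blk$path, column_map = blk$column_map,
                  trait_name = blk$trait_name,
                  trait_type = blk$trait_type %||% "continuous",
                  trait_sd_label = blk$trait_sd_label %||% NA_character_)
  }
  e1 <- read_one(data_cfg$exposure1)
  e2 <- read_one(data_cfg$exposure2)
  ou <- read_one(data_cfg$outcome)
  instruments <- stats::setNames(
    list(data_cfg$exposure1$instruments %||% e1$snp_id,
         data_cfg$exposure2$instruments %||% e2$snp_id),
    c(trait_name(e1), trait_name(e2)))
  mr_study(stats::setNames(list(e1, e2),
                           c(trait_name(e1), trait_name(e2))),
           ou, instruments)
}

#' Regenerate human-readable tables from a completed run directory
#'
#' Reads the manifest and stored estimate tables of an [mr_run()] output
#' directory and rewrites each table under `tables/regenerated/` without
#' any recomputation (byte-identical content), returning the printed
#' summary invisibly. Used to re-render results from an archived run.
#'
#' @param run_dir directory previously written by [mr_run()].
#' @return Invisibly, named list of the tables read.
#' @export
mr_report_run <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("not a run directory (no manifest.json): ", run_dir,
         call. = FALSE)
  }
  tabs <- list.files(file.path(run_dir, "tables"), pattern = "\\.tsv$",
                     full.names = TRUE)
  tabs <- tabs[!grepl("regenerated", tabs)]
  regen_dir <- file.path(run_dir, "tables", "regenerated")
  dir.create(regen_dir, showWarnings = FALSE)
  out <- list()
  for (tb in tabs) {
    raw <- readLines(tb)
    writeLines(raw, file.path(regen_dir, basename(tb)))
    out[[basename(tb)]] <- read_report(tb)
    cat("==", basename(tb), "==\n")
    print(utils::head(out[[basename(tb)]], 20L))
  }
  invisible(out)
}
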
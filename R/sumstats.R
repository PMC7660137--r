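#' GWAS summary-statistic tables
#'
#' A `sumstats` object is a data frame with one row per biallelic SNP and the
#' canonical columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, carrying the trait it
#' describes in attributes (`trait_name`, `trait_type`, `trait_sd_label`).
#' Betas are per copy of the effect allele: standard-deviation units for
#' continuous traits, log odds ratios for binary traits. Positions are
#' 1-based base pairs and are never reinterpreted.
#'
#' Rows violating the per-variant invariants (single-base A/C/G/T alleles,
#' `effect_allele != other_allele`, `se > 0`, `0 < pval <= 1`, `eaf` in
#' (0, 1) when present, `n > 0`) are rejected, not repaired; rejected rows
#' and their reasons are kept in the `rejections` attribute so that
#' `nrow(kept) + nrow(rejected)` always equals the input row count. Missing
#' EAF is tolerated on input but any operation that needs EAF fails loudly
#' rather than imputing.
#'
#' @param x data frame with the canonical columns above (`eaf` may be `NA`).
#' @param trait_name trait label, e.g. `"education"`.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param trait_sd_label free-text unit note, e.g. `"3.6 years"`.
#' @param allow_empty allow a zero-row table (in-memory construction only).
#' @return A `sumstats` data frame; rejected rows in `attr(, "rejections")`.
#' @export
sumstats <- function(x, trait_name, trait_type = c("continuous", "binary"),
                     trait_sd_label = NA_character_, allow_empty = FALSE) {
  trait_type <- match.arg(trait_type)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.sumstats_cols, names(x))
  if (length(missing_cols) > 0L) {
    stop("summary-statistic table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, .sumstats_cols]
  if (nrow(x) == 0L && !allow_empty) {
    stop("summary-statistic table for '", trait_name, "' is empty",
         call. = FALSE)
  }
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    x[[col]] <- as.numeric(x[[col]])
  }

  reason <- .row_rejection_reason(x)
  keep <- is.na(reason)
  rejections <- data.frame(snp_id = x$snp_id[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  x <- x[keep, , drop = FALSE]
  rownames(x) <- NULL
  if (nrow(x) == 0L && !allow_empty) {
    stop("no valid rows remain for trait '", trait_name, "' (",
         nrow(rejections), " rejected)", call. = FALSE)
  }
  dup <- unique(x$snp_id[duplicated(x$snp_id)])
  if (length(dup) > 0L) {
    stop("duplicate snp_id in '", trait_name, "' table: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  if (nrow(rejections) > 0L) {
    message(nrow(rejections), " row(s) rejected for trait '", trait_name,
            "' (see attr(x, 'rejections'))")
  }
  structure(x,
            class = c("sumstats", "data.frame"),
            trait_name = trait_name,
            trait_type = trait_type,
            trait_sd_label = trait_sd_label,
            rejections = rejections)
}

.sumstats_cols <- c("snp_id", "chrom", "pos", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "pval", "n")

# One reason per row, NA when the row is valid. Checked in a fixed order so
# the logged reason is deterministic.
.row_rejection_reason <- function(x) {
  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    ifelse(is.na(reason) & bad, why, reason)
  }
  bases <- c("A", "C", "G", "T")
  reason <- flag(is.na(x$snp_id) | x$snp_id == "", "missing snp_id")
  reason <- flag(!(x$effect_allele %in% bases),
                 "effect_allele not a single base in {A,C,G,T}")
  reason <- flag(!(x$other_allele %in% bases),
                 "other_allele not a single base in {A,C,G,T}")
  reason <- flag(x$effect_allele == x$other_allele,
                 "effect_allele equals other_allele")
  reason <- flag(is.na(x$beta), "missing beta")
  reason <- flag(is.na(x$se) | x$se <= 0, "se not positive")
  reason <- flag(is.na(x$pval) | x$pval <= 0 | x$pval > 1,
                 "pval outside (0, 1]")
  reason <- flag(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1),
                 "eaf outside (0, 1)")
  reason <- flag(is.na(x$n) | x$n <= 0, "n not positive")
  reason <- flag(is.na(x$pos) | x$pos < 1 | x$pos != round(x$pos),
                 "pos not a positive 1-based integer")
  reason
}

#' Read a GWAS summary-statistic table from delimited text
#'
#' Reads a tab- or comma-delimited file (delimiter auto-detected by
#' [data.table::fread()]), renames source columns to the canonical schema via
#' `column_map`, and validates every row. Numbers are parsed at full double
#' precision; scientific notation is accepted. Alleles are upper-cased.
#'
#' @param path file path.
#' @param column_map named character vector or list mapping canonical field
#'   names (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pval`, `n`) to the column names used in the file.
#'   Fields whose source column already carries the canonical name may be
#'   omitted; `eaf` may be omitted entirely (recorded as missing).
#' @param trait_name,trait_type,trait_sd_label trait metadata, see
#'   [sumstats()].
#' @return A validated [sumstats] table, row order preserved.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name,
                          trait_type = c("continuous", "binary"),
                          trait_sd_label = NA_character_) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  raw <- data.table::fread(path, sep = "auto", header = TRUE,
                           data.table = FALSE)
  if (nrow(raw) == 0L) {
    stop("summary-statistics file is empty: ", path, call. = FALSE)
  }
  column_map <- .complete_column_map(column_map, names(raw))
  missing_src <- setdiff(unlist(column_map), names(raw))
  if (length(missing_src) > 0L) {
    stop("column map refers to column(s) absent from ", path, ": ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in .sumstats_cols) {
    src <- column_map[[field]]
    out[[field]] <- if (is.null(src)) NA else raw[[src]]
  }
  sumstats(out, trait_name = trait_name, trait_type = trait_type,
           trait_sd_label = trait_sd_label)
}

# Canonical fields default to same-named source columns; only eaf may be
# absent altogether.
.complete_column_map <- function(column_map, available) {
  column_map <- as.list(column_map)
  unknown <- setdiff(names(column_map), .sumstats_cols)
  if (length(unknown) > 0L) {
    stop("column map contains unknown canonical field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (field in .sumstats_cols) {
    if (is.null(column_map[[field]])) {
      if (field %in% available) {
        column_map[[field]] <- field
      } else if (field != "eaf") {
        stop("no source column for required field '", field,
             "': supply it in column_map", call. = FALSE)
      }
    }
  }
  column_map
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s (%s), %d SNPs",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej) > 0L) cat(sprintf(", %d rejected", nrow(rej)))
  cat("\n")
  print(as.data.frame(utils::head(x, 6L)))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Write MR results and a machine-readable run manifest
#'
#' Writes the estimate table as TSV at full double precision (round-trip
#' safe) together with a JSON manifest recording configuration, seed and
#' versions so a run can be audited and regenerated.
#'
#' @param results data frame of estimates, e.g. rows produced by
#'   [mr_ivw()], [mr_egger()], [mr_mvmr_ivw()] (any data frame with a
#'   `method` column).
#' @param path output TSV path; the manifest is written alongside it as
#'   `<path without extension>_manifest.json`.
#' @param config optional list recorded verbatim in the manifest.
#' @param seed optional integer seed recorded in the manifest.
#' @return Invisibly, paths of the files written.
#' @export
write_report <- function(results, path, config = NULL, seed = NULL) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) {
    stop("no results to write", call. = FALSE)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    data.table::fwrite(results, path, sep = "\t", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write report to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  manifest_path <- paste0(sub("\\.[A-Za-z0-9]+$", "", path),
                          "_manifest.json")
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seed = seed,
    n_rows = nrow(results),
    methods = unique(as.character(results$method)),
    versions = list(
      mrpath = as.character(utils::packageVersion("mrpath")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(c(table = path, manifest = manifest_path))
}

#' Read back a results table written by [write_report()]
#'
#' @param path TSV path previously passed to [write_report()].
#' @return data frame with numeric fields at full stored precision.
#' @export
read_report <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE)
}

# Accessors used throughout the package ---------------------------------

#' @export
trait_name <- function(x) attr(x, "trait_name")

#' @export
trait_type <- function(x) attr(x, "trait_type")
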
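#' Allele harmonization, overlap exclusion and LD clumping
#'
#' Two-sample MR needs every instrument's exposure and outcome associations
#' expressed per copy of the *same* effect allele. [harmonize_pair()] aligns
#' an outcome table to an exposure table SNP by SNP:
#'
#' * alleles identical as given: row copied unchanged;
#' * outcome alleles swapped relative to the exposure: outcome beta negated
#'   and EAF reflected (`eaf -> 1 - eaf`), flagged `allele_swapped`;
#' * alleles match only after complementing (A<->T, C<->G): reported on the
#'   opposite strand, complemented and flagged `strand_flipped` (attempted
#'   only after direct and swapped matching both fail);
#' * palindromic SNPs (A/T or C/G pairs), where strand cannot be resolved
#'   from allele letters: under `"drop_ambiguous"` the row is dropped when
#'   either trait's EAF falls inside `eaf_ambiguity_band` (or is missing),
#'   otherwise aligned by EAF concordance (same side of 0.5 keeps the row as
#'   is, opposite sides swap it); under `"infer_by_eaf"` alignment always
#'   uses EAF concordance and a missing EAF is a hard error naming the SNP;
#' * irreconcilable allele sets are dropped and flagged
#'   `dropped_incompatible`.
#'
#' SNPs absent from the outcome table are dropped and counted, so
#' `retained + dropped + missing_from_outcome` always equals the number of
#' exposure instruments (conservation of rows).
#'
#' @param exposure,outcome validated [sumstats] tables; the exposure table
#'   holds the instruments.
#' @param palindrome_policy `"drop_ambiguous"` (default) or `"infer_by_eaf"`.
#' @param eaf_ambiguity_band numeric length-2, the EAF interval treated as
#'   uninformative for palindrome resolution; default `c(0.42, 0.58)`.
#' @return An `mr_dataset`: one row per retained SNP with columns
#'   `snp_id`, `effect_allele`, `other_allele`, `beta_exposure`,
#'   `se_exposure`, `eaf_exposure`, `eaf_outcome`, `beta_outcome`,
#'   `se_outcome`, `n_exposure`, `n_outcome`, `flag`; attributes carry trait
#'   names/types, the dropped rows and the attrition counts.
#' @export
harmonize_pair <- function(exposure, outcome,
                           palindrome_policy = c("drop_ambiguous",
                                                 "infer_by_eaf"),
                           eaf_ambiguity_band = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  n_missing <- nrow(exposure) - length(shared)
  if (length(shared) == 0L) {
    stop("no shared SNPs between '", trait_name(exposure), "' and '",
         trait_name(outcome), "'", call. = FALSE)
  }
  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  act <- character(length(shared))
  for (i in seq_along(shared)) {
    act[i] <- .align_action(
      ex$effect_allele[i], ex$other_allele[i],
      ou$effect_allele[i], ou$other_allele[i],
      ex$eaf[i], ou$eaf[i],
      palindrome_policy, eaf_ambiguity_band, shared[i])
  }

  swap <- act %in% c("swap", "flip_swap")
  flip <- act %in% c("flip", "flip_swap")
  beta_out <- ifelse(swap, -ou$beta, ou$beta)
  eaf_out <- ifelse(swap, 1 - ou$eaf, ou$eaf)
  flag <- rep("unchanged", length(act))
  flag[swap] <- "allele_swapped"
  flag[flip & !swap] <- "strand_flipped"
  flag[flip & swap] <- "strand_flipped"  # swap recorded via beta/eaf change
  flag[act == "drop_palindromic"] <- "dropped_palindromic"
  flag[act == "drop_incompatible"] <- "dropped_incompatible"

  rows <- data.frame(
    snp_id = shared,
    chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_exposure = ex$beta, se_exposure = ex$se,
    eaf_exposure = ex$eaf, eaf_outcome = eaf_out,
    beta_outcome = beta_out, se_outcome = ou$se,
    pval_exposure = ex$pval, pval_outcome = ou$pval,
    n_exposure = ex$n, n_outcome = ou$n,
    flag = flag, stringsAsFactors = FALSE)
  kept <- !startsWith(rows$flag, "dropped")
  counts <- c(
    exposure_instruments = nrow(exposure),
    shared = length(shared),
    missing_from_outcome = n_missing,
    retained = sum(kept),
    dropped_palindromic = sum(rows$flag == "dropped_palindromic"),
    dropped_incompatible = sum(rows$flag == "dropped_incompatible"))
  out <- rows[kept, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    stop("harmonization retained no SNPs for '", trait_name(exposure),
         "' vs '", trait_name(outcome), "'", call. = FALSE)
  }
  structure(out,
            class = c("mr_dataset", "data.frame"),
            exposure_names = trait_name(exposure),
            exposure_types = trait_type(exposure),
            outcome_name = trait_name(outcome),
            outcome_type = trait_type(outcome),
            dropped = rows[!kept, , drop = FALSE],
            counts = counts)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) unname(.complement[a1]) == a2

# Decide how one outcome row must be transformed to match the exposure
# orientation. Returns one of: keep, swap, flip, flip_swap,
# drop_palindromic, drop_incompatible.
.align_action <- function(ea_x, oa_x, ea_y, oa_y, eaf_x, eaf_y,
                          policy, band, snp_id) {
  if (.is_palindromic(ea_x, oa_x)) {
    # Same unordered pair required; for a palindromic pair the complement of
    # the pair is the swapped pair, so letters alone cannot orient it.
    if (!setequal(c(ea_x, oa_x), c(ea_y, oa_y))) return("drop_incompatible")
    if (policy == "infer_by_eaf") {
      if (is.na(eaf_x) || is.na(eaf_y)) {
        stop("palindromic SNP ", snp_id,
             " cannot be aligned: EAF missing under policy 'infer_by_eaf'",
             call. = FALSE)
      }
    } else {
      if (is.na(eaf_x) || is.na(eaf_y)) return("drop_palindromic")
      if ((eaf_x > band[1] && eaf_x < band[2]) ||
          (eaf_y > band[1] && eaf_y < band[2])) {
        return("drop_palindromic")
      }
    }
    # Reading the letters at face value (same strand), the outcome
    # frequency of the exposure's effect allele is eaf_y when the printed
    # effect alleles agree and 1 - eaf_y when they are printed swapped.
    # If that frequency sits on the same side of 0.5 as the exposure EAF,
    # the face-value reading is accepted; otherwise the strand is taken as
    # flipped, which for a palindromic pair is equivalent to the opposite
    # orientation.
    direct <- ea_y == ea_x
    f_letters <- if (direct) eaf_y else 1 - eaf_y
    concordant <- (eaf_x < 0.5) == (f_letters < 0.5)
    if (direct) return(if (concordant) "keep" else "swap")
    return(if (concordant) "swap" else "keep")
  }
  if (ea_y == ea_x && oa_y == oa_x) return("keep")
  if (ea_y == oa_x && oa_y == ea_x) return("swap")
  cea <- unname(.complement[ea_y]); coa <- unname(.complement[oa_y])
  if (cea == ea_x && coa == oa_x) return("flip")
  if (cea == oa_x && coa == ea_x) return("flip_swap")
  "drop_incompatible"
}

#' @export
print.mr_dataset <- function(x, ...) {
  cat(sprintf("<mr_dataset> %s -> %s, %d SNPs\n",
              paste(attr(x, "exposure_names"), collapse = " + "),
              attr(x, "outcome_name"), nrow(x)))
  cts <- attr(x, "counts")
  if (!is.null(cts)) {
    cat("  attrition:", paste(names(cts), cts, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Remove instruments shared between two GWAS
#'
#' Used for the bidirectional education/intelligence analysis, where SNPs
#' appearing as instruments in both GWAS would let the same variant proxy
#' both traits. Not applied in the univariable exposure-to-disease
#' analyses, where overlapping instruments are deliberately retained.
#'
#' @param instruments_a,instruments_b validated [sumstats] tables.
#' @return list with elements `a`, `b` (tables with shared SNPs removed) and
#'   `overlap` (character vector of shared `snp_id`s, possibly empty).
#' @export
exclude_overlap <- function(instruments_a, instruments_b) {
  overlap <- intersect(instruments_a$snp_id, instruments_b$snp_id)
  list(a = .subset_sumstats(instruments_a,
                            !instruments_a$snp_id %in% overlap),
       b = .subset_sumstats(instruments_b,
                            !instruments_b$snp_id %in% overlap),
       overlap = overlap)
}

.subset_sumstats <- function(x, keep) {
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("class", "trait_name", "trait_type",
                    "trait_sd_label")] <-
    attributes(x)[c("class", "trait_name", "trait_type", "trait_sd_label")]
  out
}

#' Pairwise LD information for clumping
#'
#' Accepts either a 3-column pair list (`snp_a`, `snp_b`, `r2`) or a square
#' r-squared matrix with snp_ids as dimnames (a header row of snp_ids in
#' delimited form). The diagonal is 1 by definition; values must lie in
#' \[0, 1\]. Lookups for a pair absent from a pair list are an error at query
#' time: independence is never silently assumed.
#'
#' @param x data frame pair list or numeric matrix.
#' @param window_bp metadata, the window within which r2 values were
#'   computed.
#' @return An `ld_info` object.
#' @export
ld_info <- function(x, window_bp = 1e7) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == ncol(x), !is.null(rownames(x)),
              identical(rownames(x), colnames(x)))
    if (any(x < 0 | x > 1, na.rm = TRUE)) {
      stop("r2 values must lie in [0, 1]", call. = FALSE)
    }
    return(structure(list(kind = "matrix", m = x, window_bp = window_bp),
                     class = "ld_info"))
  }
  x <- as.data.frame(x)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(x)))
  if (any(x$r2 < 0 | x$r2 > 1, na.rm = TRUE)) {
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  }
  key <- c(paste(x$snp_a, x$snp_b, sep = "\r"),
           paste(x$snp_b, x$snp_a, sep = "\r"))
  structure(list(kind = "pairs",
                 r2 = stats::setNames(rep(x$r2, 2L), key),
                 window_bp = window_bp),
            class = "ld_info")
}

#' Read LD information from delimited text
#'
#' @param path a TSV/CSV file: either columns `snp_a`, `snp_b`, `r2`, or a
#'   square matrix whose first column and header row are snp_ids.
#' @param window_bp see [ld_info()].
#' @export
read_ld <- function(path, window_bp = 1e7) {
  x <- data.table::fread(path, data.table = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(x))) {
    return(ld_info(x, window_bp = window_bp))
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  ld_info(m, window_bp = window_bp)
}

.ld_r2 <- function(ld, a, b) {
  if (a == b) return(1)
  if (ld$kind == "matrix") {
    if (!(a %in% rownames(ld$m)) || !(b %in% rownames(ld$m))) {
      stop("LD information missing for pair (", a, ", ", b, ")",
           call. = FALSE)
    }
    return(ld$m[a, b])
  }
  v <- ld$r2[paste(a, b, sep = "\r")]
  if (is.na(v)) {
    stop("LD information missing for pair (", a, ", ", b, ")",
         call. = FALSE)
  }
  unname(v)
}

#' Greedy LD clumping to approximately independent SNPs
#'
#' Iteratively retains the SNP with the smallest p-value and removes all
#' SNPs on the same chromosome within `window_bp` whose r-squared with it is
#' at least `r2_threshold`; repeats until the table is exhausted. Ties on
#' p-value are broken by (chrom, pos) order so the result is independent of
#' input row order. With `ld = NULL` the table is declared pre-clumped and
#' returned unchanged with a logged notice (published lead-SNP lists are
#' already approximately independent).
#'
#' @param table validated [sumstats] table.
#' @param ld an [ld_info()] object, or `NULL` for pre-clumped input.
#' @param r2_threshold r-squared above which two SNPs are dependent
#'   (default 0.01).
#' @param window_bp window in base pairs (default 10 Mb).
#' @return The clumped [sumstats] table (input row order preserved among
#'   retained SNPs).
#' @export
greedy_clump <- function(table, ld = NULL, r2_threshold = 0.01,
                         window_bp = 1e7) {
  if (is.null(ld)) {
    message("no LD information supplied: '", trait_name(table),
            "' treated as pre-clumped")
    return(table)
  }
  stopifnot(inherits(ld, "ld_info"))
  avail <- rep(TRUE, nrow(table))
  keep <- rep(FALSE, nrow(table))
  ord <- order(table$pval, table$chrom, table$pos)
  while (any(avail)) {
    lead <- ord[avail[ord]][1L]
    keep[lead] <- TRUE
    avail[lead] <- FALSE
    in_window <- which(avail &
                       table$chrom == table$chrom[lead] &
                       abs(table$pos - table$pos[lead]) <= window_bp)
    for (j in in_window) {
      if (.ld_r2(ld, table$snp_id[lead], table$snp_id[j]) >= r2_threshold) {
        avail[j] <- FALSE
      }
    }
  }
  .subset_sumstats(table, keep)
}

#' Assemble a two-exposure dataset for multivariable MR
#'
#' Takes the instrument lists of two exposures, forms their union (each SNP
#' once; for SNPs instrumenting both exposures the smaller p-value is used
#' for clumping precedence), clumps to independent SNPs, looks up every
#' retained SNP's association with *both* exposures in the full association
#' tables, harmonizes the second exposure and the outcome to the first
#' exposure's effect allele, and returns a two-exposure `mr_dataset`. SNPs
#' missing a cross association or absent from the outcome are dropped and
#' counted.
#'
#' @param exposure1,exposure2 instrument [sumstats] tables (exposure2 may be
#'   empty, giving the univariable reduction).
#' @param cross_assoc named list of two full [sumstats] tables, one per
#'   exposure trait (names must match the two trait names), holding each
#'   union SNP's association with that trait.
#' @param outcome validated [sumstats] outcome table.
#' @param ld optional [ld_info()] for clumping of the union list.
#' @param palindrome_policy,eaf_ambiguity_band see [harmonize_pair()].
#' @param r2_threshold,window_bp see [greedy_clump()].
#' @return A two-exposure `mr_dataset` with columns `beta_exposure1`,
#'   `se_exposure1`, `beta_exposure2`, `se_exposure2`, outcome columns and
#'   provenance counts (instruments per source and their overlap).
#' @export
build_mvmr_dataset <- function(exposure1, exposure2, cross_assoc, outcome,
                               ld = NULL,
                               palindrome_policy = "drop_ambiguous",
                               eaf_ambiguity_band = c(0.42, 0.58),
                               r2_threshold = 0.01, window_bp = 1e7) {
  t1 <- trait_name(exposure1)
  t2 <- trait_name(exposure2)
  if (!all(c(t1, t2) %in% names(cross_assoc))) {
    stop("cross_assoc must contain tables named '", t1, "' and '", t2, "'",
         call. = FALSE)
  }
  a1 <- cross_assoc[[t1]]
  a2 <- cross_assoc[[t2]]

  ids <- union(exposure1$snp_id, exposure2$snp_id)
  overlap <- intersect(exposure1$snp_id, exposure2$snp_id)
  if (length(ids) == 0L) stop("no instruments supplied", call. = FALSE)
  # union table for clumping: coordinates from whichever list has the SNP,
  # p-value the smaller of the two exposures' discovery p-values
  src1 <- match(ids, exposure1$snp_id)
  src2 <- match(ids, exposure2$snp_id)
  take1 <- !is.na(src1)
  base <- as.data.frame(exposure1)[ifelse(take1, src1, 1L), , drop = FALSE]
  base[!take1, ] <- as.data.frame(exposure2)[src2[!take1], , drop = FALSE]
  p2 <- ifelse(is.na(src2), Inf, exposure2$pval[src2])
  p1 <- ifelse(is.na(src1), Inf, exposure1$pval[src1])
  base$pval <- pmin(p1, p2)
  base$snp_id <- ids
  union_tab <- sumstats(base, trait_name = paste(t1, t2, sep = "+"),
                        trait_type = "continuous")
  clumped <- greedy_clump(union_tab, ld = ld, r2_threshold = r2_threshold,
                          window_bp = window_bp)

  has_cross <- clumped$snp_id %in% a1$snp_id & clumped$snp_id %in% a2$snp_id
  n_missing_cross <- sum(!has_cross)
  clumped <- .subset_sumstats(clumped, has_cross)
  if (nrow(clumped) == 0L) {
    stop("no SNPs with associations available for both exposures",
         call. = FALSE)
  }

  e1 <- .subset_sumstats(a1, match(clumped$snp_id, a1$snp_id))
  # align exposure 2 to exposure 1's effect alleles, then the outcome
  h12 <- harmonize_pair(e1, a2, palindrome_policy = palindrome_policy,
                        eaf_ambiguity_band = eaf_ambiguity_band)
  hxy <- harmonize_pair(e1, outcome, palindrome_policy = palindrome_policy,
                        eaf_ambiguity_band = eaf_ambiguity_band)
  keep <- intersect(h12$snp_id, hxy$snp_id)
  if (length(keep) == 0L) {
    stop("multivariable harmonization retained no SNPs", call. = FALSE)
  }
  i12 <- match(keep, h12$snp_id)
  ixy <- match(keep, hxy$snp_id)
  out <- data.frame(
    snp_id = keep,
    chrom = h12$chrom[i12], pos = h12$pos[i12],
    effect_allele = h12$effect_allele[i12],
    other_allele = h12$other_allele[i12],
    beta_exposure1 = h12$beta_exposure[i12],
    se_exposure1 = h12$se_exposure[i12],
    beta_exposure2 = h12$beta_outcome[i12],
    se_exposure2 = h12$se_outcome[i12],
    eaf_exposure = h12$eaf_exposure[i12],
    beta_outcome = hxy$beta_outcome[ixy],
    se_outcome = hxy$se_outcome[ixy],
    n_exposure1 = h12$n_exposure[i12],
    n_exposure2 = h12$n_outcome[i12],
    n_outcome = hxy$n_outcome[ixy],
    flag = hxy$flag[ixy],
    stringsAsFactors = FALSE)
  counts <- c(instruments_exposure1 = nrow(exposure1),
              instruments_exposure2 = nrow(exposure2),
              instrument_overlap = length(overlap),
              union = length(ids),
              after_clump = nrow(clumped) + n_missing_cross,
              missing_cross_association = n_missing_cross,
              retained = nrow(out))
  structure(out,
            class = c("mr_dataset", "data.frame"),
            exposure_names = c(t1, t2),
            exposure_types = c(trait_type(a1), trait_type(a2)),
            outcome_name = trait_name(outcome),
            outcome_type = trait_type(outcome),
            counts = counts)
}
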
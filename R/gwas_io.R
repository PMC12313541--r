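# Reading, writing and harmonizing GWAS summary statistics.
#
# A summary-statistics table holds one row per SNP with columns
# snp, chr, pos, effect_allele, other_allele, eaf, beta, se, pval, n.
# "NA" encodes a missing value. Alleles are single bases over {A,C,G,T};
# multi-base (indel) records are rejected so the allele algebra used by
# harmonization stays exact.

STRAND_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited file with a header into a canonical
#' summary-statistics data frame. Rows whose beta, se or p-value cannot be
#' parsed (or violate their domains: se > 0, p in (0,1]), or whose alleles
#' are not single bases over A/C/G/T, are dropped and recorded in the
#' `drop_log` attribute.
#'
#' @param path Path to the file.
#' @param column_map Optional named character vector mapping canonical column
#'   names (`snp`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`,
#'   optionally `chr`, `pos`, `eaf`, `n`) to the names used in the file.
#' @return A data.frame with columns `snp, chr, pos, effect_allele,
#'   other_allele, eaf, beta, se, pval, n`, alleles upper-cased, row order
#'   preserved. Attribute `drop_log` is a data.frame (`snp`, `reason`) of
#'   dropped rows; attribute `n_dropped` its row count.
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    mr_error(sprintf("file not found: %s", path), "mr_io_error")
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    mr_error(sprintf("empty summary-statistics file: %s", path),
             "mr_empty_input_error")
  }
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = "NA",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  optional <- c("chr", "pos", "eaf", "n")
  resolve <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      column_map[[canon]]
    } else {
      canon
    }
  }
  missing_cols <- mandatory[!vapply(mandatory, function(cn) {
    resolve(cn) %in% names(raw)
  }, logical(1))]
  if (length(missing_cols) > 0L) {
    mr_error(sprintf("missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "mr_config_error")
  }
  if (nrow(raw) == 0L) {
    mr_error(sprintf("summary-statistics file has no data rows: %s", path),
             "mr_empty_input_error")
  }
  get_col <- function(canon, default = NA_character_) {
    nm <- resolve(canon)
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  rec <- data.frame(
    snp = as.character(get_col("snp")),
    chr = as.character(get_col("chr")),
    pos = num(get_col("pos")),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele = toupper(as.character(get_col("other_allele"))),
    eaf = num(get_col("eaf")),
    beta = num(get_col("beta")),
    se = num(get_col("se")),
    pval = num(get_col("pval")),
    n = num(get_col("n")),
    stringsAsFactors = FALSE
  )
  valid_allele <- function(a) a %in% names(STRAND_COMPLEMENT)
  reason <- rep(NA_character_, nrow(rec))
  bad_num <- is.na(rec$beta) | is.na(rec$se) | is.na(rec$pval)
  reason[bad_num] <- "unparseable beta/se/pval"
  bad_dom <- !bad_num & (rec$se <= 0 | rec$pval <= 0 | rec$pval > 1)
  reason[bad_dom] <- "beta/se/pval outside domain"
  bad_allele <- is.na(reason) &
    (!valid_allele(rec$effect_allele) | !valid_allele(rec$other_allele) |
       rec$effect_allele == rec$other_allele)
  reason[bad_allele] <- "invalid or multi-base alleles"
  bad_eaf <- is.na(reason) & !is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1)
  reason[bad_eaf] <- "eaf outside [0,1]"
  keep <- is.na(reason)
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_log") <- data.frame(
    snp = rec$snp[!keep], reason = reason[!keep], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write a summary-statistics table
#'
#' Writes records in the canonical tab-delimited layout, `NA` for missing
#' values, so that `read_summary_stats(write_summary_stats(x))` round-trips
#' field-for-field.
#'
#' @param records Canonical summary-statistics data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  cols <- sumstat_columns()
  out <- records
  for (cn in cols) if (!cn %in% names(out)) out[[cn]] <- NA
  out <- out[, cols, drop = FALSE]
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) mr_error(sprintf("cannot write to %s", path), "mr_io_error")
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  unname(STRAND_COMPLEMENT[a1]) == a2
}

#' Construct a harmonized exposure-outcome SNP set
#'
#' Low-level constructor for the container all MR estimators consume: paired
#' per-SNP effects of the instruments on the exposure and on the outcome,
#' expressed on a single effect-allele convention.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Numeric vectors of
#'   equal length; SEs strictly positive.
#' @param snp Optional SNP identifiers (defaults to `snp1..snpk`); must be
#'   unique.
#' @param eaf Optional effect-allele frequencies.
#' @param n_exposure,n_outcome Optional GWAS sample sizes.
#' @param log Optional provenance data.frame (`snp`, `action`, `reason`).
#' @return An object of class `harmonized_set` with element `data` (one row
#'   per SNP) and `log`.
#' @export
harmonized_set <- function(beta_exposure, se_exposure, beta_outcome,
                           se_outcome, snp = NULL, eaf = NULL,
                           n_exposure = NA_integer_, n_outcome = NA_integer_,
                           log = NULL) {
  k <- length(beta_exposure)
  if (k < 1L) mr_error("harmonized set must contain at least one SNP",
                       "mr_empty_input_error")
  lens <- c(length(se_exposure), length(beta_outcome), length(se_outcome))
  if (any(lens != k)) {
    mr_error("beta/se vectors must have equal length", "mr_validation_error")
  }
  if (any(se_exposure <= 0) || any(se_outcome <= 0)) {
    mr_error("standard errors must be strictly positive",
             "mr_validation_error")
  }
  if (is.null(snp)) snp <- paste0("snp", seq_len(k))
  if (anyDuplicated(snp)) {
    mr_error("duplicate SNP identifiers in harmonized set",
             "mr_validation_error")
  }
  if (is.null(eaf)) eaf <- rep(NA_real_, k)
  structure(list(
    data = data.frame(snp = as.character(snp),
                      beta_exposure = as.numeric(beta_exposure),
                      se_exposure = as.numeric(se_exposure),
                      beta_outcome = as.numeric(beta_outcome),
                      se_outcome = as.numeric(se_outcome),
                      eaf = as.numeric(eaf),
                      stringsAsFactors = FALSE),
    n_exposure = n_exposure,
    n_outcome = n_outcome,
    log = if (is.null(log)) {
      data.frame(snp = character(), action = character(),
                 reason = character(), stringsAsFactors = FALSE)
    } else log
  ), class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized exposure-outcome set: %d SNPs\n", nrow(x$data)))
  if (nrow(x$log) > 0) {
    tab <- table(x$log$action)
    cat("  provenance:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of SNPs in a harmonized set
#' @param hset A `harmonized_set`.
#' @return Integer SNP count.
#' @export
n_snps <- function(hset) nrow(hset$data)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome study's per-SNP effects onto the exposure study's
#' effect-allele convention. For each SNP present in both studies:
#' identical allele pairs are kept as-is; swapped pairs have the outcome
#' beta sign-flipped and eaf complemented; strand-complement pairs are
#' complemented first and then treated the same way; palindromic (A/T, C/G)
#' pairs are kept only when both allele frequencies fall on the same side of
#' 0.5 and both lie outside the ambiguity window `0.5 +/- palindrome_eaf_window`
#' (orientation by frequency), and are dropped otherwise; incompatible allele
#' pairs are dropped. Every decision is recorded in the provenance log.
#'
#' @param exposure,outcome Canonical summary-statistics data.frames.
#' @param palindrome_eaf_window Half-width of the allele-frequency ambiguity
#'   window around 0.5 inside which a palindromic SNP cannot be oriented.
#' @return A `harmonized_set`. Exposure columns `pval` and `n` are carried
#'   through as `pval_exposure` / `n` when present.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  if (nrow(exposure) == 0L || nrow(outcome) == 0L) {
    mr_error("exposure and outcome record sets must be nonempty",
             "mr_empty_input_error")
  }
  oidx <- match(exposure$snp, outcome$snp)
  log <- list()
  note <- function(snp, action, reason = "") {
    log[[length(log) + 1L]] <<- data.frame(
      snp = snp, action = action, reason = reason, stringsAsFactors = FALSE)
  }
  keep <- logical(nrow(exposure))
  by_out <- numeric(nrow(exposure))
  sey_out <- numeric(nrow(exposure))
  eaf_out <- numeric(nrow(exposure))

  for (i in seq_len(nrow(exposure))) {
    j <- oidx[i]
    snp <- exposure$snp[i]
    if (is.na(j)) {
      note(snp, "dropped", "absent-from-outcome")
      next
    }
    ea_x <- exposure$effect_allele[i]; oa_x <- exposure$other_allele[i]
    ea_y <- outcome$effect_allele[j]; oa_y <- outcome$other_allele[j]
    by <- outcome$beta[j]; sey <- outcome$se[j]; fy <- outcome$eaf[j]
    fx <- exposure$eaf[i]

    if (is_palindromic(ea_x, oa_x)) {
      # Strand is undecidable from alleles; orient by allele frequency.
      same_pair <- setequal(c(ea_y, oa_y), c(ea_x, oa_x))
      if (!same_pair) {
        note(snp, "dropped", "incompatible-alleles")
        next
      }
      if (is.na(fx) || is.na(fy)) {
        note(snp, "dropped", "palindromic-missing-eaf")
        next
      }
      unambig <- abs(fx - 0.5) > palindrome_eaf_window &&
        abs(fy - 0.5) > palindrome_eaf_window
      if (!unambig) {
        note(snp, "dropped", "palindromic-ambiguous")
        next
      }
      same_side <- (fx - 0.5) * (fy - 0.5) > 0
      if (!same_side) {
        by <- -by
        fy <- 1 - fy
      }
      keep[i] <- TRUE
      by_out[i] <- by; sey_out[i] <- sey; eaf_out[i] <- fy
      note(snp, if (same_side) "kept" else "sign-flipped",
           "palindromic-frequency-oriented")
      next
    }

    # Try direct, then strand-complemented, orientation.
    flip <- NA
    strand <- FALSE
    if (ea_y == ea_x && oa_y == oa_x) {
      flip <- FALSE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      flip <- TRUE
    } else {
      cea <- unname(STRAND_COMPLEMENT[ea_y])
      coa <- unname(STRAND_COMPLEMENT[oa_y])
      if (identical(cea, ea_x) && identical(coa, oa_x)) {
        flip <- FALSE; strand <- TRUE
      } else if (identical(cea, oa_x) && identical(coa, ea_x)) {
        flip <- TRUE; strand <- TRUE
      }
    }
    if (is.na(flip)) {
      note(snp, "dropped", "incompatible-alleles")
      next
    }
    if (flip) {
      by <- -by
      if (!is.na(fy)) fy <- 1 - fy
    }
    keep[i] <- TRUE
    by_out[i] <- by; sey_out[i] <- sey; eaf_out[i] <- fy
    note(snp, if (strand && flip) "strand-and-sign-flipped"
         else if (strand) "strand-flipped"
         else if (flip) "sign-flipped" else "kept")
  }

  log_df <- do.call(rbind, log)
  n_overlap <- sum(!is.na(oidx))
  if (n_overlap == 0L) {
    mr_error("no overlapping SNPs between exposure and outcome",
             "mr_empty_overlap_error")
  }
  if (!any(keep)) {
    mr_error("all overlapping SNPs were dropped during harmonization",
             "mr_empty_overlap_error")
  }
  hs <- harmonized_set(
    beta_exposure = exposure$beta[keep],
    se_exposure = exposure$se[keep],
    beta_outcome = by_out[keep],
    se_outcome = sey_out[keep],
    snp = exposure$snp[keep],
    eaf = exposure$eaf[keep],
    n_exposure = if ("n" %in% names(exposure))
      suppressWarnings(as.integer(stats::median(exposure$n, na.rm = TRUE)))
      else NA_integer_,
    n_outcome = if ("n" %in% names(outcome))
      suppressWarnings(as.integer(stats::median(outcome$n, na.rm = TRUE)))
      else NA_integer_,
    log = log_df
  )
  hs$data$eaf_outcome <- eaf_out[keep]
  if ("pval" %in% names(exposure)) hs$data$pval_exposure <- exposure$pval[keep]
  hs
}

#' Write a harmonization provenance log
#'
#' Sidecar TSV with one row per input SNP: identifier, action taken
#' (kept / sign-flipped / strand-flipped / dropped), and reason.
#'
#' @param hset A `harmonized_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(hset, path) {
  utils::write.table(hset$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
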
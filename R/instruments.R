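# Instrument selection and strength scoring.
#
# Instruments are SNPs passing a genome-wide(-ish) p-value threshold, pruned
# to independent loci by greedy LD clumping, and scored with the
# variance-explained / F-statistic formulas
#   R^2 = 2 * MAF * (1 - MAF) * beta^2
#   F   = R^2 * (n - k - 1) / (k * (1 - R^2))
# with F < 10 flagging weak instruments.

#' Filter records by association p-value
#'
#' Keeps exactly the records with `pval < threshold` (strict), preserving
#' input order. The conventional exposure threshold in this package is
#' 5e-6, with 5e-8 for well-powered exposures.
#'
#' @param records Summary-statistics data.frame.
#' @param threshold P-value threshold in (0, 1).
#' @return Subset of `records`.
#' @export
filter_by_pvalue <- function(records, threshold) {
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1) {
    mr_error("threshold must be a single number in (0, 1)",
             "mr_validation_error")
  }
  out <- records[!is.na(records$pval) & records$pval < threshold, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_ld_matrix <- function(ld, snps) {
  if (is.null(rownames(ld)) || is.null(colnames(ld)) ||
      nrow(ld) != ncol(ld)) {
    mr_error("LD matrix must be square with snp_id row/column names",
             "mr_validation_error")
  }
  missing <- setdiff(snps, rownames(ld))
  if (length(missing) > 0L) {
    mr_error(sprintf("LD matrix missing SNP(s): %s",
                     paste(missing, collapse = ", ")),
             "mr_validation_error")
  }
  sub <- ld[snps, snps, drop = FALSE]
  if (max(abs(sub - t(sub))) > 1e-8) {
    mr_error("LD matrix is not symmetric", "mr_validation_error")
  }
  sub
}

#' Greedy LD clumping
#'
#' Prunes records to an independent instrument set: SNPs are visited in
#' ascending p-value order (ties broken by snp_id); each accepted SNP
#' discards every remaining SNP that is both in LD with it
#' (`r2 >= r2_threshold`) and within `kb_window` kilobases on the same
#' chromosome. When no LD matrix is supplied the fallback is pure distance
#' pruning (discard within the window on the same chromosome). Deterministic
#' given its input.
#'
#' @param records Summary-statistics data.frame.
#' @param ld Optional square r-squared matrix with snp_id dimnames.
#' @param r2_threshold LD threshold (default 0.001).
#' @param kb_window Window in kilobases (default 10000).
#' @return The retained records, in original input order.
#' @export
ld_clump <- function(records, ld = NULL, r2_threshold = 0.001,
                     kb_window = 10000) {
  k <- nrow(records)
  if (k == 0L) return(records)
  have_pos <- all(!is.na(records$chr)) && all(!is.na(records$pos))
  if (is.null(ld) && !have_pos) {
    mr_error("distance-only clumping requires chr and pos on all records",
             "mr_validation_error")
  }
  if (!is.null(ld)) ld <- validate_ld_matrix(ld, records$snp)

  ord <- order(records$pval, records$snp)
  status <- rep(NA, k)  # NA undecided, TRUE accepted, FALSE discarded
  for (i in ord) {
    if (!is.na(status[i])) next
    status[i] <- TRUE
    for (j in seq_len(k)) {
      if (!is.na(status[j])) next
      near <- if (have_pos) {
        records$chr[j] == records$chr[i] &&
          abs(records$pos[j] - records$pos[i]) <= kb_window * 1000
      } else TRUE
      in_ld <- if (is.null(ld)) TRUE else {
        ld[records$snp[j], records$snp[i]] >= r2_threshold
      }
      if (near && in_ld) status[j] <- FALSE
    }
  }
  out <- records[which(status), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument strength (variance explained and F-statistic)
#'
#' Scores instruments with `R^2 = 2*MAF*(1-MAF)*beta^2` and
#' `F = R^2*(n-k-1)/(k*(1-R^2))`. Per-SNP mode uses `k = 1` per SNP;
#' aggregate mode sums the per-SNP R-squared values and uses `k` equal to
#' the number of instruments. Betas are assumed to be on a standardized
#' trait scale (the caller's responsibility). An instrument set is flagged
#' weak when `F < 10`.
#'
#' @param records Summary-statistics data.frame with non-missing `eaf`.
#' @param n GWAS sample size; must exceed `k + 1`.
#' @param aggregate If `TRUE`, return one aggregate row; otherwise one row
#'   per SNP.
#' @return A data.frame with columns `snp, maf, r2, f_stat, n, k, weak`
#'   (the aggregate row has `snp = "(aggregate)"`).
#' @export
instrument_strength <- function(records, n, aggregate = FALSE) {
  if (any(is.na(records$eaf))) {
    mr_error(sprintf("missing eaf for SNP(s): %s",
                     paste(records$snp[is.na(records$eaf)], collapse = ", ")),
             "mr_validation_error")
  }
  maf <- pmin(records$eaf, 1 - records$eaf)
  r2 <- 2 * maf * (1 - maf) * records$beta^2
  k_all <- nrow(records)
  if (aggregate) {
    k <- k_all
    if (n <= k + 1) mr_error("n must exceed k + 1", "mr_domain_error")
    r2_tot <- sum(r2)
    f <- r2_tot * (n - k - 1) / (k * (1 - r2_tot))
    data.frame(snp = "(aggregate)", maf = NA_real_, r2 = r2_tot, f_stat = f,
               n = n, k = k, weak = f < 10, stringsAsFactors = FALSE)
  } else {
    if (n <= 2) mr_error("n must exceed k + 1", "mr_domain_error")
    f <- r2 * (n - 2) / (1 - r2)
    data.frame(snp = records$snp, maf = maf, r2 = r2, f_stat = f,
               n = n, k = 1L, weak = f < 10, stringsAsFactors = FALSE)
  }
}

#' Select instruments for an exposure
#'
#' Convenience wrapper: p-value filter then LD clump.
#'
#' @inheritParams filter_by_pvalue
#' @inheritParams ld_clump
#' @param pval_threshold Association threshold (default 5e-6).
#' @return Retained instrument records.
#' @export
select_instruments <- function(records, pval_threshold = 5e-6, ld = NULL,
                               r2_threshold = 0.001, kb_window = 10000) {
  ld_clump(filter_by_pvalue(records, pval_threshold), ld = ld,
           r2_threshold = r2_threshold, kb_window = kb_window)
}
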
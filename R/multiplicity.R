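# Benjamini-Hochberg FDR across an exposure panel and assembly of
# Table-style results with significance flags.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, take
#' `adj_(i) = min_{j >= i} min(1, m * p_(j) / j)`, and map back to input
#' order (delegated to [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) {
    mr_error("bh_adjust needs a nonempty p-value vector",
             "mr_validation_error")
  }
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    mr_error("p-values must lie in (0, 1]", "mr_validation_error")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Bonferroni adjustment (utility)
#' @inheritParams bh_adjust
#' @return Adjusted p-values in input order.
#' @export
bonferroni_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    mr_error("p-values must lie in (0, 1]", "mr_validation_error")
  }
  stats::p.adjust(pvals, method = "bonferroni")
}

#' Assemble an exposure-panel report with FDR flags
#'
#' Combines one primary (IVW) result per exposure into a panel table with
#' BH-adjusted p-values and significance flags, plus forest-plot
#' coordinates. Display convention: ORs to 2 dp, p-values in scientific
#' notation at 3 significant digits (the underlying columns keep full
#' precision; `or_disp`/`p_disp` carry the rounded forms).
#'
#' @param results Either a data.frame with columns `exposure, n_snp, beta,
#'   se, pval, or, or_low, or_high` or a named list of `mr_result` objects
#'   (names = exposures).
#' @param alpha FDR significance level (default 0.05).
#' @return List with `panel` (rows sorted by adjusted p) and `forest`
#'   (label, or, or_low, or_high).
#' @export
assemble_panel <- function(results, alpha = 0.05) {
  if (!is.data.frame(results)) {
    if (length(results) == 0L) {
      mr_error("assemble_panel needs at least one result",
               "mr_validation_error")
    }
    rows <- lapply(names(results), function(nm) {
      cbind(data.frame(exposure = nm, stringsAsFactors = FALSE),
            as.data.frame(results[[nm]]))
    })
    results <- do.call(rbind, rows)
  }
  if (nrow(results) == 0L) {
    mr_error("assemble_panel needs at least one result",
             "mr_validation_error")
  }
  if (anyDuplicated(results$exposure)) {
    mr_error("duplicate exposure labels in panel", "mr_validation_error")
  }
  panel <- results
  panel$pval_adj <- bh_adjust(panel$pval)
  panel$significant <- panel$pval_adj < alpha
  panel <- panel[order(panel$pval_adj, panel$pval), , drop = FALSE]
  rownames(panel) <- NULL
  panel$or_disp <- sprintf("%.2f (%.2f-%.2f)", panel$or, panel$or_low,
                           panel$or_high)
  panel$p_disp <- sprintf("%.2e", signif(panel$pval, 3))
  forest <- data.frame(label = panel$exposure, or = panel$or,
                       or_low = panel$or_low, or_high = panel$or_high,
                       stringsAsFactors = FALSE)
  list(panel = panel, forest = forest)
}
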
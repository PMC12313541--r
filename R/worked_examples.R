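# Bundled worked-example estimates from a published two-sample MR study of
# beverage intake and irritable bowel syndrome (IBS). These are summary
# results (per-exposure IVW p-values and ORs; mediation stage coefficients
# with 95% CIs for five psychiatric mediators), shipped as plain-text
# tables so the panel-FDR and mediation decision machinery can be exercised
# end-to-end on real printed numbers without any GWAS download.

#' Worked example: beverage-panel MR results
#'
#' Ten exposures (alcohol measures plus other beverages) tested against
#' IBS with IVW: raw p-values and ORs with 95% CIs. Feeding the `pval`
#' column through [bh_adjust()] reproduces the published FDR ladder.
#'
#' @return A data.frame with columns `exposure, gwas_id, n_snp, pval, or,
#'   or_low, or_high`.
#' @export
beverage_panel_example <- function() {
  utils::read.table(
    system.file("extdata", "beverage_panel_mr.tsv", package = "mrmediate"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE, quote = "\"")
}

#' Worked example: psychiatric-mediator stage estimates
#'
#' Stage coefficients of the two-step mediation decomposition of the
#' alcohol-IBS effect through five psychiatric mediators: total effect
#' (`c`), exposure->mediator (`a`), mediator->outcome (`b`) and the
#' MVMR-adjusted direct effects (`c_adj`, `b_adj`), each with a 95% CI.
#'
#' @return A data.frame, one row per mediator.
#' @export
mediation_stages_example <- function() {
  utils::read.table(
    system.file("extdata", "psych_mediation_estimates.tsv",
                package = "mrmediate"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE, quote = "\"")
}

#' Apply the mediation decision rule to a table of stage estimates
#'
#' Runs [mediation_decide()] on each row of a stage table in the layout of
#' [mediation_stages_example()] (SEs back-derived from the CIs as
#' width/3.92).
#'
#' @param stages Data.frame in the layout of [mediation_stages_example()].
#' @param alpha Significance level for the decision rule.
#' @return A data.frame with one row per mediator: `mediator`,
#'   `method_flag`, `indirect`, `proportion_pct`, `sobel_z`, `sobel_p`.
#' @export
mediation_decide_table <- function(stages, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(stages)), function(i) {
    r <- stages[i, ]
    blk <- function(pre) list(est = r[[paste0(pre, "_est")]],
                              ci_low = r[[paste0(pre, "_lo")]],
                              ci_high = r[[paste0(pre, "_hi")]])
    res <- mediation_decide(blk("a"), blk("b"), blk("c"),
                            beta_b_adj = blk("b_adj"),
                            beta_c_adj = blk("c_adj"), alpha = alpha,
                            exposure = r$exposure, mediator = r$mediator,
                            outcome = r$outcome)
    data.frame(mediator = r$mediator, method_flag = res$method_flag,
               indirect = res$indirect,
               proportion_pct = 100 * res$proportion,
               sobel_z = res$sobel_z, sobel_p = res$sobel_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
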
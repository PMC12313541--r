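# Internal helpers shared across modules.

#' @keywords internal
mr_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mrmediate_error")))
}

# Two-sided normal p-value for an estimate/SE pair.
#' @keywords internal
z_pvalue <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

# SE back-derived from a 95% CI: width / (2 * 1.96). Used when only printed
# confidence intervals are available for a coefficient.
#' @export
#' @rdname ci_to_se
#' @title Standard error from a 95\% confidence interval
#' @description Recovers an approximate standard error from a normal-theory
#'   95\% confidence interval as `(upper - lower) / (2 * 1.96)`.
#' @param lower,upper CI endpoints.
#' @return Numeric standard error.
ci_to_se <- function(lower, upper) {
  (upper - lower) / (2 * 1.96)
}

# Canonical column order for summary-statistic tables.
#' @keywords internal
sumstat_columns <- function() {
  c("snp", "chr", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pval", "n")
}

#' @keywords internal
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
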
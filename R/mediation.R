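# Two-step MR mediation decomposition.
#
# Notation (standard two-step MR):
#   beta_a  exposure -> mediator effect
#   beta_b  mediator -> outcome effect (univariable)
#   beta_c  exposure -> outcome total effect
#   beta_b_adj, beta_c_adj  the mediator and exposure direct effects after
#     MVMR adjustment for each other
# Indirect effect = beta_a * beta_b_adj (Propagation of Error, when the
# adjusted mediator effect is significant) or beta_a * beta_b (Sobel
# fallback); mediated proportion = indirect / beta_c.

#' Indirect effect with Propagation-of-Error standard error
#'
#' Product-of-coefficients indirect effect `a*b` with first-order
#' (delta-method) SE `sqrt(a^2*se_b^2 + b^2*se_a^2)`; symmetric in the two
#' coefficient blocks.
#'
#' @param a,se_a First-stage estimate and SE (exposure -> mediator).
#' @param b,se_b Second-stage estimate and SE (mediator -> outcome).
#' @return List `(indirect, indirect_se)`.
#' @export
indirect_effect_poe <- function(a, se_a, b, se_b) {
  if (se_a <= 0 || se_b <= 0) {
    mr_error("standard errors must be positive", "mr_validation_error")
  }
  list(indirect = a * b,
       indirect_se = sqrt(a^2 * se_b^2 + b^2 * se_a^2))
}

#' Sobel test of the indirect effect
#'
#' `z = a*b / sqrt(a^2*se_b^2 + b^2*se_a^2)` with a two-sided normal
#' p-value. The denominator is exactly the Propagation-of-Error SE.
#'
#' @inheritParams indirect_effect_poe
#' @return List `(z, p)`.
#' @export
sobel_test <- function(a, se_a, b, se_b) {
  ind <- indirect_effect_poe(a, se_a, b, se_b)
  if (ind$indirect_se == 0) {
    mr_error("Sobel test undefined: both coefficients are zero",
             "mr_degenerate_error")
  }
  z <- ind$indirect / ind$indirect_se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Mediated proportion
#'
#' `indirect / beta_c`, reported as a percentage by callers. The SE uses
#' first-order ratio propagation
#' `|prop| * sqrt((se_ind/ind)^2 + (se_c/beta_c)^2)` when the indirect
#' effect is non-zero.
#'
#' @param indirect Indirect (product) effect.
#' @param beta_c Total effect; must be non-zero.
#' @param se_indirect,se_c Optional SEs for the propagation formula.
#' @return List `(proportion, proportion_se)` on the raw (not percent)
#'   scale.
#' @export
mediated_proportion <- function(indirect, beta_c, se_indirect = NA_real_,
                                se_c = NA_real_) {
  if (!is_scalar_number(beta_c) || beta_c == 0) {
    mr_error("mediated proportion undefined: total effect is zero",
             "mr_degenerate_error")
  }
  prop <- indirect / beta_c
  prop_se <- if (indirect != 0 && is.finite(se_indirect) &&
                 is.finite(se_c)) {
    abs(prop) * sqrt((se_indirect / indirect)^2 + (se_c / beta_c)^2)
  } else if (indirect == 0) 0 else NA_real_
  list(proportion = prop, proportion_se = prop_se)
}

est_block <- function(est, se = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_) {
  if (is.na(se) && is.finite(ci_low) && is.finite(ci_high)) {
    se <- ci_to_se(ci_low, ci_high)
  }
  if (is.na(ci_low) && is.finite(se)) {
    ci_low <- est - 1.96 * se
    ci_high <- est + 1.96 * se
  }
  list(est = est, se = se, ci_low = ci_low, ci_high = ci_high,
       pval = if (is.finite(se) && se > 0) z_pvalue(est, se) else NA_real_)
}

#' Mediation decomposition from stage estimates
#'
#' Applies the two-step decision rule to precomputed stage estimates. Each
#' block is a list with `est` and either `se` or a 95% CI (SEs are
#' back-derived from CIs as width/3.92 when absent). The rule: if the
#' MVMR-adjusted mediator effect's 95% CI excludes zero, use Propagation of
#' Error with `indirect = beta_a * beta_b_adj`; otherwise if the Sobel test
#' on the unadjusted product `beta_a * beta_b` has p < alpha, use the Sobel
#' route; otherwise the mediated proportion is not available.
#'
#' @param beta_a,beta_b,beta_c Stage blocks (see above); `beta_c` is the
#'   total effect.
#' @param beta_b_adj,beta_c_adj MVMR-adjusted blocks; may be `NULL` when
#'   MVMR could not be run (forces the Sobel route).
#' @param alpha Significance level for the switch (default 0.05).
#' @param exposure,mediator,outcome Labels.
#' @return An object of class `mediation_result`.
#' @export
mediation_decide <- function(beta_a, beta_b, beta_c, beta_b_adj = NULL,
                             beta_c_adj = NULL, alpha = 0.05,
                             exposure = "exposure", mediator = "mediator",
                             outcome = "outcome") {
  mk <- function(b) if (is.null(b)) NULL else do.call(est_block, b)
  a <- mk(beta_a); b <- mk(beta_b); cc <- mk(beta_c)
  b_adj <- mk(beta_b_adj); c_adj <- mk(beta_c_adj)

  sig <- function(blk) !is.null(blk) && (blk$ci_low > 0 || blk$ci_high < 0)
  # PoE route needs both legs of the adjusted pathway: a non-null
  # first-stage effect and a significant MVMR-adjusted mediator effect.
  b_adj_sig <- sig(b_adj) && sig(a)
  sob <- sobel_test(a$est, a$se, b$est, b$se)

  if (b_adj_sig) {
    method <- "propagation_of_error"
    ind <- indirect_effect_poe(a$est, a$se, b_adj$est, b_adj$se)
  } else if (sob$p < alpha) {
    method <- "sobel"
    ind <- indirect_effect_poe(a$est, a$se, b$est, b$se)
  } else {
    method <- "not_available"
    ind <- list(indirect = NA_real_, indirect_se = NA_real_)
  }

  prop <- if (method == "not_available") {
    list(proportion = NA_real_, proportion_se = NA_real_)
  } else {
    mediated_proportion(ind$indirect, cc$est, ind$indirect_se, cc$se)
  }

  structure(list(
    exposure = exposure, mediator = mediator, outcome = outcome,
    beta_a = a, beta_b = b, beta_c = cc,
    beta_b_adj = b_adj, beta_c_adj = c_adj,
    indirect = ind$indirect, indirect_se = ind$indirect_se,
    sobel_z = sob$z, sobel_p = sob$p,
    proportion = prop$proportion, proportion_se = prop$proportion_se,
    method_flag = method, alpha = alpha
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s\n", x$exposure, x$mediator,
              x$outcome))
  cat(sprintf("  method: %s\n", x$method_flag))
  if (!is.na(x$proportion)) {
    cat(sprintf("  indirect = %.4g, mediated proportion = %.2f%%\n",
                x$indirect, 100 * x$proportion))
  } else {
    cat("  mediated proportion: not available\n")
  }
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  blk <- function(b, nm) {
    if (is.null(b)) {
      out <- data.frame(NA_real_, NA_real_, NA_real_, NA_real_)
    } else {
      out <- data.frame(b$est, b$se, b$ci_low, b$ci_high)
    }
    names(out) <- paste0(nm, c("", "_se", "_lci", "_uci"))
    out
  }
  cbind(data.frame(exposure = x$exposure, mediator = x$mediator,
                   outcome = x$outcome, stringsAsFactors = FALSE),
        blk(x$beta_c, "beta_c"), blk(x$beta_a, "beta_a"),
        blk(x$beta_b, "beta_b"), blk(x$beta_c_adj, "beta_c_adj"),
        blk(x$beta_b_adj, "beta_b_adj"),
        data.frame(sobel_z = x$sobel_z, sobel_p = x$sobel_p,
                   indirect = x$indirect, indirect_se = x$indirect_se,
                   proportion_pct = 100 * x$proportion,
                   method_flag = x$method_flag,
                   stringsAsFactors = FALSE))
}

#' Run the full two-step MR mediation analysis
#'
#' Estimates `beta_a` (IVW of exposure on mediator), `beta_b` (IVW of
#' mediator on outcome), `beta_c` (IVW of exposure on outcome), fits MVMR
#' of exposure + mediator on the outcome to obtain the adjusted direct
#' effects `beta_c_adj` (exposure row) and `beta_b_adj` (mediator row),
#' then applies the decision rule of [mediation_decide()].
#'
#' @param exposure,mediator,outcome Full summary-statistics data.frames.
#' @param pval_threshold Instrument thresholds: scalar or length-2 vector
#'   `(exposure, mediator)`.
#' @param ld,r2_threshold,kb_window Clumping parameters.
#' @param alpha Significance level for the decision rule.
#' @param labels Character vector of length 3 naming the traits.
#' @return A `mediation_result`.
#' @export
run_two_step_mediation <- function(exposure, mediator, outcome,
                                   pval_threshold = 5e-6, ld = NULL,
                                   r2_threshold = 0.001, kb_window = 10000,
                                   alpha = 0.05,
                                   labels = c("exposure", "mediator",
                                              "outcome")) {
  thr <- rep_len(pval_threshold, 2)
  stage <- function(expr, name) {
    tryCatch(expr, error = function(e) {
      mr_error(sprintf("mediation stage '%s' failed: %s", name,
                       conditionMessage(e)), "mr_stage_error")
    })
  }
  iv_exp <- stage(select_instruments(exposure, thr[1], ld = ld,
                                     r2_threshold = r2_threshold,
                                     kb_window = kb_window),
                  "exposure instruments")
  iv_med <- stage(select_instruments(mediator, thr[2], ld = ld,
                                     r2_threshold = r2_threshold,
                                     kb_window = kb_window),
                  "mediator instruments")
  fit_uv <- function(iv, target, name) {
    stage(mr_ivw_primary(harmonize(iv, target)), name)
  }
  res_a <- fit_uv(iv_exp, mediator, "beta_a (exposure->mediator)")
  res_b <- fit_uv(iv_med, outcome, "beta_b (mediator->outcome)")
  res_c <- fit_uv(iv_exp, outcome, "beta_c (exposure->outcome)")

  mv <- tryCatch({
    mh <- mvmr_harmonize(stats::setNames(list(exposure, mediator),
                                         labels[1:2]),
                         outcome, pval_threshold = thr, ld = ld,
                         r2_threshold = r2_threshold,
                         kb_window = kb_window)
    mvmr_fit(mh)
  }, error = function(e) NULL)

  blk <- function(r) list(est = r$beta, se = r$se)
  b_adj <- c_adj <- NULL
  if (!is.null(mv)) {
    c_adj <- list(est = mv$betas[1], se = mv$ses[1])
    b_adj <- list(est = mv$betas[2], se = mv$ses[2])
  }
  mediation_decide(blk(res_a), blk(res_b), blk(res_c),
                   beta_b_adj = b_adj, beta_c_adj = c_adj, alpha = alpha,
                   exposure = labels[1], mediator = labels[2],
                   outcome = labels[3])
}
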
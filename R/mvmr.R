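# Multivariable MR: joint estimation of direct effects of several
# exposures on one outcome, used here mainly to adjust an exposure effect
# for a mediator (and vice versa).

#' Construct a multi-exposure harmonized set
#'
#' Low-level constructor around a k x p matrix of exposure betas paired
#' with outcome betas.
#'
#' @param beta_exposures Numeric matrix (SNPs x exposures) with column
#'   names.
#' @param se_exposures Matrix of matching dimensions, entries > 0.
#' @param beta_outcome,se_outcome Numeric vectors of length `nrow(beta_exposures)`.
#' @param snp Optional SNP identifiers.
#' @return An object of class `mvmr_set`.
#' @export
mvmr_set <- function(beta_exposures, se_exposures, beta_outcome, se_outcome,
                     snp = NULL) {
  beta_exposures <- as.matrix(beta_exposures)
  se_exposures <- as.matrix(se_exposures)
  k <- nrow(beta_exposures)
  if (is.null(colnames(beta_exposures))) {
    colnames(beta_exposures) <- paste0("exposure", seq_len(ncol(beta_exposures)))
  }
  if (length(beta_outcome) != k || length(se_outcome) != k ||
      !all(dim(se_exposures) == dim(beta_exposures))) {
    mr_error("mvmr_set: inconsistent dimensions", "mr_validation_error")
  }
  if (any(se_outcome <= 0) || any(se_exposures <= 0)) {
    mr_error("mvmr_set: standard errors must be positive",
             "mr_validation_error")
  }
  if (is.null(snp)) snp <- paste0("snp", seq_len(k))
  structure(list(snp = as.character(snp), beta_exposures = beta_exposures,
                 se_exposures = se_exposures,
                 beta_outcome = as.numeric(beta_outcome),
                 se_outcome = as.numeric(se_outcome),
                 exposures = colnames(beta_exposures),
                 log = data.frame(snp = character(), action = character(),
                                  reason = character(),
                                  stringsAsFactors = FALSE)),
            class = "mvmr_set")
}

#' @export
print.mvmr_set <- function(x, ...) {
  cat(sprintf("MVMR set: %d SNPs x %d exposures (%s)\n",
              length(x$snp), length(x$exposures),
              paste(x$exposures, collapse = ", ")))
  invisible(x)
}

#' Harmonize several exposures and one outcome for MVMR
#'
#' Builds the joint instrument set: the union of each exposure's clumped
#' instruments, restricted to SNPs present in every exposure GWAS and in
#' the outcome GWAS, re-clumped jointly (ranked by the best p-value across
#' exposures). Alleles are aligned pairwise onto the first exposure's
#' effect-allele convention using the same rules as [harmonize()].
#'
#' @param exposure_sets Named list (>= 2) of full summary-statistics
#'   data.frames, one per exposure.
#' @param outcome Outcome summary-statistics data.frame.
#' @param pval_threshold Instrument threshold applied to each exposure
#'   (scalar or vector, one per exposure).
#' @param ld Optional LD matrix for clumping.
#' @param r2_threshold,kb_window Clumping parameters.
#' @param palindrome_eaf_window Passed to the allele-alignment rules.
#' @return An `mvmr_set`.
#' @export
mvmr_harmonize <- function(exposure_sets, outcome, pval_threshold = 5e-6,
                           ld = NULL, r2_threshold = 0.001,
                           kb_window = 10000,
                           palindrome_eaf_window = 0.08) {
  p <- length(exposure_sets)
  if (p < 2L) mr_error("MVMR needs at least 2 exposures",
                       "mr_validation_error")
  if (is.null(names(exposure_sets))) {
    names(exposure_sets) <- paste0("exposure", seq_len(p))
  }
  thr <- rep_len(pval_threshold, p)

  # Per-exposure clumped instruments, then union.
  inst <- mapply(function(recs, t) {
    select_instruments(recs, pval_threshold = t, ld = ld,
                       r2_threshold = r2_threshold, kb_window = kb_window)
  }, exposure_sets, thr, SIMPLIFY = FALSE)
  union_snps <- unique(unlist(lapply(inst, function(x) x$snp)))

  # Restrict to SNPs present in every source.
  present <- Reduce(intersect,
                    c(lapply(exposure_sets, function(x) x$snp),
                      list(outcome$snp)))
  joint <- intersect(union_snps, present)
  if (length(joint) == 0L) {
    counts <- vapply(c(exposure_sets, list(outcome = outcome)),
                     function(x) length(intersect(union_snps, x$snp)),
                     integer(1))
    mr_error(paste0("no SNPs shared across all sources; per-source overlap: ",
                    paste(sprintf("%s=%d", names(counts), counts),
                          collapse = ", ")),
             "mr_empty_overlap_error")
  }

  # Joint re-clump, ranking by the best p-value across exposures.
  first <- exposure_sets[[1]]
  base <- first[match(joint, first$snp), , drop = FALSE]
  best_p <- do.call(pmin, c(lapply(exposure_sets, function(x) {
    x$pval[match(joint, x$snp)]
  }), list(na.rm = TRUE)))
  base$pval <- best_p
  base <- ld_clump(base, ld = ld, r2_threshold = r2_threshold,
                   kb_window = kb_window)
  joint <- base$snp

  # Align every other exposure and the outcome onto exposure 1's alleles.
  ref <- first[match(joint, first$snp), , drop = FALSE]
  align <- function(target) {
    hs <- harmonize(ref, target,
                    palindrome_eaf_window = palindrome_eaf_window)
    hs
  }
  aligned <- lapply(c(exposure_sets[-1], list(.outcome = outcome)), align)
  kept <- Reduce(intersect, c(list(joint),
                              lapply(aligned, function(h) h$data$snp)))
  if (length(kept) <= p) {
    mr_error("too few jointly harmonized SNPs for MVMR",
             "mr_empty_overlap_error")
  }

  bmat <- matrix(NA_real_, length(kept), p,
                 dimnames = list(kept, names(exposure_sets)))
  smat <- bmat
  ridx <- match(kept, ref$snp)
  bmat[, 1] <- ref$beta[ridx]; smat[, 1] <- ref$se[ridx]
  for (e in seq_len(p - 1)) {
    h <- aligned[[e]]
    idx <- match(kept, h$data$snp)
    bmat[, e + 1] <- h$data$beta_outcome[idx]
    smat[, e + 1] <- h$data$se_outcome[idx]
  }
  ho <- aligned[[p]]  # the outcome alignment
  oidx <- match(kept, ho$data$snp)
  mvmr_set(bmat, smat, ho$data$beta_outcome[oidx],
           ho$data$se_outcome[oidx], snp = kept)
}

#' Fit a multivariable MR model
#'
#' Weighted least squares of the outcome betas on the exposure-beta matrix
#' with no intercept, weights `1/se_outcome^2`. SEs from the weighted
#' normal equations are inflated by `max(1, sqrt(Q_mv/df))`, where `Q_mv`
#' is the weighted residual sum of squares and `df = n_snp - n_exposures`.
#'
#' @param mh An `mvmr_set`.
#' @return List of class `mvmr_result`: `exposures`, `betas`, `ses`,
#'   `pvals`, `ci_low`, `ci_high`, `q`, `df`, `n_snp`.
#' @export
mvmr_fit <- function(mh) {
  X <- mh$beta_exposures
  k <- nrow(X); p <- ncol(X)
  if (k <= p + 1) {
    mr_error("MVMR requires n_snp > n_exposures + 1", "mr_domain_error")
  }
  # An exposure with no instrument signal at all (all-zero column) carries
  # no identifying information; drop it from the fit and report NA.
  nonzero <- colSums(X != 0) > 0
  Xf <- X[, nonzero, drop = FALSE]
  if (ncol(Xf) == 0L) {
    mr_error("all exposure-beta columns are zero", "mr_collinearity_error")
  }
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    bad <- mh$exposures[nonzero][qrX$pivot[seq(qrX$rank + 1, ncol(Xf))]]
    mr_error(sprintf("collinear MVMR design; offending exposure(s): %s",
                     paste(bad, collapse = ", ")),
             "mr_collinearity_error")
  }
  fit <- wls_fit(Xf, mh$beta_outcome, 1 / mh$se_outcome^2)
  betas <- ses <- rep(NA_real_, p)
  betas[nonzero] <- fit$coef
  ses[nonzero] <- fit$se
  pvals <- 2 * stats::pnorm(-abs(betas / ses))
  structure(list(exposures = mh$exposures,
                 betas = betas, ses = ses, pvals = pvals,
                 ci_low = betas - 1.96 * ses,
                 ci_high = betas + 1.96 * ses,
                 q = fit$rss_w, df = fit$df, n_snp = k),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("MVMR fit on %d SNPs (Q = %.3g, df = %d)\n", x$n_snp, x$q,
              x$df))
  for (i in seq_along(x$exposures)) {
    cat(sprintf("  %s: beta = %.4g (se %.4g), p = %.3g\n",
                x$exposures[i], x$betas[i], x$ses[i], x$pvals[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.mvmr_result <- function(x, ...) {
  data.frame(exposure = x$exposures, beta = x$betas, se = x$ses,
             pval = x$pvals, ci_low = x$ci_low, ci_high = x$ci_high,
             n_snp = x$n_snp, stringsAsFactors = FALSE)
}
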
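# Univariable two-sample MR estimators.
#
# All estimators consume a harmonized_set of per-SNP (beta_exposure,
# beta_outcome) pairs with standard errors. The IVW estimate is the
# inverse-variance-weighted consolidation of per-SNP Wald ratios,
# equivalently weighted regression of the outcome betas on the exposure
# betas through the origin with weights 1/se_outcome^2.

new_mr_result <- function(method, beta, se, pval, n_snp, extra = list()) {
  ci_low <- beta - 1.96 * se
  ci_high <- beta + 1.96 * se
  structure(list(
    method = method, beta = beta, se = se, pval = pval,
    ci_low = ci_low, ci_high = ci_high,
    or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
    n_snp = n_snp, extra = extra
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), p = %.3g, OR = %.2f [%.2f-%.2f], nSNP = %d\n",
              x$method, x$beta, x$se, x$pval, x$or, x$or_low, x$or_high,
              x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             pval = x$pval, ci_low = x$ci_low, ci_high = x$ci_high,
             or = x$or, or_low = x$or_low, or_high = x$or_high,
             stringsAsFactors = FALSE)
}

#' Wald ratio estimate for a single instrument
#'
#' Per-SNP causal estimate `by/bx` with first-order standard error
#' `sey/|bx|` (the exposure-side uncertainty is ignored at first order) and
#' a two-sided normal p-value.
#'
#' @param bx,by Per-allele effects on exposure and outcome.
#' @param sey Standard error of `by`.
#' @param sex Standard error of `bx` (carried for future use; not entering
#'   the first-order SE).
#' @return An `mr_result` with method `"wald"`.
#' @export
wald_ratio <- function(bx, by, sey, sex = NA_real_) {
  if (!is_scalar_number(bx) || bx == 0) {
    mr_error("degenerate instrument: exposure beta is zero",
             "mr_degenerate_error")
  }
  beta <- by / bx
  se <- sey / abs(bx)
  new_mr_result("wald", beta, se, z_pvalue(beta, se), 1L)
}

ivw_weights <- function(hset) 1 / hset$data$se_outcome^2

# Cochran's Q for the IVW model: Q = sum w_j (theta_j - theta_ivw)^2 with
# theta_j the Wald ratios and w_j = bx_j^2 / sey_j^2.
ivw_q <- function(hset, beta_ivw) {
  d <- hset$data
  theta <- d$beta_outcome / d$beta_exposure
  w <- d$beta_exposure^2 / d$se_outcome^2
  sum(w * (theta - beta_ivw)^2)
}

#' Inverse-variance-weighted estimate
#'
#' The primary MR estimator: weighted regression of outcome betas on
#' exposure betas through the origin, weights `1/se_outcome^2`. Both the
#' fixed-effect SE and the multiplicative-random-effects (MRE) SE are
#' returned; they share the same point estimate, and the MRE SE inflates
#' the fixed SE by `max(1, sqrt(Q/(k-1)))` where Q is Cochran's Q over the
#' per-SNP Wald ratios. With a single SNP the estimator falls back to the
#' Wald ratio (with a logged notice).
#'
#' @param hset A `harmonized_set`.
#' @return A list with elements `fixed` and `random` (both `mr_result`),
#'   plus `q`, `q_df`, `q_pval`. With one SNP both elements are the Wald
#'   ratio and Q is `NA`.
#' @export
mr_ivw <- function(hset) {
  d <- hset$data
  k <- nrow(d)
  if (k < 2L) {
    res <- wald_ratio(d$beta_exposure[1], d$beta_outcome[1],
                      d$se_outcome[1], d$se_exposure[1])
    message("mr_ivw: single instrument; falling back to Wald ratio")
    return(list(fixed = res, random = res,
                q = NA_real_, q_df = NA_integer_, q_pval = NA_real_))
  }
  w <- ivw_weights(hset)
  sxx <- sum(w * d$beta_exposure^2)
  beta <- sum(w * d$beta_exposure * d$beta_outcome) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- ivw_q(hset, beta)
  scale <- max(1, sqrt(q / (k - 1)))
  se_mre <- se_fixed * scale
  list(
    fixed = new_mr_result("ivw_fixed", beta, se_fixed,
                          z_pvalue(beta, se_fixed), k,
                          extra = list(q = q, q_df = k - 1L)),
    random = new_mr_result("ivw_mre", beta, se_mre,
                           z_pvalue(beta, se_mre), k,
                           extra = list(q = q, q_df = k - 1L,
                                        scale = scale)),
    q = q, q_df = k - 1L,
    q_pval = stats::pchisq(q, k - 1L, lower.tail = FALSE)
  )
}

# Headline IVW: MRE when over-dispersed (Q/(k-1) > 1), else fixed.
#' @rdname mr_ivw
#' @param which Which variant to return from [mr_ivw_primary()]: `"auto"`
#'   picks MRE when `Q/(k-1) > 1`, else fixed.
#' @export
mr_ivw_primary <- function(hset, which = c("auto", "fixed", "random")) {
  which <- match.arg(which)
  fit <- mr_ivw(hset)
  if (which == "fixed") return(fit$fixed)
  if (which == "random") return(fit$random)
  if (!is.na(fit$q) && fit$q / fit$q_df > 1) fit$random else fit$fixed
}

# Orient every pair so the exposure beta is non-negative (flip both signs
# otherwise); required for MR-Egger's intercept to be interpretable.
egger_orient <- function(hset) {
  d <- hset$data
  s <- ifelse(d$beta_exposure < 0, -1, 1)
  list(bx = s * d$beta_exposure, by = s * d$beta_outcome,
       sey = d$se_outcome)
}

# Weighted least squares via the normal equations; returns coefficients,
# SEs scaled by max(1, residual standard error), and the weighted RSS.
wls_fit <- function(X, y, w) {
  XtW <- t(X * w)
  xtx <- XtW %*% X
  if (abs(det(xtx)) < 1e-300) {
    mr_error("rank-deficient weighted least-squares design",
             "mr_collinearity_error")
  }
  xtx_inv <- solve(xtx)
  coef <- drop(xtx_inv %*% (XtW %*% y))
  resid <- y - drop(X %*% coef)
  rss_w <- sum(w * resid^2)
  df <- nrow(X) - ncol(X)
  sigma <- if (df > 0) sqrt(rss_w / df) else NA_real_
  scale <- if (df > 0) max(1, sigma) else 1
  se <- sqrt(diag(xtx_inv)) * scale
  list(coef = coef, se = se, rss_w = rss_w, df = df, sigma = sigma)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome betas on exposure betas
#' *with* an intercept (weights `1/se_outcome^2`), after orienting every
#' SNP so its exposure beta is non-negative. The slope is the
#' pleiotropy-adjusted causal estimate; a non-zero intercept indicates
#' directional pleiotropy. SEs are inflated by `max(1, residual standard
#' error)` and p-values use the t distribution with `k - 2` df.
#'
#' @param hset A `harmonized_set` with at least 3 SNPs.
#' @return An `mr_result` with method `"egger"`; `extra` carries
#'   `intercept`, `intercept_se`, `intercept_pval`, `sigma`, `q` (weighted
#'   residual sum of squares) and `q_df`.
#' @export
mr_egger <- function(hset) {
  k <- n_snps(hset)
  if (k < 3L) {
    mr_error("MR-Egger requires at least 3 instruments",
             "mr_insufficient_instruments_error")
  }
  o <- egger_orient(hset)
  X <- cbind(intercept = 1, slope = o$bx)
  fit <- wls_fit(X, o$by, 1 / o$sey^2)
  slope <- fit$coef[["slope"]]; slope_se <- fit$se[[2]]
  int <- fit$coef[["intercept"]]; int_se <- fit$se[[1]]
  p_t <- function(est, se) 2 * stats::pt(-abs(est / se), df = k - 2)
  new_mr_result("egger", slope, slope_se, p_t(slope, slope_se), k,
                extra = list(intercept = int, intercept_se = int_se,
                             intercept_pval = p_t(int, int_se),
                             sigma = fit$sigma, q = fit$rss_w,
                             q_df = k - 2L))
}

# Wald ratios and their weights; SNPs with bx == 0 are excluded.
theta_weights <- function(hset) {
  d <- hset$data
  ok <- d$beta_exposure != 0
  if (!all(ok)) {
    message(sprintf("excluding %d SNP(s) with zero exposure beta: %s",
                    sum(!ok), paste(d$snp[!ok], collapse = ", ")))
  }
  d <- d[ok, , drop = FALSE]
  list(theta = d$beta_outcome / d$beta_exposure,
       w = d$beta_exposure^2 / d$se_outcome^2,
       data = d)
}

# Weighted median of values x with weights w: the point where the weighted
# empirical CDF (midpoint convention) crosses 0.5, linearly interpolated.
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cdf <- cumsum(w) - w / 2
  if (cdf[1] >= 0.5) return(x[1])
  n <- length(x)
  if (cdf[n] <= 0.5) return(x[n])
  j <- max(which(cdf < 0.5))
  x[j] + (x[j + 1] - x[j]) * (0.5 - cdf[j]) / (cdf[j + 1] - cdf[j])
}

boot_se <- function(hset, n_boot, seed, point_fun) {
  d <- hset$data
  k <- nrow(d)
  if (!is.null(seed)) set.seed(seed)
  bx <- matrix(stats::rnorm(n_boot * k, mean = rep(d$beta_exposure,
                                                   each = n_boot),
                            sd = rep(d$se_exposure, each = n_boot)),
               nrow = n_boot)
  by <- matrix(stats::rnorm(n_boot * k, mean = rep(d$beta_outcome,
                                                   each = n_boot),
                            sd = rep(d$se_outcome, each = n_boot)),
               nrow = n_boot)
  est <- vapply(seq_len(n_boot), function(b) {
    nz <- bx[b, ] != 0
    point_fun(by[b, nz] / bx[b, nz],
              bx[b, nz]^2 / d$se_outcome[nz]^2)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted median estimator
#'
#' Consistent when at least half the weight comes from valid instruments.
#' The estimate is the weighted median of the per-SNP Wald ratios with
#' weights `bx^2/sey^2`; the SE comes from a seeded parametric bootstrap
#' (resampling bx and by from normals with their reported SEs).
#'
#' @param hset A `harmonized_set` with at least 3 usable SNPs.
#' @param n_boot Bootstrap replicates (default 5000).
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_result` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(hset, n_boot = 5000, seed = NULL) {
  tw <- theta_weights(hset)
  if (length(tw$theta) < 3L) {
    mr_error("weighted median requires at least 3 usable instruments",
             "mr_insufficient_instruments_error")
  }
  beta <- weighted_median_point(tw$theta, tw$w)
  hs_use <- hset; hs_use$data <- tw$data
  se <- boot_se(hs_use, n_boot, seed, weighted_median_point)
  new_mr_result("weighted_median", beta, se, z_pvalue(beta, se),
                length(tw$theta))
}

# Modified Silverman bandwidth on the ratio estimates.
mode_bandwidth <- function(theta, bandwidth_factor) {
  s <- min(stats::sd(theta), stats::IQR(theta) / 1.349)
  h <- bandwidth_factor * 0.9 * s * length(theta)^(-1 / 5)
  h
}

weighted_mode_point <- function(theta, w, bandwidth_factor = 1) {
  w <- w / sum(w)
  h <- mode_bandwidth(theta, bandwidth_factor)
  if (!is.finite(h) || h <= 0) {
    # Degenerate spread: fall back to the most-weighted value.
    return(theta[which.max(w)])
  }
  dens <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm((xi - theta) / h)),
           numeric(1))
  }
  grid <- seq(min(theta), max(theta), length.out = 512)
  x0 <- grid[which.max(dens(grid))]
  lo <- max(min(theta), x0 - 2 * h)
  hi <- min(max(theta), x0 + 2 * h)
  if (lo >= hi) return(x0)
  stats::optimize(dens, c(lo, hi), maximum = TRUE)$maximum
}

#' Weighted mode estimator
#'
#' Mode of the weighted kernel-smoothed density of the per-SNP Wald ratios
#' (normal kernel; bandwidth = `bandwidth_factor` times a modified Silverman
#' rule), consistent when the largest group of instruments sharing a causal
#' estimate is valid. Bootstrap SE as in [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the Silverman bandwidth.
#' @return An `mr_result` with method `"weighted_mode"`.
#' @export
mr_weighted_mode <- function(hset, bandwidth_factor = 1, n_boot = 5000,
                             seed = NULL) {
  tw <- theta_weights(hset)
  if (length(tw$theta) < 3L) {
    mr_error("weighted mode requires at least 3 usable instruments",
             "mr_insufficient_instruments_error")
  }
  beta <- weighted_mode_point(tw$theta, tw$w, bandwidth_factor)
  hs_use <- hset; hs_use$data <- tw$data
  se <- boot_se(hs_use, n_boot, seed,
                function(th, w) weighted_mode_point(th, w, bandwidth_factor))
  new_mr_result("weighted_mode", beta, se, z_pvalue(beta, se),
                length(tw$theta))
}

#' Log-odds effect to odds ratio with 95\% CI
#'
#' Exponentiates a log-odds estimate and its normal-theory 95\% CI. Either
#' supply `se` (CI taken as `beta +/- 1.96*se`) or an explicit CI pair.
#'
#' @param beta Log-odds effect estimate.
#' @param se Optional standard error.
#' @param ci Optional length-2 CI `(low, high)` on the log-odds scale;
#'   overrides `se`.
#' @return Named numeric vector `(or, or_low, or_high)`.
#' @export
effect_to_or <- function(beta, se = NULL, ci = NULL) {
  if (!is.null(ci)) {
    c(or = exp(beta), or_low = exp(ci[1]), or_high = exp(ci[2]))
  } else {
    if (is.null(se) || se <= 0) {
      mr_error("effect_to_or needs se > 0 or an explicit CI",
               "mr_validation_error")
    }
    c(or = exp(beta), or_low = exp(beta - 1.96 * se),
      or_high = exp(beta + 1.96 * se))
  }
}

#' Run a set of univariable MR estimators
#'
#' @param hset A `harmonized_set`.
#' @param methods Character subset of
#'   `c("ivw", "egger", "weighted_median", "weighted_mode")`.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param seed Seed governing all bootstrap resampling.
#' @return A data.frame with one row per fitted method (IVW contributes its
#'   fixed and MRE variants).
#' @export
mr_all_methods <- function(hset,
                           methods = c("ivw", "egger", "weighted_median",
                                       "weighted_mode"),
                           n_boot = 5000, seed = NULL) {
  rows <- list()
  if ("ivw" %in% methods) {
    fit <- mr_ivw(hset)
    rows <- c(rows, list(as.data.frame(fit$fixed),
                         as.data.frame(fit$random)))
  }
  if ("egger" %in% methods && n_snps(hset) >= 3) {
    rows <- c(rows, list(as.data.frame(mr_egger(hset))))
  }
  if ("weighted_median" %in% methods && n_snps(hset) >= 3) {
    rows <- c(rows, list(as.data.frame(
      mr_weighted_median(hset, n_boot = n_boot, seed = seed))))
  }
  if ("weighted_mode" %in% methods && n_snps(hset) >= 3) {
    rows <- c(rows, list(as.data.frame(
      mr_weighted_mode(hset, n_boot = n_boot, seed = seed))))
  }
  do.call(rbind, rows)
}
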
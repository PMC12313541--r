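# Sensitivity diagnostics for a univariable MR fit: heterogeneity,
# directional pleiotropy, leave-one-out stability, MR-PRESSO outlier
# detection, and funnel-plot coordinates.

#' Cochran's Q heterogeneity test
#'
#' IVW variant: `Q = sum w_j (theta_j - theta_ivw)^2` over the per-SNP Wald
#' ratios with `w_j = bx_j^2/sey_j^2`, df `k - 1`. Egger variant: the
#' weighted residual sum of squares from the MR-Egger fit, df `k - 2`.
#' Heterogeneity is conventionally flagged at `p < 0.05`.
#'
#' @param hset A `harmonized_set`.
#' @param method `"ivw"` (k >= 2) or `"egger"` (k >= 3).
#' @return List `(method, q, df, pval)`.
#' @export
cochran_q <- function(hset, method = c("ivw", "egger")) {
  method <- match.arg(method)
  k <- n_snps(hset)
  if (method == "ivw") {
    if (k < 2L) mr_error("Cochran's Q (IVW) requires k >= 2",
                         "mr_insufficient_instruments_error")
    fit <- mr_ivw(hset)
    q <- fit$q; df <- k - 1L
  } else {
    if (k < 3L) mr_error("Cochran's Q (Egger) requires k >= 3",
                         "mr_insufficient_instruments_error")
    fit <- mr_egger(hset)
    q <- fit$extra$q; df <- k - 2L
  }
  list(method = method, q = q, df = df,
       pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Egger-intercept test for directional pleiotropy
#'
#' Returns the intercept block of the MR-Egger regression; a two-sided
#' t(k-2) p-value below 0.05 indicates directional pleiotropy.
#'
#' @param hset A `harmonized_set` with k >= 3.
#' @return List `(intercept, se, pval)`.
#' @export
pleiotropy_test <- function(hset) {
  fit <- mr_egger(hset)
  list(intercept = fit$extra$intercept, se = fit$extra$intercept_se,
       pval = fit$extra$intercept_pval)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the random-effects IVW estimate excluding each SNP in turn, plus
#' an `"all"` row for the full set. Rows whose 95% CI excludes the full-set
#' estimate are flagged `influential`.
#'
#' @param hset A `harmonized_set` with k >= 3.
#' @return A data.frame `(excluded_snp, n_snp, beta, se, pval, ci_low,
#'   ci_high, influential)` with `k + 1` rows.
#' @export
leave_one_out <- function(hset) {
  k <- n_snps(hset)
  if (k < 3L) mr_error("leave-one-out requires k >= 3",
                       "mr_insufficient_instruments_error")
  full <- mr_ivw(hset)$random
  rows <- lapply(seq_len(k), function(j) {
    sub <- hset
    sub$data <- hset$data[-j, , drop = FALSE]
    fit <- mr_ivw(sub)$random
    data.frame(excluded_snp = hset$data$snp[j], n_snp = k - 1L,
               beta = fit$beta, se = fit$se, pval = fit$pval,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(excluded_snp = "all", n_snp = k,
                               beta = full$beta, se = full$se,
                               pval = full$pval, ci_low = full$ci_low,
                               ci_high = full$ci_high,
                               stringsAsFactors = FALSE))
  out$influential <- full$beta < out$ci_low | full$beta > out$ci_high
  out
}

# Leave-one-out IVW slopes theta_(-j) for every j, computed by downdating
# the weighted sums; w = 1/sey^2.
loo_slopes <- function(bx, by, sey) {
  w <- 1 / sey^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global and outlier tests
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. The observed
#' global statistic is `RSS = sum w_j (by_j - theta_(-j) * bx_j)^2` with
#' leave-one-out IVW slopes `theta_(-j)` and `w_j = 1/sey_j^2`. Its null
#' distribution is simulated by drawing `by*_j ~ N(theta_(-j)*bx_j, sey_j)`
#' and `bx*_j ~ N(bx_j, sex_j)` and recomputing RSS `n_sim` times; the
#' global p-value is `(1 + #{RSS* >= RSS_obs}) / (n_sim + 1)`. Each SNP's
#' outlier p-value is the empirical tail of its observed weighted squared
#' residual within its own simulated residual distribution,
#' Bonferroni-adjusted by k; SNPs below `sig` are flagged and the IVW
#' estimate is refit without them (`beta_corrected`).
#'
#' @param hset A `harmonized_set` with k >= 4.
#' @param n_sim Number of simulated null datasets (default 1000; a value
#'   below 100 triggers a warning).
#' @param sig Outlier significance threshold on the adjusted p (default
#'   0.05).
#' @param seed Integer seed; the same seed and input give bit-identical
#'   results.
#' @return List `(global_rss, global_pval, outlier_pvals, outliers, n_sim,
#'   seed, beta_raw, beta_corrected)`.
#' @export
mr_presso <- function(hset, n_sim = 1000, sig = 0.05, seed = NULL) {
  d <- hset$data
  k <- nrow(d)
  if (k < 4L) mr_error("MR-PRESSO requires k >= 4",
                       "mr_insufficient_instruments_error")
  if (n_sim < 100) warning("mr_presso: n_sim < 100 gives a coarse p-value")
  bx <- d$beta_exposure; by <- d$beta_outcome
  sex <- d$se_exposure; sey <- d$se_outcome
  w <- 1 / sey^2

  th <- loo_slopes(bx, by, sey)
  res_obs <- w * (by - th * bx)^2
  rss_obs <- sum(res_obs)

  if (!is.null(seed)) set.seed(seed)
  bx_sim <- matrix(stats::rnorm(n_sim * k, rep(bx, each = n_sim),
                                rep(sex, each = n_sim)), nrow = n_sim)
  by_sim <- matrix(stats::rnorm(n_sim * k, rep(th * bx, each = n_sim),
                                rep(sey, each = n_sim)), nrow = n_sim)
  res_sim <- matrix(0, n_sim, k)
  rss_sim <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    th_s <- loo_slopes(bx_sim[s, ], by_sim[s, ], sey)
    rs <- w * (by_sim[s, ] - th_s * bx_sim[s, ])^2
    res_sim[s, ] <- rs
    rss_sim[s] <- sum(rs)
  }
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_p <- vapply(seq_len(k), function(j) {
    p <- (1 + sum(res_sim[, j] >= res_obs[j])) / (n_sim + 1)
    min(1, p * k)  # Bonferroni by number of instruments
  }, numeric(1))
  names(outlier_p) <- d$snp
  outliers <- d$snp[outlier_p < sig]

  beta_raw <- mr_ivw(hset)$fixed$beta
  beta_corrected <- if (length(outliers) > 0 &&
                        k - length(outliers) >= 2) {
    sub <- hset
    sub$data <- d[!d$snp %in% outliers, , drop = FALSE]
    mr_ivw(sub)$fixed$beta
  } else beta_raw

  list(global_rss = rss_obs, global_pval = global_pval,
       outlier_pvals = outlier_p, outliers = outliers,
       n_sim = n_sim, seed = seed,
       beta_raw = beta_raw, beta_corrected = beta_corrected)
}

#' Funnel-plot coordinates
#'
#' Per-SNP Wald ratio and its precision (reciprocal first-order SE); a
#' symmetric funnel around the IVW estimate indicates balanced pleiotropy.
#' SNPs with zero exposure beta are excluded with a message.
#'
#' @param hset A `harmonized_set`.
#' @return A data.frame `(snp, theta, precision)`.
#' @export
funnel_coordinates <- function(hset) {
  tw <- theta_weights(hset)
  d <- tw$data
  data.frame(snp = d$snp, theta = tw$theta,
             precision = abs(d$beta_exposure) / d$se_outcome,
             stringsAsFactors = FALSE)
}

#' Full sensitivity suite
#'
#' Convenience wrapper running heterogeneity (IVW + Egger), the Egger
#' intercept test, leave-one-out, MR-PRESSO and funnel coordinates.
#'
#' @inheritParams mr_presso
#' @param presso_n_sim Simulations for MR-PRESSO.
#' @return Named list of the individual results.
#' @export
sensitivity_suite <- function(hset, presso_n_sim = 1000, sig = 0.05,
                              seed = NULL) {
  k <- n_snps(hset)
  list(
    heterogeneity_ivw = if (k >= 2) cochran_q(hset, "ivw"),
    heterogeneity_egger = if (k >= 3) cochran_q(hset, "egger"),
    pleiotropy = if (k >= 3) pleiotropy_test(hset),
    leave_one_out = if (k >= 3) leave_one_out(hset),
    presso = if (k >= 4) mr_presso(hset, n_sim = presso_n_sim, sig = sig,
                                   seed = seed),
    funnel = funnel_coordinates(hset)
  )
}
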
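# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

make_hset <- function(bx, by, sey, sex = NULL, snp = NULL) {
  if (is.null(sex)) sex <- rep(1e-3, length(bx))
  harmonized_set(beta_exposure = bx, se_exposure = sex,
                 beta_outcome = by, se_outcome = sey, snp = snp)
}

# Canonical records data.frame with sensible defaults.
make_records <- function(snp, beta, se, pval = NULL, eaf = 0.3,
                         ea = "A", oa = "G", chr = "1", pos = NULL,
                         n = 1e5) {
  k <- length(snp)
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  if (is.null(pos)) pos <- seq_len(k) * 3e7
  data.frame(snp = snp, chr = rep_len(chr, k), pos = pos,
             effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
             eaf = rep_len(eaf, k), beta = beta, se = se, pval = pval,
             n = rep_len(n, k), stringsAsFactors = FALSE)
}

# Convert a harmonized set back into exposure/outcome record tables (used
# for the idempotence property).
hset_to_records <- function(hs) {
  d <- hs$data
  k <- nrow(d)
  base <- function(beta, se) {
    make_records(d$snp, beta, se, eaf = ifelse(is.na(d$eaf), 0.3, d$eaf))
  }
  list(exposure = base(d$beta_exposure, d$se_exposure),
       outcome = base(d$beta_outcome, d$se_outcome))
}

# Independent WLS oracle built on base lm().
wls_oracle <- function(y, X, w, intercept = FALSE) {
  df <- as.data.frame(X)
  form <- if (intercept) y ~ . else y ~ . - 1
  dat <- cbind(data.frame(y = y), df)
  fit <- lm(form, data = dat, weights = w)
  list(coef = unname(coef(fit)),
       se = unname(sqrt(diag(vcov(fit)))),
       sigma = summary(fit)$sigma)
}

# Brute-force weighted median via the weighted empirical CDF.
weighted_median_oracle <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cdf <- cumsum(w) - w / 2
  approx(cdf, x, xout = 0.5, rule = 2)$y
}

# Brute-force BH step-up following the definition directly.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}
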
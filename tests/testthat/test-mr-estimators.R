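# Univariable estimators against closed forms and independent oracles.

test_that("Wald ratio matches the direct formula and handles edge cases", {
  r <- wald_ratio(bx = 0.2, by = 0.1, sey = 0.02)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1)
  r0 <- wald_ratio(bx = 0.2, by = 0, sey = 0.02)
  expect_equal(r0$beta, 0)
  expect_equal(r0$pval, 1)
  expect_equal(wald_ratio(bx = 0.033, by = 0.0406, sey = 0.01)$beta,
               0.0406 / 0.033)
  expect_equal(round(wald_ratio(0.033, 0.0406, 0.01)$beta, 3), 1.230)
  expect_error(wald_ratio(0, 0.1, 0.02), class = "mr_degenerate_error")
})

test_that("IVW reduces to exact ratio on collinear data and matches hand sums", {
  hs <- make_hset(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.10, 0.15),
                  sey = rep(0.01, 3))
  fit <- mr_ivw(hs)
  expect_equal(fit$fixed$beta, 0.5)
  expect_equal(fit$q, 0)
  expect_equal(fit$fixed$se, fit$random$se)  # scale floored at 1
  hs2 <- make_hset(bx = c(0.1, 0.2, 0.3), by = c(0.06, 0.10, 0.12),
                   sey = rep(0.01, 3))
  expect_equal(mr_ivw(hs2)$fixed$beta, 0.062 / 0.14)
})

test_that("IVW equals a weighted regression-through-origin oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    k <- 12
    bx <- rnorm(k, 0.1, 0.05); by <- 0.3 * bx + rnorm(k, 0, 0.02)
    sey <- runif(k, 0.005, 0.05)
    hs <- make_hset(bx, by, sey)
    fit <- mr_ivw(hs)
    orc <- wls_oracle(by, matrix(bx, ncol = 1), 1 / sey^2)
    expect_equal(fit$fixed$beta, orc$coef[1], tolerance = 1e-10)
    # fixed-effect SE is the lm SE with the residual scale divided out
    expect_equal(fit$fixed$se, orc$se[1] / orc$sigma, tolerance = 1e-10)
  }
})

test_that("IVW weights are scale-coherent and single-SNP IVW is Wald", {
  hs <- make_hset(bx = c(0.1, 0.2, 0.3), by = c(0.06, 0.10, 0.12),
                  sey = c(0.01, 0.02, 0.015))
  f1 <- mr_ivw(hs)
  hs10 <- make_hset(hs$data$beta_exposure, hs$data$beta_outcome,
                    hs$data$se_outcome * 10)
  f10 <- mr_ivw(hs10)
  expect_equal(f10$fixed$beta, f1$fixed$beta)
  expect_equal(f10$fixed$se, f1$fixed$se * 10)
  hs1 <- make_hset(0.2, 0.1, 0.02)
  expect_message(f <- mr_ivw(hs1), "Wald")
  w <- wald_ratio(0.2, 0.1, 0.02)
  expect_equal(f$fixed$beta, w$beta)
  expect_equal(f$fixed$se, w$se)
})

test_that("Egger recovers an exact line and matches the WLS oracle", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  hs <- make_hset(bx, by = 0.01 + 0.5 * bx, sey = rep(0.01, 4))
  fit <- mr_egger(hs)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$extra$intercept, 0.01, tolerance = 1e-12)
  # exact fit: residual scale hits the floor of 1
  expect_equal(fit$extra$sigma, 0, tolerance = 1e-6)
  for (seed in 1:5) {
    set.seed(seed)
    k <- 10
    bx <- abs(rnorm(k, 0.1, 0.05)) + 0.01
    by <- 0.02 + 0.4 * bx + rnorm(k, 0, 0.03)
    sey <- runif(k, 0.01, 0.05)
    hs <- make_hset(bx, by, sey)
    fit <- mr_egger(hs)
    orc <- wls_oracle(by, cbind(x = bx), 1 / sey^2, intercept = TRUE)
    expect_equal(fit$beta, orc$coef[2], tolerance = 1e-10)
    expect_equal(fit$extra$intercept, orc$coef[1], tolerance = 1e-10)
    # lm SEs already carry sigma; the package floors sigma at 1
    scale_ratio <- max(1, orc$sigma) / orc$sigma
    expect_equal(fit$se, orc$se[2] * scale_ratio, tolerance = 1e-10)
    expect_equal(fit$extra$intercept_se, orc$se[1] * scale_ratio,
                 tolerance = 1e-10)
  }
})

test_that("Egger is invariant to joint sign flips of (bx, by)", {
  set.seed(4)
  k <- 8
  bx <- rnorm(k, 0.1, 0.05)
  by <- 0.01 + 0.5 * bx + rnorm(k, 0, 0.02)
  sey <- runif(k, 0.01, 0.04)
  hs <- make_hset(bx, by, sey)
  flip <- c(1, -1, 1, -1, -1, 1, 1, -1)
  hs2 <- make_hset(flip * bx, flip * by, sey)
  f1 <- mr_egger(hs); f2 <- mr_egger(hs2)
  expect_equal(f2$beta, f1$beta)
  expect_equal(f2$extra$intercept, f1$extra$intercept)
  expect_equal(f2$se, f1$se)
})

test_that("Egger with the intercept forced to zero is IVW", {
  set.seed(9)
  k <- 10
  bx <- abs(rnorm(k, 0.1, 0.05)) + 0.01
  by <- 0.3 * bx + rnorm(k, 0, 0.02)
  sey <- runif(k, 0.01, 0.05)
  hs <- make_hset(bx, by, sey)
  # through-origin WLS (the Egger model minus its intercept) == IVW
  orc <- wls_oracle(by, matrix(bx, ncol = 1), 1 / sey^2)
  expect_equal(mr_ivw(hs)$fixed$beta, orc$coef[1], tolerance = 1e-12)
})

test_that("weighted median: symmetry, oracle agreement, outlier resistance", {
  hs <- make_hset(bx = rep(1, 3), by = c(0.4, 0.5, 0.6), sey = rep(1, 3))
  expect_equal(mr_weighted_median(hs, n_boot = 50, seed = 1)$beta, 0.5)
  # 7 concordant SNPs near 0.5 plus 3 low-weight outliers near 2
  set.seed(21)
  bx <- c(rep(0.2, 7), rep(0.05, 3))
  theta_true <- c(rnorm(7, 0.5, 0.01), rnorm(3, 2, 0.05))
  by <- theta_true * bx
  sey <- c(rep(0.01, 7), rep(0.02, 3))
  hs <- make_hset(bx, by, sey)
  fit <- mr_weighted_median(hs, n_boot = 200, seed = 5)
  expect_lt(abs(fit$beta - 0.5), 0.05)
  w <- bx^2 / sey^2
  expect_equal(fit$beta, weighted_median_oracle(by / bx, w),
               tolerance = 1e-12)
  # order invariance
  perm <- sample(10)
  hs_p <- make_hset(bx[perm], by[perm], sey[perm])
  expect_equal(mr_weighted_median(hs_p, n_boot = 50, seed = 5)$beta,
               fit$beta)
})

test_that("weighted median bootstrap SE is seed-reproducible", {
  set.seed(2)
  bx <- rnorm(6, 0.2, 0.02); by <- 0.4 * bx + rnorm(6, 0, 0.01)
  hs <- make_hset(bx, by, rep(0.01, 6), sex = rep(0.005, 6))
  a <- mr_weighted_median(hs, n_boot = 300, seed = 77)
  b <- mr_weighted_median(hs, n_boot = 300, seed = 77)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
})

test_that("weighted mode: point mass, clusters, large-bandwidth limit", {
  hs <- make_hset(bx = rep(0.2, 3), by = rep(0.14, 3), sey = rep(0.01, 3))
  expect_equal(mr_weighted_mode(hs, n_boot = 50, seed = 1)$beta, 0.7)
  # dominant cluster at 0.5, minority at 1.5
  set.seed(13)
  theta <- c(rnorm(6, 0.5, 0.02), rnorm(2, 1.5, 0.02))
  bx <- rep(0.2, 8); by <- theta * bx
  hs <- make_hset(bx, by, rep(0.01, 8))
  fit <- mr_weighted_mode(hs, n_boot = 50, seed = 2)
  expect_lt(abs(fit$beta - 0.5), 0.1)
  # grid-search density oracle at the same bandwidth
  w <- rep(1 / 8, 8)
  h <- 0.9 * min(sd(theta), IQR(theta) / 1.349) * 8^(-0.2)
  grid <- seq(min(theta), max(theta), length.out = 20001)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - theta) / h)),
                 numeric(1))
  expect_equal(fit$beta, grid[which.max(dens)], tolerance = 1e-3)
  # huge bandwidth: mode approaches the weighted mean of the ratios
  fit_wide <- mr_weighted_mode(hs, bandwidth_factor = 1e4, n_boot = 50,
                               seed = 2)
  wm <- weighted.mean(theta, bx^2 / 0.01^2)
  expect_lt(abs(fit_wide$beta - wm), 0.02)
})

test_that("median and mode are invariant to joint sign flips", {
  set.seed(31)
  bx <- rnorm(8, 0.2, 0.05); by <- 0.5 * bx + rnorm(8, 0, 0.01)
  sey <- runif(8, 0.01, 0.03)
  hs <- make_hset(bx, by, sey)
  flip <- rep(c(1, -1), 4)
  hs_f <- make_hset(flip * bx, flip * by, sey)
  expect_equal(mr_weighted_median(hs_f, n_boot = 50, seed = 3)$beta,
               mr_weighted_median(hs, n_boot = 50, seed = 3)$beta)
  expect_equal(mr_weighted_mode(hs_f, n_boot = 50, seed = 3)$beta,
               mr_weighted_mode(hs, n_boot = 50, seed = 3)$beta)
})

test_that("zero-exposure-beta SNPs are excluded; too few remaining errors", {
  hs <- make_hset(bx = c(0, 0.2, 0.3, 0.25), by = c(0.1, 0.1, 0.15, 0.12),
                  sey = rep(0.01, 4))
  expect_message(fit <- mr_weighted_median(hs, n_boot = 50, seed = 1),
                 "zero exposure")
  expect_equal(fit$n_snp, 3L)
  hs_small <- make_hset(bx = c(0, 0.2, 0.3), by = c(0.1, 0.1, 0.15),
                        sey = rep(0.01, 3))
  expect_error(suppressMessages(
    mr_weighted_median(hs_small, n_boot = 50, seed = 1)),
    class = "mr_insufficient_instruments_error")
})

test_that("log-odds effects convert to the published OR scale", {
  or1 <- effect_to_or(0.162, se = ci_to_se(0.090, 0.234))
  expect_equal(round(unname(or1["or"]), 2), 1.18)
  or2 <- effect_to_or(0.162, ci = c(0.090, 0.234))
  expect_equal(round(unname(or2["or_low"]), 2), 1.09)
  expect_equal(round(unname(or2["or_high"]), 2), 1.26)
  expect_equal(unname(effect_to_or(0, se = 1)["or"]), 1)
})

test_that("estimators recover theta on clean synthetic data", {
  # no pleiotropy: every estimator's mean over seeded replicates should sit
  # within 3 Monte-Carlo SEs of the true effect
  n_rep <- 60
  est <- matrix(NA_real_, n_rep, 4,
                dimnames = list(NULL, c("ivw", "egger", "median", "mode")))
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(k = 40, theta = 0.2, seed = 1000 + r)
    sim <- simulate_instrument_set(cfg)
    # every generated SNP is a true instrument; harmonize the full panel so
    # the check isolates estimator bias from selection effects
    hs <- harmonize(sim$exposure, sim$outcome)
    est[r, "ivw"] <- mr_ivw(hs)$fixed$beta
    est[r, "egger"] <- mr_egger(hs)$beta
    est[r, "median"] <- mr_weighted_median(hs, n_boot = 2, seed = r)$beta
    est[r, "mode"] <- mr_weighted_mode(hs, n_boot = 2, seed = r)$beta
  }
  for (m in colnames(est)) {
    mc_se <- sd(est[, m]) / sqrt(n_rep)
    expect_lt(abs(mean(est[, m]) - 0.2), 3 * mc_se,
              label = paste("bias of", m))
  }
})
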
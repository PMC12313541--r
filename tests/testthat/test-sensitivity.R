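# Heterogeneity, pleiotropy, leave-one-out, MR-PRESSO and funnel checks.

test_that("Cochran's Q is zero on collinear ratios and matches brute force", {
  hs <- make_hset(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.10, 0.15),
                  sey = rep(0.01, 3))
  q <- cochran_q(hs, "ivw")
  expect_equal(q$q, 0)
  expect_equal(q$pval, 1)
  expect_equal(q$df, 2L)
  hs2 <- make_hset(bx = c(0.1, 0.2, 0.3), by = c(0.06, 0.10, 0.12),
                   sey = rep(0.01, 3))
  beta <- 0.062 / 0.14
  theta <- hs2$data$beta_outcome / hs2$data$beta_exposure
  w <- hs2$data$beta_exposure^2 / hs2$data$se_outcome^2
  expect_equal(cochran_q(hs2, "ivw")$q, sum(w * (theta - beta)^2))
})

test_that("Egger Q is the weighted residual sum of squares with k-2 df", {
  set.seed(5)
  bx <- abs(rnorm(8, 0.1, 0.04)) + 0.01
  by <- 0.02 + 0.4 * bx + rnorm(8, 0, 0.02)
  sey <- runif(8, 0.01, 0.03)
  hs <- make_hset(bx, by, sey)
  q <- cochran_q(hs, "egger")
  orc <- wls_oracle(by, cbind(x = bx), 1 / sey^2, intercept = TRUE)
  fitted <- orc$coef[1] + orc$coef[2] * bx
  expect_equal(q$q, sum((by - fitted)^2 / sey^2), tolerance = 1e-10)
  expect_equal(q$df, 6L)
})

test_that("Q requires enough instruments", {
  hs1 <- make_hset(0.2, 0.1, 0.02)
  expect_error(cochran_q(hs1, "ivw"),
               class = "mr_insufficient_instruments_error")
  hs2 <- make_hset(c(0.1, 0.2), c(0.05, 0.1), c(0.01, 0.01))
  expect_error(cochran_q(hs2, "egger"),
               class = "mr_insufficient_instruments_error")
})

test_that("pleiotropy test returns the Egger intercept block", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  hs <- make_hset(bx, by = 0.01 + 0.5 * bx, sey = rep(0.01, 4))
  p <- pleiotropy_test(hs)
  expect_equal(p$intercept, 0.01, tolerance = 1e-12)
})

test_that("balanced pleiotropy leaves the intercept near zero, directional is recovered", {
  n_rep <- 50
  int_bal <- int_dir <- se_bal <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    # the intercept is interpretable on a genuine instrument panel, so
    # SNPs are p-value-selected first (near-null SNPs are not instruments
    # and sit at high leverage for the intercept)
    cfg_b <- sim_config(k = 60, theta = 0.2, pleiotropy_frac = 1,
                        pleiotropy_mean = 0, pleiotropy_sd = 0.01,
                        seed = 2000 + r)
    sim_b <- simulate_instrument_set(cfg_b)
    hs_b <- harmonize(select_instruments(sim_b$exposure, 5e-6),
                      sim_b$outcome)
    pb <- pleiotropy_test(hs_b)
    int_bal[r] <- pb$intercept; se_bal[r] <- pb$se
    cfg_d <- sim_config(k = 60, theta = 0.2, pleiotropy_frac = 1,
                        pleiotropy_mean = 0.02, pleiotropy_sd = 0.005,
                        seed = 3000 + r)
    sim_d <- simulate_instrument_set(cfg_d)
    int_dir[r] <- pleiotropy_test(
      harmonize(select_instruments(sim_d$exposure, 5e-6),
                sim_d$outcome))$intercept
  }
  # balanced: |intercept| < 3 se in nearly all replicates
  expect_gte(mean(abs(int_bal) < 3 * se_bal), 0.9)
  # directional: mean intercept within 3 MC-SE of the planted mean
  mc_se <- sd(int_dir) / sqrt(n_rep)
  expect_lt(abs(mean(int_dir) - 0.02), 3 * mc_se)
})

test_that("leave-one-out is stable on homogeneous data and finds outliers", {
  hs <- make_hset(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.10, 0.15),
                  sey = rep(0.01, 3))
  loo <- leave_one_out(hs)
  expect_equal(nrow(loo), 4L)
  expect_equal(loo$beta, rep(0.5, 4))
  expect_false(any(loo$influential))
  # a planted outlier: excluding it moves the estimate the most
  set.seed(8)
  bx <- rnorm(10, 0.2, 0.02)
  by <- 0.5 * bx + rnorm(10, 0, 0.005)
  by[4] <- by[4] + 0.15
  hs2 <- make_hset(bx, by, rep(0.01, 10))
  loo2 <- leave_one_out(hs2)
  full_beta <- loo2$beta[loo2$excluded_snp == "all"]
  shifts <- abs(loo2$beta[loo2$excluded_snp != "all"] - full_beta)
  expect_equal(which.max(shifts), 4L)
})

test_that("full-set Q is at least every leave-one-out Q", {
  for (seed in 1:5) {
    set.seed(seed)
    k <- 8
    bx <- rnorm(k, 0.15, 0.05)
    by <- 0.3 * bx + rnorm(k, 0, 0.02)
    sey <- runif(k, 0.01, 0.03)
    hs <- make_hset(bx, by, sey)
    q_full <- cochran_q(hs, "ivw")$q
    for (j in seq_len(k)) {
      sub <- hs; sub$data <- hs$data[-j, , drop = FALSE]
      expect_lte(cochran_q(sub, "ivw")$q, q_full + 1e-12)
    }
  }
})

test_that("MR-PRESSO is deterministic and clean data passes the global test", {
  set.seed(3)
  bx <- rnorm(12, 0.2, 0.03)
  by <- 0.4 * bx + rnorm(12, 0, 0.01)
  hs <- make_hset(bx, by, rep(0.01, 12), sex = rep(0.004, 12))
  a <- mr_presso(hs, n_sim = 300, seed = 99)
  b <- mr_presso(hs, n_sim = 300, seed = 99)
  expect_identical(a, b)
  expect_gte(a$global_pval, 1 / 301)
  expect_lte(a$global_pval, 1)
  expect_error(mr_presso(make_hset(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.15),
                                   rep(0.01, 3)), seed = 1),
               class = "mr_insufficient_instruments_error")
  expect_warning(mr_presso(hs, n_sim = 50, seed = 1), "n_sim")
})

test_that("MR-PRESSO flags a planted 10-SE outlier and corrects the estimate", {
  cfg <- sim_config(k = 30, theta = 0.2, seed = 71,
                    outlier = list(index = 7, shift = 10))
  sim <- simulate_instrument_set(cfg)
  hs <- harmonize(sim$exposure, sim$outcome)
  pr <- mr_presso(hs, n_sim = 1000, seed = 17)
  expect_true("rs00007" %in% pr$outliers)
  expect_lt(pr$global_pval, 0.05)
  expect_lt(abs(pr$beta_corrected - 0.2), abs(pr$beta_raw - 0.2))
  # corrected estimate re-covers theta within its sampling error
  sub <- hs; sub$data <- hs$data[hs$data$snp != "rs00007", , drop = FALSE]
  expect_lt(abs(pr$beta_corrected - 0.2), 3 * mr_ivw(sub)$fixed$se)
})

test_that("MR-PRESSO global type-I error is near nominal under the null", {
  n_rep <- 200
  rejections <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(k = 20, theta = 0.15, seed = 5000 + r)
    sim <- simulate_instrument_set(cfg)
    hs <- harmonize(sim$exposure, sim$outcome)
    rejections[r] <- mr_presso(hs, n_sim = 500,
                               seed = 6000 + r)$global_pval < 0.05
  }
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.10)
})

test_that("funnel coordinates are Wald ratios with reciprocal-SE precision", {
  hs <- make_hset(bx = 0.2, by = 0.1, sey = 0.02)
  fc <- funnel_coordinates(hs)
  expect_equal(fc$theta, 0.5)
  expect_equal(fc$precision, 10)
  # weighted mean of ratios equals the IVW estimate
  set.seed(12)
  bx <- rnorm(15, 0.2, 0.05)
  by <- 0.3 * bx + rnorm(15, 0, 0.01)
  hs2 <- make_hset(bx, by, rep(0.01, 15))
  fc2 <- funnel_coordinates(hs2)
  expect_equal(nrow(fc2), 15L)
  expect_equal(weighted.mean(fc2$theta, fc2$precision^2),
               mr_ivw(hs2)$fixed$beta, tolerance = 1e-12)
})
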
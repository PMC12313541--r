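# Seeded generator of two-sample GWAS summary statistics with known
# causal, pleiotropic and mediation structure.
#
# Summary statistics are simulated directly (no individual-level
# genotypes): per SNP j the true instrument effect is gamma_j ~ N(0,
# gamma_sd^2), the sampling SE of a per-allele estimate in a GWAS of n
# individuals is se_j = (2 * maf_j * (1 - maf_j) * n)^(-1/2) (the
# standardized-trait approximation), and observed betas are normal draws
# around the true values. Horizontal pleiotropy enters as a per-SNP direct
# outcome effect alpha_j, non-zero with probability pleiotropy_frac.

NON_PALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                  "G", "A", "C", "A", "G", "T", "C", "T"),
                                ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)

#' Simulation configuration
#'
#' Collects every generative parameter of the synthetic GWAS world.
#'
#' @param k Number of instrument SNPs.
#' @param theta True causal effect of the exposure on the outcome (the
#'   direct effect `c_prime` when a mediation block is present).
#' @param n_exp,n_out,n_med GWAS sample sizes.
#' @param maf_range Uniform range for minor allele frequencies.
#' @param gamma_sd SD of the true per-SNP instrument effects.
#' @param pleiotropy_frac Fraction of instruments with a direct (pleiotropic)
#'   outcome effect.
#' @param pleiotropy_mean,pleiotropy_sd Normal parameters of the pleiotropic
#'   effects (mean 0 = balanced, non-zero = directional).
#' @param mediation Optional list `(a, b, c_prime, k_med)` defining an
#'   exposure -> mediator -> outcome chain; `k_med` (default `k`) is the
#'   number of mediator-specific instruments.
#' @param outlier Optional list `(index, shift)`: after generation, SNP
#'   `index`'s outcome beta is shifted by `shift` outcome-SE units.
#' @param palindrome_frac Fraction of SNPs assigned palindromic (A/T, C/G)
#'   allele pairs; default 0 (used only to exercise harmonization drops).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(k = 100, theta = 0.2, n_exp = 100000,
                       n_out = 100000, n_med = 100000,
                       maf_range = c(0.05, 0.5), gamma_sd = 0.05,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0.01, mediation = NULL,
                       outlier = NULL, palindrome_frac = 0, seed = 1L) {
  if (k < 1) mr_error("k must be >= 1", "mr_validation_error")
  if (pleiotropy_frac < 0 || pleiotropy_frac > 1) {
    mr_error("pleiotropy_frac must lie in [0, 1]", "mr_validation_error")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    mr_error("maf_range must lie within (0, 0.5]", "mr_validation_error")
  }
  if (!is.null(mediation)) {
    need <- c("a", "b", "c_prime")
    if (!all(need %in% names(mediation))) {
      mr_error("mediation block needs a, b, c_prime", "mr_validation_error")
    }
    if (is.null(mediation$k_med)) mediation$k_med <- k
  }
  if (!is.null(outlier)) {
    if (is.null(outlier$index) || is.null(outlier$shift) ||
        outlier$index < 1 || outlier$index > k) {
      mr_error("outlier block needs index in 1..k and shift",
               "mr_validation_error")
    }
  }
  structure(list(k = as.integer(k), theta = theta,
                 n_exp = as.integer(n_exp), n_out = as.integer(n_out),
                 n_med = as.integer(n_med), maf_range = maf_range,
                 gamma_sd = gamma_sd, pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd, mediation = mediation,
                 outlier = outlier, palindrome_frac = palindrome_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_alleles <- function(k, palindrome_frac) {
  pal <- stats::runif(k) < palindrome_frac
  idx_np <- sample(nrow(NON_PALINDROMIC_PAIRS), k, replace = TRUE)
  idx_p <- sample(nrow(PALINDROMIC_PAIRS), k, replace = TRUE)
  ea <- ifelse(pal, PALINDROMIC_PAIRS[idx_p, 1],
               NON_PALINDROMIC_PAIRS[idx_np, 1])
  oa <- ifelse(pal, PALINDROMIC_PAIRS[idx_p, 2],
               NON_PALINDROMIC_PAIRS[idx_np, 2])
  list(ea = ea, oa = oa)
}

sim_positions <- function(k) {
  # Spread SNPs across chromosomes with > 20 Mb spacing so that the default
  # distance-clumping window treats them as independent loci.
  chr <- as.character(rep(1:22, length.out = k))
  within <- stats::ave(seq_len(k), chr, FUN = seq_along)
  pos <- 1e6 + (within - 1) * 2.5e7
  list(chr = chr, pos = pos)
}

records_df <- function(snp, chr, pos, ea, oa, eaf, beta, se, n) {
  data.frame(snp = snp, chr = chr, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pval = 2 * stats::pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}

#' Simulate a two-sample exposure-outcome instrument set
#'
#' Generates matched exposure and outcome GWAS summary statistics for `k`
#' instruments under the generative model described in the package
#' vignette, plus a truth record with every latent value.
#'
#' @param cfg A [sim_config()].
#' @return List `(exposure, outcome, truth)`; the first two are canonical
#'   summary-statistics data.frames, `truth` is a list holding `gamma`,
#'   `alpha`, `maf`, `theta` and the config.
#' @export
simulate_instrument_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  k <- cfg$k
  maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
  # Effect alleles are reported in the exposure-increasing orientation
  # (gamma >= 0), the convention instrument lists are published in; this
  # also gives directional pleiotropy a well-defined sign.
  gamma <- abs(stats::rnorm(k, 0, cfg$gamma_sd))
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exp)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_out)
  has_pleio <- stats::runif(k) < cfg$pleiotropy_frac
  alpha <- ifelse(has_pleio,
                  stats::rnorm(k, cfg$pleiotropy_mean, cfg$pleiotropy_sd),
                  0)
  bx <- stats::rnorm(k, gamma, se_x)
  by <- stats::rnorm(k, cfg$theta * gamma + alpha, se_y)
  al <- sim_alleles(k, cfg$palindrome_frac)
  loc <- sim_positions(k)
  if (!is.null(cfg$outlier)) {
    i <- cfg$outlier$index
    by[i] <- by[i] + cfg$outlier$shift * se_y[i]
  }
  snp <- sprintf("rs%05d", seq_len(k))
  list(
    exposure = records_df(snp, loc$chr, loc$pos, al$ea, al$oa, maf, bx,
                          se_x, cfg$n_exp),
    outcome = records_df(snp, loc$chr, loc$pos, al$ea, al$oa, maf, by,
                         se_y, cfg$n_out),
    truth = list(gamma = gamma, alpha = alpha, maf = maf,
                 theta = cfg$theta, config = cfg)
  )
}

#' Simulate a mediation study (exposure -> mediator -> outcome)
#'
#' Generates three GWASs sharing one SNP panel: `k` exposure instruments
#' (true effect `gamma_j` on the exposure, `a*gamma_j` on the mediator,
#' `(c_prime + a*b)*gamma_j` on the outcome) and `k_med` mediator-specific
#' instruments (effect `delta_j` on the mediator, `b*delta_j` on the
#' outcome, none on the exposure). The mediator-specific instruments are
#' what make the mediator -> outcome MR and the MVMR adjustment
#' identifiable. The closed-form mediated proportion is
#' `a*b / (c_prime + a*b)`.
#'
#' @param cfg A [sim_config()] with a `mediation` block.
#' @return List `(exposure, mediator, outcome, truth)`.
#' @export
simulate_mediation_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  med <- cfg$mediation
  if (is.null(med)) {
    mr_error("cfg$mediation block is required", "mr_validation_error")
  }
  set.seed(cfg$seed)
  k <- cfg$k; km <- med$k_med
  total <- k + km
  maf <- stats::runif(total, cfg$maf_range[1], cfg$maf_range[2])
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exp)
  se_m <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_med)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_out)
  gamma <- c(abs(stats::rnorm(k, 0, cfg$gamma_sd)), rep(0, km))
  delta <- c(rep(0, k), abs(stats::rnorm(km, 0, cfg$gamma_sd)))
  mu_x <- gamma
  mu_m <- med$a * gamma + delta
  mu_y <- (med$c_prime + med$a * med$b) * gamma + med$b * delta
  bx <- stats::rnorm(total, mu_x, se_x)
  bm <- stats::rnorm(total, mu_m, se_m)
  by <- stats::rnorm(total, mu_y, se_y)
  al <- sim_alleles(total, cfg$palindrome_frac)
  loc <- sim_positions(total)
  snp <- sprintf("rs%05d", seq_len(total))
  list(
    exposure = records_df(snp, loc$chr, loc$pos, al$ea, al$oa, maf, bx,
                          se_x, cfg$n_exp),
    mediator = records_df(snp, loc$chr, loc$pos, al$ea, al$oa, maf, bm,
                          se_m, cfg$n_med),
    outcome = records_df(snp, loc$chr, loc$pos, al$ea, al$oa, maf, by,
                         se_y, cfg$n_out),
    truth = list(gamma = gamma, delta = delta, maf = maf,
                 a = med$a, b = med$b, c_prime = med$c_prime,
                 beta_c = med$c_prime + med$a * med$b,
                 proportion = med$a * med$b /
                   (med$c_prime + med$a * med$b),
                 config = cfg)
  )
}

#' Inject block LD structure
#'
#' Builds a block-diagonal r-squared matrix over the records' SNPs
#' (`r2_within` inside consecutive blocks of `block_size`, 0 between,
#' unit diagonal) and places each block's SNPs within 1 kb of each other on
#' one chromosome so that joint (r2, distance) clumping applies.
#'
#' @param records Summary-statistics data.frame.
#' @param block_size SNPs per LD block (>= 1).
#' @param r2_within Within-block r-squared.
#' @return List `(records, ld)`; records have updated chr/pos.
#' @export
inject_ld_structure <- function(records, block_size, r2_within) {
  if (block_size < 1) mr_error("block_size must be >= 1",
                               "mr_validation_error")
  k <- nrow(records)
  block <- (seq_len(k) - 1) %/% block_size
  ld <- outer(block, block, function(a, b) {
    ifelse(a == b, r2_within, 0)
  })
  diag(ld) <- 1
  dimnames(ld) <- list(records$snp, records$snp)
  records$chr <- as.character(block + 1)
  records$pos <- 1e6 + (seq_len(k) - 1) %% block_size * 100
  list(records = records, ld = ld)
}
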
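---
title: "Two-sample MR with mediation: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with mediation: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The estimation problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure X on an outcome Y from two independent GWAS: for each instrument
SNP j we observe the per-allele association with the exposure, `bx_j`
(SE `sx_j`), and with the outcome, `by_j` (SE `sy_j`). Under the three
instrumental-variable assumptions — the SNP associates with X, is
independent of confounders of X and Y, and affects Y only through X — each
SNP yields a Wald ratio `theta_j = by_j / bx_j` estimating the same causal
effect, and the estimators below consolidate these ratios.

`mrmediate` implements the full chain: instrument selection, allele
harmonization, the univariable estimators, sensitivity diagnostics,
multivariable MR (MVMR), and a two-step mediation decomposition for an
exposure → mediator → outcome pathway. Binary-trait effects are log-odds;
`effect_to_or()` maps estimates and CIs to the odds-ratio scale.

## Instrument selection and strength

Instruments are SNPs passing an association threshold on the exposure
(default `p < 5e-6`; `5e-8` is conventional for well-powered exposures),
pruned to independent loci by greedy LD clumping: visit SNPs in ascending
p-value order and discard any remaining SNP with `r² >= 0.001` against an
accepted SNP *and* within a 10,000 kb window on the same chromosome. The
window value reads the conventional "r² < 0.001, kb > 10,000" pairing as a
10,000-kb clumping radius, the standard interpretation of those paired
thresholds. LD is supplied as an explicit r² matrix (or pure distance
pruning when absent); the package never computes LD from reference panels,
which keeps selection deterministic and offline. Ties in p-value break
lexicographically by SNP id, so clumping is a pure function of its input.

Strength is scored by the variance explained and the F-statistic

    R² = 2 · MAF · (1 − MAF) · β²
    F  = R² (n − k − 1) / (k (1 − R²))

with `F < 10` flagging weak instruments. Both a per-SNP mode (`k = 1`) and
an aggregate mode (`R²` summed over the `k` instruments) are exposed,
because published reports rarely state which was used; the aggregate value
is what `F`'s `k` term implies. The formula assumes betas on a
standardized trait scale — that scaling is the caller's responsibility and
is deliberately not guessed from the data.

## Harmonization

Estimators need `(bx_j, by_j)` on one effect-allele convention.
`harmonize()` aligns the outcome study to the exposure study per SNP:
identical allele pairs pass through; swapped pairs flip the outcome beta's
sign and complement its allele frequency; strand-complement pairs (A↔T,
C↔G relabelings) are complemented first; anything else is dropped as
incompatible. Palindromic SNPs (A/T or C/G pairs) cannot be strand-resolved
from alleles, so they are oriented by allele frequency: dropped when either
study's EAF lies inside 0.5 ± 0.08 (or is missing), sign-flipped when the
two frequencies fall on opposite sides of 0.5. The window half-width 0.08
is common MR practice. Orientation-by-frequency (rather than dropping
opposite-side pairs) was chosen because it makes harmonization invariant
to how the outcome study happens to label its alleles — re-expressing every
outcome record with swapped alleles and negated beta leaves the result
unchanged — and idempotent. Every decision is logged per SNP
(kept / sign-flipped / strand-flipped / dropped + reason), and
`|kept| + |dropped|` always equals the overlap.

Matching is by SNP identifier only; positions are carried but not used for
joins, since summary statistics in this domain are rsID-keyed.
Multi-base (indel) alleles are rejected at parse time so the allele algebra
stays exact.

## Univariable estimators

**IVW.** The primary estimator: weighted regression of `by` on `bx`
through the origin with weights `1/sy²`,

    beta_IVW = Σ w_j bx_j by_j / Σ w_j bx_j² ,   w_j = sy_j^−2 .

The fixed-effect SE is `(Σ w_j bx_j²)^−1/2`; the multiplicative
random-effects (MRE) SE inflates it by `max(1, sqrt(Q/(k−1)))`, with Q the
Cochran heterogeneity statistic over the Wald ratios. Both variants share
the point estimate and both are always reported; `mr_ivw_primary()` labels
the MRE variant the headline when `Q/(k−1) > 1` so the choice is auditable
rather than silent. With one SNP, IVW degrades to the Wald ratio with a
logged notice. The Wald-ratio SE is first order (`sy/|bx|`), ignoring
exposure-side noise; `sx` is retained in the data model for a future
second-order version.

**MR-Egger.** The same regression with an intercept, after orienting each
pair so `bx_j >= 0`. The slope is robust to directional pleiotropy under
the InSIDE assumption; the intercept estimates the mean pleiotropic
effect, and its t-test (df `k−2`) is the pleiotropy diagnostic. SEs are
inflated by `max(1, residual standard error)`, the usual over-dispersion
floor.

**Weighted median / weighted mode.** Order-robust consolidations of the
Wald ratios with weights `bx_j²/sy_j²`: the median is where the weighted
empirical CDF (midpoint convention, linearly interpolated) crosses 0.5,
consistent when at least half the weight is valid; the mode maximizes a
normal-kernel weighted density of the ratios (bandwidth = a modified
Silverman rule times a user factor), consistent when the largest
homogeneous group is valid. Both get parametric-bootstrap SEs (resampling
`bx`, `by` from normals at their reported SEs), governed by a single
integer seed; results are bit-identical across runs at the same seed.
P-values are normal-theory for IVW/median/mode and t-based for Egger —
recorded per result rather than hidden.

## Sensitivity suite

Heterogeneity: Cochran's Q (IVW form, df `k−1`) and the Egger weighted
residual sum of squares (df `k−2`), with `p < 0.05` flagging
heterogeneity. Leave-one-out refits the MRE IVW without each SNP and flags
refits whose CI excludes the full-set estimate. Funnel coordinates emit
`(theta_j, precision_j = |bx_j|/sy_j)` for symmetry inspection — plot data
only, no rendering.

MR-PRESSO detects outlying instruments by residual simulation: the
observed global statistic is `RSS = Σ w_j (by_j − theta_(−j) bx_j)²` with
leave-one-out IVW slopes; its null distribution comes from `n_sim` seeded
parametric redraws of `(bx, by)`; the global p-value uses the add-one
estimator `(1 + #{RSS* ≥ RSS_obs})/(n_sim + 1)`, which floors p at
`1/(n_sim+1)` and never returns zero. Per-SNP outlier p-values are the
empirical tails of each SNP's observed residual in its own simulated
distribution, Bonferroni-adjusted by `k` (the method's original
multiplicity convention); flagged SNPs are removed and IVW refit gives the
corrected estimate. The distortion test is deliberately out of scope —
the workflow this package reproduces used PRESSO only to exclude outliers.

## Multivariable MR and mediation

`mvmr_fit()` regresses `by` on the matrix of exposure betas (no
intercept, weights `1/sy²`), giving each exposure's direct effect after
mutual adjustment. SEs from the weighted normal equations are scaled by
`max(1, sqrt(Q_mv/df))`, `df = k − p` — the same over-dispersion rule as
the univariable estimators, so the single-exposure case collapses exactly
to IVW (MRE SE). The joint instrument set is built union → intersect →
re-clump: the union of each exposure's clumped instruments, restricted to
SNPs present in every GWAS, re-clumped jointly ranked by best p-value
across exposures, then allele-aligned to the first exposure's convention.
An exposure whose beta column is identically zero carries no identifying
information and is reported `NA` rather than crashing the normal
equations; genuine collinearity between informative exposures raises an
error naming the offending exposures. Conditional F-statistics are not
computed in this version.

The two-step mediation decomposition estimates, for an exposure E,
mediator M and outcome Y:

* `beta_a`: IVW of E on M (E's instruments),
* `beta_b`: IVW of M on Y (M's instruments),
* `beta_c`: IVW of E on Y (total effect),
* `beta_c'`, `beta_b'`: the MVMR-adjusted direct effects of E and M on Y.

The indirect effect is the product of coefficients, with the
Propagation-of-Error (first-order delta) SE
`sqrt(a²·se_b² + b²·se_a²)`; the Sobel z is the same product over the same
SE, so the two share one implementation by construction. The mediated
proportion is `indirect / beta_c` (×100 for display), with a first-order
ratio SE.

**Decision rule.** Published two-step analyses switch between
Propagation-of-Error on the adjusted product `a·b'` and a Sobel test on
the unadjusted product `a·b` without always stating the switch condition.
The rule implemented here — chosen to reproduce the worked-example pattern
and to behave correctly under a null first stage — is:

1. if `beta_a` is significant *and* the MVMR-adjusted `beta_b'` CI
   excludes zero → Propagation of Error on `a·b'`;
2. else if the Sobel test on `a·b` has `p < alpha` → Sobel route;
3. else the mediated proportion is reported not-available.

Requiring the first-stage effect in step 1 matters: without it, a mediator
that genuinely affects the outcome would be declared a mediator even when
the exposure does not affect the mediator at all. The rule and `alpha`
(default 0.05) are arguments, not constants. When only printed CIs are
available for a coefficient, its SE is back-derived as width/3.92;
`mediation_decide_table()` applies the rule to a whole table of such
stage estimates.

## Multiplicity

`bh_adjust()` is the Benjamini–Hochberg step-up adjustment (delegating to
`stats::p.adjust`); `assemble_panel()` attaches adjusted p-values and
significance flags across an exposure panel and emits forest-plot
coordinates. The FDR family is a deliberate modelling choice — here, the
exposures tested against one outcome form one family, and each mediation
screen forms its own — expressed by what the caller passes in one call.
Display rounding (OR to 2 dp, p to 3 significant digits) lives in separate
`*_disp` columns; underlying values keep full precision.

## The synthetic-GWAS generator

`simulate_instrument_set()` draws, per SNP: MAF ~ U(0.05, 0.5); a true
instrument effect `gamma_j ~ |N(0, gamma_sd²)|`; sampling SEs
`se = (2·MAF·(1−MAF)·n)^−1/2` (the standardized-trait approximation, which
makes SEs scale as `n^−1/2` and lets sample size be a single knob); a
pleiotropic direct effect `alpha_j` present with probability
`pleiotropy_frac`, drawn `N(pleiotropy_mean, pleiotropy_sd²)`; then
observed `bx ~ N(gamma, se_x²)` and `by ~ N(theta·gamma + alpha, se_y²)`.
Effect alleles are reported in the exposure-increasing orientation
(`gamma >= 0`), the convention published instrument lists follow; this is
what gives "directional" pleiotropy a direction — under a symmetric-sign
convention, re-orientation inside MR-Egger would cancel any planted mean.
Defaults (`k = 100`, `n = 1e5`, `gamma_sd = 0.05`, MAF 0.05–0.5) emulate
biobank-scale GWAS of common variants with realistic instrument strength
(median per-SNP F in the hundreds, as in the alcohol-IBS application the
package validates against).

`simulate_mediation_study()` adds a mediator: exposure instruments carry
`a·gamma` to the mediator and `(c' + a·b)·gamma` to the outcome, and a
second set of mediator-specific instruments (`delta_j`, affecting the
mediator and, via `b`, the outcome) is generated as well. The
mediator-specific instruments are essential, not decorative: with exposure
instruments alone the MVMR design columns are proportional in expectation
and `(c', b)` is unidentified. The closed-form truth
`proportion = a·b/(c' + a·b)` anchors recovery tests.

What the generator does *not* emulate: realistic LD (only
`inject_ld_structure()`'s block-diagonal r² for exercising the clumper),
binary-trait liability scaling, sample overlap between the two GWAS,
population stratification, and allele-frequency differences between
studies. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to those real-data
complications.

## Numerical and reproducibility choices

* Weighted least squares is solved by the normal equations with an
  explicit determinant guard; rank deficiency raises a collinearity error
  rather than a silent pseudo-inverse.
* All SE inflation factors floor at 1 (never deflating below the
  fixed-effect SE).
* Empirical p-values use the add-one rule and cannot be zero.
* Every stochastic routine (bootstrap SEs, PRESSO simulations, the
  generator) takes one integer seed and is bit-reproducible;
  `run_pipeline()` reruns byte-identically for a fixed config + seed.
* Degenerate inputs fail loudly with classed conditions
  (`mr_degenerate_error`, `mr_collinearity_error`,
  `mr_insufficient_instruments_error`, ...), each naming what was wrong;
  pipeline stage failures name their stage.

## Validation problem sizes

The shipped test-suite and acceptance script validate at desk scale,
chosen so the full run completes in a few minutes while leaving
Monte-Carlo error well below the tested tolerances: causal-effect recovery
over 200 replicates of 40-SNP panels; IVW type-I error over 500 null
replicates; Egger-intercept recovery over 150 replicates of 60-SNP
selected panels; two-step mediation recovery over 100 replicates of
50 + 50-SNP studies; MR-PRESSO null calibration over 200 replicates at 500
simulations each. Recovery fixtures for the selection-dependent pipelines
use `gamma_sd = 0.1` (consortium-strength instruments): with weaker
instruments, p-value selection itself induces a small winner's-curse
attenuation (a genuine property of instrument selection, visible at about
0.3% absolute at `gamma_sd = 0.05`), which is documented here as a known
limitation of two-step pipelines rather than hidden inside looser test
tolerances.

## Known limitations

* First-order Wald-ratio SEs; no second-order or exact ratio CIs.
* No conditional F-statistics or weak-instrument-robust MVMR.
* No Steiger directionality filtering; reverse-direction analyses are run
  by swapping exposure and outcome in the config.
* The MR-PRESSO distortion test is not implemented.
* Harmonization handles biallelic SNPs only; indels are rejected.
* Winner's-curse attenuation from instrument selection is not corrected.
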
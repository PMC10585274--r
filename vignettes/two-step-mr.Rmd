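---
title: "Two-sample and two-step Mendelian randomization with mrmediate"
author: "mrmediate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample and two-step Mendelian randomization with mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Mendelian randomization (MR) uses genetic variants as instrumental variables
to estimate the causal effect of an exposure on an outcome from GWAS summary
statistics alone.  A variant $j$ is a valid instrument when it is (a)
associated with the exposure, (b) independent of confounders, and (c)
affects the outcome only through the exposure.  For each instrument the Wald
ratio $\hat\beta_j = \hat\beta^{out}_j / \hat\beta^{exp}_j$ estimates the
causal effect, with first-order standard error
$se_j = se^{out}_j / |\hat\beta^{exp}_j|$ (exposure-side uncertainty
neglected — see *Numerical behaviour* below).

The inverse-variance weighted (IVW) estimator pools the ratios with weights
$w_j = 1/se_j^2$:

$$\hat\beta_{IVW} = \frac{\sum_j w_j \hat\beta_j}{\sum_j w_j}, \qquad
  se_{fixed} = \Big(\sum_j w_j\Big)^{-1/2}.$$

Cochran's statistic $Q = \sum_j w_j (\hat\beta_j - \hat\beta_{IVW})^2$ on
$J-1$ degrees of freedom measures heterogeneity between ratios.  Under the
multiplicative random-effects model — the package default and the primary
estimate of the pipeline — the fixed-effect standard error is inflated by
$\max\{1, \sqrt{Q/(J-1)}\}$, so between-variant heterogeneity widens but
never narrows the interval.

Two supplementary estimators guard against invalid instruments:

* **MR-Egger** regresses outcome effects on exposure effects with a free
  intercept (weights $1/se_{out}^2$) after orienting every variant so its
  exposure effect is nonnegative.  The slope estimates the causal effect
  under the weaker InSIDE assumption; the intercept estimates the mean
  directional pleiotropy of the instruments, and its test is the standard
  pleiotropy diagnostic.  Coefficient SEs are inflated by
  $\max\{1, \sqrt{Q_{res}/(J-2)}\}$, mirroring the IVW treatment.
* The **weighted median** is the inverse-variance weighted median of the
  ratios (piecewise-linear interpolation at cumulative weight $1/2$).  It is
  consistent whenever valid instruments carry more than half the weight.
  Its SE comes from a seeded parametric bootstrap: ratios are resampled from
  $N(\hat\beta_j, se_j^2)$ with the weights held fixed and the SD of the
  recomputed medians taken.

Leave-one-out re-estimates the random-effects IVW $J$ times, each omitting
one variant, flagging omissions that flip the sign of the estimate or move
its p-value across $\alpha$.

All confidence intervals are $\hat\beta \pm 1.96\,se$ and all p-values are
two-sided normal.  The normal (not $t$) reference and the literal 1.96 are
deliberate: they make `(UCI - LCI) / 3.92` an exact inverse for recovering
standard errors from published intervals, which the validation against the
bundled reference tables depends on.

## Instrument selection

`select_instruments()` chains three steps, each available separately:

1. **Association threshold** (`p_threshold = 5e-5`): variants with
   $p < 5\times10^{-5}$ against the exposure, the relaxed threshold often
   used for traits with few genome-wide-significant hits.
2. **LD clumping** (`clump_r2 = 0.001`, `clump_window_bp = 1e7`): greedy
   index-variant selection — repeatedly keep the remaining variant with the
   smallest p and remove every variant on the same chromosome strictly
   within the window whose $r^2$ with it reaches the threshold.  Ties on p
   break by (chromosome, position, id), making the result invariant to input
   row order.  The LD matrix is supplied directly or expanded from a
   `snp_a/snp_b/r2` pair list with absent pairs at $r^2 = 0$; the package
   never computes LD from genotypes.
3. **Weak-instrument screening** (`f_min = 10`): the set-level
   $F = (R^2/K)\,/\,\big((1-R^2)/(N-K-1)\big)$, with $R^2$ the variance in
   the exposure jointly explained by the $K$ instruments.  Because $F$ is a
   property of the whole set, "excluding IVs with F < 10" is operationalized
   as iterative pruning: while $F < 10$ and more than one variant remains,
   drop the variant with the smallest variance-explained contribution and
   recompute.  The decision trail is logged.

Two variance-explained modes exist because the widely quoted shorthand
$2\,\mathrm{EAF}(1-\mathrm{EAF})(\beta/se)^2$ is unnormalized — with
$se \approx 1/\sqrt{2\,\mathrm{EAF}(1-\mathrm{EAF})\,N}$ it equals the
squared z-score times a frequency factor and can exceed 1.  `snp_r2()`
offers it as `mode = "printed"` for fidelity to published usage, while the
properly scaled `mode = "normalized"`, $r^2_j = z_j^2/(n + z_j^2)$, is the
pipeline default used for the F-statistic.

## Harmonization

Two GWAS report effects relative to arbitrarily chosen effect alleles, so
`harmonize()` places both studies on a common orientation before any
estimation: direct allele matches pass through; swapped effect/other labels
negate the outcome beta and complement its EAF; alleles matching only under
strand complement (A↔T, C↔G) are complemented first.  Palindromic variants
(A/T or G/C pairs) carry no strand information in their alleles; they are
dropped when either study's EAF lies within `palindromic_eaf_window = 0.08`
of 0.5 (the dominant two-sample-MR convention; the window is configurable
and the drop is counted) and otherwise oriented by allele-frequency
concordance.  Irreconcilable alleles are dropped and counted separately.
Because every downstream estimator consumes only harmonized betas and SEs —
and double negation is exact in floating point — MR estimates are
bit-identical under any permutation of either study's allele coding, a
property the test suite checks end to end.

## Two-step mediation

For an exposure $X$, candidate mediator $M$, and outcome $Y$,
`run_two_step()` estimates three arms by IVW:

* $\beta_0$ — total effect $X \to Y$, using $X$'s instruments **excluding**
  any variant associated with $M$ at the instrument threshold, so the
  total-effect instruments are independent of the mediator;
* $\beta_1$ — step one, $X \to M$, on $X$'s instruments;
* $\beta_2$ — step two, $M \to Y$, on $M$'s instruments.

The indirect (mediated) effect is the product of coefficients
$\beta_1\beta_2$ with the first-order delta-method standard error
$\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}$; the covariance term is zero
because the two steps come from non-overlapping samples.  Results are also
reported as odds ratios, $\exp(\beta_1\beta_2 \pm 1.96\,se)$, matching the
reporting convention for binary outcomes (beta = log OR).

The pattern is classified at $\alpha = 0.05$ (configurable, no
multiple-testing correction): *partial mediation* when $p_0$, $p_1$, $p_2$
are all significant; *indirect only* when $p_0$ is not significant but
$p_1$, $p_2$, and the indirect effect all are; *no mediation* otherwise.
Note that the classification is a statement about detectability, not
structure: a chain with a nonzero product $\beta_1\beta_2$ and no direct
effect still has a nonzero *total* effect, so with enough power $p_0$
becomes significant and the same data generating process migrates from
"indirect only" to "partial mediation".  The simulation tests assert the
power-consistent label.  An exact $p = 0$ (double underflow at extreme
sample sizes) is accepted and treated as significant.

## The synthetic-data generator

`simulate_study()` produces the three coherent summary-statistics tables the
pipeline needs, with ground truth attached.  Its defaults are the study
conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_snps` | 100 | variants per table |
| `n_exposure/…` | 50,000 | GWAS sample size per trait |
| `sigma_gamma` | 0.08 | SD of true SNP→exposure effects (trait-SD units) |
| `beta_xm`, `beta_my` | 0.3, 0.2 | causal chain coefficients |
| `beta_xy_direct` | 0 | direct exposure→outcome path |
| `prop_invalid` | 0 | fraction of pleiotropic variants |
| `pleiotropy_mean`, `pleiotropy_sd` | 0, 0 | pleiotropy distribution |
| `eaf_range` | (0.05, 0.95) | uniform effect-allele frequencies |
| `ld_block_size`, `ld_rho` | 1, 0 | LD blocks, within-block decay |
| `prop_palindromic` | 0.2 | A/T or G/C variants |

True exposure effects are $\gamma_j \sim N(0, \sigma_\gamma^2)$; observed
betas add $N(0, se_j^2)$ noise with the frequency-dependent
$se_j = 1/\sqrt{2\,\mathrm{EAF}_j(1-\mathrm{EAF}_j)N}$, so weak-instrument
behaviour emerges naturally from frequency and sample size.  Three design
choices deserve comment:

* **Instrument strength.**  With $\sigma_\gamma = 0.08$ and $N = 50{,}000$
  the selected panel's F-statistics are in the hundreds and the two-sample
  regression-dilution factor $\sigma_\gamma^2/(\sigma_\gamma^2 + se^2)$
  leaves a bias below 0.003 on a true effect of 0.3 — small relative to the
  per-study sampling error, so IVW recovery is a clean oracle.  A hundred
  variants at this effect size correspond to a strongly heritable,
  oligogenic exposure (roughly 20–25% of variance through the panel),
  consistent with the instrument-strength claims the estimates are checked
  against.
* **Pleiotropy is anchored to the exposure-increasing allele**: invalid
  variants contribute $s_j\,\alpha_j$ with $s_j = \mathrm{sign}(\gamma_j)$,
  $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$.  Allele coding is
  arbitrary, so "directional" pleiotropy with a nonzero mean is only well
  defined in that orientation; it is also what makes the Egger intercept a
  consistent estimate of the mean pleiotropic effect across instruments
  ($\mu_\alpha \times$ `prop_invalid` when averaged over all variants).
* **Allele coding is randomized independently per trait table** (labels
  swapped, beta negated, EAF complemented, with probability 1/2 per
  variant), so harmonization is load-bearing in every simulated analysis,
  not decorative.

LD enters only through the block-diagonal $r^2$ matrix
($r^2 = \rho^{|i-k|}$ within blocks, blocks 20 Mb apart); clumping is its
only consumer, and the defaults produce independent variants, emulating
post-clumping data.  The generator does **not** simulate individual-level
genotypes, case-control ascertainment or liability-scale effects, sample
overlap between the two studies, allele-frequency estimation error, or
realistic genome-wide LD.  Passing tests therefore demonstrate estimator
correctness under the stated generative model, not robustness to those
real-data complications.

## Validation against published estimates

The package bundles, under `inst/extdata/`, the IVW estimates and
significant indirect effects reported by a published two-sample MR study of
three air pollutants, nine obesity-related traits, and three COVID-19
phenotypes (`load_reference_estimates()`).  Two checks run in the test
suite and the acceptance script:

* applying `indirect_effect()` to the published step-one and step-two IVW
  rows (SEs recovered as CI width / 3.92) reproduces the published indirect
  ORs and CI bounds.  The published inputs carry two significant figures,
  which bounds the achievable agreement: every one of the 87 derived cells
  lands within one unit of the last printed decimal, and 84 match exactly
  after rounding to two decimals — the three exceptions sit within half a
  rounding unit of the propagated input precision;
* feeding the published p-values into `classify_mediation()` labels exactly
  the published significant-indirect-effect triples `indirect_only` and all
  other 52 triples `no_mediation`, with no partial-mediation calls (every
  published total effect is non-significant).

## Numerical behaviour and problem sizes

The first-order Wald-ratio SE ignores exposure-side uncertainty; the
resulting mild underdispersion is absorbed by the multiplicative
random-effects inflation, and simulated 95% CI coverage sits near 94%.
Degenerate inputs fail loudly: zero exposure effects (Wald ratio), fewer
than 3 variants (Egger, weighted median, leave-one-out), constant exposure
effects (Egger design), empty instrument sets, and unreconcilable or
all-palindromic harmonization inputs each raise a typed error, and
`run_all()` isolates per-pair failures so one degenerate trait cannot abort
a multi-trait run.  The simulation experiments in the tests and the
acceptance script use J = 60–150 variants, sample sizes of 50,000–100,000,
and 200–1,000 replicates per experiment — sizes at which the Monte-Carlo
error of the reported summaries is comfortably below the margins being
asserted, while a full run of the suite completes in well under a minute.
Every random quantity, including the weighted-median bootstrap, is
seed-scoped with `withr::with_seed()`, so identical configurations are
byte-identical end to end.

## A worked example

```{r example}
st <- simulate_study(sim_config(seed = 7))
res <- run_two_step(st$exposure_stats, st$mediator_stats, st$outcome_stats,
                    "exposure", "mediator", "outcome")
res
```

The true indirect effect is $0.3 \times 0.2 = 0.06$; the classification is
`partial_mediation` because the (purely mediated) total effect is detected
at these sample sizes.
```{r diagnostics}
mr <- run_mr(st$exposure_stats, st$mediator_stats, "exposure", "mediator",
             settings = list(n_boot = 200))
mr$egger
head(mr$loo, 3)
```
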
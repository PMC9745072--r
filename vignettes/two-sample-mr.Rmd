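---
title: "Two-sample Mendelian randomization with twosmr: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with twosmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twosmr)
```

## The question and the method

Observational cohorts disagree about whether heart failure (HF) raises or
lowers the risk of late-onset Alzheimer's disease (AD); both diseases share
strong confounders (age, diabetes, hypertension, smoking), and survival
bias cuts the other way.  Two-sample Mendelian randomization (2SMR)
sidesteps confounding by using germline variants as instruments: variant
effects on the exposure come from one GWAS (here the CVDKP HF study,
GCST009541, 47,309 cases / 930,014 controls) and effects on the outcome
from an independent GWAS (the EADB AD study, GCST90027158, 85,934 cases /
401,577 controls), both as summary statistics only.

A valid instrument must (1) associate with the exposure, (2) be independent
of confounders, and (3) affect the outcome only through the exposure (no
horizontal pleiotropy).  The package implements the full workflow around
those assumptions: instrument selection, allele harmonization, four causal
estimators, heterogeneity/pleiotropy diagnostics, homogeneous-subset
selection, and power analysis, plus a summary-statistic simulator whose
scenarios deliberately satisfy or violate each assumption so every stage is
testable offline.

## Estimators

Write $\hat\gamma_j \pm \sigma_{X,j}$ for the variant–exposure association
and $\hat\Gamma_j \pm \sigma_{Y,j}$ for the variant–outcome association
after harmonization.  The per-variant Wald ratio is
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard
error $\sigma_{Y,j}/|\hat\gamma_j|$ (the "no measurement error"
approximation, NOME, which ignores $\sigma_{X,j}$), and weight
$w_j = 1/\mathrm{se}(\hat\theta_j)^2$.

* **IVW**: $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$, identical to the
  $1/\sigma_{Y,j}^2$-weighted regression of $\hat\Gamma$ on $\hat\gamma$
  through the origin.  The default standard error is multiplicative random
  effects floored at one: the fixed-effect SE times
  $\max\{1, \sqrt{Q/(m-1)}\}$, so heterogeneity widens the interval but can
  never shrink it below the fixed-effect value.  A `fixed` mode is a flag
  away; on the five-instrument HF analysis the two coincide wherever
  $Q \le m-1$.
* **MR-Egger**: the same regression with an intercept, after orienting all
  $\hat\gamma_j \ge 0$.  Under InSIDE (direct effects independent of
  instrument strength) the slope is the causal effect and the intercept the
  average directional pleiotropy; p-values use $t_{m-2}$, and the SE carries
  the same floored residual scale.
* **Weighted median**: the ratio at cumulative weight one half, linearly
  interpolated across the ordered $\hat\theta_j$; consistent while valid
  instruments hold a majority of the weight.  Its SE is a parametric
  bootstrap (each $\hat\theta_j$ resampled from
  $N(\hat\theta_j, \mathrm{se}_j)$, 1000 replicates by default, seed
  recorded).
* **Weighted mode**: the argmax of a precision-weighted Gaussian kernel
  density over the ratios; consistent while the largest homogeneous cluster
  is valid.  The bandwidth is a modified Silverman rule,
  $0.9\,\min(\mathrm{sd}_w, \mathrm{MAD}_w)\, m^{-1/5}$, computed on the
  weighted ratios and scaled by a user `bandwidth_factor` (default 1); the
  density is evaluated on a 2048-point grid, and a degenerate spread falls
  back to the most heavily weighted value.  SE by the same bootstrap.

Causal effects are log odds ratios; `to_odds_ratio()` applies the
two-sided 95% multiplier 1.959964 throughout.

## Harmonization rules

Variants are matched across studies by rsid only (builds may differ;
chromosome/position are annotation).  Outcome records are aligned to the
exposure's effect allele by direct comparison and by reverse complement;
swapped configurations negate the outcome beta and reflect its allele
frequency.  For palindromic variants (A/T, C/G) strand cannot be read off
the alleles, so orientation is inferred from allele-frequency concordance —
but only when both frequencies lie outside the ambiguity band
$[0.5 - b, 0.5 + b]$ with $b = 0.08$ by default (EAF in [0.42, 0.58] is
"intermediate", the common 2SMR convention).  Ambiguous palindromes are
dropped with an explicit reason, which is exactly how the HF candidate set
narrows from 12 to 9 instruments (rs1556516, rs4746140, rs4766578 in the
real data).  Strict mode (default) also drops palindromes with a missing
frequency; permissive mode assumes a shared strand instead.  When a variant
is absent from the outcome study, an LD proxy with $r^2 > 0.8$ can stand in;
the record is reported under the query rsid with the proxy noted.

## Instrument selection

The exposure screen keeps variants with $p < 5\times10^{-8}$, then prunes
LD by greedy p-value-ranked clumping: the best remaining variant indexes a
clump and removes everything within ±10,000 kb on the same chromosome with
$r^2 \ge 0.001$.  Ties on p-value break lexicographically by rsid, so the
result is order-invariant.  LD comes from a user-supplied matrix or
3-column pair file — never a remote panel query — and variants absent from
it are retained as independent with a warning (conservative and auditable).
Instrument strength is $F = \beta^2/\mathrm{SE}^2$ with the conventional
$F \le 10$ weak-instrument flag.  Note that the packaged HF instrument
table carries the published F values (computed upstream from unrounded
statistics) alongside; recomputing from the rounded table gives slightly
smaller numbers (31.2 vs 32.31 for rs1510226), a discrepancy the fixture
documents rather than hides.

## Heterogeneity, influence, and subset selection

Cochran's $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ is referred to
$\chi^2_{m-1}$ (IVW reference) or, as the weighted residual sum of the
Egger fit, to $\chi^2_{m-2}$.  Per-variant contributions sum exactly to
$Q$ and drive the subset selection.  Leave-one-out recomputes IVW $m$
times and flags variants whose omission moves the estimate by more than
one all-SNP SE (a stated default; adjust `flag_multiple`).  Single-SNP and
funnel tables are plot-ready data, not figures.

The published HF–AD analysis chose its five homogeneous instruments
(rs55730499, rs4135240, rs17617337, rs600038, rs1510226) by visual
inspection of the leave-one-out plot.  `select_homogeneous_subset()`
formalises that judgment call so it is deterministic and logged: `greedy_q`
repeatedly removes the largest Q-contributor until the Q p-value exceeds
0.05 (or three instruments remain); `exhaustive_small` enumerates all
subsets of size ≥ 3 (feasible to $m = 12$) and returns the largest
qualifying subset, ties broken by larger p-value and then lexicographic
rsid order.  Whether a visual choice coincides with the exhaustive optimum
is answerable the moment the outcome-side data are supplied.

## Power

For a binary outcome the package uses the standard normal approximation
behind the widely used online 2SMR power calculators:
$\mathrm{power} = \Phi\!\big(|b|\sqrt{n\,R^2\,K(1-K)} - z_{1-\alpha/2}\big)$
with outcome sample size $n$, case fraction $K$, and instrument $R^2$ on
the exposure.  Only the tail on the side of the true effect is counted.
Because published analyses rarely state their $R^2$ convention, two are
implemented and always reported side by side: the allele-frequency form
$\sum_j 2\beta_j^2\,p_j(1-p_j)$ (default) and the F-based form
$\sum_j F_j/(F_j + n - 2)$.  On the five HF instruments with the AD
outcome design ($n = 487{,}511$, $K = 85{,}934/487{,}511$,
$b = \ln 0.752$) they give 99.98% and 17.3% respectively — bracketing,
but not reproducing, the 97.9% computed upstream with a calculator whose
internal $R^2$ (a log-OR-based binary-exposure correlation) is not
reconstructible from the printed instrument table.  The run log records
which convention produced any number the pipeline reports.

## The simulator: what it emulates and what it does not

`simulate_two_sample()` works at the summary-statistic level.  Per variant
it draws an allele frequency $p_j \sim U(0.05, 0.95)$ and a true exposure
effect $\gamma_j$ with $|\gamma_j| \sim U(0.03, 0.2)$ (random signs by
default), sets the outcome-side truth to $\theta\gamma_j + \alpha_j$ with
$\alpha_j$ the scenario's direct effect, and adds Normal sampling noise
with the standardised-genotype SE $(2p_jq_jn)^{-1/2}$.  Binary-trait
case-fraction factors are absorbed into the effective $n$, chosen so the
default exposure size (10,000) puts F statistics in the realistic 10–100
band of the HF instruments (published range 30.89–83.10); the default
outcome size is 50,000.  Allele pairs include a configurable palindromic
fraction, and the outcome file's representation is scrambled with random
allele swaps and strand complements (frequencies perturbed by
$N(0, 0.005^2)$ between studies), so harmonization is exercised for real:
a test verifies that harmonization restores the truth-frame betas exactly.
The generated truth (θ, per-variant γ and α, scenario, seed) travels with
every dataset, and a single integer seed reproduces it bit for bit without
touching the caller's RNG stream.

Scenario presets cover the IV-assumption grid: `null`, `causal`
(θ = ln 0.752, the scale of the HF–AD IVW estimate),
`directional_pleiotropy` (30% of instruments with
$\alpha \sim N(0.05, 0.02)$ oriented to the exposure-increasing allele,
InSIDE holding), `balanced_pleiotropy`, `weak_instruments` (median
F ≤ 10), and `ld_structured` (10 blocks of 5 variants at within-block
$r^2 = 0.8$, emitted with its LD matrix for clumping tests).

What the simulator does **not** emulate: individual-level genotypes,
realistic LD decay from reference panels, selection/survival bias, or
sample overlap between the two studies.  Passing recovery tests on these
simulations therefore demonstrates correctness of the estimators and
plumbing under the stated model, not robustness to everything real GWAS
data can do.

## Numerical choices and degenerate inputs

* P-values: normal for IVW/median/mode, $t_{m-2}$ for both Egger
  coefficients (stated explicitly since conventions differ across
  software).
* Residual scales are floored at 1 in both IVW-MRE and Egger SEs.
* Clumping ties break by rsid; missing chromosome/position puts a pair
  inside the window, so the $r^2$ rule alone decides.
* `wald_ratios()` refuses a zero exposure beta by name;
  estimators refuse $m$ below their minimum (1 for IVW, 3 for
  Egger/median/mode) with explicit messages; a harmonization that retains
  nothing returns an audited empty result rather than crashing.
* Bootstrap SEs run under an isolated RNG stream keyed by the supplied
  seed; identical seeds give identical SEs.
* The weighted median interpolates on the cumulative-weight scale
  $s_j = (\sum_{k\le j} w_k - w_j/2)/\sum_k w_k$ and clamps outside
  $[s_1, s_m]$.

## Known limitations

Two estimator properties surface honestly in the validation suite rather
than being glossed over.  First, two-sample IVW carries a finite-sample
attenuation toward the null of order $|\theta|/F$; at the realistic
instrument strength the generator defaults to (F ≈ 30–80) that is ~1–2% of
the effect, which is visible once ~500 replicates shrink the Monte-Carlo
error below it.  Second, with one-sided (directional) contamination the
weighted median's estimand sits at the $0.5/(1-c)$ quantile of the valid
ratios ($c$ the contaminated weight fraction), a shift proportional to the
per-variant ratio spread — far smaller than the IVW bias under the same
contamination, but not zero.  MR-Egger additionally relies on NOME: at
F ≈ 50 its intercept test is materially miscalibrated, which is why the
Egger-diagnostic scenario uses very strong simulated instruments
(effective exposure n of $10^6$, m = 100).  Finally, reproducing the
published HF→AD odds ratios end to end requires the AD outcome summary
statistics (GCST90027158), which are not redistributable inside the
package; the reproduction test runs whenever a user drops the extracted
five-instrument outcome rows into the test data directory.

## Problem sizes used in the test suite

The suite validates calibration with 1000 null-scenario replicates
(m = 50), recovery with 500 causal-scenario replicates, Egger level/power
with 80–120 replicates at m = 100, and consistency at two sample-size
rungs (40 replicates each); the full run takes a few minutes on one core.
These sizes are the package's own choice of Monte-Carlo resolution: large
enough that a 1.5-point miscalibration of a 5% test would be detected,
small enough to run routinely.
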
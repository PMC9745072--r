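# twosmr

Two-sample Mendelian randomization (2SMR) from GWAS summary statistics,
built around the analysis of whether genetically predicted **heart failure
(HF)** alters the risk of **late-onset Alzheimer's disease (AD)**.
Observational studies disagree on this question because the two diseases
share major confounders (age, diabetes, hypertension, smoking) and because
HF shortens survival; 2SMR uses germline variants as instruments, so the
estimate is robust to confounding.  The package ships the five
genome-wide-significant HF instruments from the CVDKP HF GWAS
(GCST009541) and everything needed to re-run the analysis against an
outcome study such as the EADB AD GWAS (GCST90027158) — or against fully
synthetic data with known causal truth.

## What it computes

Given harmonised variant effects on exposure ($\hat\gamma_j$) and outcome
($\hat\Gamma_j$), each variant's Wald ratio
$\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ estimates the causal log odds
ratio.  Four estimators combine them:

* **IVW** — the $1/\mathrm{se}^2$-weighted mean of the ratios
  (multiplicative random effects, residual scale floored at 1);
* **MR-Egger** — weighted regression with an intercept; the intercept
  tests directional pleiotropy;
* **weighted median** — the ratio at cumulative weight ½, robust while
  valid instruments hold a weight majority;
* **weighted mode** — the argmax of a precision-weighted kernel density,
  robust while the largest homogeneous cluster is valid.

Around the estimators: genome-wide significance filtering, greedy LD
clumping (±10,000 kb, $r^2 < 0.001$), exclusion screening, LD-proxy
lookup ($r^2 > 0.8$), instrument F statistics, allele harmonization with
palindromic-variant handling (ambiguity band EAF 0.42–0.58), Cochran-Q
heterogeneity, leave-one-out / single-SNP / funnel tables,
homogeneous-subset selection, and binary-outcome power analysis.

## Worked example

Simulate a two-sample study with a protective causal effect
(θ = ln 0.752 ≈ −0.285, the scale of the HF→AD IVW estimate), harmonise,
and estimate:

```r
library(twosmr)
sim <- simulate_two_sample(scenario_preset("causal", seed = 42))
h   <- harmonise(sim$exposure, sim$outcome)
mr_all(h, seed = 1)
#>            method nsnp      b      se      pval    or or_lo95 or_hi95
#> 1             IVW   50 -0.284 0.00732  0.00e+00 0.753   0.742   0.764
#> 2        MR Egger   50 -0.280 0.01935  3.80e-19 0.756   0.727   0.785
#> 3 Weighted median   50 -0.271 0.01021 6.99e-155 0.763   0.748   0.778
#> 4   Weighted mode   50 -0.262 0.01849  1.13e-45 0.769   0.742   0.798
cochran_q(h)
#>   method    Q df  pval
#> 1    IVW 45.8 49 0.603
```

All four estimators recover the simulated odds ratio (~0.75), and the Q
test correctly finds no heterogeneity.  The real exposure-side instruments
are packaged:

```r
hf_instruments()[, c("rsid", "gene", "eaf", "beta", "se", "pval")]
#>         rsid       gene  eaf   beta    se     pval
#> 1  rs1510226    SLC22A3 0.01  0.162 0.029 1.27e-08
#> 2 rs17617337       BAG3 0.22 -0.056 0.010 3.65e-09
#> 3  rs4135240     CDKN1A 0.34 -0.049 0.008 6.84e-09
#> 4 rs55730499        LPA 0.07  0.106 0.016 1.83e-11
#> 5   rs600038 ABO, SURF1 0.21  0.057 0.010 3.68e-09
```

and the power of the HF→AD design (AD outcome: 487,511 individuals,
85,934 cases) to detect OR = 0.752 is evaluated under both implemented
instrument-R² conventions:

```r
mr_power_analysis(hf_instruments(), n_outcome = 487511,
                  case_fraction = 85934 / 487511, b = log(0.752))
#>   r2_method        r2  power
#> 1       eaf 0.0052144 0.9998
#> 2         f 0.0001806 0.1733
```

`run_pipeline(run_config(...))` chains every stage (select → harmonise →
estimate → diagnose → subset → power), writes each table as TSV, and
leaves a `run_report.json` capturing every threshold, seed, and attrition
count.  Re-running the same configuration is byte-identical.

To reproduce the published HF→AD odds ratios end to end you additionally
need the AD outcome rows for these instruments from GCST90027158 (the
package does not redistribute them); see the vignette for where the test
suite picks them up.

## Package layout

* `R/` — summary-statistics I/O, instrument selection, harmonization,
  estimators, diagnostics, power, simulator, pipeline
* `inst/extdata/hf_instruments.tsv` — the five HF instruments
* `vignettes/two-sample-mr.Rmd` — models, defaults, numerical choices,
  and known limitations
* `tests/testthat/` — unit, property, and end-to-end validation suites
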
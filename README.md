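# tumorHet

Two-stage polytomous logistic regression for characterizing **etiologic
heterogeneity** of genetic susceptibility variants across breast-tumor
subtypes defined by ER, PR, HER2 and histologic grade.

Germline risk variants often confer different risks for different tumor
subtypes, but the defining markers are strongly correlated and frequently
missing in consortium data. `tumorHet` models the 24-cell
ER×PR×HER2×grade cross-classification jointly with controls and
decomposes the per-cell genotype log odds ratios into a small set of
interpretable parameters,

&nbsp;&nbsp;&nbsp;&nbsp;β = A·θ,&nbsp;&nbsp;&nbsp;
β<sub>m</sub> = θ<sub>0</sub> + θ<sub>ER</sub>·ER<sub>m</sub> +
θ<sub>PR</sub>·PR<sub>m</sub> + θ<sub>HER2</sub>·HER2<sub>m</sub> +
θ<sub>grade</sub>·(grade<sub>m</sub> − 1),

where each case-case parameter θ<sub>k</sub> measures how the genotype
effect changes with one tumor feature, adjusted for the others. Cases with
missing markers contribute through the observed-data likelihood (markers
missing at random), maximized either by an EM algorithm over tumor-cell
membership or by Newton iteration with the exact analytic Hessian.

The package implements the full screening workflow:

* **mixed-effect global heterogeneity test** per variant (ER fixed;
  PR/HER2/grade random with a boundary score test whose null is a weighted
  chi-square mixture), meta-analyzed across genotyping-array strata;
* **Benjamini–Hochberg FDR** across the screened variants;
* **marker-specific case-case tests** (fixed-effect model, mutually
  adjusted) for the FDR-significant set;
* **case–control ORs for the five intrinsic-like subtypes** (luminal
  A-like, luminal B-like/HER2−, luminal B-like/HER2+,
  HER2-positive/non-luminal, triple-negative) and **by grade** for
  grade-only variants;
* **complete-case sensitivity analysis** (standard polytomous model on
  unambiguous cases);
* clustering of absolute z-statistics, heatmap and forest-plot rendering;
* a **calibrated synthetic cohort generator** (correlated latent-Gaussian
  markers, Hardy–Weinberg dosages with exact case tilting, configurable MAR
  missingness, strata and ancestry PCs) with recorded truth.

## Worked example

Simulate a two-array cohort of 3,000 cases / 3,000 controls with six
variants — one with a true ER case-case effect (θ_ER = 0.4), five null —
then run the screen:

```r
library(tumorHet)

v <- data.frame(maf = rep(0.3, 6), theta1 = 0, theta2 = 0, theta3 = 0,
                theta4 = 0, theta5 = 0)
v[1, "theta2"] <- 0.4                       # ER heterogeneity for variant 1
sim <- simulate_cohort(simulation_config(n_cases = 1500, n_controls = 1500,
                                         n_strata = 2, variants = v,
                                         n_pcs = 2, seed = 7))
res <- run_screen(sim)
res$screen[, c("variant_id", "p_global", "q_global", "fdr_sig", "z_ER", "p_ER")]
#>        variant_id p_global q_global fdr_sig z_ER     p_ER
#> var001     var001 7.44e-06 4.46e-05    TRUE  4.2 2.71e-05
#> var002     var002 5.74e-01 7.62e-01   FALSE   NA       NA
#> var003     var003 2.30e-01 4.61e-01   FALSE   NA       NA
#> var004     var004 1.10e-01 3.31e-01   FALSE   NA       NA
#> var005     var005 6.35e-01 7.62e-01   FALSE   NA       NA
#> var006     var006 9.71e-01 9.71e-01   FALSE   NA       NA
```

The ER-heterogeneous variant is the only one passing the FDR gate
(q = 4.5e-05), and the marker-specific tests attribute its heterogeneity to
ER (z = 4.2, p = 2.7e-05) and not to PR, HER2 or grade. Its intrinsic-like
subtype ORs show the corresponding gradient — elevated risk for the luminal
(ER-driven) subtypes, none for HER2-positive/non-luminal or triple-negative:

```r
subset(res$subtype_or, variant_id == "var001")
#>   variant_id           category  log_or     se    OR    lo   hi        p
#> 1     var001           luminalA  0.3892 0.0487 1.476 1.341 1.62 1.33e-15
#> 2     var001   luminalB_HER2neg  0.4192 0.0905 1.521 1.274 1.82 3.58e-06
#> 3     var001   luminalB_HER2pos  0.3627 0.0994 1.437 1.183 1.75 2.65e-04
#> 4     var001 HER2pos_nonluminal -0.0186 0.1784 0.982 0.692 1.39 9.17e-01
#> 5     var001    triple_negative  0.0743 0.0912 1.077 0.901 1.29 4.15e-01
```

`render_reports(res, "out/")` writes the screen table, the clustered
|z|-matrix with a signed-z heatmap, and per-variant forest plots.
`write_cohort()` / `read_cohort()` round-trip cohorts through documented
TSV formats (or VCF with a `DS` dosage field).

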
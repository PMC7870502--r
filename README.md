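# arcfluid

Quantitative analysis of **fluid-therapy-induced augmented renal
clearance (ARC)** in a two-period piglet study, as a tested, reusable R
pipeline.

ARC — supraphysiological renal elimination of circulating solutes — puts
critically ill patients at risk of subtherapeutic exposure to renally
excreted drugs. `arcfluid` implements the full analysis chain for a
crossover-style animal experiment probing whether continuous IV fluid
administration drives ARC: 12 control and 12 treatment piglets each
receive IV boluses of three markers, at baseline (M1) and again (M2)
after the treatment arm has had 24 h of 0.9% saline at 6 mL/kg/h:

* **iohexol** (64.7 mg/kg) — glomerular filtration rate, as total body
  clearance;
* **para-aminohippuric acid** (10 mg/kg) — effective renal plasma flow,
  via urinary renal clearance;
* **amikacin** (7.5 mg/kg) — a renally cleared antibiotic and candidate
  GFR surrogate.

## What the package computes

At its core sits per-individual compartmental PK. Each concentration
profile `C(t) = A·e^(−αt) + B·e^(−βt)` is fitted by maximum likelihood
in the clearance/volume parameterization (CL_TOT, V1, Q, V2) under a
proportional or additive residual error model, with below-LLOQ records
excluded. Primary parameters are CL_TOT (mL/min/kg) and the volumes;
secondary parameters are V_ss = V1 + V2 (mL/kg) and

    AUC_0→inf = dose · 10⁶ / (CL_TOT · 60)   [ng·h/mL, dose in mg/kg]

A precision gate (CV% of every structural parameter) decides between
the two-compartment model and a one-compartment fallback. Around the
fits:

* non-compartmental AUC with a strict `< 10%` extrapolation quality
  gate;
* renal clearance `CL_R = Ae / AUC_0→inf` from timed urine collections,
  urine output (mL/kg/h), and plasma-volume change from hematocrit by
  the van Beaumont formula;
* test–retest reproducibility `R = √(Σ CVᵢ²/n)` and Bland–Altman
  percent-difference agreement with 95% limits of agreement;
* exact (enumeration-backed) one- and two-sided Wilcoxon signed-rank
  and Mann–Whitney U tests, Pearson correlation, linear trend test,
  median (P25–P75) summary tables;
* screening filters: hematology + fever exclusion, urine-leak
  exclusion for renal clearance;
* a seeded synthetic cohort generator reproducing the study's design
  (doses, 13-point sampling schedule, LLOQ censoring, between-animal
  and test–retest variability, treatment-arm fluid effect), so the
  entire pipeline runs and is testable without any data download.

## Worked example

```r
library(arcfluid)

sim    <- simulate_cohort(simulation_config(), seed = 1)
report <- run_analysis(sim)
report
#> <arc_report> 144 fitted profiles, 24 included animals (control 12, treatment 12)
#> reproducibility (control group):
#>   analyte  n mean_cv_pct cv_min_pct cv_max_pct r_pct
#>  amikacin 12        5.53      0.790       11.6  6.31
#>   iohexol 12        3.80      0.908        5.9  4.15
#>       pah 12       19.20      1.774       42.4 23.26
```

Duplicate clearance determinations in the control arm are highly
reproducible for iohexol and amikacin (R ≈ 4–6%) and much less so for
PAH (R ≈ 23%) — the generator is calibrated to produce exactly this
contrast, and the analysis recovers it.

```r
subset(report$summary, parameter == "cl_tot" & analyte == "iohexol")
#>  analyte parameter     group occasion  n  p25 median  p75
#>  iohexol    cl_tot   control       M1 12 3.25   3.56 3.99
#>  iohexol    cl_tot treatment       M1 12 3.49   3.67 3.91
#>  iohexol    cl_tot   control       M2 12 3.38   3.58 3.81
#>  iohexol    cl_tot treatment       M2 12 4.00   4.50 4.76

subset(report$tests, parameter == "cl_tot" & analyte == "iohexol")
#>  parameter analyte                          comparison alternative      method statistic  p_value  n  m
#>     cl_tot iohexol             within_control_M2_vs_M1     greater       exact        42 4.25e-01 12 NA
#>     cl_tot iohexol           within_treatment_M2_vs_M1     greater       exact        78 2.44e-04 12 NA
#>     cl_tot iohexol between_change_treatment_vs_control     greater approximate       137 9.81e-05 12 12
```

The treatment arm's iohexol clearance rises from a median of 3.67 to
4.50 mL/min/kg while the control arm is flat (3.56 vs 3.58): the
one-sided signed-rank test detects the within-treatment increase
(p = 2.4·10⁻⁴) and the Mann–Whitney test confirms the increase is
larger than in controls (p = 9.8·10⁻⁵). Marker agreement mirrors the
GFR-surrogate question:

```r
report$correlations
#>                    comparison     r  p_value  n
#>  iohexol_vs_amikacin_baseline 0.741 3.41e-05 24
#>     iohexol_vs_amikacin_fluid 0.584 4.61e-02 12
```

`write_report(report, "report_dir")` writes every table as CSV plus a
JSON manifest; `inst/scripts/arcfluid-cli.R` wraps `simulate` and
`analyze` for shell use.

## Package layout

| Path | Contents |
| --- | --- |
| `R/study_data.R` | dataset schema, validation, CSV I/O |
| `R/pk_models.R` | compartmental models, ML fitting, model selection |
| `R/nca.R` | non-compartmental AUC and extrapolation gate |
| `R/renal_fluid.R` | urinary excretion, CL_R, urine output, %ΔP |
| `R/agreement_stats.R` | duplicate CV, reproducibility R, Bland–Altman, Pearson |
| `R/cohort_stats.R` | rank tests, trend test, screening filters, summaries |
| `R/synthetic_data.R` | seeded cohort generator and anomaly injection |
| `R/pipeline.R` | `run_analysis()` orchestration and report writing |
| `vignettes/arcfluid-methods.Rmd` | model, assumptions, design choices |
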
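# shapcov

SHAP-based covariate analysis for population pharmacokinetic (PK) models.

`shapcov` is for pharmacometricians and biostatisticians who want to *learn*
the functional form of covariate effects (allometric curves, group shifts,
thresholds, interactions) from data instead of assuming one, using tree
ensembles explained by exact Shapley values. The package implements the
whole chain as tested, dependency-light R:

- **Two-compartment IV kinetics** — analytic bi-exponential solution for
  arbitrary bolus/infusion schedules, `predict_concentration()`.
- **Empirical Bayes (MAP) estimation** — per-occasion individual CL and V1
  under a fixed base model with log-normal IIV and combined
  additive/proportional error, `estimate_ebe_table()`.
- **From-scratch tree ensembles** — CART random forests and second-order
  gradient boosting with native missing-value routing and per-node training
  cover, `fit_forest()`, `fit_boosted()`.
- **Exact SHAP** — the tree path-dependent decomposition
  `fx = phi0 + sum_i phi_i`, exact to the Shapley definition (verified
  against brute-force subset enumeration), `exact_shapley()`,
  `shap_for_fold()`, `rank_covariates()`, `combine_shap()`.
- **Curve inference** — LOESS smooths of pooled (covariate, SHAP) clouds and
  parametric form fits: power law `a*(w/w_ref)^b + c`, linear, threshold
  step, `covariate_curve()`, `fit_power_form()`, `threshold_scan()`.
- **Synthetic study generator** — a peri-operative hemophilia-A-like study
  (119 patients / 197 procedures, 13 covariates with realistic missingness,
  guideline-targeted FVIII dosing) with a *known* ground-truth covariate
  model, so the full pipeline is validated by recovering planted effects,
  `simulate_study()`, `run_study()`.

The central quantity is the exact Shapley value of covariate `i` for a tree
ensemble `f` at row `x`,

    phi_i = sum over S ⊆ M\{i} of |S|! (M-|S|-1)! / M! * [v(S ∪ {i}) - v(S)]

with `v(S)` the path-dependent conditional expectation: splits on features
in `S` follow the row (missing values follow the node's learned default
direction), all other splits average both children weighted by training
cover. Efficiency holds per row: `phi0 + sum_i phi_i = f(x)` to 1e-8.

## Worked example

Simulate a small study from the default ground truth (allometric weight
effect `b_CL = 0.75`, blood-group-O clearance factor 1.2, BMI>25 volume
factor 0.8), run the full pipeline — empirical Bayes, 5-fold
patient-grouped CV of a random forest, exact SHAP on every test fold — and
inspect what it found:

```r
library(shapcov)
res <- run_study(design = study_design(n_patients = 60, n_procedures = 75),
                 k_folds = 5, seed = 42)
print(res)
#> <study_result: forest model, 75 occasions, 5 folds>
#>   CL : MAE 49.1 +/- 6.0 ml/h (R2 = -0.03)
#>   V1 : MAE 1200 +/- 204 ml (R2 = 0.19)
#>   concentration RMSE: 0.252 +/- 0.129 IU/ml
#>   top covariate (CL): weight; (V1): weight

head(res$ranking$cl, 5)
#>        covariate mean_abs_shap
#> 1         weight     17.114731
#> 2            age      6.741269
#> 3 fviii_baseline      6.061376
#> 4     blood_loss      4.513113
#> 5    blood_group      3.673012

categorical_effect(res$pooled$cl, "blood_group")
#>     level mean_shap   sd_shap  n
#> 1 missing -4.843867 1.9979613 14
#> 2   non-O -1.715389 0.9860518 24
#> 3       O  4.446312 2.0804861 37
```

Reading the output: the MAE is in the target's units (ml/h of clearance per
occasion) averaged over CV test folds ± SD across folds; at this small size
the forest has little skill on clearance (R² near 0) yet the *attribution*
already works — weight is the top-ranked covariate for both parameters by
mean |SHAP|, and blood group O shifts clearance SHAP upward (+4.4 ml/h vs
−1.7 ml/h for non-O), the direction planted in the generator. Recovery of
the numeric exponent `b` needs more subjects: at 500 subjects the shipped
validation requires `b` in [0.55, 0.95] (truth 0.75). `res$curves` and
`res$form_fits` hold the LOESS curves and the candidate parametric fits
with their SSEs; `res$pooled` holds the long-format pooled SHAP tables.

A thin command-line wrapper with `simulate` / `ebe` / `run` / `report`
subcommands lives at `inst/scripts/shapcov-cli.R`.

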
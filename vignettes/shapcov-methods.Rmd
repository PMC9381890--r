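---
title: "Inferring covariate functional forms for population PK models with tree ensembles and exact SHAP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring covariate functional forms for population PK models with tree ensembles and exact SHAP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapcov)
```

## The problem

Covariate model building for population pharmacokinetic (PK) models usually
proceeds either stepwise (test one covariate-parameter relation at a time) or
through a full fixed-effects fit. Both require the analyst to *choose a
functional form in advance* — allometric power, linear slope, category shift —
and a wrong choice can hide a real covariate or admit a spurious one. The
alternative implemented here lets a flexible machine-learning model learn the
covariate-parameter mapping from data, and then reads the *shape* of each
covariate's effect off an exact additive decomposition of the model's
predictions (Shapley values). The pipeline is:

1. estimate individual clearance (CL) and central volume (V1) per surgical
   occasion by empirical Bayes under a fixed base two-compartment model;
2. predict those individual parameters from 13 clinical covariates with a
   random forest or gradient-boosted trees under patient-grouped
   cross-validation;
3. decompose every held-out prediction exactly as
   $f_x = \phi_0 + \sum_{i=1}^{M} \phi_{x_i}$;
4. pool the per-fold SHAP values and smooth each covariate's
   $(x_i, \phi_{x_i})$ cloud with LOESS;
5. fit candidate parametric forms (power law, linear, threshold step) to the
   pooled cloud and report their parameters and SSEs side by side. No winner
   is declared automatically — the module reports evidence.

Because no deposited clinical dataset exists for the motivating application
(peri-operative factor VIII replacement in hemophilia A), the package ships a
synthetic study generator with a *known* ground-truth covariate model. Every
claim the package makes about itself is a recovery claim on that generator,
computed by the test suite or the acceptance script — nothing in this
vignette quotes a number the code does not produce.

## Two-compartment kinetics

Central and peripheral amounts follow
$\mathrm{d}A_1/\mathrm{d}t = \mathrm{in}(t) - (k_{10}+k_{12})A_1 + k_{21}A_2$,
$\mathrm{d}A_2/\mathrm{d}t = k_{12}A_1 - k_{21}A_2$ with
$k_{10}=CL/V_1$, $k_{12}=Q/V_1$, $k_{21}=Q/V_2$, and concentration
$C(t) = \text{baseline} + A_1(t)/V_1$. Units are fixed throughout: ml, h, IU.
The solution is the analytic bi-exponential form (eigenvalues
$-\alpha, -\beta$ of the rate matrix) with superposition over bolus and
constant-rate infusion segments; a numeric ODE integrator appears only as a
test oracle. Numerical choices:

* the repeated-eigenvalue case $\alpha=\beta$ (measure zero) is displaced by
  a $10^{-12}$ relative perturbation of $k_{10}$ rather than implementing a
  confluent branch;
* $Q=0$ degenerates cleanly to the one-compartment solution because the
  coefficient of the $\beta$-exponential is exactly zero and its infusion
  term is skipped;
* the endogenous baseline enters additively and is not cleared — a
  deliberate simplification (no endogenous turnover model), exposed as a
  per-record field.

## Empirical Bayes (MAP) stage

Population parameters are *inputs*, not estimates: typical values CL 163
ml/h, V1 3030 ml, Q 56.9 ml/h, V2 1270 ml, interindividual variability 65.2
and 83.5 %CV on CL and V1, and residual SDs fixed at $\sigma_1 = 0.08$
IU/ml (additive) and $\sigma_2 = 0.17$ (proportional). Random effects exist
on CL and V1 only; Q and V2 are used as-is for every subject. The
per-occasion estimate minimises

$$\sum_j \left[ \frac{(y_j - f_j(\eta))^2}{v_j} + \ln v_j \right]
  + \eta^\top \Omega^{-1} \eta, \qquad
  v_j = \sigma_1^2 + (\sigma_2 f_j(\eta))^2,$$

dropping $\ln|\Omega|$ and $2\pi$ constants (they cannot move the argmin).
%CV values convert to log-scale SDs by the exact log-normal relation
$\omega = \sqrt{\ln(1+CV^2)}$; $\omega \approx CV$ only for small CV.

Optimisation runs a Nelder-Mead descent followed by a BFGS polish (difference
steps $10^{-6}$), from the prior mode and from two fixed displaced starts
$(\pm 0.5, \pm 0.5)$. The displaced starts are deterministic rather than
randomly jittered so estimation never consumes RNG state. The simplex stage
matters: in the near-noiseless regime the likelihood is a very sharp, curved
valley and finite-difference gradients from a cold start are unreliable.
Non-convergence is flagged on the result, never raised.

One $\eta$ pair is estimated per surgical occasion by default (covariates in
the emulated study are per-procedure); `per_patient = TRUE` shares a pair
across a patient's occasions. A subtlety worth knowing: with sizeable
$\sigma_2$ the $\ln v_j$ term legitimately shifts the optimum away from the
data-generating $\eta$ even with zero residuals — tests of the "noise-free"
limit therefore match the population $\sigma$'s to the simulation.

## Tree ensembles

CART forests and second-order gradient boosting share one split-search
engine operating on gradient/hessian statistics. For squared loss with
$g = \hat{y} - y$, $h = 1$, the boosted gain is
$\tfrac12[G_L^2/(H_L+\lambda) + G_R^2/(H_R+\lambda) - G^2/(H+\lambda)] - \gamma$
with leaf value $-G/(H+\lambda)$; setting $\lambda=\gamma=0$ and $g=-y$
makes the same expression the SSE reduction with mean-value leaves, i.e.
plain CART — the argmax is identical, so one engine serves both honestly.
Candidate thresholds are midpoints between consecutive distinct observed
values; rows whose split feature is missing are scored down both directions
and sent down the better one, which is recorded as the node's *default
direction* (native missing-value routing). Every node stores its *cover*
(training rows routed through it); the explainer depends on both.

Determinism: gain ties break to the lowest feature index, then the lowest
threshold; a tiny relative floor ($10^{-10}$ of the parent score) rejects
splits whose "gain" is accumulated round-off, which is what guarantees a
single leaf on constant responses. Defaults: forest — 100 trees, bootstrap
on, `min_leaf` 2, *all* features per split; boosted — 100 rounds, learning
rate 0.3, depth 6, $\lambda = 1$, $\gamma = 0$. All-features-per-split is the
regression default of the reference random-forest implementations and was
chosen deliberately: with correlated covariates, per-split feature
subsampling (the classic $\lceil p/3 \rceil$ rule) forces proxy covariates
into splits and measurably dilutes Shapley credit; `mtry` remains available
for users who want extra decorrelation.

## Exact Shapley values under the path-dependent expectation

For a conditioning set $S$, the tree value function $v(S)$ follows the row's
branch wherever the split feature is in $S$ (missing values follow the
default direction) and otherwise averages both children weighted by training
cover. The contribution of covariate $i$ is the exact Shapley sum

$$\phi_i = \sum_{S \subseteq M \setminus \{i\}}
  \frac{|S|!\,(M-|S|-1)!}{M!}\,[v(S\cup\{i\}) - v(S)].$$

Implementation: $v$ decomposes over leaves, and each leaf contributes a
*multiplicative* game $u(S) = c \prod_{j\in F}(j \in S \mathbin{?} a_j : r_j)$,
where $F$ are the distinct features on its path, $a_j \in \{0,1\}$ records
whether the row's routing agrees with every $j$-split on the path, and
$r_j$ is the product of cover fractions at those splits. The Shapley value
of such a game has a closed form through the coefficients of
$\prod_{l \ne j}(r_l + a_l z)$, evaluated by building the product polynomial
once per leaf and deflating it per feature — algebraically identical to the
$2^M$ subset enumeration but polynomial in path depth, so deep forests on
hundreds of rows are explained in seconds. The test suite keeps a separate
brute-force subset-enumeration oracle (bitmask-memoised $v(S)$) and checks
the two routes agree to $10^{-10}$; the suite also reproduces an external
reference tree-SHAP implementation to $10^{-6}$ on shared fixtures (the
fixtures use float32-exact feature values, because the reference quantises
thresholds to float32 on export and rows lying between a double and its
float32 image would otherwise route differently — a representation issue,
not an attribution one).

Feature count is capped at 16 (the emulated study has $M = 13$); beyond
that the exact contract would need a sampling approximation, which is out
of scope. SHAP of a missing value is well-defined (default-direction
routing); rows with missing covariates are *kept* in the pooled table with
a flag and excluded only downstream, from continuous curves.

Per cross-validation fold, SHAP values are computed on the test fold only,
$\phi_0$ is recorded per fold, and pooling concatenates raw values without
reconciling the per-fold $\phi_0$'s — the pooled table keeps the fold id so
either convention can be reconstructed.

## Curves and functional forms

The LOESS variant is deliberately the simplest: at each of 100 grid points
spanning the observed range (no extrapolation), the $\lceil \text{span}
\cdot n\rceil$ nearest neighbours are fit by weighted least squares of
degree 0 or 1 with tricube weights $(1-(d/d_{max})^3)^3$; zero-distance
duplicates get full weight; a locally degenerate design falls back to
degree 0. Default span 0.75, degree 1. No robustness iterations: the smooth
is an *aid to the eye* over the raw pooled points, and a heavier smoother
would invite over-reading — exports therefore always carry the raw pairs.

Parametric fits target the raw pooled pairs by default (the grid is an
option): the power law $a\,(w/w_{ref})^b + c$ is fit by profiling — for
fixed $b$ the problem is linear in $(a, c)$, so a grid over $b$ (including
the classic starts 0.25, 0.75, 1, 1.5) is refined by a one-dimensional
optimiser to $10^{-9}$ — and the threshold form by exhaustive scan of
two-segment constant fits over candidate breakpoints (default: midpoints of
consecutive distinct covariate values). Categorical covariates get per-level
mean/SD/count summaries with the dedicated `missing` level kept visible.

## The synthetic study generator

The generator emulates the *structure* of a peri-operative hemophilia-A
dataset: 119 patients undergoing 197 procedures in five centers, 13
covariates with realistic marginals and missingness injected completely at
random at the study's fractions (BMI 10.7%, blood group 13.2%, concentrate
1.5%, VWF:Ag 40.1%, VWF:Act 50.3%). Because the printed population spans
0.24-77.7 years and 5-111 kg, age is an explicit child/adult mixture (25%
paediatric by default, uniform over 0.24-16 y; adults truncated normal
around 45 y) and weight and BMI follow growth-curve medians with log-normal
noise; a Gaussian copula with a configurable correlation matrix adds
correlation beyond what the growth curves induce. Blood group, severity and
center are patient-level; the remaining covariates re-draw per occasion by
default (a per-patient switch exists). VWF levels are generated lower for
blood group O — a realistic confounder that the truth model deliberately
does *not* read, so any VWF signal found downstream is honest leakage
through correlation, as in real data.

The ground-truth covariate model multiplies typical values by
$(W/70)^{0.75}$ on CL and $(W/70)^{1}$ on V1, an age slope
$(\max(\text{age},12)/40)^{-0.2}$ on CL (capped below 12 years to keep the
model continuous), a blood-group-O factor 1.2 on CL, concentrate factors
1.1/1.15, and a BMI>25 factor 0.8 on V1 — shapes chosen so that allometry,
a category shift and a threshold are all present and recoverable. Residual
(unexplained) variability defaults to $\omega_{CL} = 0.25$,
$\omega_{V1} = 0.42$: the base-model %CVs of the emulated study are *total*
IIV, so the generator splits them between covariate effects and residual
$\eta$; the split was calibrated by measuring the generator's realised
covariate variance on a large draw and matching the covariate-explained
fraction to the explained-variance levels the emulated study reports for
its ML fits. Observations follow $y = f(1+\varepsilon_2) + \varepsilon_1$
(the dominant combined-error convention), truncated at zero.

Dosing mirrors guideline practice: a loading bolus sized to the 0-24 h peak
target given the individual's V1, then either maintenance boluses computed
against the declining target windows (0.9 / 0.65 / 0.4 IU/ml) or, for 30%
of occasions, a continuous infusion at the maintenance target times the
individual clearance; 16 samples per occasion, denser in the first 24 h
(the emulated study averages 17). What the generator does *not* emulate:
assay discrepancies (one-stage vs chromogenic), informative missingness,
inter-occasion variability as a formal random effect, real surgical
case-mix, or measurement-time irregularity. Passing recovery tests on this
generator therefore shows the *pipeline* can read shapes out of data of
this geometry — it does not certify behaviour under informative
missingness or model misspecification.

## Pipeline choices

* **Targets.** EBE CL and V1 per occasion on the natural scale (ml/h, ml),
  fitted independently.
* **Cross-validation.** Ten folds, grouped by patient (round-robin after a
  seeded shuffle): 197 procedures from 119 patients would otherwise leak
  within-patient information between train and test.
* **Imputation.** Continuous missing values get the *training-fold* mean
  (applied to train and test), categorical missing cells a dedicated
  category; `fold_aware_imputation = FALSE` reproduces dataset-level
  imputation for faithful replication of the classic workflow, and the
  native-missing variant leaves the table untouched for the booster.
* **Concentration metrics.** The two-compartment model is re-solved per
  occasion with the ML-predicted CL/V1 and fixed Q/V2; RMSE is computed per
  patient first, then summarised across patients.
* **Determinism.** A master seed derives every stage seed; rerunning a
  configuration is bit-identical, including pooled SHAP tables.

## Validation sizes

The shipped validation uses problem sizes chosen to make the checks sharp
yet quick: Shapley axioms on 50 random ensembles of up to 200 rows and 13
features; 1000 random trees against the brute-force expectation oracle;
empirical Bayes recovery on 200 subjects with 12 samples each (correlation
with simulated $\eta$ above 0.9 for both parameters, and agreement within
0.02 with a 201x201 grid search in the near-noiseless limit); functional
form recovery and a covariate-free null control on 500-subject studies.
On the null control, the largest per-covariate mean |SHAP| stays below 10%
of the target SD — at much smaller sizes a fully grown forest memorises
noise and that margin narrows, which is itself informative about how much
data the method needs.

## Known limitations

* Path-dependent SHAP shares credit among correlated covariates in
  proportion to how trees use them; with strong age-weight-BMI correlation
  the weight curve's tails attenuate (the forest cannot extrapolate), so
  the recovered allometric exponent is unbiased but noticeably variable
  across study realisations at 500 subjects. The combined-SHAP tool
  (`combine_shap()`) exists precisely to read joint effects where
  single-covariate curves mislead.
* The threshold scan can lock onto a confounded child/adult boundary
  instead of a planted BMI step on unlucky draws, for the same reason.
* The natural-scale targets make the additive decomposition heteroscedastic
  for log-normal parameters; log-scale targeting is available via the EBE
  table if preferred.
* The exact explainer is capped at 16 features; no sampling fallback is
  provided.
* The M-step of classic population estimation (FOCE/SAEM) is out of scope:
  population parameters are trusted inputs.
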
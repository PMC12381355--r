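---
title: "Models and methods in swimmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in swimmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimmetab)
```

`swimmetab` analyses paired pre/post plasma metabolite profiles collected
after swimming trials in the moderate, heavy and severe exercise-intensity
domains, together with the 12 × 25 m critical-speed test that defines those
domains. This vignette documents the models, their assumptions, the
parameters that matter, and the choices made where the design was open.

## The data model

Every stage consumes an `AbundanceDataset`: a strictly-positive sample ×
feature matrix (missing cells allowed before imputation), per-sample
metadata (participant, sex, trial, timepoint, study/QC flag, injection
order), and per-feature annotation assigning each feature to one of three
platform strata — LC–MS lipids, NMR small molecules, NMR lipoprotein
subfractions. The strata matter because analytical-precision filters are
platform-specific.

## QC filtering

Pooled-QC injections estimate analytical precision. Three filters apply,
all with *strict* inequalities so boundary cases are retained:

* **RSD filter** (LC–MS only): percent RSD = 100·sd/mean over QC
  injections; removed when RSD > 30 %. Features whose QC RSD is undefined
  (fewer than two QC values, or zero mean) cannot demonstrate precision and
  are removed with the same reason code.
* **Intensity filter** (LC–MS only): removed when intensity < 5000 in more
  than 50 % of QC injections; a missing QC value counts as below the floor.
* **Missingness filter** (all platforms): removed when more than 70 % of
  *study* samples are missing. QCs are excluded from this fraction — they
  inform precision, not biology. The rule is global, not per-trial: with
  paired designs a feature absent in one whole trial still fails nothing
  biologically, and a global 70 % rule is the common reading.

Filters are evaluated on the input dataset and the union of violations
removed, so filtering is idempotent and the report satisfies
`n_input = n_retained + |removed union|`.

## Imputation

Remaining gaps are filled by an iterative random-forest scheme: initialize
missing entries with feature means, sweep features in increasing-missingness
order, regress each incomplete feature on all the others in its platform
stratum with a random-forest (ranger, 100 trees, fixed seeds per
feature/iteration so runs are reproducible), and repeat until the
normalized change in the imputed values increases, returning the previous
sweep (the classic stopping rule), or 10 sweeps. Imputation runs on
natural-log abundances and is exponentiated back — a multiplicative error
model is the natural one for intensity data — and observed cells are never
altered, bitwise. QC rows are excluded from training and never imputed.

## Fold changes and scaling

Per participant × trial, `log2(post/pre)` per feature. Pairs missing either
timepoint are dropped and named. Auto-scaling centers each column and
divides by its **population** SD (divisor n). The convention matters only
in the third decimal of R²X; it is fixed and documented because downstream
statistics shift slightly with it. Scaling parameters are always stored so
held-out or projected data are scaled with *training* parameters, never
their own; zero-variance columns are centered, set to zero, and flagged.

## OPLS-DA

The two-class discriminant model is NIPALS PLS1 with orthogonal-signal
correction, written in-package:

1. Code classes 0/1 and center. Set `w ∝ X'y`, normalized.
2. For each orthogonal component: `t = Xw`, `p = X't/t't`,
   `w_o ∝ p − (w'p)w` normalized, `t_o = X w_o`, `p_o = X't_o/t_o't_o`,
   deflate `X ← X − t_o p_o'`.
3. Final predictive component from the filtered matrix:
   `t = Xw`, `c = y't/t't`, predictions `ŷ = t c`.

With zero orthogonal components this is exactly single-component PLS1, and
the test suite holds it to an independently coded PLS1 oracle at 1e−8.
Orthogonal scores are exactly uncorrelated with the predictive scores by
construction. NIPALS leaves the sign of each weight vector undetermined;
each is flipped so its largest-magnitude element is positive, which makes
repeated fits bit-identical.

Statistics: `R²Y = 1 − SS_res(y)/SS_tot(y)`;
`R²X(cum) = Σ_components ‖t p'‖²_F / ‖X‖²_F`;
`RMSEE = sqrt(SS_res(y)/(n − 1 − n_components))`;
`VIP_j = sqrt(p · w_j²/‖w‖²)` for the single predictive component, so
`Σ VIP² = n_features` always.

**Cross-validation** is stratified 8-fold: folds are dealt round-robin
within each class after a seeded shuffle (fold sizes differ by at most one
per class), scaling is recomputed inside each training fold, and
`Q² = 1 − PRESS/SS_tot(y)`. **Permutation testing** shuffles the class
labels 50 times, re-runs the full fit + CV pipeline, and reports
`p = (1 + #{perm ≥ observed})/n_perm`. The add-one rule gives the floor
1/50 = 0.02 at the default 50 permutations — the smallest p the test can
report, and the value expected when no permutation approaches the observed
statistic.

The number of orthogonal components defaults to 1; an optional
auto-selection adds components while CV Q² improves by more than 0.01
(cap 5). R²Y is non-decreasing in the component count on training data;
Q² is not, which is exactly how overfitting shows up.

**Three-class handling.** The heavy trial is never part of the fit: the
model is trained moderate-vs-severe on fold changes, and heavy-trial rows
are projected through the stored scaling and orthogonal filters
(`t_o = X w_o`, `X ← X − t_o p_o'`, then `t = Xw`) with no refit. On
intermediate physiology the projected scores land between the two training
class means.

## Effect sizes and the eruption table

Cliff's delta `δ = (#{x>y} − #{x<y})/(n_x n_y)` is computed from sorted
positions in O((n+m) log m); the O(nm) enumeration is kept in the test
suite as an oracle, including an exhaustive sweep over all short vectors.
Per-feature p-values default to Welch's t-test between the two trial groups
(a Wilcoxon option exists): the choice of univariate test feeding the
significance colouring was open, and Welch is the least-assumption
parametric default on fold changes; mixed-model contrast p-values are
available separately and can be merged by the user. BH adjustment is
applied across features. Key features satisfy VIP > 3.0 and p < 0.05. Note
that VIP > 3 demands that a feature carry more than 9/p of the total
squared weight — with small panels (p < 10) it is unattainable by
construction, and with hundreds of features only a handful of dominant
responders can clear it.

## Mixed models

Per metabolite, REML fit of `value ~ time * trial + sex` with a participant
random intercept (nlme), treatment coding with references pre / moderate /
female. The heteroscedastic form adds per-trial residual variances
(`varIdent`); both forms are fit and the lower AIC wins, so heterogeneous
variance is kept only where it improves the fit. Degenerate inputs
(zero residual variance) fall back to OLS, which interpolates the balanced
fixed-effect surface exactly.

Contrasts are interaction contrasts — differences in the pre→post change
between trial pairs (moderate−heavy, moderate−severe, heavy−severe) — with
Wald z inference. Wald rather than Satterthwaite/Kenward–Roger degrees of
freedom is a deliberate simplification: at 14–16 participants and balanced
designs the difference is small, and the convention is stated rather than
hidden. BH correction is applied within the three-contrast family per
metabolite; across-metabolite FDR is the eruption table's job. Confidence
intervals come from a nonparametric cluster bootstrap: participants are
resampled with replacement (keeping their full observation sets, duplicates
becoming new clusters), the model is refit per replicate with the full-data
model form, and percentile 2.5/97.5 bounds are reported. Bootstrap CIs and
model SEs are reported separately — a percentile CI is not a standard
error, and conflating them would lose the asymmetry the bootstrap exists to
capture.

An equivalent entry point fits the log₂ fold-change table directly
(`log2FC ~ trial + sex` + random intercept); on balanced data the two give
identical contrast estimates, and the test suite proves it. A sex × trial
interaction is available behind a flag but off by default: the sex-modulated
FFA response is simulated, but the default model matches the main analysis,
which controls for sex without interacting it.

## Critical speed and D′

From 12 lap times: peak speed = speed of effort 1; CS = mean speed of the
slowest two of the final four efforts (ties resolved by a descending sort —
tie-invariant since only values enter); drop-off % = 100(peak − CS)/peak.
The speed–time model `S(t) = a e^{bt} + c` is fit by Levenberg–Marquardt
against lap speeds at cumulative swim-time midpoints. Rests are excluded
from the time axis by default — the model describes swimming speed decay,
not elapsed wall time — with an `include_rest` flag for sensitivity
analysis. Initialization `a = S₁ − S₁₂`, `b = −1/t₁`, `c = S₁₂`;
convergence at relative SSE change < 1e−10 or 500 iterations.
Constant-speed data leave `b` unidentifiable and return the flagged plateau
fit `a = 0, c = mean speed`.

D′ is implemented as the area between the fitted curve and the CS line over
the test, `∫₀^{t₁} max(S(t) − CS, 0) dt`, in closed form
(`(a/b)(e^{bt_u} − 1) + (c − CS)t_u` with `t_u` at the CS crossing or `t₁`).
The printed form of the source equation for D′ is not recoverable
unambiguously, so this area definition is an interpretation; a model-free
discrete variant (`Σ max(S_lap − CS, 0)·lap_time`) is provided as a
cross-check, and the closed form is held to numerical quadrature at 1e−6
relative in the tests.

## The synthetic cohort generator

The generator emulates the study conditions: 16 participants (9 male,
7 female), paired pre/post samples in the three trials, ~1000 features in
classes (100 free fatty acids, 23 glycolytic small molecules, 112
lipoprotein parameters, 765 inert lipids), participant random intercepts
(SD 0.3, log scale), trial-specific planted log₂ fold-change effects, and
pooled-QC injections at 10 % RSD. Default effects mirror the study
phenotype: FFAs up ~1 log₂ unit after the moderate trial and flat after
severe; glycolytic metabolites up ~1.5 log₂ units more after severe than
moderate; small lipoprotein shifts; inert features null. The severe-trial
FFA response carries a +0.5 additive shift for males, matching the
qualitative sex modulation, applied only to (FFA, severe) cells.

Natural-log abundances are `baseline + participant intercept +
effect·ln 2·[post] + trial noise`, exponentiated — so abundances are
strictly positive and the expected log₂(post/pre) equals the planted effect
exactly. Residual SDs default to (0.30, 0.30, 0.50) for
moderate/heavy/severe: the study models trial heteroscedasticity but does
not quantify it, so the variance ratio is a free, documented parameter with
the severe trial noisiest (the physiologically expected direction).
Baseline log-mean 10 puts typical intensities near 22 000, above the LC–MS
floor, with log-SD 1 giving a realistic dynamic range. Missingness defaults
to 5 % MCAR; a low-intensity mechanism that preferentially blanks
low-abundance cells is available for censoring studies.

What the generator does **not** emulate: correlated feature blocks
(features are independent given the participant intercept), platform batch
or injection-order drift (QCs are i.i.d. around the pooled mean — they are
used only for RSD here), non-Gaussian tails, or lap-by-lap swim physiology.
Passing tests therefore demonstrate correctness of the statistical
machinery under the assumed generative model, not robustness to correlated
or drifting real-world data.

## Problem sizes and numerical choices

The test suite runs the study-scale settings where the statistic demands it
(50 permutations, 8-fold CV, 16 participants; 200 replicate datasets for
mixed-model recovery; 100 replicates for variance-structure detection) and
smaller feature panels (tens to ~100 features) elsewhere, which keeps the
full suite under two minutes without changing any threshold. Determinism is
end-to-end: every stage's seed is derived from the single run seed and the
stage name, so inserting a stage never perturbs another stage's stream, and
identical configs produce identical output checksums.

Known limitations: a single predictive component only (two-class
discrimination; no O2PLS or kernel variants); no Pareto/range scaling; no
random slopes or crossed random effects; Wald inference throughout the
mixed models; the eruption p-value is univariate by default.
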
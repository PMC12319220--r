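---
title: "Dynamic landmark prediction of gastric cancer recurrence: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic landmark prediction of gastric cancer recurrence: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gclandmark)
```

## The prediction problem

After curative gastrectomy for stage II–III gastric cancer, patients are
followed on a fixed schedule (labs at surgery and 3, 6, 9, 12 months; imaging
at intervals) and roughly a quarter experience recurrence or death within
three years. Conventional risk models use only information available at
surgery, so a patient whose condition deteriorates during the first
postoperative year is scored exactly as on the day of surgery. This package
implements and compares three Cox proportional-hazards prediction strategies
for recurrence-free survival (RFS, time from surgery to first recurrence or
death, administratively censored at 36 months):

* **Baseline model** — covariates available at surgery only: lymphovascular
  invasion (LVI), pathological T and N stage (with sparse levels merged:
  N3a/N3b → N3, T1/T2 → "T1&2", esophagogastric junction → upper stomach),
  and the baseline value of one inflammatory biomarker.
* **Landmarking 1.0** — a landmark analysis at $s$ = 12 months: only patients
  still event-free and in follow-up at $s$ enter; the outcome clock restarts
  at $s$ and runs to the horizon (36 months). The observed change in the
  biomarker from baseline to the last measurement at or before $s$, and
  adjuvant S-1 duration (< 6 vs ≥ 6 months), join the baseline covariates.
* **Landmarking 1.5** — identical to landmarking 1.0 except that the
  biomarker value at $s$ is replaced by its Best Linear Unbiased Prediction
  (BLUP) from a linear mixed model fitted to all measurements up to $s$,
  so the predictor becomes the *predicted* change $\hat y_i(s) - y_i(0)$.

The biomarker is not fixed a priori: fifteen composite inflammatory indices
are built from six routine serum markers (neutrophils, monocytes, platelets,
CRP; lymphocytes, albumin). Same-category pairs are multiplied, mixed pairs
divided, and the prognostic nutritional index (PNI) uses its own formula.
Because assay floors produce CRP values of exactly zero, no index has CRP in
its denominator. An AIC scan over the catalog (below) picks the working
biomarker.

## The longitudinal model behind landmarking 1.5

For a biomarker value $y_{ij}$ of patient $i$ at month $t_{ij} \le s$,

$$y_{ij} = (\alpha_0 + b_{0i}) + (\alpha_1 + b_{1i})\,t_{ij} + \varepsilon_{ij},
\qquad b_i \sim N(0, G), \quad \varepsilon_{ij} \sim N(0, \sigma^2),$$

with $G$ an unstructured $2\times 2$ covariance. Variance components are
estimated by maximum likelihood (`lme4::lmer`, `REML = FALSE`); ML composes
cleanly with the bootstrap that refits the model on every resample, and at
cohort sizes near 200 the ML/REML difference in BLUPs is negligible. The
random effects are then evaluated with the package's own closed form

$$\hat b_i = \hat G Z_i^\top V_i^{-1}\,(y_i - X_i\hat\alpha), \qquad
V_i = Z_i \hat G Z_i^\top + \hat\sigma^2 I,$$

which tests verify against `lme4::ranef` and a hand-coded
generalized-least-squares computation. Five scheduled visits cannot support
more than a linear trend with random intercept and slope, which is why no
richer trajectory shape is offered. When a variance component is estimated at
the boundary the fit is flagged and the BLUPs shrink toward the population
line — the correct degenerate behaviour, not an error.

Two choices here were genuinely open:

* **Change, not level.** Landmarking 1.5 feeds the Cox model
  $\hat y_i(s) - y_i(0)$ rather than $\hat y_i(s)$, so the 1.0 and 1.5
  models differ only in *how* the landmark value is obtained. Both models
  then carry the same pair of biomarker terms (baseline value + change),
  which is also what makes their AICs comparable in the scan.
  `lm15_predicted(type = "level")` exposes the alternative.
* **Observed values only.** The mixed model is fitted to measurements that
  were actually taken. Last-observation-carried-forward (LOCF) rows are never
  fed to it: carried-forward values would flatten every individual slope and
  bias $\hat G$ downward. LOCF serves only the landmarking 1.0 change
  predictor and requires an observed baseline — patients without a
  surgery-time measurement are excluded upstream rather than silently
  imputed.

## Variable selection

LVI, pT, pN (and, in landmark models, S-1 duration) are always kept. For each
cataloged biomarker in turn, AIC-based backward elimination runs over the
optional terms (age, sex, histology, surgery type, complications, the
age×S-1 interaction, and the biomarker's baseline and change terms): at each
step the removal that most lowers the AIC is taken, interactions leave before
their main effects, and elimination stops when nothing improves. The
biomarker whose final model has the smallest AIC wins, and its selected term
set defines all three models (the baseline model drops the post-surgery
terms: S-1, the interaction, and the change). Elimination refits the model
exactly at every candidate removal rather than using a single-fit
approximation; the candidate fits are evaluated through the partial
likelihood on column subsets of one design matrix, which is numerically
identical to refitting and roughly ten times faster — the final model is
always refit through the full interface.

Ties are handled with the Efron approximation (Breslow available). One
deliberate deviation from a strict error-on-separation policy: when a rare
covariate level (for example pT T4b at ~3% prevalence) carries no events, the
partial likelihood is monotone and the coefficient diverges. `fit_cox()`
warns by default (`on_separation = "error"` restores the strict behaviour)
because with the realistic covariate frequencies roughly half of simulated
187-patient cohorts produce this situation in at least one mandatory term,
and the standard survival software this workflow mirrors also warns and
continues — the affected level's risk saturates, which is exactly what the
data say.

## Model comparison

All comparisons run on the landmark cohort, the only population on which all
three models are defined. Risk is the absolute event probability
$1 - \exp(-\hat H_0(t)\,e^{x^\top\hat\beta})$ with $\hat H_0$ the Breslow
baseline cumulative hazard on the uncentered covariate scale.

* **Concordance** counts patient pairs whose ordering is determinable under
  censoring (the shorter follow-up ends in an event; tied times are
  unusable); score ties contribute 1/2.
* **Risk-tertile Kaplan–Meier curves** split patients at the empirical
  tertiles of predicted RFS ("high risk" = lowest predicted RFS) with a
  log-rank test across the three groups.
* **Calibration** compares mean predicted risk per quintile (or decile) with
  the Kaplan–Meier complement at the horizon — under censoring the raw event
  fraction is not estimable, the KM complement is.
* **Categorical NRI** between the baseline and landmarking 1.5 risks uses
  fixed cut points (defaults 11.6%, 16.7%, 36.0% on the event-risk scale,
  matching the published reclassification table this package ships as a
  fixture); its variance is the standard two-stratum asymptotic formula with
  a Wald interval. Patients censored before the horizon count as nonevents
  in the table — the published marginal totals (27 events + 136 nonevents =
  the full landmark cohort) force that convention.
* **Internal validation** draws patient-level bootstrap resamples and
  replicates the *entire* development on each: biomarker scan, backward
  elimination, mixed-model refit, Cox fits. Optimism is the mean difference
  between each replicate model's concordance on its own resample and on the
  original data; corrected C = apparent − optimism. The same resamples yield
  a percentile CI for the concordance difference between landmarking 1.5 and
  the baseline model. Replicates that fail (for instance a resample missing
  a rare covariate level entirely) are dropped and counted, with a fatal
  threshold at 10%; when a fitted replicate must score an original patient
  whose level it never saw, that patient is scored at the reference level —
  level definitions are taken as given rather than re-derived per resample,
  a known limitation of bootstrapping categorical predictors at this sample
  size.

## What the synthetic cohorts emulate — and what they do not

No patient-level data from the motivating study were ever deposited, so the
generator is a first-class module, not a test fixture. It reproduces the
study's *structure*: ~187 patients; categorical baseline covariates drawn at
the published marginal frequencies; labs at 0/3/6/9/12 months; six raw-marker
trajectories from the same linear mixed model the analysis assumes; an event
process that is *exactly* proportional hazards, with the linear predictor
combining covariate effects and the true (noise-free) marker change since
baseline, updated piecewise at visit times and sampled by inverse-CDF within
each piece — so Cox parameter recovery is a valid test, not an approximation.
Censoring is exponential (rate 0.005/month) plus administrative at 36 months,
independent of everything; visit missingness is completely at random (10% per
post-baseline visit by default, month 0 never missing), the only mechanism
under which LOCF is even defensible. The default hazard
(`default_hazard_params()`) puts weight on nodal stage, tumour depth, LVI and
shortened adjuvant therapy, plus declines in albumin and lymphocytes — the
PNI components — and its baseline rate (0.001/month) was calibrated once so
that about 25% of patients have an event within 36 months, matching the
derivation cohort's event rate; it was not revisited afterwards. Counts and
albumin are floored at 2% of their population intercept (assay detection
limits); CRP may be exactly 0, which is what makes the no-CRP-denominator
rule in the catalog observable.

Deliberately not emulated: informative dropout or recurrence-driven visit
schedules, inter-marker correlation (an optional shared-subject factor was
considered and dropped — the motivating study reports no inter-marker
covariance to target), multi-state structure (recurrence vs death), and any
association between S-1 duration and the biomarker trajectory (S-1 is drawn
as a baseline category with an optional hazard effect only; how adjuvant
duration shapes the trajectory biologically is unknown). Passing tests
therefore demonstrate that the *pipeline* recovers what it assumes — they say
nothing about LOCF's behaviour under informative missingness or about
real-world trajectory shapes.

## Numerical and convention notes

* **PNI as printed.** The shipped formula is `albumin + 0.005 × lymphocytes`,
  exactly as in the source table, although the conventional index multiplies
  albumin by 10; `pni_convention = "standard"` switches. The two are affinely
  related, so Cox fits and AIC ranks are unaffected — only the printed values
  change.
* **Tertile cut points** are reported to 3 decimals on the RFS-probability
  scale; with fewer than three distinct predictions the grouping degenerates
  to a single group with a warning.
* **Quantile groups** for calibration use rank-based assignment, so group
  sizes differ by at most one.
* **Bootstrap streams.** Resample indices are drawn up front from the seed,
  so the first $B_1$ replicates of a longer run coincide with a shorter
  run's — comparisons at different $B$ are nested, and everything is
  reproducible from a single integer seed.
* **Problem sizes.** The shipped tests exercise parameter recovery at
  n = 2000 over 50 replicates, selection consistency at n = 1000 over 20
  replicates, the out-of-sample landmarking benefit over 10 independent
  train/test pairs of 400 patients, and the bootstrap at B = 50–200; these
  scales give the Monte-Carlo checks comfortable margins while keeping a
  full run of suite plus study on one core in a few minutes.

## Interface note

The pipeline is exposed as R functions — `run_study()` orchestrates
simulate/load → biomarkers → landmark → scan → fit → compare and writes
`biomarkers.csv`, `landmark.csv`, `models.json`, `report.json` and a
reproducibility manifest when given an output directory;
`verify_reference_reclassification()` is the packaged self-test. A shell
wrapper would add nothing for the intended users, who work in R; the
repository's `scripts/acceptance.R` shows the end-to-end invocation.

## Known limitations

Landmarking discards pre-landmark events by design, so the landmark cohort
is smaller than the full cohort and effect estimates apply to 1-year
survivors only. LOCF is a crude imputation whose bias under anything but
MCAR is uncharacterized here. The NRI cut points are taken as external
constants; nothing in the package derives them from data. And with ~30
events in a 157-patient landmark cohort, all comparative metrics carry wide
Monte-Carlo and sampling bands — the bootstrap CI for the concordance
difference routinely straddles zero at this scale, as the printed study
results themselves illustrate.
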
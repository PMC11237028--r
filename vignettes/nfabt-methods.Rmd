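---
title: "Fuzzy basis-function alarming for transfusion need: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy basis-function alarming for transfusion need: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Blood-cancer patients frequently need packed-red-blood-cell (PRBC)
transfusions: both the disease and chemotherapy suppress blood-cell
production. Deciding *when* a transfusion is needed is usually left to
clinician judgement over haemoglobin thresholds. `nfabt` implements a small,
interpretable decision core for this task — a fuzzy basis-function (FBF)
system over haemoglobin (Hgb, g/dL), arterial oxygen pressure (PaO2, mmHg)
and blood pH — together with everything needed to study it end to end
without access to patient data: a calibrated synthetic cohort generator, the
preprocessing pipeline such data requires, a measurement-noise robustness
harness, and a cross-validated sequence-classifier benchmark.

## The fuzzy inference core

### Model

Each input variable is partitioned into triangular membership functions
(MFs). A rule $R_i$ has the form

$$R_i:\ \text{IF } z_1 \text{ is } A^i_1 \text{ and } \dots \text{ and }
z_m \text{ is } A^i_m \text{ THEN } k \text{ is } B^i,$$

and the system output is the FBF expansion

$$f(z) = \sum_{i=1}^{R} d_i(z)\,\theta_i, \qquad
d_i(z) = \prod_{j=1}^{m} \mu_{A^i_j}(z_j),$$

where $\theta_i$ is the center of the consequent MF $B^i$. With triangular
partitions this expansion is equivalent to the classic singleton-fuzzifier /
product-inference / centroid-defuzzifier system. `fbf()` fits the model;
`predict()` evaluates $f(z)$; `alarm()` turns a state value into a Low/Normal
decision.

### Partitions and their parameters

The shipped configuration (`default_partitions()`, also in
`inst/extdata/partitions.yaml`):

| variable | universe        | MF centers                  | labels |
|----------|-----------------|-----------------------------|--------|
| hgb      | [7, 16.6] g/dL  | 8, 10.25, 14.1, 16.6        | Very Low, Low, Normal, High |
| pao2     | [40, 80] mmHg   | 30, 47.5, 65.75, 90         | Normal, Mild/Moderate/Severe Hypoxemia |
| ph       | [6.3, 7.8]      | 7.35, 7.40, 7.45            | Acidosis, Normal, Alkalosis |
| state    | [0, 1]          | 0.25, 0.75                  | Low, Normal |

Interior MFs put their feet at the neighbouring centers, which makes the
partition *normal* (every peak reaches 1), *consistent*, and gives the
partition-of-unity property $\sum_k \mu_k(z) = 1$ between the extreme
centers. The extreme MFs are shoulders that stay at degree 1 beyond their
center, so the partition is *complete* over the whole universe even where
centers lie outside it (the PaO2 centers 30 and 90 fall outside the stated
[40, 80] universe; the shoulders extend the effective coverage to the
centers, because the centers are the operative quantities in the expansion).
The pH partition deliberately concentrates its three centers in the
clinically decisive 7.35–7.45 band; the Acidosis/Alkalosis shoulders cover
the rest of [6.3, 7.8].

Two notes on labels. First, the PaO2 severity labels are attached to the
centers in the order listed above — i.e. the label "Severe Hypoxemia" sits on
the *highest* center. This mirrors the source configuration this package
ships as its default; clinically one would read the severity labels in the
reverse center order. The labels are names only: nothing in the arithmetic
depends on them, and `fuzzy_partition()` accepts any relabelling. Second,
with the default two-input system (hgb + pao2, four MFs each) the candidate
rule space is $4^2 \times 2 = 32$ rules; with all three inputs it is
$4 \cdot 4 \cdot 3 \cdot 2 = 96$. The two-input pairs are the shipped
configurations; the three-input system is supported but not the default.

### Rule learning

"Adaptive rule generation" is realised as Wang–Mendel table lookup, the
canonical data-driven method compatible with FBF expansions: each training
pair $(z, k)$ selects the max-membership MF for every input and for the
output; the rule degree is the product of those memberships; within one
antecedent cell only the highest-degree rule survives. Tie-breaks are fully
deterministic: equal memberships pick the lower MF index, equal degrees pick
the lower consequent index, then the earlier sample. Inputs outside the
covered range are clipped with a warning (on the default synthetic cohort
this is routine for PaO2, whose generator mean 34.54 mmHg sits below the
fuzzy universe — the shoulder MFs simply saturate there; the discrepancy
between the two published PaO2 descriptions is preserved rather than
resolved).

A learned base only covers cells seen in training. `complete_rule_base()`
(or `fbf(..., complete = TRUE)`) fills uncovered cells with the consequent
of the nearest covered cell in MF-index space (ties toward the lower
consequent), so normalized inference is defined everywhere.

### Normalization

The expansion is printed unnormalized; the package's default is the
normalized form $\sum_i d_i \theta_i / \sum_i d_i$ because it is well
defined for incomplete learned rule bases and bounded by the extreme output
centers [0.25, 0.75]. Under a complete grid rule base the two coincide
exactly (partition of unity), and the suite verifies both this equivalence
and agreement with an explicit brute-force weighted-centroid loop to 1e-9.
`normalize = FALSE` preserves the literal sum.

### Swarm evaluation and alarming

The expansion is a plain sum, so it distributes over any partition of the
rules: `swarm_infer()` assigns rules to agents (round robin by default, or
any user map), each agent reports partial sums $(\sum d_i\theta_i, \sum
d_i)$, and aggregation reproduces centralized inference to machine
precision. `alarm()` raises a transfusion alarm iff $f(z) < 0.5$ (the
midpoint of the output centers, configurable); the boundary value maps to
Normal, documented here as the tie-break. The alarm message is a structured
record (value, label, timestamp, input snapshot) emitted as JSON-lines by
the command-line wrapper — a gateway payload stub; no transport protocol is
modelled.

## The synthetic cohort generator

No public dataset exists for this problem, so the generator emulates the
published cohort summaries: 98 patients, 61 features (16 demographic, 4
clinical, 33 laboratory, plus 8 variables generated with >90% missingness so
the exclusion step has something to exclude). Demographic category counts
(55/43 male/female, cancer types 22/27/33/16, and all history flags) are
reproduced exactly by quota sampling at n = 98 and proportionally otherwise.
Continuous features are truncated Gaussians with the published mean/SD.

Choices where the sources are silent, fixed once:

* **Marginals only.** Only marginal summaries are published, so features are
  independent except haematocrit, which is coupled to haemoglobin with
  correlation 0.9 through a marginal-preserving linear form (a naive
  `Hct = c * Hgb + noise` cannot reproduce the published Hct SD, since
  `c * sd(Hgb)` alone exceeds it).
* **Truncation.** Bounds are mean ± 4 SD, clipped to a physiologic hard
  limit only when that limit is at least 3 generator SDs from the mean.
  Consequence: strongly right-skewed analytes published as mean/SD pairs
  (troponin T at 0.031 ± 0.171 ng/mL, CK, LDH) admit small negative values,
  and SpO2 can marginally exceed 100% — symmetric truncation at a close
  hard limit would visibly bias the recovered moments, and moment fidelity
  is what downstream calibration checks rely on.
* **Trajectories.** Daily dynamics are unspecified; each time-varying
  feature follows a stationary AR(1) centred on the patient's baseline with
  the feature's SD as marginal SD and default autocorrelation 0.7 (vitals
  and labs are strongly day-to-day correlated; 0 gives i.i.d. days). Day 0
  equals the baseline draw. Default horizon: 7 days.
* **Labels.** The daily PRBC label follows a logistic ground-truth model in
  the distinguishable variables — standardized Hgb and PaO2 (negative
  weights −1.2, −0.6), acidosis distance `max(0, 7.40 − pH)/0.06` (+0.8),
  standardized SBP and platelets (−0.3 each) — with intercept −4.84,
  calibrated once numerically so the default schema yields ≈7% daily
  prevalence (the published training prevalence; the 43/55 transfusion
  history counts are a static feature, not this outcome). A deterministic
  threshold mode (score > 0) supports exact tests, and a "trend" mode
  (label = haemoglobin fell since yesterday) provides a purely sequential
  signal for the benchmark.
* **Missingness.** Cells are masked independently at each feature's schema
  rate (`NA`, never a sentinel). Besides the eight >90% features, LVEF,
  ferritin and troponin T sit in the 55–60% band to exercise the indicator
  step, and the blood-gas panel at 5%.

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: between-feature covariance beyond the Hct–Hgb pair,
informative (outcome-dependent) missingness, treatment feedback (a
transfusion raising the next day's Hgb), admission/discharge processes, or
chemotherapy cycles. Results on this cohort validate the machinery, not
clinical performance.

## Preprocessing

The pipeline applies, in a fixed order: exclusion of features with >90%
observed missingness (strict inequality, per-feature over all cells) →
missingness indicators (`<name>_present`, 0 = missing / 1 = present, for
features >50% missing) → median imputation of every remaining missing
continuous cell (observed cells are never altered) → categorical encoding
(male 1 / female 2; ALL/AML/CLL/CML as 1–4; all history flags 1 = having /
applying; age bands ordinal 1–6; troponin T binarized at the conventional
assay positivity cutoff 0.014 ng/mL, configurable) → first-timepoint
anchoring → normalization. The pipeline is idempotent, and each step is
exported for standalone use.

Two open interpretations were settled as follows. "Fix the first timepoint
at the first recording" is read as *left-alignment*: heart rate, SBP and DBP
series are shifted so day 0 holds the first non-missing recording (tails are
NA-padded to keep the panel rectangular); baseline subtraction is the
plausible alternative and deliberately not implemented. "Normalize" is read
as z-scoring (the 61 features mix units spanning four orders of magnitude);
min–max is available by option. Normalization statistics are computed on the
fitted cohort and reusable on held-out splits. Pearson correlation screening
(`correlation_matrix()`) works per feature group on patient-level baseline
values, matching its diagnostic purpose of confirming inputs are relatively
uncorrelated.

## Robustness evaluation

`scenario_eval()` mirrors a measurement-noise study: for each input pair
(hgb+pao2, hgb+ph, pao2+ph), per run, patients are split 70/30, an FBF model
is learned on training days (completed rule base), and held-out days are
scored clean and under additive white Gaussian noise at 30, 10 and 5 dB SNR,
averaged over 10 runs by default. Noise variance is `Var(signal) /
10^(SNR/10)` **per feature**, using the variance (AC power) rather than the
mean square — a 5 dB noise level defined against pH's mean square of ~54
would be physiologically absurd. Noise is applied to test inputs only (a
measurement-noise reading; noising training data is the flagged
alternative). The ground-truth state is encoded at the consequent centers
(label 1 → 0.25, label 0 → 0.75), so RMSE is commensurate with the range of
$f(z)$ and bounded by 0.5 under a canonical rule base (the center swap).
The published RMSE figures themselves derive from the private cohort and are
not reproduction targets.

## Prediction benchmark

`compare_models()` reruns six classifiers on identical patient-level folds:
LSTM and bidirectional LSTM (2 layers × 128 cells, learning rate 0.01, up to
100 epochs, log-softmax head — the headline configuration), plus a
multilayer perceptron, bagged k-nearest-neighbours, a boosted tree ensemble
and bagged decision trees with their libraries' customary defaults recorded
in each config. Accuracy is scored at the day level (matching the daily
prediction framing); folds partition patients, so no patient leaks across a
fold's train/test split; everything is seeded, including tree ensembles and
network initialisation. Single-class training folds are reported and
skipped. Fixed epoch budgets with final-epoch weights are used — no early
stopping — for reproducibility.

The recurrent cells, backpropagation-through-time and Adam are implemented
in base R matrix code (`R/lstm.R`), with analytic gradients verified against
finite differences to 1e-7 in the suite. Full-batch training is exact and
fast at this package's scale (tens of patients, single-digit to low-tens
day horizons). The boosted ensemble is gradient-boosted trees via xgboost;
bagged KNN is a seeded bootstrap ensemble over `class::knn`; bagged trees
use `randomForest` with `mtry = p`.

Problem sizes in the shipped tests: the benchmark property checks run on
cohorts of 20–60 patients with 3–12 day horizons and reduced network sizes
(1 × 16 cells, 60 epochs) — sizes chosen so the whole suite runs on a
laptop in well under a minute per file while leaving the statistical
contrasts (sequence model vs static model on trend labels; permutation
null at the majority rate) clearly resolved. The headline 2 × 128
configuration is exercised through the same code path.

## Numerical and degenerate-input conventions

* Membership evaluation is piecewise linear; shoulder MFs return 1 beyond
  their extreme center.
* Normalized inference on an input activating no rule raises an explicit
  "uncovered input" error (or `NA` by option); rule-base completion removes
  the possibility.
* Zero-variance features normalize with scale 1 plus a warning; zero
  variance is an error where it is undefined (SNR, correlation).
* The boundary state value 0.5 maps to Normal (no alarm).
* Cohort CSVs serialize numerics with 17 significant digits; round trips
  are bit-exact, duplicated `(id, day, feature)` keys are an error, and
  observed values outside a feature's plausible range are surfaced as a
  validation log.
* All sampling entry points take explicit seeds and restore the caller's
  RNG state; identical arguments give bit-identical output.

## Known limitations

The generator's independence structure understates real covariance;
prevalence calibration is tied to the default schema (changing schema
parameters means re-tuning the intercept passed to `default_risk_params()`);
the fuzzy system's clinical validity rests on the shipped partitions, which
encode guideline-style cut-points rather than fitted quantities; and the
benchmark compares learning machinery on synthetic signal, not clinical
predictive value.
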
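# nfabt

Fuzzy basis-function alarming for packed-red-blood-cell transfusion need in
blood-cancer patients — plus everything required to study such a system
without access to patient data.

Blood-cancer patients routinely need packed-red-blood-cell (PRBC)
transfusions because the disease and chemotherapy suppress blood-cell
production, yet transfusion carries immunological and infectious risk and
consumes a scarce resource. `nfabt` is aimed at researchers in clinical
decision support and biostatistical method evaluation who want a small,
fully inspectable pipeline for this problem: an interpretable fuzzy
inference core over haemoglobin (Hgb), arterial oxygen pressure (PaO2) and
blood pH; a synthetic electronic-health-record cohort generator calibrated
to published summary statistics of a 98-patient blood-cancer cohort (61
demographic, clinical and laboratory features, daily trajectories, ~7%
daily label prevalence); the preprocessing pipeline such data needs; a
measurement-noise robustness harness; and a cross-validated benchmark of
six sequence and static classifiers, including a from-scratch LSTM.

## The model

Inputs are partitioned into normal, complete, consistent triangular
membership functions. Rules have the form

    R_i: IF z_1 is A_1^i and ... and z_m is A_m^i THEN k is B^i

and the blood state is the fuzzy basis-function (FBF) expansion

    f(z) = sum_i d_i(z) * theta_i,      d_i(z) = prod_j mu_{A_j^i}(z_j),

with `theta_i` the center of the consequent membership function of rule
`R_i` (0.25 = "Low", 0.75 = "Normal"); the normalized form divides by
`sum_i d_i(z)` and equals the classic singleton-fuzzifier /
product-inference / centroid-defuzzifier system. Rule bases are learned
from data by Wang–Mendel table lookup. The expansion is a plain sum, so it
distributes exactly over a swarm of agents each holding a subset of the
rules (`swarm_infer()`); an alarm is raised when `f(z)` falls below 0.5.
With the default two four-MF inputs and the two-MF output the candidate
rule space is 4² × 2 = 32 rules.

## Worked example

```r
library(nfabt)

schema <- build_default_schema()                      # 61 features, n = 98
cohort <- sample_cohort(schema, n = 98, seed = 1)     # quota demographics
cohort <- sample_trajectories(cohort, horizon = 7, seed = 2)
cohort <- assign_daily_labels(cohort, seed = 3)
cohort
#> Synthetic cohort: 98 patients, 61 features
#>   daily panel: 7 days, 43 time-varying features
#>   daily PRBC labels: prevalence 0.058

days <- data.frame(hgb   = cohort$panel$hgb,
                   ph    = cohort$panel$ph,
                   state = ifelse(cohort$labels$prbc == 1, 0.25, 0.75))
fit <- fbf(state ~ hgb + ph, days, complete = TRUE)
fit
#> Fuzzy basis-function alarming model
#>   inputs: hgb, ph  (rule space 24, learned 12)
#>   inference: normalized (weighted centroid); training RMSE 0.2398 on 686 observations
```

The learned rule base (`summary(fit)`) maps the anaemic-acidotic corner to
the Low blood state — `IF hgb is Very Low AND ph is Acidosis THEN state is
Low` — and everything else to Normal, which is exactly the clinical shape
of the ground-truth risk. Evaluating a patient:

```r
f <- predict(fit, data.frame(hgb = 7.4, ph = 7.33))   # anaemic, acidotic
alarm(f, inputs = c(hgb = 7.4, ph = 7.33))
#> Blood state 0.250 -> Low  ** TRANSFUSION ALARM **

predict(fit, data.frame(hgb = 14.0, ph = 7.40))       # healthy day
#> [1] 0.75
```

`f = 0.25` is the Low consequent center (transfusion needed); 0.75 is
Normal; intermediate values blend adjacent rules linearly. The robustness
harness sweeps the three input pairs under additive white Gaussian noise on
the held-out test inputs:

```r
scenario_eval(cohort, runs = 10, seed = 4)
#> Average blood-state RMSE over 10 run(s)
#>    inputs  clean snr_30 snr_10  snr_5
#>  hgb+pao2 0.2297 0.2300 0.2308 0.2396
#>    hgb+ph 0.2407 0.2411 0.2405 0.2413
#>   pao2+ph 0.2589 0.2591 0.2539 0.2599
```

RMSE is scored against the ground-truth state encoded at the consequent
centers, so 0 is perfect and 0.5 is the worst case; degradation from clean
to 5 dB SNR is mild because the triangular partitions absorb most
measurement jitter. `compare_models()` runs the six-classifier benchmark
(LSTM, bidirectional LSTM, boosted and bagged tree ensembles, bagged
nearest neighbours, multilayer perceptron) on identical patient-level
cross-validation folds.

A thin command-line wrapper covering the same steps ships in
`inst/exec/nfabt.R` (subcommands `simulate`, `preprocess`, `fuzzy-fit`,
`fuzzy-eval`, `robustness`, `bench`).

See the methods vignette (`vignettes/nfabt-methods.Rmd`) for the model
assumptions, the generator's design and its limits, and every numerical
convention.

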
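# nextprep

Real-time prediction of the remaining duration of a laparoscopic
cholecystectomy from the activation pattern of the electrosurgical
device, with the downstream advice operating-room schedulers actually
need: *when to start preparing the next patient*.

In this procedure type the electrosurgical device fires almost only
while the gallbladder is dissected off the liver, so the timing of its
current peaks tracks surgical progress — and even encodes the operator:
slower (trainee-assisted) surgeons activate the device for shorter
stretches with longer pauses in between. `nextprep` is for surgical
workflow and OR-scheduling researchers who want to study this class of
single-signal predictor offline, end to end, with full reproducibility.

## What it implements

* **Simulator** (`simulate_procedure()`, `simulate_cohort()`): seeded,
  phase-structured current traces — silent access phase, a dissection
  phase of Gamma-distributed activation bursts alternating with
  Exponential pauses until a sampled active-time workload is met, silent
  closure — with ground-truth durations and events. Surgeon profiles
  scale burst means proportionally and pause means inversely with a
  speed multiplier.
* **Burst detection** (`detect_activations()`, `detect_prefix()`):
  amplitude threshold on the raw ~10 Hz current, merge/min-duration
  post-passes, and a strictly causal prefix variant for replay.
* **Features + classifier bank** (`extract_features()`,
  `train_bank()`): a 9-number summary of the pattern observed so far,
  and one linear-kernel SVM per decision time deciding whether total
  duration *D* exceeds *t* + 25 min. Banks serialize to a single JSON
  model file.
* **Advice protocol** (`run_protocol()`, `replay_stream()`): first
  prediction 15 min after incision, re-prediction every 5 min, advice at
  the first "no more than 25 min remain", forced advice at the 45-min
  cap.
* **Evaluation** (`score_advice()`, `baseline_fixed_lead()`): signed
  timing errors against the ideal *D* − 25 min, MAE in minutes, the
  >40-min stratum, too-early/acceptable/too-late counts at a ±10-min
  margin, and a booked-duration baseline scheduler for comparison.

## Worked example

Train on a simulated 57-procedure cohort, evaluate on a disjoint
21-procedure cohort:

```r
library(nextprep)
cfg   <- sim_config()
train <- simulate_cohort(cfg, 57, seed = 1001, id_prefix = "train")
test  <- simulate_cohort(cfg, 21, seed = 2001, id_prefix = "test")

bank    <- train_bank(train)
advices <- lapply(test, replay_stream, bank = bank)
report  <- score_advice(advices, test)

round(report$mae_min, 2)
#> [1] 14.69
round(report$mae_min_over_40, 2)
#> [1] 12.36
report$band_counts
#>  too_early acceptable   too_late
#>          5          6         10
round(score_advice(baseline_fixed_lead(test, 3600), test)$mae_min, 2)
#> [1] 18.05
```

The system's mean absolute timing error (14.7 min) beats a scheduler who
trusts a 60-min booking (18.1 min), and procedures longer than 40 min
are better predicted (12.4 min) than the cohort as a whole — short
procedures are structurally late because data only start accruing 15 min
into the procedure.

A single replay shows the decision trail:

```r
res <- replay_stream(test[[2]], bank)   # a 78.4-min procedure
res$advice_time_s / 60
#> [1] 40
res$decision_trail$predicted_longer
#> [1]  TRUE  TRUE  TRUE  TRUE  TRUE FALSE
```

Five times the bank said "more than 25 min remain"; at 40 min it
advised preparing the next patient.

A file-based pipeline (`cli_simulate()` → `cli_train()` →
`cli_replay()` / `cli_evaluate()`, or the Rscript front-end in
`inst/cli/nextprep.R`) runs the same steps over trace CSVs, a JSON model
file and YAML configuration.

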
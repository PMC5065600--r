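---
title: "Predicting when to prepare the next surgical patient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting when to prepare the next surgical patient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nextprep)
```

## The problem

Operating-room schedulers must decide when to start preparing the next
patient. Preparation takes roughly 25 minutes; start it too late and an
entire OR team waits, start it too early and the patient waits in the
holding area. Booked durations are unreliable, and phoning the OR for an
estimate interrupts the surgical team.

In a laparoscopic cholecystectomy the electrosurgical device is used
almost exclusively during one phase — dissecting the gallbladder off the
liver bed — so the pattern of its activations tracks the progress of the
procedure. `nextprep` implements a predictor built on that single signal:
a current sensor sampled at roughly 10 Hz, a burst detector, a fixed
feature summary of the pattern observed so far, and a bank of binary
classifiers asked in sequence whether more than the 25-minute lead time
remains.

## The advice protocol

All protocol constants live in `protocol_config()` (units: seconds):

| parameter             | default | meaning                                  |
|-----------------------|---------|------------------------------------------|
| `lead_time_s`         | 1500    | preparation lead time (25 min)           |
| `margin_s`            | 600     | acceptable-timing band (±10 min)         |
| `first_decision_s`    | 900     | first prediction, 15 min after incision  |
| `decision_interval_s` | 300     | re-prediction cadence (5 min)            |
| `cap_s`               | 2700    | hard stop of the loop (45 min)           |

At each grid time $t \in \{900, 1200, \dots, 2700\}$ the system computes
features from the activations observed up to $t$ and asks the horizon
classifier whether the total duration $D$ will exceed $t + 1500$ s
(equivalently, whether remaining duration exceeds 25 min). The first
"no" triggers the advice. Decision times form a grid anchored at the
first incision, so a replay is exactly reproducible.

Three boundary rules are the package's own choices:

* **Cap.** If every prediction up to 45 min says "longer", a forced
  advice is emitted at the cap and flagged `capped = TRUE` — downstream
  scheduling always needs a trigger. The cap clock runs from first
  incision.
* **Tie.** A decision value of exactly 0 means "prepare now". Erring
  toward advising is conservative: one waiting patient is preferable to a
  waiting OR team.
* **Early end.** A procedure that ends before the first decision time
  (or between grid times while the bank still says "longer") is advised
  at trace end: the preparation is already late and the trail records
  what was predicted.

With a ground-truth oracle in place of the classifier
(`oracle_bank()`), advice lands at the first grid time $t$ with
$D - t \le 25$ min. Consequences, all verified exhaustively in the test
suite: for $40 \le D \le 70$ min the advice is never early and late by
less than one 5-min interval; for $D < 40$ min it is late by exactly
$40 - D$ min (data only start accruing 15 min in) — short procedures are
a structural failure mode of any predictor with this decision grid; for
$D > 70$ min the cap forces advice that is $D - 70$ min early. The
lateness here is measured against the unclamped ideal $D - 25$ min; the
evaluation report clamps the ideal at zero so that very short procedures
keep finite, interpretable errors.

## The synthetic cohorts

No clinical recordings ship with the package, so `simulate_cohort()`
generates them. A procedure is three consecutive phases:

1. **Access** (silent): lognormal duration, default
   $\exp(\mathcal{N}(\log 8, 0.4))$ minutes. Reaching the gallbladder is
   quick, so dissection signal exists before the first decision.
2. **Dissection**: alternating activation bursts and pauses until the
   cumulative active time reaches a workload drawn as
   $\mathcal{N}(620, 200)$ s (floored at 30 s). Burst durations are
   Gamma (shape 2) with mean `burst_duration_mean_s * speed`; pauses are
   Exponential with mean `burst_gap_mean_s / speed`.
3. **Closure** (silent): lognormal, default
   $\exp(\mathcal{N}(\log 14, 0.4))$ minutes — gallbladder extraction,
   irrigation, port closure and skin sutures form the longer silent tail.

The `speed` multiplier encodes the operator: slower surgeons activate
the device for shorter stretches with longer pauses between activations,
and need more bursts (hence more pauses) to complete the same workload,
which is what makes the pattern predictive of duration. The default
profile mix is attending-fast (speed 1.2, weight 0.35), attending (1.0,
0.35) and trainee-assisted (0.7, 0.30); 0.7 makes trainee-assisted
procedures roughly 40 % longer than an attending's, a realistic gap.
These defaults put the cohort at a mean total duration near 60 min with
SD near 19 min, so the 40-minute short/long boundary splits it
non-trivially (about 13 % short).

The trace itself is sampled at a nominal 10 Hz with Gaussian timestamp
jitter (SD 10 ms) to emulate an "approximately 10 per second" logger;
current is `activation_amplitude` (1.0, arbitrary units) plus noise (SD
0.1) inside bursts and folded-Gaussian baseline noise (SD 0.05) outside.
The configuration validator enforces at least 6σ separation so bursts
are detectable by construction.

What the generator does **not** emulate: electrosurgical use outside the
dissection phase (brief hemostasis during access), cut-vs-coagulation
modes, multi-device interference, sensor dropouts, case-mix or
anesthesia effects, and scheduling externalities such as understaffed
holding areas. Passing tests therefore demonstrate that the pipeline
recovers structure *of this kind* from signals *of this kind*, not
clinical performance.

Determinism is strict: a procedure is a pure function of
`(config, procedure_id, seed)`, and cohort members get per-procedure
seeds from a stable hash of `(cohort seed, index)` so a cohort can be
extended without reshuffling existing records.

## Detection and features

Detection is an amplitude threshold on the raw current (default: half
the activation amplitude) with a fixed post-pass order: maximal
supra-threshold runs → merge events separated by less than
`merge_gap_s` (0.3 s, blend-mode stutter) → drop events shorter than
`min_event_duration_s` (0.2 s). An event ends one median sampling
interval after its last supra-threshold sample, so an isolated
supra-threshold sample still has nonzero duration; this convention
shifts every duration by one sample and is fixed deliberately. The
real-time variant `detect_prefix()` is defined as detection on the
sub-trace observed so far, with a still-open event truncated at the
observation time — predictions can never peek ahead.

`extract_features()` reduces the events observed up to a decision time
to 9 numbers: event count, total active time, mean/SD of burst
durations, mean/SD of inter-burst gaps, time since the last burst ended,
time of the first burst, and the active fraction of the trailing 5-min
window. Degenerate cases use sentinels (undefined means/SDs are 0; with
no events the "time since" and "first start" fields equal the decision
time) so vectors stay finite without imputation. Elapsed time is *not* a
feature: each decision time has its own classifier, so it would be
constant within any one training set.

## The classifier bank

For each decision time $t$, training rows are the cohort members still
ongoing at $t$ (at inference the procedure is by definition ongoing),
labelled "longer" when $D > t + 1500$ s. Features are z-scored with the
training statistics — stored in the model and never recomputed from test
data; zero-variance features get SD 1, which zeroes their fitted weight.
A linear-kernel soft-margin SVM (C = 1) is fitted per horizon; the
hyperplane is extracted into an explicit weight vector and bias, so a
prediction is an auditable dot product and the whole bank serializes
losslessly to a single JSON document (checked by a schema version on
load). A linear kernel keeps the model fully inspectable; training
errors loudly if any horizon sees only one class, because a constant
classifier would silently break the protocol.

Classes are deliberately left **unweighted**. At early horizons nearly
every still-ongoing procedure is "longer" (≈ 85 %); weighting classes
inversely to frequency forces balanced recall there and produces a
20–25 % false-"prepare now" rate per horizon. Because the advice loop
stops at the first "prepare now", those errors compound across seven
decisions and systematically truncate long procedures' advice times. An
unweighted fit respects the class prior, drives early-horizon
false-"shorter" calls to nearly zero, and pushes residual error toward
late advice on short procedures — the same direction a human scheduler
errs, and the asymmetry the protocol tolerates best.
`class_weights = "inverse"` remains available for users who want
balanced per-horizon recall instead.

## Evaluation

`score_advice()` reports signed errors in minutes
(advice − ideal, positive = late, ideal clamped at 0), the mean absolute
error, the MAE restricted to procedures over 40 min, and
too-early / acceptable / too-late counts at the ±10-min margin. The
shipped comparator, `baseline_fixed_lead()`, emulates a scheduler who
trusts a booked duration (default 60 min) and always advises at booked
minus lead; it stands in for live staff judgement, which an offline
package cannot reproduce.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config()
train <- simulate_cohort(cfg, 57, seed = 1001, id_prefix = "train")
test  <- simulate_cohort(cfg, 21, seed = 2001, id_prefix = "test")

bank <- train_bank(train)
advices <- lapply(test, replay_stream, bank = bank)
report <- score_advice(advices, test)

report$mae_min          # cohort mean absolute timing error, minutes
report$mae_min_over_40  # same, procedures longer than 40 min
report$band_counts      # too_early / acceptable / too_late
```

At these cohort sizes (57 training, 21 test, mirroring a realistic
single-centre data collection) the trained system's MAE is typically
10–13 min, the >40-min stratum is better predicted than the cohort as a
whole, and both beat the fixed-booked-duration baseline (14–18 min).
`scripts/acceptance.R` recomputes exactly these quantities from scratch
for any seed.

## Numerical and testing choices

* Monte-Carlo sizes in the test suite — 1000 randomized traces for
  detector/oracle equivalence, 500 procedures per profile for the
  speed-law check, 1000 duration draws for the regime split, 5 seeded
  57/21 train/test replications end to end — were chosen as the smallest
  sizes at which the checked effects are stable.
* Timestamps are forced strictly increasing after jitter by an epsilon
  bump; gap statistics can therefore never be negative.
* Negative or non-finite current samples are clamped to zero with a
  warning on ingestion (sensor artifact policy).
* Stochastic end-to-end claims are asserted as a majority over 5 fixed
  seeds, not per-seed, since a 21-procedure test cohort is small.

## Known limitations

* Procedures longer than 70 min (cap + lead) are structurally advised
  early by `D − 70` min; no classifier can fix this within the 45-min
  cap.
* Procedures shorter than 40 min are structurally advised late; the
  package reproduces this failure mode rather than hiding it.
* The simulator is a single-dissection-phase model of one procedure
  type; the trained bank transfers to nothing else.
* The baseline comparator is a fixed-booking heuristic, not human
  judgement; comparisons against it say nothing about OR staff.
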
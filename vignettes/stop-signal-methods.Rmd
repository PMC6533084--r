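---
title: "Simulating and analyzing stop-signal data under the independent race model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing stop-signal data under the independent race model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopsignal)
```

## The model

In the stop-signal task a participant performs a choice ("go") task, but on
a minority of trials a stop signal appears after a stop-signal delay (SSD)
and the imminent response must be withheld. The latency of the stopping
process — the stop-signal reaction time, SSRT — is not observable, because a
successful stop leaves no response. It can nevertheless be estimated under
the *independent race model*: each stop trial is a race between a go runner,
started by the go stimulus, and a stop runner, started by the stop signal.
A response is emitted if and only if the go finishing time precedes
`SSD + stop latency`; the two finishing times are stochastically
independent.

`stopsignal` implements this model generatively and inferentially:

* **Simulation.** Go and stop finishing times are ex-Gaussian — a
  Gaussian(`mu`, `sigma`) plus an independent Exponential(`tau`) — so the
  right skew typical of empirical RT distributions is controlled by a single
  parameter. Mean and variance are `mu + tau` and `sigma^2 + tau^2`. Two
  failure processes break the idealized race: with probability
  `p_trigger_failure` the stop runner is never started (the trial can only
  end in a response, inflating p(respond|signal) at every delay), and with
  probability `p_go_failure` the go runner is never started (a go omission;
  on a stop trial a non-started go runner makes the stop trivially
  "successful").
* **SSRT estimation.** The *integration method* locates the stop process's
  finishing time at the nth fastest go RT, `n = n_go * p(respond|signal)`,
  and subtracts the mean SSD. In the consensus variant each go omission
  contributes one replacement RT so that the missing slow tail is not
  ignored. The *mean method* subtracts the mean SSD from the mean go RT; it
  is retained because it is the historical default, and the simulation
  machinery exists largely to show when it misleads.
* **Validity rules.** SSRT is not estimated when the race model's
  independence assumption visibly fails (mean RT on unsuccessful stop trials
  strictly exceeding mean go RT), when p(respond|signal) leaves
  `[0.25, 0.75]`, or when the go-omission rate exceeds a study-set ceiling.
  Excluded subjects keep all directly observable statistics in every report.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `go` (`mu`, `sigma`, `tau`) | 500, 50, 50 | ms | go finishing-time distribution; mean go RT = 550 ms |
| `stop` (`mu`, `sigma`, `tau`) | 200, 30, 20 | ms | stop latency; true mean SSRT = 220 ms |
| `p_trigger_failure`, `p_go_failure`, `p_choice_error` | 0 | prob. | failure processes |
| `p_stop` | 0.25 | prob. | stop-signal proportion; the standard design recommendation |
| `n_trials` | 200 | count | 50 stop + 150 go at the default `p_stop` |
| staircase `start`, `step`, `min`, `max` | 200, 50, 0, `max_rt - step` | ms | tracking; the step follows the common 50 ms convention |
| `max_rt` | 1500 | ms | response deadline |
| `p_low`, `p_high` | 0.25, 0.75 | prob. | p(respond|signal) inclusion range (inclusive bounds) |

Subject-level defaults mirror healthy-adult magnitudes (go RT around
550 ms, SSRT around 220 ms). Between-subject variation, needed for
reliability correlations and power studies, is Gaussian per field with
rejection-truncation into the valid range; its default SDs (e.g. 50 ms on
`go_mu`, 20 ms on `stop_mu`) are package choices — the scale a behavioral
study of healthy adults would consider ordinary — because no canonical
population values exist for them.

## Numerical and design choices

* **Rank rounding.** `n_go * p(respond|signal)` is rarely an integer. The
  package rounds half-up (`floor(x + 0.5)`) and clamps to `[1, n_go]`;
  ceiling is available (`rounding = "ceiling"`). The choice is visible in
  every estimate (`rank_n`) because studies are expected to report how the
  quantile was computed. A brute-force empirical-CDF inversion oracle in the
  test suite pins the behavior where the two rules coincide.
* **Replacement RT for go omissions.** "The maximum RT" is ambiguous between
  the maximum *observed* go RT and the response *deadline*. Both are
  implemented; the observed maximum is the default (`omission_rt =
  "max_observed"`) because it cannot exceed what the subject demonstrably
  produces. With no observed go responses at all, the deadline is used.
* **Premature responses.** Responses before the go stimulus carry negative
  RT and a `premature` flag; premature responses on stop trials (RT < SSD)
  are flagged too. They are included everywhere the consensus rules include
  them: in p(respond|signal), in mean SSD, in the staircase ("decrease after
  *all* responses"), and in the go-RT distribution at their recorded value.
* **Zero-SSD probes.** Diagnostic stop trials at SSD = 0 are flagged,
  bypass the staircase, and are excluded from mean SSD, p(respond|signal)
  and SSRT; their response rate is reported separately (`p_respond_probe`)
  as a trigger-failure diagnostic. The race-model independence check also
  ignores them, since it exists only to gate estimation.
* **One global staircase** per session, not one per response hand;
  configurable via `staircase_config`. Go failures apply on stop trials as
  well by default (`go_failures_on_stop = TRUE`) — a runner that never
  started cannot respond — and the switch exists because the convention is
  not universal.
* **File precision.** Times are real-valued milliseconds internally and in
  the CSV writer (`%.17g`), so `read_trials(write_trials(s))` reproduces a
  session field-for-field; rounding for display is left to reports.
* **Seeds.** All randomness flows through R's global RNG. The study and
  command-line layers derive independent per-cell and per-subject seeds
  from one master seed (a fixed integer congruence, kept below 2^31), so
  factorial cells are reproducible in isolation.
* **Degenerate inputs.** `validate_session` reports and never throws;
  estimators throw informative errors on empty go distributions or
  `p(respond|signal) = 0`; cells where every subject is excluded are
  *flagged* in study results, never silently dropped.

## What the simulator does and does not emulate

The generator reproduces the features the consensus analysis rules are
sensitive to: ex-Gaussian skew, staircase SSD dynamics, trigger and go
failures, choice errors, censoring at the deadline, and zero-SSD probes. It
does **not** model proactive slowing or waiting strategies, sequential
effects, fatigue, or context-dependent (non-independent) races; the ITI
setting is recorded for design completeness but has no behavioral effect
because there is no anticipation mechanism. Passing simulation-based tests
therefore shows that the estimators behave correctly *under the race model's
assumptions*; it cannot certify robustness to strategic slowing or
dependence violations in real data, which is precisely why the empirical
validity checks (independence comparison, p(respond|signal) range) remain in
the pipeline.

## Monte-Carlo study machinery

`run_cell()` simulates a population cell (factors: stop-trial count,
go-failure rate, go skew `tau_go`), applies the exclusion rules *before*
estimation — so the excluded count is shared by all estimators — and
reports per-estimator mean bias (estimated minus true SSRT, truth being
`stop_mu + stop_tau`), the SD of those difference scores, and the
correlation between estimated and true SSRT across included subjects
(Pearson by default; replications contribute to the correlation only with
at least three included subjects). `run_factorial()` crosses factor levels
with per-cell derived seeds. `estimate_power()` simulates two groups whose
true mean SSRT differs by `delta_ssrt`, estimates per-subject SSRT after
exclusions, and applies a two-sided Welch two-sample t test — chosen as the
plain-vanilla group comparison; the test is deliberately replaceable —
returning the rejection rate with its binomial standard error.

The package's own test suite runs these at deliberately modest sizes
(e.g. 100–200 subjects for recovery, 40–60 subjects x 4–5 replications for
direction checks, 120–200 replications for power calibration), chosen so the
checked effects exceed three Monte-Carlo standard errors — recovery bias in
the optimal cell (no failures, `tau_go` = 30 ms, 200 stop trials) is well
under 10 ms, skew inflates the mean method several times more than the
integration method, trigger failures push both estimators tens of
milliseconds upward, and halving stop trials from 50 to 25 multiplies
exclusions.

## A typical session

```{r example, eval = FALSE}
set.seed(1)
session <- simulate_session(subject_params(),
                            design_config(n_trials = 800, p_stop = 0.25))
p_respond_signal(session)      # ~0.50 under tracking
integration_ssrt(session)      # consensus estimator
mean_method_ssrt(session)      # for comparison
apply_exclusions(session)      # validity gate
summarize_session(session, integration_ssrt(session))
```

## Known limitations

* Non-parametric estimators only; parametric/Bayesian SSRT models with
  explicit trigger-failure parameters are out of scope — the package
  *simulates* trigger failures and surfaces the zero-SSD-probe response rate
  as a diagnostic, but does not estimate their probability.
* Independence violations are detected only through the mean-RT comparison
  and the inhibition function; no formal race-model tests.
* The staircase is single-tracked; designs with per-hand or per-category
  trackers need the fixed-set mode or external sequencing.
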
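# stopsignal

Tools for designing, simulating and analyzing **stop-signal task** data
under the independent race model.

The stop-signal task is the standard laboratory probe of response
inhibition: a participant performs a choice reaction-time task, but on a
minority of trials a stop signal appears after a stop-signal delay (SSD)
and the response must be withheld. The latency of stopping — the
stop-signal reaction time (SSRT) — cannot be observed (a successful stop
leaves no response) but can be estimated under the independent race model:
a response is emitted on a stop trial iff the go process's finishing time
beats `SSD + SSRT draw`, the two racers being independent.

The package provides, for researchers planning or analyzing stop-signal
studies:

* a **trial-level data model** (CSV in/out with a column map for foreign
  layouts, structural validation, explicit missing-value coding);
* a **race-model simulator**: ex-Gaussian go and stop finishing times,
  adaptive SSD staircase (up 50 ms after a successful stop, down 50 ms
  after *any* response on a stop trial) or fixed delay sets, trigger
  failures, go failures, choice errors, zero-SSD diagnostic probes;
* the **consensus SSRT estimators** — the integration method with
  replacement of go omissions,

      SSRT = nth fastest go RT − mean SSD,   n = n_go × p(respond|signal),

  where each go omission contributes one replacement RT (maximum observed
  go RT by default), and the mean method,
  `SSRT = mean go RT − mean SSD`;
* the **validity and exclusion rules**: race-model independence check
  (mean RT on unsuccessful stop trials must not exceed mean go RT),
  p(respond|signal) within [0.25, 0.75], go-omission ceiling — applied per
  subject and condition *before* estimation, with excluded subjects
  reported, never dropped;
* the **consensus descriptive report** (omission and choice-error
  probabilities, go RT mean/median/spread, p(respond|signal), mean SSD,
  SSRT, RT on unsuccessful stop trials) per subject and group;
* **Monte-Carlo study machinery**: factorial bias/reliability cells over
  stop-trial count, go-failure rate and go skew, and group-level power
  estimation for sample-size planning;
* a **command line** (`inst/cli/stopsignal.R`) with `simulate`, `analyze`,
  `study` and `power` subcommands driven by YAML configs, writing run
  manifests (config digest, seed, version) next to every output.

## Worked example

Simulate one tracked session (800 trials, 25% stop signals) from a subject
with mean go RT 550 ms and true SSRT 220 ms, then analyze it:

```r
library(stopsignal)
set.seed(1)
session <- simulate_session(subject_params(),
                            design_config(n_trials = 800, p_stop = 0.25))
p_respond_signal(session)
#> [1] 0.495
integration_ssrt(session)
#> <ssrt_estimate> integration_replace: SSRT = 213.1 ms
#>   p(respond|signal) = 0.495, mean SSD = 328.5 ms, n_go = 600, rank = 297, omissions replaced = 0
mean_method_ssrt(session)
#> <ssrt_estimate> mean: SSRT = 220.4 ms
apply_exclusions(session)
#> <exclusion_decision> included
cat(format_report(summarize_session(session, integration_ssrt(session))), sep = "\n")
#> subject s1 / condition default
#>   probability of go omissions:        0
#>   probability of go choice errors:    0
#>   go RT mean / median (ms):           548.9 / 543.4
#>   go RT intra-subject spread (ms):    72.13
#>   p(respond|signal):                  0.495
#>   mean SSD (ms):                      328.5
#>   SSRT (ms):                          213.1
#>   RT on unsuccessful stop trials:     510.1
```

Reading the numbers: the staircase has converged (p(respond|signal) ≈ 0.5,
so the subject failed to stop on about half the stop trials); the
integration estimate of 213 ms sits close to the generating true SSRT of
220 ms; unsuccessful-stop responses (510 ms) are faster than go responses
(549 ms), as the race model demands, so the session passes the independence
check and no exclusion applies.

For study planning:

```r
run_factorial(n_stop_trials = c(25, 50, 100), tau_go = c(50, 150),
              n_subjects = 50, n_replications = 10, master_seed = 1)
estimate_power(power_spec(delta_ssrt = 30, n_subjects_per_group = 25,
                          cell = cell_spec(n_stop_trials = 50)))
```

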
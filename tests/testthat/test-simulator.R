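test_that("trial sequences carry exactly the designed stop count", {
  set.seed(1)
  seq1 <- build_trial_sequence(design_config(n_trials = 200, p_stop = 0.25))
  expect_length(seq1, 200)
  expect_identical(sum(seq1 == "stop"), 50L)
  expect_identical(sum(seq1 == "go"), 150L)

  expect_true(all(build_trial_sequence(
    design_config(n_trials = 40, p_stop = 0)) == "go"))

  probes <- build_trial_sequence(
    design_config(n_trials = 100, p_stop = 0.25, n_zero_ssd_probes = 8))
  expect_length(probes, 108)
  expect_identical(sum(probes == "stop_probe"), 8L)

  set.seed(99); a <- build_trial_sequence(design_config())
  set.seed(99); b <- build_trial_sequence(design_config())
  expect_identical(a, b)

  expect_error(design_config(p_stop = 1.2), "p_stop")
})

test_that("the staircase moves up after stops and down after any response", {
  cfg <- staircase_config(start = 200, step = 50, min = 0, max = 900)
  expect_equal(staircase_update(300, FALSE, cfg), 350)
  expect_equal(staircase_update(300, TRUE, cfg), 250)
  # clamping at both bounds
  expect_equal(staircase_update(0, TRUE, cfg), 0)
  expect_equal(staircase_update(900, FALSE, cfg), 900)
  # a premature or choice-error response is still a response: SSD goes down
  expect_equal(staircase_update(250, TRUE, cfg), 200)
})

test_that("degenerate failure probabilities behave as the race model dictates", {
  design <- design_config(n_trials = 400, p_stop = 0.25)
  set.seed(5)
  s <- simulate_session(subject_params(p_trigger_failure = 1), design)
  expect_gt(p_respond_signal(s), 0.99)  # the stop runner never starts

  set.seed(6)
  s2 <- simulate_session(subject_params(p_go_failure = 1), design)
  go <- s2$trials[s2$trials$trial_type == "go", ]
  expect_true(all(go$response == "none"))
  expect_equal(p_respond_signal(s2), 0)
})

test_that("staircase SSDs stay in bounds and move by exactly one step", {
  set.seed(8)
  stair <- staircase_config(start = 200, step = 50, min = 0, max = 1000)
  s <- simulate_session(subject_params(), design_config(n_trials = 800),
                        stair = stair)
  ssd <- s$trials$ssd_real[s$trials$trial_type == "stop" &
                             !s$trials$zero_ssd_probe]
  expect_true(all(ssd >= 0 & ssd <= 1000))
  moves <- diff(ssd)
  expect_true(all(abs(moves) <= 50 + 1e-12))  # clamping can shorten a step
  interior <- ssd[-length(ssd)] > 0 & ssd[-length(ssd)] < 1000
  expect_true(all(abs(moves[interior]) == 50))
})

test_that("simulated go RTs track the generating ex-Gaussian mean", {
  set.seed(10)
  subj <- subject_params(go = exgauss_params(500, 50, 50))
  s <- simulate_session(subj, design_config(n_trials = 2000, p_stop = 0,
                                            max_rt = 1e6))
  rts <- s$trials$rt[!is.na(s$trials$rt)]
  expect_lt(abs(mean(rts) - 550), 3 * sqrt((50^2 + 50^2) / length(rts)))
})

test_that("fixed-SSD response rates match the brute-force race integral", {
  subj <- subject_params(go = exgauss_params(500, 50, 50),
                         stop = exgauss_params(200, 30, 20))
  ssds <- c(150, 250, 350)
  n_per <- 2000
  design <- design_config(n_trials = 2 * length(ssds) * n_per, p_stop = 0.5,
                          ssd_mode = "fixed-set", fixed_ssds = ssds,
                          max_rt = 1e6)
  set.seed(12)
  s <- simulate_session(subj, design)
  emp <- inhibition_function(s)
  expect_identical(emp$ssd, ssds)
  th <- oracle_p_respond(ssds, subj$go, subj$stop)
  for (i in seq_along(ssds)) {
    se <- sqrt(th[i] * (1 - th[i]) / emp$n_stop[i])
    expect_lt(abs(emp$p_respond[i] - th[i]), 3 * se)
  }
  # inhibition function is non-decreasing within sampling error
  expect_true(all(diff(emp$p_respond) > -3 * sqrt(0.25 / n_per)))
})

test_that("zero-SSD probes bypass the staircase and almost always stop", {
  set.seed(14)
  s <- simulate_session(subject_params(),
                        design_config(n_trials = 400, n_zero_ssd_probes = 40))
  pr <- s$trials[s$trials$zero_ssd_probe, ]
  expect_identical(nrow(pr), 40L)
  expect_true(all(pr$ssd_requested == 0))
  # with no trigger failures a zero-delay stop signal nearly always wins
  expect_lt(mean(pr$response != "none"), 0.05)
  # and with certain trigger failure the probes always respond
  set.seed(15)
  s2 <- simulate_session(subject_params(p_trigger_failure = 1),
                         design_config(n_trials = 100, n_zero_ssd_probes = 30))
  pr2 <- s2$trials[s2$trials$zero_ssd_probe, ]
  expect_gt(mean(pr2$response != "none"), 0.9)
})

test_that("population sampling is deterministic and recovers its moments", {
  pop <- population_params(sds = list(go_mu = 0, go_sigma = 0, go_tau = 0,
                                      stop_mu = 0, stop_sigma = 0,
                                      stop_tau = 0))
  set.seed(2)
  roster <- sample_population(pop, 5)
  expect_true(all(vapply(roster, function(s) identical(s, roster[[1]]),
                         logical(1))))

  pop2 <- population_params(sds = list(stop_mu = 30, stop_tau = 0,
                                       stop_sigma = 0))
  set.seed(3)
  roster2 <- sample_population(pop2, 400)
  truth <- vapply(roster2, true_ssrt, numeric(1))
  # SD of true SSRT should recover the between-subject SD of stop mu
  expect_lt(abs(sd(truth) - 30) / 30, 0.15)

  set.seed(4); a <- sample_population(pop2, 10)
  set.seed(4); b <- sample_population(pop2, 10)
  expect_identical(a, b)

  expect_error(population_params(means = list(p_go_failure = 2)), "bounds")
})
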
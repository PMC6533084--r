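test_that("p(respond|signal) counts every response and skips probes", {
  # 50 stop trials, 23 with a response (2 premature: rt before the ssd)
  rts <- c(rep(430, 21), 150, 160, rep(NA, 27))
  s <- toy_session(go_rts = rep(500, 10), stop_ssd = rep(200, 50),
                   stop_rt = rts)
  expect_equal(p_respond_signal(s), 0.46)
  expect_true(any(s$trials$premature))

  s_all <- toy_session(go_rts = 500, stop_ssd = rep(200, 5),
                       stop_rt = rep(400, 5))
  expect_equal(p_respond_signal(s_all), 1.0)

  # probes neither in the numerator nor the denominator
  s_probe <- toy_session(go_rts = rep(500, 4), stop_ssd = rep(200, 50),
                         stop_rt = rts, probe_responded = rep(TRUE, 10))
  expect_equal(p_respond_signal(s_probe), 0.46)

  s_none <- toy_session(go_rts = c(400, 500))
  expect_error(p_respond_signal(s_none), "no non-probe stop trials")
})

test_that("mean SSD averages non-probe stop trials only", {
  expect_equal(mean_ssd(toy_session(stop_ssd = c(200, 250, 300))), 250)
  expect_equal(mean_ssd(toy_session(stop_ssd = c(200, 300),
                                    probe_responded = c(TRUE, FALSE))), 250)
  expect_equal(mean_ssd(toy_session(stop_ssd = 150)), 150)
})

test_that("the integration rank follows the half-up rule and the worked example", {
  expect_identical(nth_rt_index(200, 0.45), 90L)
  expect_identical(nth_rt_index(200, 0.50), 100L)
  expect_identical(nth_rt_index(37, 0.43), 16L)   # 15.91 rounds half-up
  # cross-check against brute-force empirical-CDF inversion where the two
  # rules coincide (fractional part above one half)
  expect_identical(nth_rt_index(37, 0.43), oracle_ecdf_rank(37, 0.43))
  expect_identical(nth_rt_index(200, 0.45), oracle_ecdf_rank(200, 0.45))
  # clamping and the alternative rounding rule
  expect_identical(nth_rt_index(10, 0.01), 1L)
  expect_identical(nth_rt_index(10, 1), 10L)
  expect_identical(nth_rt_index(10, 0.41, rounding = "ceiling"), 5L)
  expect_error(nth_rt_index(10, 0), "undefined")
})

test_that("integration SSRT reproduces the hand-worked toy examples", {
  # 10 go RTs 400..580, p(respond|signal) = 0.40, mean SSD = 200
  s <- toy_session(go_rts = toy_go_rts(), stop_ssd = rep(200, 5),
                   stop_rt = c(410, 415, NA, NA, NA))
  est <- integration_ssrt(s)
  expect_identical(est$rank_n, 4L)          # 10 x 0.4
  expect_equal(est$value, 460 - 200)        # 4th fastest minus mean SSD
  expect_equal(est$p_respond_signal, 0.4)
  expect_identical(est$n_omissions_replaced, 0L)

  # two go omissions replaced with the deadline RT of 800:
  # distribution length 12, rank round(4.8) = 5, 5th fastest 480
  s2 <- toy_session(go_rts = c(toy_go_rts(), NA, NA), stop_ssd = rep(200, 5),
                    stop_rt = c(410, 415, NA, NA, NA), max_rt = 800)
  est2 <- integration_ssrt(s2, omission_rt = "max_rt")
  expect_identical(est2$n_go_distribution, 12L)
  expect_identical(est2$rank_n, 5L)
  expect_equal(est2$value, 480 - 200)
  expect_identical(est2$n_omissions_replaced, 2L)

  # default replacement uses the maximum observed go RT
  est3 <- integration_ssrt(s2)
  expect_identical(est3$rank_n, 5L)
  expect_equal(est3$value, 480 - 200)       # same rank; 580s sit in the tail

  # without replacement the omissions simply vanish from the distribution
  est4 <- integration_ssrt(s2, replace_omissions = FALSE)
  expect_identical(est4$n_go_distribution, 10L)

  # p(respond|signal) = 1 boundary: rank n, max go RT minus mean SSD
  s5 <- toy_session(go_rts = toy_go_rts(), stop_ssd = rep(200, 4),
                    stop_rt = rep(410, 4))
  est5 <- integration_ssrt(s5)
  expect_identical(est5$rank_n, 10L)
  expect_equal(est5$value, 580 - 200)
})

test_that("the mean method subtracts mean SSD from mean go RT", {
  s <- toy_session(go_rts = c(540, 560), stop_ssd = c(240, 260),
                   stop_rt = c(420, NA))
  expect_equal(mean_method_ssrt(s)$value, 550 - 250)

  # identity case: mean go RT equal to mean SSD
  s0 <- toy_session(go_rts = c(240, 260), stop_ssd = c(240, 260),
                    stop_rt = c(230, NA))
  expect_equal(mean_method_ssrt(s0)$value, 0)

  # worked toy set: mean 490 minus mean SSD 200
  s1 <- toy_session(go_rts = toy_go_rts(), stop_ssd = rep(200, 5),
                    stop_rt = c(410, 415, NA, NA, NA))
  expect_equal(mean_method_ssrt(s1)$value, 290)

  # omissions are not part of the mean-method go RT pool
  s2 <- toy_session(go_rts = c(540, 560, NA), stop_ssd = c(240, 260),
                    stop_rt = c(420, NA))
  expect_equal(mean_method_ssrt(s2)$value, 300)
})

test_that("the independence check flags strictly slower stop responses only", {
  pass <- toy_session(go_rts = c(500, 540), stop_ssd = 200, stop_rt = 480)
  expect_false(independence_check(pass)$violation)

  viol <- toy_session(go_rts = c(500, 540), stop_ssd = 200, stop_rt = 530)
  expect_true(independence_check(viol)$violation)

  tie <- toy_session(go_rts = c(500, 540), stop_ssd = 200, stop_rt = 520)
  expect_false(independence_check(tie)$violation)

  # no responded stop trials: check inapplicable, never a violation
  none <- toy_session(go_rts = c(500, 540), stop_ssd = 200, stop_rt = NA)
  chk <- independence_check(none)
  expect_false(chk$applicable)
  expect_false(chk$violation)
})

test_that("exclusion decisions accumulate every failing reason", {
  # p(respond|signal) = 0.8: outside the allowed range
  s_hi <- toy_session(go_rts = rep(500, 10), stop_ssd = rep(200, 10),
                      stop_rt = c(rep(450, 8), NA, NA))
  d <- apply_exclusions(s_hi)
  expect_true(d$excluded)
  expect_identical(d$reasons, "p_respond_out_of_range")

  # boundary values are allowed (only strict violations exclude)
  s_edge <- toy_session(go_rts = rep(500, 8), stop_ssd = rep(200, 4),
                        stop_rt = c(450, NA, NA, NA))
  expect_false(apply_exclusions(s_edge)$excluded)  # p exactly 0.25

  # a clean mid-range session is included
  s_ok <- toy_session(go_rts = rep(500, 10), stop_ssd = rep(200, 10),
                      stop_rt = c(rep(450, 5), rep(NA, 5)))
  expect_false(apply_exclusions(s_ok)$excluded)

  # independence violation and out-of-range p are both reported
  s_both <- toy_session(go_rts = rep(500, 10), stop_ssd = rep(200, 10),
                        stop_rt = c(550, 560, rep(NA, 8)))
  d2 <- apply_exclusions(s_both)
  expect_setequal(d2$reasons,
                  c("independence_violation", "p_respond_out_of_range"))

  # go-omission ceiling
  s_omit <- toy_session(go_rts = c(rep(500, 5), rep(NA, 5)),
                        stop_ssd = rep(200, 10),
                        stop_rt = c(rep(450, 5), rep(NA, 5)))
  d3 <- apply_exclusions(s_omit,
                         exclusion_criteria(max_go_omission_rate = 0.25))
  expect_true("go_omission_rate" %in% d3$reasons)

  # decisions are deterministic and idempotent
  expect_identical(apply_exclusions(s_both), d2)
})

test_that("the inhibition function tabulates response rates per delay", {
  s <- toy_session(go_rts = rep(500, 5),
                   stop_ssd = c(rep(100, 10), rep(300, 10)),
                   stop_rt = c(rep(450, 2), rep(NA, 8),
                               rep(450, 8), rep(NA, 2)))
  f <- inhibition_function(s)
  expect_equal(f$ssd, c(100, 300))
  expect_equal(f$p_respond, c(0.2, 0.8))

  f1 <- inhibition_function(toy_session(stop_ssd = rep(150, 4),
                                        stop_rt = c(400, NA, NA, NA)))
  expect_identical(nrow(f1), 1L)
  expect_equal(f1$p_respond, 0.25)
})

test_that("estimate_all keeps excluded cells visible with reasons", {
  ok <- toy_session(go_rts = rep(c(480, 500, 520), 4),
                    stop_ssd = rep(200, 10),
                    stop_rt = c(rep(450, 5), rep(NA, 5)), subject_id = "a")
  bad <- toy_session(go_rts = rep(500, 10), stop_ssd = rep(200, 10),
                     stop_rt = c(rep(450, 9), NA), subject_id = "b")
  pooled <- new_session(rbind(ok$trials, bad$trials), max_rt = 1500)
  tab <- estimate_all(pooled)
  expect_identical(nrow(tab), 2L)
  expect_false(tab$excluded[tab$subject_id == "a"])
  expect_true(is.finite(tab$ssrt_integration[tab$subject_id == "a"]))
  expect_true(tab$excluded[tab$subject_id == "b"])
  expect_true(is.na(tab$ssrt_integration[tab$subject_id == "b"]))
  expect_match(tab$reasons[tab$subject_id == "b"], "p_respond_out_of_range")
})
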
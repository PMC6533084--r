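#' Subject-level generative parameters
#'
#' The independent race model generates each trial from two racers: a go
#' runner with ex-Gaussian finishing times and, on stop trials, a stop runner
#' whose finishing time is the stop-signal delay plus an ex-Gaussian stop
#' latency. `p_trigger_failure` is the probability that the stop runner is
#' never started on a stop trial; `p_go_failure` the probability that the go
#' runner is never started (a go omission); `p_choice_error` the probability
#' that an emitted response is the wrong choice, drawn independently of RT.
#' The subject's true mean SSRT is `stop$mu + stop$tau`.
#'
#' @param go,stop [exgauss_params()] for the go and stop finishing times (ms).
#' @param p_trigger_failure,p_go_failure,p_choice_error Probabilities in
#'   `[0, 1]`.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(go = exgauss_params(500, 50, 50),
                           stop = exgauss_params(200, 30, 20),
                           p_trigger_failure = 0, p_go_failure = 0,
                           p_choice_error = 0) {
  if (!inherits(go, "exgauss_params")) go <- do.call(exgauss_params, go)
  if (!inherits(stop, "exgauss_params")) stop <- do.call(exgauss_params, stop)
  for (p in c(p_trigger_failure, p_go_failure, p_choice_error))
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      base::stop("failure/error probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(go = go, stop = stop,
                 p_trigger_failure = p_trigger_failure,
                 p_go_failure = p_go_failure,
                 p_choice_error = p_choice_error),
            class = "subject_params")
}

#' True mean SSRT of a simulated subject
#'
#' The mean of the generating stop-latency distribution, `stop$mu + stop$tau`.
#' This is the ground truth against which estimator bias is measured.
#'
#' @param subject A [subject_params()] object.
#' @return Milliseconds.
#' @export
true_ssrt <- function(subject) subject$stop$mu + subject$stop$tau

#' Staircase (tracking) configuration
#'
#' The adaptive tracking rule adjusts the stop-signal delay to converge on a
#' response probability of about one half: the delay increases by `step`
#' after every successful stop and decreases by `step` after every response
#' on a stop trial, clamped to `[min, max]`. 50 ms steps are the common
#' choice (three refreshes of a 60 Hz display).
#'
#' @param start Initial SSD in ms.
#' @param step Step size in ms, `> 0`.
#' @param min,max Clamping bounds in ms, `min <= start <= max`.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(start = 200, step = 50, min = 0, max = 1450) {
  stopifnot(is.numeric(start), is.numeric(step), is.numeric(min), is.numeric(max))
  if (step <= 0) stop("'step' must be > 0", call. = FALSE)
  if (!(min <= start && start <= max))
    stop("'start' must lie in [min, max]", call. = FALSE)
  structure(list(start = start, step = step, min = min, max = max),
            class = "staircase_config")
}

#' Session design configuration
#'
#' @param n_trials Total number of core (non-probe) trials.
#' @param p_stop Stop-signal probability in `[0, 1)`; `n_trials * p_stop`
#'   must round to the intended stop count. One quarter is the recommended
#'   default for standard designs.
#' @param max_rt Response deadline in ms.
#' @param ssd_mode `"staircase"` (adaptive tracking) or `"fixed-set"`
#'   (delays cycled from `fixed_ssds`).
#' @param fixed_ssds Numeric vector of delays in ms (fixed-set mode only).
#' @param n_zero_ssd_probes Number of extra diagnostic stop trials presented
#'   at SSD = 0, interleaved at random, flagged, and excluded from both the
#'   staircase and estimation. They expose trigger failures: with none, a
#'   zero-delay stop signal should almost always win the race.
#' @param iti Inter-trial-interval model: `"fixed"` or `"exponential"`
#'   (offset plus truncated exponential). Recorded in the design for
#'   reporting completeness; the simulator has no anticipation mechanism, so
#'   the ITI does not alter generated behavior.
#' @param iti_params Named list; `fixed`: `duration`; `exponential`:
#'   `offset`, `mean`, `truncate`.
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_trials = 200, p_stop = 0.25, max_rt = 1500,
                          ssd_mode = c("staircase", "fixed-set"),
                          fixed_ssds = NULL, n_zero_ssd_probes = 0,
                          iti = c("fixed", "exponential"),
                          iti_params = list(duration = 500)) {
  ssd_mode <- match.arg(ssd_mode)
  iti <- match.arg(iti)
  if (!is.numeric(p_stop) || p_stop < 0 || p_stop >= 1)
    stop("'p_stop' must lie in [0, 1)", call. = FALSE)
  stopifnot(n_trials >= 0, max_rt > 0, n_zero_ssd_probes >= 0)
  n_stop <- round(n_trials * p_stop)
  if (abs(n_trials * p_stop - n_stop) > 1e-8)
    warning("n_trials * p_stop is not an integer; rounding to ", n_stop)
  if (ssd_mode == "fixed-set" && (is.null(fixed_ssds) || !length(fixed_ssds)))
    stop("fixed-set mode requires a non-empty 'fixed_ssds'", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials), p_stop = p_stop,
                 max_rt = max_rt, ssd_mode = ssd_mode,
                 fixed_ssds = fixed_ssds,
                 n_zero_ssd_probes = as.integer(n_zero_ssd_probes),
                 iti = iti, iti_params = iti_params),
            class = "design_config")
}

#' Build a randomized trial-type sequence
#'
#' Produces exactly `round(n_trials * p_stop)` stop trials and the remainder
#' go trials in a uniformly random order, with any zero-SSD probe trials
#' interleaved at random positions as flagged extra stop trials.
#'
#' @param design A [design_config()].
#' @return Character vector over `{"go", "stop", "stop_probe"}`.
#' @examples
#' set.seed(7)
#' table(build_trial_sequence(design_config(n_trials = 200, p_stop = 0.25)))
#' @export
build_trial_sequence <- function(design) {
  stopifnot(inherits(design, "design_config"))
  n_stop <- round(design$n_trials * design$p_stop)
  core <- sample(rep(c("stop", "go"), c(n_stop, design$n_trials - n_stop)))
  if (design$n_zero_ssd_probes > 0) {
    out <- character(length(core) + design$n_zero_ssd_probes)
    pos <- sample(length(out), design$n_zero_ssd_probes)
    out[pos] <- "stop_probe"
    out[-pos] <- core
    out
  } else core
}

#' One staircase step
#'
#' Successful stop (no response): SSD moves up by one step; any response on a
#' stop trial, including premature responses and choice errors, moves it down
#' by one step. Clamped to the configured bounds.
#'
#' @param ssd Current SSD in ms.
#' @param responded `TRUE` if any response was emitted on the stop trial.
#' @param cfg A [staircase_config()].
#' @return Updated SSD in ms.
#' @examples
#' staircase_update(300, responded = FALSE, staircase_config()) # 350
#' staircase_update(0, responded = TRUE, staircase_config())    # clamped at 0
#' @export
staircase_update <- function(ssd, responded, cfg) {
  stopifnot(inherits(cfg, "staircase_config"), is.logical(responded))
  if (responded) max(ssd - cfg$step, cfg$min) else min(ssd + cfg$step, cfg$max)
}

#' Simulate one stop-signal session under the independent race model
#'
#' Each trial draws a go finishing time from the subject's go distribution
#' (absent with probability `p_go_failure`). On stop trials the stop runner's
#' finishing time is the current SSD plus a stop-latency draw, absent with
#' probability `p_trigger_failure` (a trigger failure). A response is
#' recorded iff the go runner started, finished before the stop runner (or
#' the stop runner never started), and beat the `max_rt` deadline. Go
#' failures also silence the go runner on stop trials (so those trials always
#' end as successful stops); set `go_failures_on_stop = FALSE` to restrict
#' go failures to go trials. In staircase mode one global tracker spans the
#' session's non-probe stop trials; zero-SSD probes are flagged and bypass
#' the tracker. Times are real-valued milliseconds throughout.
#'
#' @param subject A [subject_params()].
#' @param design A [design_config()].
#' @param stair A [staircase_config()] (staircase mode). Defaults to a
#'   200 ms start, 50 ms steps, and bounds `[0, max_rt - step]`.
#' @param subject_id,condition Labels stamped on every trial.
#' @param go_failures_on_stop Apply `p_go_failure` on stop trials as well.
#' @return An `sst_session`.
#' @export
simulate_session <- function(subject, design = design_config(),
                             stair = NULL, subject_id = "s1",
                             condition = "default",
                             go_failures_on_stop = TRUE) {
  stopifnot(inherits(subject, "subject_params"), inherits(design, "design_config"))
  if (is.null(stair))
    stair <- staircase_config(start = 200, step = 50, min = 0,
                              max = design$max_rt - 50)
  stopifnot(inherits(stair, "staircase_config"))

  types <- build_trial_sequence(design)
  n <- length(types)
  is_stop <- types != "go"
  is_probe <- types == "stop_probe"

  go_rt <- sample_exgaussian(subject$go, n)
  go_started <- stats::runif(n) >= subject$p_go_failure
  stop_lat <- sample_exgaussian(subject$stop, n)
  stop_triggered <- stats::runif(n) >= subject$p_trigger_failure
  choice_err <- stats::runif(n) < subject$p_choice_error
  if (!go_failures_on_stop) go_started[is_stop] <- TRUE

  ssd <- rep(NA_real_, n)
  responded <- logical(n)
  cur <- stair$start
  fixed_i <- 0L
  for (i in seq_len(n)) {
    if (!is_stop[i]) {
      responded[i] <- go_started[i] && go_rt[i] <= design$max_rt
      next
    }
    if (is_probe[i]) d <- 0
    else if (design$ssd_mode == "staircase") d <- cur
    else {
      fixed_i <- fixed_i + 1L
      d <- design$fixed_ssds[((fixed_i - 1L) %% length(design$fixed_ssds)) + 1L]
    }
    ssd[i] <- d
    go_wins <- go_started[i] && go_rt[i] <= design$max_rt &&
      (!stop_triggered[i] || go_rt[i] < d + stop_lat[i])
    responded[i] <- go_wins
    if (!is_probe[i] && design$ssd_mode == "staircase")
      cur <- staircase_update(d, responded[i], stair)
  }

  resp_lab <- ifelse(responded, ifelse(choice_err, "choice-2", "choice-1"),
                     "none")
  trials <- data.frame(
    subject_id = subject_id, condition = condition, block = 0L,
    trial_index = seq_len(n) - 1L,
    trial_type = ifelse(is_stop, "stop", "go"),
    ssd_requested = ssd, ssd_real = ssd,
    response = resp_lab,
    rt = ifelse(responded, go_rt, NA_real_),
    choice_correct = ifelse(responded, !choice_err, NA),
    # before go onset on go trials; before the stop signal on stop trials
    premature = responded &
      (go_rt < 0 | (is_stop & !is.na(ssd) & go_rt < ssd)),
    zero_ssd_probe = is_probe,
    stringsAsFactors = FALSE)
  new_session(trials, max_rt = design$max_rt,
              metadata = list(ssd_mode = design$ssd_mode))
}

#' Population-level parameter distribution
#'
#' Between-subject variation for every subject-level parameter, used by the
#' Monte-Carlo study machinery: each field is drawn from an independent
#' Gaussian with the given mean and SD, truncated by rejection to the bounds
#' that keep the subject parameters valid (`sigma`, `tau` non-negative,
#' probabilities in `[0, 1]`, plus any user bounds).
#'
#' @param means Named list of field means. Fields: `go_mu`, `go_sigma`,
#'   `go_tau`, `stop_mu`, `stop_sigma`, `stop_tau`, `p_trigger_failure`,
#'   `p_go_failure`, `p_choice_error`.
#' @param sds Named list of between-subject SDs (0 = fixed across subjects).
#' @param bounds Named list of `c(lower, upper)` truncation bounds; defaults
#'   keep each field in its valid range.
#' @return An object of class `population_params`.
#' @export
population_params <- function(means = list(), sds = list(), bounds = list()) {
  fields <- c("go_mu", "go_sigma", "go_tau", "stop_mu", "stop_sigma",
              "stop_tau", "p_trigger_failure", "p_go_failure",
              "p_choice_error")
  def_means <- list(go_mu = 500, go_sigma = 50, go_tau = 50,
                    stop_mu = 200, stop_sigma = 30, stop_tau = 20,
                    p_trigger_failure = 0, p_go_failure = 0,
                    p_choice_error = 0)
  def_sds <- list(go_mu = 50, go_sigma = 10, go_tau = 10,
                  stop_mu = 20, stop_sigma = 5, stop_tau = 5,
                  p_trigger_failure = 0, p_go_failure = 0, p_choice_error = 0)
  def_bounds <- list(go_mu = c(0, Inf), go_sigma = c(1, Inf),
                     go_tau = c(0, Inf), stop_mu = c(0, Inf),
                     stop_sigma = c(1, Inf), stop_tau = c(0, Inf),
                     p_trigger_failure = c(0, 1), p_go_failure = c(0, 1),
                     p_choice_error = c(0, 1))
  means <- modifyList(def_means, means)
  sds <- modifyList(def_sds, sds)
  bounds <- modifyList(def_bounds, bounds)
  for (f in fields) {
    b <- bounds[[f]]
    if (means[[f]] < b[1] || means[[f]] > b[2])
      stop(sprintf("mean of '%s' (%g) lies outside its bounds [%g, %g]",
                   f, means[[f]], b[1], b[2]), call. = FALSE)
    if (sds[[f]] < 0) stop("between-subject SDs must be >= 0", call. = FALSE)
  }
  structure(list(means = means[fields], sds = sds[fields],
                 bounds = bounds[fields]),
            class = "population_params")
}

#' Sample a roster of subjects from a population
#'
#' Independent truncated-Gaussian draws per field (rejection sampling), so
#' every returned [subject_params()] is valid. Deterministic under a fixed
#' RNG state.
#'
#' @param pop A [population_params()].
#' @param n_subjects Number of subjects, `>= 1`.
#' @return List of `subject_params`.
#' @export
sample_population <- function(pop, n_subjects) {
  stopifnot(inherits(pop, "population_params"), n_subjects >= 1)
  draw <- function(f) {
    m <- pop$means[[f]]; s <- pop$sds[[f]]; b <- pop$bounds[[f]]
    if (s == 0) return(rep(m, n_subjects))
    x <- stats::rnorm(n_subjects, m, s)
    bad <- which(x < b[1] | x > b[2])
    guard <- 0L
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), m, s)
      bad <- bad[x[bad] < b[1] | x[bad] > b[2]]
      guard <- guard + 1L
      if (guard > 10000L) { x[bad] <- pmin(pmax(x[bad], b[1]), b[2]); break }
    }
    x
  }
  vals <- lapply(stats::setNames(names(pop$means), names(pop$means)), draw)
  lapply(seq_len(n_subjects), function(i) subject_params(
    go = exgauss_params(vals$go_mu[i], vals$go_sigma[i], vals$go_tau[i]),
    stop = exgauss_params(vals$stop_mu[i], vals$stop_sigma[i],
                          vals$stop_tau[i]),
    p_trigger_failure = vals$p_trigger_failure[i],
    p_go_failure = vals$p_go_failure[i],
    p_choice_error = vals$p_choice_error[i]))
}
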
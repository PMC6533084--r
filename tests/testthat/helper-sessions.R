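# Build small hand-specified sessions for estimator tests.
#
# go_rts: RTs of responded go trials (NA entries become omissions);
# stop_ssd / stop_rt: one entry per stop trial, stop_rt NA = successful stop;
# go_correct: per responded go trial, default all correct.
toy_session <- function(go_rts = numeric(0), stop_ssd = numeric(0),
                        stop_rt = rep(NA_real_, length(stop_ssd)),
                        go_correct = NULL, probe_responded = logical(0),
                        max_rt = 1500, subject_id = "s1",
                        condition = "default") {
  n_go <- length(go_rts)
  n_stop <- length(stop_ssd)
  n_probe <- length(probe_responded)
  if (is.null(go_correct)) go_correct <- rep(TRUE, n_go)
  rows <- list()
  if (n_go) rows$go <- data.frame(
    trial_type = "go", ssd_requested = NA_real_, ssd_real = NA_real_,
    response = ifelse(is.na(go_rts), "none",
                      ifelse(go_correct, "choice-1", "choice-2")),
    rt = go_rts, choice_correct = ifelse(is.na(go_rts), NA, go_correct),
    premature = !is.na(go_rts) & go_rts < 0, zero_ssd_probe = FALSE,
    stringsAsFactors = FALSE)
  if (n_stop) rows$stop <- data.frame(
    trial_type = "stop", ssd_requested = stop_ssd, ssd_real = stop_ssd,
    response = ifelse(is.na(stop_rt), "none", "choice-1"),
    rt = stop_rt, choice_correct = ifelse(is.na(stop_rt), NA, TRUE),
    premature = !is.na(stop_rt) & stop_rt < stop_ssd,
    zero_ssd_probe = FALSE, stringsAsFactors = FALSE)
  if (n_probe) rows$probe <- data.frame(
    trial_type = "stop", ssd_requested = 0, ssd_real = 0,
    response = ifelse(probe_responded, "choice-1", "none"),
    rt = ifelse(probe_responded, 400, NA_real_),
    choice_correct = ifelse(probe_responded, TRUE, NA),
    premature = FALSE, zero_ssd_probe = TRUE, stringsAsFactors = FALSE)
  trials <- do.call(rbind, rows)
  trials$subject_id <- subject_id
  trials$condition <- condition
  trials$block <- 0L
  trials$trial_index <- seq_len(nrow(trials)) - 1L
  new_session(trials, max_rt = max_rt)
}

# the worked 10-RT go distribution used across estimator tests
toy_go_rts <- function() seq(400, 580, by = 20)
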
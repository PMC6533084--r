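#' Consensus descriptive summary of one session
#'
#' Computes the full check-list of descriptive statistics that a stop-signal
#' study should report for each group and condition: go-omission probability,
#' choice-error probability on go trials, go RT (mean, median, and
#' intra-subject variability), p(respond|signal) (overall, and per SSD for
#' fixed-delay designs), mean SSD, SSRT, and the mean RT of go responses on
#' unsuccessful stop trials. The same inclusion rules as estimation apply
#' (zero-SSD probes excluded; probe response rate reported separately as a
#' trigger-failure diagnostic). For an excluded subject the directly
#' observable quantities are still reported; only SSRT is absent.
#'
#' Denominators differ deliberately: the go-omission probability is over all
#' go trials, the choice-error probability over responded go trials only (an
#' omission is not a choice error).
#'
#' @param session An `sst_session` (one subject, one condition).
#' @param estimate An `ssrt_estimate`, or `NULL` when estimation was skipped.
#' @param decision An `exclusion_decision` from [apply_exclusions()].
#' @param variability `"sd"` (default) or `"iqr"` for the intra-subject
#'   go-RT spread.
#' @return An object of class `box_summary` (a one-row data frame).
#' @export
summarize_session <- function(session, estimate = NULL,
                              decision = apply_exclusions(session),
                              variability = c("sd", "iqr")) {
  variability <- match.arg(variability)
  stopifnot(inherits(session, "sst_session"),
            inherits(decision, "exclusion_decision"))
  go <- .go_trials(session)
  st <- .stop_trials(session)
  probes <- .stop_trials(session, include_probes = TRUE)
  probes <- probes[probes$zero_ssd_probe, , drop = FALSE]
  go_resp <- go$rt[.responded(go)]
  spread <- function(x) {
    if (!length(x)) return(NA_real_)
    if (variability == "sd") stats::sd(x) else stats::IQR(x)
  }
  has_stop <- nrow(st) > 0
  ssrt <- if (!decision$excluded && !is.null(estimate)) estimate$value
          else NA_real_
  usrt <- st$rt[.responded(st)]
  out <- data.frame(
    subject_id = if (nrow(session$trials)) session$trials$subject_id[1L]
                 else NA_character_,
    condition = if (nrow(session$trials)) session$trials$condition[1L]
                else NA_character_,
    n_go = nrow(go), n_stop = nrow(st), n_zero_ssd_probe = nrow(probes),
    p_go_omission = if (nrow(go)) mean(!.responded(go)) else NA_real_,
    p_choice_error_go = if (length(go_resp))
      mean(!go$choice_correct[.responded(go)], na.rm = TRUE) else NA_real_,
    go_rt_mean = if (length(go_resp)) mean(go_resp) else NA_real_,
    go_rt_median = if (length(go_resp)) stats::median(go_resp) else NA_real_,
    go_rt_spread = spread(go_resp),
    p_respond_signal = if (has_stop) mean(.responded(st)) else NA_real_,
    p_respond_probe = if (nrow(probes)) mean(.responded(probes)) else NA_real_,
    mean_ssd = if (has_stop) mean_ssd(session) else NA_real_,
    ssrt = ssrt,
    ssrt_method = if (!is.na(ssrt)) estimate$method else NA_character_,
    usrt_mean = if (length(usrt)) mean(usrt) else NA_real_,
    excluded = decision$excluded,
    exclusion_reasons = paste(decision$reasons, collapse = ";"),
    stringsAsFactors = FALSE)
  class(out) <- c("box_summary", class(out))
  out
}

#' Group-level aggregation of session summaries
#'
#' Means and SDs of every descriptive field per condition, with the count of
#' excluded subjects and a tally of exclusion reasons — studies must report
#' how many participants had no SSRT estimate and why.
#'
#' @param summaries A list of [summarize_session()] results, or a data frame
#'   row-binding them.
#' @return List with `table` (one row per condition: n, n_excluded, field
#'   means/SDs) and `exclusion_reasons` (reason tallies per condition).
#' @export
summarize_group <- function(summaries) {
  if (is.data.frame(summaries)) df <- summaries
  else {
    if (!length(summaries)) stop("no summaries to aggregate", call. = FALSE)
    df <- do.call(rbind, summaries)
  }
  if (!nrow(df)) stop("no summaries to aggregate", call. = FALSE)
  fields <- c("p_go_omission", "p_choice_error_go", "go_rt_mean",
              "go_rt_median", "go_rt_spread", "p_respond_signal",
              "mean_ssd", "ssrt", "usrt_mean")
  tab <- do.call(rbind, lapply(split(df, df$condition), function(d) {
    row <- data.frame(condition = d$condition[1L], n = nrow(d),
                      n_excluded = sum(d$excluded),
                      stringsAsFactors = FALSE)
    for (f in fields) {
      row[[paste0(f, "_mean")]] <- mean(d[[f]], na.rm = TRUE)
      row[[paste0(f, "_sd")]] <- stats::sd(d[[f]][!is.na(d[[f]])])
    }
    row
  }))
  rownames(tab) <- NULL
  reasons <- lapply(split(df, df$condition), function(d) {
    r <- unlist(strsplit(d$exclusion_reasons[d$excluded], ";", fixed = TRUE))
    if (!length(r)) table(character(0)) else table(r)
  })
  list(table = tab, exclusion_reasons = reasons)
}

#' Render a plain-text consensus report
#'
#' Human-readable report mirroring the consensus reporting check-list item
#' order, one block per subject-by-condition summary.
#'
#' @param summaries Data frame of [summarize_session()] rows.
#' @param file Optional path; when given the report is written there.
#' @return Character vector of report lines, invisibly when `file` is set.
#' @export
format_report <- function(summaries, file = NULL) {
  fmt <- function(x, d = 3) ifelse(is.na(x), "-", formatC(x, digits = d,
                                                          format = "fg"))
  lines <- character(0)
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    lines <- c(lines,
      sprintf("subject %s / condition %s", s$subject_id, s$condition),
      sprintf("  probability of go omissions:        %s", fmt(s$p_go_omission)),
      sprintf("  probability of go choice errors:    %s", fmt(s$p_choice_error_go)),
      sprintf("  go RT mean / median (ms):           %s / %s",
              fmt(s$go_rt_mean, 4), fmt(s$go_rt_median, 4)),
      sprintf("  go RT intra-subject spread (ms):    %s", fmt(s$go_rt_spread, 4)),
      sprintf("  p(respond|signal):                  %s", fmt(s$p_respond_signal)),
      if (!is.na(s$p_respond_probe))
        sprintf("  p(respond|signal), zero-SSD probes: %s",
                fmt(s$p_respond_probe)),
      sprintf("  mean SSD (ms):                      %s", fmt(s$mean_ssd, 4)),
      sprintf("  SSRT (ms):                          %s%s", fmt(s$ssrt, 4),
              if (s$excluded) sprintf("  [not estimated: %s]",
                                      s$exclusion_reasons) else ""),
      sprintf("  RT on unsuccessful stop trials:     %s", fmt(s$usrt_mean, 4)),
      "")
  }
  lines <- lines[!vapply(lines, is.null, logical(1))]
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
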
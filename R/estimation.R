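#' Probability of responding on stop trials
#'
#' The fraction of non-probe stop trials on which any response was emitted.
#' Premature responses and choice errors on stop trials count as responses;
#' zero-SSD probe trials are diagnostic only and are excluded from both the
#' numerator and the denominator.
#'
#' @param session An `sst_session` (one subject, one condition).
#' @return Probability in `[0, 1]`.
#' @export
p_respond_signal <- function(session) {
  st <- .stop_trials(session)
  if (!nrow(st))
    stop("no non-probe stop trials: p(respond|signal) undefined", call. = FALSE)
  mean(.responded(st))
}

#' Mean stop-signal delay
#'
#' Arithmetic mean of the real SSD (falling back to the requested SSD where
#' the real one is unrecorded) over non-probe stop trials.
#'
#' @inheritParams p_respond_signal
#' @return Milliseconds.
#' @export
mean_ssd <- function(session) {
  st <- .stop_trials(session)
  if (!nrow(st)) stop("no non-probe stop trials: mean SSD undefined",
                      call. = FALSE)
  ssd <- ifelse(is.na(st$ssd_real), st$ssd_requested, st$ssd_real)
  mean(ssd)
}

#' Rank of the go-RT order statistic used by the integration method
#'
#' The stop process's finishing time is located at the nth fastest go RT
#' with `n = n_go * p_respond`. A fractional product is resolved by rounding
#' half-up (`floor(x + 0.5)`) or, alternatively, rounding up; the result is
#' clamped to `[1, n_go]`.
#'
#' @param n_go Size of the go-RT distribution (responses plus any replaced
#'   omissions), `>= 1`.
#' @param p_respond Overall p(respond|signal), in `(0, 1]`.
#' @param rounding `"half_up"` (default) or `"ceiling"`.
#' @return Integer rank.
#' @examples
#' nth_rt_index(200, 0.45) # 90
#' @export
nth_rt_index <- function(n_go, p_respond, rounding = c("half_up", "ceiling")) {
  rounding <- match.arg(rounding)
  stopifnot(is.numeric(n_go), n_go >= 1, is.numeric(p_respond))
  if (p_respond <= 0)
    stop("p(respond|signal) = 0: the integration rank is undefined",
         call. = FALSE)
  if (p_respond > 1) stop("p_respond must be <= 1", call. = FALSE)
  x <- n_go * p_respond
  r <- if (rounding == "half_up") floor(x + 0.5) else ceiling(x)
  as.integer(min(max(r, 1), n_go))
}

.new_estimate <- function(method, value, p_respond, mean_ssd, n_go,
                          rank_n = NA_integer_, n_replaced = 0L) {
  structure(list(method = method, value = value,
                 p_respond_signal = p_respond, mean_ssd = mean_ssd,
                 n_go_distribution = as.integer(n_go),
                 rank_n = rank_n, n_omissions_replaced = as.integer(n_replaced)),
            class = "ssrt_estimate")
}

#' @export
print.ssrt_estimate <- function(x, ...) {
  cat(sprintf("<ssrt_estimate> %s: SSRT = %.1f ms\n", x$method, x$value))
  cat(sprintf("  p(respond|signal) = %.3f, mean SSD = %.1f ms, n_go = %d",
              x$p_respond_signal, x$mean_ssd, x$n_go_distribution))
  if (!is.na(x$rank_n))
    cat(sprintf(", rank = %d, omissions replaced = %d",
                x$rank_n, x$n_omissions_replaced))
  cat("\n")
  invisible(x)
}

#' SSRT by the integration method (with replacement of go omissions)
#'
#' Integrates the go-RT distribution to the point where its cumulative
#' probability equals the overall p(respond|signal): the estimate is the nth
#' fastest go RT minus the mean SSD. The go-RT distribution contains every
#' go trial with a response — including choice errors and premature
#' responses, at their recorded RT — and, when `replace_omissions = TRUE`
#' (the consensus variant), one replacement value per go omission to
#' compensate for the missing slow responses. The replacement value is the
#' maximum observed go RT (`omission_rt = "max_observed"`) or the response
#' deadline (`"max_rt"`).
#'
#' @param session An `sst_session` (one subject, one condition).
#' @param replace_omissions Replace go omissions with the maximum RT.
#' @param omission_rt `"max_observed"` (default) or `"max_rt"`.
#' @param rounding Rank rounding rule, see [nth_rt_index()].
#' @return An `ssrt_estimate`.
#' @export
integration_ssrt <- function(session, replace_omissions = TRUE,
                             omission_rt = c("max_observed", "max_rt"),
                             rounding = "half_up") {
  omission_rt <- match.arg(omission_rt)
  go <- .go_trials(session)
  rts <- go$rt[.responded(go)]
  n_omit <- sum(!.responded(go))
  n_repl <- 0L
  if (replace_omissions && n_omit > 0) {
    repl <- if (omission_rt == "max_rt" || !length(rts)) session$max_rt
            else max(rts)
    rts <- c(rts, rep(repl, n_omit))
    n_repl <- n_omit
  }
  if (!length(rts))
    stop("empty go-RT distribution: cannot estimate SSRT", call. = FALSE)
  p <- p_respond_signal(session)
  if (p <= 0)
    stop("p(respond|signal) = 0: integration SSRT undefined", call. = FALSE)
  ssd <- mean_ssd(session)
  rank <- nth_rt_index(length(rts), p, rounding = rounding)
  nth <- sort(rts)[rank]
  .new_estimate(if (replace_omissions) "integration_replace"
                else "integration_noreplace",
                value = nth - ssd, p_respond = p, mean_ssd = ssd,
                n_go = length(rts), rank_n = rank, n_replaced = n_repl)
}

#' SSRT by the mean method
#'
#' Assumes the tracking procedure has converged so that mean go RT equals
#' SSRT plus mean SSD, and estimates SSRT as mean go RT (over responded go
#' trials) minus mean SSD. Simple, but biased by the right tail of the go-RT
#' distribution and by go omissions; retained for comparison with the
#' integration method.
#'
#' @inheritParams integration_ssrt
#' @return An `ssrt_estimate`.
#' @export
mean_method_ssrt <- function(session) {
  go <- .go_trials(session)
  rts <- go$rt[.responded(go)]
  if (!length(rts)) stop("no responded go trials: mean method undefined",
                         call. = FALSE)
  ssd <- mean_ssd(session)
  .new_estimate("mean", value = mean(rts) - ssd,
                p_respond = p_respond_signal(session), mean_ssd = ssd,
                n_go = length(rts))
}

#' Race-model independence check
#'
#' Under the independent race, responses that escape inhibition are drawn
#' from the fast side of the go-RT distribution, so the mean RT on
#' unsuccessful stop trials must not exceed the mean go RT. The comparison
#' includes all trials with a response (choice errors and premature
#' responses too) and is run per subject and condition. A violation is
#' declared only when the unsuccessful-stop mean is strictly greater.
#'
#' @param session An `sst_session` (one subject, one condition).
#' @return List with `applicable`, `violation`, `mean_usrt` (mean RT on
#'   unsuccessful stop trials, ms) and `mean_go_rt` (ms).
#' @export
independence_check <- function(session) {
  st <- .stop_trials(session)
  go <- .go_trials(session)
  usrt <- st$rt[.responded(st)]
  go_rt <- go$rt[.responded(go)]
  if (!length(usrt) || !length(go_rt))
    return(list(applicable = FALSE, violation = FALSE,
                mean_usrt = if (length(usrt)) mean(usrt) else NA_real_,
                mean_go_rt = if (length(go_rt)) mean(go_rt) else NA_real_))
  list(applicable = TRUE, violation = mean(usrt) > mean(go_rt),
       mean_usrt = mean(usrt), mean_go_rt = mean(go_rt))
}

#' Exclusion criteria for SSRT estimation
#'
#' The consensus validity rules: do not estimate SSRT when the race-model
#' independence check fails, when p(respond|signal) falls outside
#' `[p_low, p_high]` (defaults one quarter and three quarters, bounds
#' inclusive — only strict violations exclude), or when the go-omission
#' rate exceeds a study-set ceiling.
#'
#' @param p_low,p_high Acceptable p(respond|signal) range.
#' @param max_go_omission_rate Maximum tolerated go-omission rate (default 1,
#'   i.e. no omission-based exclusion unless the study sets one).
#' @param require_independence Run the race-model independence check.
#' @return An object of class `exclusion_criteria`.
#' @export
exclusion_criteria <- function(p_low = 0.25, p_high = 0.75,
                               max_go_omission_rate = 1,
                               require_independence = TRUE) {
  stopifnot(0 <= p_low, p_low < p_high, p_high <= 1,
            max_go_omission_rate >= 0, max_go_omission_rate <= 1)
  structure(list(p_low = p_low, p_high = p_high,
                 max_go_omission_rate = max_go_omission_rate,
                 require_independence = isTRUE(require_independence)),
            class = "exclusion_criteria")
}

#' Decide whether a session is excluded from SSRT estimation
#'
#' Evaluates, in order: the independence check, the p(respond|signal) range,
#' and the go-omission-rate ceiling; every failing reason is listed, and a
#' session with no usable stop trials is flagged as such. The decision is a
#' plain report — estimation callers must skip excluded sessions; observable
#' quantities are still reported for them.
#'
#' @param session An `sst_session` (one subject, one condition).
#' @param criteria An [exclusion_criteria()].
#' @return An object of class `exclusion_decision`: `excluded`, `reasons`
#'   (subset of `independence_violation`, `p_respond_out_of_range`,
#'   `go_omission_rate`, `no_stop_trials`), `p_respond_signal`,
#'   `go_omission_rate`, `mean_usrt`, `mean_go_rt`.
#' @export
apply_exclusions <- function(session, criteria = exclusion_criteria()) {
  stopifnot(inherits(criteria, "exclusion_criteria"))
  reasons <- character(0)
  st <- .stop_trials(session)
  go <- .go_trials(session)
  indep <- independence_check(session)
  p <- if (nrow(st)) mean(.responded(st)) else NA_real_
  omit <- if (nrow(go)) mean(!.responded(go)) else NA_real_
  if (!nrow(st)) reasons <- c(reasons, "no_stop_trials")
  if (criteria$require_independence && indep$applicable && indep$violation)
    reasons <- c(reasons, "independence_violation")
  if (!is.na(p) && (p < criteria$p_low || p > criteria$p_high))
    reasons <- c(reasons, "p_respond_out_of_range")
  if (!is.na(omit) && omit > criteria$max_go_omission_rate)
    reasons <- c(reasons, "go_omission_rate")
  structure(list(excluded = length(reasons) > 0L, reasons = reasons,
                 p_respond_signal = p, go_omission_rate = omit,
                 mean_usrt = indep$mean_usrt, mean_go_rt = indep$mean_go_rt),
            class = "exclusion_decision")
}

#' @export
print.exclusion_decision <- function(x, ...) {
  if (x$excluded)
    cat("<exclusion_decision> EXCLUDED:", paste(x$reasons, collapse = ", "), "\n")
  else cat("<exclusion_decision> included\n")
  invisible(x)
}

#' Empirical inhibition function
#'
#' The probability of responding on stop trials as a function of the
#' stop-signal delay; under the race model it is non-decreasing in SSD.
#' Meant for fixed-delay designs; for staircase data the observed delays can
#' be binned first via `bin_width`. Zero-SSD probe trials are excluded by
#' default and can be inspected separately.
#'
#' @param session An `sst_session`.
#' @param bin_width Optional bin width in ms; delays are grouped by
#'   `floor(ssd / bin_width) * bin_width`.
#' @param include_probes Include zero-SSD probe trials.
#' @return Data frame with columns `ssd`, `n_stop`, `n_respond`, `p_respond`,
#'   ordered by `ssd`.
#' @export
inhibition_function <- function(session, bin_width = NULL,
                                include_probes = FALSE) {
  st <- .stop_trials(session, include_probes = include_probes)
  if (!nrow(st))
    return(data.frame(ssd = numeric(0), n_stop = integer(0),
                      n_respond = integer(0), p_respond = numeric(0)))
  ssd <- ifelse(is.na(st$ssd_real), st$ssd_requested, st$ssd_real)
  if (!is.null(bin_width)) ssd <- floor(ssd / bin_width) * bin_width
  resp <- .responded(st)
  agg <- stats::aggregate(resp, by = list(ssd = ssd),
                          FUN = function(z) c(n = length(z), k = sum(z)))
  out <- data.frame(ssd = agg$ssd, n_stop = as.integer(agg$x[, "n"]),
                    n_respond = as.integer(agg$x[, "k"]))
  out$p_respond <- out$n_respond / out$n_stop
  out[order(out$ssd), , drop = FALSE]
}

#' Estimate SSRT for every subject-by-condition cell of a data set
#'
#' Applies the exclusion rules, then (for included cells only) both
#' non-parametric estimators, returning one row per subject and condition.
#' Excluded cells keep their observable quantities and the reasons they were
#' excluded; their SSRT columns are `NA`.
#'
#' @param session An `sst_session`, possibly holding many subjects.
#' @param criteria An [exclusion_criteria()].
#' @param omission_rt Replacement-RT rule for [integration_ssrt()].
#' @param rounding Rank rounding rule for [nth_rt_index()].
#' @return Data frame with one row per subject x condition: identifiers,
#'   exclusion status/reasons, `p_respond_signal`, `mean_ssd`,
#'   `ssrt_integration`, `ssrt_mean`, `mean_go_rt`, `mean_usrt`,
#'   `go_omission_rate`.
#' @export
estimate_all <- function(session, criteria = exclusion_criteria(),
                         omission_rt = "max_observed",
                         rounding = "half_up") {
  cells <- split_session(session)
  rows <- lapply(cells, function(s) {
    id <- s$trials$subject_id[1L]
    cond <- s$trials$condition[1L]
    dec <- apply_exclusions(s, criteria)
    has_stop <- nrow(.stop_trials(s)) > 0
    ssrt_i <- ssrt_m <- NA_real_
    mssd <- if (has_stop) mean_ssd(s) else NA_real_
    if (!dec$excluded) {
      ssrt_i <- tryCatch(
        integration_ssrt(s, omission_rt = omission_rt,
                         rounding = rounding)$value,
        error = function(e) NA_real_)
      ssrt_m <- tryCatch(mean_method_ssrt(s)$value,
                         error = function(e) NA_real_)
    }
    data.frame(subject_id = id, condition = cond,
               excluded = dec$excluded,
               reasons = paste(dec$reasons, collapse = ";"),
               p_respond_signal = dec$p_respond_signal,
               mean_ssd = mssd,
               ssrt_integration = ssrt_i, ssrt_mean = ssrt_m,
               mean_go_rt = dec$mean_go_rt, mean_usrt = dec$mean_usrt,
               go_omission_rate = dec$go_omission_rate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$condition), , drop = FALSE]
}
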
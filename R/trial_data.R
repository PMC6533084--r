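#' @importFrom utils read.csv write.csv modifyList
NULL

.trial_cols <- c("subject_id", "condition", "block", "trial_index",
                 "trial_type", "ssd_requested", "ssd_real", "response",
                 "rt", "choice_correct", "premature", "zero_ssd_probe")

#' Construct a stop-signal session
#'
#' A session is the canonical container for one (or more) subjects' trial-level
#' stop-signal data: a data frame with one row per trial, the response
#' deadline `max_rt`, and free-form metadata. Reaction times are milliseconds
#' from go-stimulus onset on all trials, including stop trials, so a premature
#' stop-trial response can carry an RT shorter than the stop-signal delay.
#' Missing values (no response, no delay on go trials) are `NA`, never a
#' numeric sentinel, because both `rt = 0` and `ssd = 0` are meaningful.
#'
#' @param trials Data frame with columns `subject_id`, `condition`, `block`,
#'   `trial_index`, `trial_type` (`"go"`/`"stop"`), `ssd_requested`,
#'   `ssd_real`, `response` (`"none"` or a choice label), `rt`,
#'   `choice_correct`, `premature`, `zero_ssd_probe`. Missing columns are
#'   filled with sensible defaults where possible.
#' @param max_rt Response deadline in ms (`> 0`).
#' @param metadata Named list of free-form key/value pairs.
#' @return An object of class `sst_session`.
#' @seealso [read_trials()], [write_trials()], [validate_session()]
#' @export
new_session <- function(trials, max_rt, metadata = list()) {
  stopifnot(is.data.frame(trials), is.numeric(max_rt), length(max_rt) == 1L)
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  n <- nrow(trials)
  defaults <- list(
    subject_id = "s1", condition = "default", block = 0L,
    trial_index = if (n) seq_len(n) - 1L else integer(0),
    ssd_requested = NA_real_, ssd_real = NA_real_,
    response = "none", rt = NA_real_, choice_correct = NA,
    premature = FALSE, zero_ssd_probe = FALSE)
  for (col in .trial_cols) {
    if (!col %in% names(trials)) {
      if (col %in% names(defaults)) trials[[col]] <- rep_len(defaults[[col]], n)
      else stop(sprintf("trials is missing mandatory column '%s'", col),
                call. = FALSE)
    }
  }
  trials$subject_id <- as.character(trials$subject_id)
  trials$condition <- as.character(trials$condition)
  trials$block <- as.integer(trials$block)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$trial_type <- as.character(trials$trial_type)
  trials$response <- as.character(trials$response)
  for (col in c("ssd_requested", "ssd_real", "rt"))
    trials[[col]] <- as.numeric(trials[[col]])
  for (col in c("choice_correct", "premature", "zero_ssd_probe"))
    trials[[col]] <- as.logical(trials[[col]])
  trials$premature[is.na(trials$premature)] <- FALSE
  trials$zero_ssd_probe[is.na(trials$zero_ssd_probe)] <- FALSE
  structure(list(trials = trials[, .trial_cols], max_rt = as.numeric(max_rt),
                 metadata = metadata),
            class = "sst_session")
}

#' @export
print.sst_session <- function(x, ...) {
  tt <- x$trials$trial_type
  cat(sprintf(
    "<sst_session> %d trials (%d go, %d stop, %d zero-SSD probes), max_rt = %g ms\n",
    nrow(x$trials), sum(tt == "go"), sum(tt == "stop"),
    sum(x$trials$zero_ssd_probe), x$max_rt))
  invisible(x)
}

# stop trials entering estimation: probes are diagnostic only
.stop_trials <- function(session, include_probes = FALSE) {
  tr <- session$trials
  keep <- tr$trial_type == "stop"
  if (!include_probes) keep <- keep & !tr$zero_ssd_probe
  tr[keep, , drop = FALSE]
}

.go_trials <- function(session) {
  tr <- session$trials
  tr[tr$trial_type == "go", , drop = FALSE]
}

.responded <- function(trials) trials$response != "none"

#' Read trial-level stop-signal data from a delimited file
#'
#' Reads a comma-delimited UTF-8 file with a header row into an
#' [new_session()] container. Leading lines of the form `# key=value` carry
#' session-level metadata (`max_rt` in particular) and are written by
#' [write_trials()]; foreign files without them can pass `max_rt` explicitly.
#' A `column_map` translates third-party column layouts onto the canonical
#' schema; the mapped columns must at least cover trial type, response, RT
#' and SSD. Empty RT cells with an empty/`none` response are coded as go
#' omissions (`response = "none"`, `rt` absent).
#'
#' @param path File to read.
#' @param column_map Optional named character vector `canonical = file_column`.
#'   The alias `ssd` maps one file column onto both `ssd_requested` and
#'   `ssd_real`.
#' @param max_rt Response deadline in ms; overrides any value found in the
#'   file's metadata lines. Required (error) if the file has none.
#' @return An `sst_session`.
#' @export
read_trials <- function(path, column_map = NULL, max_rt = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list()
  n_meta <- 0L
  while (n_meta < length(lines) && startsWith(lines[n_meta + 1L], "#")) {
    n_meta <- n_meta + 1L
    kv <- sub("^#\\s*", "", lines[n_meta])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }
  raw <- read.csv(text = lines[seq.int(n_meta + 1L, length(lines))],
                  stringsAsFactors = FALSE, colClasses = "character")
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop(sprintf("column map refers to missing column '%s'", src),
             call. = FALSE)
      if (canon == "ssd") {
        raw$ssd_requested <- raw[[src]]
        raw$ssd_real <- raw[[src]]
      } else raw[[canon]] <- raw[[src]]
    }
  }
  mandatory <- c("trial_type", "response", "rt")
  missing_cols <- setdiff(mandatory, names(raw))
  if (!any(c("ssd_requested", "ssd_real") %in% names(raw)))
    missing_cols <- c(missing_cols, "ssd")
  if (length(missing_cols))
    stop(sprintf("format error: missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (!"ssd_real" %in% names(raw)) raw$ssd_real <- raw$ssd_requested
  if (!"ssd_requested" %in% names(raw)) raw$ssd_requested <- raw$ssd_real

  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  num_or_na <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    out[blank(x)] <- NA_real_
    bad <- which(!blank(x) & is.na(out))
    if (length(bad))
      stop(sprintf("row %d: non-numeric %s value '%s'", bad[1L], what,
                   x[bad[1L]]), call. = FALSE)
    out
  }
  rt <- num_or_na(raw$rt, "rt")
  ssd_req <- num_or_na(raw$ssd_requested, "ssd_requested")
  ssd_real <- num_or_na(raw$ssd_real, "ssd_real")
  response <- raw$response
  response[blank(response)] <- "none"
  # a blank-RT row with a recorded response has no usable latency: keep the
  # response label, rt stays NA; validate_session reports the inconsistency
  is_stop <- raw$trial_type == "stop"
  no_ssd <- which(is_stop & is.na(ssd_req) & is.na(ssd_real))
  if (length(no_ssd))
    stop(sprintf("row %d: stop trial without an SSD", no_ssd[1L]),
         call. = FALSE)

  lg <- function(col, default) {
    if (!col %in% names(raw)) return(rep(default, nrow(raw)))
    v <- toupper(trimws(raw[[col]]))
    out <- rep(NA, nrow(raw))
    out[v %in% c("TRUE", "T", "1")] <- TRUE
    out[v %in% c("FALSE", "F", "0")] <- FALSE
    out[blank(raw[[col]])] <- NA
    out
  }
  trials <- data.frame(
    subject_id = if ("subject_id" %in% names(raw)) raw$subject_id else "s1",
    condition = if ("condition" %in% names(raw)) raw$condition else "default",
    block = if ("block" %in% names(raw))
      as.integer(num_or_na(raw$block, "block")) else 0L,
    trial_index = if ("trial_index" %in% names(raw))
      as.integer(num_or_na(raw$trial_index, "trial_index"))
      else seq_len(nrow(raw)) - 1L,
    trial_type = raw$trial_type,
    ssd_requested = ssd_req, ssd_real = ssd_real,
    response = response, rt = rt,
    choice_correct = lg("choice_correct", NA),
    premature = lg("premature", FALSE),
    zero_ssd_probe = lg("zero_ssd_probe", FALSE),
    stringsAsFactors = FALSE)

  if (is.null(max_rt)) {
    if (!is.null(meta$max_rt)) max_rt <- as.numeric(meta$max_rt)
    else stop("max_rt not found in file metadata; pass max_rt=", call. = FALSE)
  }
  meta$max_rt <- NULL
  new_session(trials, max_rt = max_rt, metadata = meta)
}

#' Write a session to a delimited file
#'
#' Writes the canonical comma-delimited layout with `# key=value` metadata
#' lines (always including `max_rt`) ahead of the header. Absent values are
#' written as empty cells, never as zeros, so a round trip through
#' [read_trials()] reproduces the session field-for-field. The session must
#' pass [validate_session()] with no structural errors.
#'
#' @param session An `sst_session`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(session, path) {
  stopifnot(inherits(session, "sst_session"))
  rep_ <- validate_session(session)
  if (length(rep_$structural_errors))
    stop(sprintf("session has structural errors (first: %s)",
                 rep_$structural_errors[1L]), call. = FALSE)
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e)
                    stop(sprintf("cannot write to '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  on.exit(close(con))
  writeLines(sprintf("# max_rt=%.17g", session$max_rt), con)
  for (k in names(session$metadata))
    writeLines(sprintf("# %s=%s", k, as.character(session$metadata[[k]])), con)
  out <- session$trials
  for (col in c("ssd_requested", "ssd_real", "rt"))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.17g", out[[col]]))
  write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Structural validation of a session
#'
#' Checks every structural invariant of the trial schema and returns a report
#' rather than throwing: go trials carry no SSD and stop trials do; an RT is
#' present exactly when a response is; real SSDs are non-negative; RTs do not
#' exceed the deadline; trial indices increase within subject and block; and
#' zero-SSD probe trials are stop trials with a requested delay of 0. Probe
#' trials are counted separately because they are diagnostic only and never
#' enter SSD averaging or SSRT estimation.
#'
#' @param session An `sst_session`.
#' @return An object of class `sst_validation` with counts `n_go`, `n_stop`,
#'   `n_zero_ssd_probe` and character vectors `structural_errors`, `warnings`.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "sst_session"))
  tr <- session$trials
  errs <- character(0)
  warns <- character(0)
  bad_type <- which(!tr$trial_type %in% c("go", "stop"))
  for (i in bad_type)
    errs <- c(errs, sprintf("row %d: unknown trial_type '%s'", i, tr$trial_type[i]))
  if (!is.finite(session$max_rt) || session$max_rt <= 0)
    errs <- c(errs, sprintf("max_rt must be > 0 (got %g)", session$max_rt))
  is_go <- tr$trial_type == "go"
  i <- which(is_go & (!is.na(tr$ssd_requested) | !is.na(tr$ssd_real)))
  for (j in i) errs <- c(errs, sprintf("row %d: go trial carries an SSD", j))
  i <- which(!is_go & tr$trial_type == "stop" &
               is.na(tr$ssd_requested) & is.na(tr$ssd_real))
  for (j in i) errs <- c(errs, sprintf("row %d: stop trial without an SSD", j))
  i <- which(is.na(tr$rt) != (tr$response == "none"))
  for (j in i)
    errs <- c(errs, sprintf("row %d: rt present/absent inconsistent with response", j))
  i <- which(!is.na(tr$ssd_real) & tr$ssd_real < 0)
  for (j in i) errs <- c(errs, sprintf("row %d: negative ssd_real", j))
  i <- which(!is.na(tr$rt) & tr$rt > session$max_rt)
  for (j in i)
    errs <- c(errs, sprintf("row %d: rt %g exceeds max_rt %g", j, tr$rt[j],
                            session$max_rt))
  i <- which(tr$zero_ssd_probe &
               (tr$trial_type != "stop" |
                  is.na(tr$ssd_requested) | tr$ssd_requested != 0))
  for (j in i)
    errs <- c(errs, sprintf("row %d: zero_ssd_probe must be a stop trial with ssd_requested = 0", j))
  i <- which(!is.na(tr$rt) & tr$rt < 0 & !tr$premature)
  for (j in i)
    warns <- c(warns, sprintf("row %d: negative rt without premature flag", j))
  if (nrow(tr)) {
    for (key in split(seq_len(nrow(tr)),
                      list(tr$subject_id, tr$block), drop = TRUE)) {
      idx <- tr$trial_index[key]
      if (any(diff(idx) <= 0))
        errs <- c(errs, sprintf(
          "subject %s block %d: trial_index not strictly increasing",
          tr$subject_id[key[1L]], tr$block[key[1L]]))
    }
  }
  structure(list(n_go = sum(is_go),
                 n_stop = sum(tr$trial_type == "stop"),
                 n_zero_ssd_probe = sum(tr$zero_ssd_probe),
                 structural_errors = errs, warnings = warns),
            class = "sst_validation")
}

#' @export
print.sst_validation <- function(x, ...) {
  cat(sprintf("<sst_validation> %d go, %d stop (%d probes); %d error(s), %d warning(s)\n",
              x$n_go, x$n_stop, x$n_zero_ssd_probe,
              length(x$structural_errors), length(x$warnings)))
  for (e in x$structural_errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Split a multi-subject session by subject and condition
#'
#' Estimation and reporting are always performed per subject and condition,
#' never on pooled data. This helper splits a session container into a list
#' of single-cell sessions sharing the parent's deadline and metadata.
#'
#' @param session An `sst_session`.
#' @return Named list of `sst_session` objects, names `subject.condition`.
#' @export
split_session <- function(session) {
  stopifnot(inherits(session, "sst_session"))
  tr <- session$trials
  parts <- split(tr, list(tr$subject_id, tr$condition), drop = TRUE, sep = ".")
  lapply(parts, function(d)
    new_session(d, max_rt = session$max_rt, metadata = session$metadata))
}
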
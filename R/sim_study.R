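# seeds for cells/subjects are derived from a master seed; keep them in
# [1, 2^31 - 1] so they stay valid R integers
.derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 16807) %% 2147483647L) + 1L
}

#' Specification of one Monte-Carlo simulation cell
#'
#' One cell of a factorial estimator study: a population of subjects, a
#' session design (derived from the number of stop trials and the
#' stop-signal proportion), the estimators to compare, and replication
#' counts. The bias factors of interest — go-failure rate and go skew
#' `tau_go` — override the corresponding population means.
#'
#' @param n_stop_trials Non-probe stop trials per session.
#' @param p_stop Stop-signal probability (total trials =
#'   `n_stop_trials / p_stop`).
#' @param p_go_failure Go-failure probability (the go-omission factor).
#' @param tau_go Mean go-RT skew parameter in ms.
#' @param population A [population_params()]; `p_go_failure` and `tau_go`
#'   override its means.
#' @param n_subjects Simulated participants per replication.
#' @param n_replications Monte-Carlo replications.
#' @param estimators Subset of `"integration_replace"`,
#'   `"integration_noreplace"`, `"mean"`.
#' @param master_seed Integer seed from which all cell randomness derives.
#' @param criteria [exclusion_criteria()] applied before estimation.
#' @param max_rt Response deadline in ms.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(n_stop_trials = 50, p_stop = 0.25, p_go_failure = 0,
                      tau_go = 50, population = population_params(),
                      n_subjects = 25, n_replications = 10,
                      estimators = c("integration_replace", "mean"),
                      master_seed = 1L,
                      criteria = exclusion_criteria(),
                      max_rt = 1500) {
  stopifnot(n_stop_trials >= 1, n_subjects >= 1, n_replications >= 1,
            p_stop > 0, p_stop < 1)
  estimators <- match.arg(estimators,
                          c("integration_replace", "integration_noreplace",
                            "mean"), several.ok = TRUE)
  population$means$p_go_failure <- p_go_failure
  population$means$go_tau <- tau_go
  structure(list(n_stop_trials = as.integer(n_stop_trials), p_stop = p_stop,
                 p_go_failure = p_go_failure, tau_go = tau_go,
                 population = population, n_subjects = as.integer(n_subjects),
                 n_replications = as.integer(n_replications),
                 estimators = estimators,
                 master_seed = as.integer(master_seed),
                 criteria = criteria, max_rt = max_rt),
            class = "cell_spec")
}

.estimate_by_name <- function(name, session) {
  switch(name,
         integration_replace = integration_ssrt(session, TRUE),
         integration_noreplace = integration_ssrt(session, FALSE),
         mean = mean_method_ssrt(session),
         stop(sprintf("unknown estimator '%s'", name), call. = FALSE))$value
}

#' Run one simulation cell
#'
#' For each replication: sample a subject roster from the population,
#' simulate one tracked session per subject, apply the exclusion rules
#' *before* estimation (so the excluded count is shared by all estimators),
#' then estimate SSRT for every included subject with every estimator.
#' Bias is estimated minus true SSRT (`stop_mu + stop_tau` of the generating
#' subject); reliability is the linear (optionally rank) correlation of
#' estimated with true SSRT across included subjects, pooled over
#' replications. Replications in which fewer than 3 subjects survive
#' exclusion contribute to bias but not to the correlation; replications
#' with no included subjects are flagged and counted, never silently
#' dropped.
#'
#' @param spec A [cell_spec()].
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `cell_result`: `n_excluded`,
#'   `frac_excluded`, `n_flagged_replications`, and per estimator
#'   `bias_mean`, `bias_sd`, `correlation_true`; also the raw per-subject
#'   table in `$subjects`.
#' @export
run_cell <- function(spec, cor_method = c("pearson", "spearman")) {
  stopifnot(inherits(spec, "cell_spec"))
  cor_method <- match.arg(cor_method)
  n_total <- round(spec$n_stop_trials / spec$p_stop)
  design <- design_config(n_trials = n_total, p_stop = spec$p_stop,
                          max_rt = spec$max_rt)
  rows <- vector("list", spec$n_replications * spec$n_subjects)
  flagged <- 0L
  k <- 0L
  for (r in seq_len(spec$n_replications)) {
    set.seed(.derive_seed(spec$master_seed, r))
    roster <- sample_population(spec$population, spec$n_subjects)
    any_included <- FALSE
    for (s in seq_along(roster)) {
      subj <- roster[[s]]
      session <- simulate_session(subj, design,
                                  subject_id = sprintf("r%d_s%d", r, s))
      dec <- apply_exclusions(session, spec$criteria)
      est <- rep(NA_real_, length(spec$estimators))
      if (!dec$excluded) {
        any_included <- TRUE
        est <- vapply(spec$estimators, .estimate_by_name, numeric(1),
                      session = session)
      }
      k <- k + 1L
      row <- data.frame(replication = r, subject = s,
                        true_ssrt = true_ssrt(subj),
                        excluded = dec$excluded,
                        stringsAsFactors = FALSE)
      for (j in seq_along(spec$estimators))
        row[[spec$estimators[j]]] <- est[j]
      rows[[k]] <- row
    }
    if (!any_included) flagged <- flagged + 1L
  }
  subjects <- do.call(rbind, rows)
  inc <- subjects[!subjects$excluded, , drop = FALSE]
  res <- list(n_excluded = sum(subjects$excluded),
              frac_excluded = mean(subjects$excluded),
              n_flagged_replications = flagged,
              estimators = spec$estimators, subjects = subjects)
  # correlations only pool replications with >= 3 included subjects
  inc_cor <- inc[ave(inc$replication, inc$replication,
                     FUN = length) >= 3, , drop = FALSE]
  for (e in spec$estimators) {
    d <- inc[[e]] - inc$true_ssrt
    res[[paste0("bias_mean_", e)]] <- if (length(d)) mean(d) else NA_real_
    res[[paste0("bias_sd_", e)]] <- if (length(d) > 1) stats::sd(d) else NA_real_
    res[[paste0("correlation_", e)]] <-
      if (nrow(inc_cor) >= 3 && stats::sd(inc_cor$true_ssrt) > 0)
        stats::cor(inc_cor[[e]], inc_cor$true_ssrt, method = cor_method)
      else NA_real_
  }
  class(res) <- "cell_result"
  res
}

#' @export
print.cell_result <- function(x, ...) {
  cat(sprintf("<cell_result> %d/%d subjects excluded (%.1f%%), %d flagged replication(s)\n",
              x$n_excluded, nrow(x$subjects), 100 * x$frac_excluded,
              x$n_flagged_replications))
  for (e in x$estimators)
    cat(sprintf("  %-22s bias %7.2f ms (SD %.2f), r(true) = %s\n", e,
                x[[paste0("bias_mean_", e)]], x[[paste0("bias_sd_", e)]],
                formatC(x[[paste0("correlation_", e)]], digits = 3)))
  invisible(x)
}

#' Run a factorial grid of simulation cells
#'
#' Crosses the given factor levels, derives one independent seed per cell
#' from the master seed, runs [run_cell()] on each, and returns a tidy table
#' keyed by factor levels. Duplicate factor combinations are an error.
#'
#' @param n_stop_trials,p_go_failure,tau_go Factor levels (vectors).
#' @param population,criteria,n_subjects,n_replications,estimators,p_stop,max_rt
#'   Shared across cells; see [cell_spec()].
#' @param master_seed Master seed for the whole grid.
#' @return Data frame, one row per cell x estimator: factor levels,
#'   `estimator`, `bias_mean`, `bias_sd`, `correlation_true`, `n_excluded`,
#'   `frac_excluded`, `n_flagged_replications`.
#' @export
run_factorial <- function(n_stop_trials = c(50, 100),
                          p_go_failure = 0, tau_go = 50,
                          population = population_params(),
                          criteria = exclusion_criteria(),
                          n_subjects = 25, n_replications = 10,
                          estimators = c("integration_replace", "mean"),
                          p_stop = 0.25, max_rt = 1500, master_seed = 1L) {
  grid <- expand.grid(n_stop_trials = n_stop_trials,
                      p_go_failure = p_go_failure, tau_go = tau_go,
                      KEEP.OUT.ATTRS = FALSE)
  if (anyDuplicated(grid)) stop("duplicate factor combinations", call. = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- cell_spec(n_stop_trials = grid$n_stop_trials[i],
                      p_stop = p_stop, p_go_failure = grid$p_go_failure[i],
                      tau_go = grid$tau_go[i], population = population,
                      n_subjects = n_subjects,
                      n_replications = n_replications,
                      estimators = estimators,
                      master_seed = .derive_seed(master_seed, i),
                      criteria = criteria, max_rt = max_rt)
    res <- run_cell(spec)
    out[[i]] <- do.call(rbind, lapply(estimators, function(e)
      data.frame(n_stop_trials = grid$n_stop_trials[i],
                 p_go_failure = grid$p_go_failure[i],
                 tau_go = grid$tau_go[i], estimator = e,
                 bias_mean = res[[paste0("bias_mean_", e)]],
                 bias_sd = res[[paste0("bias_sd_", e)]],
                 correlation_true = res[[paste0("correlation_", e)]],
                 n_excluded = res$n_excluded,
                 frac_excluded = res$frac_excluded,
                 n_flagged_replications = res$n_flagged_replications,
                 stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Specification of a group-comparison power study
#'
#' Two simulated groups whose true mean SSRT differs by `delta_ssrt`
#' (applied to the stop-latency `mu`); power is the fraction of Monte-Carlo
#' replications in which a two-sided Welch two-sample t test on the
#' per-subject SSRT estimates rejects at level `alpha`.
#'
#' @param delta_ssrt True between-group SSRT difference in ms.
#' @param n_subjects_per_group Group size.
#' @param cell A [cell_spec()] describing design, population, estimator and
#'   exclusions (its `n_subjects` is ignored; the first listed estimator is
#'   used).
#' @param alpha Test level in `(0, 1)`.
#' @param n_replications Monte-Carlo replications.
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(delta_ssrt, n_subjects_per_group,
                       cell = cell_spec(), alpha = 0.05,
                       n_replications = 200) {
  stopifnot(alpha > 0, alpha < 1, n_subjects_per_group >= 2,
            n_replications >= 1)
  structure(list(delta_ssrt = delta_ssrt,
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 cell = cell, alpha = alpha,
                 n_replications = as.integer(n_replications)),
            class = "power_spec")
}

#' Monte-Carlo power of a two-group SSRT comparison
#'
#' Per replication: sample both groups, shift group 2's stop-latency mean by
#' `delta_ssrt`, simulate one tracked session per subject, apply exclusions,
#' estimate SSRT for the included subjects, and run a two-sided Welch t
#' test. Replications with fewer than two included subjects in either group
#' are flagged and excluded from the power estimate (never silently
#' dropped). A binomial standard error accompanies the estimate.
#'
#' @param spec A [power_spec()].
#' @return List: `power`, `se` (binomial standard error), `n_replications`,
#'   `n_flagged`, `alpha`, `delta_ssrt`, `mean_included_per_group`.
#' @export
estimate_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  cell <- spec$cell
  n_total <- round(cell$n_stop_trials / cell$p_stop)
  design <- design_config(n_trials = n_total, p_stop = cell$p_stop,
                          max_rt = cell$max_rt)
  estimator <- cell$estimators[1L]
  pop2 <- cell$population
  pop2$means$stop_mu <- pop2$means$stop_mu + spec$delta_ssrt
  reject <- logical(spec$n_replications)
  ok <- logical(spec$n_replications)
  n_inc <- numeric(spec$n_replications)
  one_group <- function(pop) {
    roster <- sample_population(pop, spec$n_subjects_per_group)
    est <- vapply(roster, function(subj) {
      session <- simulate_session(subj, design)
      dec <- apply_exclusions(session, cell$criteria)
      if (dec$excluded) NA_real_
      else .estimate_by_name(estimator, session)
    }, numeric(1))
    est[!is.na(est)]
  }
  for (r in seq_len(spec$n_replications)) {
    set.seed(.derive_seed(cell$master_seed, r))
    g1 <- one_group(cell$population)
    g2 <- one_group(pop2)
    n_inc[r] <- (length(g1) + length(g2)) / 2
    if (length(g1) < 2 || length(g2) < 2) next
    ok[r] <- TRUE
    reject[r] <- stats::t.test(g1, g2, var.equal = FALSE)$p.value < spec$alpha
  }
  n_ok <- sum(ok)
  p <- if (n_ok) mean(reject[ok]) else NA_real_
  list(power = p,
       se = if (n_ok) sqrt(p * (1 - p) / n_ok) else NA_real_,
       n_replications = n_ok, n_flagged = spec$n_replications - n_ok,
       alpha = spec$alpha, delta_ssrt = spec$delta_ssrt,
       mean_included_per_group = mean(n_inc))
}
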
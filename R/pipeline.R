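#' Run configuration for a per-condition analysis
#'
#' Collects everything one end-to-end run needs: the condition preset,
#' ensemble sizes, seed, and fit options. All fields have defaults matching
#' the standard protocol (100-ms pulses, 100 sweeps for noise analysis, a
#' 20-ms two-pulse series over 20-720 ms, I-V family from -80 to +80 mV).
#'
#' @param condition a preset name (see [ampar_preset()]).
#' @param n_sweeps sweeps for the noise-analysis ensemble.
#' @param seed integer seed; recorded in every output artifact.
#' @param n_bins,fix_background,alpha NSFA fit options.
#' @param recovery_intervals two-pulse onset-to-onset intervals (ms).
#' @param sweeps_per_interval sweeps per recovery interval.
#' @param recovery_mode `"single"` or `"double"` recovery fit.
#' @param voltages I-V family holding potentials (mV).
#' @param iv_sweeps sweeps per voltage.
#' @param model_overrides named list passed to [ampar_preset()] (e.g.
#'   `list(n_channels = 200)`).
#' @return a `run_config` list.
#' @export
run_config <- function(condition, n_sweeps = 100, seed = 1,
                       n_bins = 10, fix_background = TRUE, alpha = 0.05,
                       recovery_intervals = c(20, 40, 70, 120, 200, 320,
                                              480, 720),
                       sweeps_per_interval = 20,
                       recovery_mode = "single",
                       voltages = seq(-80, 80, by = 20), iv_sweeps = 30,
                       model_overrides = list()) {
  structure(
    list(condition = condition, n_sweeps = n_sweeps, seed = seed,
         n_bins = n_bins, fix_background = fix_background, alpha = alpha,
         recovery_intervals = recovery_intervals,
         sweeps_per_interval = sweeps_per_interval,
         recovery_mode = recovery_mode,
         voltages = voltages, iv_sweeps = iv_sweeps,
         model_overrides = model_overrides),
    class = "run_config")
}

#' Full per-condition analysis: simulate, NSFA, kinetics, recovery, I-V
#'
#' Composes the whole chain for one condition: sweep simulation, run-down
#' screening and non-stationary fluctuation analysis (conductance, channel
#' count, peak open probability), desensitization kinetics (weighted tau,
#' rise time, steady-state percentage), two-pulse recovery, and the
#' current-voltage family with rectification index. Any stage failure is
#' recorded under `errors` and dependent quantities are left `NA`; the run
#' never aborts downstream stages that do not need the failed one.
#'
#' @param config a [run_config()] (or a condition name, for defaults).
#' @param out_path optional path; when given, the report is written as JSON.
#' @return a `condition_report` list: `config`, `summary` (one-row data
#'   frame of the headline estimates), per-stage results (`nsfa`,
#'   `kinetics`, `recovery`, `iv`), and `errors`.
#' @export
run_condition <- function(config, out_path = NULL) {
  if (is.character(config)) config <- run_config(config)
  stopifnot(inherits(config, "run_config"))
  model <- do.call(ampar_preset,
                   c(list(condition = config$condition),
                     config$model_overrides))
  errors <- list()
  note <- function(stage, e) errors[[stage]] <<- conditionMessage(e)

  # --- ensemble + NSFA ------------------------------------------------
  res_nsfa <- NULL; kin <- NULL; rise10 <- NA_real_; rise_op <- NA_real_
  ss_pct <- NA_real_
  sweeps <- tryCatch(
    simulate_sweeps(model, pulse_dur = 100, n_sweeps = config$n_sweeps,
                    seed = config$seed),
    error = function(e) { note("simulate", e); NULL })
  if (!is.null(sweeps)) {
    res_nsfa <- tryCatch(
      nsfa(sweeps, n_bins = config$n_bins,
           fix_background = config$fix_background, alpha = config$alpha),
      error = function(e) { note("nsfa", e); NULL })
    mt <- mean_trace(sweeps)
    kin <- tryCatch(
      fit_desensitization(sweeps$time_ms, mt,
                          t_end = sweeps$t0_agonist + sweeps$pulse_dur),
      error = function(e) { note("kinetics", e); NULL })
    rise10 <- tryCatch(rise_time(sweeps$time_ms, mt, mode = "10-90"),
                       error = function(e) { note("rise_time", e); NA_real_ })
    rise_op <- tryCatch(rise_time(sweeps$time_ms, mt, mode = "onset-peak"),
                        error = function(e) NA_real_)
    pulse_end <- sweeps$t0_agonist + sweeps$pulse_dur
    ss_pct <- tryCatch(
      steady_state_percent(sweeps$time_ms, mt,
                           window = c(pulse_end - 10, pulse_end)),
      error = function(e) { note("steady_state", e); NA_real_ })
  }

  # --- recovery -------------------------------------------------------
  rec <- tryCatch({
    tp <- simulate_two_pulse(model, intervals = config$recovery_intervals,
                             sweeps_per_interval = config$sweeps_per_interval,
                             seed = config$seed)
    ratios <- vapply(tp, function(s) paired_pulse_ratio(s)["ratio"],
                     numeric(1))
    fit_recovery(config$recovery_intervals, unname(ratios),
                 mode = config$recovery_mode)
  }, error = function(e) { note("recovery", e); NULL })

  # --- I-V ------------------------------------------------------------
  iv <- tryCatch({
    fam <- simulate_iv(model, voltages = config$voltages,
                       n_sweeps = config$iv_sweeps, seed = config$seed)
    build_iv(iv_peaks(fam))
  }, error = function(e) { note("iv", e); NULL })

  summary <- data.frame(
    condition = config$condition,
    seed = config$seed,
    g_pS = if (!is.null(res_nsfa) && res_nsfa$ok) res_nsfa$g_hat else NA_real_,
    po_peak = if (!is.null(res_nsfa) && res_nsfa$ok) res_nsfa$po_peak_hat
              else NA_real_,
    n_channels = if (!is.null(res_nsfa) && res_nsfa$ok) res_nsfa$n_hat
                 else NA_real_,
    tau_w_ms = if (!is.null(kin) && kin$ok) kin$tau_w else NA_real_,
    rise_10_90_ms = rise10,
    rise_onset_peak_ms = rise_op,
    ss_percent = ss_pct,
    tau_rec_ms = if (!is.null(rec) && rec$ok) rec$tau_rec else NA_real_,
    ri = if (!is.null(iv)) iv$ri else NA_real_
  )

  report <- structure(
    list(config = config, summary = summary, nsfa = res_nsfa,
         kinetics = kin, recovery = rec, iv = iv, errors = errors),
    class = "condition_report")
  if (!is.null(out_path)) write_report(report, out_path)
  report
}

#' @export
print.condition_report <- function(x, ...) {
  cat("<condition_report>", x$config$condition,
      sprintf("(seed %d)\n", x$config$seed))
  s <- x$summary
  cat(sprintf(
    "  g = %.2f pS, Po = %.3f, N = %.0f | tau_w = %.2f ms, rise(10-90) = %.2f ms, ss = %.1f%% | tau_rec = %.1f ms, RI = %.3f\n",
    s$g_pS, s$po_peak, s$n_channels, s$tau_w_ms, s$rise_10_90_ms,
    s$ss_percent, s$tau_rec_ms, s$ri))
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), unlist(x$errors),
                                 sep = ": ", collapse = "; "), "\n")
  invisible(x)
}

# Flatten a report into JSON-friendly plain lists.
report_to_list <- function(x) {
  num_or_null <- function(v) if (is.null(v)) NULL else unclass(v)
  list(
    config = unclass(x$config),
    summary = as.list(x$summary),
    nsfa = if (!is.null(x$nsfa))
      x$nsfa[c("i_hat", "n_hat", "sigma_b2", "g_hat", "po_peak_hat",
               "i_peak", "fit_sse", "v_hold_corrected", "n_sweeps_used",
               "ok", "flags")],
    nsfa_bins = if (!is.null(x$nsfa) && !is.null(x$nsfa$bins))
      as.list(x$nsfa$bins),
    kinetics = num_or_null(x$kinetics),
    recovery = num_or_null(x$recovery),
    iv = num_or_null(x$iv),
    errors = x$errors
  )
}

#' Write a condition report as JSON
#'
#' @param report a `condition_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Run every preset condition and tabulate the headline estimates
#'
#' One [run_condition()] per preset at a shared seed, returned as a single
#' summary table mirroring the cross-condition comparisons (conductance,
#' peak open probability, weighted desensitization tau, steady-state
#' percentage, recovery tau, rectification index).
#'
#' @param seed integer seed used for every condition.
#' @param conditions preset names (default all).
#' @param ... passed to [run_config()].
#' @return a data frame, one row per condition.
#' @export
run_all_conditions <- function(seed = 1, conditions = ampar_conditions(),
                               ...) {
  rows <- lapply(conditions, function(cc)
    run_condition(run_config(cc, seed = seed, ...))$summary)
  do.call(rbind, rows)
}
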
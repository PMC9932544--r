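#' Process one session end to end
#'
#' Runs the full single-session chain: resample to the analysis rate, band
#' split (FFR / alpha / controls), epoch, alpha indexing (RMS, per-run median
#' normalization, percentile categorization), leadfield pseudo-inverse source
#' transform, category averaging, steady-state spectra, F0 amplitudes,
#' response SNRs, and the F0 ratio. The indexing stream can be switched to
#' the POz beta band or the Fz alpha control without touching anything else.
#'
#' @param session a raw `ffr_session`.
#' @param leadfield channels x 3 leadfield matrix.
#' @param analysis_fs analysis sampling rate, Hz.
#' @param index_stream which stream indexes arousal state: `"alpha"` (POz
#'   8-12 Hz), `"beta"` (POz 18-22 Hz control), or `"control_alpha"` (Fz
#'   8-12 Hz control).
#' @param low_pct,high_pct categorization percentiles.
#' @return list: `trial_table`, `spectra` (low/high `ffr_spectrum`), `f0`
#'   (amplitudes, peak frequencies, `ratio`), `snr` (per category), `spans`,
#'   `n_trials`, `condition`.
#' @export
process_session <- function(session, leadfield, analysis_fs = 5000,
                            index_stream = c("alpha", "beta", "control_alpha"),
                            low_pct = 35, high_pct = 65) {
  index_stream <- match.arg(index_stream)
  stopifnot(inherits(session, "ffr_session"))
  if (session$fs != analysis_fs)
    session <- resample_session(session, analysis_fs)
  streams <- bandsplit(session)

  idx_epochs <- epoch_stream(streams[[index_stream]])
  tt <- trial_table(idx_epochs, condition = session$condition,
                    low_pct = low_pct, high_pct = high_pct)

  ffr_epochs <- epoch_stream(streams$ffr)
  filt <- build_spatial_filter(leadfield)
  src <- to_source(ffr_epochs, filt)

  avg <- average_ffr(src, tt$category)
  spectra <- lapply(avg, function(a)
    steady_state_spectrum(a$waveform, fs = analysis_fs,
                          n_trials = a$n_trials))
  f0 <- lapply(spectra, f0_amplitude)
  snr <- lapply(spectra, response_snr)
  list(trial_table = tt,
       spectra = spectra,
       f0 = list(low = f0$low$amp, high = f0$high$amp,
                 freq_low = f0$low$freq, freq_high = f0$high$freq,
                 ratio = f0_ratio(f0$low$amp, f0$high$amp)),
       snr = snr,
       spans = span_lengths(tt$category),
       n_trials = c(low = avg$low$n_trials, high = avg$high$n_trials),
       condition = session$condition)
}

#' Run the synthetic-cohort analysis pipeline
#'
#' Orchestrates synthesis and analysis for a whole cohort: for every
#' participant and condition a token schedule is generated, a session is
#' simulated at the acquisition rate, and [process_session()] produces the
#' per-participant F0 summary. Deterministic under `seed` (identical configs
#' reproduce identical outputs).
#'
#' @param cohort an [make_cohort()] result.
#' @param stimulus a [stimulus_spec()]; scale `n_ba`/`n_pa`/`n_ta` down for
#'   tractable runs (a full-length 32-channel session at 20 kHz is ~7 GB and
#'   should not be materialized in memory).
#' @param conditions conditions to run.
#' @param acquisition_fs synthesis sampling rate, Hz.
#' @param seed master seed.
#' @inheritParams process_session
#' @return An `ffr_run`: list with `f0_table` (participant x condition rows:
#'   F0 amplitudes per alpha state, ratio, SNRs, alpha RMS means), `behavior`
#'   (cohort data frame), `config`.
#' @export
run_pipeline <- function(cohort, stimulus = stimulus_spec(),
                         conditions = c("clear", "noise"),
                         acquisition_fs = 20000, analysis_fs = 5000,
                         index_stream = "alpha", seed = NULL) {
  stopifnot(inherits(cohort, "ffr_cohort"))
  with_seed_opt(seed, {
    rows <- list()
    for (i in seq_along(cohort$participants)) {
      p <- cohort$participants[[i]]
      for (cond in conditions) {
        sched <- make_event_schedule(stimulus)
        ses <- simulate_session(p, cohort$leadfield, sched, cond,
                                fs = acquisition_fs)
        res <- process_session(ses, cohort$leadfield,
                               analysis_fs = analysis_fs,
                               index_stream = index_stream)
        tt <- res$trial_table
        rows[[length(rows) + 1L]] <- data.frame(
          id = p$id, group = p$group, condition = cond,
          f0_low = res$f0$low, f0_high = res$f0$high,
          f0_ratio = res$f0$ratio,
          snr_low_db = res$snr$low$snr_db, snr_high_db = res$snr$high$snr_db,
          alpha_rms_low = mean(tt$raw_rms[tt$category == "low"]),
          alpha_rms_high = mean(tt$raw_rms[tt$category == "high"]),
          span_mean = res$spans$overall,
          n_low = res$n_trials[["low"]], n_high = res$n_trials[["high"]])
      }
    }
    structure(list(
      f0_table = do.call(rbind, rows),
      behavior = cohort$cohort,
      config = list(stimulus = stimulus, conditions = conditions,
                    acquisition_fs = acquisition_fs,
                    analysis_fs = analysis_fs, index_stream = index_stream,
                    seed = seed)),
      class = "ffr_run")
  })
}

#' Summarize a pipeline run with the statistical battery
#'
#' Builds the result tables the analysis reports: alpha RMS by group and
#' state, one-sample t-tests of F0 ratios against 1 per group and condition,
#' the group Mann-Whitney comparison of ratios, the mixed ANOVA on log F0
#' amplitudes (when both conditions are present), and brain-behavior Spearman
#' correlations of low-alpha F0 amplitudes.
#'
#' @param run an `ffr_run`.
#' @return list of result tables; `NULL` entries where the run lacks the
#'   required cells.
#' @export
ffr_report <- function(run) {
  stopifnot(inherits(run, "ffr_run"))
  ft <- run$f0_table
  if (nrow(ft) == 0) stop("empty run")
  out <- list()

  out$alpha_rms <- do.call(rbind, lapply(split(ft, ft[c("group", "condition")]),
    function(d) if (nrow(d)) data.frame(
      group = d$group[1], condition = d$condition[1],
      rms_low = mean(d$alpha_rms_low), rms_high = mean(d$alpha_rms_high),
      n = nrow(d))))

  one_sample <- lapply(split(ft, ft[c("group", "condition")]), function(d) {
    if (nrow(d) >= 2 && sd(d$f0_ratio) > 0) {
      r <- f0_ratio_one_sample(d$f0_ratio)
      data.frame(group = d$group[1], condition = d$condition[1],
                 mean_ratio = r$mean, t = r$statistic, df = r$df, p = r$p)
    }
  })
  out$f0_ratio_tests <- do.call(rbind, one_sample)

  out$ratio_group_compare <- do.call(rbind, lapply(split(ft, ft$condition),
    function(d) {
      if (length(unique(d$group)) == 2) {
        mw <- group_compare(d$f0_ratio, d$group, "mann-whitney", m = 2)
        data.frame(condition = d$condition[1], U = mw$statistic, p = mw$p,
                   p_adj = mw$p_adj)
      }
    }))

  if (all(c("clear", "noise") %in% ft$condition)) {
    long <- do.call(rbind, lapply(c("low", "high"), function(a) {
      data.frame(participant = ft$id, group = ft$group, snr = ft$condition,
                 alpha = a, f0_amp = ft[[paste0("f0_", a)]])
    }))
    out$mixed_anova <- tryCatch(mixed_anova_f0(long), error = function(e) NULL)
  }

  beh <- run$behavior
  clear <- ft[ft$condition == "clear", ]
  if (nrow(clear) >= 4 && all(clear$id %in% beh$id)) {
    b <- beh[match(clear$id, beh$id), ]
    out$brain_behavior <- brain_behavior_corr(
      clear$f0_low, data.frame(quicksin = b$snr_loss, pta = b$pta,
                               percent_correct = b$pc_clear,
                               rt = b$rt_clear))
    out$pta_regression <- tryCatch(
      fit_group_regression(clear$f0_low, b$pta, clear$group),
      error = function(e) NULL)
  }
  out
}
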
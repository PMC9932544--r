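#' Per-trial RMS amplitude
#'
#' Root-mean-square amplitude of each single-trial waveform over the full
#' epoch window - the per-trial index of band power (alpha RMS when applied to
#' the POz alpha epochs; the same machinery serves the POz beta and Fz alpha
#' control streams).
#'
#' @param epochs single-channel `ffr_epochs` (trials x samples) or a plain
#'   trials x samples matrix.
#' @return numeric vector, one RMS value (uV) per trial.
#' @export
trial_rms <- function(epochs) {
  d <- if (inherits(epochs, "ffr_epochs")) epochs$data else epochs
  stopifnot(is.matrix(d))
  if (ncol(d) == 0L || nrow(d) == 0L) stop("empty epochs")
  sqrt(rowMeans(d^2))
}

#' Normalize trial RMS to each run's median
#'
#' Divides every trial's RMS by the median RMS of its run (block), so each
#' run's normalized median is exactly 1 and slow between-run gain drifts
#' cancel. Scale-invariant within run.
#'
#' @param raw_rms numeric vector of per-trial RMS values.
#' @param run_ids run/block identifier per trial.
#' @return numeric vector of normalized (unitless) RMS values.
#' @export
normalize_by_run <- function(raw_rms, run_ids) {
  stopifnot(length(raw_rms) == length(run_ids))
  med <- tapply(raw_rms, run_ids, median)
  if (any(med == 0)) stop("degenerate input: run median RMS is zero")
  as.numeric(raw_rms / med[as.character(run_ids)])
}

#' Categorize trials into low / middle / high alpha states
#'
#' Pools normalized RMS values within participant x condition and labels
#' trials at or below the `low_pct` percentile "low", at or above the
#' `high_pct` percentile "high", and the rest "middle" (excluded from FFR
#' averaging). Percentiles use linear-interpolation quantiles; boundary ties
#' are assigned to the extreme category and, if a category then exceeds its
#' share, trimmed back by trial index (earliest kept; low resolved before
#' high). With 6,000 frequent-token trials and the default 35/65 cutoffs this
#' yields exactly 2,100 low and 2,100 high trials.
#'
#' @param norm_rms normalized RMS values (one participant x condition).
#' @param low_pct,high_pct percentile cutoffs (defaults 35 and 65).
#' @return factor with levels `low`, `middle`, `high`, in trial order.
#' @export
categorize_trials <- function(norm_rms, low_pct = 35, high_pct = 65) {
  n <- length(norm_rms)
  if (n < 3) stop("need at least 3 trials to categorize")
  stopifnot(low_pct > 0, high_pct < 100, low_pct <= high_pct)
  q <- quantile(norm_rms, c(low_pct, high_pct) / 100, type = 7, names = FALSE)
  low <- norm_rms <= q[1]
  high <- norm_rms >= q[2]
  trim <- function(sel, target) {
    if (sum(sel) > target) {
      boundary <- which(sel)
      # demote latest-index trials among the boundary-valued ones
      val <- if (identical(sel, low)) max(norm_rms[sel]) else min(norm_rms[sel])
      cand <- boundary[norm_rms[boundary] == val]
      drop_n <- sum(sel) - target
      sel[rev(cand)[seq_len(min(drop_n, length(cand)))]] <- FALSE
    }
    sel
  }
  low <- trim(low, ceiling(low_pct / 100 * n))
  high[low] <- FALSE                      # a trial belongs to one category
  high <- trim(high, ceiling((100 - high_pct) / 100 * n))
  factor(ifelse(low, "low", ifelse(high, "high", "middle")),
         levels = c("low", "middle", "high"))
}

#' Mean consecutive span length per alpha category
#'
#' Mean length of maximal runs of identical low / high labels in trial order
#' (middle trials break runs): how many consecutive trials the cortical state
#' persists.
#'
#' @param categories factor from [categorize_trials()], in trial order.
#' @return list with mean span `low`, `high`, and `overall` (all low/high
#'   runs pooled).
#' @export
span_lengths <- function(categories) {
  r <- rle(as.character(categories))
  keep <- r$values %in% c("low", "high")
  lens <- r$lengths[keep]
  vals <- r$values[keep]
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  list(low = mean_or_na(lens[vals == "low"]),
       high = mean_or_na(lens[vals == "high"]),
       overall = mean_or_na(lens))
}

#' Assemble the per-trial table for one session
#'
#' Runs the alpha-indexing chain on an epoch set: per-trial RMS, per-run
#' median normalization, and percentile categorization, returned as one row
#' per trial.
#'
#' @param alpha_epochs single-channel `ffr_epochs` of the indexing stream.
#' @param condition condition label recorded in the table.
#' @inheritParams categorize_trials
#' @return data frame: `token`, `block`, `condition`, `raw_rms`, `norm_rms`,
#'   `category`.
#' @export
trial_table <- function(alpha_epochs, condition = "clear",
                        low_pct = 35, high_pct = 65) {
  stopifnot(inherits(alpha_epochs, "ffr_epochs"))
  raw <- trial_rms(alpha_epochs)
  norm <- normalize_by_run(raw, alpha_epochs$info$block)
  data.frame(token = alpha_epochs$info$token,
             block = alpha_epochs$info$block,
             condition = condition,
             raw_rms = raw,
             norm_rms = norm,
             category = categorize_trials(norm, low_pct, high_pct))
}
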
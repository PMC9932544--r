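#' Score one QuickSiN list
#'
#' Spearman-Karber scoring of the keyword psychometric function: with six
#' sentences (five keywords each) presented at SNRs from 25 down to 0 dB in
#' 5-dB steps, SNR-50 = 27.5 - (total keywords correct) and the SNR-loss is
#' SNR-50 minus the 2 dB normal-hearing reference. A listener's score is the
#' mean SNR-loss over (typically four) lists.
#'
#' @param tallies integer vector of keywords correct (0-5) per sentence, one
#'   per SNR step `{25, 20, 15, 10, 5, 0}`.
#' @return SNR-loss for the list, dB.
#' @export
quicksin_score <- function(tallies) {
  tallies <- as.numeric(tallies)
  if (length(tallies) != 6 || any(is.na(tallies)) ||
      any(tallies < 0 | tallies > 5 | tallies != round(tallies)))
    stop("malformed tallies: need 6 integer keyword counts in 0..5")
  snr50 <- 27.5 - sum(tallies)
  snr50 - 2
}

#' Summarize target-detection behavior
#'
#' Percent correct detection of the rare /ta/ target and mean reaction time
#' over hits for one condition. With no hits the RT is reported as missing.
#'
#' @param hits logical (or 0/1) vector of per-target hit flags.
#' @param rts reaction times, ms (NA on misses).
#' @param n_targets number of targets presented (defaults to `length(hits)`).
#' @return list: `percent_correct`, `mean_rt` (NA when no hits), `n_hits`.
#' @export
detection_summary <- function(hits, rts, n_targets = length(hits)) {
  if (n_targets == 0L) stop("zero targets")
  hits <- as.logical(hits)
  stopifnot(length(rts) == length(hits))
  nh <- sum(hits)
  list(percent_correct = nh / n_targets * 100,
       mean_rt = if (nh > 0) mean(rts[hits], na.rm = TRUE) else NA_real_,
       n_hits = nh)
}

#' Categorize perceptual performance levels across a cohort
#'
#' Three-way split of clear-condition percent-correct scores: `poor` at or
#' below the 30th percentile, `good` at or above the 70th, `average` between.
#' Boundary ties go to the extreme class, then classes are trimmed to the
#' percentile share by score rank when ties inflate them; with all scores
#' equal no split exists and classification is refused. The poor/good subset
#' feeds the classifier (with a 32-listener cohort and distinct scores the
#' split yields 10 poor and 10 good).
#'
#' @param scores percent-correct scores, one per participant.
#' @param low_pct,high_pct percentile cutoffs (defaults 30 and 70).
#' @return factor with levels `poor`, `average`, `good`.
#' @export
performance_levels <- function(scores, low_pct = 30, high_pct = 70) {
  n <- length(scores)
  if (n < 4) stop("cohort too small to categorize (need >= 4)")
  if (diff(range(scores)) == 0)
    stop("all scores equal: performance levels undefined, ",
         "classification refused")
  q <- quantile(scores, c(low_pct, high_pct) / 100, type = 7, names = FALSE)
  poor <- scores <= q[1]
  good <- scores >= q[2]
  trim <- function(sel, target, from_top) {
    if (sum(sel) > target) {
      val <- if (from_top) max(scores[sel]) else min(scores[sel])
      cand <- which(sel & scores == val)
      drop_n <- sum(sel) - target
      sel[rev(cand)[seq_len(min(drop_n, length(cand)))]] <- FALSE
    }
    sel
  }
  poor <- trim(poor, ceiling(low_pct / 100 * n), from_top = TRUE)
  good[poor] <- FALSE
  good <- trim(good, ceiling((100 - high_pct) / 100 * n), from_top = FALSE)
  factor(ifelse(poor, "poor", ifelse(good, "good", "average")),
         levels = c("poor", "average", "good"))
}
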
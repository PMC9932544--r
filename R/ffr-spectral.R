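#' Average source FFR waveforms per alpha category
#'
#' Arithmetic mean of the single-trial z-source waveforms within each alpha
#' category (alternating-polarity trials pooled, which emphasizes the
#' envelope-following F0 component).
#'
#' @param source_epochs a `source_epochs` (trials x samples).
#' @param categories factor from [categorize_trials()], same trial order.
#' @param which categories to average (default low and high).
#' @return list per category: `waveform` (numeric vector), `n_trials`.
#' @export
average_ffr <- function(source_epochs, categories, which = c("low", "high")) {
  stopifnot(inherits(source_epochs, "ffr_epochs"),
            nrow(source_epochs$data) == length(categories))
  out <- lapply(which, function(cat) {
    sel <- categories == cat
    if (!any(sel)) stop("empty cell: no trials in category '", cat, "'")
    list(waveform = colMeans(source_epochs$data[sel, , drop = FALSE]),
         n_trials = sum(sel))
  })
  names(out) <- which
  out
}

#' Steady-state amplitude spectrum of an averaged FFR
#'
#' Extracts the steady-state portion of the averaged waveform (default 10-100
#' ms post onset, half-open, i.e. 450 samples at 5 kHz), applies a Blackman
#' taper, and computes the one-sided absolute amplitude spectrum without
#' zero-padding: 226 bins at fs/450 = 11.1 Hz spacing. Amplitudes are
#' normalized by the taper's coherent gain (sum of the window), so a
#' unit-amplitude sinusoid at a bin center reads ~1.
#'
#' @param waveform averaged FFR waveform (one epoch, uV).
#' @param fs sampling rate, Hz.
#' @param window steady-state window in seconds post onset (half-open).
#' @param epoch_start epoch start time relative to onset, s.
#' @param n_trials optional trial count recorded in the result.
#' @return An `ffr_spectrum`: list with `freqs` (Hz), `amps`, `n_window`,
#'   `fs`, `n_trials`.
#' @export
steady_state_spectrum <- function(waveform, fs, window = c(0.010, 0.100),
                                  epoch_start = -0.050, n_trials = NA) {
  i1 <- round((window[1] - epoch_start) * fs) + 1
  i2 <- round((window[2] - epoch_start) * fs)
  if (i1 < 1 || i2 > length(waveform))
    stop("steady-state window outside the epoch")
  seg <- waveform[i1:i2]
  n <- length(seg)
  k <- 0:(n - 1)
  taper <- 0.42 - 0.5 * cos(2 * pi * k / (n - 1)) +
    0.08 * cos(4 * pi * k / (n - 1))
  sp <- fft(seg * taper)
  nb <- n %/% 2 + 1
  amps <- Mod(sp[seq_len(nb)]) * 2 / sum(taper)
  amps[1] <- amps[1] / 2
  if (n %% 2 == 0) amps[nb] <- amps[nb] / 2
  structure(list(freqs = (seq_len(nb) - 1) * fs / n, amps = amps,
                 n_window = n, fs = fs, n_trials = n_trials),
            class = "ffr_spectrum")
}

#' @export
print.ffr_spectrum <- function(x, ...) {
  cat("<ffr_spectrum> ", length(x$freqs), " bins, ",
      round(x$freqs[2], 2), " Hz spacing",
      if (!is.na(x$n_trials)) paste0(", ", x$n_trials, " trials averaged"),
      "\n", sep = "")
  invisible(x)
}

#' F0 amplitude: peak within the search bin around the voice fundamental
#'
#' Maximum spectral amplitude over the grid bins covering an 11-Hz interval
#' centered on the stimulus F0 (150 Hz): bins whose coverage interval
#' (center +/- spacing/2) overlaps `f0 +/- bin_width/2`. With the 11.1 Hz
#' grid the two bins flanking 150 Hz qualify.
#'
#' @param spectrum an `ffr_spectrum`.
#' @param f0 fundamental frequency, Hz.
#' @param bin_width width of the search interval, Hz.
#' @return list: `amp` (peak amplitude), `freq` (center of the peak bin),
#'   `bins` (indices searched).
#' @export
f0_amplitude <- function(spectrum, f0 = 150, bin_width = 11) {
  stopifnot(inherits(spectrum, "ffr_spectrum"))
  spacing <- spectrum$freqs[2] - spectrum$freqs[1]
  lo <- f0 - bin_width / 2
  hi <- f0 + bin_width / 2
  sel <- which(spectrum$freqs + spacing / 2 >= lo &
                 spectrum$freqs - spacing / 2 <= hi)
  if (length(sel) == 0L)
    stop("F0 search interval does not intersect the frequency grid")
  peak <- sel[which.max(spectrum$amps[sel])]
  list(amp = spectrum$amps[peak], freq = spectrum$freqs[peak], bins = sel)
}

#' Response SNR of an averaged FFR spectrum
#'
#' `20 * log10(f0_amp / noise_floor)` where the noise floor is the mean
#' amplitude over symmetric flanking bands (bin centers within
#' `f0 +/- [22, 55]` Hz, clear of F0 leakage). Averages below 3 dB are
#' flagged, not dropped.
#'
#' @param spectrum an `ffr_spectrum`.
#' @param f0 fundamental, Hz.
#' @param flank inner/outer flank offsets, Hz.
#' @param snr_criterion_db flagging threshold, dB.
#' @return list: `snr_db`, `f0_amp`, `noise_floor`, `flagged`.
#' @export
response_snr <- function(spectrum, f0 = 150, flank = c(22, 55),
                         snr_criterion_db = 3) {
  f0a <- f0_amplitude(spectrum, f0 = f0)
  fr <- spectrum$freqs
  sel <- (fr >= f0 - flank[2] & fr <= f0 - flank[1]) |
    (fr >= f0 + flank[1] & fr <= f0 + flank[2])
  sel[f0a$bins] <- FALSE
  if (!any(sel)) stop("no noise-floor flank bins available")
  floor_amp <- mean(spectrum$amps[sel])
  if (floor_amp == 0) stop("zero noise floor")
  snr <- 20 * log10(f0a$amp / floor_amp)
  list(snr_db = snr, f0_amp = f0a$amp, noise_floor = floor_amp,
       flagged = snr < snr_criterion_db)
}

#' The F0-ratio modulation statistic
#'
#' `f0_high / f0_low`: the within-participant ratio of F0 amplitudes during
#' high versus low cortical alpha states. Values above 1 indicate stronger
#' brainstem FFRs during high cortical alpha power; equal amplitudes give
#' exactly 1.
#'
#' @param f0_low,f0_high F0 amplitudes (both > 0).
#' @return the ratio (unitless scalar).
#' @export
f0_ratio <- function(f0_low, f0_high) {
  if (any(c(f0_low, f0_high) < 0)) stop("F0 amplitudes must be positive")
  if (f0_low == 0) stop("zero denominator: low-alpha F0 amplitude is 0")
  f0_high / f0_low
}
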
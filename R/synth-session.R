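#' Standard 32-channel montage used by the synthetic recordings
#'
#' Approximate 2D scalp coordinates (top view; x = right, y = anterior, head
#' radius 1) for a standard 10-20 arrangement of 32 electrodes, including the
#' mastoid sites TP9/TP10 and the midline sites Fz/Cz/Pz/Oz used downstream.
#'
#' @return Data frame with columns `channel`, `x`, `y`.
#' @export
montage_32 <- function() {
  ch <- c("Fp1","Fp2","F7","F3","Fz","F4","F8","FT9","FC5","FC1","FC2","FC6",
          "FT10","T7","C3","Cz","C4","T8","TP9","CP5","CP1","CP2","CP6","TP10",
          "P7","P3","Pz","P4","P8","O1","Oz","O2")
  x <- c(-0.31,0.31,-0.81,-0.36,0,0.36,0.81,-1.0,-0.59,-0.19,0.19,0.59,
         1.0,-1,-0.5,0,0.5,1,-1.05,-0.59,-0.19,0.19,0.59,1.05,
         -0.81,-0.36,0,0.36,0.81,-0.31,0,0.31)
  y <- c(0.95,0.95,0.59,0.52,0.5,0.52,0.59,0.31,0.28,0.26,0.26,0.28,
         0.31,0,0,0,0,0,-0.31,-0.28,-0.26,-0.26,-0.28,-0.31,
         -0.59,-0.52,-0.5,-0.52,-0.59,-0.95,-1,-0.95)
  data.frame(channel = ch, x = x, y = y)
}

#' Leadfield of the brainstem regional source
#'
#' Gain of a unit brainstem/midbrain dipole in three orthogonal orientations
#' (x, y, z) at each scalp electrode: a `channels x 3` matrix. The default
#' model places the z (vertical) orientation's maximum along the fronto-central
#' vertex line, mimicking the predominantly vertical current flow of the
#' auditory midbrain pathways, with smooth lateral/anterior gradients for the
#' x and y orientations. Any user-supplied `channels x 3` matrix (e.g. read
#' from CSV with [read_leadfield()]) can be used instead.
#'
#' @param montage data frame as returned by [montage_32()].
#' @return A `leadfield` object: numeric matrix (channels x 3, columns
#'   `x`,`y`,`z`) with channel row names.
#' @export
default_leadfield <- function(montage = montage_32()) {
  r <- sqrt(montage$x^2 + montage$y^2)
  lz <- 1.2 * exp(-(r / 0.9)^2) - 0.1
  lx <- 0.8 * montage$x * exp(-(r / 1.2)^2)
  ly <- 0.8 * montage$y * exp(-(r / 1.2)^2)
  L <- cbind(x = lx, y = ly, z = lz)
  rownames(L) <- montage$channel
  structure(L, class = c("leadfield", "matrix", "array"))
}

#' Read / write a leadfield as CSV (channels x 3 with orientation header)
#' @param path file path.
#' @return `read_leadfield()` returns a `leadfield` matrix.
#' @export
read_leadfield <- function(path) {
  d <- utils::read.csv(path, row.names = 1)
  stopifnot(ncol(d) == 3)
  L <- as.matrix(d)
  colnames(L) <- c("x", "y", "z")
  structure(L, class = c("leadfield", "matrix", "array"))
}

#' @rdname read_leadfield
#' @param leadfield a `leadfield` matrix.
#' @export
write_leadfield <- function(leadfield, path) {
  write.csv(as.data.frame(unclass(leadfield)), path, row.names = TRUE)
  invisible(path)
}

# Posterior alpha-source scalp topography (parieto-occipital maximum).
alpha_topography <- function(montage = montage_32()) {
  w <- exp(-((montage$y + 0.85) / 0.55)^2) * exp(-(montage$x / 1.2)^2)
  names(w) <- montage$channel
  w
}

#' Per-participant generative parameters
#'
#' Bundles everything the session generator needs for one listener: hearing
#' group and pure-tone average (PTA), posterior alpha source amplitude and its
#' slow modulation depth, FFR source gain, the alpha-FFR coupling strength per
#' condition (the ground-truth driver of the F0 ratio), sensor-noise levels,
#' and the behavior-linkage parameters.
#'
#' `coupling` is the multiplicative change in FFR source amplitude per unit of
#' normalized alpha envelope: trial amplitude = `ffr_gain * (1 + coupling *
#' (alpha_state - 1))` where `alpha_state` is the instantaneous alpha envelope
#' normalized to its session median.
#'
#' @param group `"NH"` or `"HL"`.
#' @param pta pure-tone average (0.5/1/2 kHz), dB HL. NH draws live in
#'   8.3-20.83 dB HL and HL draws in 15.8-45 dB HL.
#' @param alpha_base posterior alpha source RMS amplitude, uV.
#' @param alpha_mod_depth depth (0-1) of the slow alpha amplitude modulation.
#' @param ffr_gain brainstem source amplitude scale, uV.
#' @param coupling named numeric `c(clear = , noise = )`, each >= 0.
#' @param noise_sd white sensor-noise SD per channel, uV.
#' @param lf_sd SD of the band-limited low-frequency (1/f-surrogate) sensor
#'   noise, uV.
#' @param noise_ffr_scale multiplicative FFR gain reduction in the noise
#'   condition.
#' @param id participant identifier.
#' @return A `participant_params` object.
#' @export
participant_params <- function(group = c("NH", "HL"), pta = 15,
                               alpha_base = 1.5, alpha_mod_depth = 0.5,
                               ffr_gain = 0.15,
                               coupling = c(clear = 0.3, noise = 0.05),
                               noise_sd = 2, lf_sd = 4,
                               noise_ffr_scale = 0.85, id = "P01") {
  group <- match.arg(group)
  stopifnot(ffr_gain > 0, alpha_base > 0, alpha_mod_depth >= 0,
            alpha_mod_depth <= 1, all(coupling >= 0), noise_sd >= 0, lf_sd >= 0,
            noise_ffr_scale > 0)
  if (group == "NH" && (pta < 8.3 || pta > 20.83))
    stop("NH pta must lie within 8.3-20.83 dB HL")
  if (group == "HL" && (pta < 15.8 || pta > 45))
    stop("HL pta must lie within 15.8-45 dB HL")
  structure(list(id = id, group = group, pta = pta, alpha_base = alpha_base,
                 alpha_mod_depth = alpha_mod_depth, ffr_gain = ffr_gain,
                 coupling = coupling, noise_sd = noise_sd, lf_sd = lf_sd,
                 noise_ffr_scale = noise_ffr_scale),
            class = "participant_params")
}

# Slowly varying modulation signal in [-0.95, 0.95]: iid normals on a 0.5-s
# grid, linearly interpolated (content well below the alpha band), sd ~ 1.
slow_modulation <- function(n, fs, knot_spacing = 0.5) {
  nk <- max(4L, ceiling(n / fs / knot_spacing) + 2L)
  k <- rnorm(nk)
  m <- approx(seq(0, by = knot_spacing, length.out = nk),
              k, xout = (seq_len(n) - 1) / fs, rule = 2)$y
  pmin(pmax(m / max(sd(m), 1e-12), -0.95), 0.95)
}

# Unit-amplitude evoked FFR burst occupying 10-100 ms post token onset:
# F0 plus two harmonics, 5-ms raised-cosine on/off ramps. Polarity-invariant
# (envelope-following), so alternating-polarity trials average coherently.
ffr_burst <- function(fs, f0 = 150) {
  n <- round(0.090 * fs)
  t <- (seq_len(n) - 1) / fs
  w <- sin(2 * pi * f0 * t) + 0.4 * sin(2 * pi * 2 * f0 * t) +
    0.2 * sin(2 * pi * 3 * f0 * t)
  nr <- round(0.005 * fs)
  ramp <- rep(1, n)
  ramp[seq_len(nr)] <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / nr))
  ramp[n + 1 - seq_len(nr)] <- ramp[seq_len(nr)]
  w * ramp
}

#' Simulate one multichannel EEG session
#'
#' Generates a 32-channel recording for one participant and condition with the
#' statistical structure the analysis pipeline assumes: each token evokes a
#' phase-locked brainstem source burst (F0 = 150 Hz plus harmonics, 10-100 ms
#' post onset) whose amplitude is coupled to the instantaneous normalized
#' alpha envelope; a posterior alpha source (8-12 Hz carrier with slow
#' amplitude modulation) is projected to parieto-occipital channels; white and
#' band-limited low-frequency sensor noise is added per channel. In the
#' `"noise"` condition a 100-1,000 Hz Gaussian masker is added to the evoked
#' source drive at -10 dB relative amplitude and the FFR gain is scaled by
#' `params$noise_ffr_scale`.
#'
#' @param params a [participant_params()].
#' @param leadfield `channels x 3` leadfield matrix.
#' @param schedule event schedule from [make_event_schedule()].
#' @param condition `"clear"` or `"noise"`.
#' @param fs sampling rate, Hz (acquisition-rate default 20 kHz; must be at
#'   least 5 kHz to carry the 1 kHz response content).
#' @param seed optional integer seed.
#' @return An `ffr_session`: list with `data` (channels x samples matrix, uV),
#'   `fs`, `channel_labels`, `events` (data frame: `sample`, `token`,
#'   `polarity`, `block`), `condition`, `reference`, and a `ground_truth` list
#'   (noiseless z-source waveform, alpha envelope, per-trial source amplitude
#'   and alpha state).
#' @export
simulate_session <- function(params, leadfield, schedule,
                             condition = c("clear", "noise"),
                             fs = 20000, seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "participant_params"))
  if (fs < 5000) stop("fs must be >= 5000 Hz for 1,000 Hz response content")
  channels <- rownames(leadfield)
  if (is.null(channels)) stop("leadfield must carry channel row names")
  if (!schedule_satisfies_rare_rule(schedule))
    stop("schedule violates the rare-token spacing rule")

  with_seed_opt(seed, {
    pad <- 1.0                       # s of context on both sides (filter edges)
    dur <- max(schedule$onset_s) + 0.16
    n <- round((dur + 2 * pad) * fs)
    onset_sample <- round((schedule$onset_s + pad) * fs) + 1L

    # posterior alpha source: 10 Hz carrier, slow AM envelope
    m <- slow_modulation(n, fs)
    env <- params$alpha_base * sqrt(2) * (1 + params$alpha_mod_depth * m)
    alpha_src <- env * sin(2 * pi * 10 * (seq_len(n) - 1) / fs + runif(1, 0, 2 * pi))
    alpha_state <- env / median(env)

    # brainstem source drive: coupled evoked bursts (+ masker in noise)
    gain <- params$ffr_gain * if (condition == "noise") params$noise_ffr_scale else 1
    g <- unname(params$coupling[condition])
    burst <- ffr_burst(fs)
    lag <- round(0.010 * fs)
    src <- numeric(n)
    amp <- gain * (1 + g * (alpha_state[onset_sample] - 1))
    amp <- pmax(amp, 0)
    for (i in seq_along(onset_sample)) {
      idx <- onset_sample[i] + lag + seq_along(burst) - 1L
      src[idx] <- src[idx] + amp[i] * burst
    }
    if (condition == "noise") {
      bp <- design_fir_bandpass(fs, 100, 1000)
      masker <- apply_fir(rnorm(n), bp)
      src <- src + masker / sd(masker) * gain * 10^(-10 / 20)
    }

    # project to sensors and add noise channel by channel; noise_sd is the
    # white-noise SD at the 20 kHz acquisition rate (i.e. fixed spectral
    # density), so synthesizing at a lower rate gives the same statistics as
    # acquiring at 20 kHz and resampling
    white_sd <- params$noise_sd * sqrt(fs / 20000)
    atopo <- alpha_topography(montage_32())[channels]
    lz <- leadfield[, "z"]
    data <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
    for (c_i in seq_along(channels)) {
      ch_noise <- white_sd * rnorm(n)
      if (params$lf_sd > 0) {
        # band-limited drift (content below ~7 Hz): the 1/f-surrogate part
        # of sensor noise, kept clear of the alpha band's lower cutoff
        nk <- ceiling(n / (fs * 0.15)) + 2L
        lf <- approx(seq(0, by = 0.15, length.out = nk), rnorm(nk),
                     xout = (seq_len(n) - 1) / fs, rule = 2)$y
        ch_noise <- ch_noise + params$lf_sd * lf / max(sd(lf), 1e-12)
      }
      data[c_i, ] <- lz[c_i] * src + atopo[c_i] * alpha_src + ch_noise
    }

    events <- data.frame(sample = onset_sample,
                         token = schedule$token,
                         polarity = schedule$polarity,
                         block = schedule$block)
    structure(
      list(data = data, fs = fs, channel_labels = channels, events = events,
           condition = condition, reference = "none",
           ground_truth = list(source_z = src, alpha_env = env,
                               alpha_state_at_onset = alpha_state[onset_sample],
                               trial_amp = amp, coupling = g)),
      class = "ffr_session")
  })
}

#' @export
print.ffr_session <- function(x, ...) {
  cat("<ffr_session> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz; ", nrow(x$events), " events; condition=",
      x$condition, "; reference=", x$reference, "\n", sep = "")
  invisible(x)
}
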
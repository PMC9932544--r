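test_that("FIR design reproduces the printed lengths and cutoffs", {
  ffr <- design_fir_bandpass(5000, 100, 1000)
  expect_equal(ffr$n_taps, 661L)
  expect_equal(ffr$n_taps / 5000, 0.1322)      # 0.132 s at 5 kHz

  alpha <- design_fir_bandpass(5000, 8, 12)
  expect_equal(alpha$n_taps, 8251L)
  expect_equal(alpha$n_taps / 5000, 1.6502)    # 1.65 s
  expect_equal(unname(alpha$minus6db_cutoffs), c(7, 13.5))

  # hand application of the transition rule to an 18-22 Hz band:
  # lower tbw = 0.25*18 = 4.5 Hz, upper = 0.25*22 = 5.5 Hz
  beta <- design_fir_bandpass(5000, 18, 22)
  expect_equal(unname(beta$transition_bw), c(4.5, 5.5))
  expect_equal(unname(beta$minus6db_cutoffs), c(18 - 2.25, 22 + 2.75))
  expect_equal(beta$n_taps, as.integer(ceiling(3.3 / 4.5 * 5000)))
})

test_that("FIR design is a pure function with the claimed response", {
  a <- design_fir_bandpass(5000, 8, 12)
  b <- design_fir_bandpass(5000, 8, 12)
  expect_identical(a, b)

  for (spec in list(a, design_fir_bandpass(5000, 100, 1000))) {
    centre <- sqrt(prod(spec$band))
    # passband centre within 0.02 dB of unity
    expect_lt(abs(20 * log10(fir_gain(spec, centre))), 0.02)
    # realized -6 dB points at the designed cutoffs
    expect_equal(unname(20 * log10(fir_gain(spec, spec$minus6db_cutoffs))),
                 c(-6.02, -6.02), tolerance = 0.05)
    # stopband attenuation >= 53 dB at band edge -/+ 2 transition widths
    stops <- c(spec$band[1] - 2 * spec$transition_bw[1],
               spec$band[2] + 2 * spec$transition_bw[2])
    stops <- stops[stops > 0 & stops < spec$fs / 2]
    expect_true(all(20 * log10(fir_gain(spec, stops)) < -53))
  }
  expect_error(design_fir_bandpass(5000, 100, 2600), "Nyquist|band edges")
})

test_that("zero-phase application preserves latency and amplitude", {
  spec <- design_fir_bandpass(5000, 100, 1000)
  t <- (0:9999) / 5000
  x <- sin(2 * pi * 150 * t)
  y <- apply_fir(x, spec)
  mid <- 2000:8000
  # no delay: in-band sinusoid reproduced in place
  expect_gt(cor(x[mid], y[mid]), 0.99999)
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.01)
})

test_that("re-referencing follows both schemes exactly", {
  ses <- tiny_session(seed = 2, n_ba = 4, n_pa = 4, n_ta = 0)
  car <- rereference(ses, "common-average")
  expect_lt(max(abs(colSums(car$data))), 1e-9)

  # a common offset added to all channels is removed by both schemes
  off <- sin(2 * pi * 3 * seq_len(ncol(ses$data)) / ses$fs)
  ses_off <- ses
  ses_off$data <- sweep(ses$data, 2, off, `+`)
  for (sch in c("linked-mastoids", "common-average")) {
    expect_equal(rereference(ses_off, sch)$data, rereference(ses, sch)$data,
                 tolerance = 1e-10)
  }

  # zero mastoids: linked-mastoid referencing is the identity
  ses0 <- ses
  ses0$data["TP9", ] <- 0
  ses0$data["TP10", ] <- 0
  expect_equal(rereference(ses0, "linked-mastoids")$data, ses0$data)

  ses_miss <- ses
  rn <- rownames(ses_miss$data)
  rn[rn == "TP9"] <- "XX"
  rownames(ses_miss$data) <- rn
  ses_miss$channel_labels <- rn
  expect_error(rereference(ses_miss, "linked-mastoids"), "TP9")
})

test_that("resampling preserves passband content and rescales events", {
  fs <- 20000
  n <- fs * 4
  t <- (0:(n - 1)) / fs
  ses <- structure(list(
    data = matrix(sin(2 * pi * 150 * t), 1, n, dimnames = list("Cz", NULL)),
    fs = fs, channel_labels = "Cz",
    events = data.frame(sample = c(20000L, 40000L), token = c("ba", "pa"),
                        polarity = c(1L, -1L), block = c(1L, 1L)),
    condition = "clear", reference = "none", ground_truth = NULL),
    class = "ffr_session")
  out <- resample_session(ses, 5000)
  expect_equal(out$fs, 5000)
  expect_equal(out$events$sample, c(5000L, 10000L))
  mid <- 5000:15000
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.01)

  # broadband noise: energy above 2.5 kHz (pre-decimation) is suppressed
  set.seed(1)
  ses$data[1, ] <- rnorm(n)
  filt <- apply_fir(ses$data[1, ], alphaFFR:::design_fir_lowpass(fs, 2200, 400))
  pw <- function(x, f_lo, fs_x) {
    sp <- Mod(fft(x))^2
    fr <- (seq_along(x) - 1) / length(x) * fs_x
    sum(sp[fr > f_lo & fr < fs_x / 2])
  }
  expect_lt(pw(filt, 2500, fs) / pw(ses$data[1, ], 2500, fs), 0.01)

  expect_error(resample_session(out, 20000), "exceeds")
})

test_that("band splitting isolates the FFR and alpha streams", {
  ses <- tiny_session(seed = 4, n_ba = 4, n_pa = 4, n_ta = 0,
                      params = participant_params(noise_sd = 0.01, lf_sd = 0))
  n <- ncol(ses$data)
  t <- (0:(n - 1)) / ses$fs
  # inject pure tones on top: 150 Hz everywhere, 10 Hz posterior
  ses$data <- ses$data * 0
  ses$data["Cz", ] <- sin(2 * pi * 150 * t)
  ses$data["Pz", ] <- sin(2 * pi * 10 * t)
  ses$data["Oz", ] <- sin(2 * pi * 10 * t)
  st <- bandsplit(ses)
  mid <- round(n * 0.3):round(n * 0.7)
  # 150 Hz survives the FFR stream; after common-average referencing the Cz
  # tone keeps 31/32 of its amplitude (minus a removed 10 Hz leak)
  expect_equal(max(abs(st$ffr$data["Cz", mid])), 31 / 32, tolerance = 0.02)
  # 10 Hz survives the alpha stream, 150 Hz is removed from it
  expect_gt(max(abs(st$alpha$data[mid])), 0.9)
  expect_lt(max(abs(st$beta$data[mid])), 1e-2)
  # alpha stream is the Pz/Oz mean: opposite-phase channels cancel
  ses2 <- ses
  ses2$data["Oz", ] <- -ses2$data["Pz", ]
  st2 <- bandsplit(ses2)
  expect_lt(max(abs(st2$alpha$data)), 1e-9)

  # 10 Hz is removed from the FFR stream
  gains <- fir_gain(st$ffr$filter, c(150, 10))
  expect_gt(gains[1], 0.95)
  expect_lt(gains[2], 1e-3)
  a_gains <- fir_gain(st$alpha$filter, c(10, 150))
  expect_gt(a_gains[1], 0.95)
  expect_lt(a_gains[2], 1e-3)
})

test_that("epoching follows the 195-ms half-open convention", {
  fs <- 5000
  n <- fs * 10
  events <- data.frame(sample = c(1000L, seq(5000L, 35000L, 5000L), n - 100L),
                       token = c("ba", "ba", "pa", "ta", "ba", "pa", "ba",
                                 "pa", "ba"),
                       polarity = 1L, block = 1L)
  x <- numeric(n)
  x[events$sample] <- 1            # impulse at each onset
  st <- vector_stream(x, fs, events)
  suppressMessages(ep <- epoch_stream(st))
  # /ta/ excluded; the trailing event's window exceeds the recording
  expect_equal(nrow(ep$data), sum(events$token != "ta") - 1L)
  expect_equal(ncol(ep$data), 975L)          # round(0.195 * 5000)
  # onset impulse lands at in-epoch position round(0.050*fs) + 1 (1-based)
  expect_true(all(ep$data[, round(0.050 * fs) + 1] == 1))
  expect_equal(sum(ep$data), nrow(ep$data))

  # epoching a constant signal is lossless
  stc <- vector_stream(rep(2.5, n), fs, events[2:8, ])
  epc <- epoch_stream(stc)
  expect_true(all(epc$data == 2.5))
})

test_that("a full-length schedule epochs to 6000 frequent trials", {
  # alpha-chain scale check: 6,000 frequent + 210 rare tokens, one stream
  sch <- make_event_schedule(stimulus_spec(), seed = 77)
  fs <- 5000
  events <- data.frame(sample = round(sch$onset_s * fs) + fs,
                       token = sch$token, polarity = sch$polarity,
                       block = sch$block)
  n <- max(events$sample) + fs
  st <- vector_stream(numeric(n), fs, events)
  ep <- epoch_stream(st)
  expect_equal(dim(ep$data), c(6000L, 975L))
  expect_false(any(ep$info$token == "ta"))
})
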
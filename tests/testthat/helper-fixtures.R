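# Shared fixtures built in code: scaled-down schedules and sessions that run
# the full machinery quickly. Token counts are reduced proportionally; all
# generator parameters keep their defaults.

tiny_spec <- function(n_ba = 30, n_pa = 30, n_ta = 4) {
  stimulus_spec(n_ba = n_ba, n_pa = n_pa, n_ta = n_ta)
}

tiny_session <- function(seed = 1, condition = "clear", fs = 5000,
                         n_ba = 30, n_pa = 30, n_ta = 4,
                         params = participant_params(),
                         leadfield = default_leadfield()) {
  sch <- make_event_schedule(tiny_spec(n_ba, n_pa, n_ta), seed = seed)
  simulate_session(params, leadfield, sch, condition, fs = fs,
                   seed = seed + 7000)
}

# Deterministic single-channel "stream" for epoching tests.
vector_stream <- function(data, fs, events, kind = "test") {
  list(data = data, fs = fs, events = events, reference = "none", kind = kind)
}

# Quick F0-ratio estimate from a scaled synthetic session (full pipeline).
pipeline_ratio <- function(seed, coupling, n_tokens = 200, fs = 5000) {
  p <- participant_params(coupling = c(clear = coupling, noise = 0.05))
  sch <- make_event_schedule(
    stimulus_spec(n_ba = n_tokens / 2, n_pa = n_tokens / 2, n_ta = 0),
    seed = seed)
  L <- default_leadfield()
  ses <- simulate_session(p, L, sch, "clear", fs = fs, seed = seed + 5000)
  process_session(ses, L)$f0$ratio
}

# Random spectra feature set with labels independent of features.
null_features <- function(n_per_class = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(abs(rnorm(2 * n_per_class * 226, 1, 0.3)),
                nrow = 2 * n_per_class)
    build_features(x, rep(c("poor", "good"), each = n_per_class))
  })
}
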
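#' Stimulus specification for the oddball speech-token paradigm
#'
#' Describes one condition's token train: frequent /ba/ and /pa/ syllables and
#' the rare /ta/ target, presented with a jittered inter-stimulus interval and
#' alternating polarity. Defaults are the paradigm's standard values: 3,000 +
#' 3,000 frequent and 210 rare 100-ms tokens per condition, F0 = 150 Hz
#' (formants F1 = 885 Hz, F2 = 1,389 Hz used only as spectral coloring), ISI
#' uniform on 95-155 ms in 5-ms steps, three blocks per condition.
#'
#' @param n_ba,n_pa,n_ta token counts per condition.
#' @param token_duration token duration in seconds.
#' @param f0 voice fundamental frequency, Hz.
#' @param formants named numeric vector of formant frequencies, Hz.
#' @param isi_ms allowed inter-stimulus intervals, ms (uniform over this grid).
#' @param n_blocks number of presentation blocks the train is split into.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(n_ba = 3000, n_pa = 3000, n_ta = 210,
                          token_duration = 0.1, f0 = 150,
                          formants = c(F1 = 885, F2 = 1389),
                          isi_ms = seq(95, 155, by = 5), n_blocks = 3) {
  stopifnot(n_ba >= 0, n_pa >= 0, n_ta >= 0, token_duration > 0, f0 > 0,
            all(isi_ms > 0), n_blocks >= 1)
  structure(
    list(n_ba = as.integer(n_ba), n_pa = as.integer(n_pa),
         n_ta = as.integer(n_ta), token_duration = token_duration, f0 = f0,
         formants = formants, isi_ms = isi_ms, n_blocks = as.integer(n_blocks)),
    class = "stimulus_spec")
}

#' Generate a pseudo-random event schedule
#'
#' Builds one condition's token sequence honoring the paradigm constraints:
#' frequent /ba/ and /pa/ tokens in random order, rare /ta/ targets placed so
#' that at least two frequent tokens intervene before every rare token (and
#' between consecutive rare tokens), ISIs drawn uniformly from the 5-ms grid,
#' polarity alternating trial by trial, and the train split evenly into blocks.
#'
#' @param spec a [stimulus_spec()].
#' @param seed optional integer seed for reproducibility.
#' @return A data frame with one row per token: `token`, `polarity` (+1/-1),
#'   `block`, `onset_s` (onset time in seconds from train start), `isi_ms`
#'   (interval following the token).
#' @export
make_event_schedule <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n_freq <- spec$n_ba + spec$n_pa
  n_rare <- spec$n_ta
  if (n_rare > 0 && n_freq < 2L * n_rare) {
    stop("rare-token constraint unsatisfiable: need at least 2 frequent ",
         "tokens per rare token (", n_freq, " frequent < 2 x ", n_rare, ")")
  }
  with_seed_opt(seed, {
    freq_tokens <- sample(c(rep("ba", spec$n_ba), rep("pa", spec$n_pa)))
    if (n_rare > 0) {
      # b[i] = number of frequent tokens preceding rare i; constraints
      # b[1] >= 2 and b[i+1] >= b[i] + 2 via the substitution c = b - 2*(1:r).
      c_off <- sort(sample.int(n_freq - 2L * n_rare + 1L, n_rare,
                               replace = TRUE) - 1L)
      b <- c_off + 2L * seq_len(n_rare)
      tokens <- character(n_freq + n_rare)
      pos <- seq_len(n_rare) + b        # rare positions in the full sequence
      tokens[pos] <- "ta"
      tokens[-pos] <- freq_tokens
    } else {
      tokens <- freq_tokens
    }
    n <- length(tokens)
    isi <- sample(spec$isi_ms, n, replace = TRUE)
    onset <- cumsum(c(0, head(spec$token_duration + isi / 1000, -1)))
    data.frame(
      token = tokens,
      polarity = rep_len(c(1L, -1L), n),
      block = rep(seq_len(spec$n_blocks), each = ceiling(n / spec$n_blocks),
                  length.out = n),
      onset_s = onset,
      isi_ms = isi)
  })
}

# Internal check used by tests and simulate_session(): every rare token must
# be preceded by >= 2 frequent tokens since the previous rare (or train start).
schedule_satisfies_rare_rule <- function(schedule) {
  rare <- which(schedule$token == "ta")
  if (length(rare) == 0L) return(TRUE)
  bounds <- c(0L, rare)
  all(diff(bounds) > 2L)
}
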
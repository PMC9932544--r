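#' Draw a synthetic cohort of NH and HL listeners
#'
#' Samples per-participant generative parameters honoring the group structure
#' the analysis assumes: NH pure-tone averages within 8.3-20.83 dB HL and HL
#' within 15.8-45 dB HL; posterior alpha power higher on average in the NH
#' group; FFR gain mildly decreasing with PTA (which links neural and
#' behavioral measures); and group-by-condition alpha-FFR coupling defaults
#' that mirror the qualitative result pattern (NH coupled for clear speech and
#' weakly in noise; HL uncoupled for clear speech but coupled in noise).
#' Behavior (target detection, reaction times, QuickSiN tallies) is generated
#' per participant with [simulate_behavior()].
#'
#' @param n_nh,n_hl group sizes (defaults 13 and 19).
#' @param seed optional integer seed.
#' @param coupling_nh,coupling_hl named vectors `c(clear=, noise=)` of
#'   alpha-FFR coupling per condition.
#' @return An `ffr_cohort`: list with `participants` (list of
#'   [participant_params()]), `behavior` (one [simulate_behavior()] record per
#'   participant), `leadfield`, and a `cohort` data frame (id, group, pta,
#'   snr_loss, percent correct and mean RT per condition).
#' @export
make_cohort <- function(n_nh = 13, n_hl = 19, seed = NULL,
                        coupling_nh = c(clear = 0.3, noise = 0.05),
                        coupling_hl = c(clear = 0.0, noise = 0.25)) {
  stopifnot(n_nh >= 1, n_hl >= 1)
  with_seed_opt(seed, {
    groups <- c(rep("NH", n_nh), rep("HL", n_hl))
    n <- length(groups)
    participants <- vector("list", n)
    behavior <- vector("list", n)
    for (i in seq_len(n)) {
      g <- groups[i]
      pta <- if (g == "NH") rtrunc_norm(1, 15.3, 3.27, 8.3, 20.83)
             else           rtrunc_norm(1, 26.4, 7.1, 15.8, 45)
      participants[[i]] <- participant_params(
        group = g, pta = pta,
        alpha_base = rtrunc_norm(1, if (g == "NH") 1.5 else 1.0, 0.25, 0.4, Inf),
        alpha_mod_depth = rtrunc_norm(1, 0.5, 0.1, 0.2, 0.8),
        ffr_gain = rtrunc_norm(1, 0.2 - 0.003 * pta, 0.02, 0.05, Inf),
        coupling = if (g == "NH") coupling_nh else coupling_hl,
        id = sprintf("%s%02d", g, i))
      behavior[[i]] <- simulate_behavior(participants[[i]])
    }
    cohort <- data.frame(
      id = vapply(participants, `[[`, "", "id"),
      group = groups,
      pta = vapply(participants, `[[`, 0, "pta"),
      ffr_gain = vapply(participants, `[[`, 0, "ffr_gain"),
      snr_loss = vapply(behavior, `[[`, 0, "snr_loss"),
      pc_clear = vapply(behavior, function(b) b$percent_correct[["clear"]], 0),
      pc_noise = vapply(behavior, function(b) b$percent_correct[["noise"]], 0),
      rt_clear = vapply(behavior, function(b) b$mean_rt[["clear"]], 0),
      rt_noise = vapply(behavior, function(b) b$mean_rt[["noise"]], 0))
    structure(list(participants = participants, behavior = behavior,
                   leadfield = default_leadfield(), cohort = cohort),
              class = "ffr_cohort")
  })
}

#' @export
print.ffr_cohort <- function(x, ...) {
  cat("<ffr_cohort> ", sum(x$cohort$group == "NH"), " NH + ",
      sum(x$cohort$group == "HL"), " HL participants\n", sep = "")
  invisible(x)
}

#' Simulate one participant's behavior
#'
#' Target-detection behavior: the per-trial hit probability for the rare /ta/
#' token is a logistic function of the participant's FFR gain (stronger
#' subcortical encoding, better detection), and mean reaction time decreases
#' with hit probability from a floor of 250 ms, which induces the negative
#' accuracy-RT dependence in the clear condition; in noise both links are
#' weakened. QuickSiN keyword tallies are binomial draws from a logistic
#' psychometric function whose midpoint (SNR-50) tracks the participant's PTA,
#' then scored with [quicksin_score()].
#'
#' @param params a [participant_params()].
#' @param seed optional integer seed.
#' @param n_targets rare-token count per condition.
#' @param n_lists number of QuickSiN lists.
#' @return List with `percent_correct` and `mean_rt` (named by condition; RT
#'   `NA` when there are no hits), `rts`/`hits` per condition,
#'   `quicksin_tallies` (lists x 6 SNR steps), `snr_loss`, `pta`.
#' @export
simulate_behavior <- function(params, seed = NULL, n_targets = 210,
                              n_lists = 4) {
  stopifnot(inherits(params, "participant_params"))
  with_seed_opt(seed, {
    rt_floor <- 250
    hit_p <- c(
      clear = plogis(qlogis(0.85) + 25 * (params$ffr_gain - 0.15)),
      noise = plogis(qlogis(0.70) + 12 * (params$ffr_gain *
                                            params$noise_ffr_scale - 0.12)))
    hits <- rts <- list()
    pc <- mrt <- c(clear = NA_real_, noise = NA_real_)
    for (cond in c("clear", "noise")) {
      p <- hit_p[[cond]]
      h <- if (p > 1 - 1e-12) rep(1L, n_targets)
           else rbinom(n_targets, 1L, p)
      rt_mean <- rt_floor +
        (if (cond == "clear") 350 * (1 - p)
         else 270 + 80 * (1 - p) + rnorm(1, 0, 40))
      r <- rep(NA_real_, n_targets)
      nh <- sum(h)
      if (nh > 0)
        r[h == 1L] <- rlnorm(nh, log(rt_mean) - 0.15^2 / 2, 0.15)
      hits[[cond]] <- h
      rts[[cond]] <- r
      s <- detection_summary(h == 1L, r, n_targets = n_targets)
      pc[cond] <- s$percent_correct
      mrt[cond] <- s$mean_rt
    }
    snr50_true <- 2 + 0.15 * (params$pta - 15) +
      rnorm(1, 0, if (params$group == "NH") 0.6 else 1.8)
    snr_grid <- seq(25, 0, by = -5)
    tallies <- t(vapply(seq_len(n_lists), function(l) {
      rbinom(length(snr_grid), 5L, plogis((snr_grid - snr50_true) / 2.2))
    }, integer(length(snr_grid))))
    colnames(tallies) <- paste0("snr", snr_grid)
    list(percent_correct = pc, mean_rt = mrt, hits = hits, rts = rts,
         quicksin_tallies = tallies,
         snr_loss = mean(apply(tallies, 1, quicksin_score)),
         pta = params$pta)
  })
}

#' Write cohort ground truth and behavior tables to a directory
#'
#' Serializes the cohort manifest plus ground-truth parameters as JSON and the
#' behavior summary as CSV.
#'
#' @param cohort an `ffr_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ffr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(cohort$participants, function(p) unclass(p))
  names(manifest) <- vapply(cohort$participants, `[[`, "", "id")
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(cohort$cohort, file.path(dir, "behavior.csv"), row.names = FALSE)
  write_leadfield(cohort$leadfield, file.path(dir, "leadfield.csv"))
  invisible(dir)
}
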
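test_that("one-sample t on F0 ratios matches the hand computation", {
  r <- f0_ratio_one_sample(c(1.1, 1.2, 1.3))
  # t = (1.2 - 1) / (0.1 / sqrt(3)) = 3.4641, df = 2
  expect_equal(r$statistic, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(r$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_error(f0_ratio_one_sample(rep(1, 5)), "zero variance")
  expect_error(f0_ratio_one_sample(1.2), "at least 2")
})

test_that("group comparison wrappers follow the stated conventions", {
  # identical paired samples: W = 0, p = 1 by the no-difference convention
  x <- c(1, 2, 3, 4)
  w <- group_compare(c(x, x), rep(c("a", "b"), each = 4), "wilcoxon-paired")
  expect_equal(w$statistic, 0)
  expect_equal(w$p, 1)

  # equal-variance F: numerator is the larger-variance group
  set.seed(2)
  nh <- rnorm(13, sd = 0.8)
  hl <- rnorm(19, sd = 2.5)
  fv <- group_compare(c(nh, hl), rep(c("NH", "HL"), c(13, 19)),
                      "equal-variance-F")
  expect_equal(fv$statistic, var(hl) / var(nh))
  expect_equal(unname(fv$df), c(18, 12))
  expect_gt(fv$statistic, 1)
  expect_lt(fv$p, 0.05)

  # Bonferroni bookkeeping: adjusted p = min(1, m * p)
  mw <- group_compare(c(nh, hl + 10), rep(c("NH", "HL"), c(13, 19)),
                      "mann-whitney", m = 4)
  expect_equal(mw$p_adj, min(1, 4 * mw$p))
  expect_equal(bonferroni_adjust(0.4, 3), 1)
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)

  expect_error(group_compare(1:6, rep("a", 6), "mann-whitney"), "2 levels")
  expect_error(group_compare(c(x, 1), rep(c("a", "b"), c(4, 1)),
                             "wilcoxon-paired"), "mismatch")
})

test_that("Mann-Whitney type-I error is calibrated at the 5% level", {
  set.seed(11)
  rej <- mean(vapply(1:1000, function(i) {
    v <- rnorm(32)
    group_compare(v, rep(c("NH", "HL"), c(13, 19)), "mann-whitney")$p < 0.05
  }, TRUE))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("Conover post-hoc matches an independent hand computation", {
  # small 3-group example computed from the published formula by hand (rank
  # sums, pooled rank variance, KW statistic, pairwise t on N - k df)
  v <- c(1.1, 2.3, 3.1, 4.0, 5.2, 6.5, 7.1, 8.3, 9.2)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- conover_posthoc(v, g)
  # oracle: explicit arithmetic, independent of the implementation
  r <- rank(v)
  N <- 9; k <- 3
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- (sum(tapply(r, g, sum)^2 / 3) - N * (N + 1)^2 / 4) / S2
  se <- sqrt(S2 * (N - 1 - H) / (N - k) * (2 / 3))
  t_ab <- (mean(r[1:3]) - mean(r[4:6])) / se
  expect_equal(res$statistic[res$group1 == "a" & res$group2 == "b"],
               t_ab, tolerance = 1e-12)
  expect_equal(res$df[1], 6)
  expect_equal(res$p_adj, pmin(1, 3 * res$p))
  # strongly separated groups are detected; identical groups are not
  expect_true(all(res$p < 0.05))
  res0 <- conover_posthoc(rep(c(1.5, 2.5, 3.5), 3),
                          rep(c("a", "b", "c"), each = 3))
  expect_true(all(res0$p > 0.9))
})

test_that("mixed ANOVA recovers programmed interactions and handles nulls", {
  mk <- function(n_nh = 13, n_hl = 19, interaction = 0, seed = 1) {
    set.seed(seed)
    ids <- paste0("P", 1:(n_nh + n_hl))
    grp <- rep(c("NH", "HL"), c(n_nh, n_hl))
    d <- expand.grid(participant = ids, snr = c("clear", "noise"),
                     alpha = c("low", "high"), stringsAsFactors = FALSE)
    d$group <- grp[match(d$participant, ids)]
    subj_eff <- rnorm(length(ids), 0, 0.3)
    d$f0_amp <- exp(subj_eff[match(d$participant, ids)] + rnorm(nrow(d), 0, 0.2) +
      interaction * (d$group == "NH") * (d$snr == "clear") * (d$alpha == "high"))
    d
  }
  # programmed three-way interaction is detected
  res <- mixed_anova_f0(mk(interaction = 1, seed = 3))
  omni <- res$omnibus
  i3 <- omni[omni$term == "snr:alpha:group", ]
  expect_lt(i3$p, 0.05)
  expect_gt(i3$eta_p2, 0)
  expect_true(all(c("NH", "HL") %in% names(res$by_group)))
  expect_true(all(omni$eta_p2 >= 0 & omni$eta_p2 <= 1))

  # constant amplitudes: every F is 0
  dc <- mk(interaction = 0, seed = 4)
  dc$f0_amp <- 1
  resc <- mixed_anova_f0(dc)
  expect_true(all(resc$omnibus$F == 0))

  # missing cells are refused
  dm <- mk()[-1, ]
  expect_error(mixed_anova_f0(dm), "missing cells")
})

test_that("ANOVA interaction type-I error is calibrated", {
  set.seed(12)
  mk_null <- function() {
    ids <- paste0("P", 1:32)
    grp <- rep(c("NH", "HL"), c(13, 19))
    d <- expand.grid(participant = ids, snr = c("clear", "noise"),
                     alpha = c("low", "high"), stringsAsFactors = FALSE)
    d$group <- grp[match(d$participant, ids)]
    subj <- rnorm(32, 0, 0.3)
    d$f0_amp <- exp(subj[match(d$participant, ids)] + rnorm(nrow(d), 0, 0.2))
    d
  }
  rej <- mean(vapply(1:400, function(i) {
    o <- mixed_anova_f0(mk_null())$omnibus
    o$p[o$term == "snr:alpha:group"] < 0.05
  }, TRUE))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("Spearman correlations handle monotone and reversed inputs", {
  x <- c(2, 5, 1, 9, 7, 4, 8, 3)
  m <- data.frame(mono = exp(x), rev = -x)
  res <- brain_behavior_corr(x, m)
  expect_equal(res$rho[res$measure == "mono"], 1)
  expect_equal(res$rho[res$measure == "rev"], -1)
  expect_true(all(c("shapiro_p_f0", "shapiro_p_measure") %in% names(res)))
  expect_error(brain_behavior_corr(rep(1, 8), m), "constant")
  expect_error(brain_behavior_corr(x[1:3], m[1:3, ]), "n >= 4")
})

test_that("group regression recovers exact coefficients and slope algebra", {
  # noiseless construction: beta = (1, -2, 0.5, 1)
  x <- rep(seq(0, 10, length.out = 8), 2)
  g <- rep(c(0, 1), each = 8)
  y <- 1 - 2 * x + 0.5 * g + 1 * x * g
  fit <- suppressWarnings(fit_group_regression(y, x, g))
  expect_equal(unname(fit$coefficients[, "Estimate"]), c(1, -2, 0.5, 1),
               tolerance = 1e-10)
  expect_equal(fit$slopes$nh, -2, tolerance = 1e-10)
  expect_equal(fit$slopes$hl, -1, tolerance = 1e-10)
  expect_equal(fit$slopes$diff, 1, tolerance = 1e-10)
  expect_equal(fit$formula_id, "Eq2")

  # single-group data: interaction refused
  expect_error(fit_group_regression(y[1:8], x[1:8], g[1:8]), "single-group")

  # diagnostics are reported
  set.seed(13)
  yn <- y + rnorm(16, 0, 0.5)
  fitn <- fit_group_regression(yn, x, g)
  expect_true(is.finite(fitn$diagnostics$shapiro_p))
  expect_true(is.finite(fitn$diagnostics$breusch_pagan_p))
  expect_true(is.finite(fitn$diagnostics$goldfeld_quandt_p))
})

test_that("programmed slope signs are recovered under default noise", {
  # generative model mirroring the cohort structure: negative NH slope of F0
  # amplitude vs PTA, attenuated in HL (positive slope difference)
  recover <- function(seed) {
    set.seed(seed)
    n_nh <- 13; n_hl <- 19
    pta <- c(runif(n_nh, 8.3, 20.83), runif(n_hl, 15.8, 45))
    g <- rep(c(0, 1), c(n_nh, n_hl))
    y <- 2 - 0.04 * pta + 0.5 * g + 0.03 * pta * g + rnorm(32, 0, 0.15)
    s <- fit_group_regression(y, pta, g)$slopes
    (s$nh < 0) && (s$diff > 0)
  }
  hits <- mean(vapply(1:200, recover, TRUE))
  expect_gte(hits, 0.9)
})

test_that("an inert age covariate leaves the slopes essentially unchanged", {
  set.seed(14)
  x <- rep(seq(0, 10, length.out = 16), 2)
  g <- rep(c(0, 1), each = 16)
  age <- sample(rep(seq(-1, 1, length.out = 16), 2))  # orthogonalized draw
  age <- age - mean(age)
  y <- 1 - 2 * x + 0.5 * g + 1 * x * g + rnorm(32, 0, 0.4)
  f2 <- fit_group_regression(y, x, g)
  f3 <- fit_group_regression(y, x, g, age = age)
  expect_equal(f3$formula_id, "Eq3")
  expect_lt(abs(f3$slopes$nh - f2$slopes$nh), f2$slopes$se_nh)
  expect_lt(abs(f3$slopes$diff - f2$slopes$diff), f2$slopes$se_diff)
})
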
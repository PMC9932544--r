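#' One-sample t-test of F0 ratios against 1
#'
#' Tests whether a group's F0 ratios differ from 1 (no alpha modulation of
#' the brainstem FFR), two-sided.
#'
#' @param ratios numeric vector of F0 ratios (n >= 2).
#' @return list: `test`, `statistic` (t), `df`, `p`, `mean`.
#' @export
f0_ratio_one_sample <- function(ratios) {
  if (length(ratios) < 2) stop("need at least 2 ratios")
  if (sd(ratios) == 0)
    stop("zero variance: one-sample t against 1 is undefined")
  tt <- t.test(ratios, mu = 1)
  list(test = "one-sample t vs 1", statistic = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, mean = mean(ratios))
}

#' Bonferroni adjustment
#' @param p raw p-value(s).
#' @param m number of comparisons in the family.
#' @return adjusted p, `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m) pmin(1, m * p)

#' Two-group and paired comparisons used by the analysis
#'
#' Thin, bookkeeping-aware wrappers over the standard tests: Mann-Whitney U
#' (unpaired Wilcoxon rank-sum), paired Wilcoxon signed-rank (with the
#' convention that identical pairs give W = 0, p = 1), Welch t, the
#' equal-variance two-sample F test (numerator = larger-variance group, so
#' F >= 1), and Fisher's exact test for a 2 x k table. All two-sided; an
#' optional Bonferroni family size `m` adds the adjusted p.
#'
#' @param values numeric vector (or contingency matrix for
#'   `"fisher-exact"`).
#' @param groups two-level factor aligned with `values`; for
#'   `"wilcoxon-paired"` the pairing is by order within group.
#' @param test one of `"mann-whitney"`, `"wilcoxon-paired"`, `"welch-t"`,
#'   `"equal-variance-F"`, `"fisher-exact"`.
#' @param m Bonferroni family size (default 1 = no adjustment).
#' @return list: `test`, `statistic`, `df` (where defined), `p`, `p_adj`.
#' @export
group_compare <- function(values, groups = NULL,
                          test = c("mann-whitney", "wilcoxon-paired",
                                   "welch-t", "equal-variance-F",
                                   "fisher-exact"),
                          m = 1) {
  test <- match.arg(test)
  if (test == "fisher-exact") {
    ft <- fisher.test(values)
    return(list(test = test, statistic = NA_real_, df = NULL, p = ft$p.value,
                p_adj = bonferroni_adjust(ft$p.value, m)))
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  out <- switch(test,
    "mann-whitney" = {
      wt <- wilcox.test(x, y, exact = FALSE)
      list(statistic = unname(wt$statistic), df = NULL, p = wt$p.value)
    },
    "wilcoxon-paired" = {
      if (length(x) != length(y)) stop("pairing length mismatch")
      if (all(x == y)) {
        list(statistic = 0, df = NULL, p = 1)   # no-difference convention
      } else {
        wt <- wilcox.test(x, y, paired = TRUE, exact = FALSE)
        list(statistic = unname(wt$statistic), df = NULL, p = wt$p.value)
      }
    },
    "welch-t" = {
      tt <- t.test(x, y)
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
    },
    "equal-variance-F" = {
      if (var(x) >= var(y)) vt <- var.test(x, y) else vt <- var.test(y, x)
      list(statistic = unname(vt$statistic),
           df = unname(vt$parameter), p = vt$p.value)
    })
  c(list(test = test), out, list(p_adj = bonferroni_adjust(out$p, m)))
}

#' Conover-Iman post-hoc pairwise test
#'
#' Non-parametric pairwise comparisons on pooled ranks following a
#' Kruskal-Wallis test, with Bonferroni adjustment over all pairs: the
#' statistic for groups i, j is `(Rbar_i - Rbar_j) / sqrt(S2 * (N - 1 - H) /
#' (N - k) * (1/n_i + 1/n_j))`, referred to a t distribution on `N - k` df,
#' where `S2` is the pooled rank variance and `H` the (tie-corrected)
#' Kruskal-Wallis statistic.
#'
#' @param values numeric vector.
#' @param groups factor (k >= 2 levels) aligned with `values`.
#' @return data frame: one row per pair with `group1`, `group2`, `statistic`
#'   (t), `df`, `p`, `p_adj` (Bonferroni over pairs).
#' @export
conover_posthoc <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)
  n_i <- tabulate(groups)
  rbar <- tapply(r, groups, mean)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- (sum(tapply(r, groups, sum)^2 / n_i) - N * (N + 1)^2 / 4) / S2
  pairs <- utils::combn(levels(groups), 2)
  m <- ncol(pairs)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = NA_real_, df = N - k, p = NA_real_)
  denom_scale <- S2 * (N - 1 - H) / (N - k)
  for (j in seq_len(m)) {
    i1 <- match(pairs[1, j], levels(groups))
    i2 <- match(pairs[2, j], levels(groups))
    se <- sqrt(denom_scale * (1 / n_i[i1] + 1 / n_i[i2]))
    tstat <- (rbar[[i1]] - rbar[[i2]]) / se
    res$statistic[j] <- tstat
    res$p[j] <- 2 * pt(-abs(tstat), N - k)
  }
  res$p_adj <- bonferroni_adjust(res$p, m)
  res
}

#' Mixed ANOVA on log F0 amplitudes
#'
#' The 2 x 2 x 2 (SNR condition x alpha state x hearing group) mixed-model
#' ANOVA with participants as the random factor, run on log-transformed F0
#' amplitudes, followed by separate 2 x 2 (alpha x SNR) within-group ANOVAs.
#' The model structure is fixed here; the sums of squares come from the
#' classical `aov` error-strata decomposition, and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` within each term's stratum. Constant
#' data yield F = 0 for every term.
#'
#' @param data data frame with columns `participant`, `group` (between),
#'   `snr`, `alpha` (within), and `f0_amp` (positive amplitudes).
#' @param log_transform log-transform amplitudes first (the analysis
#'   convention).
#' @return list: `omnibus` (data frame of terms with F, df, p, eta_p2) and
#'   `by_group` (same per hearing group).
#' @export
mixed_anova_f0 <- function(data, log_transform = TRUE) {
  need <- c("participant", "group", "snr", "alpha", "f0_amp")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  d <- data
  d$participant <- factor(d$participant)
  d$group <- factor(d$group)
  d$snr <- factor(d$snr)
  d$alpha <- factor(d$alpha)
  cells <- table(d$participant, d$snr, d$alpha)
  if (any(cells != 1)) stop("missing cells: need one amplitude per ",
                            "participant x snr x alpha")
  d$y <- if (log_transform) log(d$f0_amp) else d$f0_amp

  omnibus <- aov_table(aov(y ~ snr * alpha * group +
                             Error(participant / (snr * alpha)), data = d))
  by_group <- lapply(split(d, d$group), function(dg) {
    aov_table(aov(y ~ snr * alpha + Error(participant / (snr * alpha)),
                  data = dg))
  })
  list(omnibus = omnibus, by_group = by_group)
}

# Flatten an aov error-strata summary into term rows with partial eta^2.
aov_table <- function(fit) {
  s <- summary(fit)
  rows <- list()
  for (stratum in s) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    terms_i <- trimws(rownames(tab))
    res_i <- terms_i == "Residuals"
    if (!any(res_i)) next
    ss_err <- tab$`Sum Sq`[res_i]
    df_err <- tab$Df[res_i]
    for (i in which(!res_i)) {
      ss <- tab$`Sum Sq`[i]
      f <- tab$`F value`[i]
      p <- tab$`Pr(>F)`[i]
      if (is.na(f) || (ss < 1e-20 && ss_err < 1e-20)) {
        f <- 0; p <- 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        term = terms_i[i], df = tab$Df[i], df_error = df_err, F = f, p = p,
        eta_p2 = if (ss + ss_err > 0) ss / (ss + ss_err) else 0)
    }
  }
  do.call(rbind, rows)
}

#' Spearman brain-behavior correlations
#'
#' Pairwise Spearman correlations between F0 amplitudes (per alpha state) and
#' behavioral measures across the pooled cohort, with Shapiro-Wilk normality
#' screens logged as the rationale for the rank-based test.
#'
#' @param f0_amps numeric vector (one value per participant, e.g. low-alpha
#'   F0 amplitudes).
#' @param measures data frame of behavioral measures (columns, one row per
#'   participant).
#' @return data frame: `measure`, `rho`, `p`, `shapiro_p_f0`,
#'   `shapiro_p_measure`.
#' @export
brain_behavior_corr <- function(f0_amps, measures) {
  stopifnot(is.data.frame(measures), nrow(measures) == length(f0_amps))
  if (length(f0_amps) < 4) stop("need n >= 4 paired observations")
  if (sd(f0_amps) == 0) stop("constant input")
  sw <- function(x) tryCatch(shapiro.test(x)$p.value,
                             error = function(e) NA_real_)
  do.call(rbind, lapply(names(measures), function(nm) {
    x <- measures[[nm]]
    ok <- is.finite(x) & is.finite(f0_amps)
    ct <- suppressWarnings(
      cor.test(f0_amps[ok], x[ok], method = "spearman", exact = FALSE))
    data.frame(measure = nm, rho = unname(ct$estimate), p = ct$p.value,
               shapiro_p_f0 = sw(f0_amps[ok]), shapiro_p_measure = sw(x[ok]))
  }))
}

#' Dummy-coded group regression with slope contrasts and diagnostics
#'
#' Ordinary least squares of `Y = b0 + b1 X + b2 group + b3 X:group`
#' (optionally `+ b4 age`), with group coded 0 for NH and 1 for HL. By
#' construction `b1` is the NH slope, `b1 + b3` the HL slope, and `b3` the
#' slope difference. Residual diagnostics (Shapiro-Wilk normality,
#' Breusch-Pagan and Goldfeld-Quandt heteroscedasticity with the median-of-X
#' split omitting the middle 20%) gate interpretation; failures are flagged,
#' not fatal.
#'
#' @param y response (e.g. low-alpha F0 amplitudes).
#' @param x behavioral predictor (QuickSiN, PTA, percent correct, or RT).
#' @param group 0/1 vector or NH/HL factor (NH = 0). Both groups must be
#'   present (otherwise the interaction is collinear and fitting is refused).
#' @param age optional covariate.
#' @return An `ffr_regression`: list with `formula_id` ("Eq2"/"Eq3"),
#'   `coefficients` (estimate/SE/t/p table), `slopes` (NH, HL, difference,
#'   with SEs), `diagnostics` (shapiro_p, breusch_pagan_p, goldfeld_quandt_p,
#'   `pass`), and the underlying `model`.
#' @export
fit_group_regression <- function(y, x, group, age = NULL) {
  g <- if (is.factor(group) || is.character(group)) {
    as.numeric(factor(group, levels = c("NH", "HL"))) - 1
  } else as.numeric(group)
  if (any(is.na(g)) || !all(g %in% c(0, 1)))
    stop("group must be 0/1 or an NH/HL factor")
  if (length(unique(g)) < 2)
    stop("single-group data: interaction term would be collinear; ",
         "fit a simple regression instead")
  d <- data.frame(y = y, x = x, g = g)
  has_age <- !is.null(age)
  if (has_age) d$age <- age
  fit <- lm(if (has_age) y ~ x + g + x:g + age else y ~ x + g + x:g, data = d)
  cf <- summary(fit)$coefficients
  V <- vcov(fit)
  b1 <- cf["x", "Estimate"]
  b3 <- cf["x:g", "Estimate"]
  se_hl <- sqrt(V["x", "x"] + V["x:g", "x:g"] + 2 * V["x", "x:g"])
  mid <- 0.20
  diag_ <- list(
    shapiro_p = tryCatch(shapiro.test(resid(fit))$p.value,
                         error = function(e) NA_real_),
    breusch_pagan_p = lmtest::bptest(fit)$p.value,
    goldfeld_quandt_p = lmtest::gqtest(
      fit, order.by = d$x, fraction = mid,
      alternative = "two.sided")$p.value)
  diag_$pass <- all(vapply(diag_[1:3], function(p) is.na(p) || p > 0.05,
                           TRUE))
  structure(list(
    formula_id = if (has_age) "Eq3" else "Eq2",
    coefficients = cf,
    slopes = list(nh = b1, hl = b1 + b3, diff = b3,
                  se_nh = cf["x", "Std. Error"], se_hl = se_hl,
                  se_diff = cf["x:g", "Std. Error"],
                  p_nh = cf["x", "Pr(>|t|)"], p_diff = cf["x:g", "Pr(>|t|)"]),
    diagnostics = diag_,
    model = fit), class = "ffr_regression")
}

#' @export
print.ffr_regression <- function(x, ...) {
  cat("<ffr_regression ", x$formula_id, "> slope_NH=",
      signif(x$slopes$nh, 4), " (p=", signif(x$slopes$p_nh, 3),
      "), slope_HL=", signif(x$slopes$hl, 4),
      ", slope_diff=", signif(x$slopes$diff, 4),
      " (p=", signif(x$slopes$p_diff, 3), "); diagnostics ",
      if (x$diagnostics$pass) "pass" else "FLAGGED", "\n", sep = "")
  invisible(x)
}
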
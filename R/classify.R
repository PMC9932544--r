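#' Assemble the classifier feature matrix
#'
#' Rows are poor/good performers, columns the 226 absolute amplitudes of the
#' steady-state FFR spectrum (the full 10-100 ms / 450-sample convention is
#' guarded by the bin count). Labels must be binary poor/good with no
#' duplicates or missing values.
#'
#' @param spectra numeric matrix (participants x 226) or list of
#'   `ffr_spectrum` objects.
#' @param labels factor/character of `"poor"`/`"good"`, one per row.
#' @param participants participant ids (unique).
#' @param alpha_state,condition provenance recorded with the matrix.
#' @return An `ffr_features`: list with `x` (matrix), `y` (factor),
#'   `participants`, `alpha_state`, `condition`.
#' @export
build_features <- function(spectra, labels, participants = NULL,
                           alpha_state = NA, condition = NA) {
  x <- if (is.list(spectra) && !is.data.frame(spectra) && !is.matrix(spectra)) {
    do.call(rbind, lapply(spectra, function(s) {
      stopifnot(inherits(s, "ffr_spectrum"))
      s$amps
    }))
  } else as.matrix(spectra)
  if (ncol(x) != 226)
    stop("feature matrix must have exactly 226 spectral bins, got ", ncol(x),
         " (check the 450-sample steady-state window)")
  y <- factor(labels)
  if (!setequal(levels(y), c("poor", "good")) || nlevels(y) != 2)
    stop("labels must be binary poor/good")
  y <- factor(y, levels = c("poor", "good"))
  if (length(y) != nrow(x)) stop("labels/rows mismatch")
  if (anyNA(x)) stop("feature matrix contains missing values")
  participants <- participants %||% paste0("P", seq_len(nrow(x)))
  if (anyDuplicated(participants)) stop("duplicate participant ids")
  structure(list(x = x, y = y, participants = participants,
                 alpha_state = alpha_state, condition = condition),
            class = "ffr_features")
}

# Stratified split into k folds of (near-)equal total size with class counts
# balanced across folds. Returns a list of test-index vectors.
stratified_folds <- function(y, k = 4) {
  n <- length(y)
  fold_of <- integer(n)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  remaining <- sizes
  for (lev in sample(levels(y))) {           # class order randomized
    idx <- sample(which(y == lev))
    nl <- length(idx)
    base <- nl %/% k
    extra <- nl - base * k
    take <- rep(base, k)
    if (extra > 0) {
      # give extras to the folds with the most remaining capacity (ties random)
      ord <- order(remaining - take, sample(k), decreasing = TRUE)
      take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
    }
    pos <- 1L
    for (f in seq_len(k)) {
      if (take[f] > 0) {
        fold_of[idx[pos:(pos + take[f] - 1L)]] <- f
        pos <- pos + take[f]
      }
    }
    remaining <- remaining - take
  }
  lapply(seq_len(k), function(f) which(fold_of == f))
}

# Random oversampling of the minority class: returns training indices with
# the minority resampled (with replacement) up to the majority count.
oversample_minority <- function(train_idx, y) {
  tab <- table(y[train_idx])
  if (length(tab) < 2 || any(tab == 0))
    stop("a class is absent from the training fold")
  if (tab[1] == tab[2]) return(train_idx)
  minority <- names(tab)[which.min(tab)]
  mino_idx <- train_idx[y[train_idx] == minority]
  extra <- sample(mino_idx, max(tab) - min(tab), replace = TRUE)
  c(train_idx, extra)
}

#' Mean cross-validated SVM accuracy for one iteration
#'
#' One iteration of the classification procedure: stratified 4-fold split of
#' participants; within each training portion the minority class is randomly
#' oversampled (the held-out fold is never resampled); a radial-basis SVM
#' (C = 1,000, gamma by the "scale" convention `1 / (p * var(X_train))`, no
#' feature standardization) is trained and scored on the held-out fold; fold
#' accuracies are averaged.
#'
#' @param features an [build_features()] result.
#' @param seed optional integer seed for this iteration.
#' @param k folds.
#' @param cost SVM penalty.
#' @return mean accuracy in `[0, 1]`.
#' @export
crossval_accuracy <- function(features, seed = NULL, k = 4, cost = 1000) {
  stopifnot(inherits(features, "ffr_features"))
  if (min(table(features$y)) < k)
    stop("need at least ", k, " participants per class")
  with_seed_opt(seed, {
    folds <- stratified_folds(features$y, k)
    acc <- vapply(folds, function(test_idx) {
      train_idx <- setdiff(seq_along(features$y), test_idx)
      train_idx <- oversample_minority(train_idx, features$y)
      xtr <- features$x[train_idx, , drop = FALSE]
      gam <- 1 / (ncol(xtr) * var(as.vector(xtr)))
      fit <- e1071::svm(xtr, features$y[train_idx],
                        type = "C-classification", kernel = "radial",
                        cost = cost, gamma = gam, scale = FALSE)
      pred <- predict(fit, features$x[test_idx, , drop = FALSE])
      mean(pred == features$y[test_idx])
    }, 0)
    mean(acc)
  })
}

#' Distribution of cross-validated accuracies over iterations
#'
#' Repeats [crossval_accuracy()] with fresh random fold assignments (and
#' oversampling draws) `n_iter` times; the published procedure uses
#' N = 5,000 iterations.
#'
#' @param features an `ffr_features`.
#' @param n_iter number of iterations.
#' @param seed master seed (the whole distribution is reproducible under it).
#' @inheritParams crossval_accuracy
#' @return numeric vector of `n_iter` mean accuracies.
#' @export
run_iterations <- function(features, n_iter = 5000, seed = NULL, k = 4,
                           cost = 1000) {
  with_seed_opt(seed, {
    vapply(seq_len(n_iter),
           function(i) crossval_accuracy(features, k = k, cost = cost), 0)
  })
}

#' Null accuracy distribution via within-participant feature shuffling
#'
#' Each null iteration independently permutes the 226 spectral values within
#' every participant's row (destroying the frequency structure while
#' preserving each row's amplitude multiset), then runs the identical
#' stratified-CV / oversampling / SVM procedure.
#'
#' @inheritParams run_iterations
#' @return numeric vector of `n_iter` null accuracies.
#' @export
null_distribution <- function(features, n_iter = 5000, seed = NULL, k = 4,
                              cost = 1000) {
  with_seed_opt(seed, {
    vapply(seq_len(n_iter), function(i) {
      shuffled <- features
      shuffled$x <- t(apply(features$x, 1, sample))
      crossval_accuracy(shuffled, k = k, cost = cost)
    }, 0)
  })
}

#' Empirical p-value of classifier performance
#'
#' `p = (a + 1) / (n + 1)` where `a` counts null accuracies strictly
#' exceeding the median of the actual accuracy distribution and `n` is the
#' null count.
#'
#' @param actual,null accuracy vectors from [run_iterations()] and
#'   [null_distribution()].
#' @return A `classifier_significance`: list with `a`, `n`, `p`,
#'   `median_actual`, `median_null`.
#' @export
empirical_p <- function(actual, null) {
  stopifnot(length(actual) > 0, length(null) > 0)
  a <- sum(null > median(actual))
  n <- length(null)
  structure(list(a = a, n = n, p = (a + 1) / (n + 1),
                 median_actual = median(actual), median_null = median(null)),
            class = "classifier_significance")
}

#' @export
print.classifier_significance <- function(x, ...) {
  cat("<classifier_significance> median accuracy ",
      round(100 * x$median_actual, 1), "% vs null ",
      round(100 * x$median_null, 1), "%; a=", x$a, ", n=", x$n,
      ", p=", signif(x$p, 3), "\n", sep = "")
  invisible(x)
}

#' Full permutation-validated classification of perceptual performance
#'
#' Convenience wrapper running the actual and null iteration distributions
#' and the empirical p-value for one feature set.
#'
#' @inheritParams run_iterations
#' @return list: `actual`, `null` (accuracy vectors), `significance`
#'   (a [empirical_p()] result).
#' @export
classify_performance <- function(features, n_iter = 5000, seed = NULL,
                                 k = 4, cost = 1000) {
  with_seed_opt(seed, {
    actual <- run_iterations(features, n_iter, k = k, cost = cost)
    null <- null_distribution(features, n_iter, k = k, cost = cost)
    list(actual = actual, null = null,
         significance = empirical_p(actual, null))
  })
}
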
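#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov coef cor.test fft fisher.test lm median plogis pnorm
#'   predict pt qlogis quantile rbinom rlnorm rnorm runif sd shapiro.test
#'   t.test var var.test vcov wilcox.test approx nextn resid
#' @importFrom utils head write.csv
NULL

# Evaluate `code` under a fixed RNG seed when one is given; otherwise use the
# current RNG stream.  All stochastic entry points funnel through this so a
# seed makes them bit-reproducible.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Truncated-normal draw by rejection; bounds are hard constraints (used for
# audiometric and amplitude parameters that live on printed ranges).
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  for (i in 1:1000) {
    out[need] <- rnorm(length(need), mean, sd)
    need <- which(out < lower | out > upper)
    if (length(need) == 0L) return(out)
  }
  # pathological bounds: clamp remainder
  pmin(pmax(out, lower), upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
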
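# Simulation-based power analysis for detecting an observed precision
# (1 SD of device-minus-reference differences) below a stated bound.
#
# The published-style statement "an experiment with N subjects has an 80%
# chance of observing a precision of t% or less when the true precision is
# 3%" depends on how strongly differences cluster within subject, so the
# intraclass correlation is an explicit parameter here and power is
# reported as a function of it.

#' Closed-form power under independence
#'
#' With `n` independent differences of true SD `sigma`, the sample SD
#' satisfies \eqn{(n-1) S^2 / \sigma^2 \sim \chi^2_{n-1}}, so
#' \eqn{P(S \le t) = F_{\chi^2}\!\big((n-1) t^2 / \sigma^2;\; n-1\big)}.
#' Serves as the analytic reference for [precision_power()] at `icc = 0`.
#'
#' @param n number of independent differences.
#' @param true_sd true SD (%).
#' @param threshold observed-precision bound (%).
#' @return probability that the observed SD is at most `threshold`.
#' @export
precision_power_exact <- function(n, true_sd, threshold) {
  stopifnot(n >= 2L, true_sd > 0)
  if (any(threshold <= 0)) {
    stop_oxival("threshold must be positive", "oxival_value_error")
  }
  pchisq((n - 1) * threshold^2 / true_sd^2, df = n - 1)
}

#' Simulated power to observe a precision below a bound
#'
#' Simulates `reps` studies of `n_subjects` x `n_per_subject` clustered
#' differences whose total variance `true_sd^2` is split into a
#' between-subject component `icc * true_sd^2` and a within-subject
#' remainder, and reports the fraction of studies whose pooled sample SD is
#' at most `threshold`.
#'
#' @param n_subjects,n_per_subject study dimensions.
#' @param true_sd true total SD of the differences (%).
#' @param icc intraclass correlation of differences within subject,
#'   in \[0, 1).
#' @param threshold observed-precision bound (%); may be a vector.
#' @param reps number of simulated studies (>= 100).
#' @param seed integer RNG seed.
#' @return data frame with columns `threshold`, `power`, `mc_se`
#'   (binomial Monte-Carlo SE), plus attributes `icc` and `reps`.
#' @export
precision_power <- function(n_subjects = 24L, n_per_subject = 9L,
                            true_sd = 3, icc = 0, threshold = 3.8,
                            reps = 2000L, seed = 1L) {
  stopifnot(true_sd > 0, icc >= 0, icc < 1, reps >= 100L)
  if (any(threshold <= 0)) {
    stop_oxival("threshold must be positive", "oxival_value_error")
  }
  n_tot <- n_subjects * n_per_subject
  sd_b <- sqrt(icc) * true_sd
  sd_w <- sqrt(1 - icc) * true_sd
  obs_sd <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      b <- rnorm(n_subjects, 0, sd_b)
      d <- rep(b, each = n_per_subject) + rnorm(n_tot, 0, sd_w)
      sd1(d)
    }, numeric(1))
  })
  power <- vapply(threshold, function(t) mean(obs_sd <= t), numeric(1))
  out <- data.frame(threshold = threshold, power = power,
                    mc_se = sqrt(power * (1 - power) / reps))
  attr(out, "icc") <- icc
  attr(out, "reps") <- reps
  out
}
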
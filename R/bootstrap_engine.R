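# Bootstrap model validation for panel (subject x plateau) data.
#
# Scheme I resamples whole subjects with replacement, keeping each
# subject's plateau series intact so the within-subject correlation
# structure is preserved.  Scheme II is a double bootstrap: subjects are
# resampled first, then each drawn subject's 9-point series is resampled
# with overlapping moving blocks (block 3, overlap 2 for a 9-point series)
# to respect serial dependence along the plateau sequence.

#' Resample subjects with replacement (scheme I)
#'
#' Draws `n_subjects` subject ids with replacement; each drawn subject
#' contributes its entire point series intact.  Duplicated draws receive
#' distinct resample ids so downstream per-subject fits treat them as
#' separate clusters.
#'
#' @param series a `paired_series` with at least 2 subjects.
#' @return a `paired_series` with the same number of subjects.
#' @export
resample_subjects <- function(series) {
  subjects <- unique(as.character(series$subject_id))
  if (length(subjects) < 2L) {
    stop_oxival("subject resampling needs at least 2 subjects",
                "oxival_insufficient_data_error")
  }
  draw <- sample(subjects, length(subjects), replace = TRUE)
  idx <- split(seq_len(nrow(series)), series$subject_id)
  pieces <- lapply(seq_along(draw), function(k) {
    piece <- series[idx[[draw[k]]], , drop = FALSE]
    piece$subject_id <- sprintf("%s.%d", draw[k], k)
    piece
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "r_v") <- attr(series, "r_v")
  class(out) <- class(series)
  out
}

#' Overlapping moving blocks of a series
#'
#' All contiguous index windows of length `b` advancing by stride
#' `b - v`.  With the protocol's 9-point series, block size 3 and overlap 2
#' give the 7 windows 1:3, 2:4, ..., 7:9.
#'
#' @param n series length.
#' @param b block size, `1 <= b <= n`.
#' @param v overlap between consecutive blocks; default `b - 1` (stride 1).
#' @return list of integer index vectors.
#' @export
moving_blocks <- function(n, b, v = b - 1L) {
  if (b > n) stop_oxival("block size exceeds series length",
                         "oxival_value_error")
  stopifnot(b >= 1L, v >= 0L, v < b)
  stride <- b - v
  starts <- seq.int(1L, n - b + 1L, by = stride)
  lapply(starts, function(s) seq.int(s, s + b - 1L))
}

#' Data-driven block size for the moving-block bootstrap
#'
#' The cube-root rule \eqn{b = n^{1/3}}, rounded up and clamped to
#' \[2, n\]: a 9-point plateau series gives block size 3.
#'
#' @param n series length, `n >= 2`.
#' @return integer block size.
#' @export
choose_block_size <- function(n) {
  stopifnot(n >= 2L)
  n <- as.integer(n)
  min(n, max(2L, as.integer(ceiling(n^(1 / 3) - 1e-9))))
}

#' Moving-block resample of a within-subject series (scheme II inner step)
#'
#' Draws `ceiling(n / b)` blocks with replacement from [moving_blocks()],
#' concatenates them in draw order and truncates to the original length.
#'
#' @param n length of the subject's ordered series.
#' @param b block size; default [choose_block_size()].
#' @param v overlap; default `b - 1`.
#' @return integer vector of `n` indices into the original series.
#' @export
resample_within_subject <- function(n, b = choose_block_size(n), v = b - 1L) {
  blocks <- moving_blocks(n, b, v)
  draws <- sample.int(length(blocks), ceiling(n / b), replace = TRUE)
  idx <- unlist(blocks[draws], use.names = FALSE)
  idx[seq_len(n)]
}

# named statistics evaluated on a series_split() subject list
boot_statistics <- function(lambda, model) {
  list(
    "deming_pooled.slope" = function(subjects) {
      fit <- pooled_deming_core(subjects, lambda, model)
      if (is.null(fit)) NA_real_ else fit$slope$estimate
    },
    "deming_pooled.intercept" = function(subjects) {
      fit <- pooled_deming_core(subjects, lambda, model)
      if (is.null(fit)) NA_real_ else fit$intercept$estimate
    },
    "rcm.slope" = function(subjects) rcm_core(subjects)["slope"],
    "rcm.intercept" = function(subjects) rcm_core(subjects)["intercept"],
    "ccc" = function(subjects) {
      x <- unlist(lapply(subjects, `[[`, "x"), use.names = FALSE)
      y <- unlist(lapply(subjects, `[[`, "y"), use.names = FALSE)
      ccc_naive_core(x, y)
    })
}

rcm_core <- function(subjects) {
  df <- data.frame(
    y = unlist(lapply(subjects, `[[`, "y"), use.names = FALSE),
    x = unlist(lapply(subjects, `[[`, "x"), use.names = FALSE),
    subject = rep(seq_along(subjects),
                  vapply(subjects, function(s) length(s$x), integer(1))))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(y ~ x + (x | subject), data = df, REML = TRUE,
               control = ctrl))), error = function(e) NULL)
  if (is.null(fit)) return(c(slope = NA_real_, intercept = NA_real_))
  b <- lme4::fixef(fit)
  c(slope = unname(b["x"]), intercept = unname(b["(Intercept)"]))
}

#' Bootstrap validation of an agreement statistic
#'
#' Recomputes a statistic on `B` bootstrap replicates of the study and
#' reports the observed value, the bootstrap SE, the normal-approximation
#' 95% CI (`observed +/- 1.96 se_boot`) and the bias-corrected percentile
#' 95% CI (\eqn{z_0 = \Phi^{-1}(\#\{replicate < observed\}/B)}, bounds at
#' the \eqn{\Phi(2 z_0 \pm 1.96)} percentiles of the replicates).
#'
#' Scheme `"I"` resamples subjects only ([resample_subjects()]); scheme
#' `"II"` additionally moving-block-resamples each drawn subject's ordered
#' plateau series ([resample_within_subject()]).  The CCC statistic uses
#' the naive Lin estimator within replicates: the cluster structure is
#' carried by the subject resampling itself.
#'
#' @param series a `paired_series`.
#' @param statistic one of `"deming_pooled.slope"`,
#'   `"deming_pooled.intercept"`, `"rcm.slope"`, `"rcm.intercept"`, `"ccc"`.
#' @param scheme `"I"` or `"II"`.
#' @param B number of bootstrap replicates; default 500.
#' @param seed integer seed; the call is deterministic given
#'   (series, statistic, scheme, B, seed).
#' @param lambda,model Deming settings for the pooled statistics.
#' @param block,overlap moving-block parameters for scheme II; defaults per
#'   [choose_block_size()] of the per-subject series length.
#' @return an `oxi_bootstrap` list: `estimand`, `observed`, `replicates`,
#'   `B`, `n_failed`, `se_boot`, `ci_normal`, `ci_bias_corrected`, `scheme`,
#'   `seed`.
#' @export
bootstrap_validate <- function(series, statistic, scheme = c("I", "II"),
                               B = 500L, seed = 1L, lambda = 1,
                               model = "random", block = NULL,
                               overlap = NULL) {
  scheme <- match.arg(scheme)
  if (B < 100L) {
    stop_oxival("B must be at least 100", "oxival_value_error")
  }
  stats_tab <- boot_statistics(lambda, model)
  if (!statistic %in% names(stats_tab)) {
    stop_oxival(sprintf("unknown statistic '%s'", statistic),
                "oxival_value_error")
  }
  stat_fun <- stats_tab[[statistic]]
  subjects <- series_split(series)
  n_subj <- length(subjects)
  if (n_subj < 2L) {
    stop_oxival("bootstrap needs at least 2 subjects",
                "oxival_insufficient_data_error")
  }
  observed <- stat_fun(subjects)
  if (is.na(observed)) {
    stop_oxival("statistic is undefined on the observed data",
                "oxival_degenerate_error")
  }

  reps <- with_seed(seed, {
    vapply(seq_len(B), function(bb) {
      draw <- sample.int(n_subj, n_subj, replace = TRUE)
      boot_subj <- subjects[draw]
      if (scheme == "II") {
        boot_subj <- lapply(boot_subj, function(s) {
          n <- length(s$x)
          bsize <- if (is.null(block)) choose_block_size(n) else block
          if (bsize > n) bsize <- n
          ov <- if (is.null(overlap)) bsize - 1L else min(overlap, bsize - 1L)
          idx <- resample_within_subject(n, bsize, ov)
          list(x = s$x[idx], y = s$y[idx])
        })
      }
      tryCatch(stat_fun(boot_subj), error = function(e) NA_real_)
    }, numeric(1))
  })

  n_failed <- sum(is.na(reps))
  if (n_failed > 0.10 * B) {
    stop_oxival(sprintf(
      "statistic failed on %d of %d bootstrap replicates", n_failed, B),
      "oxival_bootstrap_error")
  }
  reps_ok <- reps[!is.na(reps)]
  se_boot <- sd1(reps_ok)
  prop_below <- mean(reps_ok < observed)
  # clamp so that z0 stays finite when all replicates fall on one side
  z0 <- qnorm(min(max(prop_below, 1 / (2 * length(reps_ok))),
                  1 - 1 / (2 * length(reps_ok))))
  bc_probs <- pnorm(2 * z0 + c(-1.96, 1.96))
  ci_bc <- unname(quantile(reps_ok, probs = bc_probs, type = 1))
  structure(list(
    estimand = statistic, observed = observed, replicates = reps_ok,
    B = B, n_failed = n_failed, se_boot = se_boot,
    ci_normal = observed + c(-1.96, 1.96) * se_boot,
    ci_bias_corrected = ci_bc, scheme = scheme, seed = seed),
    class = "oxi_bootstrap")
}

#' @export
print.oxi_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrap %s of %s: observed %.4f, SE %.4f (B = %d, %d failed)\n",
    x$scheme, x$estimand, x$observed, x$se_boot, x$B, x$n_failed))
  cat(sprintf("  normal 95%% CI       %.4f .. %.4f\n",
              x$ci_normal[1], x$ci_normal[2]))
  cat(sprintf("  bias-corrected 95%%  %.4f .. %.4f\n",
              x$ci_bias_corrected[1], x$ci_bias_corrected[2]))
  invisible(x)
}
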
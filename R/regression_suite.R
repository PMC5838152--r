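# Errors-in-variables regression and agreement indices for clustered
# method-comparison data.
#
# The two-step pooled analysis: (1) fit a Deming line per subject and
# estimate coefficient standard errors by the delete-one jackknife;
# (2) assess heterogeneity with Cochran's Q and pool the per-subject
# coefficients with inverse-variance (DerSimonian-Laird random-effects by
# default) meta-analysis.  A random-coefficients linear mixed model and the
# concordance correlation coefficient complete the suite.

new_regression <- function(slope, intercept, se_slope = NA_real_,
                           se_intercept = NA_real_, method, extra = list()) {
  ci <- function(est, se) if (is.na(se)) c(NA_real_, NA_real_) else
    est + c(-1.96, 1.96) * se
  structure(c(list(slope = slope, intercept = intercept,
                   se_slope = se_slope, se_intercept = se_intercept,
                   ci95_slope = ci(slope, se_slope),
                   ci95_intercept = ci(intercept, se_intercept),
                   method = method), extra),
            class = "oxi_regression")
}

#' @export
print.oxi_regression <- function(x, ...) {
  cat(sprintf("<%s> y = %.4f + %.4f x", x$method, x$intercept, x$slope))
  if (!is.na(x$se_slope)) {
    cat(sprintf("  [slope SE %.4f, 95%% CI %.4f..%.4f]",
                x$se_slope, x$ci95_slope[1], x$ci95_slope[2]))
  }
  cat("\n")
  invisible(x)
}

# slope/intercept from centered second moments; the workhorse used by every
# Deming path (single fit, vectorized jackknife, bootstrap replicates)
deming_core <- function(cxx, cyy, cxy, mx, my, lambda) {
  num <- cyy - lambda * cxx
  slope <- ifelse(cxy != 0,
                  (num + sqrt(num^2 + 4 * lambda * cxy^2)) / (2 * cxy),
                  ifelse(num < 0, 0, NA_real_))
  list(slope = slope, intercept = my - slope * mx)
}

#' Deming errors-in-variables regression
#'
#' Fits `y = intercept + slope * x` minimizing residuals weighted
#' perpendicular to the line, allowing measurement error in both variables:
#' \deqn{slope = \frac{S_{yy} - \lambda S_{xx} +
#'   \sqrt{(S_{yy} - \lambda S_{xx})^2 + 4 \lambda S_{xy}^2}}{2 S_{xy}}}
#' with centered second moments and error-variance ratio `lambda`
#' (y-error variance over x-error variance).  `lambda = 1` is orthogonal
#' regression; as `lambda` grows the fit approaches ordinary least squares
#' of y on x.
#'
#' @param x,y numeric vectors (the reference and device readings).
#' @param lambda positive error-variance ratio; default 1.
#' @return an `oxi_regression` (method `"deming_subject"`); standard errors
#'   are `NA` until estimated by [jackknife_se()] or the bootstrap.
#' @examples
#' deming_fit(c(0, 1, 2), c(0, 1, 1))  # slope (-2 + sqrt(13))/3
#' @export
deming_fit <- function(x, y, lambda = 1) {
  stopifnot(length(x) == length(y), lambda > 0)
  if (length(x) < 2L) {
    stop_oxival("Deming regression needs at least 2 points",
                "oxival_insufficient_data_error")
  }
  mx <- mean(x); my <- mean(y)
  cxx <- sum((x - mx)^2); cyy <- sum((y - my)^2)
  cxy <- sum((x - mx) * (y - my))
  if (cxx == 0) {
    stop_oxival("x values are all equal: vertical data cannot be fitted",
                "oxival_degenerate_error")
  }
  fit <- deming_core(cxx, cyy, cxy, mx, my, lambda)
  if (is.na(fit$slope)) {
    stop_oxival("degenerate orientation: S_xy = 0 with S_yy = lambda * S_xx",
                "oxival_degenerate_error")
  }
  new_regression(fit$slope, fit$intercept, method = "deming_subject",
                 extra = list(lambda = lambda, n = length(x)))
}

#' Jackknife standard errors for Deming coefficients
#'
#' Delete-one refits: for each i the line is refitted without point i and
#' \deqn{SE = \sqrt{\frac{n-1}{n} \sum_i (\theta_{(i)} - \bar\theta_{(.)})^2}}
#' for the slope and intercept.  Implemented by downdating the moment sums,
#' so the n refits cost one pass.
#'
#' @inheritParams deming_fit
#' @return list with `se_slope`, `se_intercept` and the delete-one
#'   coefficient vectors `slopes`, `intercepts`.
#' @export
jackknife_se <- function(x, y, lambda = 1) {
  n <- length(x)
  stopifnot(length(y) == n, lambda > 0)
  if (n < 4L) {
    stop_oxival("jackknife requires at least 4 points",
                "oxival_insufficient_data_error")
  }
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  n1 <- n - 1L
  sx_i <- sx - x;  sy_i <- sy - y
  mx_i <- sx_i / n1; my_i <- sy_i / n1
  cxx_i <- (sxx - x * x) - sx_i^2 / n1
  cyy_i <- (syy - y * y) - sy_i^2 / n1
  cxy_i <- (sxy - x * y) - sx_i * sy_i / n1
  if (any(cxx_i <= 0)) {
    stop_oxival(sprintf(
      "delete-1 subset %d is degenerate (x constant after deletion)",
      which(cxx_i <= 0)[1]), "oxival_degenerate_error")
  }
  fit <- deming_core(cxx_i, cyy_i, cxy_i, mx_i, my_i, lambda)
  if (any(is.na(fit$slope))) {
    stop_oxival(sprintf("delete-1 subset %d has degenerate orientation",
                        which(is.na(fit$slope))[1]),
                "oxival_degenerate_error")
  }
  jk <- function(th) sqrt(n1 / n * sum((th - mean(th))^2))
  list(se_slope = jk(fit$slope), se_intercept = jk(fit$intercept),
       slopes = fit$slope, intercepts = fit$intercept)
}

#' Cochran's Q heterogeneity test
#'
#' Fixed-effect weights \eqn{w_i = 1/se_i^2};
#' \eqn{Q = \sum w_i (\theta_i - \hat\theta_{FE})^2} on `k - 1` degrees of
#' freedom, with the DerSimonian-Laird between-study variance
#' \eqn{\tau^2 = \max(0, (Q - df)/C)}, \eqn{C = \sum w - \sum w^2 / \sum w}.
#'
#' @param estimates per-subject coefficient estimates.
#' @param ses their standard errors, all positive.
#' @return list with `Q`, `df`, `p`, `tau2`.
#' @export
cochran_q <- function(estimates, ses) {
  k <- length(estimates)
  stopifnot(length(ses) == k)
  if (k < 2L) {
    stop_oxival("heterogeneity assessment needs at least 2 estimates",
                "oxival_insufficient_data_error")
  }
  if (any(ses <= 0)) {
    stop_oxival("all standard errors must be positive", "oxival_value_error")
  }
  w <- 1 / ses^2
  fe <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - fe)^2)
  df <- k - 1L
  C <- sum(w) - sum(w^2) / sum(w)
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE),
       tau2 = max(0, (Q - df) / C))
}

#' Meta-analytic pooling of per-subject coefficients
#'
#' Inverse-variance weighted average.  Under the default random-effects
#' model (DerSimonian-Laird) the weights are \eqn{w_i^* = 1/(se_i^2 +
#' \tau^2)} with \eqn{\tau^2} from [cochran_q()]; the fixed-effect model
#' sets \eqn{\tau^2 = 0}.  The 95% CI uses the normal 1.96 multiplier.
#'
#' @inheritParams cochran_q
#' @param model `"random"` (default) or `"fixed"`.
#' @return list with `estimate`, `se`, `ci95`, `tau2`, `model`.
#' @export
meta_pool <- function(estimates, ses, model = c("random", "fixed")) {
  model <- match.arg(model)
  het <- cochran_q(estimates, ses)
  tau2 <- if (model == "random") het$tau2 else 0
  w <- 1 / (ses^2 + tau2)
  est <- sum(w * estimates) / sum(w)
  se <- sqrt(1 / sum(w))
  list(estimate = est, se = se, ci95 = est + c(-1.96, 1.96) * se,
       tau2 = tau2, model = model)
}

# minimal fast path: per-subject Deming + jackknife + DL pooling on a
# series_split() list; returns pooled slope and intercept only
pooled_deming_core <- function(subjects, lambda, model = "random") {
  k <- length(subjects)
  sl <- numeric(k); ic <- numeric(k); se_sl <- numeric(k); se_ic <- numeric(k)
  keep <- logical(k)
  for (i in seq_len(k)) {
    s <- subjects[[i]]
    if (length(s$x) < 4L) next
    mx <- mean(s$x); my <- mean(s$y)
    cxx <- sum((s$x - mx)^2); cyy <- sum((s$y - my)^2)
    cxy <- sum((s$x - mx) * (s$y - my))
    if (cxx == 0) next
    fit <- deming_core(cxx, cyy, cxy, mx, my, lambda)
    if (is.na(fit$slope)) next
    jk <- tryCatch(jackknife_se(s$x, s$y, lambda), oxival_error = function(e) NULL)
    if (is.null(jk) || jk$se_slope == 0 || jk$se_intercept == 0) next
    keep[i] <- TRUE
    sl[i] <- fit$slope; ic[i] <- fit$intercept
    se_sl[i] <- jk$se_slope; se_ic[i] <- jk$se_intercept
  }
  if (sum(keep) < 2L) return(NULL)
  ps <- meta_pool(sl[keep], se_sl[keep], model)
  pi <- meta_pool(ic[keep], se_ic[keep], model)
  list(slope = ps, intercept = pi,
       per_subject = list(slope = sl[keep], intercept = ic[keep],
                          se_slope = se_sl[keep], se_intercept = se_ic[keep],
                          keep = keep))
}

#' Two-step pooled Deming regression for clustered data
#'
#' Step 1: a Deming line per subject with [jackknife_se()] coefficient SEs.
#' Step 2: Cochran's Q heterogeneity assessment and meta-analytic pooling
#' ([meta_pool()]) of the per-subject slopes and intercepts, treating
#' subjects as random draws from a population.  Subjects with fewer than 4
#' points (or with a perfectly collinear series, whose jackknife SE is zero)
#' are excluded with a warning.
#'
#' @param series a `paired_series`.
#' @param lambda Deming error-variance ratio; default 1.
#' @param model pooling model, `"random"` (default) or `"fixed"`.
#' @return an `oxi_pooled_deming` list: `slope` and `intercept`
#'   (`oxi_regression`-style pooled estimates with SEs and 95% CIs),
#'   `heterogeneity` (per-coefficient Cochran Q results), `per_subject`
#'   data frame of the Step-1 fits, `excluded` subject ids, `lambda`.
#' @export
pooled_deming <- function(series, lambda = 1, model = c("random", "fixed")) {
  model <- match.arg(model)
  subjects <- series_split(series)
  k <- length(subjects)
  rows <- vector("list", k)
  excluded <- character()
  for (i in seq_len(k)) {
    s <- subjects[[i]]
    id <- names(subjects)[i]
    ok <- length(s$x) >= 4L
    if (ok) {
      fit <- tryCatch(deming_fit(s$x, s$y, lambda),
                      oxival_error = function(e) NULL)
      jk <- if (!is.null(fit)) {
        tryCatch(jackknife_se(s$x, s$y, lambda),
                 oxival_error = function(e) NULL)
      }
      ok <- !is.null(fit) && !is.null(jk)
    }
    if (!ok) { excluded <- c(excluded, id); next }
    rows[[i]] <- data.frame(subject_id = id, n = length(s$x),
                            slope = fit$slope, intercept = fit$intercept,
                            se_slope = jk$se_slope,
                            se_intercept = jk$se_intercept,
                            stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  # SEs at floating-noise level count as zero (exactly collinear subjects)
  se_tol <- function(se, est) se < 1e-8 * pmax(1, abs(est))
  if (!is.null(per) && nrow(per) >= 2L &&
      all(se_tol(per$se_slope, per$slope)) &&
      all(se_tol(per$se_intercept, per$intercept)) &&
      diff(range(per$slope)) < 1e-8 && diff(range(per$intercept)) < 1e-6) {
    # every subject lies exactly on one common line: pooling is exact
    degen <- function(est) list(estimate = est, se = 0, ci95 = c(est, est),
                                tau2 = 0, model = model)
    het0 <- list(Q = 0, df = nrow(per) - 1L, p = 1, tau2 = 0)
    ps <- degen(mean(per$slope)); pi <- degen(mean(per$intercept))
    return(structure(list(
      slope = ps, intercept = pi,
      estimate = new_regression(ps$estimate, pi$estimate, 0, 0,
                                method = "deming_pooled",
                                extra = list(lambda = lambda, model = model)),
      heterogeneity = list(slope = het0, intercept = het0),
      per_subject = per, excluded = excluded, lambda = lambda,
      model = model), class = "oxi_pooled_deming"))
  }
  zero_se <- !is.null(per) & (se_tol(per$se_slope, per$slope) |
                                se_tol(per$se_intercept, per$intercept))
  if (any(zero_se)) {
    excluded <- c(excluded, per$subject_id[zero_se])
    per <- per[!zero_se, , drop = FALSE]
  }
  if (length(excluded)) {
    warning(sprintf("excluded %d subject(s) with <4 points or degenerate fits: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  if (is.null(per) || nrow(per) < 2L) {
    stop_oxival("fewer than 2 subjects usable for pooling",
                "oxival_insufficient_data_error")
  }
  het <- list(slope = cochran_q(per$slope, per$se_slope),
              intercept = cochran_q(per$intercept, per$se_intercept))
  ps <- meta_pool(per$slope, per$se_slope, model)
  pi <- meta_pool(per$intercept, per$se_intercept, model)
  structure(list(
    slope = ps, intercept = pi,
    estimate = new_regression(ps$estimate, pi$estimate, ps$se, pi$se,
                              method = "deming_pooled",
                              extra = list(lambda = lambda, model = model)),
    heterogeneity = het, per_subject = per, excluded = excluded,
    lambda = lambda, model = model), class = "oxi_pooled_deming")
}

#' @export
print.oxi_pooled_deming <- function(x, ...) {
  cat(sprintf(
    "Pooled Deming (%s effects, lambda = %g, %d subjects):\n", x$model,
    x$lambda, nrow(x$per_subject)))
  cat(sprintf("  slope     %.4f (SE %.4f, 95%% CI %.4f..%.4f)\n",
              x$slope$estimate, x$slope$se, x$slope$ci95[1], x$slope$ci95[2]))
  cat(sprintf("  intercept %.4f (SE %.4f, 95%% CI %.4f..%.4f)\n",
              x$intercept$estimate, x$intercept$se,
              x$intercept$ci95[1], x$intercept$ci95[2]))
  cat(sprintf("  heterogeneity: slope Q = %.2f (df %d, p = %.3g), tau2 = %.4g\n",
              x$heterogeneity$slope$Q, x$heterogeneity$slope$df,
              x$heterogeneity$slope$p, x$heterogeneity$slope$tau2))
  invisible(x)
}

#' Random-coefficients mixed model
#'
#' Fits \eqn{y_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i}) x_{ij} +
#' \epsilon_{ij}} by REML ([lme4::lmer()]) with a subject-level random
#' intercept and slope (unstructured 2x2 covariance).  If the unstructured
#' fit is singular the model is refitted with independent (diagonal) random
#' effects, with a warning.  Fixed-effect 95% CIs use the normal 1.96
#' multiplier on the Wald SEs.
#'
#' @param series a `paired_series`.
#' @param keep_fit if `TRUE`, attach the `lmerMod` object.
#' @return an `oxi_regression` (method `"random_coefficients"`) with a
#'   `varcomp` element: SDs of the random intercept and slope, their
#'   correlation (if estimated), and the residual SD.
#' @export
random_coefficients_fit <- function(series, keep_fit = FALSE) {
  df <- data.frame(y = series$device, x = series$ref,
                   subject = as.character(series$subject_id))
  if (length(unique(df$subject)) < 2L) {
    stop_oxival("random-coefficients model needs at least 2 subjects",
                "oxival_insufficient_data_error")
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(
    lme4::lmer(y ~ x + (x | subject), data = df, REML = TRUE, control = ctrl))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("unstructured random-effects covariance is singular; ",
            "refitting with independent random intercept and slope")
    fit <- suppressMessages(
      lme4::lmer(y ~ x + (x || subject), data = df, REML = TRUE,
                 control = ctrl))
  }
  b <- lme4::fixef(fit)
  se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(fit)))),
                 error = function(e) {
                   warning("Wald covariance unavailable (degenerate fit); ",
                           "standard errors set to NA")
                   c("(Intercept)" = NA_real_, x = NA_real_)
                 })
  se <- suppressWarnings(se)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- list(
    sd_intercept = vc$sdcor[vc$grp != "Residual" & vc$var1 == "(Intercept)" &
                              is.na(vc$var2)][1],
    sd_slope = vc$sdcor[vc$grp != "Residual" & vc$var1 == "x" &
                          is.na(vc$var2)][1],
    cor_intercept_slope = if (any(!is.na(vc$var2))) {
      vc$sdcor[!is.na(vc$var2)][1]
    } else NA_real_,
    sd_residual = vc$sdcor[vc$grp == "Residual"][1],
    singular = singular)
  new_regression(unname(b["x"]), unname(b["(Intercept)"]),
                 unname(se["x"]), unname(se["(Intercept)"]),
                 method = "random_coefficients",
                 extra = c(list(varcomp = varcomp),
                           if (keep_fit) list(fit = fit)))
}

ccc_naive_core <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) return(NA_real_)
  2 * sxy / denom
}

#' Concordance correlation coefficient
#'
#' Agreement index in \[-1, 1\] combining precision (correlation) and
#' accuracy (closeness of means and variances).
#'
#' `method = "naive"` is Lin's estimator
#' \eqn{\hat\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' (n-denominator moments), with the delta-method SE and a Fisher
#' z-transformed 95% CI.
#'
#' `method = "variance_components"` (default) accounts for the repeated
#' measurements per subject: the stacked readings are modelled as
#' \eqn{value = \mu + \beta_{method} + subject + subject{:}pair + error}
#' (random subject and pair-within-subject intercepts, REML) and
#' \deqn{CCC = \frac{\sigma^2_{subj} + \sigma^2_{pair}}
#'   {\sigma^2_{subj} + \sigma^2_{pair} + \sigma^2_{e} + d^2/2}}
#' where `d` is the fixed method difference; this reduces to the population
#' value of Lin's CCC under the exchangeable model.  Its SE is estimated by
#' a delete-one-subject jackknife (set `se = FALSE` to skip the refits).
#'
#' @param series a `paired_series`.
#' @param method `"variance_components"` (default) or `"naive"`.
#' @param se compute a standard error and 95% CI (default `TRUE`).
#' @return an `oxi_ccc` list: `estimate`, `se`, `ci95`, `method`.
#' @export
ccc <- function(series, method = c("variance_components", "naive"),
                se = TRUE) {
  method <- match.arg(method)
  x <- series$ref; y <- series$device
  if (length(x) < 3L) {
    stop_oxival("CCC needs at least 3 pairs", "oxival_insufficient_data_error")
  }
  if (method == "naive") {
    est <- ccc_naive_core(x, y)
    if (is.na(est)) {
      stop_oxival("total variance is zero: CCC undefined",
                  "oxival_undefined_ccc_error")
    }
    out <- list(estimate = est, se = NA_real_, ci95 = c(NA_real_, NA_real_),
                method = "naive")
    if (se) {
      n <- length(x)
      r <- stats::cor(x, y)
      u <- (mean(x) - mean(y)) /
        sqrt(sqrt(sum((x - mean(x))^2) / n) * sqrt(sum((y - mean(y))^2) / n))
      # Lin's delta-method variance of the CCC
      v <- ((1 - r^2) * est^2 * (1 - est^2) / r^2 +
            2 * est^3 * (1 - est) * u^2 / r -
            est^4 * u^4 / (2 * r^2)) / (n - 2)
      out$se <- sqrt(max(0, v))
      z <- atanh(min(1 - 1e-12, max(-1 + 1e-12, est)))
      se_z <- out$se / (1 - est^2)
      out$ci95 <- tanh(z + c(-1.96, 1.96) * se_z)
    }
  } else {
    est <- ccc_vc_core(series)
    out <- list(estimate = est, se = NA_real_, ci95 = c(NA_real_, NA_real_),
                method = "variance_components")
    if (se) {
      subj <- unique(as.character(series$subject_id))
      if (length(subj) >= 3L) {
        reps <- vapply(subj, function(s) {
          sub <- series[series$subject_id != s, , drop = FALSE]
          class(sub) <- class(series)
          ccc_vc_core(sub)
        }, numeric(1))
        k <- length(reps)
        out$se <- sqrt((k - 1) / k * sum((reps - mean(reps))^2))
        z <- atanh(min(1 - 1e-12, max(-1 + 1e-12, est)))
        se_z <- out$se / (1 - est^2)
        out$ci95 <- tanh(z + c(-1.96, 1.96) * se_z)
      }
    }
  }
  structure(out, class = "oxi_ccc")
}

ccc_vc_core <- function(series) {
  n <- nrow(series)
  df <- data.frame(
    value = c(series$ref, series$device),
    method = rep(c("ref", "device"), each = n),
    subject = rep(as.character(series$subject_id), 2L),
    pair = rep(seq_len(n), 2L))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(
    lme4::lmer(value ~ method + (1 | subject) + (1 | subject:pair),
               data = df, REML = TRUE, control = ctrl))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_pair <- vc$vcov[vc$grp == "subject:pair"]
  v_subj <- vc$vcov[vc$grp == "subject"]
  v_err <- vc$vcov[vc$grp == "Residual"]
  d <- unname(lme4::fixef(fit)[2])
  (v_subj + v_pair) / (v_subj + v_pair + v_err + d^2 / 2)
}

#' @export
print.oxi_ccc <- function(x, ...) {
  cat(sprintf("CCC (%s): %.4f", x$method, x$estimate))
  if (!is.na(x$se)) {
    cat(sprintf(" (SE %.4f, 95%% CI %.4f..%.4f)", x$se, x$ci95[1], x$ci95[2]))
  }
  cat("\n")
  invisible(x)
}
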
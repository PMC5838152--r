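# Bland-Altman agreement for method comparison with repeated measures.
#
# Bias is the mean device-minus-reference difference; precision is its
# 1 SD spread.  With several plateaus per subject the differences are
# clustered, so alongside the standard sample SD the package reports a
# "modified" SD from a one-way random-effects decomposition of the
# differences (subject + residual), which is the repeated-measures analogue
# of the Bland-Altman limits-of-agreement SD.

series_differences <- function(series,
                               convention = c("device_minus_reference",
                                              "reference_minus_device")) {
  stopifnot(inherits(series, "paired_series") || is.data.frame(series))
  convention <- match.arg(convention)
  d <- series$device - series$ref
  if (convention == "reference_minus_device") d <- -d
  list(d = d, subject = as.character(series$subject_id))
}

new_agreement <- function(bias, sd_standard, sd_modified, n_pairs,
                          n_subjects, convention) {
  structure(list(bias = bias, sd_standard = sd_standard,
                 sd_modified = sd_modified, n_pairs = n_pairs,
                 n_subjects = n_subjects,
                 limits_of_agreement = bias + c(-1.96, 1.96) *
                   (if (is.na(sd_modified)) sd_standard else sd_modified),
                 convention = convention),
            class = "oxi_agreement")
}

#' @export
print.oxi_agreement <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (%s): bias %.2f%% +/- %.2f%% (modified %s), n = %d pairs / %d subjects\n",
    x$convention, x$bias, x$sd_standard,
    if (is.na(x$sd_modified)) "n/a" else sprintf("%.2f%%", x$sd_modified),
    x$n_pairs, x$n_subjects))
  invisible(x)
}

#' Standard Bland-Altman bias and precision
#'
#' @param series a `paired_series` from [build_paired_series()].
#' @param convention difference direction; default device minus reference.
#' @return an `oxi_agreement` with `bias`, `sd_standard` (sample SD, n-1
#'   denominator), limits of agreement at +/- 1.96 SD, and counts;
#'   `sd_modified` is `NA` (see [bland_altman_repeated()]).
#' @export
bland_altman <- function(series, convention = c("device_minus_reference",
                                                "reference_minus_device")) {
  convention <- match.arg(convention)
  dd <- series_differences(series, convention)
  if (length(dd$d) < 2L) {
    stop_oxival("Bland-Altman requires at least 2 pairs",
                "oxival_insufficient_data_error")
  }
  new_agreement(mean(dd$d), sd1(dd$d), NA_real_, length(dd$d),
                length(unique(dd$subject)), convention)
}

# one-way random-effects ANOVA moment estimators for clustered differences;
# handles unbalanced clusters via the n0 coefficient of expected mean squares
anova_components <- function(d, subject) {
  n_i <- tapply(d, subject, length)
  k <- length(n_i)
  N <- length(d)
  grand <- mean(d)
  means <- tapply(d, subject, mean)
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum((d - means[subject])^2)
  msw <- if (N - k > 0) ss_within / (N - k) else 0
  msb <- ss_between / (k - 1)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  s2_between <- max(0, (msb - msw) / n0)
  list(s2_between = s2_between, s2_within = msw)
}

#' Repeated-measures Bland-Altman precision
#'
#' Decomposes the differences \eqn{d_{ij} = \mu + b_i + e_{ij}} (subject
#' random effect plus residual) with one-way ANOVA moment estimators and
#' reports the modified precision
#' \eqn{\sqrt{\hat\sigma^2_{between} + \hat\sigma^2_{within}}}, the
#' repeated-measures analogue of the Bland-Altman SD.  A negative
#' between-subject moment estimate is truncated at zero, in which case the
#' modified SD can fall slightly below the standard SD.
#'
#' @inheritParams bland_altman
#' @return an `oxi_agreement` with both `sd_standard` and `sd_modified`.
#' @export
bland_altman_repeated <- function(series,
                                  convention = c("device_minus_reference",
                                                 "reference_minus_device")) {
  convention <- match.arg(convention)
  dd <- series_differences(series, convention)
  if (length(dd$d) < 2L) {
    stop_oxival("Bland-Altman requires at least 2 pairs",
                "oxival_insufficient_data_error")
  }
  n_subj <- length(unique(dd$subject))
  if (n_subj < 2L) {
    warning("single subject: modified SD falls back to the standard SD")
    return(new_agreement(mean(dd$d), sd1(dd$d), sd1(dd$d), length(dd$d),
                         1L, convention))
  }
  comp <- anova_components(dd$d, dd$subject)
  new_agreement(mean(dd$d), sd1(dd$d),
                sqrt(comp$s2_between + comp$s2_within),
                length(dd$d), n_subj, convention)
}

#' Agreement within subgroups of subjects
#'
#' Computes the repeated-measures Bland-Altman result and a Deming fit on
#' the pooled points within each subgroup (e.g. skin-tone categories),
#' mirroring the rows of a per-tone accuracy table.
#'
#' @param series a `paired_series`.
#' @param grouping named character vector mapping every `subject_id` in the
#'   series to a label.
#' @param lambda Deming error-variance ratio for the per-group fit.
#' @return named list (one element per label) of lists with `agreement`
#'   (an `oxi_agreement`) and `deming` (an `oxi_regression`).
#' @export
subgroup_agreement <- function(series, grouping, lambda = 1) {
  subj <- unique(as.character(series$subject_id))
  if (!all(subj %in% names(grouping))) {
    stop_oxival("grouping must map every subject in the series",
                "oxival_value_error")
  }
  labels <- unique(unname(grouping[subj]))
  out <- lapply(labels, function(lab) {
    ids <- subj[grouping[subj] == lab]
    if (length(ids) < 2L) {
      warning(sprintf("subgroup '%s' has fewer than 2 subjects", lab))
    }
    sub <- series[series$subject_id %in% ids, , drop = FALSE]
    class(sub) <- class(series)
    list(agreement = bland_altman_repeated(sub),
         deming = deming_fit(sub$ref, sub$device, lambda = lambda))
  })
  names(out) <- labels
  out
}

#' Compare mean bias between two subject subgroups
#'
#' Welch two-sample t-test on the per-subject mean differences (one value
#' per subject, respecting the within-subject clustering of plateau points).
#'
#' @param series a `paired_series`.
#' @param grouping named character vector mapping subjects to labels.
#' @param pair length-2 character vector of labels to compare.
#' @param convention difference direction.
#' @return list with `t`, `df`, `p_value`, and the per-group subject counts.
#' @export
compare_groups <- function(series, grouping, pair,
                           convention = c("device_minus_reference",
                                          "reference_minus_device")) {
  convention <- match.arg(convention)
  stopifnot(length(pair) == 2L)
  dd <- series_differences(series, convention)
  means <- tapply(dd$d, dd$subject, mean)
  lab <- grouping[names(means)]
  a <- means[!is.na(lab) & lab == pair[1]]
  b <- means[!is.na(lab) & lab == pair[2]]
  if (length(a) < 2L || length(b) < 2L) {
    stop_oxival("each group needs at least 2 subjects for a t-test",
                "oxival_insufficient_data_error")
  }
  tt <- t.test(a, b)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n = c(length(a), length(b)))
}
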
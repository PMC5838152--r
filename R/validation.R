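# End-to-end validation pipeline: from a study CSV (real or simulated) to
# the full set of agreement tables a device-validation report needs.

#' Run the complete oximeter validation analysis
#'
#' Orchestrates the pipeline: weighted-reference pairing, skin-tone
#' subgroup accuracy table (bias +/- modified SD with the standard SD
#' alongside, and a pooled-points Deming equation per row), the
#' observed/Bootstrap-I/Bootstrap-II regression and CCC table, the
#' venous:arterial ratio uncertainty sweep, sensor-side (cerebral) or
#' per-site (somatic) subgroup agreement, and run metadata.  Deterministic
#' given `seed`.
#'
#' @param study an `oxi_study`, or a CSV path readable by [load_study()].
#' @param cohort required when `study` is a path.
#' @param r_v venous weight of the reference; default 0.70.
#' @param lambda Deming error-variance ratio; default 1.
#' @param B bootstrap replicates per scheme; default 500.
#' @param seed integer seed driving the bootstrap.
#' @param sweep_ratios venous weights for the uncertainty sweep.
#' @param site_policy `"auto"` (per-site for cerebral, averaged sites for
#'   somatic headline analyses), `"per_site"`, or `"average_sites"`.
#' @param bootstrap logical; skip the bootstrap table when `FALSE`.
#' @param bootstrap_estimands statistics to bootstrap; default pooled
#'   Deming slope/intercept, RCM slope/intercept, and CCC.
#' @return an `oxi_validation` list of tables; see [write_report()].
#' @export
run_validation <- function(study, cohort = NULL, r_v = 0.70, lambda = 1,
                           B = 500L, seed = 1L,
                           sweep_ratios = c(0.60, 0.65, 0.70, 0.75, 0.80),
                           site_policy = c("auto", "per_site",
                                           "average_sites"),
                           bootstrap = TRUE,
                           bootstrap_estimands = c("deming_pooled.slope",
                                                   "deming_pooled.intercept",
                                                   "rcm.slope",
                                                   "rcm.intercept", "ccc")) {
  site_policy <- match.arg(site_policy)
  if (is.character(study)) {
    if (is.null(cohort)) {
      stop_oxival("cohort is required when loading a study from file",
                  "oxival_value_error")
    }
    study <- load_study(study, cohort)
  }
  stopifnot(inherits(study, "oxi_study"))
  report_policy <- if (site_policy == "auto") {
    if (study$cohort == "somatic") "average_sites" else "per_site"
  } else site_policy

  violations <- validate_study(study)
  if (any(violations$severity == "error")) {
    stop_oxival(sprintf("study fails validation with %d structural error(s)",
                        sum(violations$severity == "error")),
                "oxival_validation_error")
  }

  headline <- build_paired_series(study, r_v = r_v,
                                  site_policy = report_policy)
  tone <- stats::setNames(study$subjects$skin_tone, study$subjects$subject_id)

  tone_table <- accuracy_table(headline, tone, lambda)
  site_tables <- NULL
  if (study$cohort == "somatic") {
    per_site <- build_paired_series(study, r_v = r_v,
                                    site_policy = "per_site")
    site_tables <- lapply(split_series_by(per_site, per_site$site),
                          accuracy_table, grouping = tone, lambda = lambda)
    site_tables[["average"]] <- tone_table
  }

  side <- stats::setNames(study$subjects$sensor_side,
                          study$subjects$subject_id)
  side_table <- accuracy_table(headline, side, lambda)

  pooled <- suppressWarnings(pooled_deming(headline, lambda = lambda))
  rcm <- suppressWarnings(random_coefficients_fit(headline))
  ccc_vc <- suppressWarnings(ccc(headline, "variance_components"))
  ccc_nv <- ccc(headline, "naive")

  boot_tab <- NULL
  if (bootstrap) {
    boot_tab <- do.call(rbind, lapply(bootstrap_estimands, function(st) {
      obs <- switch(st,
        "deming_pooled.slope" = c(pooled$slope$estimate, pooled$slope$se,
                                  pooled$slope$ci95),
        "deming_pooled.intercept" = c(pooled$intercept$estimate,
                                      pooled$intercept$se,
                                      pooled$intercept$ci95),
        "rcm.slope" = c(rcm$slope, rcm$se_slope, rcm$ci95_slope),
        "rcm.intercept" = c(rcm$intercept, rcm$se_intercept,
                            rcm$ci95_intercept),
        "ccc" = c(ccc_nv$estimate, ccc_nv$se, ccc_nv$ci95))
      rows <- list(data.frame(
        estimand = st, row = "observed", statistic = obs[1], se = obs[2],
        ci_lo = obs[3], ci_hi = obs[4], stringsAsFactors = FALSE))
      for (sch in c("I", "II")) {
        bt <- suppressWarnings(bootstrap_validate(
          headline, st, scheme = sch, B = B,
          seed = seed + match(sch, c("I", "II")), lambda = lambda))
        rows[[length(rows) + 1L]] <- data.frame(
          estimand = st, row = paste0("bootstrap_", sch),
          statistic = mean(bt$replicates), se = bt$se_boot,
          ci_lo = bt$ci_bias_corrected[1], ci_hi = bt$ci_bias_corrected[2],
          stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }))
  }

  sweep <- va_ratio_sweep(study, ratios = sweep_ratios,
                          site_policy = report_policy)

  structure(list(
    cohort = study$cohort,
    n_subjects = nrow(study$subjects),
    n_pairs = nrow(headline),
    accuracy_by_skin_tone = tone_table,
    accuracy_by_site = site_tables,
    accuracy_by_sensor_side = side_table,
    pooled_deming = pooled,
    random_coefficients = rcm,
    ccc = list(variance_components = ccc_vc, naive = ccc_nv),
    bootstrap_table = boot_tab,
    va_sweep = sweep,
    validation_warnings = violations,
    meta = list(r_v = r_v, lambda = lambda, B = if (bootstrap) B else NA,
                seed = seed, site_policy = report_policy,
                difference_convention = "device_minus_reference",
                sweep_convention = "reference_minus_device")),
    class = "oxi_validation")
}

split_series_by <- function(series, f) {
  lapply(split(seq_len(nrow(series)), f), function(i) {
    sub <- series[i, , drop = FALSE]
    class(sub) <- class(series)
    sub
  })
}

# one accuracy-table row per subgroup label plus an "all" row
accuracy_table <- function(series, grouping, lambda) {
  subj <- unique(as.character(series$subject_id))
  labels <- c("all", unique(unname(grouping[subj])))
  rows <- lapply(labels, function(lab) {
    sub <- if (lab == "all") series else {
      ids <- subj[grouping[subj] == lab]
      s <- series[series$subject_id %in% ids, , drop = FALSE]
      class(s) <- class(series)
      s
    }
    ba <- suppressWarnings(bland_altman_repeated(sub))
    dm <- deming_fit(sub$ref, sub$device, lambda = lambda)
    data.frame(group = lab, n_subjects = ba$n_subjects, n_points = ba$n_pairs,
               deming_intercept = dm$intercept, deming_slope = dm$slope,
               bias = ba$bias, sd_modified = ba$sd_modified,
               sd_standard = ba$sd_standard, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.oxi_validation <- function(x, ...) {
  cat(sprintf("Oximeter validation report: %s cohort, %d subjects, %d pairs\n",
              x$cohort, x$n_subjects, x$n_pairs))
  cat("\nAccuracy by skin tone (bias +/- modified SD, standard in parens):\n")
  t <- x$accuracy_by_skin_tone
  for (i in seq_len(nrow(t))) {
    cat(sprintf(
      "  %-9s N=%2d, %3d pts: StO2 = %.2f + %.2f REF, %6.2f +/- %.2f (%.2f)\n",
      t$group[i], t$n_subjects[i], t$n_points[i], t$deming_intercept[i],
      t$deming_slope[i], t$bias[i], t$sd_modified[i], t$sd_standard[i]))
  }
  cat(sprintf("\nPooled Deming: y = %.3f + %.3f x;  RCM: y = %.3f + %.3f x;  CCC (vc) = %.3f\n",
              x$pooled_deming$intercept$estimate,
              x$pooled_deming$slope$estimate,
              x$random_coefficients$intercept, x$random_coefficients$slope,
              x$ccc$variance_components$estimate))
  cat("\nV:A ratio sweep (reference - device):\n")
  for (i in seq_len(nrow(x$va_sweep))) {
    cat(sprintf("  r_v = %.2f: bias %6.2f +/- %.2f\n", x$va_sweep$r_v[i],
                x$va_sweep$bias[i], x$va_sweep$precision_sd[i]))
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' Writes a two-section JSON document: `display` (values rounded to the
#' conventional table precision, 2 decimals for percentages and 3 for
#' slopes and CCC) and `full_precision` (unrounded), plus run metadata.
#' Re-running the pipeline with the same inputs and seed reproduces the
#' file byte for byte.
#'
#' @param report an `oxi_validation` from [run_validation()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "oxi_validation"))
  strip <- function(x) {
    if (inherits(x, "oxi_pooled_deming")) {
      x <- list(slope = x$slope, intercept = x$intercept,
                heterogeneity = x$heterogeneity, per_subject = x$per_subject)
    }
    if (inherits(x, c("oxi_regression", "oxi_ccc", "oxi_agreement"))) {
      x <- unclass(x)
    }
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  round_rec <- function(x, digits) {
    if (is.data.frame(x)) {
      num <- vapply(x, is.numeric, logical(1))
      x[num] <- lapply(x[num], round, digits = digits)
      return(x)
    }
    if (is.list(x)) return(lapply(x, round_rec, digits = digits))
    if (is.numeric(x)) return(round(x, digits))
    x
  }
  body <- strip(unclass(report))
  body$validation_warnings <- NULL
  out <- list(
    meta = report$meta,
    display = round_rec(body, 3L),
    full_precision = body,
    validation_warnings = report$validation_warnings)
  jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
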
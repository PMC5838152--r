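# Weighted co-oximetry reference (REF CX) and the venous:arterial ratio
# uncertainty sweep.
#
# NIRS StO2 interrogates a microvascular mixture of venous and arterial
# blood, so the blood reference is a weighted combination of the venous and
# arterial co-oximetry saturations with venous weight r_v (default 0.70,
# the assumed 70:30 V:A volume ratio).

#' Weighted venous/arterial blood reference
#'
#' \deqn{REF = r_v \cdot SvO2 + (1 - r_v) \cdot SaO2}
#'
#' @param svo2,sao2 venous and arterial saturations (%), in \[0, 100\].
#' @param r_v venous weight, in (0, 1); default 0.70.
#' @return reference saturation (%), vectorized.
#' @examples
#' weighted_reference(60, 100, 0.70)  # 72
#' @export
weighted_reference <- function(svo2, sao2, r_v = 0.70) {
  assert_pct(svo2, "svo2"); assert_pct(sao2, "sao2")
  if (any(r_v <= 0 | r_v >= 1)) {
    stop_oxival("r_v must lie strictly in (0, 1)", "oxival_value_error")
  }
  r_v * svo2 + (1 - r_v) * sao2
}

#' Build the paired (reference, device) series for agreement analysis
#'
#' Computes the weighted reference for every sample and pairs it with the
#' device StO2, grouped by subject.  Under `site_policy = "average_sites"`
#' (somatic cohorts) the StO2 at each plateau is the unweighted mean of the
#' sites available at that plateau, so a subject missing one site still
#' contributes averaged points.
#'
#' @param study an `oxi_study`.
#' @param r_v venous weight of the reference.
#' @param site_policy `"per_site"` keeps one pair per (subject, plateau,
#'   site); `"average_sites"` collapses sites to their mean per plateau.
#' @return a `paired_series`: data frame with columns `subject_id`,
#'   `plateau_index`, `site`, `ref`, `device`, carrying `r_v` as an
#'   attribute.
#' @export
build_paired_series <- function(study, r_v = 0.70,
                                site_policy = c("per_site", "average_sites")) {
  stopifnot(inherits(study, "oxi_study"))
  site_policy <- match.arg(site_policy)
  sm <- study$samples
  sm <- sm[!is.na(sm$sto2_pct), , drop = FALSE]
  if (nrow(sm) == 0L) {
    stop_oxival("study has no usable paired samples", "oxival_empty_series_error")
  }
  if (site_policy == "average_sites") {
    if (study$cohort != "somatic") {
      stop_oxival("average_sites applies to somatic cohorts only",
                  "oxival_value_error")
    }
    agg <- stats::aggregate(
      sm[, c("sto2_pct", "sao2_pct", "svo2_pct")],
      by = list(subject_id = sm$subject_id, plateau_index = sm$plateau_index),
      FUN = mean)
    sm <- data.frame(subject_id = agg$subject_id,
                     plateau_index = agg$plateau_index,
                     site = "average", sto2_pct = agg$sto2_pct,
                     sao2_pct = agg$sao2_pct, svo2_pct = agg$svo2_pct,
                     stringsAsFactors = FALSE)
  }
  out <- data.frame(subject_id = as.character(sm$subject_id),
                    plateau_index = sm$plateau_index,
                    site = sm$site,
                    ref = weighted_reference(sm$svo2_pct, sm$sao2_pct, r_v),
                    device = sm$sto2_pct,
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$site, out$plateau_index), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, r_v = r_v, class = c("paired_series", "data.frame"))
}

# split a paired series into a per-subject list of (x = ref, y = device),
# ordered by plateau within subject -- the fast path for pooled fits and
# bootstrap resampling
series_split <- function(series) {
  ord <- order(series$subject_id, series$site, series$plateau_index)
  s <- series[ord, , drop = FALSE]
  key <- s$subject_id
  idx <- split(seq_len(nrow(s)), key)
  lapply(idx, function(i) list(x = s$ref[i], y = s$device[i]))
}

#' Closed-form bias implied by a shift of the venous:arterial ratio
#'
#' Because the weighted reference is linear in the venous weight, the
#' Bland-Altman bias recomputed at venous weight `r_v` differs from the bias
#' at the conventional 70:30 weighting by a term proportional to the mean
#' arteriovenous saturation difference (sweep sign convention, under which a
#' smaller venous weight gives a more positive reported bias):
#' \deqn{bias(r_v) = bias(0.70) + (0.70 - r_v)\,\overline{SaO2 - SvO2}}
#' Equivalently, the bias moves by about 0.01 x mean(SaO2 - SvO2) percent
#' per one-point shift of the V:A ratio.
#'
#' @param bias_70 Bland-Altman bias (%) at the 70:30 weighting.
#' @param mean_av_diff mean arteriovenous saturation difference (%).
#' @param r_v venous weight of interest, in (0, 1).
#' @return implied bias (%) at `r_v`.
#' @examples
#' implied_bias(-0.14, 30.15, 0.65)  # 1.3675
#' @export
implied_bias <- function(bias_70, mean_av_diff, r_v) {
  if (any(r_v <= 0 | r_v >= 1)) {
    stop_oxival("r_v must lie strictly in (0, 1)", "oxival_value_error")
  }
  bias_70 + (0.70 - r_v) * mean_av_diff
}

#' Uncertainty sweep over the assumed venous:arterial ratio
#'
#' Rebuilds the weighted reference at each candidate venous weight and
#' reports Bland-Altman bias and precision (1 SD).  The sweep uses the
#' reference-minus-device difference convention so that a smaller venous
#' weight (more arterial reference, hence a higher reference value) yields a
#' more positive bias; this is the direction in which such sweeps are
#' conventionally tabulated, and [implied_bias()] is its closed-form
#' companion.  Set `convention = "device_minus_reference"` for the
#' opposite sign.
#'
#' @param study an `oxi_study`.
#' @param ratios venous weights to evaluate; default
#'   `c(0.60, 0.65, 0.70, 0.75, 0.80)`.
#' @param site_policy forwarded to [build_paired_series()].
#' @param convention difference direction; default `"reference_minus_device"`.
#' @return data frame with columns `r_v`, `bias`, `precision_sd` (standard
#'   1 SD of the differences), ordered by `r_v`.
#' @export
va_ratio_sweep <- function(study, ratios = c(0.60, 0.65, 0.70, 0.75, 0.80),
                           site_policy = c("per_site", "average_sites"),
                           convention = c("reference_minus_device",
                                          "device_minus_reference")) {
  site_policy <- match.arg(site_policy)
  convention <- match.arg(convention)
  if (any(ratios <= 0 | ratios >= 1)) {
    stop_oxival("ratios must lie strictly in (0, 1)", "oxival_value_error")
  }
  ratios <- sort(ratios)
  rows <- lapply(ratios, function(r) {
    series <- build_paired_series(study, r_v = r, site_policy = site_policy)
    d <- if (convention == "reference_minus_device") {
      series$ref - series$device
    } else {
      series$device - series$ref
    }
    data.frame(r_v = r, bias = mean(d),
               precision_sd = if (length(d) > 1L) sd1(d) else 0)
  })
  do.call(rbind, rows)
}
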
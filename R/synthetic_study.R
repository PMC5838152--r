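# Synthetic hypoxia-plateau study generator.
#
# Emulates the data-generating structure the agreement analysis assumes:
# stepped SpO2 plateaus, one arterial/venous blood draw per plateau shared by
# all sensor sites, a subject-level venous:arterial mixing ratio around 0.70,
# a subject-level device offset, and per-reading device noise.  The generator
# does not simulate respiratory physiology or within-plateau time series.

#' Default SpO2 plateau targets
#'
#' One room-air plateau followed by eight hypoxia plateaus.  Room air is set
#' at 98% and the hypoxia steps descend evenly to the protocol floor of 70%;
#' the interior step values are a documented artifact choice (the protocol
#' fixes only the 100-70% span and the step count).
#'
#' @return numeric vector of 9 non-increasing SpO2 targets (%).
#' @export
default_plateau_targets <- function() {
  seq(98, 70, length.out = 9)
}

#' Simulation configuration
#'
#' Parameters of the generative model used by [simulate_study()].  Defaults
#' encode the published study conditions: a 25-subject cerebral cohort (or
#' 24-subject somatic), 1 room-air + 8 hypoxia plateaus, mean arteriovenous
#' saturation difference 30.15% (SD 6.17), subject venous:arterial mixing
#' ratio centered at 0.70 (SD 0.033, i.e. roughly +/-10% of the ratio at
#' 3 SD), and device noise giving a total device-vs-reference spread of
#' about 3% (1 SD): residual SD 2.5% within subject plus a 1.5% SD
#' between-subject offset.
#'
#' @param n_subjects number of subjects (default 25 cerebral, 24 somatic).
#' @param cohort `"cerebral"` or `"somatic"`.
#' @param sites sensor sites; defaults to forehead (cerebral) or
#'   flank/quadriceps/calf (somatic).
#' @param plateau_targets 9 non-increasing SpO2 targets in \[70, 100\].
#' @param av_diff_mean,av_diff_sd mean and SD (%) of the per-plateau
#'   arteriovenous saturation difference (truncated at 0).
#' @param va_ratio_mean,va_ratio_sd center and SD of the subject-level
#'   venous weight r_i in the tissue mixture (clipped to (0, 1)).
#' @param device_slope,device_intercept device response versus true tissue
#'   saturation (unitless; %).
#' @param subject_offset_sd SD (%) of the subject-level device offset.
#' @param residual_sd SD (%) of per-reading device noise.
#' @param sao2_jitter_sd SD (%) of arterial saturation around its plateau
#'   target.
#' @param skin_tone_counts named counts (`light`, `moderate`, `dark`) summing
#'   to `n_subjects`; defaults mirror the published cohorts
#'   (cerebral 15/5/5, somatic 8/2/14).
#' @param seed integer RNG seed; identical config + seed reproduces the
#'   study exactly.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_subjects = NULL,
                       cohort = c("cerebral", "somatic"),
                       sites = NULL,
                       plateau_targets = default_plateau_targets(),
                       av_diff_mean = 30.15,
                       av_diff_sd = 6.17,
                       va_ratio_mean = 0.70,
                       va_ratio_sd = 0.033,
                       device_slope = 1.0,
                       device_intercept = 0.0,
                       subject_offset_sd = 1.5,
                       residual_sd = 2.5,
                       sao2_jitter_sd = 1.0,
                       skin_tone_counts = NULL,
                       seed = 1L) {
  cohort <- match.arg(cohort)
  if (is.null(n_subjects)) n_subjects <- if (cohort == "cerebral") 25L else 24L
  if (is.null(sites)) {
    sites <- if (cohort == "cerebral") "forehead" else
      c("flank", "quadriceps", "calf")
  }
  if (is.null(skin_tone_counts)) {
    base <- if (cohort == "cerebral") c(light = 15, moderate = 5, dark = 5)
            else c(light = 8, moderate = 2, dark = 14)
    # rescale to n_subjects if the caller changed the cohort size
    skin_tone_counts <- round(base * n_subjects / sum(base))
    skin_tone_counts["light"] <- n_subjects - sum(skin_tone_counts[-1])
  }
  cfg <- list(n_subjects = as.integer(n_subjects), cohort = cohort,
              sites = sites, plateau_targets = plateau_targets,
              av_diff_mean = av_diff_mean, av_diff_sd = av_diff_sd,
              va_ratio_mean = va_ratio_mean, va_ratio_sd = va_ratio_sd,
              device_slope = device_slope,
              device_intercept = device_intercept,
              subject_offset_sd = subject_offset_sd,
              residual_sd = residual_sd, sao2_jitter_sd = sao2_jitter_sd,
              skin_tone_counts = skin_tone_counts, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(msg) stop_oxival(msg, "oxival_config_error")
  pt <- cfg$plateau_targets
  if (length(pt) != 9L || any(diff(pt) > 0) || any(pt < 70 | pt > 100)) {
    fail("plateau_targets must be 9 non-increasing values within [70, 100]")
  }
  sds <- c(cfg$av_diff_sd, cfg$va_ratio_sd, cfg$subject_offset_sd,
           cfg$residual_sd, cfg$sao2_jitter_sd)
  if (any(sds < 0)) fail("all SD parameters must be >= 0")
  if (cfg$va_ratio_mean <= 0 || cfg$va_ratio_mean >= 1) {
    fail("va_ratio_mean must lie in (0, 1)")
  }
  if (cfg$n_subjects < 1L) fail("n_subjects must be positive")
  if (sum(cfg$skin_tone_counts) != cfg$n_subjects) {
    fail("skin_tone_counts must sum to n_subjects")
  }
  if (!all(names(cfg$skin_tone_counts) %in% SKIN_TONES)) {
    fail("skin_tone_counts names must be light/moderate/dark")
  }
  if (cfg$cohort == "cerebral" && !identical(cfg$sites, "forehead")) {
    fail("cerebral cohort uses the forehead site only")
  }
  if (cfg$cohort == "somatic" &&
      !all(cfg$sites %in% c("flank", "quadriceps", "calf"))) {
    fail("somatic sites must be among flank/quadriceps/calf")
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML or JSON
#'
#' @param path file whose top-level keys are [sim_config()] arguments.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_oxival("the yaml package is required to read YAML configs",
                  "oxival_config_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$skin_tone_counts)) {
    raw$skin_tone_counts <- unlist(raw$skin_tone_counts)
  }
  do.call(sim_config, raw)
}

#' Simulate a hypoxia-plateau study
#'
#' Generative model, per subject i and plateau j:
#' \deqn{SaO2_{ij} = target_j + N(0, jitter),\quad
#'       SvO2_{ij} = SaO2_{ij} - AV_{ij},\quad AV_{ij} \sim N(\mu_{AV},
#'       \sigma_{AV}) \text{ truncated at } 0}
#' \deqn{T_{ij} = r_i SvO2_{ij} + (1 - r_i) SaO2_{ij},\quad
#'       StO2_{ij} = a + o_i + b\,T_{ij} + N(0, \sigma_e)}
#' with subject venous weight \eqn{r_i \sim N(\mu_r, \sigma_r)} clipped to
#' (0, 1) and subject offset \eqn{o_i \sim N(0, \sigma_o)}.  All saturations
#' are clipped to \[0, 100\] after noise; clipping events are counted in the
#' truth record.  For somatic cohorts every site shares the plateau's blood
#' draw and true tissue saturation and receives an independent device-noise
#' draw.  Sensor side alternates with subject parity.
#'
#' @param config a [sim_config()].
#' @return an `oxi_study`; `attr(, "truth")` records per-subject `r`
#'   and `offset`, per-sample true tissue saturation `t_true`, and clipping
#'   counts, for parameter-recovery experiments.
#' @export
simulate_study <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  n <- cfg$n_subjects
  np <- length(cfg$plateau_targets)
  ids <- sprintf("S%02d", seq_len(n))

  tones <- rep(names(cfg$skin_tone_counts), times = cfg$skin_tone_counts)
  race_for_tone <- function(tone, k) switch(tone,
    light = "White", dark = "Black",
    moderate = if (k %% 2L == 0L) "Hispanic" else "Asian")
  races <- mapply(race_for_tone, tones, seq_len(n))
  subjects <- data.frame(
    subject_id = ids, cohort = cfg$cohort, race = races,
    skin_tone = tones,
    sex = sample(c("M", "F"), n, replace = TRUE),
    age_years = round(runif(n, 21, 45)),
    weight_kg = round(runif(n, 52, 98), 1),
    sensor_side = ifelse(seq_len(n) %% 2L == 0L, "left", "right"),
    stringsAsFactors = FALSE)

  r_i <- pmin(1 - 1e-9, pmax(1e-9,
          rnorm(n, cfg$va_ratio_mean, cfg$va_ratio_sd)))
  o_i <- rnorm(n, 0, cfg$subject_offset_sd)

  n_clipped <- 0L
  clip <- function(x) {
    out <- pmin(100, pmax(0, x))
    n_clipped <<- n_clipped + sum(out != x)
    out
  }

  sao2 <- clip(rep(cfg$plateau_targets, times = n) +
               rnorm(n * np, 0, cfg$sao2_jitter_sd))
  av <- rnorm(n * np, cfg$av_diff_mean, cfg$av_diff_sd)
  av <- pmax(0, av)  # truncated at zero: a venous value above arterial is not generated
  svo2 <- clip(sao2 - av)
  subj_of <- rep(seq_len(n), each = np)
  t_true <- r_i[subj_of] * svo2 + (1 - r_i[subj_of]) * sao2

  blood <- data.frame(
    subject_id = ids[subj_of],
    plateau_index = rep(seq_len(np) - 1L, times = n),
    sao2_pct = sao2, svo2_pct = svo2, t_true = t_true,
    stringsAsFactors = FALSE)

  samples <- do.call(rbind, lapply(cfg$sites, function(site) {
    sto2 <- clip(cfg$device_intercept + o_i[subj_of] +
                 cfg$device_slope * blood$t_true +
                 rnorm(nrow(blood), 0, cfg$residual_sd))
    data.frame(subject_id = blood$subject_id,
               plateau_index = blood$plateau_index,
               site = site, sto2_pct = sto2,
               sao2_pct = blood$sao2_pct, svo2_pct = blood$svo2_pct,
               stringsAsFactors = FALSE)
  }))
  samples <- samples[order(samples$subject_id, samples$site,
                           samples$plateau_index), , drop = FALSE]

  st <- new_study(cfg$cohort, subjects, samples)
  attr(st, "truth") <- list(
    subjects = data.frame(subject_id = ids, r = r_i, offset = o_i,
                          stringsAsFactors = FALSE),
    samples = blood[, c("subject_id", "plateau_index", "t_true")],
    n_clipped = n_clipped,
    config = cfg)
  st
}

#' Write the hidden truth record of a simulated study to JSON
#'
#' @param study a study from [simulate_study()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(study, path) {
  truth <- attr(study, "truth")
  if (is.null(truth)) {
    stop_oxival("study carries no truth record (not simulated?)",
                "oxival_value_error")
  }
  out <- list(
    subjects = truth$subjects,
    samples = truth$samples,
    n_clipped = truth$n_clipped)
  jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
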
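# Domain model for hypoxia-plateau oximeter validation studies.
#
# A study is a pair of tables: one row per subject (metadata) and one row per
# paired observation (subject x plateau x sensor site) holding the device
# StO2 reading and the co-oximetry arterial/venous saturations drawn at that
# plateau.  Saturations are always percentages in [0, 100].

STUDY_COLUMNS <- c("subject_id", "cohort", "race", "skin_tone", "sex",
                   "age_years", "weight_kg", "sensor_side", "plateau_index",
                   "site", "sto2_pct", "sao2_pct", "svo2_pct")

COHORTS    <- c("cerebral", "somatic")
RACES      <- c("White", "Black", "Asian", "Hispanic", "other")
SKIN_TONES <- c("light", "moderate", "dark")
SITES      <- c("forehead", "flank", "quadriceps", "calf")
SIDES      <- c("left", "right")

#' Construct a hypoxia study object
#'
#' Bundles subject metadata and paired observations into an `oxi_study`.
#' Most users will obtain studies from [load_study()] or [simulate_study()]
#' rather than calling this directly.
#'
#' @param cohort `"cerebral"` (forehead sensor, jugular-bulb venous blood) or
#'   `"somatic"` (flank/quadriceps/calf sensors, central venous blood).
#' @param subjects data frame with columns `subject_id`, `cohort`, `race`,
#'   `skin_tone`, `sex`, `age_years`, `weight_kg`, `sensor_side`.
#' @param samples data frame with columns `subject_id`, `plateau_index`
#'   (0 = room air, 1..8 = hypoxia plateaus), `site`, `sto2_pct`, `sao2_pct`,
#'   `svo2_pct`.
#' @return An object of class `oxi_study`: a list with elements `cohort`,
#'   `subjects` and `samples`.
#' @export
new_study <- function(cohort, subjects, samples) {
  cohort <- match.arg(cohort, COHORTS)
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  samples  <- as.data.frame(samples, stringsAsFactors = FALSE)
  rownames(subjects) <- NULL
  rownames(samples) <- NULL
  structure(list(cohort = cohort, subjects = subjects, samples = samples),
            class = "oxi_study")
}

#' @export
print.oxi_study <- function(x, ...) {
  cat(sprintf("<oxi_study> %s cohort: %d subjects, %d samples, sites: %s\n",
              x$cohort, nrow(x$subjects), nrow(x$samples),
              paste(sort(unique(x$samples$site)), collapse = "/")))
  invisible(x)
}

#' Map self-reported race to the skin-tone category used in subgroup tables
#'
#' White maps to light; Asian and Hispanic to moderate; Black to dark.  Any
#' other value is an error so that the caller must supply an explicit tone.
#'
#' @param race character vector of race labels.
#' @return character vector of `"light"`, `"moderate"`, `"dark"`.
#' @examples
#' map_skin_tone(c("White", "Asian", "Black"))
#' @export
map_skin_tone <- function(race) {
  tone <- c(White = "light", Asian = "moderate", Hispanic = "moderate",
            Black = "dark")[race]
  if (any(is.na(tone))) {
    bad <- unique(race[is.na(tone)])
    stop_oxival(sprintf(
      "no skin-tone mapping for race(s) %s; supply skin_tone explicitly",
      paste(shQuote(bad), collapse = ", ")), "oxival_value_error")
  }
  unname(tone)
}

#' Read a study from CSV
#'
#' Expects the long format written by [write_study()]: one row per
#' (subject, plateau, site), blood values repeated across sites within a
#' plateau, header row mandatory, `.` decimal separator.  Rows missing the
#' StO2 or either blood value are dropped and counted in the load report
#' (`attr(study, "load_report")`); rows where SvO2 exceeds SaO2 are retained
#' but flagged there, since co-oximeter noise can produce such values near
#' full saturation.
#'
#' @param path CSV file path.
#' @param cohort expected cohort; rows must agree.
#' @return An `oxi_study`; `attr(, "load_report")` holds counts of read,
#'   dropped and flagged rows.
#' @export
load_study <- function(path, cohort = c("cerebral", "somatic")) {
  cohort <- match.arg(cohort)
  if (!file.exists(path)) {
    stop_oxival(sprintf("file not found: %s", path), "oxival_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop_oxival("study file contains no data rows", "oxival_empty_study_error")
  }
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_oxival(sprintf("missing mandatory column(s): %s",
                        paste(missing_cols, collapse = ", ")),
                "oxival_schema_error")
  }
  if (any(!df$cohort %in% COHORTS) || any(df$cohort != cohort)) {
    stop_oxival("cohort column disagrees with requested cohort",
                "oxival_value_error")
  }
  if (any(!df$site %in% SITES)) {
    stop_oxival(sprintf("unknown site token(s): %s",
                        paste(unique(setdiff(df$site, SITES)), collapse = ", ")),
                "oxival_value_error")
  }
  n_read <- nrow(df)
  keep <- !(is.na(df$sto2_pct) | is.na(df$sao2_pct) | is.na(df$svo2_pct))
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop_oxival("all rows missing StO2 or blood values",
                "oxival_empty_study_error")
  }
  df$subject_id <- as.character(df$subject_id)
  df <- df[order(df$subject_id, df$site, df$plateau_index), , drop = FALSE]

  meta_cols <- c("subject_id", "cohort", "race", "skin_tone", "sex",
                 "age_years", "weight_kg", "sensor_side")
  subjects <- unique(df[, meta_cols])
  samples <- df[, c("subject_id", "plateau_index", "site",
                    "sto2_pct", "sao2_pct", "svo2_pct")]
  st <- new_study(cohort, subjects, samples)
  attr(st, "load_report") <- list(
    n_rows_read = n_read,
    n_dropped_missing = n_read - nrow(df),
    flagged_av_inversion = which(samples$svo2_pct > samples$sao2_pct))
  st
}

#' Write a study to CSV
#'
#' Inverse of [load_study()]: emits the long one-row-per-(subject, plateau,
#' site) format with the full column schema.
#'
#' @param study an `oxi_study`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "oxi_study"))
  df <- merge(study$samples, study$subjects, by = "subject_id", sort = FALSE)
  df <- df[, STUDY_COLUMNS]
  df <- df[order(df$subject_id, df$site, df$plateau_index), , drop = FALSE]
  # 17 significant digits so saturations survive the round trip value-exact
  for (col in c("sto2_pct", "sao2_pct", "svo2_pct", "weight_kg")) {
    df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Structural validation of a study
#'
#' Checks the structural invariants of the data model and reports violations
#' without raising: saturations in range, samples referencing known subjects,
#' cohort-consistent sensor sites (cerebral = forehead only), no duplicated
#' (subject, site, plateau) rows, plateau indices within 0..8, race-consistent
#' skin tone where the race is one of the four mapped categories, and the
#' physiological SaO2 >= SvO2 ordering (severity `"warning"` only).
#'
#' @param study an `oxi_study`.
#' @return data frame with columns `rule`, `severity` (`"error"`/`"warning"`),
#'   `subject_id`, `detail`; zero rows means the study is valid.  Serialize
#'   with [jsonlite::toJSON()] if a machine-readable report is needed.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "oxi_study"))
  sm <- study$samples
  sb <- study$subjects
  viol <- list()
  add <- function(rule, severity, subject_id, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      rule = rule, severity = severity,
      subject_id = as.character(subject_id), detail = detail,
      stringsAsFactors = FALSE)
  }

  for (col in c("sto2_pct", "sao2_pct", "svo2_pct")) {
    bad <- which(!is.finite(sm[[col]]) | sm[[col]] < 0 | sm[[col]] > 100)
    for (i in bad) add("saturation_range", "error", sm$subject_id[i],
                       sprintf("%s = %s outside [0, 100]", col, sm[[col]][i]))
  }
  orphan <- setdiff(unique(sm$subject_id), sb$subject_id)
  for (s in orphan) add("unknown_subject", "error", s,
                        "sample references a subject with no metadata row")
  allowed <- if (study$cohort == "cerebral") "forehead" else
    c("flank", "quadriceps", "calf")
  bad_site <- unique(sm[!sm$site %in% allowed, c("subject_id", "site")])
  if (nrow(bad_site)) for (i in seq_len(nrow(bad_site))) {
    add("cohort_site", "error", bad_site$subject_id[i],
        sprintf("site '%s' not permitted in %s cohort",
                bad_site$site[i], study$cohort))
  }
  key <- paste(sm$subject_id, sm$site, sm$plateau_index, sep = "\r")
  dup <- unique(key[duplicated(key)])
  for (k in dup) add("duplicate_plateau", "error", strsplit(k, "\r")[[1]][1],
                     sprintf("duplicated (subject, site, plateau): %s",
                             gsub("\r", "/", k)))
  bad_idx <- which(!sm$plateau_index %in% 0:8)
  for (i in bad_idx) add("plateau_index_range", "error", sm$subject_id[i],
                         sprintf("plateau_index %s outside 0..8",
                                 sm$plateau_index[i]))
  mapped <- sb$race %in% c("White", "Black", "Asian", "Hispanic")
  if (any(mapped)) {
    expect <- map_skin_tone(sb$race[mapped])
    off <- which(mapped)[expect != sb$skin_tone[mapped]]
    for (i in off) add("skin_tone_mapping", "error", sb$subject_id[i],
                       sprintf("race %s maps to tone %s, found %s",
                               sb$race[i], map_skin_tone(sb$race[i]),
                               sb$skin_tone[i]))
  }
  inv <- which(sm$svo2_pct > sm$sao2_pct)
  for (i in inv) add("av_inversion", "warning", sm$subject_id[i],
                     sprintf("SvO2 (%.2f) exceeds SaO2 (%.2f) at plateau %d",
                             sm$svo2_pct[i], sm$sao2_pct[i],
                             sm$plateau_index[i]))

  if (length(viol)) do.call(rbind, viol) else
    data.frame(rule = character(), severity = character(),
               subject_id = character(), detail = character(),
               stringsAsFactors = FALSE)
}
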
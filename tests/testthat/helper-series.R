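# fixtures built in code: paired series and small studies

# wrap a data frame of (subject_id, ref, device) as a paired_series
as_series <- function(df, r_v = 0.70) {
  if (is.null(df$plateau_index)) {
    df$plateau_index <- stats::ave(seq_len(nrow(df)), df$subject_id,
                                   FUN = seq_along) - 1L
  }
  if (is.null(df$site)) df$site <- "forehead"
  df <- df[, c("subject_id", "plateau_index", "site", "ref", "device")]
  structure(df, r_v = r_v, class = c("paired_series", "data.frame"))
}

# series from per-subject difference vectors (ref fixed, device = ref + d)
series_from_diffs <- function(diffs) {
  rows <- lapply(names(diffs), function(id) {
    d <- diffs[[id]]
    ref <- seq(60, 90, length.out = length(d))
    data.frame(subject_id = id, ref = ref, device = ref + d,
               stringsAsFactors = FALSE)
  })
  as_series(do.call(rbind, rows))
}

# errors-in-variables panel with equal error SDs on both axes, so that
# lambda = 1 Deming is correctly specified and the generating slope is the
# estimand of the pooled fit; caller controls the RNG state
make_eiv_series <- function(n_subjects, n_per, intercept, slope, sigma,
                            offset_sd = 1.0, t_jitter = 2.0) {
  t_grid <- seq(45, 80, length.out = n_per)
  rows <- lapply(seq_len(n_subjects), function(i) {
    t <- t_grid + rnorm(n_per, 0, t_jitter)
    o <- rnorm(1, 0, offset_sd)
    data.frame(subject_id = sprintf("S%02d", i),
               ref = t + rnorm(n_per, 0, sigma),
               device = intercept + o + slope * t + rnorm(n_per, 0, sigma),
               stringsAsFactors = FALSE)
  })
  as_series(do.call(rbind, rows))
}

# minimal hand-built somatic study (2 subjects, 2 plateaus, 3 sites)
tiny_somatic_study <- function() {
  subjects <- data.frame(
    subject_id = c("A", "B"), cohort = "somatic",
    race = c("White", "Black"), skin_tone = c("light", "dark"),
    sex = c("F", "M"), age_years = c(30, 41), weight_kg = c(61.5, 82),
    sensor_side = c("right", "left"), stringsAsFactors = FALSE)
  grid <- expand.grid(subject_id = c("A", "B"), plateau_index = 0:1,
                      site = c("flank", "quadriceps", "calf"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject_id, grid$site, grid$plateau_index), ]
  grid$sao2_pct <- 95 - 10 * grid$plateau_index
  grid$svo2_pct <- grid$sao2_pct - 28
  grid$sto2_pct <- 0.7 * grid$svo2_pct + 0.3 * grid$sao2_pct +
    c(-1, 1)[match(grid$subject_id, c("A", "B"))]
  new_study("somatic", subjects, grid)
}

# independent naive jackknife over points: the textbook delete-one loop
naive_jackknife <- function(x, y, lambda = 1) {
  n <- length(x)
  th <- t(vapply(seq_len(n), function(i) {
    f <- deming_fit(x[-i], y[-i], lambda)
    c(f$slope, f$intercept)
  }, numeric(2)))
  se <- function(v) sqrt((n - 1) / n * sum((v - mean(v))^2))
  list(se_slope = se(th[, 1]), se_intercept = se(th[, 2]))
}

# orthogonal-regression oracle: first principal axis of the centered scatter
principal_axis <- function(x, y) {
  cm <- cov(cbind(x, y))
  ev <- eigen(cm)
  v <- ev$vectors[, 1]
  slope <- v[2] / v[1]
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}
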
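test_that("Deming fit on exact and hand-derived instances", {
  x <- c(40, 55, 70, 85)
  f <- deming_fit(x, 2 + 0.97 * x)
  expect_equal(f$slope, 0.97, tolerance = 1e-12)
  expect_equal(f$intercept, 2.0, tolerance = 1e-10)

  f <- deming_fit(c(0, 1), c(0, 2))
  expect_equal(f$slope, 2.0)
  expect_equal(f$intercept, 0.0)

  # slope (-2 + sqrt(13))/3, intercept 2/3 - slope (orthogonal distance
  # minimizer, verified against the principal-axis oracle)
  f <- deming_fit(c(0, 1, 2), c(0, 1, 1))
  expect_equal(f$slope, (-2 + sqrt(13)) / 3, tolerance = 1e-12)
  expect_equal(f$intercept, 2 / 3 - (-2 + sqrt(13)) / 3, tolerance = 1e-12)

  expect_error(deming_fit(c(1, 1, 1), c(0, 1, 2)),
               class = "oxival_degenerate_error")
  # S_xy = 0 with S_yy = lambda S_xx: orientation undefined
  expect_error(deming_fit(c(0, 1, 0, 1), c(0, 0, 1, 1)),
               class = "oxival_degenerate_error")
})

test_that("lambda = 1 Deming equals the first principal axis on random instances", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    x <- runif(n, 0, 100)
    y <- runif(1, -5, 5) + runif(1, 0.5, 1.5) * x + rnorm(n, 0, 3)
    f <- deming_fit(x, y)
    pa <- principal_axis(x, y)
    expect_equal(f$slope, unname(pa["slope"]), tolerance = 1e-8)
    expect_equal(f$intercept, unname(pa["intercept"]), tolerance = 1e-8)
  }
})

test_that("Deming limits and symmetry: OLS at extreme lambda, axis exchange", {
  set.seed(55)
  x <- runif(20, 40, 90)
  y <- 3 + 0.9 * x + rnorm(20, 0, 2)
  ols_yx <- unname(coef(lm(y ~ x))[2])
  ols_xy <- unname(coef(lm(x ~ y))[2])
  expect_equal(deming_fit(x, y, lambda = 1e6)$slope, ols_yx, tolerance = 1e-4)
  expect_equal(deming_fit(x, y, lambda = 1e-6)$slope, 1 / ols_xy,
               tolerance = 1e-4)
  for (lam in c(0.5, 1, 2)) {
    expect_equal(deming_fit(y, x, 1 / lam)$slope,
                 1 / deming_fit(x, y, lam)$slope, tolerance = 1e-10)
  }
})

test_that("jackknife SEs: zero on collinear data, match the naive delete-one loop", {
  x <- c(10, 20, 30, 40, 50)
  jk <- jackknife_se(x, 1 + 2 * x)
  expect_equal(jk$se_slope, 0, tolerance = 1e-10)
  expect_equal(jk$se_intercept, 0, tolerance = 1e-8)

  set.seed(8)
  x <- runif(9, 40, 90)
  y <- 2 + 0.95 * x + rnorm(9, 0, 2.5)
  jk <- jackknife_se(x, y)
  nv <- naive_jackknife(x, y)
  expect_equal(jk$se_slope, nv$se_slope, tolerance = 1e-10)
  expect_equal(jk$se_intercept, nv$se_intercept, tolerance = 1e-10)

  # duplicating every point shrinks the jackknife SE
  jk2 <- jackknife_se(rep(x, 2), rep(y, 2))
  expect_lt(jk2$se_slope, jk$se_slope)
  expect_lt(jk2$se_intercept, jk$se_intercept)

  expect_error(jackknife_se(x[1:3], y[1:3]),
               class = "oxival_insufficient_data_error")
})

test_that("Cochran Q and meta pooling on hand-computed cases", {
  het <- cochran_q(c(1, 3), c(1, 1))
  expect_equal(het$Q, 2)
  expect_identical(het$df, 1L)
  expect_equal(het$tau2, 1)
  expect_equal(het$p, pchisq(2, 1, lower.tail = FALSE))

  het0 <- cochran_q(c(2, 2, 2), c(0.5, 1, 2))
  expect_equal(het0$Q, 0)
  expect_equal(het0$tau2, 0)
  expect_equal(het0$p, 1)

  expect_error(cochran_q(1, 1), class = "oxival_insufficient_data_error")
  expect_error(cochran_q(c(1, 2), c(0, 1)), class = "oxival_value_error")

  fx <- meta_pool(c(1, 3), c(1, 1), "fixed")
  expect_equal(fx$estimate, 2.0)
  expect_equal(fx$se, 1 / sqrt(2))
  rd <- meta_pool(c(1, 3), c(1, 1), "random")
  expect_equal(rd$estimate, 2.0)
  expect_equal(rd$se, 1.0)
  expect_equal(rd$ci95, c(2 - 1.96, 2 + 1.96))

  same <- meta_pool(c(0.9, 0.9, 0.9), c(0.1, 0.1, 0.1))
  expect_equal(same$estimate, 0.9)

  # fixed pooling with equal SEs is the arithmetic mean
  est <- c(0.8, 1.1, 0.95, 1.3)
  expect_equal(meta_pool(est, rep(0.2, 4), "fixed")$estimate, mean(est))
})

test_that("meta pooling agrees with an established meta-analysis implementation", {
  skip_if_not_installed("metafor")
  set.seed(14)
  est <- rnorm(10, 1, 0.2)
  ses <- runif(10, 0.05, 0.3)
  ours <- meta_pool(est, ses, "random")
  ref <- metafor::rma(yi = est, sei = ses, method = "DL")
  expect_equal(ours$estimate, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$se, ref$se, tolerance = 1e-10)
  expect_equal(cochran_q(est, ses)$Q, ref$QE, tolerance = 1e-10)
})

test_that("two-step pooled Deming: common line, duplication identity, Q growth", {
  # every subject on one shared line: pooled fit is that line, Q = 0
  line <- function(id) {
    x <- seq(40, 80, length.out = 9)
    data.frame(subject_id = id, ref = x, device = 2 + 0.97 * x)
  }
  s <- as_series(do.call(rbind, lapply(c("A", "B", "C"), line)))
  pd <- pooled_deming(s)
  expect_equal(pd$slope$estimate, 0.97, tolerance = 1e-10)
  expect_equal(pd$intercept$estimate, 2, tolerance = 1e-8)
  expect_equal(pd$heterogeneity$slope$Q, 0)

  # every subject a copy of one noisy subject: pooled = single-subject fit
  set.seed(33)
  x <- runif(9, 40, 90); y <- 1 + x + rnorm(9, 0, 2)
  one <- data.frame(subject_id = "A", ref = x, device = y)
  s1 <- as_series(one)
  s4 <- as_series(do.call(rbind, lapply(c("A", "B", "C", "D"), function(id) {
    d <- one; d$subject_id <- id; d
  })))
  single <- deming_fit(x, y)
  pd4 <- pooled_deming(s4)
  expect_equal(pd4$slope$estimate, single$slope, tolerance = 1e-10)
  expect_equal(pd4$intercept$estimate, single$intercept, tolerance = 1e-10)

  # subjects with <4 points are excluded with a warning
  s_mix <- as_series(rbind(
    data.frame(subject_id = "Z", ref = c(50, 60, 70), device = c(51, 61, 71)),
    do.call(rbind, lapply(c("A", "B"), function(id) {
      d <- one; d$subject_id <- id
      d$device <- d$device + rnorm(9, 0, 0.5)
      d
    }))))
  expect_warning(pd_mix <- pooled_deming(s_mix), "excluded")
  expect_false("Z" %in% pd_mix$per_subject$subject_id)

  # heterogeneity grows with true line separation
  set.seed(60)
  qs <- vapply(c(0, 0.1, 0.3), function(delta) {
    rows <- lapply(1:6, function(i) {
      x <- seq(40, 85, length.out = 9) + rnorm(9, 0, 1)
      b <- 1 + (i %% 2 == 0) * delta
      data.frame(subject_id = sprintf("S%d", i), ref = x,
                 device = b * x + rnorm(9, 0, 1))
    })
    pooled_deming(as_series(do.call(rbind, rows)))$heterogeneity$slope$Q
  }, numeric(1))
  expect_true(all(diff(qs) > 0))
})

test_that("pooled Deming recovers the slope under matched error structure", {
  # equal x/y error variances make lambda = 1 correctly specified; the
  # generating slope is then the estimand of the two-step pooled fit
  set.seed(90)
  cover <- vapply(1:30, function(k) {
    s <- make_eiv_series(25, 9, 2.45, 0.97, 2.0)
    ci <- pooled_deming(s)$slope$ci95
    ci[1] <= 0.97 && 0.97 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("random-coefficients model: degenerate line, OLS collapse, recovery", {
  x <- seq(40, 80, length.out = 9)
  rows <- lapply(c("A", "B", "C"), function(id) {
    data.frame(subject_id = id, ref = x, device = 1.728 + 0.977 * x)
  })
  s <- as_series(do.call(rbind, rows))
  r <- suppressWarnings(random_coefficients_fit(s))
  expect_equal(r$slope, 0.977, tolerance = 1e-6)
  expect_equal(r$intercept, 1.728, tolerance = 1e-4)
  expect_lt(max(r$varcomp$sd_slope, r$varcomp$sd_residual, na.rm = TRUE),
            1e-3)

  # one shared line + residual noise only: fixed effects match pooled OLS
  set.seed(71)
  rows <- lapply(sprintf("S%d", 1:8), function(id) {
    data.frame(subject_id = id, ref = x,
               device = 2 + 0.9 * x + rnorm(9, 0, 1.5))
  })
  s <- as_series(do.call(rbind, rows))
  r <- suppressWarnings(random_coefficients_fit(s))
  ols <- coef(lm(device ~ ref, data = s))
  expect_equal(r$slope, unname(ols[2]), tolerance = 1e-6)
  expect_equal(r$intercept, unname(ols[1]), tolerance = 1e-6)

  # simulated study with known device line: recovery within 3 SE
  st <- simulate_study(sim_config(device_slope = 0.97,
                                  device_intercept = 2.45, seed = 19))
  r <- suppressWarnings(random_coefficients_fit(build_paired_series(st)))
  expect_lt(abs(r$slope - 0.97), 3 * r$se_slope)

  expect_error(random_coefficients_fit(
    as_series(data.frame(subject_id = "A", ref = x, device = x))),
    class = "oxival_insufficient_data_error")
})

test_that("CCC: exact identities, Lin hand value, Pearson bound", {
  s <- as_series(data.frame(subject_id = rep(c("A", "B"), each = 3),
                            ref = c(1, 2, 3, 4, 5, 6),
                            device = c(1, 2, 3, 4, 5, 6)))
  expect_equal(ccc(s, "naive")$estimate, 1)

  s <- as_series(data.frame(subject_id = "A", ref = c(1, 2, 3),
                            device = c(2, 3, 4)))
  expect_equal(ccc(s, "naive", se = FALSE)$estimate, 4 / 7)

  s <- as_series(data.frame(subject_id = "A", ref = c(-1, 0, 1),
                            device = c(1, 0, -1)))
  expect_equal(ccc(s, "naive", se = FALSE)$estimate, -1)

  # |CCC| <= |Pearson r|, equality iff means and variances match
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(15, 50, 8); y <- rnorm(1, 0, 3) + 0.9 * x + rnorm(15, 0, 4)
    est <- ccc(as_series(data.frame(subject_id = "A", ref = x, device = y)),
               "naive", se = FALSE)$estimate
    expect_lte(abs(est), abs(cor(x, y)) + 1e-12)
  }

  expect_error(ccc(as_series(data.frame(subject_id = "A", ref = rep(5, 4),
                                        device = rep(5, 4))), "naive"),
               class = "oxival_undefined_ccc_error")
})

test_that("variance-components CCC targets the same estimand as Lin's CCC", {
  # exchangeable clustered data: both estimators approximate the population
  # CCC; at 25 x 9 they should sit close together
  set.seed(23)
  s <- make_eiv_series(25, 9, 0, 1, 2.0, offset_sd = 1.5)
  vc <- ccc(s, "variance_components", se = FALSE)$estimate
  nv <- ccc(s, "naive", se = FALSE)$estimate
  expect_lt(abs(vc - nv), 0.03)
  full <- ccc(s, "variance_components")
  expect_gt(full$se, 0)
  expect_true(full$ci95[1] <= full$estimate & full$estimate <= full$ci95[2])
})
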
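test_that("standard Bland-Altman bias and SD on hand-checkable inputs", {
  s <- series_from_diffs(list(A = c(2, 2, 2), B = c(2, 2, 2)))
  ba <- bland_altman(s)
  expect_equal(ba$bias, 2.0)
  expect_equal(ba$sd_standard, 0.0)

  s <- as_series(data.frame(subject_id = "A", ref = c(70, 80, 90),
                            device = c(70, 80, 90)))
  ba <- bland_altman(s)
  expect_equal(ba$bias, 0); expect_equal(ba$sd_standard, 0)

  s <- series_from_diffs(list(A = c(-1, 0, 1)))
  ba <- bland_altman(s)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_standard, 1.0)  # sample SD, n-1 denominator
  expect_equal(ba$limits_of_agreement, c(-1.96, 1.96))

  expect_error(bland_altman(series_from_diffs(list(A = 1))),
               class = "oxival_insufficient_data_error")
})

test_that("sd_standard equals the brute-force sample SD; bias is translation-equivariant", {
  set.seed(31)
  s <- make_eiv_series(6, 7, 1, 0.95, 2)
  ba <- bland_altman(s)
  expect_equal(ba$sd_standard, sd(s$device - s$ref))
  expect_equal(ba$bias, mean(s$device - s$ref))

  s2 <- s; s2$device <- s2$device + 3.5
  ba2 <- bland_altman(s2)
  expect_equal(ba2$bias, ba$bias + 3.5)
  expect_equal(ba2$sd_standard, ba$sd_standard)
  expect_equal(bland_altman_repeated(s2)$sd_modified,
               bland_altman_repeated(s)$sd_modified)
  # reversed convention flips the bias sign
  expect_equal(bland_altman(s, "reference_minus_device")$bias, -ba$bias)
})

test_that("repeated-measures SD follows the one-way ANOVA moment decomposition", {
  # 2 subjects x 3 replicates, differences {0,0,0} and {2,2,2}:
  # MSW = 0, MSB = 6, n0 = 3 => between variance 2
  s <- series_from_diffs(list(A = c(0, 0, 0), B = c(2, 2, 2)))
  ba <- bland_altman_repeated(s)
  expect_equal(ba$bias, 1.0)
  expect_equal(ba$sd_modified, sqrt(2))

  # zero between-subject spread: modified SD equals the within SD
  s <- series_from_diffs(list(A = c(-1, 0, 1), B = c(0, 1, -1),
                              C = c(1, -1, 0)))
  ba <- bland_altman_repeated(s)
  expect_equal(ba$sd_modified, 1.0)  # sigma2_b truncated at 0, sigma_w = 1

  # balanced design: components reproduce the decomposition identity
  set.seed(12)
  s <- make_eiv_series(8, 9, 0, 1, 2, offset_sd = 2)
  d <- s$device - s$ref
  comp <- oxival:::anova_components(d, s$subject_id)
  m <- tapply(d, s$subject_id, mean)
  expect_equal(comp$s2_within,
               sum((d - m[s$subject_id])^2) / (length(d) - 8))
  expect_gte(comp$s2_between, 0)

  expect_warning(ba1 <- bland_altman_repeated(
    series_from_diffs(list(A = c(0, 1, 2)))), "single subject")
  expect_equal(ba1$sd_modified, ba1$sd_standard)
})

test_that("subgroup agreement mirrors whole-sample results and permutation invariance", {
  set.seed(44)
  s <- make_eiv_series(6, 6, 1, 1, 1.5)
  ids <- unique(s$subject_id)
  one <- setNames(rep("g", 6), ids)
  res <- subgroup_agreement(s, one)
  whole <- bland_altman_repeated(s)
  expect_equal(res$g$agreement$bias, whole$bias)
  expect_equal(res$g$agreement$sd_modified, whole$sd_modified)

  grp <- setNames(rep(c("p", "q"), each = 3), ids)
  grp_swapped <- setNames(rep(c("q", "p"), each = 3), ids)
  r1 <- subgroup_agreement(s, grp)
  r2 <- subgroup_agreement(s, grp_swapped)
  # swapped labels: the same subject sets now carry the other name
  expect_equal(r1$p$agreement$bias, r2$q$agreement$bias)
  expect_equal(sort(c(r1$p$agreement$bias, r1$q$agreement$bias)),
               sort(c(r2$p$agreement$bias, r2$q$agreement$bias)))
})

test_that("a subgroup offset injected in simulation is recovered", {
  st <- simulate_study(sim_config(seed = 21))
  tone <- setNames(st$subjects$skin_tone, st$subjects$subject_id)
  dark <- st$samples$subject_id %in%
    st$subjects$subject_id[st$subjects$skin_tone == "dark"]
  st$samples$sto2_pct[dark] <- st$samples$sto2_pct[dark] + 1
  s <- build_paired_series(st)
  res <- subgroup_agreement(s, tone)
  diff_bias <- res$dark$agreement$bias - res$light$agreement$bias
  # 3 SE margin on the between-group contrast of subject means
  se <- sqrt(res$dark$agreement$sd_modified^2 / 5 +
               res$light$agreement$sd_modified^2 / 15)
  expect_lt(abs(diff_bias - 1), 3 * se)
})

test_that("group comparison is a Welch t-test on per-subject mean differences", {
  # per-subject means A-group {0,0,1,1}, B-group {0,1,1,2}: t = -1, df = 5.4
  diffs <- list(a1 = c(0, 0), a2 = c(0, 0), a3 = c(1, 1), a4 = c(1, 1),
                b1 = c(0, 0), b2 = c(1, 1), b3 = c(1, 1), b4 = c(2, 2))
  s <- series_from_diffs(diffs)
  grp <- setNames(rep(c("A", "B"), each = 4), names(diffs))
  res <- compare_groups(s, grp, c("A", "B"))
  expect_equal(res$t, -1, tolerance = 1e-12)
  expect_equal(res$df, 5.4, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-1, 5.4), tolerance = 1e-12)

  # identical per-subject mean sets: t = 0, p = 1
  diffs <- list(a1 = c(0, 0), a2 = c(1, 1), b1 = c(0, 0), b2 = c(1, 1))
  s <- series_from_diffs(diffs)
  grp <- setNames(c("A", "A", "B", "B"), names(diffs))
  res <- compare_groups(s, grp, c("A", "B"))
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  grp1 <- setNames(c("A", "B", "B", "B"), names(diffs))
  expect_error(compare_groups(s, grp1, c("A", "B")),
               class = "oxival_insufficient_data_error")
})

test_that("tone comparison keeps its nominal type-I error on null simulations", {
  # groups drawn from one population: p < 0.05 should occur ~5% of the time
  set.seed(77)
  reps <- 400
  hits <- 0L
  for (r in seq_len(reps)) {
    s <- make_eiv_series(12, 4, 0, 1, 1.5, offset_sd = 1)
    grp <- setNames(rep(c("A", "B"), each = 6), unique(s$subject_id))
    if (compare_groups(s, grp, c("A", "B"))$p_value < 0.05) hits <- hits + 1L
  }
  rate <- hits / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})
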
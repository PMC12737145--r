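# Synthetic cohort generation and the train/test split.

test_that("generated cohorts respect size, bounds, and determinism", {
  cfg <- cohort_config(n = 653)
  cohort <- generate_cohort(cfg, seed = 4)
  expect_equal(nrow(cohort), 653)
  expect_true(all(cohort$weight_kg >= 46 & cohort$weight_kg <= 133))
  expect_true(all(cohort$height_m >= 1.47 & cohort$height_m <= 1.77))
  expect_true(all(cohort$age_years >= 33 & cohort$age_years <= 88))
  expect_true(all(cohort$breast_thickness_mm >= 25 &
                    cohort$breast_thickness_mm <= 80))
  expect_true(all(cohort$total_dlp_mgycm >= 68.81 &
                    cohort$total_dlp_mgycm <= 914.5))
  expect_false(anyDuplicated(cohort$patient_id) > 0)
  # byte-identical under the same seed, different under another
  expect_identical(cohort, generate_cohort(cfg, seed = 4))
  expect_false(identical(cohort, generate_cohort(cfg, seed = 5)))
})

test_that("realized rank correlations track the copula targets", {
  cohort <- generate_cohort(cohort_config(n = 2000), seed = 21)
  rc <- function(a, b) cor(a, b, method = "spearman")
  expect_equal(rc(cohort$weight_kg, cohort$height_m), 0.3, tolerance = 0.1 / 0.3)
  expect_equal(rc(cohort$weight_kg, cohort$breast_thickness_mm), 0.4,
               tolerance = 0.1 / 0.4)
  expect_equal(rc(cohort$weight_kg, cohort$total_dlp_mgycm), 0.5,
               tolerance = 0.1 / 0.5)
})

test_that("zero correlation targets give independent features", {
  cfg <- cohort_config(n = 5000, rank_cor = c(weight_height = 0,
                                              weight_bt = 0, weight_dlp = 0))
  cohort <- generate_cohort(cfg, seed = 8)
  cols <- c("weight_kg", "height_m", "age_years", "breast_thickness_mm",
            "total_dlp_mgycm")
  for (i in 1:4) for (j in (i + 1):5) {
    r <- cor(cohort[[cols[i]]], cohort[[cols[j]]], method = "spearman")
    expect_lt(abs(r), 0.05)
  }
})

test_that("sample means converge to the configured means", {
  cfg <- cohort_config(n = 5000)
  cohort <- generate_cohort(cfg, seed = 31)
  # truncation is mild for these marginals, so the configured mean is
  # close to the truncated mean; allow 2 standard errors plus a small
  # truncation offset
  check <- function(x, mean_target, sd_target) {
    se <- sd_target / sqrt(5000)
    expect_lt(abs(mean(x) - mean_target), 2 * se + 0.02 * sd_target)
  }
  check(cohort$weight_kg, 73.1, 15)
  check(cohort$height_m, 1.59, 0.06)
  check(cohort$age_years, 58.6, 12)
  check(cohort$breast_thickness_mm, 50, 12)
})

test_that("infeasible correlation targets are rejected", {
  expect_error(cohort_config(rank_cor = c(weight_height = 0.99,
                                          weight_bt = 0.99,
                                          weight_dlp = -0.99)),
               "not positive definite")
})

test_that("splits are disjoint, exhaustive, reproducible, 522/131 at n=653", {
  lab <- labelled_small_cohort(n = 653, seed = 13)
  sp <- split_cohort(lab, train_fraction = 0.8, seed = 42)
  expect_equal(nrow(sp$train), 522)
  expect_equal(nrow(sp$test), 131)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_setequal(c(sp$train$patient_id, sp$test$patient_id), lab$patient_id)
  # determinism
  sp2 <- split_cohort(lab, train_fraction = 0.8, seed = 42)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)
  # comparability report covers both sides
  expect_equal(sp$report$split, c("train", "test"))
  expect_equal(sum(sp$report$n), 653)
  expect_lt(abs(diff(sp$report$mean_ir)), 2)
  # partition property at n = 10, fraction 0.5
  small <- lab[1:10, ]
  sp10 <- split_cohort(small, train_fraction = 0.5, seed = 1)
  expect_equal(nrow(sp10$train), 5)
  expect_setequal(c(sp10$train$patient_id, sp10$test$patient_id),
                  small$patient_id)
  expect_error(split_cohort(lab[1:2, ], train_fraction = 0.1), "empty")
})

test_that("noiseless labels satisfy the recomputability invariant", {
  lab <- labelled_small_cohort(n = 120, seed = 17)
  params <- attr(lab, "dose_params")
  expect_identical(lab$ir_mgy, internal_radiation(lab, params))
})
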
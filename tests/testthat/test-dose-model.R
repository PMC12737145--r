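# The IR dose model: BMI, min-max factors, BODY combination, calibration
# and cohort labelling.

test_that("BMI matches hand calculations and the identity case", {
  expect_equal(compute_bmi(73.1, 1.59), 28.9150, tolerance = 1e-4)
  expect_equal(compute_bmi(46, 1.77), 14.6828, tolerance = 1e-4)
  x <- c(0.5, 42, 133)
  expect_equal(compute_bmi(x, rep(1, 3)), x)
  expect_error(compute_bmi(0, 1.6), "weight")
  expect_error(compute_bmi(70, -1), "height")
})

test_that("min-max normalization hits its bounds, midpoint, and clamps", {
  expect_equal(minmax_normalize(3, 3, 9), 0)
  expect_equal(minmax_normalize(9, 3, 9), 1)
  expect_equal(minmax_normalize(6, 3, 9), 0.5)
  expect_equal(minmax_normalize(c(-10, 100), 3, 9), c(0, 1))
  expect_error(minmax_normalize(1, 5, 5), "degenerate")
  expect_error(minmax_normalize(1, 5, 4), "degenerate")
})

test_that("BODY factor is a convex combination with the 40/30/30 default", {
  stats <- normalization_stats(tiny_patients())
  p <- dose_model_params(stats = stats)
  expect_equal(body_factor(1, 1, 1, p), 1)
  expect_equal(body_factor(0, 0, 0, p), 0)
  expect_equal(body_factor(1, 0, 0, p), 0.40)
  expect_equal(body_factor(0, 1, 0, p), 0.30)
  # bounded by min and max of the inputs for random factors
  set.seed(1)
  for (i in 1:25) {
    f <- runif(3)
    b <- body_factor(f[1], f[2], f[3], p)
    expect_gte(b, min(f)); expect_lte(b, max(f))
  }
  expect_error(dose_model_params(w_bmi = 0.5, w_bt = 0.3, w_age = 0.3,
                                 stats = stats), "sum to 1")
  # product form multiplies the factors
  pp <- dose_model_params(stats = stats, form = "product")
  expect_equal(body_factor(0.5, 0.5, 0.5, pp), 0.125)
})

test_that("IR is linear in DLP, zero iff BODY is zero, and monotone", {
  pats <- tiny_patients()
  stats <- normalization_stats(pats)
  p <- dose_model_params(k = 0.05, stats = stats)
  ir <- internal_radiation(pats, p)
  expect_true(all(ir >= 0))
  # patient A sits at every feature minimum -> BODY = 0 -> IR = 0
  expect_equal(ir[1], 0)
  # doubling DLP doubles IR
  pats2 <- pats; pats2$total_dlp_mgycm <- 2 * pats$total_dlp_mgycm
  expect_equal(internal_radiation(pats2, p), 2 * ir)
  # k = 1 and all factors at max -> IR = DLP
  expect_equal(ir[3] / 0.05, pats$total_dlp_mgycm[3])
  # monotone non-decreasing in each anthropometric at fixed DLP
  base <- pats[2, , drop = FALSE]
  for (col in c("age_years", "breast_thickness_mm", "weight_kg")) {
    up <- base; up[[col]] <- up[[col]] * 1.05
    expect_gte(internal_radiation(up, p), internal_radiation(base, p))
  }
})

test_that("calibration hits the target mean exactly and scales correctly", {
  pats <- labelled_small_cohort(n = 200, seed = 3)
  stats <- normalization_stats(pats)
  k <- calibrate_k(pats, stats, target_mean = 9.76)
  params <- dose_model_params(k = k, stats = stats)
  expect_equal(mean(internal_radiation(pats, params)), 9.76,
               tolerance = 1e-9)
  # fixed point: target equal to current mean under k = 1 returns k = 1
  m1 <- mean(internal_radiation(pats, dose_model_params(k = 1, stats = stats)))
  expect_equal(calibrate_k(pats, stats, target_mean = m1), 1, tolerance = 1e-12)
  # homogeneity: scaling all DLP by c scales k by 1/c
  pats_c <- pats; pats_c$total_dlp_mgycm <- 4 * pats$total_dlp_mgycm
  expect_equal(calibrate_k(pats_c, stats, target_mean = 9.76), k / 4,
               tolerance = 1e-12)
  # closed form on a single patient: DLP x BODY = 100 -> k = target / 100
  one <- tiny_patients()[3, , drop = FALSE]
  stats3 <- normalization_stats(tiny_patients())
  body3 <- 1  # patient C sits at every feature maximum
  one$total_dlp_mgycm <- 100 / body3
  expect_equal(calibrate_k(one, stats3, target_mean = 9.76), 0.0976)
  # calibration impossible when every DLP x BODY product is zero
  a_only <- tiny_patients()[1, , drop = FALSE]
  expect_error(calibrate_k(a_only, stats3), "calibration impossible")
})

test_that("labelling is aligned, recomputable, and idempotent", {
  pats <- small_cohort(n = 50, seed = 9)
  stats <- normalization_stats(pats)
  params <- dose_model_params(k = 0.03, stats = stats)
  lab <- label_cohort(pats, params)
  expect_equal(nrow(lab), nrow(pats))
  expect_equal(lab$ir_mgy, internal_radiation(pats, params))
  # relabelling with its own params reproduces ir exactly
  relab <- label_cohort(lab[, setdiff(names(lab), "ir_mgy")],
                        attr(lab, "dose_params"))
  expect_identical(relab$ir_mgy, lab$ir_mgy)
  # empty cohort -> empty labelled cohort
  empty <- pats[0, , drop = FALSE]
  expect_equal(nrow(label_cohort(empty, params)), 0)
  # invalid record errors name the offending patient
  bad <- pats; bad$weight_kg[7] <- -1
  expect_error(label_cohort(bad, params), bad$patient_id[7])
})

test_that("normalization stats reject degenerate feature ranges", {
  pats <- tiny_patients()
  pats$age_years <- rep(50, 3)
  expect_error(normalization_stats(pats), "degenerate")
})
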
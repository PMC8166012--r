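# Hand-derived oracle values for the three estimators, frozen from
# term-by-term arithmetic:
#   spot24, male at cohort-mean covariates:
#     909.368 + 24.052*66.60 - 0.11*49.08^2 + 538.38 + 0.269*2002.75
#     - 5.469*96.34 + 5.541*37.65 = 3005.11
#   tanaka toy: PRCr = -2.04*50 + 14.89*65 + 16.14*160 - 2244.45 = 1203.80;
#     21.98 * (100/(100*10) * 1203.80)^0.392 = 143.75
#   intersalt male toy: 25.46 + 0.46*150 - 2.75*8.8402 - 0.13*40
#     + 4.10*26 + 0.26*50 = 184.55

mean_covariates <- function(sex = "M") {
  data.frame(
    sex = sex, age_y = 49.08, weight_kg = 66.60, height_m = 1.58,
    spot_na_mg_l = 2002.75, spot_cr_mg_dl = 96.34, spot_k_mmol_l = 37.65,
    stringsAsFactors = FALSE
  )
}

test_that("spot24 equation reproduces hand-computed values and the sex offset", {
  expect_equal(predict_spot24(mean_covariates("M")), 3005.11, tolerance = 1e-5)
  expect_equal(predict_spot24(mean_covariates("F")), 2466.73, tolerance = 1e-5)
  expect_equal(
    predict_spot24(mean_covariates("M")) - predict_spot24(mean_covariates("F")),
    538.38
  )
  # intercept only: female with all covariates zero
  zero <- mean_covariates("F")
  zero[c("age_y", "weight_kg", "spot_na_mg_l", "spot_cr_mg_dl", "spot_k_mmol_l")] <- 0
  expect_equal(predict_spot24(zero), 909.368)
})

test_that("spot24 is affine in spot sodium and warns on mmol-like inputs", {
  r1 <- mean_covariates()
  r2 <- r1
  r2$spot_na_mg_l <- r1$spot_na_mg_l + 1000
  expect_equal(
    predict_spot24(r2) - predict_spot24(r1),
    0.269 * 1000
  )
  low <- r1
  low$spot_na_mg_l <- 87 # plausible mmol/L value
  expect_warning(predict_spot24(low), "mmol/L")
})

test_that("tanaka equation matches the hand oracle in both variants", {
  toy <- data.frame(
    sex = "M", age_y = 50, weight_kg = 65, height_m = 1.60,
    spot_na_mg_l = 100 * 23, spot_cr_mg_dl = 100, spot_k_mmol_l = 40
  )
  expect_equal(predict_tanaka(toy), 143.7491, tolerance = 1e-4)
  # printed-constant variant shifts PRCr by exactly +2020
  prcr_canon <- -2.04 * 50 + 14.89 * 65 + 16.14 * 160 - 2244.45
  expect_equal(prcr_canon, 1203.80)
  expect_equal(
    predict_tanaka(toy, variant = "as_printed"),
    21.98 * (0.1 * (prcr_canon + 2020))^0.392,
    tolerance = 1e-10
  )
  # zero spot sodium -> zero estimate
  z <- toy
  z$spot_na_mg_l <- 0
  expect_equal(predict_tanaka(z), 0)
  # division and domain errors
  bad <- toy
  bad$spot_cr_mg_dl <- 0
  expect_error(predict_tanaka(bad), "division")
  neg <- toy
  neg$weight_kg <- 5 # small and short: PRCr = -102 + 74.45 + 1614 - 2244.45 < 0
  neg$height_m <- 1.0
  expect_error(predict_tanaka(neg), "negative base")
})

test_that("tanaka is increasing in spot sodium and decreasing in spot creatinine", {
  base <- data.frame(
    sex = "M", age_y = 50, weight_kg = 65, height_m = 1.60,
    spot_na_mg_l = 2000, spot_cr_mg_dl = 100, spot_k_mmol_l = 40
  )
  na_grid <- do.call(rbind, replicate(20, base, simplify = FALSE))
  na_grid$spot_na_mg_l <- seq(100, 5000, length.out = 20)
  expect_true(all(diff(predict_tanaka(na_grid)) > 0))
  cr_grid <- do.call(rbind, replicate(20, base, simplify = FALSE))
  cr_grid$spot_cr_mg_dl <- seq(20, 300, length.out = 20)
  expect_true(all(diff(predict_tanaka(cr_grid)) < 0))
})

test_that("intersalt equation matches the hand oracle per sex", {
  toy <- data.frame(
    sex = "M", age_y = 50, weight_kg = 26 * 1.6^2, height_m = 1.6,
    spot_na_mg_l = 150 * 23, spot_cr_mg_dl = 100, spot_k_mmol_l = 40
  )
  expect_equal(predict_intersalt(toy), 184.5495, tolerance = 1e-3)
  toy_f <- toy
  toy_f$sex <- "F"
  expect_false(predict_intersalt(toy_f) == predict_intersalt(toy))
  # female constant term: all inputs zero, age zero
  zero_f <- data.frame(
    sex = "F", age_y = 0, weight_kg = 0, height_m = 1,
    spot_na_mg_l = 0, spot_cr_mg_dl = 0, spot_k_mmol_l = 0
  )
  expect_equal(predict_intersalt(zero_f), 5.07)
  # missing BMI inputs
  nah <- toy
  nah$height_m <- NA
  expect_error(predict_intersalt(nah), "BMI")
})

test_that("all three estimators give physiologic values at mean covariates", {
  rec <- mean_covariates("M")
  ests <- standard_estimators()
  for (name in names(ests)) {
    mg <- ests[[name]](rec)
    expect_gt(mg, 1000)
    expect_lt(mg, 6000)
  }
})

test_that("sodium conversions use the exact published constants and round-trip", {
  expect_equal(convert_sodium(100, "mmol_day", "mg_day"), 2300)
  expect_equal(convert_sodium(2300, "mg_day", "g_salt_day"), 5.842)
  x <- c(0.3, 17, 2694.4)
  expect_equal(
    convert_sodium(convert_sodium(x, "mg_day", "mmol_day"), "mmol_day", "mg_day"),
    x,
    tolerance = 1e-12
  )
  expect_equal(
    convert_sodium(convert_sodium(x, "mg_day", "g_salt_day"), "g_salt_day", "mg_day"),
    x,
    tolerance = 1e-12
  )
  expect_error(convert_sodium(1, "mg_day", "furlongs"), "unknown sodium unit")
})

test_that("creatinine conversions follow the 113.12 g/mol molar mass", {
  expect_equal(convert_creatinine(100, "mg_dl", "mmol_l"), 1000 / 113.12, tolerance = 1e-12)
  expect_equal(convert_creatinine(1.0, "g_day", "mmol_day"), 1000 / 113.12, tolerance = 1e-12)
  expect_equal(convert_creatinine(7.5, "mmol_l", "mmol_l"), 7.5)
  expect_equal(
    convert_creatinine(convert_creatinine(96.34, "mg_dl", "mmol_l"), "mmol_l", "mg_dl"),
    96.34,
    tolerance = 1e-12
  )
  expect_error(convert_creatinine(1, "mg_dl", "g_day"), "cannot convert")
  expect_error(convert_creatinine(1, "mg_dl", "stones"), "unknown creatinine unit")
})
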
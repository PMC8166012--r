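test_that("split_cohort gives a seeded, exhaustive, balanced partition", {
  co <- generate_cohort(cohort_params(n = 768, seed = 2))
  halves <- split_cohort(co, seed = 10)
  expect_equal(sort(c(nrow(halves$group1), nrow(halves$group2))), c(384, 384))
  expect_setequal(c(halves$group1$id, halves$group2$id), co$id)
  expect_length(intersect(halves$group1$id, halves$group2$id), 0)
  again <- split_cohort(co, seed = 10)
  expect_identical(halves$group1$id, again$group1$id)
  # odd n differs by one
  odd <- split_cohort(co[1:99, ], seed = 1)
  expect_equal(abs(nrow(odd$group1) - nrow(odd$group2)), 1)
  expect_error(split_cohort(co[1, , drop = FALSE]), "at least 2")
})

test_that("fit_ols recovers exact coefficients from noise-free data", {
  set.seed(31)
  X <- data.frame(a = rnorm(40), b = runif(40), c = rnorm(40))
  y <- 2.5 - 1.2 * X$a + 0.4 * X$b + 7 * X$c
  # lm's summary warns about the essentially perfect fit; that is the point
  fit <- suppressWarnings(fit_ols(y, X))
  expect_equal(fit$intercept, 2.5, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients$b[-1]), c(-1.2, 0.4, 7), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("fit_ols agrees with the normal-equations oracle on random designs", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(15:40, 1)
    p <- sample(2:4, 1)
    X <- as.data.frame(matrix(rnorm(n * p), n, p))
    y <- rnorm(n, sd = runif(1, 0.5, 3))
    fit <- fit_ols(y, X)
    orc <- oracle_ols(y, X)
    expect_equal(fit$coefficients$b, orc$b, tolerance = 1e-10)
    expect_equal(fit$coefficients$se, orc$se, tolerance = 1e-10)
    expect_equal(fit$coefficients$p, orc$p, tolerance = 1e-8)
    expect_equal(unname(fit$beta), orc$beta, tolerance = 1e-10)
    expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-10)
  }
})

test_that("fit_ols residuals are orthogonal to the design and identities hold", {
  co <- generate_cohort(cohort_params(n = 300, seed = 14))
  X <- spotsodium:::design_columns(
    co, c("male", "weight_kg", "spot_na_mg_l", "spot_k_mmol_l")
  )
  fit <- fit_ols(co$na24_mg, X)
  pred <- fit$intercept + as.matrix(X) %*% fit$coefficients$b[-1]
  resid <- co$na24_mg - pred
  for (j in seq_along(X)) {
    expect_lt(abs(sum(resid * X[[j]])), 1e-8 * nrow(X) * sd(X[[j]]) * sd(resid))
  }
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  # beta_j = b_j sd(x_j)/sd(y)
  expect_equal(
    unname(fit$beta),
    fit$coefficients$b[-1] * vapply(X, sd, numeric(1)) / sd(co$na24_mg),
    ignore_attr = TRUE
  )
})

test_that("fit_ols rejects degenerate designs", {
  X <- data.frame(a = rnorm(20), b = 1)
  expect_error(fit_ols(rnorm(20), X), "constant|collinear")
  X2 <- data.frame(a = rnorm(20))
  X2$b <- 2 * X2$a
  expect_error(fit_ols(rnorm(20), X2), "collinear")
  expect_error(fit_ols(rnorm(3), data.frame(a = rnorm(3), b = rnorm(3))), "n > p")
})

test_that("stepwise selection keeps true predictors and respects thresholds", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 2000
    cand <- data.frame(
      true1 = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n)
    )
    y <- 3 + 1.5 * cand$true1 + rnorm(n, sd = 4)
    fit <- stepwise_select(y, cand)
    if (identical(fit$terms, "true1")) hits <- hits + 1
    expect_true("true1" %in% fit$terms)
    # nothing retained with p above the removal threshold
    expect_true(all(fit$coefficients$p[-1] <= 0.10))
  }
  expect_gte(hits, 9)
})

test_that("stepwise with degenerate entry threshold equals the full OLS fit", {
  set.seed(8)
  cand <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  y <- rnorm(50)
  fit_all <- stepwise_select(y, cand, p_enter = 1.0, p_remove = 1.0)
  expect_setequal(fit_all$terms, c("a", "b", "c"))
  expect_equal(fit_all$coefficients, fit_ols(y, cand)$coefficients)
  # determinism: same data, same selection
  co <- generate_cohort(cohort_params(n = 400, seed = 33))
  cand2 <- spotsodium:::design_columns(
    co, c("male", "weight_kg", "age2", "spot_na_mg_l")
  )
  f1 <- stepwise_select(co$na24_mg, cand2)
  f2 <- stepwise_select(co$na24_mg, cand2)
  expect_identical(f1$terms, f2$terms)
  # no candidate reaching entry -> intercept-only fit with warning
  set.seed(12)
  pure_noise <- data.frame(a = rnorm(80), b = rnorm(80))
  y2 <- rnorm(80)
  expect_warning(f0 <- stepwise_select(y2, pure_noise, p_enter = 1e-6, p_remove = 1e-5))
  expect_length(f0$terms, 0)
  expect_equal(f0$intercept, mean(y2))
})

test_that("double cross-validation on identical groups gives zero shrinkage", {
  co <- generate_cohort(cohort_params(n = 200, seed = 6))
  preds <- c("male", "weight_kg", "spot_na_mg_l")
  cv <- double_cross_validate(co, co, preds)
  expect_equal(cv$shrinkage1, 0)
  expect_equal(cv$shrinkage2, 0)
  expect_equal(cv$R11, cv$R12)
  expect_equal(cv$R22, cv$R21)
  # own-weight multiple correlation equals the OLS multiple R
  expect_equal(cv$R11, cv$fit1$r, tolerance = 1e-12)
})

test_that("double cross-validation matches a brute-force composite oracle on a toy set", {
  g1 <- make_cohort(
    make_record(weight_kg = 60, spot_na_mg_l = 1500, na24_mg = 2100),
    make_record(weight_kg = 70, spot_na_mg_l = 2500, na24_mg = 3200),
    make_record(weight_kg = 55, spot_na_mg_l = 1200, na24_mg = 1900),
    make_record(weight_kg = 80, spot_na_mg_l = 2800, na24_mg = 3600),
    make_record(weight_kg = 65, spot_na_mg_l = 2000, na24_mg = 2500),
    make_record(weight_kg = 75, spot_na_mg_l = 1800, na24_mg = 3100)
  )
  g2 <- make_cohort(
    make_record(weight_kg = 58, spot_na_mg_l = 1400, na24_mg = 2000),
    make_record(weight_kg = 72, spot_na_mg_l = 2600, na24_mg = 3300),
    make_record(weight_kg = 61, spot_na_mg_l = 1700, na24_mg = 2450),
    make_record(weight_kg = 78, spot_na_mg_l = 2300, na24_mg = 3500),
    make_record(weight_kg = 64, spot_na_mg_l = 2100, na24_mg = 2700),
    make_record(weight_kg = 69, spot_na_mg_l = 1600, na24_mg = 2900)
  )
  preds <- c("weight_kg", "spot_na_mg_l")
  cv <- double_cross_validate(g1, g2, preds)

  # oracle: explicit z-scores, normal-equations betas, composites by hand
  oracle_R <- function(target, source) {
    Xs <- as.matrix(target[, preds])
    bs <- oracle_ols(source$na24_mg, source[, preds])
    beta <- bs$beta
    Z <- scale(Xs) # own-group standardization
    comp <- Z %*% beta
    cor(comp, target$na24_mg)[1]
  }
  expect_equal(cv$R11, oracle_R(g1, g1), tolerance = 1e-12)
  expect_equal(cv$R12, oracle_R(g1, g2), tolerance = 1e-12)
  expect_equal(cv$R22, oracle_R(g2, g2), tolerance = 1e-12)
  expect_equal(cv$R21, oracle_R(g2, g1), tolerance = 1e-12)
  expect_equal(cv$shrinkage1, cv$R11^2 - cv$R12^2)
  expect_equal(cv$shrinkage2, cv$R22^2 - cv$R21^2)
})

test_that("shrinkage is small when both halves share one generating model", {
  preds <- c(
    "male", "weight_kg", "age2", "spot_na_mg_l", "spot_cr_mg_dl", "spot_k_mmol_l"
  )
  shrink <- numeric(0)
  for (seed in 1:50) {
    co <- generate_cohort(cohort_params(n = 4000, seed = seed))
    halves <- split_cohort(co, seed = seed) # 2000 per half
    cv <- double_cross_validate(halves$group1, halves$group2, preds)
    shrink <- c(shrink, cv$shrinkage1, cv$shrinkage2)
  }
  # own-minus-cross optimism scales as ~2p(1 - R^2)/n, about 0.005 here
  expect_lt(mean(abs(shrink)), 0.02)
})

test_that("finalize_equation recovers the generating model and refuses unstable pools", {
  co <- generate_cohort(cohort_params(n = 5000, seed = 42))
  preds <- c(
    "weight_kg", "age2", "male", "spot_na_mg_l", "spot_cr_mg_dl", "spot_k_mmol_l"
  )
  res <- finalize_equation(co, preds, seed = 1)
  truth <- c(
    weight_kg = 24.052, age2 = -0.11, male = 538.38,
    spot_na_mg_l = 0.269, spot_cr_mg_dl = -5.469, spot_k_mmol_l = 5.541
  )
  cf <- res$fit$coefficients
  for (term in names(truth)) {
    i <- match(term, cf$term)
    expect_lt(
      abs(cf$b[i] - truth[[term]]), 3 * cf$se[i],
      label = sprintf("|b(%s) - truth| < 3 SE", term)
    )
  }
  # the fitted equation predicts through predict_spot24
  expect_s3_class(res$equation, "spot24_coefficients")
  pred <- predict_spot24(co, res$equation)
  expect_equal(cor(pred, co$na24_mg), res$fit$r, tolerance = 1e-10)

  # discordant halves: different generating models -> refusal
  co_a <- generate_cohort(cohort_params(n = 300, seed = 7))
  co_b <- generate_cohort(cohort_params(
    n = 300, seed = 8,
    true_model = true_model_spec(
      coef_weight = 0, coef_age2 = 0, coef_male = 0,
      coef_spot_na = 3, coef_spot_cr = 0, coef_spot_k = 0, noise_sd = 300
    )
  ))
  co_b$id <- sprintf("T%05d", seq_len(nrow(co_b)))
  mixed <- rbind(co_a, co_b)
  cv_bad <- double_cross_validate(co_a, co_b, preds)
  expect_error(
    finalize_equation(mixed, preds, cv = cv_bad),
    "shrinkage"
  )
  forced <- finalize_equation(mixed, preds, cv = cv_bad, force = TRUE)
  expect_s3_class(forced$fit, "regression_fit")
})

test_that("correlation-based sample size reproduces the published calculation", {
  expect_identical(sample_size_correlation(0.15, 0.05, 0.80), 346L)
  expect_identical(sample_size_correlation(0.5, 0.05, 0.80), 29L)
  # strictly decreasing in |r|
  rs <- seq(0.05, 0.9, by = 0.05)
  ns <- vapply(rs, sample_size_correlation, integer(1))
  expect_true(all(diff(ns) < 0))
  expect_identical(
    sample_size_correlation(-0.15),
    sample_size_correlation(0.15)
  )
  expect_error(sample_size_correlation(0), "unbounded")
  expect_error(sample_size_correlation(0.15, alpha = 1.5), "alpha")
})
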
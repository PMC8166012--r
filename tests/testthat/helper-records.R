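# Fixture builders: handcrafted participant records with sensible adult
# defaults; every field overridable.

make_record <- function(id = "S00001", sex = "M", age_y = 40,
                        weight_kg = 65, height_m = 1.60,
                        spot_na_mg_l = 2000, spot_k_mmol_l = 35,
                        spot_cr_mg_dl = 95, vol24_ml = 1500, dur_h = 24,
                        missing_void = FALSE, na24_mg = 2700,
                        k24_mg = 1000, cr24_g = 1.0, pregnant = FALSE,
                        fasting = FALSE, kidney_disease = FALSE) {
  data.frame(
    id = id, sex = sex, age_y = age_y, weight_kg = weight_kg,
    height_m = height_m, spot_na_mg_l = spot_na_mg_l,
    spot_k_mmol_l = spot_k_mmol_l, spot_cr_mg_dl = spot_cr_mg_dl,
    vol24_ml = vol24_ml, dur_h = dur_h, missing_void = missing_void,
    na24_mg = na24_mg, k24_mg = k24_mg, cr24_g = cr24_g,
    pregnant = pregnant, fasting = fasting,
    kidney_disease = kidney_disease, stringsAsFactors = FALSE
  )
}

make_cohort <- function(...) {
  rows <- list(...)
  for (i in seq_along(rows)) rows[[i]]$id <- sprintf("S%05d", i)
  do.call(rbind, rows)
}

# Independent normal-equations OLS oracle: explicit solve of X'X b = X'y
# with textbook SE / p / standardized-beta formulas. Deliberately avoids
# lm() so it can cross-check fit_ols.
oracle_ols <- function(y, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  D <- cbind(1, X)
  XtX <- t(D) %*% D
  b <- solve(XtX, t(D) %*% y)
  resid <- y - D %*% b
  df <- n - p - 1
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- b / se
  pval <- 2 * pt(-abs(tval), df = df)
  ssr <- sum((D %*% b - mean(y))^2)
  sst <- sum((y - mean(y))^2)
  list(
    b = as.numeric(b), se = as.numeric(se), p = as.numeric(pval),
    beta = as.numeric(b[-1]) * unname(apply(X, 2, sd)) / sd(y),
    r_squared = ssr / sst,
    residual_sd = sqrt(sigma2)
  )
}
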
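#' Coefficients of the Malaysian spot-urine sodium equation
#'
#' The published Malaysian adult equation for measured 24-h urinary sodium
#' (mg/day) from a single morning spot urine:
#'
#' \deqn{\hat{Na}_{24h} = 909.368 + 24.052\,weight_{kg} - 0.11\,age^2
#'   + 538.38\,[male] + 0.269\,Na_{spot,mg/L} - 5.469\,Cr_{spot,mg/dL}
#'   + 5.541\,K_{spot,mmol/L}}
#'
#' `spot24_coefficients()` with no arguments returns exactly these printed
#' values. A fitted equation from [finalize_equation()] produces the same
#' class, possibly with a different term set (any subset of
#' `weight_kg, age2, male, height_m, spot_na_mg_l, spot_cr_mg_dl,
#' spot_k_mmol_l`), so refitted equations are evaluated by the same
#' predictor.
#'
#' @param intercept mg/day.
#' @param terms named numeric vector of term coefficients; names must be
#'   known design columns (see Details).
#' @return an object of class `spot24_coefficients`.
#' @seealso [predict_spot24()]
#' @export
spot24_coefficients <- function(intercept = 909.368,
                                terms = c(
                                  weight_kg = 24.052,
                                  age2 = -0.11,
                                  male = 538.38,
                                  spot_na_mg_l = 0.269,
                                  spot_cr_mg_dl = -5.469,
                                  spot_k_mmol_l = 5.541
                                )) {
  known <- c(
    "weight_kg", "age2", "male", "height_m", "age_y",
    "spot_na_mg_l", "spot_cr_mg_dl", "spot_k_mmol_l"
  )
  if (is.null(names(terms)) || !all(names(terms) %in% known)) {
    stopf(
      "spot24 terms must be named with known design columns: %s",
      paste(known, collapse = ", ")
    )
  }
  structure(
    list(intercept = intercept, terms = terms),
    class = "spot24_coefficients"
  )
}

# Derived design columns shared by the fitted equation and the stepwise
# candidate set. `male` is a 0/1 indicator; `age2` is age in years squared.
design_columns <- function(records, columns) {
  base <- list(
    weight_kg = records$weight_kg,
    age2 = records$age_y^2,
    age_y = records$age_y,
    male = as.numeric(records$sex == "M"),
    height_m = records$height_m,
    spot_na_mg_l = records$spot_na_mg_l,
    spot_cr_mg_dl = records$spot_cr_mg_dl,
    spot_k_mmol_l = records$spot_k_mmol_l
  )
  missing <- setdiff(columns, names(base))
  if (length(missing) > 0) {
    stopf("unknown design columns: %s", paste(missing, collapse = ", "))
  }
  as.data.frame(base[columns], optional = TRUE)
}

#' Predict 24-h sodium with the spot-urine linear equation
#'
#' Evaluates a [spot24_coefficients()] equation on each record. Unit
#' contract: weight kg, age years, spot sodium mg/L, spot creatinine
#' mg/dL, spot potassium mmol/L; output mg/day. The sex term is added for
#' males only; age enters squared. If the spot sodium column looks like it
#' is in mmol/L rather than mg/L (all positive values below 400 mg/L, far
#' below any plausible mg/L cohort), a warning is raised but prediction
#' proceeds.
#'
#' @param records a cohort data frame.
#' @param coefficients a [spot24_coefficients()] object.
#' @return numeric vector of predicted 24-h sodium, mg/day.
#' @examples
#' rec <- data.frame(
#'   sex = "M", age_y = 49.08, weight_kg = 66.60, height_m = 1.58,
#'   spot_na_mg_l = 2002.75, spot_cr_mg_dl = 96.34, spot_k_mmol_l = 37.65
#' )
#' predict_spot24(rec) # 3005.11 mg/day
#' @export
predict_spot24 <- function(records, coefficients = spot24_coefficients()) {
  if (!inherits(coefficients, "spot24_coefficients")) {
    stopf("coefficients must be a spot24_coefficients object")
  }
  na <- records$spot_na_mg_l
  pos <- na[!is.na(na) & na > 0]
  if (length(pos) > 0 && all(pos < 400)) {
    warnf(
      "spot_na_mg_l values are all below 400; they may be in mmol/L, not the mg/L this equation expects"
    )
  }
  X <- as.matrix(design_columns(records, names(coefficients$terms)))
  as.numeric(coefficients$intercept + X %*% coefficients$terms)
}

#' Coefficients of the Tanaka equation
#'
#' Tanaka's estimator scales the spot sodium-to-creatinine ratio by
#' predicted 24-h creatinine excretion (PRCr, mg/day), itself a linear
#' function of age, weight and height:
#' \deqn{PRCr = -2.04\,age + 14.89\,weight_{kg} + 16.14\,height_{cm} + c}
#' \deqn{\hat{Na}_{24h} = 21.98 \left(\frac{Na_{spot,mmol/L}}
#'   {10\,Cr_{spot,mg/dL}} \cdot PRCr\right)^{0.392} \ \mathrm{mmol/day}}
#'
#' The canonical constant is c = -2244.45. Some secondary sources print
#' c = -224.45, which inflates PRCr by exactly 2020 for any covariates and
#' yields implausible predicted creatinine; the `"as_printed"` variant of
#' [predict_tanaka()] makes that value selectable for audit.
#'
#' @param scale,exponent power-law parameters (21.98, 0.392).
#' @param prcr_age,prcr_weight,prcr_height_cm,prcr_const PRCr coefficients.
#' @return an object of class `tanaka_coefficients`.
#' @export
tanaka_coefficients <- function(scale = 21.98,
                                exponent = 0.392,
                                prcr_age = -2.04,
                                prcr_weight = 14.89,
                                prcr_height_cm = 16.14,
                                prcr_const = -2244.45) {
  if (scale <= 0 || exponent <= 0 || exponent >= 1) {
    stopf("tanaka coefficients require scale > 0 and exponent in (0, 1)")
  }
  structure(
    list(
      scale = scale, exponent = exponent, prcr_age = prcr_age,
      prcr_weight = prcr_weight, prcr_height_cm = prcr_height_cm,
      prcr_const = prcr_const
    ),
    class = "tanaka_coefficients"
  )
}

#' Predict 24-h sodium with the Tanaka equation
#'
#' Unit contract: the cohort stores spot sodium in mg/L and height in
#' metres; both conversions happen explicitly at this call boundary
#' (mg/L / 23 -> mmol/L; m x 100 -> cm). Output is mmol/day — convert with
#' [convert_sodium()] if mg/day is needed.
#'
#' @param records a cohort data frame.
#' @param coefficients a [tanaka_coefficients()] object.
#' @param variant `"canonical"` (PRCr constant -2244.45, default) or
#'   `"as_printed"` (-224.45).
#' @return numeric vector of predicted 24-h sodium, mmol/day. Records with
#'   non-positive PRCr yield a domain error: the power-law base would be
#'   negative.
#' @export
predict_tanaka <- function(records, coefficients = tanaka_coefficients(),
                           variant = c("canonical", "as_printed")) {
  variant <- match.arg(variant)
  cf <- coefficients
  if (variant == "as_printed") cf$prcr_const <- cf$prcr_const + 2020
  spot_na_mmol <- records$spot_na_mg_l / NA_MG_PER_MMOL
  spot_cr <- records$spot_cr_mg_dl
  if (any(spot_cr == 0, na.rm = TRUE)) {
    stopf("predict_tanaka: spot creatinine of 0 mg/dL gives division by zero")
  }
  prcr <- cf$prcr_age * records$age_y + cf$prcr_weight * records$weight_kg +
    cf$prcr_height_cm * (records$height_m * 100) + cf$prcr_const
  base <- spot_na_mmol / (spot_cr * 10) * prcr
  bad <- !is.na(base) & base < 0
  if (any(bad)) {
    stopf(
      "predict_tanaka: negative base for fractional power in %d record(s) (PRCr <= 0 with positive spot sodium); the power-law model is undefined there",
      sum(bad)
    )
  }
  cf$scale * base^cf$exponent
}

#' Coefficients of the INTERSALT equation (no potassium correction, sex-specific)
#'
#' Sex-specific linear estimators of 24-h sodium (mmol/day) from spot
#' concentrations (all mmol/L), body-mass index and age; the female
#' equation carries an additional age-squared term.
#'
#' @param male,female named numeric vectors with elements
#'   `constant, spot_na, spot_cr, spot_k, bmi, age, age2` (spot
#'   concentrations mmol/L, BMI kg/m2, age years).
#' @return an object of class `intersalt_coefficients`.
#' @export
intersalt_coefficients <- function(male = c(
                                     constant = 25.46, spot_na = 0.46,
                                     spot_cr = -2.75, spot_k = -0.13,
                                     bmi = 4.10, age = 0.26, age2 = 0
                                   ),
                                   female = c(
                                     constant = 5.07, spot_na = 0.34,
                                     spot_cr = -2.16, spot_k = -0.09,
                                     bmi = 2.39, age = 2.35, age2 = -0.03
                                   )) {
  need <- c("constant", "spot_na", "spot_cr", "spot_k", "bmi", "age", "age2")
  for (set in list(male, female)) {
    if (!all(need %in% names(set))) {
      stopf("intersalt coefficient sets need elements: %s", paste(need, collapse = ", "))
    }
  }
  structure(list(male = male, female = female), class = "intersalt_coefficients")
}

#' Predict 24-h sodium with the INTERSALT equation
#'
#' Unit contract: the cohort stores spot sodium in mg/L and spot
#' creatinine in mg/dL; both are converted to mmol/L at this boundary
#' (mg/L / 23; mg/dL x 10/113.12). BMI is computed as weight/height^2
#' (kg/m2). Output is mmol/day.
#'
#' @param records a cohort data frame.
#' @param coefficients an [intersalt_coefficients()] object.
#' @return numeric vector of predicted 24-h sodium, mmol/day.
#' @export
predict_intersalt <- function(records, coefficients = intersalt_coefficients()) {
  if (any(is.na(records$weight_kg) | is.na(records$height_m))) {
    stopf("predict_intersalt: weight and height are required to compute BMI")
  }
  spot_na <- records$spot_na_mg_l / NA_MG_PER_MMOL
  spot_cr <- convert_creatinine(records$spot_cr_mg_dl, "mg_dl", "mmol_l")
  spot_k <- records$spot_k_mmol_l
  bmi <- records$weight_kg / records$height_m^2
  age <- records$age_y
  eval_set <- function(cf) {
    cf[["constant"]] + cf[["spot_na"]] * spot_na + cf[["spot_cr"]] * spot_cr +
      cf[["spot_k"]] * spot_k + cf[["bmi"]] * bmi + cf[["age"]] * age +
      cf[["age2"]] * age^2
  }
  ifelse(records$sex == "M",
    eval_set(coefficients$male),
    eval_set(coefficients$female)
  )
}

#' Standard estimator set for equation comparison
#'
#' Packages the three estimators as closures over their coefficient
#' objects, each returning predictions in mg/day (the Tanaka and INTERSALT
#' mmol/day outputs are converted explicitly), ready for
#' [compare_equations()].
#'
#' @param spot24 a [spot24_coefficients()] object (defaults to the
#'   published Malaysian equation).
#' @param tanaka_variant passed to [predict_tanaka()].
#' @return named list of functions `cohort -> mg/day predictions`.
#' @export
standard_estimators <- function(spot24 = spot24_coefficients(),
                                tanaka_variant = "canonical") {
  list(
    spot24 = function(records) predict_spot24(records, spot24),
    tanaka = function(records) {
      convert_sodium(
        predict_tanaka(records, variant = tanaka_variant),
        "mmol_day", "mg_day"
      )
    },
    intersalt = function(records) {
      convert_sodium(predict_intersalt(records), "mmol_day", "mg_day")
    }
  )
}
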
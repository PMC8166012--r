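#' Bland-Altman agreement between predicted and measured values
#'
#' Differences are taken as predicted minus measured, so a positive mean
#' bias means over-estimation. With d_i the paired differences:
#' mean bias = mean(d); SD of differences = sample SD (n - 1); limits of
#' agreement = bias +/- k SD; 95% CI of the bias = bias +/- k SD/sqrt(n).
#' The multiplier k is 1.96 under the default `ci = "z"` convention
#' (matching the back-calculated half-widths of published
#' spot-urine-equation agreement tables); `ci = "t"` uses the t quantile
#' with n - 1 df instead.
#'
#' Internal identities (hold to numerical precision, any input):
#' (loa_low + loa_high)/2 = mean_bias; loa_high - loa_low = 2 k sd_diff.
#'
#' @param predicted,measured equal-length numeric vectors, n >= 2.
#' @param ci `"z"` (multiplier 1.96, default) or `"t"`.
#' @return an object of class `agreement_result`: list with `n`,
#'   `mean_bias`, `bias_ci_low`, `bias_ci_high`, `loa_low`, `loa_high`,
#'   `sd_diff`, `p_value` (two-sided test of mean difference 0, same
#'   convention as `ci`), `multiplier`.
#' @examples
#' bland_altman(c(1, 3, 7), c(3, 3, 5)) # differences -2, 0, 2
#' @export
bland_altman <- function(predicted, measured, ci = c("z", "t")) {
  ci <- match.arg(ci)
  if (length(predicted) != length(measured)) {
    stopf("bland_altman: predicted and measured must have equal length")
  }
  keep <- !(is.na(predicted) | is.na(measured))
  d <- predicted[keep] - measured[keep]
  n <- length(d)
  if (n < 2) stopf("bland_altman: need at least 2 complete pairs")
  bias <- mean(d)
  sd_d <- stats::sd(d)
  k <- if (ci == "z") 1.96 else stats::qt(0.975, df = n - 1)
  se <- sd_d / sqrt(n)
  stat <- if (se == 0) 0 else bias / se
  p <- if (ci == "z") {
    2 * stats::pnorm(-abs(stat))
  } else {
    2 * stats::pt(-abs(stat), df = n - 1)
  }
  structure(
    list(
      n = n,
      mean_bias = bias,
      bias_ci_low = bias - k * se,
      bias_ci_high = bias + k * se,
      loa_low = bias - k * sd_d,
      loa_high = bias + k * sd_d,
      sd_diff = sd_d,
      p_value = p,
      multiplier = k
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (predicted - measured), n = %d\n  mean bias %.2f (95%% CI %.2f, %.2f)\n  limits of agreement %.2f to %.2f (SD of differences %.2f)\n",
    x$n, x$mean_bias, x$bias_ci_low, x$bias_ci_high,
    x$loa_low, x$loa_high, x$sd_diff
  ))
  invisible(x)
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation; the p-value comes from
#' t = r sqrt((n - 2)/(1 - r^2)) on n - 2 df (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors, n >= 3, each with nonzero variance.
#' @return list with `r`, `p_value`, `n` (class `correlation_result`).
#' @export
pearson_r <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stopf("pearson_r: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("pearson_r: zero variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x)),
    class = "correlation_result"
  )
}

#' Compare estimators against measured 24-h sodium
#'
#' Runs each estimator over the screened cohort, converts nothing (each
#' estimator must already return mg/day — see [standard_estimators()]),
#' and reports Bland-Altman agreement plus Pearson correlation against the
#' measured outcome. Records on which an estimator fails (error or
#' non-finite prediction) are skipped for that estimator with a logged
#' reason and the estimator's n is reduced accordingly. Rows are ordered
#' by increasing absolute mean bias, so the best-agreeing equation is
#' first; the ordering is deterministic for a fixed cohort.
#'
#' @param records screened cohort data frame with measured `na24_mg`.
#' @param estimators named list of functions `cohort -> mg/day
#'   predictions` (default: the three standard equations).
#' @param ci passed to [bland_altman()].
#' @return a data frame with one row per estimator: `equation, n,
#'   mean_bias, ci_low, ci_high, loa_low, loa_high, sd_diff, pearson_r, p`;
#'   attribute `"skipped"` holds a data frame of skipped record ids and
#'   reasons.
#' @export
compare_equations <- function(records, estimators = standard_estimators(),
                              ci = "z") {
  if (is.null(names(estimators)) || any(names(estimators) == "")) {
    stopf("estimators must be a named list")
  }
  skipped <- list()
  rows <- lapply(names(estimators), function(name) {
    f <- estimators[[name]]
    pred <- tryCatch(f(records), error = function(e) NULL)
    if (is.null(pred)) {
      # whole-cohort evaluation failed: retry record-by-record so one bad
      # record does not discard the estimator
      pred <- vapply(seq_len(nrow(records)), function(i) {
        tryCatch(
          as.numeric(f(records[i, , drop = FALSE])),
          error = function(e) NA_real_
        )
      }, numeric(1))
    }
    ok <- is.finite(pred) & is.finite(records$na24_mg)
    if (any(!ok)) {
      skipped[[name]] <<- data.frame(
        equation = name, id = records$id[!ok],
        reason = "estimator failed or non-finite prediction",
        stringsAsFactors = FALSE
      )
    }
    ba <- bland_altman(pred[ok], records$na24_mg[ok], ci = ci)
    pr <- pearson_r(pred[ok], records$na24_mg[ok])
    data.frame(
      equation = name, n = ba$n, mean_bias = ba$mean_bias,
      ci_low = ba$bias_ci_low, ci_high = ba$bias_ci_high,
      loa_low = ba$loa_low, loa_high = ba$loa_high, sd_diff = ba$sd_diff,
      pearson_r = pr$r, p = pr$p_value, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$mean_bias)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) {
    do.call(rbind, unname(skipped))
  } else {
    data.frame(
      equation = character(0), id = character(0), reason = character(0),
      stringsAsFactors = FALSE
    )
  }
  out
}
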
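#' Random split of a cohort into development subgroups
#'
#' Seeded, reproducible partition of the records into two disjoint,
#' exhaustive subgroups. At the default ratio 0.5 the sizes differ by at
#' most one.
#'
#' @param records a cohort data frame with at least 2 rows.
#' @param seed integer seed.
#' @param ratio fraction assigned to group 1 (default 0.5).
#' @return list with elements `group1` and `group2`.
#' @export
split_cohort <- function(records, seed = 1L, ratio = 0.5) {
  n <- nrow(records)
  if (n < 2) stopf("split_cohort needs at least 2 records")
  if (ratio <= 0 || ratio >= 1) stopf("ratio must be in (0, 1)")
  n1 <- round(n * ratio)
  n1 <- max(1L, min(n - 1L, n1))
  idx <- with_seed(seed, sample.int(n, n1))
  list(
    group1 = records[sort(idx), , drop = FALSE],
    group2 = records[setdiff(seq_len(n), sort(idx)), , drop = FALSE]
  )
}

#' Ordinary least-squares fit with standardized coefficients
#'
#' Least-squares via QR decomposition (through [stats::lm()]), reporting
#' unstandardized coefficients with standard errors and two-sided
#' p-values (t distribution, n - p - 1 df), standardized coefficients
#' (beta_j = b_j SD(x_j)/SD(y)), the multiple correlation R, R-squared,
#' and the residual SD.
#'
#' @param y numeric outcome vector.
#' @param X data frame of predictors (no constant columns; a rank-deficient
#'   design is an error naming the collinear columns).
#' @return an object of class `regression_fit`: list with `coefficients`
#'   (data frame `term, b, se, p`, intercept first), `beta` (named vector
#'   of standardized coefficients), `intercept`, `r`, `r_squared`,
#'   `residual_sd`, `n`, `terms`.
#' @export
fit_ols <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stopf("fit_ols: outcome and predictors have different lengths")
  if (n <= p + 1) stopf("fit_ols: need n > p + 1 (n = %d, p = %d)", n, p)
  dat <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stopf("fit_ols: rank-deficient design; collinear columns: %s", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  b <- ct[-1, 1]
  sd_y <- stats::sd(y)
  sd_x <- vapply(X, stats::sd, numeric(1))
  if (any(sd_x == 0)) {
    stopf(
      "fit_ols: constant predictor column(s): %s",
      paste(names(sd_x)[sd_x == 0], collapse = ", ")
    )
  }
  structure(
    list(
      coefficients = data.frame(
        term = c("(intercept)", colnames(X)),
        b = unname(ct[, 1]),
        se = unname(ct[, 2]),
        p = unname(ct[, 4]),
        stringsAsFactors = FALSE
      ),
      beta = stats::setNames(b * sd_x / sd_y, colnames(X)),
      intercept = unname(ct[1, 1]),
      r = sqrt(sm$r.squared),
      r_squared = sm$r.squared,
      residual_sd = sm$sigma,
      n = n,
      terms = colnames(X)
    ),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "Linear fit: n = %d, R = %.3f, R^2 = %.3f, residual SD = %.1f\n",
    x$n, x$r, x$r_squared, x$residual_sd
  ))
  tab <- x$coefficients
  tab$beta <- c(NA, unname(x$beta))
  print(format(tab, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Stepwise predictor selection by p-value
#'
#' Classic bidirectional stepwise regression: at each cycle the candidate
#' with the smallest entry p-value below `p_enter` is added, then any
#' retained predictor whose p-value exceeds `p_remove` is dropped (worst
#' first). Termination is guaranteed by requiring `p_remove > p_enter`
#' (a variable cannot oscillate in and out) plus an iteration cap.
#' Selection is deterministic given the data. If no candidate reaches
#' `p_enter`, an intercept-only fit is returned with a warning.
#'
#' @param y numeric outcome vector.
#' @param candidates data frame of candidate predictors. The conventional
#'   candidate set for spot-urine equation development is produced by
#'   [design_columns()] with
#'   `c("male", "weight_kg", "height_m", "age2", "spot_na_mg_l",
#'   "spot_cr_mg_dl", "spot_k_mmol_l")`.
#' @param p_enter entry threshold (default 0.05, the "5% significance"
#'   convention).
#' @param p_remove removal threshold (default 0.10; must exceed `p_enter`).
#' @return a `regression_fit` on the selected predictors, or an
#'   intercept-only fit (class `regression_fit`, empty `terms`) when
#'   nothing enters.
#' @export
stepwise_select <- function(y, candidates, p_enter = 0.05, p_remove = 0.10) {
  candidates <- as.data.frame(candidates)
  if (p_enter >= 1) {
    # degenerate threshold: everything enters and nothing can be removed
    return(fit_ols(y, candidates))
  }
  if (p_remove <= p_enter) {
    stopf("stepwise_select: p_remove must be greater than p_enter")
  }
  selected <- character(0)
  pool <- colnames(candidates)
  entry_p <- function(sel, cand) {
    fit <- fit_ols(y, candidates[, c(sel, cand), drop = FALSE])
    fit$coefficients$p[match(cand, fit$coefficients$term)]
  }
  for (iter in seq_len(2 * length(pool) + 2)) {
    changed <- FALSE
    remaining <- setdiff(pool, selected)
    if (length(remaining) > 0) {
      ps <- vapply(remaining, function(cand) entry_p(selected, cand), numeric(1))
      if (min(ps) < p_enter) {
        selected <- c(selected, remaining[which.min(ps)])
        changed <- TRUE
      }
    }
    if (length(selected) > 0) {
      fit <- fit_ols(y, candidates[, selected, drop = FALSE])
      ps <- stats::setNames(
        fit$coefficients$p[-1],
        fit$coefficients$term[-1]
      )
      while (length(ps) > 0 && max(ps) > p_remove) {
        worst <- names(ps)[which.max(ps)]
        selected <- setdiff(selected, worst)
        changed <- TRUE
        if (length(selected) == 0) break
        fit <- fit_ols(y, candidates[, selected, drop = FALSE])
        ps <- stats::setNames(fit$coefficients$p[-1], fit$coefficients$term[-1])
      }
    }
    if (!changed) break
  }
  if (length(selected) == 0) {
    warnf("stepwise_select: no candidate reached p_enter = %g; returning intercept-only fit", p_enter)
    return(intercept_only_fit(y))
  }
  fit_ols(y, candidates[, selected, drop = FALSE])
}

intercept_only_fit <- function(y) {
  n <- length(y)
  m <- mean(y)
  s <- stats::sd(y)
  structure(
    list(
      coefficients = data.frame(
        term = "(intercept)", b = m, se = s / sqrt(n),
        p = 2 * stats::pt(-abs(m / (s / sqrt(n))), df = n - 1),
        stringsAsFactors = FALSE
      ),
      beta = stats::setNames(numeric(0), character(0)),
      intercept = m, r = 0, r_squared = 0,
      residual_sd = s, n = n, terms = character(0)
    ),
    class = "regression_fit"
  )
}

#' Double cross-validation of a prediction equation
#'
#' Fits the same predictor set by OLS in each of two subgroups and
#' evaluates each group's standardized beta weights on both groups via
#' composite z-scores: for target group h and weight source g, each
#' subject's composite is \eqn{\sum_j \beta_j^{(g)} z_j^{(h)}}, and
#' R\[h,g\] is the Pearson correlation between composite and outcome in
#' group h. With own weights (g = h) this equals the multiple correlation
#' of the fit. Stability is summarized by the shrinkage statistics
#' `shrinkage1 = R11^2 - R12^2` and `shrinkage2 = R22^2 - R21^2` (own
#' minus cross-applied squared correlation within each group); values near
#' zero indicate a replicable equation.
#'
#' @param group1,group2 cohort data frames (nonempty, same columns).
#' @param predictors character vector of design columns (see
#'   [design_columns()]) present in both groups.
#' @param outcome outcome column name (default `"na24_mg"`).
#' @param standardize `"own"` (default): each group z-scores predictors by
#'   its own mean/SD; `"cross"`: the weight-source group's mean/SD are
#'   used instead.
#' @return an object of class `cv_result`: list with `R11, R12, R22, R21`,
#'   `shrinkage1`, `shrinkage2`, `fit1`, `fit2`.
#' @export
double_cross_validate <- function(group1, group2, predictors,
                                  outcome = "na24_mg",
                                  standardize = c("own", "cross")) {
  standardize <- match.arg(standardize)
  if (nrow(group1) == 0 || nrow(group2) == 0) {
    stopf("double_cross_validate: both groups must be nonempty")
  }
  X1 <- design_columns(group1, predictors)
  X2 <- design_columns(group2, predictors)
  y1 <- group1[[outcome]]
  y2 <- group2[[outcome]]
  fit1 <- fit_ols(y1, X1)
  fit2 <- fit_ols(y2, X2)

  composite <- function(X_target, fit_source, X_source) {
    ref <- if (standardize == "own") X_target else X_source
    mu <- vapply(ref, mean, numeric(1))
    sdv <- vapply(ref, stats::sd, numeric(1))
    Z <- sweep(sweep(as.matrix(X_target), 2, mu), 2, sdv, "/")
    as.numeric(Z %*% fit_source$beta[predictors])
  }

  R11 <- stats::cor(composite(X1, fit1, X1), y1)
  R12 <- stats::cor(composite(X1, fit2, X2), y1)
  R22 <- stats::cor(composite(X2, fit2, X2), y2)
  R21 <- stats::cor(composite(X2, fit1, X1), y2)
  structure(
    list(
      R11 = R11, R12 = R12, R22 = R22, R21 = R21,
      shrinkage1 = R11^2 - R12^2,
      shrinkage2 = R22^2 - R21^2,
      fit1 = fit1, fit2 = fit2
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "Double cross-validation:\n  R[1,1] = %.3f  R[1,2] = %.3f  shrinkage1 = % .4f\n  R[2,2] = %.3f  R[2,1] = %.3f  shrinkage2 = % .4f\n",
    x$R11, x$R12, x$shrinkage1, x$R22, x$R21, x$shrinkage2
  ))
  invisible(x)
}

#' Final pooled equation after a shrinkage check
#'
#' Pools all records and fits the given predictors by OLS, but only after
#' verifying equation stability: both double-cross-validation shrinkage
#' statistics (computed on a seeded 50:50 split, or supplied via `cv`)
#' must be below `shrinkage_threshold` in absolute value. An unstable
#' equation is refused with a diagnostic unless `force = TRUE`.
#'
#' @param records screened cohort data frame.
#' @param predictors character vector of design columns.
#' @param outcome outcome column name.
#' @param shrinkage_threshold maximum tolerated `|shrinkage|` (default
#'   0.05).
#' @param cv an existing [double_cross_validate()] result to reuse;
#'   if `NULL`, one is computed from a fresh split with `seed`.
#' @param seed seed for the internal split when `cv` is `NULL`.
#' @param force bypass the shrinkage refusal (diagnostic still attached).
#' @return list with `fit` (the pooled `regression_fit`), `equation` (a
#'   [spot24_coefficients()] usable by [predict_spot24()]) and `cv`.
#' @export
finalize_equation <- function(records, predictors, outcome = "na24_mg",
                              shrinkage_threshold = 0.05, cv = NULL,
                              seed = 1L, force = FALSE) {
  if (is.null(cv)) {
    halves <- split_cohort(records, seed = seed)
    cv <- double_cross_validate(halves$group1, halves$group2, predictors, outcome)
  }
  worst <- max(abs(cv$shrinkage1), abs(cv$shrinkage2))
  if (worst > shrinkage_threshold && !force) {
    stopf(
      "finalize_equation: shrinkage %.4f exceeds threshold %.3f; the equation does not replicate across subgroups (shrinkage1 = %.4f, shrinkage2 = %.4f). Use force = TRUE to pool anyway.",
      worst, shrinkage_threshold, cv$shrinkage1, cv$shrinkage2
    )
  }
  fit <- fit_ols(records[[outcome]], design_columns(records, predictors))
  b <- fit$coefficients$b[-1]
  names(b) <- fit$coefficients$term[-1]
  list(
    fit = fit,
    equation = spot24_coefficients(intercept = fit$intercept, terms = b),
    cv = cv
  )
}

#' Minimum sample size for detecting a correlation
#'
#' Fisher-z method for the sample size needed to detect a population
#' correlation `target_r` at two-sided level `alpha` with the given power:
#' \eqn{C = \tfrac{1}{2}\ln\frac{1+r}{1-r}}, and
#' \eqn{n = \lfloor ((z_{1-\alpha/2} + z_{power}) / C)^2 \rfloor + 3},
#' with the squared term truncated to an integer before adding 3 (the
#' convention of the standard biostatistics calculators, which this
#' function reproduces exactly: r = 0.15 at alpha 0.05 / power 0.80 gives
#' n = 346 per group).
#'
#' @param target_r assumed population correlation, 0 < |r| < 1.
#' @param alpha two-sided type-I error (default 0.05).
#' @param power 1 - beta (default 0.80).
#' @return required sample size (integer).
#' @export
sample_size_correlation <- function(target_r, alpha = 0.05, power = 0.80) {
  if (!is.numeric(target_r) || length(target_r) != 1 || target_r == 0 ||
    abs(target_r) >= 1) {
    stopf("target_r must satisfy 0 < |r| < 1 (r = 0 needs unbounded n)")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stopf("alpha and power must lie in (0, 1)")
  }
  C <- 0.5 * log((1 + abs(target_r)) / (1 - abs(target_r)))
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(trunc((z / C)^2) + 3)
}
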
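#' Completeness criteria for 24-h urine collections
#'
#' A complete 24-h collection is defined by four rules, evaluated in fixed
#' order: (1) total volume >= `min_volume` mL, (2) recorded collection
#' timing >= `min_duration` h, (3) no missing void, (4) a sex-specific
#' 24-h creatinine rule (thresholds in mmol/day; record creatinine in
#' g/day is converted via molar mass 113.12 g/mol).
#'
#' The creatinine clause is direction-configurable. Standard practice
#' treats *low* creatinine as the signature of an incomplete collection,
#' so the default `cr_rule_direction = "exclude_below"` removes records
#' with creatinine below the sex threshold. Some survey protocols print
#' the clause the other way around ("creatinine < threshold" as a
#' completeness condition); `"exclude_above"` reproduces that literal
#' reading for audit.
#'
#' @param min_volume minimum 24-h volume, mL (default 500).
#' @param min_duration minimum recorded duration, hours (default 20).
#' @param require_no_missing_void flag; if `TRUE` (default) any reported
#'   missing void fails the collection.
#' @param cr_threshold_male,cr_threshold_female creatinine thresholds,
#'   mmol/day (defaults 6 and 4).
#' @param cr_rule_direction `"exclude_below"` (default) or `"exclude_above"`.
#' @return an object of class `completeness_criteria`.
#' @export
completeness_criteria <- function(min_volume = 500,
                                  min_duration = 20,
                                  require_no_missing_void = TRUE,
                                  cr_threshold_male = 6,
                                  cr_threshold_female = 4,
                                  cr_rule_direction = c("exclude_below", "exclude_above")) {
  for (v in c(min_volume, min_duration, cr_threshold_male, cr_threshold_female)) {
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      stopf("completeness thresholds must be single non-negative numbers")
    }
  }
  structure(
    list(
      min_volume = min_volume, min_duration = min_duration,
      require_no_missing_void = isTRUE(require_no_missing_void),
      cr_threshold_male = cr_threshold_male,
      cr_threshold_female = cr_threshold_female,
      cr_rule_direction = match.arg(cr_rule_direction)
    ),
    class = "completeness_criteria"
  )
}

ELIGIBILITY_LABELS <- c(
  "age_lt_18", "pregnant", "fasting", "kidney_disease", "unable_collect_24h"
)

#' Participant eligibility check
#'
#' Eligible participants are adults (age >= 18) who are not pregnant, not
#' fasting during the study, not diagnosed with kidney disease, and able
#' to provide a 24-h collection (volume and duration recorded). Returns
#' `character(0)` on pass, otherwise the stable failure labels
#' `age_lt_18, pregnant, fasting, kidney_disease, unable_collect_24h`, in
#' that fixed order; all failures are reported, not just the first.
#'
#' @param record a single-row cohort data frame.
#' @return character vector of failure labels (empty on pass).
#' @export
check_eligibility <- function(record) {
  if (nrow(record) != 1) stopf("check_eligibility expects a single record")
  for (f in c("age_y", "pregnant", "fasting", "kidney_disease")) {
    if (is.null(record[[f]]) || is.na(record[[f]])) {
      stopf("eligibility check: field '%s' is missing", f)
    }
  }
  fails <- character(0)
  if (record$age_y < 18) fails <- c(fails, "age_lt_18")
  if (record$pregnant) fails <- c(fails, "pregnant")
  if (record$fasting) fails <- c(fails, "fasting")
  if (record$kidney_disease) fails <- c(fails, "kidney_disease")
  if (is.na(record$vol24_ml) || is.na(record$dur_h)) {
    fails <- c(fails, "unable_collect_24h")
  }
  fails
}

#' Completeness assessment of a 24-h collection
#'
#' Evaluates all four completeness rules (see [completeness_criteria()])
#' and returns the failures in rule order: `volume_lt_min`,
#' `duration_lt_min`, `missing_void`, then `cr_below_threshold` or
#' `cr_above_threshold` depending on the configured direction.
#'
#' @param record a single-row cohort data frame with populated 24-h fields.
#' @param criteria a [completeness_criteria()] object.
#' @return character vector of failure labels (empty on pass).
#' @export
assess_completeness <- function(record, criteria = completeness_criteria()) {
  if (nrow(record) != 1) stopf("assess_completeness expects a single record")
  if (is.na(record$vol24_ml) || record$vol24_ml < 0) {
    stopf("completeness check: vol24_ml missing or negative")
  }
  if (is.na(record$dur_h) || record$dur_h < 0) {
    stopf("completeness check: dur_h missing or negative")
  }
  fails <- character(0)
  if (record$vol24_ml < criteria$min_volume) fails <- c(fails, "volume_lt_min")
  if (record$dur_h < criteria$min_duration) fails <- c(fails, "duration_lt_min")
  if (criteria$require_no_missing_void && isTRUE(record$missing_void)) {
    fails <- c(fails, "missing_void")
  }
  cr_mmol <- convert_creatinine(record$cr24_g, "g_day", "mmol_day")
  threshold <- if (record$sex == "M") criteria$cr_threshold_male else criteria$cr_threshold_female
  if (criteria$cr_rule_direction == "exclude_below") {
    if (cr_mmol < threshold) fails <- c(fails, "cr_below_threshold")
  } else {
    if (cr_mmol >= threshold) fails <- c(fails, "cr_above_threshold")
  }
  fails
}

#' Screen a cohort for eligibility, collection completeness, and spot availability
#'
#' Applies [check_eligibility()] and [assess_completeness()] to every
#' record, additionally requiring a usable spot urine panel (present,
#' non-negative spot sodium — no other quality criterion is applied to the
#' spot specimen). Kept records preserve input order; excluded records
#' carry the ordered list of every rule they failed. Screening is pure:
#' the same input always yields the same partition, and
#' `nrow(kept) + length(unique(excluded$id)) == nrow(records)`.
#'
#' @param records a cohort data frame.
#' @param criteria a [completeness_criteria()] object.
#' @return an object of class `screening_result`: a list with `kept` (data
#'   frame of retained records), `excluded` (long-format data frame with
#'   columns `id, rule, observed, threshold`, one row per failed rule), and
#'   `criteria`.
#' @export
screen_cohort <- function(records, criteria = completeness_criteria()) {
  logs <- vector("list", nrow(records))
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    fails <- check_eligibility(rec)
    if (!("unable_collect_24h" %in% fails)) {
      fails <- c(fails, assess_completeness(rec, criteria))
    }
    if (is.na(rec$spot_na_mg_l) || rec$spot_na_mg_l < 0) {
      fails <- c(fails, "spot_missing")
    }
    keep[i] <- length(fails) == 0
    if (length(fails) > 0) {
      logs[[i]] <- data.frame(
        id = rec$id,
        rule = fails,
        observed = vapply(fails, rule_observed, numeric(1), record = rec),
        threshold = vapply(fails, rule_threshold, numeric(1),
          record = rec, criteria = criteria
        ),
        stringsAsFactors = FALSE
      )
    }
  }
  excluded <- do.call(rbind, logs[!vapply(logs, is.null, logical(1))])
  if (is.null(excluded)) {
    excluded <- data.frame(
      id = character(0), rule = character(0),
      observed = numeric(0), threshold = numeric(0), stringsAsFactors = FALSE
    )
  }
  structure(
    list(kept = records[keep, , drop = FALSE], excluded = excluded, criteria = criteria),
    class = "screening_result"
  )
}

rule_observed <- function(rule, record) {
  switch(rule,
    age_lt_18 = record$age_y,
    pregnant = as.numeric(record$pregnant),
    fasting = as.numeric(record$fasting),
    kidney_disease = as.numeric(record$kidney_disease),
    unable_collect_24h = NA_real_,
    volume_lt_min = record$vol24_ml,
    duration_lt_min = record$dur_h,
    missing_void = as.numeric(record$missing_void),
    cr_below_threshold = ,
    cr_above_threshold = convert_creatinine(record$cr24_g, "g_day", "mmol_day"),
    spot_missing = if (is.na(record$spot_na_mg_l)) NA_real_ else record$spot_na_mg_l,
    NA_real_
  )
}

rule_threshold <- function(rule, record, criteria) {
  switch(rule,
    age_lt_18 = 18,
    volume_lt_min = criteria$min_volume,
    duration_lt_min = criteria$min_duration,
    cr_below_threshold = ,
    cr_above_threshold = if (record$sex == "M") {
      criteria$cr_threshold_male
    } else {
      criteria$cr_threshold_female
    },
    NA_real_
  )
}

#' @export
print.screening_result <- function(x, ...) {
  n_in <- nrow(x$kept) + length(unique(x$excluded$id))
  cat(sprintf(
    "Screening result: %d of %d records kept (%d excluded)\n",
    nrow(x$kept), n_in, length(unique(x$excluded$id))
  ))
  if (nrow(x$excluded) > 0) {
    tab <- table(x$excluded$rule)
    for (r in names(tab)) cat(sprintf("  %-20s %d\n", r, tab[[r]]))
  }
  invisible(x)
}
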
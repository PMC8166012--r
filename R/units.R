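#' Unit conversions for sodium and creatinine
#'
#' Spot-urine equations in the literature mix units freely: sodium appears
#' as mg/L, mmol/L, mg/day, mmol/day and g salt (NaCl) per day; creatinine
#' as mg/dL, mmol/L, g/day and mmol/day. These converters make every change
#' of unit an explicit step with exact, documented constants, so no
#' coefficient ever has a conversion silently baked in.
#'
#' Constants: 1 mmol sodium = 23 mg; 1 mg sodium = 2.54/1000 g salt
#' (NaCl mass per unit Na mass); creatinine molar mass 113.12 g/mol.
#'
#' @param value numeric vector of amounts.
#' @param from,to unit names. For sodium one of `"mg_day"`, `"mmol_day"`,
#'   `"g_salt_day"`; for creatinine one of `"mg_dl"`, `"mmol_l"` (spot
#'   concentrations) or `"g_day"`, `"mmol_day"` (daily excretion).
#' @return numeric vector in the target unit.
#' @examples
#' convert_sodium(100, "mmol_day", "mg_day")      # 2300
#' convert_sodium(2300, "mg_day", "g_salt_day")   # 5.842
#' convert_creatinine(1.0, "g_day", "mmol_day")   # 8.84
#' @export
convert_sodium <- function(value, from, to) {
  units <- c("mg_day", "mmol_day", "g_salt_day")
  from <- match_unit(from, units, "sodium")
  to <- match_unit(to, units, "sodium")
  # hub unit: mg/day
  mg <- switch(from,
    mg_day = value,
    mmol_day = value * NA_MG_PER_MMOL,
    g_salt_day = value / SALT_G_PER_MG_NA
  )
  switch(to,
    mg_day = mg,
    mmol_day = mg / NA_MG_PER_MMOL,
    g_salt_day = mg * SALT_G_PER_MG_NA
  )
}

#' @rdname convert_sodium
#' @export
convert_creatinine <- function(value, from, to) {
  conc <- c("mg_dl", "mmol_l")
  daily <- c("g_day", "mmol_day")
  from <- match_unit(from, c(conc, daily), "creatinine")
  to <- match_unit(to, c(conc, daily), "creatinine")
  if (from == to) {
    return(value)
  }
  if ((from %in% conc) != (to %in% conc)) {
    stopf(
      "cannot convert creatinine between a concentration (%s) and a daily excretion (%s)",
      from, to
    )
  }
  if (from %in% conc) {
    # mg/dL <-> mmol/L: 1 mg/dL = 10 mg/L = 10/113.12 mmol/L
    if (from == "mg_dl") value * 10 / CREATININE_G_MOL else value * CREATININE_G_MOL / 10
  } else {
    # g/day <-> mmol/day
    if (from == "g_day") value * 1000 / CREATININE_G_MOL else value * CREATININE_G_MOL / 1000
  }
}

NA_MG_PER_MMOL <- 23
SALT_G_PER_MG_NA <- 2.54 / 1000
CREATININE_G_MOL <- 113.12

match_unit <- function(unit, choices, what) {
  if (length(unit) != 1 || !is.character(unit) || !unit %in% choices) {
    stopf(
      "unknown %s unit %s; expected one of: %s",
      what, deparse(unit), paste(choices, collapse = ", ")
    )
  }
  unit
}
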
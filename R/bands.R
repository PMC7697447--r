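#' Band constants
#'
#' Canonical band labels used throughout the package, in increasing order of
#' exposure potential.
#' @name bands
#' @keywords internal
NULL

FUGACITY_BANDS <- c("low", "medium", "high")
CONC_BANDS <- c("<1%", "1-5%", "5-25%", ">25%")
DURATION_BANDS <- c("<15 min", "15-60 min", "1-4 h", ">4 h")
GV_CLASSES <- c("enhanced", "good", "basic")  # increasing exposure
RPE_CLASSES <- c("none", "90", "95")

#' Assign the fugacity band of a substance
#'
#' Liquids are banded on vapour pressure: low below 0.5 kPa, medium from
#' 0.5 to 10 kPa (both bounds inclusive, matching the tool's published
#' "0.5-10 kPa" medium range), high above 10 kPa. Solids take their
#' user-supplied dustiness class directly; no dustiness index is computed.
#'
#' @param physical_state `"liquid"` or `"solid"` (vectorized).
#' @param vapour_pressure kPa, required for liquids.
#' @param dustiness `"low"`, `"medium"` or `"high"`, required for solids.
#' @return Character vector of bands (`"low"`, `"medium"`, `"high"`).
#' @examples
#' fugacity_band("liquid", vapour_pressure = 4)     # "medium"
#' fugacity_band("liquid", vapour_pressure = 0.5)   # boundary -> "medium"
#' fugacity_band("solid", dustiness = "high")       # "high"
#' @export
fugacity_band <- function(physical_state, vapour_pressure = NA_real_,
                          dustiness = NA_character_) {
  n <- max(length(physical_state), length(vapour_pressure), length(dustiness))
  physical_state <- rep_len(as.character(physical_state), n)
  vapour_pressure <- rep_len(vapour_pressure, n)
  dustiness <- rep_len(as.character(dustiness), n)
  bad_state <- !physical_state %in% c("liquid", "solid")
  if (any(bad_state)) {
    abort(paste0("physical_state must be 'liquid' or 'solid', got: ",
                 paste(unique(physical_state[bad_state]), collapse = ", ")))
  }
  is_liq <- physical_state == "liquid"
  if (any(is_liq & (is.na(vapour_pressure) | vapour_pressure <= 0))) {
    abort("a liquid requires a positive vapour_pressure in kPa to assign its volatility band")
  }
  if (any(!is_liq & !dustiness %in% FUGACITY_BANDS)) {
    abort("a solid requires dustiness 'low', 'medium' or 'high'")
  }
  out <- character(n)
  vp <- vapour_pressure[is_liq]
  out[is_liq] <- ifelse(vp < 0.5, "low", ifelse(vp <= 10, "medium", "high"))
  out[!is_liq] <- dustiness[!is_liq]
  out
}

#' Assign the concentration band of a mixture
#'
#' Bands the weight percentage of the substance in the product into the
#' tool's four bands. Boundary values (1, 5, 25) fall in the lower band.
#'
#' @param percent Percent w/w in (0, 100].
#' @return Character vector of bands (`"<1%"`, `"1-5%"`, `"5-25%"`, `">25%"`).
#' @examples
#' concentration_band(c(30, 3, 100))
#' @export
concentration_band <- function(percent) {
  if (!is.numeric(percent) || any(is.na(percent) | percent <= 0 | percent > 100)) {
    abort("percent must be in (0, 100]")
  }
  CONC_BANDS[findInterval(percent, c(0, 1, 5, 25), left.open = TRUE) ]
}

#' Assign the exposure-duration band
#'
#' Bands exposure duration in minutes; boundaries (15, 60, 240 min) fall in
#' the lower band.
#'
#' @param minutes Positive exposure duration in minutes.
#' @return Character vector of bands (`"<15 min"`, `"15-60 min"`, `"1-4 h"`,
#'   `">4 h"`).
#' @examples
#' duration_band(c(320, 120, 240))
#' @export
duration_band <- function(minutes) {
  if (!is.numeric(minutes) || any(is.na(minutes) | minutes <= 0)) {
    abort("duration must be a positive number of minutes")
  }
  DURATION_BANDS[findInterval(minutes, c(0, 15, 60, 240), left.open = TRUE)]
}
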
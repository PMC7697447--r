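# Molar volume of an ideal gas at 25 degC / 101.325 kPa, L/mol.
# This value reproduces published ppm <-> mg/m3 pairs for isopropanol and
# sevoflurane within rounding; the 20 degC value (24.06) does not.
MOLAR_VOLUME_L_MOL <- 24.45

#' Convert between mg/m3 and ppm
#'
#' Gas-phase concentration conversion using the ideal-gas molar volume at
#' 25 degC and 101.325 kPa (24.45 L/mol). `ppm_to_mgm3()` is the exact
#' inverse of `mgm3_to_ppm()`.
#'
#' @param x Numeric vector of concentrations (>= 0); mg/m3 for
#'   `mgm3_to_ppm()`, ppm for `ppm_to_mgm3()`.
#' @param molecular_weight Molecular weight in g/mol (> 0). Recycled against
#'   `x`.
#' @return Numeric vector of converted concentrations.
#' @examples
#' mgm3_to_ppm(59.3, 60.10)   # isopropanol, ~24.1 ppm
#' ppm_to_mgm3(0.97, 200.05)  # sevoflurane, ~7.96 mg/m3
#' @export
mgm3_to_ppm <- function(x, molecular_weight) {
  check_conc_mw(x, molecular_weight)
  x * MOLAR_VOLUME_L_MOL / molecular_weight
}

#' @rdname mgm3_to_ppm
#' @export
ppm_to_mgm3 <- function(x, molecular_weight) {
  check_conc_mw(x, molecular_weight)
  x * molecular_weight / MOLAR_VOLUME_L_MOL
}

check_conc_mw <- function(x, mw) {
  if (!is.numeric(x) || any(x < 0, na.rm = TRUE)) {
    abort("concentrations must be numeric and >= 0")
  }
  if (!is.numeric(mw) || any(!is.finite(mw) | mw <= 0)) {
    abort("molecular_weight must be a positive number (g/mol)")
  }
  invisible(TRUE)
}

#' Reconcile a concentration to target units
#'
#' Converts `x` from `from` units to `to` units ("ppm" or "mg/m3"),
#' requiring a molecular weight when an actual conversion is needed.
#'
#' @param x Numeric concentration vector.
#' @param from,to Unit strings, `"ppm"` or `"mg/m3"`.
#' @param molecular_weight g/mol; may be `NA` when `from == to`.
#' @return `x` expressed in `to` units.
#' @export
convert_units <- function(x, from, to, molecular_weight = NA_real_) {
  from <- normalize_units(from)
  to <- normalize_units(to)
  if (from == to) return(x)
  if (any(is.na(molecular_weight))) {
    abort("unit conversion between ppm and mg/m3 requires a molecular weight")
  }
  if (from == "mg/m3") mgm3_to_ppm(x, molecular_weight)
  else ppm_to_mgm3(x, molecular_weight)
}

normalize_units <- function(u) {
  u <- tolower(trimws(as.character(u)))
  u[u %in% c("mg/m^3", "mg/m3", "mg m-3", "mgm3")] <- "mg/m3"
  bad <- !u %in% c("ppm", "mg/m3")
  if (any(bad)) {
    abort(paste0("unsupported units: ", paste(unique(u[bad]), collapse = ", "),
                 " (expected 'ppm' or 'mg/m3')"))
  }
  u
}
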
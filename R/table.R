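#' Parameter tables for the exposure engine
#'
#' A `tra_table` holds everything the multiplicative engine looks up: base
#' estimates keyed by (PROC, setting, phase, fugacity band) and modifying
#' factors for concentration band, duration band, general ventilation,
#' local exhaust ventilation (keyed by PROC and setting) and respiratory
#' protective equipment. Every entry carries a provenance string so a table
#' is auditable row by row, and missing (PROC, setting, band) combinations
#' are explicit absences that raise errors, never silent defaults.
#'
#' @param base_estimates,conc_factors,dur_factors,gv_factors,lev_factors,rpe_factors
#'   Tibbles as produced by [read_tra_table()]; see the bundled CSV
#'   (`system.file("extdata", "tra_default_table.csv", package = "traworker")`)
#'   for the long-format schema.
#' @return A validated object of class `tra_table`.
#' @export
tra_table <- function(base_estimates, conc_factors, dur_factors,
                      gv_factors, lev_factors, rpe_factors) {
  x <- structure(
    list(base_estimates = tibble::as_tibble(base_estimates),
         conc_factors = tibble::as_tibble(conc_factors),
         dur_factors = tibble::as_tibble(dur_factors),
         gv_factors = tibble::as_tibble(gv_factors),
         lev_factors = tibble::as_tibble(lev_factors),
         rpe_factors = tibble::as_tibble(rpe_factors)),
    class = "tra_table")
  validate_tra_table(x)
}

#' Validate a parameter table
#'
#' Rejects, at load time, any modifying factor outside (0, 1], any
#' non-positive base estimate, unknown band labels, and duplicate keys.
#'
#' @param x A `tra_table`.
#' @return `x`, invisibly usable, after validation; errors are itemized.
#' @export
validate_tra_table <- function(x) {
  problems <- character()
  be <- x$base_estimates
  need <- c("proc", "setting", "phase", "band", "value", "units", "provenance")
  miss <- setdiff(need, names(be))
  if (length(miss)) {
    problems <- c(problems, paste0("base estimates missing columns: ",
                                   paste(miss, collapse = ", ")))
  } else {
    if (any(!is.finite(be$value) | be$value <= 0)) {
      problems <- c(problems, "base estimates must all be > 0")
    }
    if (any(!be$band %in% FUGACITY_BANDS)) problems <- c(problems, "unknown fugacity band in base estimates")
    if (any(!be$setting %in% c("industrial", "professional"))) problems <- c(problems, "unknown setting in base estimates")
    if (any(!be$phase %in% c("vapour", "dust"))) problems <- c(problems, "unknown phase in base estimates")
    if (any(be$proc < 1 | be$proc > 28)) problems <- c(problems, "PROC outside 1-28 in base estimates")
    if (anyDuplicated(be[c("proc", "setting", "phase", "band")])) {
      problems <- c(problems, "duplicate (proc, setting, phase, band) base-estimate keys")
    }
  }
  check_factors <- function(tab, what, keys) {
    if (is.null(tab) || !nrow(tab)) return(paste0("empty ", what, " factor table"))
    out <- character()
    if (any(!is.finite(tab$value) | tab$value <= 0 | tab$value > 1)) {
      out <- c(out, paste0(what, " factors must lie in (0, 1]"))
    }
    if (anyDuplicated(tab[keys])) out <- c(out, paste0("duplicate ", what, " factor keys"))
    out
  }
  problems <- c(problems,
                check_factors(x$conc_factors, "concentration", "class"),
                check_factors(x$dur_factors, "duration", "class"),
                check_factors(x$gv_factors, "ventilation", c("setting", "location", "class")),
                check_factors(x$lev_factors, "LEV", c("proc", "setting")),
                check_factors(x$rpe_factors, "RPE", "class"))
  if (length(problems)) {
    abort(paste0("invalid parameter table:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  x
}

#' @export
print.tra_table <- function(x, ...) {
  cat("<tra_table>\n")
  cat("  base estimates:", nrow(x$base_estimates), "rows (",
      length(unique(x$base_estimates$proc)), "PROCs )\n")
  cat("  factors: concentration", nrow(x$conc_factors),
      "| duration", nrow(x$dur_factors),
      "| ventilation", nrow(x$gv_factors),
      "| LEV", nrow(x$lev_factors),
      "| RPE", nrow(x$rpe_factors), "\n")
  invisible(x)
}

table_env <- new.env(parent = emptyenv())

#' The bundled default parameter table
#'
#' Loads (and caches) the parameter table shipped with the package. Two base
#' estimates are fixed by back-solving published end-to-end TRA results
#' (PROC 10 / industrial / vapour / medium and PROC 2 / professional /
#' vapour / high, both 50 ppm); the modifying-factor tables carry the
#' documented TRA v3 band factors; all other base estimates are
#' representative defaults whose provenance column marks them as
#' user-replaceable. Swap in an official table with [read_tra_table()].
#'
#' @return A `tra_table`.
#' @examples
#' tra_default_table()
#' @export
tra_default_table <- function() {
  if (is.null(table_env$default)) {
    path <- system.file("extdata", "tra_default_table.csv", package = "traworker")
    table_env$default <- read_tra_table(path)
  }
  table_env$default
}

#' Read a parameter table from CSV or JSON
#'
#' The CSV form is one long table with columns `section` (base,
#' concentration, duration, ventilation, lev, rpe), `proc`, `setting`,
#' `phase`, `band`, `class`, `location`, `value`, `units`, `provenance`;
#' the JSON form is the same six tables as named arrays. The table is fully
#' validated before it is returned; malformed content is reported with an
#' itemized error.
#'
#' @param path Path to a `.csv` or `.json` parameter table.
#' @return A validated `tra_table`.
#' @export
read_tra_table <- function(path) {
  if (!file.exists(path)) abort(paste0("parameter table not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    parts <- lapply(raw[c("base_estimates", "conc_factors", "dur_factors",
                          "gv_factors", "lev_factors", "rpe_factors")],
                    tibble::as_tibble)
    return(do.call(tra_table, unname(parts)))
  }
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            section = "c", proc = "d", setting = "c",
                            phase = "c", band = "c", class = "c",
                            location = "c", value = "d", units = "c",
                            provenance = "c"))
  if (!nrow(long)) abort("empty parameter table file")
  bad <- which(is.na(long$value) | !long$section %in%
                 c("base", "concentration", "duration", "ventilation", "lev", "rpe"))
  if (length(bad)) {
    abort(paste0("malformed parameter table rows (1-based, excluding header): ",
                 paste(bad, collapse = ", ")))
  }
  pick <- function(sec, cols) long[long$section == sec, cols]
  tra_table(
    base_estimates = pick("base", c("proc", "setting", "phase", "band",
                                    "value", "units", "provenance")),
    conc_factors = pick("concentration", c("class", "value", "provenance")),
    dur_factors = pick("duration", c("class", "value", "provenance")),
    gv_factors = pick("ventilation", c("setting", "location", "class",
                                       "value", "provenance")),
    lev_factors = pick("lev", c("proc", "setting", "value", "provenance")),
    rpe_factors = pick("rpe", c("class", "value", "provenance")))
}

#' Write a parameter table
#'
#' Inverse of [read_tra_table()]; `.csv` writes the long form, `.json` the
#' six named tables.
#'
#' @param x A `tra_table`.
#' @param path Destination `.csv` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_tra_table <- function(x, path) {
  stopifnot(inherits(x, "tra_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lapply(unclass(x), as.data.frame), path,
                         dataframe = "columns", na = "null", digits = NA)
    return(invisible(path))
  }
  col_or <- function(tab, name, default) {
    if (name %in% names(tab)) tab[[name]] else default
  }
  blank <- function(tab, sec) {
    tibble::tibble(section = sec,
                   proc = col_or(tab, "proc", NA_real_),
                   setting = col_or(tab, "setting", NA_character_),
                   phase = col_or(tab, "phase", NA_character_),
                   band = col_or(tab, "band", NA_character_),
                   class = col_or(tab, "class", NA_character_),
                   location = col_or(tab, "location", NA_character_),
                   value = tab$value,
                   units = col_or(tab, "units", NA_character_),
                   provenance = tab$provenance)
  }
  long <- dplyr::bind_rows(
    blank(x$base_estimates, "base"),
    blank(x$conc_factors, "concentration"),
    blank(x$dur_factors, "duration"),
    blank(x$gv_factors, "ventilation"),
    blank(x$lev_factors, "lev"),
    blank(x$rpe_factors, "rpe"))
  readr::write_csv(long, path, na = "")
  invisible(path)
}

#' Look up a base exposure estimate
#'
#' Pure lookup of the tabulated base estimate for a (PROC, setting, phase,
#' fugacity band) key. An absent combination raises a "scenario not
#' supported by parameter table" error naming the missing key — some PROCs
#' legitimately have no professional (or industrial) variant.
#'
#' @param table A `tra_table`.
#' @param proc Integer PROC code (1-28).
#' @param setting `"industrial"` or `"professional"`.
#' @param band Fugacity band, `"low"`, `"medium"` or `"high"`.
#' @param phase `"vapour"` (liquids) or `"dust"` (solids).
#' @return Named list with `value` (concentration) and `units`.
#' @examples
#' lookup_base_estimate(tra_default_table(), 10, "industrial", "medium")
#' @export
lookup_base_estimate <- function(table, proc, setting, band, phase = "vapour") {
  stopifnot(inherits(table, "tra_table"))
  be <- table$base_estimates
  hit <- be$proc == proc & be$setting == setting &
    be$phase == phase & be$band == band
  if (sum(hit) != 1) {
    abort(paste0("scenario not supported by parameter table: no base estimate for ",
                 "(PROC ", proc, ", ", setting, ", ", phase, ", ", band, ")"))
  }
  list(value = be$value[hit], units = be$units[hit])
}

#' Resolve the modifying factors of a scenario
#'
#' Returns one multiplicative factor per modifier group. When no LEV is
#' present `f_lev` is 1; when no RPE is assigned `f_rpe` is 1; outdoor
#' locations use the table's outdoor ventilation entry and ignore the
#' indoor ventilation class (it is not applicable outdoors).
#'
#' @param table A `tra_table`.
#' @param proc,setting As in [lookup_base_estimate()].
#' @param conc_band,dur_band Band labels (see [concentration_band()],
#'   [duration_band()]).
#' @param location `"indoor"` or `"outdoor"`.
#' @param general_ventilation `"basic"`, `"good"` or `"enhanced"` (indoor).
#' @param lev_present Logical.
#' @param rpe RPE percent-reduction class, `"none"`, `"90"` or `"95"`.
#' @return Named list `f_conc`, `f_dur`, `f_gv`, `f_lev`, `f_rpe`.
#' @export
resolve_modifiers <- function(table, proc, setting, conc_band, dur_band,
                              location = "indoor",
                              general_ventilation = "basic",
                              lev_present = FALSE, rpe = "none") {
  stopifnot(inherits(table, "tra_table"))
  one <- function(tab, hit, what, key) {
    if (sum(hit) != 1) {
      abort(paste0("no ", what, " factor in parameter table for ", key))
    }
    tab$value[hit]
  }
  f_conc <- one(table$conc_factors, table$conc_factors$class == conc_band,
                "concentration", conc_band)
  f_dur <- one(table$dur_factors, table$dur_factors$class == dur_band,
               "duration", dur_band)
  gv <- table$gv_factors
  if (identical(location, "outdoor")) {
    f_gv <- one(gv, gv$setting == setting & gv$location == "outdoor",
                "ventilation", paste0(setting, "/outdoor"))
  } else {
    f_gv <- one(gv, gv$setting == setting & gv$location == "indoor" &
                  gv$class == general_ventilation,
                "ventilation", paste0(setting, "/indoor/", general_ventilation))
  }
  f_lev <- if (isTRUE(lev_present)) {
    lv <- table$lev_factors
    one(lv, lv$proc == proc & lv$setting == setting, "LEV",
        paste0("PROC ", proc, "/", setting))
  } else 1
  f_rpe <- if (is.null(rpe) || is.na(rpe) || rpe == "none") 1 else {
    rp <- table$rpe_factors
    one(rp, rp$class == as.character(rpe), "RPE", rpe)
  }
  list(f_conc = f_conc, f_dur = f_dur, f_gv = f_gv, f_lev = f_lev, f_rpe = f_rpe)
}
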
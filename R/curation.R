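CURATED_COLUMNS <- c(
  "record_id", "source_ref", "substance", "cas", "molecular_weight",
  "physical_state", "vapour_pressure_kpa", "dustiness", "proc", "setting",
  "conc_band", "dur_band", "duration_min", "sampling_duration_min",
  "location", "general_ventilation", "lev_present", "lev_reported_effective",
  "rpe", "rpe_worn", "measurement_inside_rpe",
  "n", "gm", "gsd", "units", "notes")

EXCLUSION_CODES <- c("insufficient_n", "no_proc_assignable", "insufficient_context")

#' Build curated records from raw study descriptions
#'
#' Validates a table of study datasets (one row = one workplace scenario
#' dataset), assigns deterministic record ids, derives missing bands from
#' continuous inputs where possible, and attaches an inclusion decision via
#' [apply_inclusion_rules()]. Where both a sampling duration and an actual
#' exposure duration are reported, the exposure duration drives the
#' duration band; both are stored. Schema violations are itemized, not
#' silently coerced.
#'
#' @param studies Data frame or path to a CSV in the curated-database
#'   schema (see `CURATED_COLUMNS` in the source; minimally `source_ref`,
#'   `substance`, `proc`, `setting`, `n`, `gm`, `gsd`, `units` plus scenario
#'   descriptors).
#' @return Tibble of curated records with `record_id`, `included` and
#'   `exclusion_reasons` columns.
#' @export
build_records <- function(studies) {
  if (is.character(studies)) {
    studies <- read_curation_csv(studies)
  }
  stopifnot(is.data.frame(studies))
  rec <- tibble::as_tibble(studies)
  problems <- character()
  for (col in c("source_ref", "substance", "n", "units")) {
    if (!col %in% names(rec)) problems <- c(problems, paste0("missing column: ", col))
  }
  if (length(problems)) {
    abort(paste0("invalid study table:\n", paste0("- ", problems, collapse = "\n")))
  }
  for (col in setdiff(CURATED_COLUMNS, names(rec))) {
    rec[[col]] <- if (col %in% c("molecular_weight", "vapour_pressure_kpa",
                                 "proc", "duration_min", "sampling_duration_min",
                                 "n", "gm", "gsd")) NA_real_
    else if (col %in% c("lev_present", "lev_reported_effective",
                        "rpe_worn", "measurement_inside_rpe")) NA
    else NA_character_
  }
  if (any(!is.na(rec$units) & !rec$units %in% c("ppm", "mg/m3"))) {
    abort("invalid study table:\n- units must be 'ppm' or 'mg/m3'")
  }
  if (any(is.na(rec$units))) abort("invalid study table:\n- units are required for every record")
  if (any(!is.na(rec$gm) & rec$gm <= 0)) abort("invalid study table:\n- gm must be > 0")
  if (any(!is.na(rec$gsd) & rec$gsd < 1)) abort("invalid study table:\n- gsd must be >= 1")

  if ("concentration_pct" %in% names(rec)) {
    derive <- is.na(rec$conc_band) & !is.na(rec$concentration_pct)
    if (any(derive)) {
      rec$conc_band[derive] <- concentration_band(rec$concentration_pct[derive])
    }
  }
  derive_d <- is.na(rec$dur_band) & !is.na(rec$duration_min)
  if (any(derive_d)) rec$dur_band[derive_d] <- duration_band(rec$duration_min[derive_d])

  no_id <- is.na(rec$record_id)
  rec$record_id[no_id] <- make_record_id(rec$source_ref[no_id], rec$substance[no_id],
                                         rec$proc[no_id], rec$setting[no_id])
  dup <- duplicated(rec$record_id)
  if (any(dup)) {
    abort(paste0("duplicate record_id: ",
                 paste(unique(rec$record_id[dup]), collapse = ", ")))
  }
  apply_inclusion_rules(rec)
}

make_record_id <- function(source_ref, substance, proc, setting) {
  slug <- function(x) {
    x <- tolower(gsub("[^A-Za-z0-9]+", "-", ifelse(is.na(x), "na", as.character(x))))
    gsub("(^-|-$)", "", x)
  }
  paste(slug(source_ref), slug(substance), slug(proc), slug(setting), sep = "_")
}

#' Apply the task-force inclusion criteria
#'
#' A record enters the analysis only if (1) it has at least six
#' measurements, so a 75th percentile and its confidence interval can be
#' computed; (2) the work activity is clear enough that a PROC is assigned;
#' and (3) the context suffices to resolve every model input at band level
#' without guessing — any unknown scenario field fails this criterion.
#' Failures are coded (`insufficient_n`, `no_proc_assignable`,
#' `insufficient_context`), so the rule set is extensible and every
#' exclusion is auditable. Decisions, not errors: defective records are
#' flagged, never dropped.
#'
#' @param records Curated-record tibble (see [build_records()]).
#' @return `records` with `included` (logical) and `exclusion_reasons`
#'   (comma-separated codes, `""` when included) columns replaced.
#' @export
apply_inclusion_rules <- function(records) {
  rec <- tibble::as_tibble(records)
  reasons <- purrr::map_chr(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    codes <- character()
    if (is.na(r$n) || r$n < 6) codes <- c(codes, "insufficient_n")
    if (is.na(r$proc) || r$proc < 1 || r$proc > 28) codes <- c(codes, "no_proc_assignable")
    context_fields <- c("setting", "conc_band", "dur_band", "location",
                        "lev_present", "units")
    missing_ctx <- purrr::map_lgl(context_fields, ~ is.na(r[[.x]]))
    if (!is.na(r$location) && r$location == "indoor" && is.na(r$general_ventilation)) {
      missing_ctx <- c(missing_ctx, TRUE)
    }
    no_dist <- (is.na(r$gm) || is.na(r$gsd))
    if (any(missing_ctx) || no_dist) codes <- c(codes, "insufficient_context")
    paste(codes, collapse = ",")
  })
  rec$included <- reasons == ""
  rec$exclusion_reasons <- reasons
  rec
}

#' Adjust control credits for model-measurement comparison
#'
#' Produces the comparison scenario the validation uses, leaving the
#' original columns untouched:
#' \itemize{
#'   \item LEV credit is removed (`lev_present_cmp = FALSE`) when the study
#'     reports the LEV as not delivering its protective potential
#'     (`lev_reported_effective = FALSE`) — the estimate must then not
#'     contain the LEV effect.
#'   \item RPE credit is removed (`rpe_cmp = "none"`) unless measurements
#'     were explicitly taken inside the respirator: occupational exposure
#'     measurements are taken outside respirators, so a respirator factor
#'     in the estimate would not be reflected in the data.
#' }
#' Every adjustment is logged into `notes`; the operation is idempotent.
#' `measurement_inside_rpe = TRUE` raises a warning — measuring inside a
#' respirator goes against accepted industrial-hygiene practice and likely
#' invalidates the face seal.
#'
#' @param records Curated-record tibble.
#' @return `records` with comparison columns `lev_present_cmp` and
#'   `rpe_cmp` (and updated `notes`).
#' @export
adjust_controls <- function(records) {
  rec <- tibble::as_tibble(records)
  if (any(rec$measurement_inside_rpe %in% TRUE)) {
    warn(paste0("records ",
                paste(rec$record_id[rec$measurement_inside_rpe %in% TRUE], collapse = ", "),
                ": measurements reported taken inside respirators; this conflicts ",
                "with accepted industrial-hygiene practice and likely invalidates the seal"))
  }
  lev_cmp <- rec$lev_present %in% TRUE & !(rec$lev_reported_effective %in% FALSE)
  rpe_cmp <- ifelse(rec$measurement_inside_rpe %in% TRUE,
                    ifelse(is.na(rec$rpe), "none", rec$rpe), "none")
  note_add <- function(old, add) {
    has <- mapply(grepl, add, old, MoreArgs = list(fixed = TRUE))
    ifelse(add == "" | has, old,
           ifelse(is.na(old) | old == "", add, paste(old, add, sep = "; ")))
  }
  lev_note <- ifelse(rec$lev_present %in% TRUE & rec$lev_reported_effective %in% FALSE,
                     "comparison: LEV credit removed (reported ineffective)", "")
  rpe_note <- ifelse(!is.na(rec$rpe) & rec$rpe != "none" & rpe_cmp == "none",
                     "comparison: RPE credit removed (measurements outside respirator)", "")
  rec$notes <- note_add(note_add(rec$notes, lev_note), rpe_note)
  rec$lev_present_cmp <- lev_cmp
  rec$rpe_cmp <- rpe_cmp
  rec
}

read_curation_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read a curated database CSV
#'
#' Deterministic writer (fixed column order, 6 significant digits) and the
#' matching reader, so `read_curated_db(write_curated_db(x, p))`
#' round-trips.
#'
#' @param records Curated-record tibble.
#' @param path CSV path.
#' @return `path` (writer, invisibly); tibble (reader).
#' @export
write_curated_db <- function(records, path) {
  cols <- intersect(c(CURATED_COLUMNS, "true_gm", "true_gsd",
                      "included", "exclusion_reasons",
                      "lev_present_cmp", "rpe_cmp"), names(records))
  out <- records[cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 10))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_curated_db
#' @export
read_curated_db <- function(path) {
  rec <- read_curation_csv(path)
  for (col in c("lev_present", "lev_reported_effective", "rpe_worn",
                "measurement_inside_rpe", "included", "lev_present_cmp")) {
    if (col %in% names(rec)) rec[[col]] <- as.logical(rec[[col]])
  }
  rec
}
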
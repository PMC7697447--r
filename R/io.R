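#' Read measurement datasets from CSV
#'
#' Schema: columns `study_id`, `substance`, `units`, then either raw rows
#' with a `value` column (one measurement per row, optional `duration_min`)
#' or summary rows with `gm`, `gsd`, `n`. Readers reject rather than
#' coerce: mixed units within one study, non-positive values, or rows that
#' are neither raw nor summary are itemized errors — no silent dropping.
#' Decimal commas are rejected with a pointer to `decimal_comma = TRUE`.
#'
#' @param path CSV file path.
#' @param decimal_comma Set `TRUE` for files using "," as decimal mark.
#' @return A tibble with one row per study: `study_id`, `substance`,
#'   `units`, `n`, `gm`, `gsd` and a `values` list-column (`NULL` for
#'   summary-only studies), plus a `durations` list-column.
#' @export
read_measurements <- function(path, decimal_comma = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("study_id", "units")
  miss <- setdiff(need, names(raw))
  if (length(miss)) abort(paste0("measurement CSV missing columns: ",
                                 paste(miss, collapse = ", ")))
  parse_num <- function(col) {
    if (!col %in% names(raw)) return()
    x <- raw[[col]]
    x[!is.na(x) & x == ""] <- NA
    if (any(grepl(",", x))) {
      if (!decimal_comma) {
        abort(paste0("column '", col, "' contains decimal commas; ",
                     "re-read with decimal_comma = TRUE"))
      }
      x <- gsub(",", ".", x, fixed = TRUE)
    }
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      abort(paste0("column '", col, "': non-numeric values in rows ",
                   paste(bad, collapse = ", ")))
    }
    raw[[col]] <<- out
  }
  for (col in c("value", "gm", "gsd", "n", "duration_min")) parse_num(col)
  has_value <- "value" %in% names(raw)
  has_summary <- all(c("gm", "gsd", "n") %in% names(raw))

  out <- raw |>
    dplyr::group_by(.data$study_id) |>
    dplyr::group_map(function(g, key) {
      units <- unique(g$units)
      if (length(units) != 1) {
        abort(paste0("study ", key$study_id, ": mixed units (",
                     paste(units, collapse = ", "), ") within one measurement set"))
      }
      units <- normalize_units(units)
      is_raw <- has_value && any(!is.na(g$value))
      if (is_raw) {
        vals <- g$value[!is.na(g$value)]
        if (any(vals <= 0)) {
          abort(paste0("study ", key$study_id, ": non-positive measurement values"))
        }
        tibble::tibble(study_id = key$study_id,
                       substance = g$substance[1] %||% NA_character_,
                       units = units, n = length(vals),
                       gm = exp(mean(log(vals))),
                       gsd = if (length(vals) > 1) exp(sd(log(vals))) else 1,
                       values = list(vals),
                       durations = list(if ("duration_min" %in% names(g)) g$duration_min else NULL))
      } else {
        if (!has_summary || is.na(g$gm[1]) || is.na(g$gsd[1]) || is.na(g$n[1])) {
          abort(paste0("study ", key$study_id,
                       ": neither raw values nor a complete gm/gsd/n summary"))
        }
        if (g$gm[1] <= 0 || g$gsd[1] < 1) {
          abort(paste0("study ", key$study_id, ": invalid summary (gm <= 0 or gsd < 1)"))
        }
        tibble::tibble(study_id = key$study_id,
                       substance = g$substance[1] %||% NA_character_,
                       units = units, n = g$n[1], gm = g$gm[1], gsd = g$gsd[1],
                       values = list(NULL), durations = list(NULL))
      }
    }) |>
    dplyr::bind_rows()
  out
}

#' Write a measurement set to CSV
#'
#' One measurement per row (`study_id`, `substance`, `units`, `value`,
#' `duration_min`); summary-only sets are written as single summary rows.
#'
#' @param ms A [measurement_set()] or the tibble form from
#'   [read_measurements()].
#' @param path Output CSV path.
#' @param study_id,substance Identifiers used when `ms` is a bare
#'   `measurement_set`.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(ms, path, study_id = "study-1",
                               substance = NA_character_) {
  if (inherits(ms, "measurement_set")) {
    tab <- if (!is.null(ms$values)) {
      tibble::tibble(study_id = study_id, substance = substance,
                     units = ms$units, value = ms$values,
                     duration_min = if (is.null(ms$sample_durations)) NA_real_
                                    else ms$sample_durations)
    } else {
      tibble::tibble(study_id = study_id, substance = substance,
                     units = ms$units, gm = ms$gm, gsd = ms$gsd, n = ms$n)
    }
  } else {
    rows <- purrr::map(seq_len(nrow(ms)), function(i) {
      if (!is.null(ms$values[[i]])) {
        tibble::tibble(study_id = ms$study_id[i], substance = ms$substance[i],
                       units = ms$units[i], value = ms$values[[i]])
      } else {
        tibble::tibble(study_id = ms$study_id[i], substance = ms$substance[i],
                       units = ms$units[i], gm = ms$gm[i], gsd = ms$gsd[i],
                       n = ms$n[i])
      }
    })
    tab <- dplyr::bind_rows(rows)
  }
  readr::write_csv(tab, path, na = "")
  invisible(path)
}
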
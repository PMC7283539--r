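#' @noRd
EVENT_TYPES <- c("diagnosis", "lab", "medication", "encounter", "nlp_diagnosis")

#' @noRd
CODE_SYSTEMS <- c("ICD9CM", "ICD10CM", "MED", "LAB", "NONE")

#' @noRd
ENTRY_MODES <- c("billing", "physician", "nlp")

#' @noRd
EVENT_COLUMNS <- c(
  "patient_id", "event_type", "code_system", "code", "value",
  "date", "source_id", "entry_mode", "linkage_key"
)

#' Build a clinical event table
#'
#' Constructs a validated tibble of clinical events, the package's core data
#' structure. One row is one dated, source-tagged fact about a patient: a
#' billed or NLP-extracted diagnosis, a lab result, a medication order, or an
#' encounter. Events recorded by more than one institution share a
#' `linkage_key`, which is how union views recognise duplicates.
#'
#' @param patient_id Character, patient identifiers (opaque).
#' @param event_type One of `"diagnosis"`, `"lab"`, `"medication"`,
#'   `"encounter"`, `"nlp_diagnosis"`.
#' @param code_system One of `"ICD9CM"`, `"ICD10CM"`, `"MED"`, `"LAB"`,
#'   `"NONE"`.
#' @param code Character code; may be empty for encounters.
#' @param value Numeric lab result magnitude; must be non-missing for lab
#'   events, `NA` otherwise.
#' @param date Event date (`Date` or ISO-8601 string).
#' @param source_id Institution that recorded the event.
#' @param entry_mode How the fact entered the record: `"billing"`,
#'   `"physician"`, or `"nlp"`.
#' @param linkage_key Non-empty key identifying the same real-world event
#'   across sources.
#' @return A tibble with the nine event columns, validated.
#' @export
#' @examples
#' clinical_events(
#'   patient_id = "P1", event_type = "diagnosis", code_system = "ICD9CM",
#'   code = "714.0", value = NA_real_, date = "2012-05-01",
#'   source_id = "Mayo", entry_mode = "billing", linkage_key = "P1-e1"
#' )
clinical_events <- function(patient_id, event_type, code_system, code,
                            value = NA_real_, date, source_id,
                            entry_mode = "billing", linkage_key) {
  ev <- tibble::tibble(
    patient_id = as.character(patient_id),
    event_type = as.character(event_type),
    code_system = as.character(code_system),
    code = as.character(code),
    value = as.numeric(value),
    date = as.Date(date),
    source_id = as.character(source_id),
    entry_mode = as.character(entry_mode),
    linkage_key = as.character(linkage_key)
  )
  validate_events(ev, strict = TRUE)
}

#' Validate a clinical event table
#'
#' Checks the event-table contract: known event types, code systems and entry
#' modes; parseable dates; non-missing values on lab rows; non-empty linkage
#' keys. Row numbers of all offending rows are collected into the diagnostic
#' rather than stopping at the first.
#'
#' @param events A data frame with the columns of [clinical_events()].
#' @param strict If `TRUE` (default) any invalid row raises an error listing
#'   row numbers; if `FALSE`, invalid rows are dropped with a warning.
#' @return The validated (possibly filtered) event tibble.
#' @export
validate_events <- function(events, strict = TRUE) {
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "event table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "phenofrag_format_error")
  }
  events <- tibble::as_tibble(events)[EVENT_COLUMNS]
  events$date <- as.Date(events$date)

  problems <- character(0)
  bad <- function(which, what) {
    if (any(which, na.rm = TRUE)) {
      rows <- which(which)
      problems <<- c(problems, sprintf(
        "%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
        paste(head(rows, 10), collapse = ", ")
      ))
      which
    } else {
      rep(FALSE, nrow(events))
    }
  }
  invalid <-
    bad(!(events$event_type %in% EVENT_TYPES), "unknown event_type") |
    bad(!(events$code_system %in% CODE_SYSTEMS), "unknown code_system") |
    bad(!(events$entry_mode %in% ENTRY_MODES), "unknown entry_mode") |
    bad(is.na(events$date), "unparseable or missing date") |
    bad(events$event_type == "lab" & !is.finite(events$value),
        "lab event with empty value") |
    bad(is.na(events$linkage_key) | events$linkage_key == "",
        "empty linkage_key") |
    bad(is.na(events$patient_id) | events$patient_id == "",
        "empty patient_id")

  if (length(problems) > 0) {
    msg <- paste0("invalid event rows: ", paste(problems, collapse = "; "))
    if (strict) abort(msg, class = "phenofrag_row_error")
    warn(paste0(msg, " — dropped"))
    events <- events[!invalid, ]
  }
  events
}

#' Read clinical events from CSV
#'
#' Reads the documented nine-column event CSV
#' (`patient_id,event_type,code_system,code,value,date,source_id,entry_mode,linkage_key`,
#' ISO-8601 dates) and validates every row.
#'
#' @param path Path to an events CSV file.
#' @param strict Passed to [validate_events()]: error on malformed rows
#'   (default) or drop them with a warning.
#' @return A validated event tibble.
#' @export
read_events <- function(path, strict = TRUE) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      event_type = readr::col_character(),
      code_system = readr::col_character(),
      code = readr::col_character(),
      value = readr::col_double(),
      date = readr::col_date(format = "%Y-%m-%d"),
      source_id = readr::col_character(),
      entry_mode = readr::col_character(),
      linkage_key = readr::col_character()
    )
  )
  prb <- readr::problems(raw)
  if (nrow(prb) > 0 && strict) {
    abort(sprintf(
      "malformed CSV field(s) in %s: row%s %s",
      path, if (nrow(prb) > 1) "s" else "",
      paste(unique(head(prb$row, 10)), collapse = ", ")
    ), class = "phenofrag_row_error")
  }
  raw$code[is.na(raw$code)] <- ""
  validate_events(raw, strict = strict)
}

#' Write clinical events to CSV
#'
#' Inverse of [read_events()]; `write_events()` then [read_events()] is the
#' identity on valid event tables.
#'
#' @param events A validated event tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events, strict = TRUE)
  readr::write_csv(events, path, na = "")
  invisible(path)
}

#' Read or write the patient roster
#'
#' The roster CSV has columns `patient_id,family_history_dm`. The family
#' history flag is the self-reported first-degree diabetes family history
#' collected at enrolment; it is patient-level (identical in every source
#' view) and defaults to `FALSE` when missing.
#'
#' @param path CSV path.
#' @return `read_patients()`: a tibble with `patient_id` (unique) and
#'   `family_history_dm` (logical).
#' @export
read_patients <- function(path) {
  pts <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      family_history_dm = readr::col_logical()
    )
  )
  validate_patients(pts)
}

#' @rdname read_patients
#' @param patients A patient tibble.
#' @export
write_patients <- function(patients, path) {
  patients <- validate_patients(patients)
  readr::write_csv(patients, path, na = "")
  invisible(path)
}

#' @noRd
validate_patients <- function(patients) {
  if (!all(c("patient_id", "family_history_dm") %in% names(patients))) {
    abort("patient table needs columns patient_id, family_history_dm",
          class = "phenofrag_format_error")
  }
  patients <- tibble::as_tibble(patients)[c("patient_id", "family_history_dm")]
  if (anyDuplicated(patients$patient_id)) {
    abort("duplicate patient_id in roster", class = "phenofrag_row_error")
  }
  patients$family_history_dm[is.na(patients$family_history_dm)] <- FALSE
  patients
}

#' Restrict events to a study window
#'
#' Keeps events whose date lies in the closed interval `[start, end]`. The
#' default analysis window is 2010-01-01 through 2017-12-31.
#'
#' @param events Event tibble.
#' @param start,end Window bounds (`Date` or ISO-8601 string); `start` must
#'   not exceed `end`.
#' @return The filtered event tibble.
#' @export
filter_window <- function(events, start = as.Date("2010-01-01"),
                          end = as.Date("2017-12-31")) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) {
    abort("window bounds must be valid dates", class = "phenofrag_arg_error")
  }
  if (start > end) {
    abort("window start is after window end", class = "phenofrag_arg_error")
  }
  dplyr::filter(events, .data$date >= start, .data$date <= end)
}
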
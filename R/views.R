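#' Build a source view of an event table
#'
#' A source view is what one institution (or the union of several) can see of
#' a cohort: the events recorded by the selected sources, over the full
#' patient roster. Two contracts matter downstream:
#'
#' * **Deduplication.** When the view spans more than one source, events that
#'   share a `linkage_key` (the same real-world fact recorded by several
#'   institutions) are collapsed to one representative — the earliest-dated
#'   copy, ties broken by lexicographically smallest `source_id`.
#' * **Roster conservation.** Every cohort patient appears in every view,
#'   possibly with zero events. Absence of events means empty evidence, not a
#'   missing patient, so confusion counts over any view always sum to the
#'   cohort size.
#'
#' @param events Validated event tibble.
#' @param patients Patient roster tibble (see [read_patients()]).
#' @param sources Character vector of source ids the view may see.
#' @param label Display label; defaults to `paste(sources, collapse = "+")`.
#' @param all_sources Universe of known sources, used to flag the union view
#'   and reject unknown sources; defaults to the sources present in `events`
#'   (plus `sources`).
#' @return An object of class `source_view`: a list with `label`, `sources`,
#'   `all_sources`, `is_union`, `events`, `patients`.
#' @export
#' @examples
#' pts <- tibble::tibble(patient_id = "P1", family_history_dm = FALSE)
#' ev <- clinical_events(
#'   patient_id = "P1", event_type = "diagnosis", code_system = "ICD9CM",
#'   code = "714.0", value = NA_real_, date = c("2012-05-01", "2012-05-01"),
#'   source_id = c("Mayo", "REP"), entry_mode = "billing", linkage_key = "P1-e1"
#' )
#' nrow(make_view(ev, pts, c("Mayo", "REP"))$events)  # deduplicated: 1
make_view <- function(events, patients, sources,
                      label = paste(sources, collapse = "+"),
                      all_sources = NULL) {
  if (length(sources) == 0) {
    abort("a view needs at least one source", class = "phenofrag_arg_error")
  }
  patients <- validate_patients(patients)
  if (is.null(all_sources)) {
    all_sources <- sort(union(unique(events$source_id), character(0)))
    if (length(all_sources) == 0) all_sources <- sort(unique(sources))
  }
  unknown <- setdiff(sources, all_sources)
  if (length(unknown) > 0) {
    abort(sprintf("unknown source id(s): %s", paste(unknown, collapse = ", ")),
          class = "phenofrag_arg_error")
  }
  ev <- events[events$source_id %in% sources, , drop = FALSE]
  if (length(sources) > 1 && nrow(ev) > 0) {
    ev <- ev |>
      dplyr::arrange(.data$linkage_key, .data$date, .data$source_id) |>
      dplyr::distinct(.data$linkage_key, .keep_all = TRUE)
  }
  unknown_pat <- setdiff(unique(ev$patient_id), patients$patient_id)
  if (length(unknown_pat) > 0) {
    abort(sprintf("events reference patients missing from roster: %s",
                  paste(head(unknown_pat, 5), collapse = ", ")),
          class = "phenofrag_arg_error")
  }
  structure(
    list(
      label = label,
      sources = sort(unique(sources)),
      all_sources = sort(unique(all_sources)),
      is_union = setequal(sources, all_sources),
      events = tibble::as_tibble(ev),
      patients = patients
    ),
    class = "source_view"
  )
}

#' @export
print.source_view <- function(x, ...) {
  cat(sprintf(
    "<source_view> %s%s: %d events, %d patients (sources: %s of %s)\n",
    x$label, if (x$is_union) " [union]" else "",
    nrow(x$events), nrow(x$patients),
    paste(x$sources, collapse = ", "), paste(x$all_sources, collapse = ", ")
  ))
  invisible(x)
}

#' @noRd
assert_view <- function(view) {
  if (!inherits(view, "source_view")) {
    abort("expected a source_view (see make_view())",
          class = "phenofrag_arg_error")
  }
  view
}
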
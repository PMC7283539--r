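#' Declare a code list
#'
#' A code list names a set of code patterns within a single coding system.
#' Patterns are either exact codes (`"710.0"`) or prefix wildcards ending in
#' `*` (`"714.*"`, which matches `"714.0"` but not `"7140"`: the dot is a
#' literal character, and `*` is only valid as a trailing wildcard). Matching
#' is case-insensitive. Algorithm roles that span ICD-9-CM and ICD-10-CM are
#' represented as a list of single-system code lists sharing a role name.
#'
#' @param name Role or list name (e.g. `"ra_dx"`).
#' @param system Coding system, one of `"ICD9CM"`, `"ICD10CM"`, `"MED"`,
#'   `"LAB"`, `"NONE"`.
#' @param codes Non-empty character vector of patterns.
#' @return An object of class `code_list`.
#' @export
#' @examples
#' code_list("ra_dx", "ICD9CM", c("714.*"))
code_list <- function(name, system, codes) {
  if (!is.character(codes) || length(codes) == 0 || any(is.na(codes)) ||
      any(codes == "")) {
    abort("code list must contain at least one non-empty pattern",
          class = "phenofrag_config_error")
  }
  if (!system %in% CODE_SYSTEMS) {
    abort(sprintf("unknown code system '%s'", system),
          class = "phenofrag_config_error")
  }
  inner <- grepl("\\*", sub("\\*$", "", codes))
  if (any(inner)) {
    abort("'*' is only allowed as a trailing wildcard",
          class = "phenofrag_config_error")
  }
  structure(
    list(name = name, system = system, codes = toupper(codes)),
    class = "code_list"
  )
}

#' @export
print.code_list <- function(x, ...) {
  cat(sprintf("<code_list> %s [%s]: %s\n", x$name, x$system,
              paste(x$codes, collapse = ", ")))
  invisible(x)
}

#' Test codes against code-list patterns
#'
#' Vectorised predicate behind [match_codes()]. A code matches an exact
#' pattern by case-insensitive equality, and a `"X*"` pattern when it starts
#' with `X` (again case-insensitively, dot literal).
#'
#' @param codes Character vector of codes.
#' @param patterns Character vector of patterns (exact or trailing-`*`).
#' @return Logical vector along `codes`.
#' @export
code_matches <- function(codes, patterns) {
  codes <- toupper(codes)
  patterns <- toupper(patterns)
  hit <- rep(FALSE, length(codes))
  for (p in patterns) {
    if (endsWith(p, "*")) {
      hit <- hit | startsWith(codes, substr(p, 1, nchar(p) - 1L))
    } else {
      hit <- hit | codes == p
    }
  }
  hit
}

#' Select events matching a code-list role
#'
#' Returns the events whose `(code_system, code)` matches any pattern of the
#' given code list (or list of code lists for roles that span systems),
#' restricted to the configured event types.
#'
#' @param events Event tibble.
#' @param codelist A `code_list`, or a list of them (one per system).
#' @param event_types Event types eligible to match; defaults to billed
#'   diagnoses only. Pass `c("diagnosis", "nlp_diagnosis")` to include
#'   NLP-extracted physician diagnoses, or `"lab"` / `"medication"` for lab
#'   and medication roles.
#' @return The matching subset of `events`.
#' @export
match_codes <- function(events, codelist, event_types = "diagnosis") {
  if (inherits(codelist, "code_list")) codelist <- list(codelist)
  if (length(codelist) == 0 || !all(vapply(codelist, inherits, TRUE, "code_list"))) {
    abort("codelist must be a code_list or a list of code_list objects",
          class = "phenofrag_config_error")
  }
  keep <- events$event_type %in% event_types
  hit <- rep(FALSE, nrow(events))
  for (cl in codelist) {
    sys <- events$code_system == cl$system
    idx <- keep & sys
    if (any(idx)) hit[idx] <- hit[idx] | code_matches(events$code[idx], cl$codes)
  }
  events[hit, ]
}

#' Load code-list roles from YAML
#'
#' Reads a YAML file mapping role names (e.g. `ra_dx`, `t2dm_med`) to lists
#' of `{system, codes}` entries, as in the bundled
#' `inst/extdata/codelists.yaml`. The bundled vocabulary is a configuration
#' artifact: plausible ICD-9-CM/ICD-10-CM, medication and lab codes standing
#' in for institutional code sets, intended to be replaced per deployment.
#'
#' @param path YAML file path; defaults to the bundled vocabulary.
#' @return Named list; each element is a list of `code_list` objects.
#' @export
read_codelists <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codelists.yaml", package = "phenofrag")
  }
  if (!file.exists(path)) {
    abort(sprintf("code list file not found: %s", path),
          class = "phenofrag_config_error")
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(role) {
    lapply(raw[[role]], function(entry) {
      code_list(role, entry$system, as.character(entry$codes))
    })
  })
  names(out) <- names(raw)
  out
}

#' @rdname read_codelists
#' @export
default_codelists <- function() read_codelists(NULL)

#' @noRd
require_role <- function(codelists, role) {
  if (is.null(codelists[[role]])) {
    abort(sprintf("code list role '%s' is not configured", role),
          class = "phenofrag_config_error")
  }
  codelists[[role]]
}
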
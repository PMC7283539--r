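#' Laboratory abnormality criteria for the T2DM algorithm
#'
#' Thresholds defining an "abnormal lab": fasting glucose at or above 126
#' mg/dL, random glucose at or above 200 mg/dL, HbA1c at or above 6.5% —
#' standard diagnostic values, overridable per deployment.
#'
#' @param fasting_glucose_threshold mg/dL.
#' @param random_glucose_threshold mg/dL.
#' @param hba1c_threshold Percent.
#' @return An object of class `lab_criteria`.
#' @export
lab_criteria <- function(fasting_glucose_threshold = 126,
                         random_glucose_threshold = 200,
                         hba1c_threshold = 6.5) {
  vals <- c(fasting_glucose_threshold, random_glucose_threshold,
            hba1c_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("lab thresholds must be positive", class = "phenofrag_config_error")
  }
  structure(
    list(fasting_glucose_threshold = fasting_glucose_threshold,
         random_glucose_threshold = random_glucose_threshold,
         hba1c_threshold = hba1c_threshold),
    class = "lab_criteria"
  )
}

#' Extract T2DM evidence for every patient in a view
#'
#' Aggregates, per patient, the factors the rule-based T2DM algorithm
#' consumes: type 1 and type 2 diabetes diagnosis counts (billing plus
#' NLP-extracted), physician-asserted T2DM diagnoses (entry mode physician
#' or nlp), medication flags for type 1 and type 2 agents, whether the
#' earliest T2DM medication predates the earliest T1DM medication (defined
#' only when both are present), any abnormal glucose/HbA1c result, in-person
#' visit and glucose-measure counts, diabetes-related diagnoses, diabetes
#' medication-or-supplies orders, and the self-reported diabetes family
#' history flag.
#'
#' @param view A [make_view()] result.
#' @param codelists Code-list roles; needs `t1dm_dx`, `t2dm_dx`, `t1dm_med`,
#'   `t2dm_med`, `dm_related_dx`, `dm_supplies`, `glucose_lab`, `hba1c_lab`,
#'   and optionally `fasting_glucose_lab` (the glucose codes the fasting
#'   threshold applies to; others use the random threshold).
#' @param criteria A [lab_criteria()].
#' @return Tibble with `patient_id` and the evidence fields.
#' @export
extract_t2dm_evidence <- function(view, codelists = default_codelists(),
                                  criteria = lab_criteria()) {
  assert_view(view)
  ev <- view$events
  dx_types <- c("diagnosis", "nlp_diagnosis")

  count_ids <- function(sub) table(factor(sub$patient_id,
                                          levels = view$patients$patient_id))
  t1 <- match_codes(ev, require_role(codelists, "t1dm_dx"), dx_types)
  t2 <- match_codes(ev, require_role(codelists, "t2dm_dx"), dx_types)
  t2_phys <- t2[t2$entry_mode %in% c("physician", "nlp"), ]

  t1_med <- match_codes(ev, require_role(codelists, "t1dm_med"), "medication")
  t2_med <- match_codes(ev, require_role(codelists, "t2dm_med"), "medication")
  supplies <- match_codes(ev, require_role(codelists, "dm_supplies"),
                          "medication")
  dm_rel <- match_codes(ev, require_role(codelists, "dm_related_dx"), dx_types)

  glu <- match_codes(ev, require_role(codelists, "glucose_lab"), "lab")
  hba1c <- match_codes(ev, require_role(codelists, "hba1c_lab"), "lab")
  fasting_role <- codelists[["fasting_glucose_lab"]]
  is_fasting <- rep(FALSE, nrow(glu))
  if (!is.null(fasting_role)) {
    if (inherits(fasting_role, "code_list")) fasting_role <- list(fasting_role)
    for (cl in fasting_role) {
      sel <- glu$code_system == cl$system
      if (any(sel)) {
        is_fasting[sel] <- is_fasting[sel] | code_matches(glu$code[sel], cl$codes)
      }
    }
  }
  glu_abnormal <- ifelse(
    is_fasting,
    glu$value >= criteria$fasting_glucose_threshold,
    glu$value >= criteria$random_glucose_threshold
  )
  abnormal <- dplyr::bind_rows(glu[glu_abnormal, ],
                               hba1c[hba1c$value >= criteria$hba1c_threshold, ])

  earliest <- function(sub) {
    if (nrow(sub) == 0) {
      return(tibble::tibble(patient_id = character(0),
                            first = as.Date(character(0))))
    }
    dplyr::summarise(dplyr::group_by(sub, .data$patient_id),
                     first = min(.data$date), .groups = "drop")
  }
  first_t1 <- earliest(t1_med)
  first_t2 <- earliest(t2_med)

  roster <- view$patients$patient_id
  out <- tibble::tibble(
    patient_id = roster,
    n_t1dm_dx = as.integer(count_ids(t1)),
    n_t2dm_dx = as.integer(count_ids(t2)),
    n_t2dm_dx_physician = as.integer(count_ids(t2_phys)),
    has_t1dm_med = as.integer(count_ids(t1_med)) > 0,
    has_t2dm_med = as.integer(count_ids(t2_med)) > 0,
    has_abnormal_lab = as.integer(count_ids(abnormal)) > 0,
    n_inperson_visits = as.integer(count_ids(
      ev[ev$event_type == "encounter" & toupper(ev$code) == "INPERSON", ]
    )),
    n_glucose_measures = as.integer(count_ids(glu)),
    has_dm_related_dx = as.integer(count_ids(dm_rel)) > 0,
    has_dm_med_or_supplies =
      (as.integer(count_ids(t1_med)) + as.integer(count_ids(t2_med)) +
         as.integer(count_ids(supplies))) > 0
  )
  prec <- dplyr::left_join(
    dplyr::left_join(tibble::tibble(patient_id = roster), first_t2,
                     by = "patient_id"),
    first_t1, by = "patient_id", suffix = c("_t2", "_t1")
  )
  out$t2dm_med_precedes_t1dm_med <- ifelse(
    out$has_t1dm_med & out$has_t2dm_med,
    prec$first_t2 < prec$first_t1,
    NA
  )
  out <- dplyr::left_join(out, view$patients, by = "patient_id")
  out
}

#' Case decision paths for the rule-based T2DM algorithm
#'
#' A patient is a T2DM case when any path matches (the first matching path
#' id is recorded). The default set reconstructs the published decision tree
#' from its factor list: with no T1DM diagnosis, a case needs a T2DM
#' diagnosis plus either a T2DM medication (P1) or, lacking one, an abnormal
#' lab (P2), or — with no T2DM diagnosis at all — both a T2DM medication and
#' an abnormal lab (P3); with a T1DM diagnosis present (possible
#' miscoding), a case needs a T2DM diagnosis and T1DM medication plus
#' either a T2DM medication ordered before the first T1DM medication (P4)
#' or, with no T2DM medication, at least two physician-asserted T2DM
#' diagnoses (P5).
#'
#' Each path is declared as data: named requirements over the boolean atoms
#' `t1dm_dx`, `t2dm_dx`, `t1dm_med`, `t2dm_med`, `abnormal_lab`
#' (`TRUE`/`FALSE` required value; absent = don't care), plus optional
#' `require_precedence` and `min_physician_dx`.
#'
#' @return List of path specifications.
#' @export
default_t2dm_paths <- function() {
  list(
    list(id = "P1", require = c(t1dm_dx = FALSE, t2dm_dx = TRUE,
                                t2dm_med = TRUE)),
    list(id = "P2", require = c(t1dm_dx = FALSE, t2dm_dx = TRUE,
                                t2dm_med = FALSE, abnormal_lab = TRUE)),
    list(id = "P3", require = c(t1dm_dx = FALSE, t2dm_dx = FALSE,
                                t2dm_med = TRUE, abnormal_lab = TRUE)),
    list(id = "P4", require = c(t1dm_dx = TRUE, t2dm_dx = TRUE,
                                t1dm_med = TRUE, t2dm_med = TRUE),
         require_precedence = TRUE),
    list(id = "P5", require = c(t1dm_dx = TRUE, t2dm_dx = TRUE,
                                t1dm_med = TRUE, t2dm_med = FALSE),
         min_physician_dx = 2L)
  )
}

#' Read T2DM rule configuration from YAML
#'
#' Expects keys `paths` (list of path specs as in [default_t2dm_paths()])
#' and optionally `lab_criteria` (threshold overrides).
#'
#' @param path YAML file path; defaults to the bundled rules.
#' @return List with elements `paths` and `criteria`.
#' @export
read_t2dm_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "t2dm_rules.yaml", package = "phenofrag")
  }
  if (!file.exists(path)) {
    abort(sprintf("T2DM rules file not found: %s", path),
          class = "phenofrag_config_error")
  }
  raw <- yaml::read_yaml(path)
  paths <- lapply(raw$paths, function(p) {
    spec <- list(id = p$id, require = unlist(p$require))
    if (!is.null(p$require_precedence)) {
      spec$require_precedence <- isTRUE(p$require_precedence)
    }
    if (!is.null(p$min_physician_dx)) {
      spec$min_physician_dx <- as.integer(p$min_physician_dx)
    }
    spec
  })
  crit <- do.call(lab_criteria, as.list(raw$lab_criteria %||% list()))
  list(paths = paths, criteria = crit)
}

#' @noRd
t2dm_atoms <- function(evidence) {
  tibble::tibble(
    t1dm_dx = evidence$n_t1dm_dx >= 1,
    t2dm_dx = evidence$n_t2dm_dx >= 1,
    t1dm_med = evidence$has_t1dm_med,
    t2dm_med = evidence$has_t2dm_med,
    abnormal_lab = evidence$has_abnormal_lab
  )
}

#' Rule-based T2DM case decision
#'
#' Evaluates the case decision paths (see [default_t2dm_paths()]) over an
#' evidence table and records the first satisfied path per patient.
#'
#' @param evidence Tibble from [extract_t2dm_evidence()].
#' @param paths Path specifications (default [default_t2dm_paths()]).
#' @return Tibble with `patient_id`, `case` (logical), `path` (first
#'   satisfied path id or `NA`).
#' @export
classify_t2dm_case <- function(evidence, paths = default_t2dm_paths()) {
  atoms <- t2dm_atoms(evidence)
  nr <- nrow(evidence)
  case <- rep(FALSE, nr)
  path_id <- rep(NA_character_, nr)
  for (p in paths) {
    ok <- rep(TRUE, nr)
    for (a in names(p$require)) {
      ok <- ok & (atoms[[a]] == p$require[[a]])
    }
    if (isTRUE(p$require_precedence)) {
      ok <- ok & !is.na(evidence$t2dm_med_precedes_t1dm_med) &
        evidence$t2dm_med_precedes_t1dm_med
    }
    if (!is.null(p$min_physician_dx)) {
      ok <- ok & evidence$n_t2dm_dx_physician >= p$min_physician_dx
    }
    newly <- ok & !case
    path_id[newly] <- p$id
    case <- case | ok
  }
  tibble::tibble(patient_id = evidence$patient_id, case = case,
                 path = path_id)
}

#' Rule-based T2DM control screen
#'
#' A patient passes the control screen when all six conditions hold: at
#' least two in-person physician visits, at least one glucose measurement,
#' no abnormal glucose/HbA1c result, no diabetes-related diagnosis, no
#' diabetes medication or supplies order, and no self-reported family
#' history of diabetes.
#'
#' @param evidence Tibble from [extract_t2dm_evidence()].
#' @return Tibble with `patient_id` and `control` (logical).
#' @export
classify_t2dm_control <- function(evidence) {
  tibble::tibble(
    patient_id = evidence$patient_id,
    control = evidence$n_inperson_visits >= 2 &
      evidence$n_glucose_measures >= 1 &
      !evidence$has_abnormal_lab &
      !evidence$has_dm_related_dx &
      !evidence$has_dm_med_or_supplies &
      !evidence$family_history_dm
  )
}

#' Classify T2DM cases and controls in a view
#'
#' Composes the case decision tree and the control screen over one view.
#' A case call takes precedence over a control call; patients satisfying
#' neither are labelled `neither`.
#'
#' @param view A [make_view()] result.
#' @param codelists Code-list roles (see [extract_t2dm_evidence()]).
#' @param criteria A [lab_criteria()].
#' @param paths Case path specifications.
#' @return Tibble with `patient_id`, `label` (case/control/neither), `path`.
#' @export
classify_t2dm <- function(view, codelists = default_codelists(),
                          criteria = lab_criteria(),
                          paths = default_t2dm_paths()) {
  evidence <- extract_t2dm_evidence(view, codelists, criteria)
  cases <- classify_t2dm_case(evidence, paths)
  controls <- classify_t2dm_control(evidence)
  tibble::tibble(
    patient_id = evidence$patient_id,
    label = ifelse(cases$case, "case",
                   ifelse(controls$control, "control", "neither")),
    path = cases$path
  )
}
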
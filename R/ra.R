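#' RA scoring model
#'
#' The RA case definition scores each screen-positive patient with a
#' penalized-logistic-regression-style linear model over six record-level
#' features and declares a case when the probability reaches the cutoff.
#' The published algorithm fixes the cutoff at 0.632 (chosen for 97%
#' specificity at development time) but does not publish the fitted weights,
#' so the model here is a configuration artifact whose default weights obey
#' the documented sign structure: RA diagnoses and positive rheumatoid-factor
#' results carry positive weights; SLE diagnoses, psoriatic-arthritis (PA)
#' diagnoses and total encounter volume carry negative weights. Counts enter
#' through `log1p` by default to temper their skew.
#'
#' @param intercept Intercept on the logit scale.
#' @param weights Named numeric vector over the six feature names
#'   `n_ra_dx`, `n_sle_dx`, `n_pa_dx`, `n_rf_lab`, `n_rf_positive`,
#'   `n_encounters`.
#' @param transform Count transform applied before weighting: `"log1p"`
#'   (default) or `"raw"`.
#' @param cutoff Case probability cutoff in (0, 1); a patient scoring at or
#'   above it is a case.
#' @param check_signs Enforce the documented weight signs (default `TRUE`).
#' @return An object of class `ra_model`.
#' @export
ra_model <- function(intercept,
                     weights,
                     transform = c("log1p", "raw"),
                     cutoff = 0.632,
                     check_signs = TRUE) {
  transform <- match.arg(transform)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff >= 1) {
    abort("cutoff must lie strictly inside (0, 1)",
          class = "phenofrag_config_error")
  }
  missing_w <- setdiff(RA_FEATURES, names(weights))
  if (length(missing_w) > 0) {
    abort(paste0("model weights missing feature(s): ",
                 paste(missing_w, collapse = ", ")),
          class = "phenofrag_config_error")
  }
  extra_w <- setdiff(names(weights), RA_FEATURES)
  if (length(extra_w) > 0) {
    abort(paste0("model weights name unknown feature(s): ",
                 paste(extra_w, collapse = ", ")),
          class = "phenofrag_config_error")
  }
  if (check_signs) {
    ok <- weights["n_ra_dx"] > 0 && weights["n_rf_positive"] > 0 &&
      weights["n_sle_dx"] < 0 && weights["n_pa_dx"] < 0 &&
      weights["n_encounters"] < 0
    if (!ok) {
      abort(paste0(
        "weight signs violate the documented structure ",
        "(+RA dx, +positive RF; -SLE, -PA, -encounters)"
      ), class = "phenofrag_config_error")
    }
  }
  structure(
    list(intercept = as.numeric(intercept),
         weights = weights[RA_FEATURES],
         transform = transform,
         cutoff = cutoff),
    class = "ra_model"
  )
}

#' @noRd
RA_FEATURES <- c("n_ra_dx", "n_sle_dx", "n_pa_dx", "n_rf_lab",
                 "n_rf_positive", "n_encounters")

#' @rdname ra_model
#' @export
default_ra_model <- function() {
  ra_model(
    intercept = -4.2,
    weights = c(
      n_ra_dx = 2.2, n_sle_dx = -1.3, n_pa_dx = -1.1,
      n_rf_lab = 0.1, n_rf_positive = 1.4, n_encounters = -0.25
    ),
    transform = "log1p",
    cutoff = 0.632
  )
}

#' @export
print.ra_model <- function(x, ...) {
  cat(sprintf("<ra_model> cutoff %.3f, transform %s\n", x$cutoff, x$transform))
  cat(sprintf("  logit = %.3f + %s\n", x$intercept,
              paste(sprintf("%+.3f*%s(%s)", x$weights, x$transform,
                            names(x$weights)), collapse = " ")))
  invisible(x)
}

#' Read an RA model from YAML
#'
#' Expects top-level keys `intercept`, `weights` (map feature -> weight),
#' and optionally `transform` and `cutoff`.
#'
#' @param path YAML file path; defaults to the bundled model.
#' @return An `ra_model`.
#' @export
read_ra_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ra_model.yaml", package = "phenofrag")
  }
  if (!file.exists(path)) {
    abort(sprintf("RA model file not found: %s", path),
          class = "phenofrag_config_error")
  }
  raw <- yaml::read_yaml(path)
  ra_model(
    intercept = raw$intercept,
    weights = unlist(raw$weights),
    transform = raw$transform %||% "log1p",
    cutoff = raw$cutoff %||% 0.632
  )
}

#' RA inclusion (screen-positive) cohort
#'
#' The RA model scores only the screen-positive set: patients with at least
#' one RA diagnosis code visible in the view.
#'
#' @param view A [make_view()] result.
#' @param codelists Code-list roles (see [read_codelists()]); needs `ra_dx`.
#' @return Character vector of patient ids.
#' @export
ra_inclusion_cohort <- function(view, codelists = default_codelists()) {
  assert_view(view)
  hits <- match_codes(view$events, require_role(codelists, "ra_dx"),
                      event_types = "diagnosis")
  sort(unique(hits$patient_id))
}

#' Extract RA features for every patient in a view
#'
#' Counts, per patient: RA, SLE and PA diagnosis codes, rheumatoid-factor
#' lab tests, positive rheumatoid-factor results (value above
#' `rf_threshold`), and total encounters. Patients with no events get the
#' zero vector; the roster guarantees a row for every cohort patient.
#'
#' @param view A [make_view()] result.
#' @param codelists Code-list roles; needs `ra_dx`, `sle_dx`, `pa_dx`,
#'   `rf_lab`.
#' @param rf_threshold Rheumatoid-factor positivity threshold (IU/mL;
#'   default 14, configurable per lab).
#' @return Tibble with `patient_id` and the six feature counts.
#' @export
extract_ra_features <- function(view, codelists = default_codelists(),
                                rf_threshold = 14) {
  assert_view(view)
  ev <- view$events
  count_by_patient <- function(sub, name) {
    out <- dplyr::count(sub, .data$patient_id, name = name)
    out
  }
  rf <- match_codes(ev, require_role(codelists, "rf_lab"), event_types = "lab")
  parts <- list(
    count_by_patient(match_codes(ev, require_role(codelists, "ra_dx")), "n_ra_dx"),
    count_by_patient(match_codes(ev, require_role(codelists, "sle_dx")), "n_sle_dx"),
    count_by_patient(match_codes(ev, require_role(codelists, "pa_dx")), "n_pa_dx"),
    count_by_patient(rf, "n_rf_lab"),
    count_by_patient(rf[rf$value > rf_threshold, ], "n_rf_positive"),
    count_by_patient(ev[ev$event_type == "encounter", ], "n_encounters")
  )
  out <- tibble::tibble(patient_id = view$patients$patient_id)
  for (p in parts) out <- dplyr::left_join(out, p, by = "patient_id")
  out[RA_FEATURES] <- lapply(out[RA_FEATURES], function(x) {
    x[is.na(x)] <- 0L
    as.integer(x)
  })
  out
}

#' Score RA features with a logistic model
#'
#' Returns `logistic(intercept + sum_f w_f * t(x_f))` per patient, where `t`
#' is the model's count transform. The result is a probability strictly
#' inside (0, 1).
#'
#' @param features Tibble from [extract_ra_features()] (or any data frame
#'   with the six feature columns).
#' @param model An [ra_model()].
#' @return Numeric vector of probabilities along the rows of `features`.
#' @export
ra_score <- function(features, model = default_ra_model()) {
  missing_f <- setdiff(names(model$weights), names(features))
  if (length(missing_f) > 0) {
    abort(paste0("features lack column(s): ",
                 paste(missing_f, collapse = ", ")),
          class = "phenofrag_config_error")
  }
  tf <- switch(model$transform, log1p = log1p, raw = identity)
  eta <- rep(model$intercept, nrow(features))
  for (f in names(model$weights)) {
    eta <- eta + model$weights[[f]] * tf(as.numeric(features[[f]]))
  }
  1 / (1 + exp(-eta))
}

#' Classify RA cases and controls in a view
#'
#' Implements the full RA algorithm on one view:
#' * **case** — patient is in the inclusion cohort (>= 1 RA diagnosis code)
#'   and scores at or above the model cutoff (ties count as cases);
#' * **control** — patient has no RA diagnosis codes and no exclusion codes;
#' * **neither** — everyone else (screened-but-subthreshold patients, and
#'   unscreened patients carrying exclusion codes).
#'
#' The three labels partition every view's roster.
#'
#' @param view A [make_view()] result.
#' @param codelists Code-list roles; needs `ra_dx`, `ra_exclusion` plus the
#'   feature roles.
#' @param model An [ra_model()].
#' @param rf_threshold Passed to [extract_ra_features()].
#' @return Tibble with `patient_id`, `label` (case/control/neither),
#'   `probability` (NA for unscreened patients), `screened` (logical).
#' @export
classify_ra <- function(view, codelists = default_codelists(),
                        model = default_ra_model(), rf_threshold = 14) {
  assert_view(view)
  screened_ids <- ra_inclusion_cohort(view, codelists)
  excl <- match_codes(view$events, require_role(codelists, "ra_exclusion"),
                      event_types = "diagnosis")
  excluded_ids <- unique(excl$patient_id)

  feats <- extract_ra_features(view, codelists, rf_threshold)
  prob <- ra_score(feats, model)
  screened <- feats$patient_id %in% screened_ids

  label <- ifelse(
    screened & prob >= model$cutoff, "case",
    ifelse(!screened & !(feats$patient_id %in% excluded_ids),
           "control", "neither")
  )
  tibble::tibble(
    patient_id = feats$patient_id,
    label = label,
    probability = ifelse(screened, prob, NA_real_),
    screened = screened
  )
}
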
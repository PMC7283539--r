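#' Run a phenotype algorithm on a view
#'
#' Thin dispatcher over [classify_ra()] and [classify_t2dm()] returning the
#' per-patient call table (`patient_id`, `label`, provenance columns).
#'
#' @param view A [make_view()] result.
#' @param algorithm `"ra"` or `"t2dm"`.
#' @param codelists Code-list roles.
#' @param model RA scoring model (RA only).
#' @param criteria Lab criteria (T2DM only).
#' @param paths T2DM case paths (T2DM only).
#' @param rf_threshold Rheumatoid-factor positivity threshold (RA only).
#' @return Call tibble with a `label` column over the full roster.
#' @export
phenotype_calls <- function(view, algorithm = c("ra", "t2dm"),
                            codelists = default_codelists(),
                            model = default_ra_model(),
                            criteria = lab_criteria(),
                            paths = default_t2dm_paths(),
                            rf_threshold = 14) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "ra") {
    classify_ra(view, codelists, model, rf_threshold)
  } else {
    classify_t2dm(view, codelists, criteria, paths)
  }
}

#' Benchmark calls from the union view
#'
#' The evaluation has no chart-reviewed gold standard; the benchmark is the
#' algorithm's own output on the deduplicated union of all sources, so that
#' single-source errors isolate the effect of fragmentation. Refuses any
#' view that does not span every known source.
#'
#' @inheritParams phenotype_calls
#' @return Call tibble with attribute `benchmark = TRUE`.
#' @export
benchmark_calls <- function(view, algorithm = c("ra", "t2dm"),
                            codelists = default_codelists(),
                            model = default_ra_model(),
                            criteria = lab_criteria(),
                            paths = default_t2dm_paths(),
                            rf_threshold = 14) {
  assert_view(view)
  if (!view$is_union) {
    abort(sprintf(
      "benchmark requires the union view over all sources (%s); got '%s'",
      paste(view$all_sources, collapse = "+"), view$label
    ), class = "phenofrag_arg_error")
  }
  calls <- phenotype_calls(view, algorithm, codelists, model, criteria,
                           paths, rf_threshold)
  attr(calls, "benchmark") <- TRUE
  calls
}

#' Confusion counts against the benchmark
#'
#' Over the fixed cohort universe: TP are patients the source and benchmark
#' both assign the target label, FP are source-only, FN benchmark-only, and
#' TN everyone else — so the four counts always sum to the roster size.
#'
#' @param source_calls,benchmark_calls Call tibbles over the same roster.
#' @param target `"case"` or `"control"`.
#' @return One-row tibble: `target`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(source_calls, benchmark_calls,
                      target = c("case", "control")) {
  target <- match.arg(target)
  if (nrow(source_calls) != nrow(benchmark_calls) ||
      !setequal(source_calls$patient_id, benchmark_calls$patient_id)) {
    abort("source and benchmark calls cover different rosters",
          class = "phenofrag_arg_error")
  }
  s <- source_calls$patient_id[source_calls$label == target]
  b <- benchmark_calls$patient_id[benchmark_calls$label == target]
  tp <- length(intersect(s, b))
  fp <- length(setdiff(s, b))
  fn <- length(setdiff(b, s))
  tn <- nrow(source_calls) - tp - fp - fn
  tibble::tibble(target = target, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Performance metrics from confusion counts
#'
#' Computes, as raw (unrounded) percentages:
#' sensitivity `100*TP/(TP+FN)`, specificity `100*TN/(FP+TN)`,
#' PPV `100*TP/(TP+FP)`, and false-negative rate `100*FN/(TP+FN)`.
#' A zero denominator yields `NA` for that metric with a warning, never an
#' error. Rounding (half-up) happens only at report time.
#'
#' @param counts Data frame with columns `tp`, `fp`, `tn`, `fn` (any number
#'   of rows), or a numeric vector `c(tp, fp, tn, fn)`.
#' @return Tibble with columns `sensitivity`, `specificity`, `ppv`, `fnr`
#'   alongside the input counts.
#' @export
compute_metrics <- function(counts) {
  if (is.numeric(counts) && is.null(dim(counts))) {
    counts <- tibble::tibble(tp = counts[1], fp = counts[2],
                             tn = counts[3], fn = counts[4])
  }
  counts <- tibble::as_tibble(counts)
  safe_pct <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warn(sprintf("%s undefined (zero denominator) for %d row(s)",
                   what, sum(bad)))
    }
    ifelse(bad, NA_real_, 100 * num / den)
  }
  counts$sensitivity <- safe_pct(counts$tp, counts$tp + counts$fn, "sensitivity")
  counts$specificity <- safe_pct(counts$tn, counts$fp + counts$tn, "specificity")
  counts$ppv <- safe_pct(counts$tp, counts$tp + counts$fp, "PPV")
  counts$fnr <- safe_pct(counts$fn, counts$tp + counts$fn, "FNR")
  counts
}

#' @noRd
ra_factor_presence <- function(features) {
  tibble::tibble(
    patient_id = features$patient_id,
    ra_dx = features$n_ra_dx >= 1,
    pa_dx = features$n_pa_dx >= 1,
    sle_dx = features$n_sle_dx >= 1,
    rf_lab = features$n_rf_lab >= 1
  )
}

#' @noRd
t2dm_case_factor_presence <- function(evidence) {
  tibble::tibble(
    patient_id = evidence$patient_id,
    t1dm_dx = evidence$n_t1dm_dx >= 1,
    t2dm_dx = evidence$n_t2dm_dx >= 1,
    t1dm_med = evidence$has_t1dm_med,
    t2dm_med = evidence$has_t2dm_med,
    abnormal_lab = evidence$has_abnormal_lab,
    t2dm_dx_physician = evidence$n_t2dm_dx_physician >= 1
  )
}

#' @noRd
t2dm_control_factor_presence <- function(evidence) {
  tibble::tibble(
    patient_id = evidence$patient_id,
    inperson_visits_ge2 = evidence$n_inperson_visits >= 2,
    glucose_measure_ge1 = evidence$n_glucose_measures >= 1,
    abnormal_lab = evidence$has_abnormal_lab,
    dm_related_dx = evidence$has_dm_related_dx,
    dm_med_or_supplies = evidence$has_dm_med_or_supplies,
    family_history_dm = evidence$family_history_dm
  )
}

#' @noRd
ra_control_factor_presence <- function(view, codelists) {
  dx <- match_codes(view$events, require_role(codelists, "ra_dx"), "diagnosis")
  excl <- match_codes(view$events, require_role(codelists, "ra_exclusion"),
                      "diagnosis")
  tibble::tibble(
    patient_id = view$patients$patient_id,
    ra_dx = view$patients$patient_id %in% dx$patient_id,
    ra_exclusion = view$patients$patient_id %in% excl$patient_id
  )
}

#' Attribute phenotyping errors to missing information
#'
#' For a set of error subjects (FN or FP against the union benchmark),
#' counts how many lack each algorithm factor in the erring source view
#' despite its presence in the union view — the mechanism by which
#' fragmentation masks cases and manufactures spurious controls. Factor
#' sets follow each algorithm's evidence model: for RA cases, the four
#' patient-level presence factors (RA, PA, SLE diagnosis codes; rheumatoid
#' factor labs) plus the total encounter-count shortfall; for T2DM cases,
#' the six decision-tree factors; for T2DM controls, the six screen
#' conditions; for RA controls, RA-diagnosis and exclusion-code presence.
#'
#' The per-patient table additionally records `any_missing`: whether *any*
#' component of the patient's evidence vector (including raw counts) is
#' smaller in the source than in the union — on monotone event accrual this
#' is guaranteed for every genuine error, so `all(per_patient$any_missing)`
#' is the attribution-completeness check.
#'
#' @param error_ids Patient ids of the error subjects.
#' @param source_view,union_view The erring single-source view and the union
#'   benchmark view.
#' @param algorithm `"ra"` or `"t2dm"`.
#' @param target `"case"` or `"control"`.
#' @param error_type `"FN"` or `"FP"` (annotation only).
#' @param codelists Code-list roles.
#' @param criteria Lab criteria (T2DM).
#' @param rf_threshold RF positivity threshold (RA).
#' @return List with `table` (one summary row: error type, source, totals,
#'   one count per factor, and `missing_encounters` for RA cases) and
#'   `per_patient` (per-subject factor indicators plus `any_missing`).
#' @export
attribute_missing_info <- function(error_ids, source_view, union_view,
                                   algorithm = c("ra", "t2dm"),
                                   target = c("case", "control"),
                                   error_type = c("FN", "FP"),
                                   codelists = default_codelists(),
                                   criteria = lab_criteria(),
                                   rf_threshold = 14) {
  algorithm <- match.arg(algorithm)
  target <- match.arg(target)
  error_type <- match.arg(error_type)
  assert_view(source_view)
  assert_view(union_view)
  roster <- union_view$patients$patient_id
  if (!all(error_ids %in% roster)) {
    abort("error subjects outside the cohort roster",
          class = "phenofrag_arg_error")
  }

  if (algorithm == "ra") {
    feats_u <- extract_ra_features(union_view, codelists, rf_threshold)
    feats_s <- extract_ra_features(source_view, codelists, rf_threshold)
    if (target == "case") {
      pres_u <- ra_factor_presence(feats_u)
      pres_s <- ra_factor_presence(feats_s)
    } else {
      pres_u <- ra_control_factor_presence(union_view, codelists)
      pres_s <- ra_control_factor_presence(source_view, codelists)
    }
    num_u <- feats_u
    num_s <- feats_s
    enc_short <- setNames(
      pmax(feats_u$n_encounters - feats_s$n_encounters, 0L),
      feats_u$patient_id
    )
  } else {
    evid_u <- extract_t2dm_evidence(union_view, codelists, criteria)
    evid_s <- extract_t2dm_evidence(source_view, codelists, criteria)
    pres_u <- if (target == "case") {
      t2dm_case_factor_presence(evid_u)
    } else {
      t2dm_control_factor_presence(evid_u)
    }
    pres_s <- if (target == "case") {
      t2dm_case_factor_presence(evid_s)
    } else {
      t2dm_control_factor_presence(evid_s)
    }
    num_u <- evid_u
    num_s <- evid_s
    enc_short <- NULL
  }

  sel <- match(error_ids, roster)
  factors <- setdiff(names(pres_u), "patient_id")
  per_patient <- tibble::tibble(patient_id = error_ids)
  for (f in factors) {
    per_patient[[f]] <- pres_u[[f]][sel] & !pres_s[[f]][sel]
  }

  # full evidence diff: any component smaller/weaker in the source view,
  # including presence factors outside the numeric evidence (e.g. RA
  # exclusion codes, which gate controls but are not model features)
  diff_tbls <- list(num = list(u = num_u, s = num_s),
                    pres = list(u = pres_u, s = pres_s))
  any_missing <- rep(FALSE, length(error_ids))
  for (pair in diff_tbls) for (col in setdiff(names(pair$u), "patient_id")) {
    u <- pair$u[[col]][sel]
    s <- pair$s[[col]][sel]
    d <- if (is.logical(u)) {
      (u & !s) | (is.na(s) != is.na(u)) |
        (!is.na(u) & !is.na(s) & u != s)
    } else if (is.numeric(u)) {
      u > s
    } else {
      rep(FALSE, length(u))
    }
    d[is.na(d)] <- FALSE
    any_missing <- any_missing | d
  }
  per_patient$any_missing <- any_missing

  table <- tibble::tibble(
    algorithm = algorithm, target = target, error_type = error_type,
    source = source_view$label, total_subjects = length(error_ids)
  )
  for (f in factors) table[[f]] <- sum(per_patient[[f]])
  if (algorithm == "ra" && target == "case") {
    table$missing_encounters <- sum(enc_short[error_ids])
  }
  list(table = table, per_patient = per_patient)
}

#' Run the full fragmentation experiment
#'
#' Orchestrates the whole evaluation on one cohort: builds the union
#' benchmark view and each single-source view, runs the requested phenotype
#' algorithms on every view, and produces
#'
#' * `counts` — cases/controls identified per algorithm and view;
#' * `metrics` — confusion counts and sensitivity/specificity/PPV/FNR of
#'   each view against the union benchmark, for both targets;
#' * `missing_info` — missing-information attribution for every FN/FP set
#'   of every single-source view;
#' * `ra_probabilities` — RA model probability of every benchmark RA case
#'   under every view (computed from each view's feature vector whether or
#'   not the patient screens in there);
#' * `calls` — the raw per-view call tables.
#'
#' @param cohort A `sim_cohort` (or any list with `events` and `patients`).
#' @param sources Sources to evaluate; defaults to the cohort config's
#'   sources (or all sources present in the events).
#' @param algorithms Subset of `c("ra", "t2dm")`.
#' @param codelists,model,criteria,paths,rf_threshold Algorithm
#'   configuration, as in [phenotype_calls()].
#' @return An object of class `phenofrag_report`.
#' @export
run_experiment <- function(cohort,
                           sources = NULL,
                           algorithms = c("ra", "t2dm"),
                           codelists = default_codelists(),
                           model = default_ra_model(),
                           criteria = lab_criteria(),
                           paths = default_t2dm_paths(),
                           rf_threshold = 14) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (is.null(sources)) {
    sources <- if (!is.null(cohort$config)) {
      cohort$config$sources
    } else {
      sort(unique(cohort$events$source_id))
    }
  }
  if (length(sources) < 2) {
    abort("fragmentation evaluation needs at least 2 sources",
          class = "phenofrag_arg_error")
  }
  events <- cohort$events
  patients <- cohort$patients

  union_view <- make_view(events, patients, sources, all_sources = sources)
  single_views <- lapply(sources, function(s) {
    make_view(events, patients, s, all_sources = sources)
  })
  names(single_views) <- sources
  views <- c(setNames(list(union_view), union_view$label), single_views)

  counts <- list()
  metrics <- list()
  missing <- list()
  missing_pp <- list()
  calls <- list()
  ra_probs <- NULL

  for (alg in algorithms) {
    alg_calls <- lapply(views, phenotype_calls, algorithm = alg,
                        codelists = codelists, model = model,
                        criteria = criteria, paths = paths,
                        rf_threshold = rf_threshold)
    bench <- alg_calls[[union_view$label]]
    for (v in names(alg_calls)) {
      calls[[paste(alg, v)]] <- tibble::tibble(
        algorithm = alg, view = v, alg_calls[[v]]
      )
      for (tgt in c("case", "control")) {
        counts[[paste(alg, v, tgt)]] <- tibble::tibble(
          algorithm = alg, target = tgt, view = v,
          n_called = sum(alg_calls[[v]]$label == tgt)
        )
        cf <- confusion(alg_calls[[v]], bench, tgt)
        metrics[[paste(alg, v, tgt)]] <- tibble::tibble(
          algorithm = alg, view = v,
          suppressWarnings(compute_metrics(cf))
        )
      }
    }
    for (s in sources) {
      sc <- alg_calls[[s]]
      for (tgt in c("case", "control")) {
        b_ids <- bench$patient_id[bench$label == tgt]
        s_ids <- sc$patient_id[sc$label == tgt]
        err_sets <- list(FN = setdiff(b_ids, s_ids),
                         FP = setdiff(s_ids, b_ids))
        for (et in names(err_sets)) {
          att <- attribute_missing_info(
            err_sets[[et]], single_views[[s]], union_view,
            algorithm = alg, target = tgt, error_type = et,
            codelists = codelists, criteria = criteria,
            rf_threshold = rf_threshold
          )
          key <- paste(alg, tgt, s, et)
          missing[[key]] <- att$table
          missing_pp[[key]] <- tibble::tibble(
            algorithm = alg, target = tgt, error_type = et, source = s,
            att$per_patient
          )
        }
      }
    }
    if (alg == "ra") {
      case_ids <- bench$patient_id[bench$label == "case"]
      probs <- lapply(names(views), function(v) {
        feats <- extract_ra_features(views[[v]], codelists, rf_threshold)
        p <- ra_score(feats, model)
        tibble::tibble(patient_id = feats$patient_id, view = v,
                       probability = p)[feats$patient_id %in% case_ids, ]
      })
      ra_probs <- dplyr::bind_rows(probs)
    }
  }

  structure(
    list(
      sources = sources,
      union_label = union_view$label,
      algorithms = algorithms,
      n_patients = nrow(patients),
      counts = dplyr::bind_rows(counts),
      metrics = dplyr::bind_rows(metrics),
      missing_info = dplyr::bind_rows(missing),
      missing_info_patients = dplyr::bind_rows(missing_pp),
      ra_probabilities = ra_probs,
      calls = dplyr::bind_rows(calls)
    ),
    class = "phenofrag_report"
  )
}

#' @export
print.phenofrag_report <- function(x, ...) {
  cat(sprintf(
    "<phenofrag_report> %d patients, benchmark %s, algorithms: %s\n",
    x$n_patients, x$union_label, paste(x$algorithms, collapse = ", ")
  ))
  m <- x$metrics[x$metrics$view != x$union_label, ]
  if (nrow(m) > 0) {
    cat("  single-source performance vs union benchmark (FNR %):\n")
    for (i in seq_len(nrow(m))) {
      cat(sprintf("    %-5s %-8s %-6s FNR %5.1f  PPV %5.1f\n",
                  m$algorithm[i], m$target[i], m$view[i],
                  m$fnr[i], m$ppv[i]))
    }
  }
  invisible(x)
}
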
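# Builders for hand-constructed event tables used across tests.

mk_events <- function(pid, type = "diagnosis", system = "ICD9CM",
                      code = "714.0", value = NA_real_, date = "2012-06-01",
                      source = "Mayo", mode = "billing", key = NULL) {
  n <- max(lengths(list(pid, type, system, code, value, date, source, mode,
                        key)))
  if (is.null(key)) key <- sprintf("k%03d", seq_len(n))
  clinical_events(
    patient_id = rep_len(pid, n), event_type = rep_len(type, n),
    code_system = rep_len(system, n), code = rep_len(code, n),
    value = rep_len(value, n), date = rep_len(date, n),
    source_id = rep_len(source, n), entry_mode = rep_len(mode, n),
    linkage_key = rep_len(key, n)
  )
}

mk_patients <- function(ids, famhx = FALSE) {
  tibble::tibble(patient_id = ids,
                 family_history_dm = rep_len(famhx, length(ids)))
}

# small simulated cohort with both algorithms' evidence
sim_small <- function(n = 300, seed = 7, ...) {
  generate_cohort(sim_config(n_patients = n, seed = seed, ...))
}

both_views <- function(cohort) {
  srcs <- cohort$config$sources
  v <- lapply(srcs, function(s) {
    make_view(cohort$events, cohort$patients, s, all_sources = srcs)
  })
  names(v) <- srcs
  v$union <- make_view(cohort$events, cohort$patients, srcs,
                       all_sources = srcs)
  v
}
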
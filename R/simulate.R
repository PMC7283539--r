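#' Default per-status event-rate parameters
#'
#' Event counts per patient are drawn as `min + Poisson(lambda)` per
#' category; presence probabilities gate optional categories. The defaults
#' emulate a biobank cohort whose clinical activity is split between a local
#' EHR and a regional record-linkage system: disease-positive patients carry
#' a small number of decisive events per evidence category (one or two
#' medication orders, a handful of diagnosis codes), so that a source
#' institution needs to see most of a patient's record before the phenotype
#' algorithms fire — the regime in which fragmentation causes the
#' false-negative behaviour under study.
#'
#' @return A nested list of rate parameters; see the named entries.
#' @export
default_event_rates <- function() {
  list(
    # regression-scored RA phenotype
    ra_case_dx = list(min = 7L, lambda = 2),      # RA diagnosis codes, cases
    ra_bg_dx_prob = 0.035,                        # screen-positive non-cases
    ra_bg_dx = list(min = 1L, lambda = 0.5),
    ra_confuser_count = list(min = 1L, lambda = 1),  # SLE/PA when miscoded
    sle_bg_lambda = 0.004,
    pa_bg_lambda = 0.004,
    spond_bg_lambda = 0.004,                      # exclusion-only noise
    rf_case = list(min = 1L, lambda = 0.6),       # rheumatoid-factor labs
    rf_case_pos_prob = 0.95,
    rf_bg_lambda = 0.05,
    rf_bg_pos_prob = 0.10,
    # encounters (shared by both algorithms)
    enc_t2dm_case = list(min = 3L, lambda = 8),
    enc_t2dm_control = list(min = 2L, lambda = 6),
    enc_neither = list(min = 0L, lambda = 6),
    inperson_prob = 0.9,
    # rule-based T2DM phenotype
    t2dm_med_path_prob = 0.85,                    # case archetype: dx + med
    t2dm_case_dx = list(min = 1L, lambda = 0.5),
    t2dm_case_med = list(min = 1L, lambda = 0.2),
    t2dm_case_nlp_dx_lambda = 0.3,                # physician/NLP diagnoses
    t2dm_case_abnormal_prob = 0.4,                # med-path lab abnormality
    t2dm_labpath_abnormal_prob = 0.95,            # lab-path must show labs
    t2dm_case_glucose = list(min = 1L, lambda = 0.5),
    t2dm_case_hba1c_lambda = 0.4,
    t2dm_case_supplies_prob = 0.3,
    t2dm_bg_dx_prob = 0.01,                       # stray diabetes codes
    neither_dm_related_prob = 0.10,               # prediabetes-style findings
    neither_supplies_prob = 0.02,
    control_glucose = list(min = 1L, lambda = 1),
    neither_glucose_lambda = 0.15,
    # self-reported family history of diabetes
    famhx_case_prob = 0.35,
    famhx_neither_prob = 0.20
  )
}

#' Default lab-value distributions
#'
#' Log-normal value distributions for diseased versus healthy draws of each
#' lab analyte, on the clinical scales used by the abnormality criteria
#' (glucose in mg/dL, HbA1c in percent, rheumatoid factor in IU/mL).
#'
#' @return A nested list of `c(meanlog, sdlog)` pairs.
#' @export
default_lab_value_params <- function() {
  list(
    fasting = list(abnormal = c(log(160), 0.20), normal = c(log(92), 0.12)),
    random = list(abnormal = c(log(230), 0.20), normal = c(log(115), 0.15)),
    hba1c = list(abnormal = c(log(7.8), 0.15), normal = c(log(5.4), 0.08)),
    rf = list(positive = c(log(60), 0.40), negative = c(log(6), 0.40))
  )
}

#' Simulation configuration
#'
#' Declares the study conditions for a synthetic multi-institution cohort:
#' cohort size, disease prevalences, the 2010–2017 observation window, the
#' participating sources, and the fragmentation model. Fragmentation has two
#' dials: each patient has a home source and a per-patient probability
#' `p_home` (Beta-distributed across patients) that any given event is
#' recorded at home rather than away, and each recorded event is additionally
#' captured by each other source with an origin-specific
#' `duplication_rate`. The default capture rates are asymmetric
#' (`Mayo = 0.95`, `REP = 0.20`): the regional record-linkage source sees
#' nearly all local events, the local EHR sees few regional ones.
#'
#' Default prevalences reproduce the benchmark proportions of a 45,183
#' patient biobank cohort with 620 RA cases, 5,215 T2DM cases and 6,293
#' T2DM-control-eligible patients.
#'
#' @param n_patients Cohort size (positive integer).
#' @param seed Master RNG seed; all randomness derives from it.
#' @param window_start,window_end Observation window (closed interval).
#' @param sources Source institution ids (at least 2 for fragmentation).
#' @param home_probs Probability a patient's home is each source.
#' @param prevalence_ra Latent RA prevalence.
#' @param prevalence_t2dm Latent T2DM case prevalence.
#' @param prevalence_t2dm_control Latent T2DM control-eligible prevalence.
#' @param p_home_mean,p_home_concentration Mean and Beta concentration of
#'   the per-patient home-source affinity; `Inf` concentration makes
#'   `p_home` constant at the mean.
#' @param duplication_rate Probability an event recorded by one source is
#'   also captured by each other source, named by origin source (a scalar is
#'   recycled).
#' @param miscoding_rate Probability a diseased patient carries confuser
#'   codes (SLE/PA for RA cases; type 1 diabetes codes for T2DM cases).
#' @param event_rates See [default_event_rates()]; partial lists are merged
#'   over the defaults.
#' @param lab_value_params See [default_lab_value_params()]; merged likewise.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       window_start = as.Date("2010-01-01"),
                       window_end = as.Date("2017-12-31"),
                       sources = c("Mayo", "REP"),
                       home_probs = c(0.7, 0.3),
                       prevalence_ra = 620 / 45183,
                       prevalence_t2dm = 5215 / 45183,
                       prevalence_t2dm_control = 6293 / 45183,
                       p_home_mean = 0.8,
                       p_home_concentration = 15,
                       duplication_rate = c(Mayo = 0.95, REP = 0.20),
                       miscoding_rate = 0.05,
                       event_rates = list(),
                       lab_value_params = list()) {
  chk_prob <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      abort(sprintf("%s must lie in [0, 1]", what),
            class = "phenofrag_config_error")
    }
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    abort("n_patients must be a positive integer",
          class = "phenofrag_config_error")
  }
  if (length(sources) < 1 || anyDuplicated(sources)) {
    abort("sources must be distinct and non-empty",
          class = "phenofrag_config_error")
  }
  if (length(home_probs) != length(sources)) {
    abort("home_probs must align with sources",
          class = "phenofrag_config_error")
  }
  chk_prob(prevalence_ra, "prevalence_ra")
  chk_prob(prevalence_t2dm, "prevalence_t2dm")
  chk_prob(prevalence_t2dm_control, "prevalence_t2dm_control")
  if (prevalence_t2dm + prevalence_t2dm_control > 1) {
    abort("T2DM case + control prevalences exceed 1",
          class = "phenofrag_config_error")
  }
  chk_prob(p_home_mean, "p_home_mean")
  chk_prob(miscoding_rate, "miscoding_rate")
  if (length(duplication_rate) == 1 && is.null(names(duplication_rate))) {
    duplication_rate <- setNames(rep(duplication_rate, length(sources)), sources)
  }
  if (!all(sources %in% names(duplication_rate))) {
    abort("duplication_rate must be named for every source (or scalar)",
          class = "phenofrag_config_error")
  }
  chk_prob(duplication_rate, "duplication_rate")
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (is.na(window_start) || is.na(window_end) || window_start > window_end) {
    abort("invalid simulation window", class = "phenofrag_config_error")
  }
  rates <- modifyList(default_event_rates(), event_rates)
  labs <- modifyList(default_lab_value_params(), lab_value_params)

  structure(
    list(
      n_patients = as.integer(n_patients),
      seed = as.integer(seed),
      window_start = window_start,
      window_end = window_end,
      sources = as.character(sources),
      home_probs = home_probs / sum(home_probs),
      prevalence_ra = prevalence_ra,
      prevalence_t2dm = prevalence_t2dm,
      prevalence_t2dm_control = prevalence_t2dm_control,
      p_home_mean = p_home_mean,
      p_home_concentration = p_home_concentration,
      duplication_rate = duplication_rate[sources],
      miscoding_rate = miscoding_rate,
      event_rates = rates,
      lab_value_params = labs
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d patients, seed %d, sources %s, window %s..%s\n",
    x$n_patients, x$seed, paste(x$sources, collapse = "/"),
    format(x$window_start), format(x$window_end)
  ))
  cat(sprintf(
    "  prevalences: RA %.4f, T2DM case %.4f, T2DM control %.4f\n",
    x$prevalence_ra, x$prevalence_t2dm, x$prevalence_t2dm_control
  ))
  cat(sprintf(
    "  p_home mean %.2f (conc %s), duplication %s\n",
    x$p_home_mean, format(x$p_home_concentration),
    paste(sprintf("%s=%.2f", names(x$duplication_rate), x$duplication_rate),
          collapse = ", ")
  ))
  invisible(x)
}

# `min + Poisson(lambda)` count draw; spec may be NULL for none
#' @noRd
draw_count <- function(n, spec) {
  if (n == 0) return(integer(0))
  spec$min + rpois(n, spec$lambda)
}

#' @noRd
rln <- function(n, p) rlnorm(n, p[1], p[2])

#' Generate a synthetic fragmented cohort
#'
#' Draws latent disease status per patient, generates the event streams each
#' status implies, and fragments them across the configured sources: each
#' event is recorded by the patient's home source with probability `p_home`
#' (else by a random other source), then independently captured by every
#' other source with that origin's `duplication_rate`. Cross-source copies
#' of an event share a `linkage_key`, so union views deduplicate them.
#' Latent status is returned in a separate truth table and never appears in
#' the event or patient tables.
#'
#' Output is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_cohort`: list with `patients`, `events`,
#'   `truth` tibbles and the resolved `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("config must be a sim_config", class = "phenofrag_config_error")
  }
  set.seed(config$seed)
  n <- config$n_patients
  r <- config$event_rates
  lv <- config$lab_value_params
  pid <- sprintf("P%06d", seq_len(n))

  # latent truth ------------------------------------------------------------
  ra <- runif(n) < config$prevalence_ra
  u <- runif(n)
  t2dm <- ifelse(
    u < config$prevalence_t2dm, "case",
    ifelse(u < config$prevalence_t2dm + config$prevalence_t2dm_control,
           "control_eligible", "neither")
  )
  famhx <- (t2dm == "case" & runif(n) < r$famhx_case_prob) |
    (t2dm == "neither" & runif(n) < r$famhx_neither_prob)

  # per-patient fragmentation parameters ------------------------------------
  home <- sample(config$sources, n, replace = TRUE, prob = config$home_probs)
  p_home <- if (is.infinite(config$p_home_concentration)) {
    rep(config$p_home_mean, n)
  } else if (config$p_home_mean %in% c(0, 1)) {
    rep(config$p_home_mean, n)
  } else {
    rbeta(n,
          config$p_home_mean * config$p_home_concentration,
          (1 - config$p_home_mean) * config$p_home_concentration)
  }

  # event blocks -------------------------------------------------------------
  blocks <- list()
  add_block <- function(idx, event_type, code_system, code, value, entry_mode) {
    if (length(idx) == 0) return(invisible(NULL))
    blocks[[length(blocks) + 1L]] <<- tibble::tibble(
      idx = idx, event_type = event_type, code_system = code_system,
      code = code, value = value, entry_mode = entry_mode
    )
    invisible(NULL)
  }
  pool_draw <- function(k, codes, systems) {
    j <- sample.int(length(codes), k, replace = TRUE)
    list(code = codes[j], system = systems[j])
  }

  # --- RA diagnosis codes
  ra_counts <- integer(n)
  ra_counts[ra] <- draw_count(sum(ra), r$ra_case_dx)
  bg_scr <- !ra & runif(n) < r$ra_bg_dx_prob
  ra_counts[bg_scr] <- draw_count(sum(bg_scr), r$ra_bg_dx)
  idx <- rep(seq_len(n), ra_counts)
  p <- pool_draw(length(idx), c("714.0", "714.81", "M05.79", "M06.09"),
                 c("ICD9CM", "ICD9CM", "ICD10CM", "ICD10CM"))
  add_block(idx, "diagnosis", p$system, p$code, NA_real_, "billing")

  # --- SLE / PA confusers (miscoded RA cases) + background, spondylitis noise
  ra_misc <- ra & runif(n) < config$miscoding_rate
  conf_sle <- ra_misc & runif(n) < 0.5
  conf_pa <- ra_misc & !conf_sle
  sle_counts <- rpois(n, r$sle_bg_lambda)
  sle_counts[conf_sle] <- sle_counts[conf_sle] +
    draw_count(sum(conf_sle), r$ra_confuser_count)
  idx <- rep(seq_len(n), sle_counts)
  p <- pool_draw(length(idx), c("710.0", "M32.9"), c("ICD9CM", "ICD10CM"))
  add_block(idx, "diagnosis", p$system, p$code, NA_real_, "billing")

  pa_counts <- rpois(n, r$pa_bg_lambda)
  pa_counts[conf_pa] <- pa_counts[conf_pa] +
    draw_count(sum(conf_pa), r$ra_confuser_count)
  idx <- rep(seq_len(n), pa_counts)
  p <- pool_draw(length(idx), c("696.0", "L40.52"), c("ICD9CM", "ICD10CM"))
  add_block(idx, "diagnosis", p$system, p$code, NA_real_, "billing")

  idx <- rep(seq_len(n), rpois(n, r$spond_bg_lambda))
  p <- pool_draw(length(idx), c("720.0", "M45.9"), c("ICD9CM", "ICD10CM"))
  add_block(idx, "diagnosis", p$system, p$code, NA_real_, "billing")

  # --- rheumatoid-factor labs
  rf_counts <- rpois(n, r$rf_bg_lambda)
  rf_counts[ra] <- draw_count(sum(ra), r$rf_case)
  idx <- rep(seq_len(n), rf_counts)
  pos_prob <- ifelse(ra[idx], r$rf_case_pos_prob, r$rf_bg_pos_prob)
  pos <- runif(length(idx)) < pos_prob
  val <- numeric(length(idx))
  val[pos] <- rln(sum(pos), lv$rf$positive)
  val[!pos] <- rln(sum(!pos), lv$rf$negative)
  add_block(idx, "lab", "LAB", "RF", val, "billing")

  # --- encounters
  enc_counts <- integer(n)
  enc_counts[t2dm == "case"] <- draw_count(sum(t2dm == "case"), r$enc_t2dm_case)
  enc_counts[t2dm == "control_eligible"] <-
    draw_count(sum(t2dm == "control_eligible"), r$enc_t2dm_control)
  enc_counts[t2dm == "neither"] <- draw_count(sum(t2dm == "neither"), r$enc_neither)
  idx <- rep(seq_len(n), enc_counts)
  inperson <- runif(length(idx)) < r$inperson_prob
  add_block(idx, "encounter", "NONE", ifelse(inperson, "INPERSON", "REMOTE"),
            NA_real_, "billing")

  # --- T2DM diagnoses, medications, supplies
  t2 <- t2dm == "case"
  med_path <- t2 & runif(n) < r$t2dm_med_path_prob
  lab_path <- t2 & !med_path

  t2dx_counts <- integer(n)
  t2dx_counts[t2] <- draw_count(sum(t2), r$t2dm_case_dx)
  bg_dx <- t2dm == "neither" & runif(n) < r$t2dm_bg_dx_prob
  t2dx_counts[bg_dx] <- 1L
  idx <- rep(seq_len(n), t2dx_counts)
  p <- pool_draw(length(idx), c("250.00", "250.02", "E11.9", "E11.65"),
                 c("ICD9CM", "ICD9CM", "ICD10CM", "ICD10CM"))
  add_block(idx, "diagnosis", p$system, p$code, NA_real_, "billing")

  idx <- rep(seq_len(n), ifelse(t2, rpois(n, r$t2dm_case_nlp_dx_lambda), 0L))
  p <- pool_draw(length(idx), c("250.00", "E11.9"), c("ICD9CM", "ICD10CM"))
  add_block(idx, "nlp_diagnosis", p$system, p$code, NA_real_, "nlp")

  med_counts <- integer(n)
  med_counts[med_path] <- draw_count(sum(med_path), r$t2dm_case_med)
  idx <- rep(seq_len(n), med_counts)
  p <- pool_draw(length(idx), c("METFORMIN", "GLIPIZIDE", "PIOGLITAZONE"),
                 c("MED", "MED", "MED"))
  add_block(idx, "medication", p$system, p$code, NA_real_, "billing")

  sup <- (t2 & runif(n) < r$t2dm_case_supplies_prob) |
    (t2dm == "neither" & runif(n) < r$neither_supplies_prob)
  idx <- which(sup)
  p <- pool_draw(length(idx), c("TEST-STRIPS", "LANCETS"), c("MED", "MED"))
  add_block(idx, "medication", p$system, p$code, NA_real_, "billing")

  # miscoded T2DM cases carry type 1 diabetes codes (and sometimes insulin)
  t1_misc <- t2 & runif(n) < config$miscoding_rate
  idx <- which(t1_misc)
  p <- pool_draw(length(idx), c("250.01", "E10.9"), c("ICD9CM", "ICD10CM"))
  add_block(idx, "diagnosis", p$system, p$code, NA_real_, "billing")
  t1_med <- t1_misc & runif(n) < 0.5
  idx <- which(t1_med)
  p <- pool_draw(length(idx), c("INSULIN-GLARGINE", "INSULIN-LISPRO"),
                 c("MED", "MED"))
  add_block(idx, "medication", p$system, p$code, NA_real_, "billing")

  # prediabetes-style findings disqualifying controls
  dmrel <- t2dm == "neither" & runif(n) < r$neither_dm_related_prob
  idx <- which(dmrel)
  p <- pool_draw(length(idx), c("R73.03", "790.29"), c("ICD10CM", "ICD9CM"))
  add_block(idx, "diagnosis", p$system, p$code, NA_real_, "billing")

  # --- glucose and HbA1c labs
  glu_counts <- integer(n)
  glu_counts[t2] <- draw_count(sum(t2), r$t2dm_case_glucose)
  ctrl <- t2dm == "control_eligible"
  glu_counts[ctrl] <- draw_count(sum(ctrl), r$control_glucose)
  nei <- t2dm == "neither"
  glu_counts[nei] <- rpois(sum(nei), r$neither_glucose_lambda)
  idx <- rep(seq_len(n), glu_counts)
  abn_prob <- rep(0, n)
  abn_prob[med_path] <- r$t2dm_case_abnormal_prob
  abn_prob[lab_path] <- r$t2dm_labpath_abnormal_prob
  abn <- runif(length(idx)) < abn_prob[idx]
  fasting <- runif(length(idx)) < 0.5
  val <- numeric(length(idx))
  val[abn & fasting] <- rln(sum(abn & fasting), lv$fasting$abnormal)
  val[abn & !fasting] <- rln(sum(abn & !fasting), lv$random$abnormal)
  val[!abn & fasting] <- rln(sum(!abn & fasting), lv$fasting$normal)
  val[!abn & !fasting] <- rln(sum(!abn & !fasting), lv$random$normal)
  add_block(idx, "lab", "LAB", ifelse(fasting, "GLU-F", "GLU-R"), val, "billing")

  idx <- rep(seq_len(n), ifelse(t2, rpois(n, r$t2dm_case_hba1c_lambda), 0L))
  abn <- runif(length(idx)) < abn_prob[idx]
  val <- numeric(length(idx))
  val[abn] <- rln(sum(abn), lv$hba1c$abnormal)
  val[!abn] <- rln(sum(!abn), lv$hba1c$normal)
  add_block(idx, "lab", "LAB", "HBA1C", val, "billing")

  # assemble, date, link and fragment ----------------------------------------
  ev <- dplyr::bind_rows(blocks)
  ev <- ev[order(ev$idx), , drop = FALSE]
  ne <- nrow(ev)
  ndays <- as.integer(config$window_end - config$window_start) + 1L
  ev$date <- config$window_start + (sample.int(ndays, ne, replace = TRUE) - 1L)
  seq_in_pat <- stats::ave(rep(1L, ne), ev$idx, FUN = seq_along)
  ev$linkage_key <- sprintf("%s-e%04d", pid[ev$idx], seq_in_pat)

  k <- length(config$sources)
  at_home <- runif(ne) < p_home[ev$idx]
  home_idx <- match(home, config$sources)
  origin_idx <- home_idx[ev$idx]
  if (k > 1) {
    shift <- sample.int(k - 1L, ne, replace = TRUE)
    away_idx <- (origin_idx - 1L + shift) %% k + 1L
    origin_idx <- ifelse(at_home, origin_idx, away_idx)
  }
  ev$source_id <- config$sources[origin_idx]

  primary <- ev
  copies <- list()
  if (k > 1) {
    dup <- config$duplication_rate
    for (s in config$sources) {
      cand <- primary$source_id != s
      captured <- cand & runif(ne) < dup[primary$source_id]
      if (any(captured)) {
        cp <- primary[captured, , drop = FALSE]
        cp$source_id <- s
        copies[[s]] <- cp
      }
    }
  }
  ev <- dplyr::bind_rows(c(list(primary), copies))

  events <- tibble::tibble(
    patient_id = pid[ev$idx],
    event_type = ev$event_type,
    code_system = ev$code_system,
    code = ev$code,
    value = ev$value,
    date = ev$date,
    source_id = ev$source_id,
    entry_mode = ev$entry_mode,
    linkage_key = ev$linkage_key
  )
  events <- events[order(events$patient_id, events$linkage_key,
                         events$source_id), , drop = FALSE]

  structure(
    list(
      patients = tibble::tibble(patient_id = pid, family_history_dm = famhx),
      events = validate_events(events),
      truth = tibble::tibble(patient_id = pid, ra_status = ra,
                             t2dm_status = t2dm),
      config = config
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d patients, %d event records (%d distinct events), seed %d\n",
    nrow(x$patients), nrow(x$events), length(unique(x$events$linkage_key)),
    x$config$seed
  ))
  invisible(x)
}

#' @noRd
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(i)) %% 2147483647)
}

#' Generate cohorts across a home-affinity sweep
#'
#' Re-runs [generate_cohort()] once per `p_home` value with that affinity
#' held constant across patients (the sweep isolates the fragmentation dial)
#' and with replicate seeds derived deterministically from the base seed.
#'
#' @param config Base [sim_config()].
#' @param p_home_values Values in `[0.5, 1]`, e.g. `c(1, 0.8, 0.6)`.
#' @return Named list of `sim_cohort` objects, one per value.
#' @export
fragmentation_sweep <- function(config, p_home_values) {
  if (length(p_home_values) == 0) {
    abort("p_home_values must be non-empty", class = "phenofrag_arg_error")
  }
  if (any(p_home_values < 0.5 | p_home_values > 1)) {
    abort("p_home_values must lie in [0.5, 1]", class = "phenofrag_arg_error")
  }
  out <- lapply(seq_along(p_home_values), function(i) {
    cfg <- config
    cfg$p_home_mean <- p_home_values[i]
    cfg$p_home_concentration <- Inf
    cfg$seed <- derive_seed(config$seed, i)
    generate_cohort(cfg)
  })
  names(out) <- sprintf("p_home=%g", p_home_values)
  out
}

#' Write or read a simulated cohort directory
#'
#' `write_cohort()` writes `events.csv`, `patients.csv`, `truth.csv` and a
#' resolved `config.yaml` snapshot; `read_cohort()` reads them back.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Directory path (created if needed).
#' @return The directory (`write_cohort`) or a `sim_cohort` (`read_cohort`),
#'   whose `config` is `NULL` when the snapshot is absent.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(cohort$events, file.path(dir, "events.csv"))
  write_patients(cohort$patients, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  cfg <- cohort$config
  if (!is.null(cfg)) {
    snap <- lapply(unclass(cfg), function(x) {
      if (inherits(x, "Date")) return(format(x))
      if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
      x
    })
    yaml::write_yaml(snap, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, col_types = readr::cols(
      patient_id = readr::col_character(),
      ra_status = readr::col_logical(),
      t2dm_status = readr::col_character()
    ))
  } else {
    NULL
  }
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) sim_config_from_yaml(cfg_path) else NULL
  structure(
    list(
      patients = read_patients(file.path(dir, "patients.csv")),
      events = read_events(file.path(dir, "events.csv")),
      truth = truth,
      config = cfg
    ),
    class = "sim_cohort"
  )
}

#' Read a simulation configuration from YAML
#'
#' Accepts any subset of [sim_config()] arguments as top-level YAML keys;
#' nested `event_rates` / `lab_value_params` entries are merged over the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("simulation config not found: %s", path),
          class = "phenofrag_config_error")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(sprintf("unknown simulation config field(s): %s",
                  paste(extra, collapse = ", ")),
          class = "phenofrag_config_error")
  }
  if (!is.null(raw$duplication_rate)) {
    raw$duplication_rate <- unlist(raw$duplication_rate)
  }
  if (!is.null(raw$home_probs)) raw$home_probs <- unlist(raw$home_probs)
  if (!is.null(raw$sources)) raw$sources <- unlist(raw$sources)
  do.call(sim_config, raw)
}
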
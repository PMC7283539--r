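calls_tbl <- function(ids, case_ids, control_ids = character(0)) {
  tibble::tibble(
    patient_id = ids,
    label = ifelse(ids %in% case_ids, "case",
                   ifelse(ids %in% control_ids, "control", "neither"))
  )
}

test_that("confusion is set arithmetic over a fixed patient universe", {
  roster <- c("A", "B", "C", "D", "E")
  bench <- calls_tbl(roster, c("A", "B"))
  src <- calls_tbl(roster, c("B", "C"))
  cf <- confusion(src, bench, "case")
  expect_equal(unlist(cf[c("tp", "fp", "tn", "fn")], use.names = FALSE),
               c(1, 1, 2, 1))
  expect_equal(cf$tp + cf$fp + cf$tn + cf$fn, length(roster))
  expect_error(confusion(src[-1, ], bench, "case"),
               class = "phenofrag_arg_error")
})

test_that("large-cohort confusion reproduces the published count identities", {
  n <- 45183
  roster <- sprintf("S%05d", seq_len(n))
  # RA case, local-EHR source: TP=455, FP=43, FN=165 forces TN=44520
  bench <- calls_tbl(roster, roster[1:620])
  src <- calls_tbl(roster, c(roster[1:455], roster[621:663]))
  cf <- confusion(src, bench, "case")
  expect_equal(unlist(cf[c("tp", "fp", "tn", "fn")], use.names = FALSE),
               c(455, 43, 44520, 165))
  # T2DM control, local-EHR source: TP=6218, FP=597, FN=75 forces TN=38293
  bench2 <- calls_tbl(roster, character(0), roster[1:6293])
  src2 <- calls_tbl(roster, character(0),
                    c(roster[1:6218], roster[6294:6890]))
  cf2 <- confusion(src2, bench2, "control")
  expect_equal(unlist(cf2[c("tp", "fp", "tn", "fn")], use.names = FALSE),
               c(6218, 597, 38293, 75))
})

test_that("metrics use the published formulas, with safe degenerate cases", {
  m <- compute_metrics(c(455, 43, 44520, 165))
  expect_equal(round_half_up(m$sensitivity), 73.4)
  expect_equal(round_half_up(m$specificity), 99.9)
  expect_equal(round_half_up(m$ppv), 91.4)
  expect_equal(round_half_up(m$fnr), 26.6)

  m2 <- compute_metrics(c(45, 5, 49, 1))
  expect_equal(round_half_up(unlist(m2[c("sensitivity", "specificity",
                                         "ppv", "fnr")])),
               c(sensitivity = 97.8, specificity = 90.7, ppv = 90.0,
                 fnr = 2.2))

  w <- capture_warnings(m3 <- compute_metrics(c(0, 0, 100, 0)))
  expect_match(w, "undefined", all = TRUE)
  expect_length(w, 3)  # sensitivity, PPV and FNR are all undefined
  expect_true(is.na(m3$sensitivity) && is.na(m3$ppv) && is.na(m3$fnr))
  expect_equal(m3$specificity, 100)

  # sensitivity + FNR = 100 exactly on raw values
  set.seed(8)
  counts <- tibble::tibble(tp = sample(1:500, 20), fp = sample(0:50, 20),
                           tn = sample(100:1000, 20), fn = sample(0:100, 20))
  mm <- compute_metrics(counts)
  expect_equal(mm$sensitivity + mm$fnr, rep(100, 20))
})

test_that("the benchmark must be the union view and agrees with itself", {
  co <- sim_small(200, 2)
  v <- both_views(co)
  expect_error(benchmark_calls(v$Mayo, "ra"), "union",
               class = "phenofrag_arg_error")
  for (alg in c("ra", "t2dm")) {
    b <- benchmark_calls(v$union, alg)
    for (tgt in c("case", "control")) {
      cf <- confusion(b, b, tgt)
      expect_equal(cf$fp, 0)
      expect_equal(cf$fn, 0)
    }
  }
})

test_that("an empty event store yields the degenerate partition", {
  pts <- mk_patients(sprintf("P%d", 1:6))
  empty <- mk_events("P1", key = "x")[0, ]
  v <- make_view(empty, pts, c("Mayo", "REP"),
                 all_sources = c("Mayo", "REP"))
  ra <- classify_ra(v)
  expect_true(all(ra$label == "control"))   # nothing screens in or excludes
  t2 <- classify_t2dm(v)
  expect_true(all(t2$label == "neither"))   # the control screen needs visits
  expect_equal(nrow(ra), 6)
})

test_that("attribution equals a per-patient brute-force evidence diff", {
  co <- sim_small(400, 29)
  v <- both_views(co)
  cls <- default_codelists()

  for (alg in c("ra", "t2dm")) {
    bench <- phenotype_calls(v$union, alg, cls)
    src <- phenotype_calls(v$Mayo, alg, cls)
    b_case <- bench$patient_id[bench$label == "case"]
    s_case <- src$patient_id[src$label == "case"]
    fn_ids <- setdiff(b_case, s_case)
    att <- attribute_missing_info(fn_ids, v$Mayo, v$union, alg, "case", "FN",
                                  cls)
    expect_equal(att$table$total_subjects, length(fn_ids))

    if (alg == "ra") {
      fu <- extract_ra_features(v$union, cls)
      fs <- extract_ra_features(v$Mayo, cls)
      mapping <- c(ra_dx = "n_ra_dx", pa_dx = "n_pa_dx",
                   sle_dx = "n_sle_dx", rf_lab = "n_rf_lab")
      for (fac in names(mapping)) {
        col <- mapping[[fac]]
        manual <- sum(vapply(fn_ids, function(id) {
          fu[[col]][fu$patient_id == id] >= 1 &&
            fs[[col]][fs$patient_id == id] == 0
        }, logical(1)))
        expect_equal(att$table[[fac]], manual)
      }
      manual_short <- sum(vapply(fn_ids, function(id) {
        max(fu$n_encounters[fu$patient_id == id] -
              fs$n_encounters[fs$patient_id == id], 0)
      }, numeric(1)))
      expect_equal(att$table$missing_encounters, manual_short)
    } else {
      eu <- extract_t2dm_evidence(v$union, cls)
      es <- extract_t2dm_evidence(v$Mayo, cls)
      manual_med <- sum(vapply(fn_ids, function(id) {
        eu$has_t2dm_med[eu$patient_id == id] &&
          !es$has_t2dm_med[es$patient_id == id]
      }, logical(1)))
      expect_equal(att$table$t2dm_med, manual_med)
      manual_dx <- sum(vapply(fn_ids, function(id) {
        eu$n_t2dm_dx[eu$patient_id == id] >= 1 &&
          es$n_t2dm_dx[es$patient_id == id] == 0
      }, logical(1)))
      expect_equal(att$table$t2dm_dx, manual_dx)
    }
    # patients with identical evidence in both views contribute nothing
    same <- intersect(b_case, s_case)
    if (length(same) > 0) {
      att_same <- attribute_missing_info(same[1], v$Mayo, v$union, alg,
                                         "case", "FN", cls)
      fac_cols <- setdiff(names(att_same$per_patient),
                          c("patient_id", "any_missing"))
      if (!att_same$per_patient$any_missing) {
        expect_true(all(!unlist(att_same$per_patient[fac_cols])))
      }
    }
  }
  expect_error(
    attribute_missing_info("NOT-A-PATIENT", v$Mayo, v$union, "ra", "case",
                           "FN", cls),
    class = "phenofrag_arg_error"
  )
})

test_that("the experiment bundle satisfies its structural invariants", {
  co <- sim_small(300, 41)
  rep <- run_experiment(co)
  m <- rep$metrics
  # universe conservation on every row
  expect_true(all(m$tp + m$fp + m$tn + m$fn == nrow(co$patients)))
  # benchmark rows are perfect by definition
  u <- m[m$view == rep$union_label, ]
  expect_true(all(u$fp == 0 & u$fn == 0))
  expect_true(all(u$sensitivity == 100 & u$ppv == 100 & u$fnr == 0))
  # counts table agrees with the call tables
  for (i in seq_len(nrow(rep$counts))) {
    r <- rep$counts[i, ]
    sub <- rep$calls[rep$calls$algorithm == r$algorithm &
                       rep$calls$view == r$view, ]
    expect_equal(r$n_called, sum(sub$label == r$target))
  }
  # RA probabilities cover every benchmark case under every view
  n_case <- rep$counts$n_called[rep$counts$algorithm == "ra" &
                                  rep$counts$target == "case" &
                                  rep$counts$view == rep$union_label]
  expect_equal(nrow(rep$ra_probabilities), n_case * 3)
  expect_true(all(rep$ra_probabilities$probability > 0 &
                    rep$ra_probabilities$probability < 1))
  expect_error(run_experiment(co, sources = "Mayo"),
               class = "phenofrag_arg_error")
})
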
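test_that("logistic scoring matches an independent sigmoid to 1e-12", {
  set.seed(77)
  for (i in 1:50) {
    w <- c(n_ra_dx = runif(1, 0.5, 3), n_sle_dx = -runif(1, 0.1, 2),
           n_pa_dx = -runif(1, 0.1, 2), n_rf_lab = runif(1, 0, 0.5),
           n_rf_positive = runif(1, 0.5, 2), n_encounters = -runif(1, 0.05, 1))
    m <- ra_model(intercept = rnorm(1), weights = w,
                  transform = sample(c("log1p", "raw"), 1))
    rf <- sample(0:4, 1)
    f <- tibble::tibble(
      n_ra_dx = sample(0:12, 1), n_sle_dx = sample(0:3, 1),
      n_pa_dx = sample(0:3, 1), n_rf_lab = rf,
      n_rf_positive = sample(0:rf, 1), n_encounters = sample(0:30, 1)
    )
    tf <- if (m$transform == "log1p") log1p else identity
    eta <- m$intercept
    for (nm in names(w)) eta <- eta + w[[nm]] * tf(f[[nm]])
    expect_equal(ra_score(f, m), plogis(eta), tolerance = 1e-12)
  }
})

test_that("scoring identities hold for hand-set weights", {
  m0 <- ra_model(0, c(n_ra_dx = 1, n_sle_dx = -1, n_pa_dx = -1,
                      n_rf_lab = 0, n_rf_positive = 1, n_encounters = -1),
                 transform = "raw")
  zero <- tibble::tibble(n_ra_dx = 0, n_sle_dx = 0, n_pa_dx = 0,
                         n_rf_lab = 0, n_rf_positive = 0, n_encounters = 0)
  expect_equal(ra_score(zero, m0), 0.5)

  m2 <- ra_model(-2, c(n_ra_dx = 1, n_sle_dx = -1, n_pa_dx = -1,
                       n_rf_lab = 0, n_rf_positive = 1, n_encounters = -1),
                 transform = "raw")
  two <- zero
  two$n_ra_dx <- 2
  expect_equal(ra_score(two, m2), 0.5)  # logistic(-2 + 1*2)
})

test_that("the inclusion cohort is exactly the screen-positive set", {
  pts <- mk_patients(sprintf("P%d", 1:8))
  ev <- dplyr::bind_rows(
    mk_events("P1", code = "714.0", source = "Mayo", key = "a"),
    mk_events("P2", system = "ICD10CM", code = "M06.09", source = "REP",
              key = "b"),
    mk_events("P3", code = "714.81", source = "Mayo", key = "c"),
    mk_events("P4", code = "710.0", source = "Mayo", key = "d"),  # SLE only
    mk_events("P5", type = "lab", system = "LAB", code = "RF", value = 60,
              source = "Mayo", key = "e")
  )
  cls <- default_codelists()
  uv <- make_view(ev, pts, c("Mayo", "REP"))
  expect_setequal(ra_inclusion_cohort(uv, cls), c("P1", "P2", "P3"))

  # brute-force oracle over patients
  manual <- unique(ev$patient_id[
    ev$event_type == "diagnosis" &
      (startsWith(ev$code, "714.") | startsWith(ev$code, "M05.") |
         startsWith(ev$code, "M06."))
  ])
  expect_setequal(ra_inclusion_cohort(uv, cls), manual)

  # source membership: P2's only RA code lives in REP
  v_mayo <- make_view(ev, pts, "Mayo", all_sources = c("Mayo", "REP"))
  v_rep <- make_view(ev, pts, "REP", all_sources = c("Mayo", "REP"))
  expect_false("P2" %in% ra_inclusion_cohort(v_mayo, cls))
  expect_true("P2" %in% ra_inclusion_cohort(v_rep, cls))
})

test_that("feature extraction counts matched events per patient", {
  pts <- mk_patients(c("P1", "P2"))
  ev <- dplyr::bind_rows(
    mk_events("P1", code = c("714.0", "M05.79"),
              system = c("ICD9CM", "ICD10CM"), key = c("a", "b")),
    mk_events("P1", type = "lab", system = "LAB", code = "RF", value = 50,
              key = "c"),
    mk_events("P1", type = "encounter", system = "NONE",
              code = "INPERSON", key = sprintf("enc%d", 1:5))
  )
  v <- make_view(ev, pts, "Mayo")
  f <- extract_ra_features(v)
  p1 <- f[f$patient_id == "P1", ]
  expect_equal(
    unlist(p1[c("n_ra_dx", "n_sle_dx", "n_pa_dx", "n_rf_lab",
                "n_rf_positive", "n_encounters")], use.names = FALSE),
    c(2, 0, 0, 1, 1, 5)
  )
  # patient with no events: the zero vector, still on the roster
  p2 <- f[f$patient_id == "P2", ]
  expect_true(all(p2[-1] == 0))

  # RF below the positivity threshold counts as a test but not a positive
  ev2 <- mk_events("P2", type = "lab", system = "LAB", code = "RF",
                   value = 5, key = "neg")
  f2 <- extract_ra_features(make_view(dplyr::bind_rows(ev, ev2), pts, "Mayo"))
  expect_equal(f2$n_rf_lab[f2$patient_id == "P2"], 1L)
  expect_equal(f2$n_rf_positive[f2$patient_id == "P2"], 0L)
})

test_that("union-view features dominate single-source features", {
  co <- sim_small(150, 13)
  v <- both_views(co)
  fu <- extract_ra_features(v$union)
  for (s in co$config$sources) {
    fs <- extract_ra_features(v[[s]])
    for (col in setdiff(names(fu), "patient_id")) {
      expect_true(all(fu[[col]] >= fs[[col]]),
                  info = sprintf("%s in %s", col, s))
    }
  }
})

test_that("case/control labels follow the two-rule definition", {
  cls <- default_codelists()
  pts <- mk_patients(sprintf("P%02d", 1:12))
  ev <- dplyr::bind_rows(
    # strong case: many RA codes + positive RF
    mk_events("P01", code = "714.0", key = sprintf("a%d", 1:9)),
    mk_events("P01", type = "lab", system = "LAB", code = "RF", value = 80,
              key = "a-rf"),
    # screened but weak evidence -> neither
    mk_events("P02", code = "714.0", key = "b1"),
    # exclusion code only -> neither (not a valid control)
    mk_events("P03", code = "710.0", key = "c1"),
    mk_events("P04", code = "696.0", key = "d1"),
    # unrelated events -> control
    mk_events("P05", type = "encounter", system = "NONE", code = "INPERSON",
              key = "e1"),
    # screened + exclusion, strong evidence -> case (exclusion only blocks
    # controls)
    mk_events("P06", code = "714.0", key = sprintf("f%d", 1:9)),
    mk_events("P06", type = "lab", system = "LAB", code = "RF", value = 80,
              key = "f-rf"),
    mk_events("P06", code = "720.0", key = "f-ex")
  )
  v <- make_view(ev, pts, "Mayo")
  calls <- classify_ra(v, cls)
  got <- setNames(calls$label, calls$patient_id)
  expect_equal(got[["P01"]], "case")
  expect_equal(got[["P02"]], "neither")
  expect_equal(got[["P03"]], "neither")
  expect_equal(got[["P04"]], "neither")
  expect_equal(got[["P05"]], "control")
  expect_equal(got[["P06"]], "case")
  expect_true(all(got[sprintf("P%02d", 7:12)] == "control"))  # no events
  # labels partition the roster
  expect_setequal(unique(calls$label), c("case", "control", "neither"))
  expect_equal(sum(table(calls$label)), nrow(pts))
})

test_that("a probability exactly at the cutoff is called a case", {
  pts <- mk_patients("P1")
  ev <- mk_events("P1", code = "714.0", key = "a")
  v <- make_view(ev, pts, "Mayo")
  w <- c(n_ra_dx = 2, n_sle_dx = -1, n_pa_dx = -1, n_rf_lab = 0,
         n_rf_positive = 1, n_encounters = -1)
  p_exact <- ra_score(extract_ra_features(v), ra_model(0, w, "raw"))
  m <- ra_model(0, w, "raw", cutoff = p_exact)
  calls <- classify_ra(v, model = m)
  expect_equal(calls$probability, p_exact)
  expect_equal(calls$label, "case")
})

test_that("score monotonicity follows the weight signs", {
  m <- default_ra_model()
  set.seed(5)
  for (i in 1:25) {
    f <- tibble::tibble(
      n_ra_dx = sample(1:10, 1), n_sle_dx = sample(0:2, 1),
      n_pa_dx = sample(0:2, 1), n_rf_lab = sample(0:3, 1),
      n_rf_positive = 0, n_encounters = sample(0:20, 1)
    )
    f$n_rf_positive <- sample(0:f$n_rf_lab, 1)
    base <- ra_score(f, m)
    up <- function(col, by = 1) {
      g <- f
      g[[col]] <- g[[col]] + by
      ra_score(g, m)
    }
    expect_gte(up("n_ra_dx"), base)
    g <- f; g$n_rf_lab <- g$n_rf_lab + 1; g$n_rf_positive <- g$n_rf_positive + 1
    expect_gte(ra_score(g, m), base)   # an additional positive RF result
    expect_lte(up("n_sle_dx"), base)
    expect_lte(up("n_pa_dx"), base)
    expect_lte(up("n_encounters"), base)
  }
})

test_that("model validation enforces the documented structure", {
  w <- c(n_ra_dx = 2, n_sle_dx = -1, n_pa_dx = -1, n_rf_lab = 0,
         n_rf_positive = 1, n_encounters = -1)
  expect_error(ra_model(0, w, cutoff = 1.2), class = "phenofrag_config_error")
  expect_error(ra_model(0, w[-1]), class = "phenofrag_config_error")
  bad <- w
  bad["n_sle_dx"] <- 0.5
  expect_error(ra_model(0, bad), "sign", class = "phenofrag_config_error")
  expect_s3_class(ra_model(0, bad, check_signs = FALSE), "ra_model")
  dflt <- read_ra_model()
  expect_equal(dflt$cutoff, 0.632)
  expect_error(ra_score(tibble::tibble(n_ra_dx = 1), dflt),
               class = "phenofrag_config_error")
})
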
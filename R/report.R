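#' Round half-up
#'
#' Reported percentages use conventional half-up rounding (0.05 rounds to
#' 0.1), not R's round-half-to-even. Used only at report time; all internal
#' values stay at full precision.
#'
#' @param x Numeric vector (non-negative use case).
#' @param digits Decimal places (0 for integer precision).
#' @return Rounded numeric vector (`NA` passed through).
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  out <- floor(x * m + 0.5 + 1e-9) / m
  out[is.na(x)] <- NA_real_
  out
}

#' @noRd
round_metric_cols <- function(df, digits) {
  for (col in c("sensitivity", "specificity", "ppv", "fnr")) {
    if (col %in% names(df)) df[[col]] <- round_half_up(df[[col]], digits)
  }
  df
}

#' @noRd
md_table <- function(df) {
  fmt <- vapply(df, function(x) {
    if (is.numeric(x)) format(x, trim = TRUE) else as.character(x)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1) fmt <- matrix(fmt, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render an experiment report to disk
#'
#' Writes the [run_experiment()] bundle as `counts.csv`, `metrics.csv`
#' (percentages rounded half-up at the requested precision),
#' `missing_info.csv` (long format: one row per error set and factor),
#' `ra_probabilities.csv`, `summary.json` (full precision, plus provenance)
#' and a human-readable `report.md`. Row ordering is deterministic
#' (algorithm, then target, then view).
#'
#' @param bundle A `phenofrag_report`.
#' @param dir Output directory (created if needed).
#' @param precision Decimal places for reported percentages (default 1;
#'   0 gives integer precision).
#' @param provenance Optional named list (seed, config, hashes) echoed into
#'   `summary.json`.
#' @return `dir`, invisibly.
#' @export
render_report <- function(bundle, dir, precision = 1, provenance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ord <- function(df) {
    df[order(df$algorithm, df$target,
             match(df$view, c(bundle$union_label, bundle$sources))), ]
  }

  counts <- ord(bundle$counts)
  readr::write_csv(counts, file.path(dir, "counts.csv"))

  metrics <- ord(bundle$metrics)
  readr::write_csv(round_metric_cols(metrics, precision),
                   file.path(dir, "metrics.csv"))

  mi <- bundle$missing_info
  mi_long <- if (is.null(mi) || nrow(mi) == 0) {
    tibble::tibble(algorithm = character(0), target = character(0),
                   error_type = character(0), source = character(0),
                   total_subjects = integer(0), factor = character(0),
                   n_missing = numeric(0))
  } else {
    fixed <- c("algorithm", "target", "error_type", "source", "total_subjects")
    rows <- lapply(seq_len(nrow(mi)), function(i) {
      fac_cols <- setdiff(names(mi), fixed)
      fac_cols <- fac_cols[!is.na(unlist(mi[i, fac_cols]))]
      tibble::tibble(
        mi[i, fixed],
        factor = fac_cols,
        n_missing = as.numeric(unlist(mi[i, fac_cols]))
      )
    })
    dplyr::bind_rows(rows)
  }
  readr::write_csv(mi_long, file.path(dir, "missing_info.csv"))

  if (!is.null(bundle$ra_probabilities)) {
    readr::write_csv(bundle$ra_probabilities,
                     file.path(dir, "ra_probabilities.csv"))
  }

  summary <- list(
    provenance = provenance,
    n_patients = bundle$n_patients,
    sources = bundle$sources,
    union_label = bundle$union_label,
    algorithms = bundle$algorithms,
    counts = counts,
    metrics = metrics,
    missing_info = mi_long
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  md <- c(
    "# Fragmentation evaluation report",
    "",
    sprintf("Cohort: %d patients; benchmark: %s.", bundle$n_patients,
            bundle$union_label),
    "",
    "## Phenotype counts by data source",
    "",
    md_table(counts),
    "",
    "## Performance against the union benchmark",
    "",
    md_table(round_metric_cols(metrics, precision)),
    "",
    "## Missing information for error subjects",
    "",
    md_table(mi_long),
    ""
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
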
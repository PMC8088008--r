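# Cohort data model and CSV I/O.
#
# A cohort is scan-level: one row per ultrasound observation, with
# participant linkage to a one-row-per-participant outcome table. Two
# scans from the same participant enter as two observation rows (the
# non-independence this creates for paired analyses is documented, not
# modelled). Dates are ISO-8601 in files and Date objects in memory; GA
# is always decimal weeks (days/7), never completed-weeks integers.

#' Cohort schema configuration
#'
#' Describes how a flat scan-level CSV maps onto the cohort model: which
#' file columns hold the id, dates and CRL, and the CRL plausibility
#' bound. Every column not named in the mapping is carried along as a
#' covariate. `config` may be a named list or a path to a YAML file with
#' the same keys; supplied values override the defaults.
#'
#' The default CRL bound is 10 cm because CRL at 14 weeks -- the clinical
#' truncation point for CRL-based dating -- is about 8.5 cm; anything far
#' above that in a first-trimester table is a data error.
#'
#' @param config Named list or YAML path of overrides.
#' @return A list with elements `columns` (named character vector) and
#'   `crl_max_cm`.
#' @export
cohort_schema <- function(config = NULL) {
  schema <- list(
    columns = c(participant_id = "participant_id",
                scan_index = "scan_index",
                scan_date = "scan_date",
                lmp_date = "lmp_date",
                crl_cm = "crl_cm",
                delivery_date = "delivery_date"),
    crl_max_cm = 10)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    if (!is.null(config$columns)) {
      schema$columns[names(config$columns)] <- unlist(config$columns)
    }
    if (!is.null(config$crl_max_cm)) schema$crl_max_cm <- config$crl_max_cm
  }
  schema
}

new_cohort_table <- function(observations, outcomes, provenance = "unknown",
                             exclusion_log = NULL, extra_meta = list()) {
  if (is.null(exclusion_log)) {
    exclusion_log <- data.frame(row = integer(0), participant_id = character(0),
                                reason = character(0))
  }
  structure(list(
    observations = observations,
    outcomes = outcomes,
    metadata = c(list(n_p = length(unique(observations$participant_id)),
                      n_o = nrow(observations),
                      provenance = provenance,
                      exclusion_log = exclusion_log),
                 extra_meta)),
    class = "cohort_table")
}

#' Build a cohort table from a scan-level data frame
#'
#' Low-level constructor used by the synthetic generator and by tests.
#' Expects canonical column names (`participant_id`, `scan_index`,
#' `scan_date`, `lmp_date`, `crl_cm`, `delivery_date`); all other columns
#' are covariates. Derives `ga_lmp_weeks` and splits the per-participant
#' delivery date into the outcome table.
#'
#' @param df Scan-level data frame.
#' @param provenance Tag recorded in metadata (e.g. `"synthetic"`,
#'   `"training"`, `"test"`).
#' @param extra_meta Named list merged into metadata.
#' @return A `cohort_table`.
#' @export
as_cohort_table <- function(df, provenance = "unknown", extra_meta = list()) {
  stopifnot(is.data.frame(df), "participant_id" %in% names(df))
  df$participant_id <- as.character(df$participant_id)
  if (is.null(df$scan_index)) df$scan_index <- 1L
  for (col in c("scan_date", "lmp_date", "delivery_date")) {
    if (!is.null(df[[col]]) && !inherits(df[[col]], "Date")) {
      df[[col]] <- as.Date(df[[col]])
    }
  }
  outcomes <- unique(df[!is.na(df$participant_id),
                        c("participant_id", "delivery_date"), drop = FALSE])
  outcomes <- outcomes[!duplicated(outcomes$participant_id), , drop = FALSE]
  rownames(outcomes) <- NULL
  obs <- df[, setdiff(names(df), "delivery_date"), drop = FALSE]
  cohort <- new_cohort_table(obs, outcomes, provenance,
                             extra_meta = extra_meta)
  derive_ga_lmp(cohort)
}

#' @export
print.cohort_table <- function(x, ...) {
  m <- x$metadata
  cat("<cohort_table> ", m$provenance, ": N_p = ", m$n_p,
      " participants, N_o = ", m$n_o, " observations\n", sep = "")
  n_excl <- nrow(m$exclusion_log)
  if (n_excl > 0) cat("  ", n_excl, "row(s) rejected at read; see metadata$exclusion_log\n")
  invisible(x)
}

#' Derive LMP-based gestational age
#'
#' Populates `ga_lmp_weeks` as the exact day difference between scan and
#' LMP dates divided by 7 (decimal weeks). Rows with a missing LMP date
#' keep `NA` and are counted in metadata, not dropped.
#'
#' @param cohort A `cohort_table`.
#' @return The cohort with `observations$ga_lmp_weeks` filled in.
#' @export
derive_ga_lmp <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  obs <- cohort$observations
  ga <- rep(NA_real_, nrow(obs))
  ok <- !is.na(obs$lmp_date) & !is.na(obs$scan_date)
  ga[ok] <- as.numeric(obs$scan_date[ok] - obs$lmp_date[ok]) / 7
  cohort$observations$ga_lmp_weeks <- ga
  cohort$metadata$n_missing_lmp <- sum(!ok)
  cohort
}

#' Read a scan-level cohort CSV
#'
#' Validation is collect-and-report, not fail-fast: rows violating hard
#' invariants (unparseable dates, scan before LMP, implausible CRL) are
#' rejected with a per-row reason recorded in
#' `metadata$exclusion_log`, so a messy real-world CSV yields a usable
#' table plus an audit trail. Missing optional fields (LMP date, CRL,
#' delivery date) are preserved as `NA`, never coerced to 0.
#'
#' When the file carries three raw CRL measurement columns (named in
#' `crl_triplicate`), their row mean is used as `crl_cm` — the standard
#' protocol averages three calliper placements.
#'
#' @param path CSV file path.
#' @param schema From [cohort_schema()]; list or YAML path accepted.
#' @param provenance Metadata tag.
#' @param crl_triplicate Optional character vector of three column names
#'   to average into `crl_cm`.
#' @return A validated `cohort_table`.
#' @export
read_cohort <- function(path, schema = cohort_schema(), provenance = "file",
                        crl_triplicate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) || !is.list(schema) || is.null(schema$columns)) {
    schema <- cohort_schema(schema)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  cols <- schema$columns
  required <- cols[c("participant_id", "scan_date")]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: required column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    warning("'", path, "' has a header but no data rows")
  }
  if (!is.null(crl_triplicate)) {
    stopifnot(length(crl_triplicate) == 3, all(crl_triplicate %in% names(raw)))
    trip <- vapply(crl_triplicate, function(cn) as_num(raw[[cn]]),
                   numeric(nrow(raw)))
    raw[[cols[["crl_cm"]]]] <- rowMeans(matrix(trip, nrow = nrow(raw)))
    raw <- raw[, setdiff(names(raw), crl_triplicate), drop = FALSE]
  }

  # normalise to canonical names
  present <- cols[cols %in% names(raw)]
  df <- raw
  names(df)[match(present, names(df))] <- names(present)
  covariate_cols <- setdiff(names(df), names(cols))

  n <- nrow(df)
  reject_reason <- rep(NA_character_, n)
  note <- function(idx, reason) {
    new <- idx & is.na(reject_reason)
    reject_reason[new] <<- reason
  }

  parse_date <- function(x) as.Date(x, format = "%Y-%m-%d", optional = TRUE)
  for (col in c("scan_date", "lmp_date", "delivery_date")) {
    if (is.null(df[[col]])) { df[[col]] <- rep(as.Date(NA), n); next }
    given <- !is.na(df[[col]]) & nzchar(trimws(df[[col]]))
    parsed <- parse_date(df[[col]])
    note(given & is.na(parsed), paste0("unparseable ", col))
    df[[col]] <- parsed
  }
  note(is.na(df$scan_date), "missing scan_date")
  note(is.na(df$participant_id) | !nzchar(df$participant_id),
       "missing participant_id")

  df$crl_cm <- if (is.null(raw[[cols[["crl_cm"]]]]) && is.null(crl_triplicate))
    rep(NA_real_, n) else as_num(df$crl_cm)
  bad_crl <- !is.na(df$crl_cm) &
    (df$crl_cm <= 0 | df$crl_cm > schema$crl_max_cm)
  note(bad_crl, paste0("implausible CRL (bound ", schema$crl_max_cm, " cm)"))

  neg_ga <- !is.na(df$lmp_date) & !is.na(df$scan_date) &
    df$scan_date < df$lmp_date
  note(neg_ga, "negative GA")

  df$scan_index <- if (is.null(raw[[cols[["scan_index"]]]]))
    rep(1L, n) else as.integer(as_num(df$scan_index))

  rejected <- !is.na(reject_reason)
  log <- data.frame(row = which(rejected),
                    participant_id = as.character(df$participant_id[rejected]),
                    reason = reject_reason[rejected],
                    stringsAsFactors = FALSE)
  kept <- df[!rejected, c("participant_id", "scan_index", "scan_date",
                          "lmp_date", "crl_cm", "delivery_date",
                          covariate_cols), drop = FALSE]
  kept$participant_id <- as.character(kept$participant_id)
  for (cv in covariate_cols) {
    num <- as_num(kept[[cv]])
    given <- !is.na(kept[[cv]]) & nzchar(trimws(kept[[cv]]))
    if (all(!given | !is.na(num))) kept[[cv]] <- num
  }
  rownames(kept) <- NULL
  cohort <- as_cohort_table(kept, provenance = provenance)
  cohort$metadata$exclusion_log <- log
  cohort$metadata$n_input_rows <- n
  if (n > 0 && nrow(kept) == 0) {
    stop("all ", n, " rows failed validation; first reason: ", log$reason[1])
  }
  cohort
}

as_num <- function(x) suppressWarnings(as.numeric(x))

#' Write a cohort table to CSV
#'
#' Serialises back to the flat scan-level schema: the per-participant
#' delivery date is joined onto each observation row, dates are written
#' ISO-8601 and missing values as empty strings, so
#' `read_cohort(write_cohort(x))` round-trips all modelled fields.
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  obs <- cohort$observations
  obs$delivery_date <- cohort$outcomes$delivery_date[
    match(obs$participant_id, cohort$outcomes$participant_id)]
  obs$ga_lmp_weeks <- NULL # derived, recomputed on read
  for (col in names(obs)) {
    if (inherits(obs[[col]], "Date")) obs[[col]] <- format(obs[[col]], "%Y-%m-%d")
  }
  ok <- tryCatch({
    write.csv(obs, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) stop("cannot write cohort to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Write the exclusion log as JSON lines
#'
#' One JSON object per rejected row (`row`, `participant_id`, `reason`),
#' mirroring the study-flowchart style of exclusion accounting.
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(cohort, path) {
  log <- cohort$metadata$exclusion_log
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
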
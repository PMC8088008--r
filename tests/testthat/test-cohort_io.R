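write_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

test_that("a valid CSV reads with row-count conservation", {
  path <- write_fixture(c(
    "participant_id,scan_index,scan_date,lmp_date,crl_cm,delivery_date,smoker",
    "P1,1,2020-03-10,2020-01-01,2.1,2020-10-01,FALSE",
    "P1,2,2020-04-01,2020-01-01,4.6,2020-10-01,FALSE",
    "P2,1,2020-03-15,2020-01-05,2.4,,TRUE"))
  on.exit(unlink(path))
  coh <- read_cohort(path)
  expect_s3_class(coh, "cohort_table")
  expect_equal(coh$metadata$n_o, 3)
  expect_equal(coh$metadata$n_p, 2)
  expect_equal(nrow(coh$metadata$exclusion_log), 0)
  # delivery date missing stays NA, not coerced
  expect_true(is.na(coh$outcomes$delivery_date[
    coh$outcomes$participant_id == "P2"]))
})

test_that("header-only file warns and yields an empty table", {
  path <- write_fixture("participant_id,scan_date,lmp_date,crl_cm")
  on.exit(unlink(path))
  expect_warning(coh <- read_cohort(path), "no data rows")
  expect_equal(coh$metadata$n_o, 0)
})

test_that("invalid rows are rejected with reasons, N_o is conserved", {
  path <- write_fixture(c(
    "participant_id,scan_date,lmp_date,crl_cm",
    "P1,2020-03-10,2020-01-01,2.1",
    "P2,2020-01-01,2020-03-10,2.1",   # scan before LMP
    "P3,2020-03-10,2020-01-01,12.5",  # CRL above plausibility bound
    "P4,not-a-date,2020-01-01,2.0"))  # unparseable date
  on.exit(unlink(path))
  coh <- read_cohort(path)
  log <- coh$metadata$exclusion_log
  expect_equal(coh$metadata$n_o, 1)
  expect_equal(coh$metadata$n_input_rows, nrow(log) + coh$metadata$n_o)
  expect_setequal(log$participant_id, c("P2", "P3", "P4"))
  expect_equal(log$reason[log$participant_id == "P2"], "negative GA")
  expect_match(log$reason[log$participant_id == "P3"], "implausible CRL")
  expect_match(log$reason[log$participant_id == "P4"], "unparseable")
})

test_that("ga_lmp_weeks is the exact day difference over 7", {
  base <- as.Date("2020-01-01")
  df <- data.frame(participant_id = c("A", "B", "C"),
                   scan_date = base + c(0, 7, 80),
                   lmp_date = base, crl_cm = c(1, 1, 1),
                   delivery_date = base + 273)
  coh <- as_cohort_table(df)
  expect_equal(coh$observations$ga_lmp_weeks, c(0, 1, 80 / 7))
  expect_true(all(coh$observations$ga_lmp_weeks >= 0))
})

test_that("write/read round-trip preserves all modelled fields", {
  coh <- generate_cohort(synthetic_config(n_participants = 10, seed = 4))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort(coh, path)
  # ISO-8601 on disk
  expect_match(readLines(path, n = 2)[2], "\\d{4}-\\d{2}-\\d{2}")
  back <- read_cohort(path, provenance = "synthetic")
  for (col in c("participant_id", "scan_index", "scan_date", "lmp_date",
                "ga_lmp_weeks")) {
    expect_equal(back$observations[[col]], coh$observations[[col]],
                 tolerance = 1e-12, label = col)
  }
  expect_equal(back$observations$crl_cm, coh$observations$crl_cm,
               tolerance = 1e-12)
  expect_equal(back$outcomes$delivery_date, coh$outcomes$delivery_date)
  expect_equal(back$metadata$n_o, coh$metadata$n_o)
})

test_that("triplicate CRL columns average into crl_cm", {
  path <- write_fixture(c(
    "participant_id,scan_date,lmp_date,crl1,crl2,crl3",
    "P1,2020-03-10,2020-01-01,2.0,2.2,2.4"))
  on.exit(unlink(path))
  coh <- read_cohort(path, crl_triplicate = c("crl1", "crl2", "crl3"))
  expect_equal(coh$observations$crl_cm, 2.2)
})

test_that("exclusion log serialises as JSON lines", {
  path_csv <- write_fixture(c(
    "participant_id,scan_date,lmp_date,crl_cm",
    "P1,2020-03-10,2020-01-01,2.1",
    "P2,2020-01-01,2020-03-10,2.1"))
  path_log <- tempfile(fileext = ".jsonl")
  on.exit(unlink(c(path_csv, path_log)))
  coh <- read_cohort(path_csv)
  write_exclusion_log(coh, path_log)
  rec <- jsonlite::fromJSON(readLines(path_log)[1])
  expect_equal(rec$participant_id, "P2")
  expect_equal(rec$reason, "negative GA")
})

test_that("schema errors on missing required columns", {
  path <- write_fixture(c("id,when", "P1,2020-01-01"))
  on.exit(unlink(path))
  expect_error(read_cohort(path), "schema error")
  # but a schema mapping can point at the nonstandard names
  sch <- cohort_schema(list(columns = list(participant_id = "id",
                                           scan_date = "when")))
  coh <- read_cohort(path, schema = sch)
  expect_equal(coh$metadata$n_o, 1)
})
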
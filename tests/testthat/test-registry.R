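# Registry model: CSV round trips, validation, and the inclusion filter.

test_that("cohort CSV round-trips at field level", {
  co <- worked_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$records, co$records)
  expect_equal(nrow(back$exclusion_log), 0L)
})

test_that("missing and unparseable optional fields become NA", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- make_record()
  rec$gcs <- ""    # blank optional
  rec$asa <- "n/a" # unparseable optional
  utils::write.csv(rec, path, row.names = FALSE)
  co <- read_cohort(path)
  expect_true(is.na(co$records$gcs))
  expect_true(is.na(co$records$asa))
})

test_that("format errors name the offending column", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- make_record()
  utils::write.csv(rec[, setdiff(names(rec), "died_in_hospital")], path,
                   row.names = FALSE)
  expect_error(read_cohort(path), "died_in_hospital")
  utils::write.csv(rec[0, ], path, row.names = FALSE)
  expect_error(read_cohort(path), "empty")
})

test_that("unparseable required fields raise", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- make_record()
  rec$age <- "eighty"
  utils::write.csv(rec, path, row.names = FALSE)
  expect_error(read_cohort(path), "age")
})

test_that("column map resolves non-canonical headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- make_record()
  names(rec)[names(rec) == "age"] <- "patient_age"
  utils::write.csv(rec, path, row.names = FALSE)
  expect_error(read_cohort(path), "age")
  co <- read_cohort(path, column_map = c(age = "patient_age"))
  expect_equal(co$records$age, 70L)
  expect_error(read_cohort(path, column_map = c(age = "nope")), "nope")
})

test_that("record validation enforces clinical ranges", {
  expect_error(validate_records(make_record(hn = 7)), "\\[0, 6\\]")
  expect_error(validate_records(make_record(gcs = 2)), "gcs")
  expect_error(validate_records(make_record(asa = 5)), "asa")
  expect_error(validate_records(rbind(make_record(id = "a"),
                                      make_record(id = "a"))),
               "duplicate")
  expect_error(validate_records(make_record(died = NA)), "died_in_hospital")
})

test_that("boolean fields accept the common spellings", {
  expect_equal(parse_boolean(c("1", "0", "true", "FALSE", "Yes", "no", "")),
               c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, NA))
  expect_error(parse_boolean("maybe"), "unparseable")
})

test_that("inclusion filter applies the documented rules", {
  co <- worked_fixture()
  f <- apply_inclusion_filter(co)
  reasons <- setNames(f$exclusion_log$reason, f$exclusion_log$patient_id)
  expect_equal(unname(reasons["W08_under_65"]), "under_65")
  expect_equal(unname(reasons["W09_missing_transfusion"]),
               "missing_transfusion_data")
  expect_equal(unname(reasons["W10_minor_no_icu"]), "minor_trauma_no_icu")
  expect_equal(unname(reasons["W11_transfer_in"]), "transfer")
  expect_equal(nrow(f$records) + nrow(f$exclusion_log), 12L)
  # minor trauma with ICU care stays in
  minor_icu <- new_cohort(make_record(ch = 0, ex = 2, icu = TRUE))
  expect_equal(nrow(apply_inclusion_filter(minor_icu)$records), 1L)
  # non-European hospital goes, and precedence puts under_65 first
  mixed <- new_cohort(rbind(
    make_record(id = "eu", region = "non_europe"),
    make_record(id = "young_noneu", age = 60, region = "non_europe")))
  log <- apply_inclusion_filter(mixed)$exclusion_log
  expect_equal(setNames(log$reason, log$patient_id),
               c(eu = "non_european", young_noneu = "under_65"))
})

test_that("filtering conserves counts and is idempotent", {
  for (seed in 1:3) {
    rec <- random_records(200, seed)
    rec$icu_admitted <- seed %% 2 == 0
    co <- new_cohort(rec)
    f1 <- apply_inclusion_filter(co)
    expect_equal(nrow(f1$records) + nrow(f1$exclusion_log), nrow(rec))
    f2 <- apply_inclusion_filter(f1)
    expect_equal(f2$records, f1$records)
    expect_equal(nrow(f2$exclusion_log), nrow(f1$exclusion_log))
  }
})

test_that("cohort summary reports percentages to one decimal", {
  one <- new_cohort(make_record(died = FALSE))
  s <- summarize_cohort(one)
  expect_equal(
    s$categorical$percent[s$categorical$measure == "hospital_mortality"],
    0.0)
  expect_error(summarize_cohort(new_cohort(make_record()[0, ])), "empty")
  # 2 deaths in 9 -> 22.2%
  rec <- make_record()[rep(1, 9), ]
  rec$patient_id <- letters[1:9]
  rec$died_in_hospital <- rep(c(TRUE, FALSE), c(2, 7))
  s9 <- summarize_cohort(new_cohort(rec))
  expect_equal(
    s9$categorical$percent[s9$categorical$measure == "hospital_mortality"],
    22.2)
})
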
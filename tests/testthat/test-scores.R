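# Score calculators: GERtality, ISS, GTOS.

test_that("the GERtality definition has the five published criteria", {
  def <- gertality_criteria()
  expect_length(def$criteria, 5L)
  expect_equal(definition_signature(def),
               c("age ge 80", "max_ais ge 4", "transfusion true NA",
                 "asa ge 3", "gcs le 13"))
  # GCS boundary: 13 scores the point, 14 does not
  rec13 <- validate_records(make_record(gcs = 13))
  rec14 <- validate_records(make_record(gcs = 14))
  gcs_crit <- def$criteria[[5]]
  expect_equal(criterion_status(gcs_crit, rec13), "met")
  expect_equal(criterion_status(gcs_crit, rec14), "not_met")
})

test_that("GERtality points sum the met criteria", {
  all5 <- validate_records(make_record(age = 85, hn = 5, prbc = TRUE,
                                       asa = 4, gcs = 3))
  none <- validate_records(make_record(age = 70, ch = 3, prbc = FALSE,
                                       asa = 2, gcs = 15))
  expect_equal(gertality_score(all5), 5L)
  expect_equal(gertality_score(none), 0L)
})

test_that("missing-data policies differ only on unknown components", {
  partial <- validate_records(make_record(age = 85, hn = 5, prbc = TRUE,
                                          asa = NA, gcs = 3))
  expect_equal(gertality_score(partial, "zero_points"), 4L)
  expect_true(is.na(gertality_score(partial, "propagate_missing")))
  complete <- validate_records(make_record(age = 85, hn = 5, prbc = TRUE,
                                           asa = 4, gcs = 3))
  expect_equal(gertality_score(complete, "zero_points"),
               gertality_score(complete, "propagate_missing"))
})

test_that("score equals brute-force count over all 32 criterion patterns", {
  # independent oracle: evaluate the five predicates directly per pattern
  grid <- expand.grid(a = c(FALSE, TRUE), b = c(FALSE, TRUE),
                      c = c(FALSE, TRUE), d = c(FALSE, TRUE),
                      e = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rec <- validate_records(make_record(
      age = if (g$a) 80 else 79,
      hn = if (g$b) 4 else 3,
      prbc = g$c,
      asa = if (g$d) 3 else 2,
      gcs = if (g$e) 13 else 14))
    oracle <- (rec$age >= 80) + (max_ais(rec) >= 4) + rec$prbc_pre_icu +
      (rec$asa >= 3) + (rec$gcs <= 13)
    expect_equal(gertality_score(rec), as.integer(oracle))
  }
})

test_that("worsening any single component never lowers the score", {
  worsen <- list(
    function(r) { r$age <- pmin(r$age + 10L, 100L); r },
    function(r) { r$ais_head_neck <- pmin(r$ais_head_neck + 2L, 6L); r },
    function(r) { r$prbc_pre_icu <- TRUE; r },
    function(r) { r$asa <- pmin(ifelse(is.na(r$asa), 4L, r$asa + 1L), 4L); r },
    function(r) { r$gcs <- pmax(ifelse(is.na(r$gcs), 3L, r$gcs - 3L), 3L); r })
  rec <- random_records(100, seed = 11)
  base <- gertality_score(rec)
  for (w in worsen) expect_true(all(gertality_score(w(rec)) >= base))
})

test_that("ISS follows the three-region sum-of-squares rule", {
  expect_equal(iss(validate_records(make_record(hn = 5, ch = 4, ab = 3))),
               50L)  # 25 + 16 + 9
  expect_equal(iss(validate_records(make_record(ch = 0))), 0L)
  expect_equal(iss(validate_records(make_record(hn = 6, ch = 0))), 75L)
  expect_error(iss(make_record(hn = 9)), "\\[0, 6\\]")
  # 75 arises only from an AIS-6 region or a sum of squares of exactly 75
  rec <- random_records(300, seed = 5)
  v <- iss(rec)
  expect_true(all(v <= 75L))
  m <- as.matrix(rec[, paste0("ais_", ais_regions())])
  ss75 <- apply(m, 1, function(x) sum(sort(x, TRUE)[1:3]^2)) == 75
  expect_equal(v == 75L, apply(m, 1, max) == 6 | ss75)
})

test_that("GTOS evaluates age + 2.5 ISS + 22 if transfused", {
  expect_equal(gtos(validate_records(make_record(age = 80, hn = 5, ch = 4,
                                                 ab = 3, prbc = TRUE))),
               227)
  expect_equal(gtos(validate_records(make_record(age = 65, ch = 0,
                                                 prbc = FALSE))), 65)
  expect_equal(gtos(validate_records(make_record(age = 70, hn = 5, ch = 3,
                                                 prbc = FALSE))), 155)
  expect_true(is.na(gtos(validate_records(make_record(prbc = NA)))))
  rec <- random_records(200, seed = 9)
  g <- gtos(rec)
  expect_true(all(is.na(g) | g >= rec$age))
})

test_that("score_cohort composes the per-record calculators", {
  expect_equal(nrow(score_cohort(new_cohort(make_record()[0, ]))), 0L)
  co <- apply_inclusion_filter(worked_fixture())
  sc <- score_cohort(co)
  expect_equal(nrow(sc), nrow(co$records))
  expect_equal(sc$gertality, gertality_score(co$records))
  expect_equal(sc$iss, iss(co$records))
  expect_equal(sc$gtos, gtos(co$records))
  expect_equal(sc$max_ais, max_ais(co$records))
  expect_true(all(sc$comp_transfusion %in% c("met", "not_met", "unknown")))
})
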
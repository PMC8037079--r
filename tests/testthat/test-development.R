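# Development procedure: 2x2 tables, odds ratios, cut-off search,
# logistic screening, criterion selection.

test_that("contingency tables partition the evaluable records", {
  # 2 exposed (1 died), 2 unexposed (0 died)
  co <- rate_cohort(2, 2, 0.5, 0)
  tab <- contingency(co, co$records$age >= 80)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1L, 1L, 0L, 2L))
  # predicate never true
  tab0 <- contingency(co, rep(FALSE, 4))
  expect_equal(c(tab0$a, tab0$b), c(0L, 0L))
  # criterion with missing inputs: unevaluable records dropped and counted
  rec <- rbind(make_record(id = "a", asa = 3, died = TRUE),
               make_record(id = "b", asa = 2),
               make_record(id = "c", asa = NA))
  tab2 <- contingency(validate_records(rec), make_criterion("asa", "ge", 3))
  expect_equal(tab2$n_dropped, 1L)
  expect_equal(tab2$a + tab2$b + tab2$c + tab2$d, 2L)
})

test_that("odds ratio matches the odds-form oracle on random tables", {
  set.seed(303)
  for (i in 1:200) {
    cells <- sample(1:500, 4)
    tab <- contingency_from_counts(cells[1], cells[2], cells[3], cells[4])
    res <- odds_ratio(tab)
    p1 <- cells[1] / (cells[1] + cells[2])
    p2 <- cells[3] / (cells[3] + cells[4])
    oracle <- (p1 / (1 - p1)) / (p2 / (1 - p2))
    expect_equal(res$or, oracle, tolerance = 1e-12)
    expect_true(res$ci_low <= res$or && res$or <= res$ci_high)
  }
})

test_that("odds ratio handles symmetry, continuity and zero cells", {
  eq <- odds_ratio(contingency_from_counts(30, 70, 60, 140))
  expect_equal(eq$or, 1.0)
  # Haldane correction: (1.5 * 2.5) / (1.5 * 0.5) = 5
  hald <- odds_ratio(contingency_from_counts(1, 1, 0, 2), continuity = 0.5)
  expect_equal(hald$or, 5.0)
  expect_false(hald$zero_cell)
  zero <- odds_ratio(contingency_from_counts(1, 1, 0, 2))
  expect_true(zero$zero_cell)
  expect_true(is.infinite(zero$or))
  expect_true(is.na(zero$ci_low))
})

test_that("published screening rows are reproduced from sizes and rates", {
  ref <- gertality_development_reference()
  for (i in seq_len(nrow(ref))) {
    a <- round(ref$mortality_exposed[i] * ref$n_exposed[i])
    c_ <- round(ref$mortality_unexposed[i] * ref$n_unexposed[i])
    res <- odds_ratio(contingency_from_counts(
      a, ref$n_exposed[i] - a, c_, ref$n_unexposed[i] - c_))
    expect_lt(abs(res$or - ref$or[i]), 0.1)
  }
})

test_that("cut-off search picks the least extreme qualifying cut-off", {
  # mortality 31.5% above 80, 12% at 75-79, 5% below: >=80 is the least
  # extreme cut-off reaching 30%
  n <- c(1000, 1000, 2000)
  deaths <- c(315, 120, 100)
  rec <- make_record()[rep(1, sum(n)), ]
  rec$patient_id <- sprintf("c%04d", seq_len(sum(n)))
  rec$age <- rep(c(85L, 77L, 70L), n)
  rec$died_in_hospital <- unlist(mapply(
    function(k, m) rep(c(TRUE, FALSE), c(k, m - k)), deaths, n,
    SIMPLIFY = FALSE))
  co <- new_cohort(rec)
  expect_equal(cutoff_search(co, "age", c(65, 70, 75, 80, 85), "ge", 0.30),
               80)
  # target 0: least extreme candidate wins outright
  expect_equal(cutoff_search(co, "age", c(65, 70, 75, 80, 85), "ge", 0), 65)
  # target 1 with survivors in every stratum: nothing qualifies
  expect_null(cutoff_search(co, "age", c(65, 70, 75, 80, 85), "ge", 1))
  # "le" dichotomies treat the largest cut-off as least extreme
  expect_equal(cutoff_search(co, "age", c(70, 77, 85), "le", 0), 85)
})

test_that("one-predictor logistic model reproduces the table odds ratio", {
  co <- rate_cohort(400, 600, 0.434, 0.204)
  tab <- contingency(co, co$records$age >= 80)
  crude <- odds_ratio(tab)
  fit <- logistic_fit(data.frame(exposed = co$records$age >= 80),
                      co$records$died_in_hospital)
  expect_equal(unname(fit$or["exposed"]), crude$or, tolerance = 1e-8)
})

test_that("logistic model is near-null when the outcome is independent", {
  set.seed(77)
  n <- 5000
  x <- data.frame(a = runif(n) < 0.4, b = runif(n) < 0.2,
                  c = runif(n) < 0.5)
  y <- runif(n) < 0.25
  fit <- logistic_fit(x, y)
  expect_true(all(abs(fit$or - 1) < 0.15))
})

test_that("degenerate logistic inputs raise diagnostic errors", {
  set.seed(8)
  n <- 200
  y <- runif(n) < 0.3
  expect_error(logistic_fit(data.frame(x = y), y), "separation")
  expect_error(logistic_fit(data.frame(x = rep(TRUE, n)), y), "constant")
  expect_error(logistic_fit(data.frame(a = runif(20) < .5,
                                       b = runif(20) < .5),
                            runif(20) < .5), "too few")
})

test_that("selection at threshold 2 recovers the GERtality definition", {
  ref <- gertality_development_reference()
  def <- select_criteria(ref, or_threshold = 2.0)
  expect_equal(definition_signature(def),
               definition_signature(gertality_criteria()))
  # threshold 3 keeps only the injury-severity and consciousness criteria
  def3 <- select_criteria(ref, or_threshold = 3.0)
  expect_equal(vapply(def3$criteria, `[[`, character(1), "variable"),
               c("max_ais", "gcs"))
  expect_warning(empty <- select_criteria(ref, or_threshold = Inf),
                 "no candidate")
  expect_length(empty$criteria, 0L)
})

test_that("selection output order ignores candidate input order", {
  ref <- gertality_development_reference()
  set.seed(4)
  shuffled <- ref[sample(nrow(ref)), ]
  expect_equal(definition_signature(select_criteria(shuffled)),
               definition_signature(select_criteria(ref)))
})

test_that("screening a synthetic cohort reports all eight candidates", {
  co <- apply_inclusion_filter(
    generate_cohort(generator_config(n = 8000, seed = 31)))
  rep_uni <- screen_candidates(co)
  expect_equal(rep_uni$variable,
               c("age", "max_ais", "transfusion", "asa", "gcs", "sex_male",
                 "mechanism_high_energy", "sbp"))
  # the strong components screen in with large odds ratios, the noise
  # dichotomies (sex, mechanism) stay near 1
  strong <- rep_uni[rep_uni$variable %in%
                      c("max_ais", "transfusion", "gcs"), ]
  expect_true(all(strong$or > 2))
  noise <- rep_uni[rep_uni$variable %in%
                     c("sex_male", "mechanism_high_energy"), ]
  expect_true(all(abs(noise$or - 1) < 0.3))
  # per-variable missingness is surfaced, not hidden
  expect_gt(rep_uni$n_dropped[rep_uni$variable == "gcs"], 0)
  # multivariable mode replaces the odds ratios by model-based ones
  rep_multi <- screen_candidates(co, mode = "multivariable")
  expect_false(isTRUE(all.equal(rep_uni$or, rep_multi$or)))
})
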
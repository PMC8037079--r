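# Builders for small deterministic test cohorts.

# One fully specified record with overridable fields.
make_record <- function(id = "p1", age = 70, hn = 0, fa = 0, ch = 3, ab = 0,
                        ex = 0, xt = 0, gcs = 15, asa = 2, sbp = 120,
                        prbc = FALSE, icu = TRUE, sex = "male",
                        mechanism = "low_fall", transfer = "primary",
                        region = "europe", died = FALSE) {
  data.frame(patient_id = id, age = age, sex = sex,
             ais_head_neck = hn, ais_face = fa, ais_chest = ch,
             ais_abdomen = ab, ais_extremities = ex, ais_external = xt,
             gcs = gcs, asa = asa, sbp = sbp, prbc_pre_icu = prbc,
             icu_admitted = icu, mechanism = mechanism,
             transfer_status = transfer, region_of_hospital = region,
             died_in_hospital = died, stringsAsFactors = FALSE)
}

make_records <- function(...) {
  rows <- list(...)
  recs <- do.call(rbind, rows)
  recs$patient_id <- sprintf("p%03d", seq_len(nrow(recs)))
  recs
}

# Cohort of n records with a given exposure flag and per-group mortality,
# death counts exact (deterministic), exposure = age >= 80.
rate_cohort <- function(n_exposed, n_unexposed, mort_exposed,
                        mort_unexposed) {
  n <- n_exposed + n_unexposed
  age <- rep(c(85L, 70L), c(n_exposed, n_unexposed))
  deaths_e <- round(mort_exposed * n_exposed)
  deaths_u <- round(mort_unexposed * n_unexposed)
  died <- c(rep(c(TRUE, FALSE), c(deaths_e, n_exposed - deaths_e)),
            rep(c(TRUE, FALSE), c(deaths_u, n_unexposed - deaths_u)))
  rec <- make_record()[rep(1, n), ]
  rec$patient_id <- sprintf("r%05d", seq_len(n))
  rec$age <- age
  rec$died_in_hospital <- died
  new_cohort(rec)
}

# Random valid records for property-style tests.
random_records <- function(n, seed) {
  set.seed(seed)
  rec <- make_record()[rep(1, n), ]
  rec$patient_id <- sprintf("q%04d", seq_len(n))
  rec$age <- sample(65:95, n, TRUE)
  for (col in paste0("ais_", ais_regions())) {
    rec[[col]] <- sample(0:5, n, TRUE)
  }
  rec$gcs <- sample(c(NA, 3:15), n, TRUE)
  rec$asa <- sample(c(NA, 1:4), n, TRUE)
  rec$prbc_pre_icu <- sample(c(TRUE, FALSE, NA), n, TRUE)
  rec$died_in_hospital <- sample(c(TRUE, FALSE), n, TRUE)
  validate_records(rec)
}

# Independent O(n_pos * n_neg) AUC oracle: explicit pair counting with
# ties worth one half.
brute_force_auc <- function(scores, outcomes) {
  pos <- scores[as.logical(outcomes)]
  neg <- scores[!as.logical(outcomes)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

definition_signature <- function(def) {
  vapply(def$criteria, function(cr) {
    paste(cr$variable, cr$direction, cr$cutoff)
  }, character(1))
}
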
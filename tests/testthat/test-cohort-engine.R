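test_that("span merging joins overlapping and adjacent coverage", {
  adj <- tibble::tibble(
    start_date = as.Date(c("2016-01-01", "2016-07-01")),
    end_date = as.Date(c("2016-06-30", "2016-12-31"))
  )
  m <- merge_spans(adj)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start_date, as.Date("2016-01-01"))
  expect_equal(m$end_date, as.Date("2016-12-31"))

  overlap <- tibble::tibble(
    start_date = as.Date(c("2016-01-01", "2016-02-01")),
    end_date = as.Date(c("2016-03-01", "2016-04-01"))
  )
  m2 <- merge_spans(overlap)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$end_date, as.Date("2016-04-01"))

  expect_equal(nrow(merge_spans(adj[0, ])), 0L)

  # contained span, out-of-order input
  weird <- tibble::tibble(
    start_date = as.Date(c("2016-05-01", "2016-01-01", "2016-02-01")),
    end_date = as.Date(c("2016-05-10", "2016-12-31", "2016-03-01"))
  )
  m3 <- merge_spans(weird)
  expect_equal(nrow(m3), 1L)
  expect_equal(as.character(m3$end_date), "2016-12-31")
})

test_that("continuous enrollment requires whole-year coverage up to gap_days", {
  full <- tibble::tibble(start_date = as.Date("2016-01-01"),
                         end_date = as.Date("2016-12-31"))
  expect_true(continuously_enrolled(full, 2016))
  short <- tibble::tibble(start_date = as.Date("2016-01-01"),
                          end_date = as.Date("2016-12-30"))
  expect_false(continuously_enrolled(short, 2016))
  gap1 <- tibble::tibble(
    start_date = as.Date(c("2016-01-01", "2016-07-02")),
    end_date = as.Date(c("2016-06-30", "2016-12-31"))
  )
  expect_false(continuously_enrolled(gap1, 2016, gap_days = 0))
  expect_true(continuously_enrolled(gap1, 2016, gap_days = 1))
  # oracle agreement at gap_days = 0 on assorted span sets
  sets <- list(full, short, gap1,
               tibble::tibble(start_date = as.Date("2015-06-01"),
                              end_date = as.Date("2017-06-01")))
  for (s in sets) {
    expect_identical(continuously_enrolled(s, 2016, 0),
                     oracle_year_covered(s, 2016))
  }
})

test_that("era gating partitions claims at the ICD-10 transition date", {
  cfg <- study_config()
  expect_true(era_valid("icd9cm", as.Date("2015-09-30"), cfg))
  expect_false(era_valid("icd9cm", as.Date("2015-10-01"), cfg))
  expect_false(era_valid("icd9cm", as.Date("2015-11-15"), cfg))
  expect_true(era_valid("icd10cm", as.Date("2015-10-01"), cfg))
  expect_false(era_valid("icd10cm", as.Date("2015-09-30"), cfg))
})

test_that("the first qualifying claim indexes; setting scope filters", {
  b <- claims_bundle(
    persons = mini_person("A", 1950L),
    enrollment = mini_span("A"),
    diagnoses = dplyr::bind_rows(
      mini_dx("A", "2016-03-01", "I214", "icd10cm", setting = "emergency_department"),
      mini_dx("A", "2016-05-01", "I214", "icd10cm", setting = "inpatient")
    )
  )
  cl <- ami_code_list()
  any_c <- build_cohort(b, cl, year_period(2016), "any_healthcare")
  expect_equal(any_c$events$index_date, as.Date("2016-03-01"))
  inp <- build_cohort(b, cl, year_period(2016), "inpatient")
  expect_equal(inp$events$index_date, as.Date("2016-05-01"))
  expect_equal(any_c$denominator, 1L)
})

test_that("infants are excluded from numerator and denominator", {
  b <- claims_bundle(
    persons = dplyr::bind_rows(mini_person("BABY", 2016L), mini_person("AD", 1960L)),
    enrollment = dplyr::bind_rows(mini_span("BABY"), mini_span("AD")),
    diagnoses = dplyr::bind_rows(
      mini_dx("BABY", "2016-06-01", "I214", "icd10cm"),
      mini_dx("AD", "2016-06-01", "I214", "icd10cm")
    )
  )
  coh <- build_cohort(b, ami_code_list(), year_period(2016))
  expect_equal(coh$events$person_id, "AD")
  expect_equal(coh$denominator, 1L)
  # the same infant ages into the 2017 cohort
  coh17 <- build_cohort(b, ami_code_list(), year_period(2017))
  expect_equal(coh17$denominator, 2L)
})

test_that("era-invalid claims never index and the era partition holds", {
  b <- claims_bundle(
    persons = mini_person("A", 1950L),
    enrollment = mini_span("A"),
    diagnoses = dplyr::bind_rows(
      # ICD-9 code after the transition: an overt coding error, ignored
      mini_dx("A", "2015-11-15", "41071", "icd9cm"),
      mini_dx("A", "2015-12-01", "I214", "icd10cm")
    )
  )
  coh <- build_cohort(b, ami_code_list(), year_period(2015))
  expect_equal(coh$events$index_date, as.Date("2015-12-01"))
  expect_equal(coh$events$version, "icd10cm")

  bb <- shared_test_bundle()
  coh2 <- build_cohort(bb, ami_code_list(), combined_period())
  cfg <- study_config()
  bad <- (coh2$events$version == "icd9cm" &
            coh2$events$index_date >= cfg$era_boundary) |
    (coh2$events$version == "icd10cm" &
       coh2$events$index_date < cfg$era_boundary)
  expect_false(any(bad))
})

test_that("same-day ties prefer inpatient, then principal position, then code", {
  b <- claims_bundle(
    persons = mini_person("A", 1950L),
    enrollment = mini_span("A"),
    diagnoses = dplyr::bind_rows(
      mini_dx("A", "2016-03-01", "I219", "icd10cm", "principal", "emergency_department"),
      mini_dx("A", "2016-03-01", "I214", "icd10cm", "secondary", "inpatient")
    )
  )
  coh <- build_cohort(b, ami_code_list(), year_period(2016))
  expect_equal(coh$events$setting, "inpatient")
  expect_equal(coh$events$code, "I214")
})

test_that("cohort equals the per-person brute-force oracle on generated bundles", {
  cl <- ami_code_list()
  cfg <- study_config()
  for (s in c(5L, 23L)) {
    b <- generate_bundle(
      generator_config(n_persons = 120L, annual_ami_rate = 100,
                       enrollment_gap_prob = 0.2), s
    )
    for (scope in c("any_healthcare", "inpatient")) {
      for (period in list(combined_period(), year_period(2015))) {
        got <- build_cohort(b, cl, period, scope, cfg)
        want <- oracle_cohort(b, cl, period, scope, cfg)
        expect_equal(got$denominator, want$denominator)
        if (is.null(want$events)) {
          expect_equal(nrow(got$events), 0L)
        } else {
          want_ev <- want$events[order(want$events$person_id), ]
          got_ev <- got$events[order(got$events$person_id), ]
          expect_equal(got_ev$person_id, want_ev$person_id)
          expect_equal(got_ev$index_date, want_ev$service_date)
          expect_equal(got_ev$code, want_ev$code)
          expect_equal(got_ev$setting, want_ev$setting)
        }
      }
    }
  }
})

test_that("cohort construction is invariant to record order", {
  b <- shared_test_bundle()
  cl <- ami_code_list()
  coh1 <- build_cohort(b, cl, combined_period())
  set.seed(99)
  shuf <- claims_bundle(
    persons = b$persons[sample(nrow(b$persons)), ],
    enrollment = b$enrollment[sample(nrow(b$enrollment)), ],
    diagnoses = b$diagnoses[sample(nrow(b$diagnoses)), ],
    drugs = b$drugs, procedures = b$procedures, admissions = b$admissions
  )
  coh2 <- build_cohort(shuf, cl, combined_period())
  o1 <- coh1$events[order(coh1$events$person_id), ]
  o2 <- coh2$events[order(coh2$events$person_id), ]
  expect_equal(as.data.frame(o1), as.data.frame(o2))
  expect_equal(coh1$denominator, coh2$denominator)
})

test_that("narrowing scope or shortening the period never adds persons", {
  b <- shared_test_bundle()
  cl <- ami_code_list()
  full_any <- build_cohort(b, cl, combined_period(), "any_healthcare")
  full_inp <- build_cohort(b, cl, combined_period(), "inpatient")
  expect_true(all(full_inp$events$person_id %in% full_any$events$person_id))
  for (y in 2014:2017) {
    yr <- build_cohort(b, cl, year_period(y), "any_healthcare")
    expect_true(all(yr$events$person_id %in% full_any$events$person_id))
  }
})

test_that("version attribution satisfies inclusion-exclusion", {
  b <- shared_test_bundle()
  cl <- ami_code_list()
  for (period in list(year_period(2015), combined_period())) {
    att <- version_attribution(b, cl, period)
    c9 <- build_cohort(b, restrict_codelist(cl, "icd9cm"), period)
    c10 <- build_cohort(b, restrict_codelist(cl, "icd10cm"), period)
    call <- build_cohort(b, cl, period)
    expect_equal(att$icd9_only + att$icd10_only + att$both, att$total)
    expect_equal(att$total, nrow(call$events))
    expect_equal(nrow(call$events),
                 nrow(c9$events) + nrow(c10$events) - att$both)
  }
})

test_that("a person diagnosed under both versions in 2015 is counted once", {
  b <- claims_bundle(
    persons = mini_person("A", 1950L),
    enrollment = mini_span("A"),
    diagnoses = dplyr::bind_rows(
      mini_dx("A", "2015-06-01", "41071", "icd9cm"),
      mini_dx("A", "2015-11-01", "I214", "icd10cm")
    )
  )
  cl <- ami_code_list()
  att <- version_attribution(b, cl, year_period(2015))
  expect_equal(att$both, 1L)
  expect_equal(att$total, 1L)
  coh <- build_cohort(b, cl, year_period(2015))
  expect_equal(nrow(coh$events), 1L)
  expect_equal(coh$events$version, "icd9cm")

  solo <- claims_bundle(
    persons = mini_person("A", 1950L), enrollment = mini_span("A"),
    diagnoses = mini_dx("A", "2015-06-01", "41071", "icd9cm")
  )
  att2 <- version_attribution(solo, cl, year_period(2015))
  expect_equal(att2$icd9_only, 1L)
  expect_equal(att2$both, 0L)
})

test_that("an empty code list is a configuration error", {
  b <- shared_test_bundle()
  expect_error(code_list("empty", tibble::tibble(pattern = character(),
                                                 version = character())),
               "empty")
})
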
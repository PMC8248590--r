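# a small cohort + claims fixture built by hand around known index dates
two_person_cohort <- function() {
  b <- claims_bundle(
    persons = dplyr::bind_rows(mini_person("A", 1950L, "male"),
                               mini_person("B", 1940L, "female")),
    enrollment = dplyr::bind_rows(mini_span("A"), mini_span("B")),
    diagnoses = dplyr::bind_rows(
      mini_dx("A", "2016-03-10", "I214", "icd10cm"),
      mini_dx("B", "2016-06-20", "I213", "icd10cm")
    )
  )
  list(bundle = b,
       cohort = build_cohort(b, ami_code_list(), year_period(2016)))
}

test_that("percentages round half away from zero at printed precision", {
  expect_equal(pct(170147, 268424), 63.4)
  expect_equal(pct(164804, 268424), 61.4)
  expect_equal(pct(68311, 133075), 51.3)
  expect_equal(pct(0, 5), 0.0)
  expect_equal(pct(1, 8, 1), 12.5)
  expect_equal(pct(1, 16, 1), 6.3)  # 6.25 rounds away from zero
  expect_error(pct(1, 0), "denominator")
  expect_equal(per_thousand(80411, 28407959), 2.83)
  expect_equal(per_thousand(0, 100), 0)
  expect_error(per_thousand(1, 0), "denominator")
})

test_that("window boundaries are inclusive at both ends", {
  tp <- two_person_cohort()
  w <- condition_window()
  claims <- dplyr::bind_rows(
    mini_dx("A", "2016-03-11", "R079", "icd10cm"),  # index + 1: in
    mini_dx("A", "2016-03-09", "I10", "icd10cm"),   # index - 1: in
    mini_dx("A", "2016-03-12", "E785", "icd10cm"),  # index + 2: out
    mini_dx("A", "2016-03-08", "I509", "icd10cm")   # index - 2: out
  )
  ft <- windowed_items(tp$cohort, claims, w, "code", "service_date")
  expect_setequal(ft$item, c("R079", "I10"))

  w14 <- treatment_window()
  drugs <- tibble::tibble(
    person_id = "A",
    order_date = as.Date("2016-03-10") + c(-1, 14, 15, -2),
    product_code = "D", product_name = paste0("p", 1:4)
  )
  ft2 <- windowed_items(tp$cohort, drugs, w14, "product_name", "order_date")
  expect_setequal(ft2$item, c("p1", "p2"))
})

test_that("a person counts once per item and the index code is not excluded", {
  tp <- two_person_cohort()
  claims <- dplyr::bind_rows(
    mini_dx("A", "2016-03-10", "R079", "icd10cm"),
    mini_dx("A", "2016-03-11", "R079", "icd10cm"),   # duplicate item
    mini_dx("A", "2016-03-11", "I214", "icd10cm"),   # additional AMI code
    mini_dx("B", "2016-06-20", "R079", "icd10cm")
  )
  ft <- windowed_items(tp$cohort, claims, condition_window(), "code",
                       "service_date")
  expect_equal(ft$person_count[ft$item == "R079"], 2L)
  expect_equal(ft$person_count[ft$item == "I214"], 1L)
  expect_equal(ft$pct_of_cohort[ft$item == "R079"], 100.0)
  expect_true(all(ft$person_count <= nrow(tp$cohort$events)))
})

test_that("windowed ranking equals the naive per-person oracle", {
  cfg <- generator_config(n_persons = 60L, annual_ami_rate = 150)
  b <- generate_bundle(cfg, 13L)
  coh <- build_cohort(b, ami_code_list(), combined_period())
  for (w in list(condition_window(), treatment_window(), window_spec(0, 0))) {
    got <- windowed_items(coh, b$diagnoses, w, "code", "service_date")
    want <- oracle_windowed_items(coh, b$diagnoses, w, "code", "service_date")
    expect_equal(got$item, want$item)
    expect_equal(got$person_count, want$person_count)
  }
  # narrowing the window is monotone in every person_count
  wide <- windowed_items(coh, b$diagnoses, treatment_window(), "code",
                         "service_date")
  narrow <- windowed_items(coh, b$diagnoses, window_spec(-1, 7), "code",
                           "service_date")
  joined <- dplyr::left_join(narrow, wide, by = "item",
                             suffix = c("_narrow", "_wide"))
  expect_true(all(joined$person_count_narrow <= joined$person_count_wide))
})

test_that("drug classes come from top-ranked products with per-person dedup", {
  tp <- two_person_cohort()
  cat <- tibble::tibble(
    product_name = c("metoprolol tartrate", "carvedilol", "atorvastatin calcium"),
    class = c("beta_blocker", "beta_blocker", "anti_lipid")
  )
  drugs <- tibble::tibble(
    person_id = c("A", "A", "B"),
    order_date = as.Date(c("2016-03-12", "2016-03-20", "2016-06-21")),
    product_code = "X",
    product_name = c("metoprolol tartrate", "carvedilol", "atorvastatin calcium")
  )
  tbl <- drug_class_table(tp$cohort, drugs, treatment_window(), cat)
  # two distinct beta-blocker products for one person count once
  expect_equal(tbl$person_count[tbl$class == "beta_blocker"], 1L)
  expect_equal(tbl$person_count[tbl$class == "anti_lipid"], 1L)

  # orders outside the window leave an empty table
  late <- dplyr::mutate(drugs, order_date = order_date + 400)
  expect_equal(nrow(drug_class_table(tp$cohort, late, treatment_window(), cat)), 0L)

  # products beyond the top-N never contribute to a class
  tbl2 <- drug_class_table(tp$cohort, drugs, treatment_window(), cat,
                           top_products = 1L)
  expect_equal(nrow(attr(tbl2, "top_products")), 1L)
  expect_false("carvedilol" %in% attr(tbl2, "top_products")$item &&
                 "metoprolol tartrate" %in% attr(tbl2, "top_products")$item)

  # unmapped products fall into "other"
  mystery <- tibble::tibble(person_id = "A", order_date = as.Date("2016-03-12"),
                            product_code = "X", product_name = "mystery drug")
  tbl3 <- drug_class_table(tp$cohort, mystery, treatment_window(), cat)
  expect_equal(tbl3$class, "other")
})

test_that("calibrated generator recovers the configured drug-class ranking", {
  cfg <- generator_config(n_persons = 4000L, annual_ami_rate = 150)
  b <- generate_bundle(cfg, 31L)
  coh <- build_cohort(b, ami_code_list(), combined_period())
  tbl <- drug_class_table(coh, b$drugs, treatment_window(), drug_classes())
  top3 <- tbl$class[1:3]
  expect_equal(top3, c("beta_blocker", "anti_lipid", "anti_platelet"))
})

test_that("multi-code any-of query matches the union over windowed rows", {
  cfg <- generator_config(n_persons = 300L, annual_ami_rate = 150)
  b <- generate_bundle(cfg, 17L)
  coh <- build_cohort(b, ami_code_list(), combined_period())
  res <- multi_code_any(coh, b$procedures, treatment_window(), ekg_codes())
  # cross-check: union of persons over the per-code windowed rows
  x <- windowed_items(coh, b$procedures, treatment_window(), "procedure_code",
                      "service_date")
  pairs <- dplyr::inner_join(
    coh$events[c("person_id", "index_date")], b$procedures, by = "person_id",
    relationship = "many-to-many"
  )
  rel <- as.integer(pairs$service_date) - as.integer(pairs$index_date)
  pairs <- pairs[rel >= -1 & rel <= 14 & pairs$procedure_code %in% ekg_codes(), ]
  expect_equal(res$person_count, length(unique(pairs$person_id)))
  expect_equal(res$pct, pct(res$person_count, nrow(coh$events)))
  expect_error(multi_code_any(coh, b$procedures, treatment_window(),
                              character(0)), "non-empty")
})

test_that("length-of-stay summary floors at one day and links admissions", {
  b <- claims_bundle(
    persons = dplyr::bind_rows(mini_person("A", 1950L), mini_person("B", 1940L),
                               mini_person("C", 1930L)),
    enrollment = dplyr::bind_rows(mini_span("A"), mini_span("B"), mini_span("C")),
    diagnoses = dplyr::bind_rows(
      mini_dx("A", "2016-03-10", "I214", "icd10cm"),
      mini_dx("B", "2016-06-20", "I213", "icd10cm"),
      mini_dx("C", "2016-08-01", "I219", "icd10cm")
    ),
    admissions = tibble::tibble(
      person_id = c("A", "B"),
      admit_date = as.Date(c("2016-03-10", "2016-06-19")),
      discharge_date = as.Date(c("2016-03-10", "2016-06-26"))  # same-day & 7-day
    )
  )
  coh <- build_cohort(b, ami_code_list(), year_period(2016), "inpatient")
  los <- los_summary(coh, b$admissions)
  expect_equal(los$n, 2L)
  expect_equal(los$n_unlinked, 1L)  # C has no admission containing the index
  expect_equal(sort(los$los$los), c(1L, 7L))  # admit == discharge floors to 1
  expect_equal(los$median, 4)
  expect_equal(sum(los$band_props), 1)
})

test_that("median-exclusive quartiles and band proportions behave", {
  # LOS list [1,2,3,4,100]: median 3, lower-half median 1.5, upper 52
  coh <- structure(list(
    events = tibble::tibble(
      person_id = letters[1:5],
      index_date = as.Date("2016-06-01") + 0:4,
      code = "I214", version = "icd10cm", setting = "inpatient",
      gender = "male", age_at_index = 60L
    ),
    period = year_period(2016), setting_scope = "inpatient",
    denominator = 5L, config = study_config()
  ), class = "cohort")
  adm <- tibble::tibble(
    person_id = letters[1:5],
    admit_date = coh$events$index_date,
    discharge_date = coh$events$index_date + c(1, 2, 3, 4, 100)
  )
  los <- los_summary(coh, adm)
  expect_equal(los$median, 3)
  expect_equal(los$iqr, c(1.5, 52))
  expect_equal(los$range, c(1, 100))
  expect_equal(unname(los$band_props), c(0.8, 0, 0, 0.2))

  # constant LOS: zero SD and all mass in one band
  adm2 <- dplyr::mutate(adm, discharge_date = admit_date + 3)
  los2 <- los_summary(coh, adm2)
  expect_equal(los2$sd, 0)
  expect_equal(unname(los2$band_props), c(1, 0, 0, 0))
})

test_that("demographics bins sum to size and male share uses pct rounding", {
  one <- structure(list(
    events = tibble::tibble(
      person_id = "A", index_date = as.Date("2016-06-01"), code = "I214",
      version = "icd10cm", setting = "inpatient", gender = "male",
      age_at_index = 70L
    ),
    period = year_period(2016), setting_scope = "any_healthcare",
    denominator = 1L, config = study_config()
  ), class = "cohort")
  d <- demographics(one)
  expect_equal(d$size, 1L)
  expect_equal(d$age_bins$n[d$age_bins$bin == "65+"], 1L)
  expect_equal(d$male_pct, 100.0)

  b <- shared_test_bundle()
  coh <- build_cohort(b, ami_code_list(), combined_period())
  dd <- demographics(coh)
  expect_equal(sum(dd$age_bins$n), dd$size)
  expect_equal(dd$male_n, sum(coh$events$gender == "male"))

  dv <- demographics_by_version(b, ami_code_list(), combined_period())
  expect_equal(sum(dv$combined$age_bins$n), dv$combined$size)
  att <- version_attribution(b, ami_code_list(), combined_period())
  expect_equal(dv$icd9$size + dv$icd10$size - att$both, dv$combined$size)
})

test_that("annual series straddle year satisfies inclusion-exclusion", {
  b <- shared_test_bundle()
  ser <- annual_series(b, ami_code_list(), 2014:2017)
  expect_equal(nrow(ser), 4L)
  s15 <- ser[ser$year == 2015, ]
  expect_equal(s15$icd9_cases + s15$icd10_cases - s15$both_versions, s15$cases)
  expect_equal(ser$icd10_cases[ser$year == 2014], 0L)
  expect_equal(ser$icd9_cases[ser$year == 2016], 0L)
  expect_equal(ser$per_1000,
               per_thousand(ser$cases, ser$denominator))
})

test_that("gender-age curves match a brute-force stratified count", {
  cfg <- generator_config(n_persons = 100L, annual_ami_rate = 150)
  b <- generate_bundle(cfg, 29L)
  coh <- build_cohort(b, ami_code_list(), combined_period())
  curve <- gender_age_curve(coh, b)
  # brute force: count cohort members per (gender, age_at_index)
  for (i in seq_len(nrow(curve$by_age))) {
    g <- curve$by_age$gender[i]; a <- curve$by_age$age[i]
    want <- sum(coh$events$gender == g & coh$events$age_at_index == a)
    expect_equal(curve$by_age$cases[i], want)
  }
  expect_true(all(curve$by_age$enrollees > 0))
  expect_equal(sum(curve$by_bin$cases), nrow(coh$events))

  # empty cohort gives an all-zero curve
  empty_b <- claims_bundle(persons = mini_person("A", 1950L),
                           enrollment = mini_span("A"))
  empty_coh <- build_cohort(empty_b, ami_code_list(), combined_period())
  ec <- gender_age_curve(empty_coh, empty_b)
  expect_true(all(ec$by_age$cases == 0))

  # configured male excess shows up as male dominance at older ages
  cfg2 <- generator_config(n_persons = 3000L, annual_ami_rate = 100)
  b2 <- generate_bundle(cfg2, 41L)
  coh2 <- build_cohort(b2, ami_code_list(), combined_period())
  c2 <- gender_age_curve(coh2, b2)$by_bin
  old <- c2[c2$age_bin %in% c("55-64", "65+"), ]
  m <- old[old$gender == "male", ]; f <- old[old$gender == "female", ]
  expect_true(mean(m$per_1000) > mean(f$per_1000))
})

test_that("category tables bucket unmapped items into other", {
  tp <- two_person_cohort()
  claims <- dplyr::bind_rows(
    mini_dx("A", "2016-03-10", "I10", "icd10cm"),
    mini_dx("A", "2016-03-10", "ZZZ9", "icd10cm"),
    mini_dx("B", "2016-06-20", "E785", "icd10cm")
  )
  tbl <- category_table(tp$cohort, claims, condition_window(), "code",
                        "service_date", condition_categories())
  expect_setequal(tbl$category, c("cardiac", "endocrine", "other"))
  expect_equal(tbl$person_count[tbl$category == "other"], 1L)
})
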
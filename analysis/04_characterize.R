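#!/usr/bin/env Rscript
# Stage 4: descriptive characterization of the extracted cohorts.
#
# Reproduces every table-shaped output of the characterization study on the
# simulated cohorts: demographics by code version, concurrent diagnoses in
# the +/-1-day window, drug classes and procedures in the -1/+14-day
# window, the any-EKG query, length of stay, and gender-age curves.
# Requires scratch/bundle from stage 1.

library(amiclaims)

stopifnot(dir.exists("scratch/bundle"))
bundle <- read_bundle("scratch/bundle")
codelist <- ami_code_list()
period <- query_period("2014-01-01", "2017-12-31")
out <- "results/04_characterization"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

coh_any <- build_cohort(bundle, codelist, period, "any_healthcare")
coh_inp <- build_cohort(bundle, codelist, period, "inpatient")

## demographics, by code version --------------------------------------------
dem <- demographics_by_version(bundle, codelist, period)
for (s in c("icd9", "icd10", "combined")) {
  message("Demographics (", s, "): n = ", dem[[s]]$size,
          ", mean age ", round(dem[[s]]$mean_age, 1),
          ", male ", dem[[s]]$male_pct, "%",
          ", 65+ ", dem[[s]]$age_bins$pct[6], "%")
}
dem_rows <- lapply(c("icd9", "icd10", "combined"), function(s) {
  d <- dem[[s]]
  tibble::tibble(stratum = s, size = d$size, mean_age = d$mean_age,
                 sd_age = d$sd_age, male_n = d$male_n, male_pct = d$male_pct,
                 bin = d$age_bins$bin, bin_n = d$age_bins$n,
                 bin_pct = d$age_bins$pct)
})
readr::write_csv(dplyr::bind_rows(dem_rows), file.path(out, "demographics.csv"))

## concurrent conditions (+/- 1 day), by version stratum ---------------------
for (v in c("icd9cm", "icd10cm")) {
  cv <- build_cohort(bundle, restrict_codelist(codelist, v), period)
  ft <- windowed_items(cv, bundle$diagnoses, condition_window(), "code",
                       "service_date", top_n = 100L)
  readr::write_csv(ft, file.path(out, paste0("concurrent_conditions_", v, ".csv")))
  message("Top concurrent codes (", v, "): ",
          paste(utils::head(ft$item, 3), collapse = ", "),
          " (", paste(utils::head(ft$pct_of_cohort, 3), collapse = "%, "), "%)")
}

## drug classes from the top-100 products (-1 to +14 days) -------------------
drugs_tbl <- drug_class_table(coh_any, bundle$drugs, treatment_window(),
                              drug_classes())
print(as.data.frame(drugs_tbl))
readr::write_csv(drugs_tbl, file.path(out, "drug_classes_any.csv"))
readr::write_csv(attr(drugs_tbl, "top_products"),
                 file.path(out, "top_drug_products_any.csv"))
drugs_inp <- drug_class_table(coh_inp, bundle$drugs, treatment_window(),
                              drug_classes())
readr::write_csv(drugs_inp, file.path(out, "drug_classes_inpatient.csv"))

## procedures and the any-EKG query ------------------------------------------
proc <- windowed_items(coh_any, bundle$procedures, treatment_window(),
                       "procedure_code", "service_date", top_n = 100L)
readr::write_csv(proc, file.path(out, "procedures_any.csv"))
proc_cat <- category_table(coh_any, bundle$procedures, treatment_window(),
                           "procedure_code", "service_date",
                           procedure_categories())
readr::write_csv(proc_cat, file.path(out, "procedure_categories_any.csv"))
ekg <- multi_code_any(coh_any, bundle$procedures, treatment_window(), ekg_codes())
ekg_inp <- multi_code_any(coh_inp, bundle$procedures, treatment_window(), ekg_codes())
message(sprintf("Any EKG code within -1/+14 days: %.1f%% (any setting), %.1f%% (inpatient)",
                ekg$pct, ekg_inp$pct))

## length of stay -------------------------------------------------------------
los <- los_summary(coh_inp, bundle$admissions)
print(los)
jsonlite::write_json(
  list(n = los$n, n_unlinked = los$n_unlinked, mean = los$mean, sd = los$sd,
       median = los$median, iqr = los$iqr, range = los$range,
       band_props = as.list(los$band_props), ekg_any = ekg, ekg_inpatient = ekg_inp),
  file.path(out, "los_and_ekg.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA
)

## gender-age curves -----------------------------------------------------------
curve <- gender_age_curve(coh_any, bundle)
readr::write_csv(curve$by_age, file.path(out, "gender_age_curve.csv"))
readr::write_csv(curve$by_bin, file.path(out, "gender_agebin_curve.csv"))
old <- curve$by_bin[curve$by_bin$age_bin == "65+", ]
message("Per-1,000 proportion at 65+: ",
        paste(sprintf("%s %.1f", old$gender, old$per_1000), collapse = ", "))

message("Characterization written to ", out)
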
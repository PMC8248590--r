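# One-call orchestration: generate (or read) a bundle, build the cohorts,
# run the characterization analyses and write machine-readable reports.

#' Packaged electrocardiogram procedure codes
#'
#' The three CPT codes for a routine EKG: tracing with interpretation and
#' report (93000), tracing only (93005), interpretation and report only
#' (93010). Used by the "any EKG" multi-code query; override to match the
#' coding of another data source.
#'
#' @return Character vector of three codes.
#' @export
ekg_codes <- function() c("93000", "93005", "93010")

#' Packaged condition category map
#'
#' Maps diagnosis codes to organ-system categories (cardiac, endocrine,
#' pulmonary, ...). Unmapped codes fall into `"other"` downstream.
#'
#' @return Tibble with columns `item`, `category`.
#' @export
condition_categories <- function() {
  path <- system.file("extdata", "condition_categories.csv",
                      package = "amiclaims", mustWork = TRUE)
  readr::read_csv(path, col_types = "cc", progress = FALSE)
}

#' Packaged drug-class catalogue
#'
#' Maps drug product names to cardiac drug classes (beta_blocker,
#' anti_lipid, anti_platelet, ace_arb, anti_anginal, diuretic,
#' calcium_channel_blocker, other).
#'
#' @return Tibble with columns `product_name`, `class`.
#' @export
drug_classes <- function() {
  path <- system.file("extdata", "drug_classes.csv",
                      package = "amiclaims", mustWork = TRUE)
  readr::read_csv(path, col_types = "cc", progress = FALSE)
}

#' Packaged procedure category map
#'
#' Maps CPT-style procedure codes to reporting groups (evaluation and
#' management, emergency medical services, imaging, laboratory, ...).
#'
#' @return Tibble with columns `item`, `category`.
#' @export
procedure_categories <- function() {
  path <- system.file("extdata", "procedure_categories.csv",
                      package = "amiclaims", mustWork = TRUE)
  readr::read_csv(path, col_types = "cc", progress = FALSE)
}

demographics_row <- function(label, dem) {
  bins <- stats::setNames(as.list(dem$age_bins$n), paste0("n_", dem$age_bins$bin))
  pcts <- stats::setNames(as.list(dem$age_bins$pct), paste0("pct_", dem$age_bins$bin))
  tibble::as_tibble(c(
    list(stratum = label, size = dem$size, mean_age = dem$mean_age,
         sd_age = dem$sd_age),
    bins, pcts,
    list(male_n = dem$male_n, male_pct = dem$male_pct)
  ))
}

#' Run the full characterization pipeline
#'
#' Generates a synthetic bundle (or uses one supplied), builds the
#' any-setting and inpatient cohorts for the combined study period plus the
#' annual series, and writes every characterization output as CSV with a
#' JSON summary and a reproducibility manifest (seed, configuration hash).
#' Outputs are staged in a temporary directory and moved into place only on
#' success, so a failing stage leaves no partial report behind.
#'
#' @param out_dir Output directory for the report files.
#' @param seed Master seed for bundle generation.
#' @param gen_config A [generator_config()]; ignored when `bundle` is given.
#' @param bundle Optional pre-built [claims_bundle()].
#' @param codelist A [code_list()], default the packaged AMI list.
#' @param config A [study_config()].
#' @return Invisibly, a list with the cohorts and summary tables written.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         gen_config = generator_config(),
                         bundle = NULL,
                         codelist = ami_code_list(),
                         config = study_config()) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tmp <- tempfile("amiclaims_report_")
  dir.create(tmp, recursive = TRUE)

  if (is.null(bundle)) {
    bundle <- stage("generate", generate_bundle(gen_config, seed))
  }
  stage("validate", {
    v <- validate_bundle(bundle)
    if (length(v)) stop(paste(v, collapse = "; "))
  })

  years <- seq(as.integer(format(config$study_start, "%Y")),
               as.integer(format(config$study_end, "%Y")))
  period <- query_period(config$study_start, config$study_end)

  coh_any <- stage("cohort_any", build_cohort(bundle, codelist, period,
                                              "any_healthcare", config))
  coh_inp <- stage("cohort_inpatient", build_cohort(bundle, codelist, period,
                                                    "inpatient", config))
  att <- stage("version_attribution",
               version_attribution(bundle, codelist, period,
                                   "any_healthcare", config))

  series <- stage("annual_series",
                  annual_series(bundle, codelist, years, config))
  dem <- stage("demographics",
               demographics_by_version(bundle, codelist, period,
                                       "any_healthcare", config))
  dem_tbl <- dplyr::bind_rows(
    demographics_row("icd9cm", dem$icd9),
    demographics_row("icd10cm", dem$icd10),
    demographics_row("combined", dem$combined)
  )
  curve <- stage("gender_age_curve", gender_age_curve(coh_any, bundle))
  conditions <- stage("concurrent_conditions",
                      windowed_items(coh_any, bundle$diagnoses,
                                     condition_window(), "code",
                                     "service_date", top_n = 100L))
  drug_tbl <- stage("drug_classes",
                    drug_class_table(coh_any, bundle$drugs,
                                     treatment_window(), drug_classes()))
  proc_tbl <- stage("procedures",
                    windowed_items(coh_any, bundle$procedures,
                                   treatment_window(), "procedure_code",
                                   "service_date", top_n = 100L))
  ekg <- stage("ekg_any",
               multi_code_any(coh_any, bundle$procedures, treatment_window(),
                              ekg_codes()))
  los <- stage("los_summary", los_summary(coh_inp, bundle$admissions))

  stage("write", {
    readr::write_csv(coh_any$events, file.path(tmp, "cohort_any.csv"),
                     progress = FALSE)
    readr::write_csv(coh_inp$events, file.path(tmp, "cohort_inpatient.csv"),
                     progress = FALSE)
    readr::write_csv(series, file.path(tmp, "annual_series.csv"),
                     progress = FALSE)
    readr::write_csv(dem_tbl, file.path(tmp, "demographics.csv"),
                     progress = FALSE)
    readr::write_csv(curve$by_age, file.path(tmp, "gender_age_curve.csv"),
                     progress = FALSE)
    readr::write_csv(curve$by_bin, file.path(tmp, "gender_agebin_curve.csv"),
                     progress = FALSE)
    readr::write_csv(conditions, file.path(tmp, "concurrent_conditions.csv"),
                     progress = FALSE)
    readr::write_csv(drug_tbl, file.path(tmp, "drug_classes.csv"),
                     progress = FALSE)
    readr::write_csv(proc_tbl, file.path(tmp, "procedures.csv"),
                     progress = FALSE)
    summary <- list(
      seed = seed,
      config_hash = rlang::hash(list(gen_config = gen_config, config = config,
                                     codelist = codelist$patterns$pattern)),
      package_version = as.character(utils::packageVersion("amiclaims")),
      cohort_any = list(size = nrow(coh_any$events),
                        denominator = coh_any$denominator),
      cohort_inpatient = list(size = nrow(coh_inp$events),
                              denominator = coh_inp$denominator),
      inpatient_share_pct = if (nrow(coh_any$events) > 0) {
        pct(nrow(coh_inp$events), nrow(coh_any$events))
      } else NA,
      version_attribution = att,
      ekg_any = ekg,
      los = list(n = los$n, n_unlinked = los$n_unlinked, mean = los$mean,
                 sd = los$sd, median = los$median, iqr = los$iqr,
                 range = los$range, band_props = as.list(los$band_props))
    )
    jsonlite::write_json(summary, file.path(tmp, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(tmp, full.names = TRUE)) {
    file.copy(f, file.path(out_dir, basename(f)), overwrite = TRUE)
  }
  unlink(tmp, recursive = TRUE)
  invisible(list(
    cohort_any = coh_any, cohort_inpatient = coh_inp, annual_series = series,
    demographics = dem_tbl, gender_age_curve = curve, conditions = conditions,
    drug_classes = drug_tbl, procedures = proc_tbl, ekg_any = ekg, los = los,
    version_attribution = att
  ))
}
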
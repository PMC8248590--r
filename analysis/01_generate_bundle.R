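#!/usr/bin/env Rscript
# Stage 1: simulate the study database.
#
# Draws a 200,000-person claims bundle from the calibrated generator: four
# years of enrollment spanning the 2015-10-01 ICD-9-CM to ICD-10-CM
# transition, an annual AMI diagnosis rate of 3.0/1,000 enrollees, and
# case-level marginals (age, gender, setting, concurrent codes, drugs,
# procedures, length of stay) matching the published characterization.
# The full bundle is large, so it lands under scratch/; summaries go to
# results/.

library(amiclaims)

seed <- 2014L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- generator_config()
message("Generating bundle: n = ", cfg$n_persons, ", seed = ", seed)
bundle <- generate_bundle(cfg, seed)
stopifnot(length(validate_bundle(bundle)) == 0)

write_bundle(bundle, "scratch/bundle")
truth <- ground_truth(cfg, seed)
readr::write_csv(truth, "scratch/truth.csv")

summary <- list(
  seed = seed,
  n_persons = nrow(bundle$persons),
  n_cases_simulated = sum(truth$is_case),
  n_diagnosis_claims = nrow(bundle$diagnoses),
  n_drug_orders = nrow(bundle$drugs),
  n_procedure_claims = nrow(bundle$procedures),
  n_admissions = nrow(bundle$admissions)
)
jsonlite::write_json(summary, "results/01_bundle_summary.json",
                     auto_unbox = TRUE, pretty = TRUE)

message("Simulated ", summary$n_cases_simulated, " AMI cases among ",
        summary$n_persons, " persons (",
        round(1000 * summary$n_cases_simulated / summary$n_persons / 4, 2),
        "/1,000/year before eligibility filtering).")
message("Bundle written to scratch/bundle; summary in results/01_bundle_summary.json")
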
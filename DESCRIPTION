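Package: amiclaims
Title: Claims-Based Phenotyping and Characterization of Acute Myocardial Infarction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterize acute myocardial infarction (AMI)
    populations in administrative healthcare claims. Implements a diagnosis-code
    phenotyping algorithm spanning the 2015-10-01 U.S. transition from ICD-9-CM to
    ICD-10-CM, wildcard code lists, forward-backward crosswalking through General
    Equivalence Mappings (GEMs), cohort extraction under continuous-enrollment and
    code-era rules with first-event deduplication, and descriptive characterization
    of the resulting cohorts: annual diagnosis proportions, demographics, windowed
    concurrent diagnoses, drug-class and procedure frequencies, and inpatient
    length-of-stay summaries. A calibrated synthetic claims generator emulates the
    linked person-level structure of large U.S. claims databases so the whole
    pipeline runs and is testable without access to proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
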
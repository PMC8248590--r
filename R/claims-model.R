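#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

#' Healthcare settings recognized on claims
#'
#' The nine encounter settings a claim line may carry. The cohort engine's
#' "any healthcare setting" scope is exactly this set; the "inpatient" scope
#' is the single `"inpatient"` member.
#'
#' @return Character vector of the nine setting labels.
#' @export
claim_settings <- function() {
  c(
    "emergency_department", "inpatient", "lab_test",
    "non_doctor_office_visit", "other_outpatient",
    "other_outpatient_office_visit", "primary_care_office_visit",
    "pharmacy", "specialty_office_visit"
  )
}

icd_versions <- function() c("icd9cm", "icd10cm")
code_positions <- function() c("principal", "secondary", "unspecified")
genders <- function() c("male", "female")

#' Normalize a diagnosis or procedure code
#'
#' Claims store diagnosis codes undotted ("41071") while code lists and
#' publications print them with a decimal ("410.71"). All codes entering the
#' pipeline pass through this normalization: surrounding whitespace stripped,
#' decimal point removed, upper-cased. The function is idempotent.
#'
#' @param raw Character vector of codes as found in source data.
#' @param version Code system, `"icd9cm"` or `"icd10cm"` (recorded alongside
#'   codes elsewhere; normalization itself is version-independent).
#' @return Character vector of normalized codes.
#' @examples
#' normalize_code("410.71", "icd9cm")   # "41071"
#' normalize_code("I21.4", "icd10cm")   # "I214"
#' @export
normalize_code <- function(raw, version = c("icd9cm", "icd10cm")) {
  version <- match.arg(version)
  if (length(raw) == 0) return(character(0))
  out <- toupper(gsub(".", "", trimws(raw), fixed = TRUE))
  if (any(is.na(out) | out == "")) {
    stop("normalize_code: empty or missing code at position ",
         paste(which(is.na(out) | out == ""), collapse = ", "))
  }
  out
}

bundle_table_names <- function() {
  c("persons", "enrollment", "diagnoses", "drugs", "procedures", "admissions")
}

empty_bundle_tables <- function() {
  list(
    persons = tibble::tibble(
      person_id = character(), birth_year = integer(), gender = character()
    ),
    enrollment = tibble::tibble(
      person_id = character(), start_date = as.Date(character()),
      end_date = as.Date(character()), plan = character()
    ),
    diagnoses = tibble::tibble(
      person_id = character(), service_date = as.Date(character()),
      code = character(), version = character(), position = character(),
      setting = character()
    ),
    drugs = tibble::tibble(
      person_id = character(), order_date = as.Date(character()),
      product_code = character(), product_name = character()
    ),
    procedures = tibble::tibble(
      person_id = character(), service_date = as.Date(character()),
      procedure_code = character(), setting = character()
    ),
    admissions = tibble::tibble(
      person_id = character(), admit_date = as.Date(character()),
      discharge_date = as.Date(character())
    )
  )
}

#' Assemble a claims bundle
#'
#' A claims bundle is the in-memory image of a linked administrative claims
#' extract: persons, enrollment spans, diagnosis claims, drug orders,
#' procedure claims and inpatient admissions, all keyed by `person_id`.
#' Missing tables default to empty. Diagnosis codes are normalized on
#' construction.
#'
#' @param persons,enrollment,diagnoses,drugs,procedures,admissions Data frames
#'   with the columns of the corresponding empty template (see
#'   [read_bundle()] for the file dialect).
#' @return An object of class `claims_bundle`: a named list of tibbles.
#' @export
claims_bundle <- function(persons = NULL, enrollment = NULL, diagnoses = NULL,
                          drugs = NULL, procedures = NULL, admissions = NULL) {
  tpl <- empty_bundle_tables()
  got <- list(
    persons = persons, enrollment = enrollment, diagnoses = diagnoses,
    drugs = drugs, procedures = procedures, admissions = admissions
  )
  out <- lapply(bundle_table_names(), function(nm) {
    x <- got[[nm]]
    if (is.null(x)) return(tpl[[nm]])
    x <- tibble::as_tibble(x)
    missing <- setdiff(names(tpl[[nm]]), names(x))
    if (length(missing)) {
      stop("claims_bundle: table '", nm, "' is missing column(s): ",
           paste(missing, collapse = ", "))
    }
    x[names(tpl[[nm]])]
  })
  names(out) <- bundle_table_names()
  if (nrow(out$diagnoses)) {
    out$diagnoses$code <- normalize_code(out$diagnoses$code)
  }
  structure(out, class = "claims_bundle")
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in bundle_table_names()) {
    cat(sprintf("  %-11s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

bundle_file_names <- function() {
  c(
    persons = "persons.csv", enrollment = "enrollment.csv",
    diagnoses = "diagnoses.csv", drugs = "drugs.csv",
    procedures = "procedures.csv", admissions = "admissions.csv"
  )
}

parse_iso_date <- function(x, table, column) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(d))
  if (length(bad)) {
    stop(sprintf("%s: unparseable date in column '%s' at row %s",
                 table, column, paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (anyNA(x)) {
    stop(sprintf("%s: missing date in column '%s' at row %s", table, column,
                 paste(utils::head(which(is.na(x)), 5), collapse = ", ")))
  }
  d
}

check_enum <- function(x, allowed, table, column) {
  bad <- which(!x %in% allowed)
  if (length(bad)) {
    stop(sprintf("%s: invalid %s '%s' at row %s", table, column,
                 x[bad[1]], paste(utils::head(bad, 5), collapse = ", ")))
  }
  x
}

#' Read a claims bundle from a directory of CSV files
#'
#' Expects six UTF-8, comma-delimited files with header rows:
#' `persons.csv`, `enrollment.csv`, `diagnoses.csv`, `drugs.csv`,
#' `procedures.csv`, `admissions.csv`, with columns exactly matching the
#' bundle tables and dates written `YYYY-MM-DD`. Codes are normalized on
#' load; enum columns (setting, version, position, gender, plan) are checked
#' and an error names the offending row.
#'
#' @param dir Directory holding the six files.
#' @return A [claims_bundle()].
#' @export
read_bundle <- function(dir) {
  files <- bundle_file_names()
  paths <- file.path(dir, files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("read_bundle: missing file(s): ", paste(files[missing], collapse = ", "))
  }
  raw <- lapply(paths, function(p) {
    readr::read_csv(p, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  })
  names(raw) <- names(files)

  persons <- raw$persons
  persons$birth_year <- as.integer(persons$birth_year)
  check_enum(persons$gender, genders(), "persons.csv", "gender")

  enrollment <- raw$enrollment
  enrollment$start_date <- parse_iso_date(enrollment$start_date, "enrollment.csv", "start_date")
  enrollment$end_date <- parse_iso_date(enrollment$end_date, "enrollment.csv", "end_date")
  check_enum(enrollment$plan, c("commercial", "medicare_supplemental"),
             "enrollment.csv", "plan")

  diagnoses <- raw$diagnoses
  diagnoses$service_date <- parse_iso_date(diagnoses$service_date, "diagnoses.csv", "service_date")
  check_enum(diagnoses$version, icd_versions(), "diagnoses.csv", "version")
  check_enum(diagnoses$position, code_positions(), "diagnoses.csv", "position")
  check_enum(diagnoses$setting, claim_settings(), "diagnoses.csv", "setting")

  drugs <- raw$drugs
  drugs$order_date <- parse_iso_date(drugs$order_date, "drugs.csv", "order_date")

  procedures <- raw$procedures
  procedures$service_date <- parse_iso_date(procedures$service_date, "procedures.csv", "service_date")
  check_enum(procedures$setting, claim_settings(), "procedures.csv", "setting")

  admissions <- raw$admissions
  admissions$admit_date <- parse_iso_date(admissions$admit_date, "admissions.csv", "admit_date")
  admissions$discharge_date <- parse_iso_date(admissions$discharge_date, "admissions.csv", "discharge_date")

  claims_bundle(
    persons = persons, enrollment = enrollment, diagnoses = diagnoses,
    drugs = drugs, procedures = procedures, admissions = admissions
  )
}

#' Write a claims bundle to a directory of CSV files
#'
#' Inverse of [read_bundle()]: writes the six-table CSV dialect such that
#' `read_bundle(write_bundle(b, dir))` reproduces `b` record for record.
#'
#' @param bundle A [claims_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- bundle_file_names()
  for (nm in names(files)) {
    readr::write_csv(bundle[[nm]], file.path(dir, files[[nm]]), progress = FALSE)
  }
  invisible(dir)
}

#' Validate a claims bundle
#'
#' Checks type invariants and referential integrity and returns violations
#' rather than raising: person_id uniqueness, plausible birth years,
#' ordered date pairs, enum membership, non-empty procedure codes, and that
#' every claim's `person_id` exists in `persons`.
#'
#' @param bundle A [claims_bundle()].
#' @param last_study_year Upper bound for plausible birth years.
#' @return Character vector of violation messages; empty when the bundle is
#'   valid.
#' @export
validate_bundle <- function(bundle, last_study_year = 2017L) {
  stopifnot(inherits(bundle, "claims_bundle"))
  v <- character(0)
  p <- bundle$persons
  if (anyDuplicated(p$person_id)) {
    v <- c(v, paste0("persons: duplicated person_id: ",
                     paste(unique(p$person_id[duplicated(p$person_id)]), collapse = ", ")))
  }
  bad_by <- which(p$birth_year < 1900L | p$birth_year > last_study_year)
  if (length(bad_by)) {
    v <- c(v, paste0("persons: birth_year outside [1900, ", last_study_year,
                     "] at row ", paste(bad_by, collapse = ", ")))
  }
  if (any(!p$gender %in% genders())) v <- c(v, "persons: invalid gender value")

  ids <- p$person_id
  ref <- function(tab, nm) {
    bad <- which(!bundle[[tab]]$person_id %in% ids)
    if (length(bad)) {
      paste0(nm, ": unknown person_id at row ",
             paste(utils::head(bad, 10), collapse = ", "))
    } else character(0)
  }
  for (tab in setdiff(bundle_table_names(), "persons")) v <- c(v, ref(tab, tab))

  e <- bundle$enrollment
  bad <- which(e$start_date > e$end_date)
  if (length(bad)) {
    v <- c(v, paste0("enrollment: start_date after end_date at row ",
                     paste(bad, collapse = ", ")))
  }
  a <- bundle$admissions
  bad <- which(a$admit_date > a$discharge_date)
  if (length(bad)) {
    v <- c(v, paste0("admissions: discharge before admit at row ",
                     paste(bad, collapse = ", ")))
  }
  d <- bundle$diagnoses
  if (any(!d$version %in% icd_versions())) v <- c(v, "diagnoses: invalid version")
  if (any(!d$position %in% code_positions())) v <- c(v, "diagnoses: invalid position")
  if (any(!d$setting %in% claim_settings())) v <- c(v, "diagnoses: invalid setting")
  if (nrow(d) && any(d$code != normalize_code(d$code))) {
    v <- c(v, "diagnoses: codes not normalized")
  }
  pr <- bundle$procedures
  bad <- which(is.na(pr$procedure_code) | trimws(pr$procedure_code) == "")
  if (length(bad)) {
    v <- c(v, paste0("procedures: empty procedure_code at row ",
                     paste(bad, collapse = ", ")))
  }
  if (any(!pr$setting %in% claim_settings())) v <- c(v, "procedures: invalid setting")
  v
}
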
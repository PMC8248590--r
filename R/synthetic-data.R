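# Synthetic administrative-claims generator.
#
# Emulates the person-level linked structure of a large U.S. claims database
# (emergency, laboratory, pharmacy, inpatient and outpatient encounters) at
# configurable scale. Marginal frequencies default to a calibration profile
# that encodes the published AMI characterization: annual diagnosis rate
# ~3/1,000 enrollees, 63.4% inpatient share, case age/gender mixes, the
# leading concurrent diagnoses, drug classes, procedure codes and the
# inpatient length-of-stay band distribution. Marginals are independent
# given case status; no joint structure beyond the windows is simulated.

default_icd9_index_codes <- function() {
  tibble::tibble(
    code = c("41071", "41090", "41070", "41001", "41091", "41011"),
    prob = c(0.45, 0.25, 0.15, 0.08, 0.05, 0.02)
  )
}

default_icd10_index_codes <- function() {
  tibble::tibble(
    code = c("I214", "I213", "I219", "I2101", "I2109", "I220", "I221"),
    prob = c(0.50, 0.22, 0.14, 0.07, 0.04, 0.02, 0.01)
  )
}

default_concurrent_marginals <- function() {
  tibble::tibble(
    code = c(
      "78650", "4019", "41401", "41071", "41090", "2724", "41070", "41400",
      "79431", "4280",
      "I214", "I10", "I2510", "R079", "E785", "I213", "R9431", "R0789",
      "I509", "I517"
    ),
    version = rep(c("icd9cm", "icd10cm"), each = 10L),
    label = c(
      "Unspecified chest pain", "Unspecified essential hypertension",
      "Coronary atherosclerosis of native coronary vessel",
      "AMI, subendocardial, initial episode",
      "AMI, unspecified site, episode unspecified",
      "Other and unspecified hyperlipidemia",
      "AMI, subendocardial, episode unspecified",
      "Coronary atherosclerosis, unspecified vessel",
      "Nonspecific abnormal electrocardiogram",
      "Congestive heart failure, unspecified",
      "NSTEMI myocardial infarction", "Essential (primary) hypertension",
      "Atherosclerotic heart disease, native coronary artery",
      "Chest pain, unspecified", "Hyperlipidemia, unspecified",
      "STEMI of unspecified site", "Abnormal electrocardiogram",
      "Other chest pain", "Heart failure, unspecified", "Cardiomegaly"
    ),
    category = "cardiac",
    prob = c(
      0.513, 0.470, 0.468, 0.437, 0.355, 0.326, 0.258, 0.247, 0.192, 0.178,
      0.536, 0.516, 0.435, 0.435, 0.299, 0.265, 0.199, 0.193, 0.137, 0.114
    )
  )
}

default_drug_catalogue <- function() {
  tibble::tribble(
    ~product_name, ~product_code, ~class, ~prob,
    "metoprolol tartrate", "D001", "beta_blocker", 0.22,
    "carvedilol", "D002", "beta_blocker", 0.10,
    "atenolol", "D003", "beta_blocker", 0.07,
    "metoprolol succinate", "D004", "beta_blocker", 0.06,
    "atorvastatin calcium", "D005", "anti_lipid", 0.283,
    "simvastatin", "D006", "anti_lipid", 0.08,
    "rosuvastatin calcium", "D007", "anti_lipid", 0.04,
    "clopidogrel bisulfate", "D008", "anti_platelet", 0.20,
    "aspirin", "D009", "anti_platelet", 0.055,
    "ticagrelor", "D010", "anti_platelet", 0.05,
    "prasugrel", "D011", "anti_platelet", 0.02,
    "lisinopril", "D012", "ace_arb", 0.16,
    "losartan potassium", "D013", "ace_arb", 0.07,
    "hydrochlorothiazide/lisinopril", "D014", "ace_arb", 0.02,
    "nitroglycerin", "D015", "anti_anginal", 0.15,
    "isosorbide mononitrate", "D016", "anti_anginal", 0.04,
    "furosemide", "D017", "diuretic", 0.10,
    "hydrochlorothiazide", "D018", "diuretic", 0.03,
    "amlodipine besylate", "D019", "calcium_channel_blocker", 0.06,
    "diltiazem hcl", "D020", "calcium_channel_blocker", 0.015,
    "digoxin", "D021", "other", 0.025,
    "ranolazine", "D022", "other", 0.018
  )
}

default_procedure_catalogue <- function() {
  tibble::tibble(
    code = c("99232", "99223", "99285", "99233", "99291", "99214", "99239",
             "99222", "99238", "99213", "99231"),
    category = "evaluation_management",
    prob = c(0.534, 0.520, 0.462, 0.423, 0.341, 0.338, 0.290, 0.277, 0.246,
             0.188, 0.175)
  )
}

default_noise_codes <- function() {
  tibble::tibble(
    code = c("4139", "412", "41072", "486", "5990", "25000", "4659",
             "I209", "I252", "I2510", "J189", "N390", "E119", "J069"),
    version = rep(c("icd9cm", "icd10cm"), each = 7L)
  )
}

#' Generator configuration
#'
#' Defaults form the calibrated profile: a four-year study population whose
#' pipeline outputs land, up to sampling error, on the published AMI
#' characterization marginals (annual rate 3.0/1,000 enrollees/year inside
#' the 2.83-3.16 published range, inpatient share 0.634, case age-bin mix
#' with 44.9% aged 65+, 61.4% male cases, 9.3% of 2015 cases carrying both
#' code versions, the leading concurrent-code / drug-class / procedure
#' marginals, and length-of-stay bands 0.699 / 0.178 / 0.054 / 0.069).
#'
#' @param n_persons Number of persons.
#' @param years First and last calendar year, inclusive.
#' @param annual_ami_rate Cases per 1,000 enrollees per year.
#' @param background_male_prob,case_male_prob P(male) for non-cases / cases.
#' @param background_age_mix,case_age_mix Probabilities over the six age
#'   bins 0-17, 18-34, 35-44, 45-54, 55-64, 65+ (normalized internally).
#' @param setting_mix Named probabilities over [claim_settings()] for the
#'   index claim; the `inpatient` entry is the inpatient share.
#' @param enrollment_gap_prob Probability a person has a mid-year coverage
#'   gap in one (non-index) year.
#' @param both_version_prob Probability an ICD-9-indexed 2015 case receives
#'   a second, ICD-10-CM qualifying claim in Oct-Dec 2015.
#' @param concurrent_marginals,drug_catalogue,procedure_catalogue Item
#'   catalogues with per-case in-window probabilities (see the defaults).
#' @param icd9_index_codes,icd10_index_codes Index-code distributions.
#' @param ekg_any_prob P(>=1 electrocardiogram procedure code in-window);
#'   `ekg_code_probs` are the per-code marginals for the three EKG codes.
#' @param ekg_code_probs Named marginals for interpretation-only, tracing
#'   and tracing-with-interpretation EKG codes.
#' @param los_bands Probabilities over stay bands 1-5 / 6-10 / 11-14 / >14
#'   days; within-band days are uniform, the >14 band is a geometric tail
#'   with success probability `los_tail_p`, capped at `los_max`.
#' @param los_tail_p,los_max Tail parameters, see above.
#' @param noise_diag_prob Probability a person carries background non-AMI
#'   diagnosis claims (decoy cardiac codes included).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_persons = 200000L,
                             years = c(2014L, 2017L),
                             annual_ami_rate = 3.0,
                             background_male_prob = 0.481,
                             case_male_prob = 0.614,
                             background_age_mix = c(0.220, 0.244, 0.148, 0.164, 0.158, 0.067),
                             case_age_mix = c(0.002, 0.017, 0.051, 0.162, 0.319, 0.449),
                             setting_mix = c(
                               inpatient = 0.634, emergency_department = 0.200,
                               other_outpatient = 0.060,
                               primary_care_office_visit = 0.040,
                               specialty_office_visit = 0.030,
                               other_outpatient_office_visit = 0.020,
                               lab_test = 0.006, non_doctor_office_visit = 0.006,
                               pharmacy = 0.004
                             ),
                             enrollment_gap_prob = 0.05,
                             both_version_prob = 0.124,
                             concurrent_marginals = default_concurrent_marginals(),
                             drug_catalogue = default_drug_catalogue(),
                             procedure_catalogue = default_procedure_catalogue(),
                             icd9_index_codes = default_icd9_index_codes(),
                             icd10_index_codes = default_icd10_index_codes(),
                             ekg_any_prob = 0.79,
                             ekg_code_probs = c(`93010` = 0.711, `93005` = 0.200,
                                                `93000` = 0.164),
                             los_bands = c(0.699, 0.178, 0.054, 0.069),
                             los_tail_p = 0.12,
                             los_max = 384L,
                             noise_diag_prob = 0.35) {
  check_prob <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
      stop("generator_config: ", nm, " must be probabilities in [0, 1]")
    }
  }
  check_prob(c(background_male_prob, case_male_prob, enrollment_gap_prob,
               both_version_prob, ekg_any_prob, noise_diag_prob, los_tail_p),
             "scalar probabilities")
  check_prob(background_age_mix, "background_age_mix")
  check_prob(case_age_mix, "case_age_mix")
  check_prob(los_bands, "los_bands")
  check_prob(concurrent_marginals$prob, "concurrent_marginals$prob")
  check_prob(drug_catalogue$prob, "drug_catalogue$prob")
  check_prob(procedure_catalogue$prob, "procedure_catalogue$prob")
  if (length(background_age_mix) != 6L || length(case_age_mix) != 6L) {
    stop("generator_config: age mixes must cover the six age bins")
  }
  if (length(los_bands) != 4L) stop("generator_config: los_bands must have 4 entries")
  bad <- setdiff(names(setting_mix), claim_settings())
  if (length(bad)) {
    stop("generator_config: unknown setting(s): ", paste(bad, collapse = ", "))
  }
  # zero-probability settings may be omitted from the mix
  full <- stats::setNames(rep(0, length(claim_settings())), claim_settings())
  full[names(setting_mix)] <- setting_mix
  setting_mix <- full
  if (annual_ami_rate < 0 || annual_ami_rate > 1000) {
    stop("generator_config: annual_ami_rate must be in [0, 1000] per 1,000")
  }
  structure(
    list(
      n_persons = as.integer(n_persons),
      years = as.integer(years),
      annual_ami_rate = annual_ami_rate,
      background_male_prob = background_male_prob,
      case_male_prob = case_male_prob,
      background_age_mix = background_age_mix / sum(background_age_mix),
      case_age_mix = case_age_mix / sum(case_age_mix),
      setting_mix = setting_mix / sum(setting_mix),
      enrollment_gap_prob = enrollment_gap_prob,
      both_version_prob = both_version_prob,
      concurrent_marginals = tibble::as_tibble(concurrent_marginals),
      drug_catalogue = tibble::as_tibble(drug_catalogue),
      procedure_catalogue = tibble::as_tibble(procedure_catalogue),
      icd9_index_codes = tibble::as_tibble(icd9_index_codes),
      icd10_index_codes = tibble::as_tibble(icd10_index_codes),
      ekg_any_prob = ekg_any_prob,
      ekg_code_probs = ekg_code_probs,
      los_bands = los_bands / sum(los_bands),
      los_tail_p = los_tail_p,
      los_max = as.integer(los_max),
      noise_diag_prob = noise_diag_prob
    ),
    class = "generator_config"
  )
}

#' Tiny generator profile for unit tests and examples
#'
#' Twenty persons with an inflated diagnosis rate so a handful of cases
#' exist at desk scale; all other marginals as in [generator_config()].
#'
#' @return A [generator_config()].
#' @export
tiny_generator_config <- function() {
  generator_config(n_persons = 20L, annual_ami_rate = 120,
                   enrollment_gap_prob = 0.1)
}

# age bin bounds used when drawing integer ages within bins; 65+ truncated
age_bin_bounds <- function() {
  list(c(0L, 17L), c(18L, 34L), c(35L, 44L), c(45L, 54L), c(55L, 64L),
       c(65L, 95L))
}

draw_ages <- function(n, mix, min_age = 0L) {
  if (n == 0) return(integer(0))
  bins <- sample.int(6L, n, replace = TRUE, prob = mix)
  bounds <- age_bin_bounds()
  lo <- vapply(bounds, `[`, integer(1), 1L)
  hi <- vapply(bounds, `[`, integer(1), 2L)
  lo <- pmax(lo, min_age)
  lo[bins] + floor(stats::runif(n) * (hi[bins] - lo[bins] + 1L))
}

clamp_dates <- function(dates, lower, upper) {
  pmin(pmax(dates, lower), upper)
}

#' Generate a synthetic claims bundle
#'
#' Reproducible: the same configuration and seed give a record-identical
#' bundle. Each claim table draws from its own RNG stream split from the
#' master seed, so adding claims to one table never perturbs another. The
#' per-person ground truth used to build the bundle is attached as
#' attribute `"truth"` and also available via [ground_truth()].
#'
#' @param config A [generator_config()].
#' @param seed Integer master seed.
#' @return A validated [claims_bundle()].
#' @export
generate_bundle <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  g <- generate_all(config, seed)
  g$bundle
}

#' Ground truth for a generated bundle
#'
#' Regenerates the per-person truth table for `generate_bundle(config,
#' seed)`: case status, index date/code/version/setting, both-version flag,
#' age at index and length-of-stay band. Enables exact end-to-end
#' verification of the cohort and characterization engines.
#'
#' @inheritParams generate_bundle
#' @return Tibble with one row per person.
#' @export
ground_truth <- function(config = generator_config(), seed = 1L) {
  generate_all(config, seed)$truth
}

generate_all <- function(config, seed) {
  seed <- as.integer(seed)
  set.seed(seed)
  ss <- sample.int(.Machine$integer.max - 1L, 10L)

  n <- config$n_persons
  years <- seq(config$years[1], config$years[2])
  n_years <- length(years)
  study_start <- as.Date(sprintf("%d-01-01", years[1]))
  study_end <- as.Date(sprintf("%d-12-31", years[n_years]))
  era_boundary <- as.Date("2015-10-01")

  ## stream 1: persons and case assignment -------------------------------
  set.seed(ss[1])
  person_id <- sprintf("P%07d", seq_len(n))
  p_ever <- min(1, config$annual_ami_rate / 1000 * n_years)
  is_case <- stats::runif(n) < p_ever
  n_case <- sum(is_case)
  index_year <- rep(NA_integer_, n)
  index_year[is_case] <- sample(years, n_case, replace = TRUE)

  gender <- ifelse(
    stats::runif(n) < ifelse(is_case, config$case_male_prob,
                             config$background_male_prob),
    "male", "female"
  )
  age_ref <- integer(n)
  age_ref[!is_case] <- draw_ages(n - n_case, config$background_age_mix)
  # case ages are ages at index (bins floor at 1: infants are excluded from
  # cohorts by design, so a case younger than 1 would be unfindable)
  age_ref[is_case] <- draw_ages(n_case, config$case_age_mix, min_age = 1L)
  ref_year <- ifelse(is_case, index_year, years[1])
  birth_year <- as.integer(ref_year - age_ref)

  persons <- tibble::tibble(person_id = person_id, birth_year = birth_year,
                            gender = gender)

  ## stream 2: enrollment -------------------------------------------------
  set.seed(ss[2])
  has_gap <- stats::runif(n) < config$enrollment_gap_prob
  gap_year <- rep(NA_integer_, n)
  gap_year[has_gap] <- sample(years, sum(has_gap), replace = TRUE)
  # cases keep their index year fully enrolled
  clash <- has_gap & is_case & gap_year == index_year
  if (n_years > 1) {
    gap_year[clash] <- vapply(index_year[clash], function(iy) {
      sample(setdiff(years, iy), 1L)
    }, integer(1))
  } else {
    has_gap[clash] <- FALSE
    gap_year[clash] <- NA_integer_
  }
  plan <- ifelse(stats::runif(n) < 0.85, "commercial", "medicare_supplemental")

  no_gap <- !has_gap | is.na(gap_year)
  gap_len <- integer(n)
  gap_start_off <- integer(n)
  idx_gap <- which(!no_gap)
  gap_len[idx_gap] <- sample(10:60, length(idx_gap), replace = TRUE)
  gap_start_off[idx_gap] <- sample(120:200, length(idx_gap), replace = TRUE)
  gap_start <- as.Date(sprintf("%d-01-01", gap_year[idx_gap])) +
    gap_start_off[idx_gap]
  gap_end <- gap_start + gap_len[idx_gap] - 1L
  enrollment <- dplyr::bind_rows(
    tibble::tibble(
      person_id = person_id[no_gap],
      start_date = study_start, end_date = study_end,
      plan = plan[no_gap]
    ),
    tibble::tibble(
      person_id = person_id[idx_gap],
      start_date = study_start, end_date = gap_start - 1L,
      plan = plan[idx_gap]
    ),
    tibble::tibble(
      person_id = person_id[idx_gap],
      start_date = gap_end + 1L, end_date = study_end,
      plan = plan[idx_gap]
    )
  )
  enrollment <- enrollment[order(enrollment$person_id, enrollment$start_date), ]

  ## stream 3: index claims ----------------------------------------------
  set.seed(ss[3])
  case_idx <- which(is_case)
  year_start <- as.Date(sprintf("%d-01-01", index_year[case_idx]))
  year_len <- ifelse(index_year[case_idx] %% 4 == 0, 366L, 365L)
  index_date <- year_start + floor(stats::runif(n_case) * year_len)
  index_version <- ifelse(index_date < era_boundary, "icd9cm", "icd10cm")
  i9 <- index_version == "icd9cm"
  index_code <- character(n_case)
  index_code[i9] <- sample(config$icd9_index_codes$code, sum(i9), replace = TRUE,
                           prob = config$icd9_index_codes$prob)
  index_code[!i9] <- sample(config$icd10_index_codes$code, sum(!i9),
                            replace = TRUE, prob = config$icd10_index_codes$prob)
  index_setting <- sample(names(config$setting_mix), n_case, replace = TRUE,
                          prob = config$setting_mix)
  index_position <- sample(code_positions(), n_case, replace = TRUE,
                           prob = c(0.5, 0.35, 0.15))
  diagnoses <- if (n_case > 0) {
    tibble::tibble(
      person_id = person_id[case_idx],
      service_date = index_date,
      code = index_code,
      version = index_version,
      position = index_position,
      setting = index_setting
    )
  } else {
    empty_bundle_tables()$diagnoses
  }
  # straddle-year cases: a second qualifying claim in the other era
  both <- is_case[case_idx] & index_year[case_idx] == 2015L & i9 &
    stats::runif(n_case) < config$both_version_prob
  n_both <- sum(both)
  if (n_both > 0) {
    extra_date <- era_boundary +
      floor(stats::runif(n_both) * as.integer(as.Date("2015-12-31") - era_boundary + 1L))
    extra <- tibble::tibble(
      person_id = person_id[case_idx][both],
      service_date = extra_date,
      code = sample(config$icd10_index_codes$code, n_both, replace = TRUE,
                    prob = config$icd10_index_codes$prob),
      version = "icd10cm",
      position = sample(code_positions(), n_both, replace = TRUE,
                        prob = c(0.5, 0.35, 0.15)),
      setting = sample(names(config$setting_mix), n_both, replace = TRUE,
                       prob = config$setting_mix)
    )
    diagnoses <- dplyr::bind_rows(diagnoses, extra)
  }

  ## stream 4: concurrent in-window diagnoses ----------------------------
  set.seed(ss[4])
  cm <- config$concurrent_marginals
  conc <- NULL
  if (n_case > 0 && nrow(cm) > 0) {
    hits <- lapply(icd_versions(), function(v) {
      rows <- which(cm$version == v)
      sel <- which(index_version == v)
      if (length(rows) == 0 || length(sel) == 0) return(NULL)
      hit <- stats::runif(length(sel) * length(rows)) <
        rep(cm$prob[rows], each = length(sel))
      tibble::tibble(
        case = rep(sel, times = length(rows))[hit],
        row = rep(rows, each = length(sel))[hit]
      )
    })
    hits <- dplyr::bind_rows(hits)
    if (nrow(hits) > 0) {
      offset <- sample(-1:1, nrow(hits), replace = TRUE)
      d <- index_date[hits$case] + offset
      v <- index_version[hits$case]
      # keep claims era-consistent and inside the study period
      d <- clamp_dates(d, study_start, study_end)
      d[v == "icd9cm" & d >= era_boundary] <- era_boundary - 1L
      d[v == "icd10cm" & d < era_boundary] <- era_boundary
      conc <- tibble::tibble(
        person_id = person_id[case_idx][hits$case],
        service_date = d,
        code = cm$code[hits$row],
        version = v,
        position = sample(code_positions(), nrow(hits), replace = TRUE,
                          prob = c(0.2, 0.5, 0.3)),
        setting = index_setting[hits$case]
      )
    }
  }

  ## stream 5: drug orders ------------------------------------------------
  set.seed(ss[5])
  dc <- config$drug_catalogue
  drugs <- empty_bundle_tables()$drugs
  if (n_case > 0 && nrow(dc) > 0) {
    hit <- stats::runif(n_case * nrow(dc)) < rep(dc$prob, each = n_case)
    case <- rep(seq_len(n_case), times = nrow(dc))[hit]
    item <- rep(seq_len(nrow(dc)), each = n_case)[hit]
    if (length(case)) {
      drugs <- tibble::tibble(
        person_id = person_id[case_idx][case],
        order_date = clamp_dates(
          index_date[case] + sample(-1:14, length(case), replace = TRUE),
          study_start, study_end
        ),
        product_code = dc$product_code[item],
        product_name = dc$product_name[item]
      )
    }
  }

  ## stream 6: procedures -------------------------------------------------
  set.seed(ss[6])
  pcat <- config$procedure_catalogue
  proc_rows <- list()
  if (n_case > 0 && nrow(pcat) > 0) {
    hit <- stats::runif(n_case * nrow(pcat)) < rep(pcat$prob, each = n_case)
    case <- rep(seq_len(n_case), times = nrow(pcat))[hit]
    item <- rep(seq_len(nrow(pcat)), each = n_case)[hit]
    if (length(case)) {
      proc_rows$catalogue <- tibble::tibble(
        person_id = person_id[case_idx][case],
        service_date = clamp_dates(
          index_date[case] + sample(-1:14, length(case), replace = TRUE),
          study_start, study_end
        ),
        procedure_code = pcat$code[item],
        setting = index_setting[case]
      )
    }
  }
  if (n_case > 0 && config$ekg_any_prob > 0) {
    any_ekg <- stats::runif(n_case) < config$ekg_any_prob
    sel <- which(any_ekg)
    if (length(sel)) {
      cond <- pmin(1, config$ekg_code_probs / config$ekg_any_prob)
      codes <- names(config$ekg_code_probs)
      got <- matrix(
        stats::runif(length(sel) * length(codes)) <
          rep(cond, each = length(sel)),
        nrow = length(sel)
      )
      none <- rowSums(got) == 0
      got[none, 1L] <- TRUE  # at least one code for an EKG-positive case
      case <- rep(sel, times = length(codes))[as.vector(got)]
      code <- rep(codes, each = length(sel))[as.vector(got)]
      proc_rows$ekg <- tibble::tibble(
        person_id = person_id[case_idx][case],
        service_date = clamp_dates(
          index_date[case] + sample(-1:14, length(case), replace = TRUE),
          study_start, study_end
        ),
        procedure_code = code,
        setting = index_setting[case]
      )
    }
  }
  procedures <- if (length(proc_rows)) dplyr::bind_rows(proc_rows)
  else empty_bundle_tables()$procedures

  ## stream 7: admissions and length of stay ------------------------------
  set.seed(ss[7])
  inpat <- which(index_setting == "inpatient")
  los_band_drawn <- rep(NA_integer_, n_case)
  los_days <- rep(NA_integer_, n_case)
  admissions <- empty_bundle_tables()$admissions
  if (length(inpat)) {
    band <- sample.int(4L, length(inpat), replace = TRUE,
                       prob = config$los_bands)
    los <- integer(length(inpat))
    los[band == 1L] <- sample(1:5, sum(band == 1L), replace = TRUE)
    los[band == 2L] <- sample(6:10, sum(band == 2L), replace = TRUE)
    los[band == 3L] <- sample(11:14, sum(band == 3L), replace = TRUE)
    n4 <- sum(band == 4L)
    if (n4 > 0) {
      los[band == 4L] <- pmin(15L + stats::rgeom(n4, config$los_tail_p),
                              config$los_max)
    }
    los_band_drawn[inpat] <- band
    los_days[inpat] <- los
    # admission begins the day before the index diagnosis claim, so the
    # admission contains the cohort index even when an in-window concurrent
    # code one day earlier becomes the first qualifying claim
    admissions <- tibble::tibble(
      person_id = person_id[case_idx][inpat],
      admit_date = index_date[inpat] - 1L,
      discharge_date = index_date[inpat] - 1L + los
    )
  }

  ## stream 8: background noise ------------------------------------------
  set.seed(ss[8])
  nz <- default_noise_codes()
  noisy <- which(stats::runif(n) < config$noise_diag_prob)
  noise <- NULL
  if (length(noisy)) {
    k <- sample(1:3, length(noisy), replace = TRUE)
    pid <- rep(person_id[noisy], k)
    d <- study_start +
      floor(stats::runif(length(pid)) *
              as.integer(study_end - study_start + 1L))
    v <- ifelse(d < era_boundary, "icd9cm", "icd10cm")
    code <- character(length(pid))
    for (vv in icd_versions()) {
      sel <- v == vv
      code[sel] <- sample(nz$code[nz$version == vv], sum(sel), replace = TRUE)
    }
    noise <- tibble::tibble(
      person_id = pid, service_date = d, code = code, version = v,
      position = sample(code_positions(), length(pid), replace = TRUE),
      setting = sample(claim_settings(), length(pid), replace = TRUE)
    )
  }

  diagnoses <- dplyr::bind_rows(diagnoses, conc, noise)
  diagnoses <- diagnoses[order(diagnoses$person_id, diagnoses$service_date,
                               diagnoses$code), ]

  bundle <- claims_bundle(
    persons = persons, enrollment = enrollment, diagnoses = diagnoses,
    drugs = drugs, procedures = procedures, admissions = admissions
  )

  truth <- tibble::tibble(
    person_id = person_id,
    is_case = is_case,
    gender = gender,
    birth_year = birth_year,
    index_year = index_year,
    index_date = as.Date(NA),
    index_code = NA_character_,
    version = NA_character_,
    setting = NA_character_,
    both_versions = FALSE,
    age_at_index = NA_integer_,
    los_band = NA_integer_,
    los_days = NA_integer_
  )
  truth$index_date[case_idx] <- index_date
  truth$index_code[case_idx] <- index_code
  truth$version[case_idx] <- index_version
  truth$setting[case_idx] <- index_setting
  truth$both_versions[case_idx] <- both
  truth$age_at_index[case_idx] <- age_ref[case_idx]
  truth$los_band[case_idx] <- los_band_drawn
  truth$los_days[case_idx] <- los_days

  attr(bundle, "truth") <- truth
  list(bundle = bundle, truth = truth)
}
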
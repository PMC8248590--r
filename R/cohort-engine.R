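# Cohort extraction: continuous-enrollment eligibility, code-era gating,
# any-position/any-setting matching, and first-event-per-period dedup.
#
# All date intervals are closed on both ends. The ICD-9-CM era runs up to
# the day before the era boundary (2015-09-30); the ICD-10-CM era starts on
# the boundary (2015-10-01).

#' Study configuration
#'
#' Holds the study window, the ICD-9/ICD-10 era boundary, the minimum age,
#' the setting scopes and the permitted enrollment gap. Defaults describe a
#' four-year study spanning the U.S. transition to ICD-10-CM on 2015-10-01.
#'
#' @param study_start,study_end Study period bounds (closed).
#' @param era_boundary First date on which ICD-10-CM codes are valid;
#'   ICD-9-CM codes are valid strictly before it.
#' @param min_age_years Minimum age (in whole years, `year - birth_year`) for
#'   cohort and denominator membership; the default 1 excludes infants.
#' @param enrollment_gap_days Maximum length of any interior coverage gap
#'   still counted as continuous enrollment (default 0: no gaps).
#' @return Object of class `study_config`.
#' @export
study_config <- function(study_start = as.Date("2014-01-01"),
                         study_end = as.Date("2017-12-31"),
                         era_boundary = as.Date("2015-10-01"),
                         min_age_years = 1L,
                         enrollment_gap_days = 0L) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  era_boundary <- as.Date(era_boundary)
  if (!(study_start < era_boundary && era_boundary < study_end)) {
    stop("study_config: require study_start < era_boundary < study_end")
  }
  structure(
    list(
      study_start = study_start, study_end = study_end,
      era_boundary = era_boundary,
      min_age_years = as.integer(min_age_years),
      any_setting = claim_settings(),
      inpatient_setting = "inpatient",
      enrollment_gap_days = as.integer(enrollment_gap_days)
    ),
    class = "study_config"
  )
}

#' A query period
#'
#' @param start,end Closed period bounds.
#' @param label Display label, e.g. `"2016"` or `"2014-2017"`.
#' @return Object of class `query_period`.
#' @export
query_period <- function(start, end, label = NULL) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(start <= end)
  if (is.null(label)) {
    y1 <- as.integer(format(start, "%Y")); y2 <- as.integer(format(end, "%Y"))
    label <- if (y1 == y2) as.character(y1) else paste0(y1, "-", y2)
  }
  structure(list(start = start, end = end, label = label), class = "query_period")
}

#' Whole-year query period
#' @param year Calendar year.
#' @return A [query_period()] covering the full calendar year.
#' @export
year_period <- function(year) {
  query_period(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)))
}

period_years <- function(period, config) {
  y1 <- as.integer(format(period$start, "%Y"))
  y2 <- as.integer(format(period$end, "%Y"))
  years <- y1:y2
  keep <- vapply(years, function(y) {
    ys <- as.Date(sprintf("%d-01-01", y)); ye <- as.Date(sprintf("%d-12-31", y))
    ys >= period$start && ye <= period$end &&
      ys >= config$study_start && ye <= config$study_end
  }, logical(1))
  years[keep]
}

#' Merge enrollment spans for one person
#'
#' Overlapping and adjacent (end + 1 day = next start) spans are merged into
#' disjoint, ordered spans covering the same set of days.
#'
#' @param spans Data frame with `start_date` and `end_date` for one person.
#' @return Tibble of disjoint spans ordered by `start_date`.
#' @export
merge_spans <- function(spans) {
  spans <- tibble::as_tibble(spans)
  if (nrow(spans) == 0) {
    return(tibble::tibble(start_date = as.Date(character()),
                          end_date = as.Date(character())))
  }
  s <- spans[order(spans$start_date, spans$end_date), , drop = FALSE]
  starts <- as.integer(s$start_date); ends <- as.integer(s$end_date)
  out_s <- starts[1]; out_e <- ends[1]; k <- 1L
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= out_e[k] + 1L) {
      out_e[k] <- max(out_e[k], ends[i])
    } else {
      k <- k + 1L
      out_s[k] <- starts[i]; out_e[k] <- ends[i]
    }
  }
  tibble::tibble(
    start_date = as.Date(out_s, origin = "1970-01-01"),
    end_date = as.Date(out_e, origin = "1970-01-01")
  )
}

# Merge spans across all persons at once. Fast path assumes spans sorted per
# person are non-overlapping (true of generated data); falls back to
# per-person merge_spans when overlaps are present.
merge_spans_all <- function(enrollment) {
  if (nrow(enrollment) == 0) {
    return(tibble::tibble(person_id = character(),
                          start_date = as.Date(character()),
                          end_date = as.Date(character())))
  }
  e <- enrollment[order(enrollment$person_id, enrollment$start_date,
                        enrollment$end_date), , drop = FALSE]
  pid <- e$person_id
  starts <- as.integer(e$start_date); ends <- as.integer(e$end_date)
  same <- c(FALSE, pid[-1] == pid[-length(pid)])
  overlap <- same & (starts <= c(-Inf, ends[-length(ends)]))
  if (!any(overlap)) {
    # disjoint within person: only adjacency merging needed
    new_grp <- !(same & (starts <= c(0L, ends[-length(ends)]) + 1L))
    last <- c(new_grp[-1], TRUE)  # ends increase within a run of disjoint spans
    tibble::tibble(
      person_id = pid[new_grp],
      start_date = as.Date(starts[new_grp], origin = "1970-01-01"),
      end_date = as.Date(ends[last], origin = "1970-01-01")
    )
  } else {
    parts <- split(tibble::tibble(start_date = e$start_date, end_date = e$end_date),
                   pid)
    dplyr::bind_rows(lapply(parts, merge_spans), .id = "person_id")
  }
}

#' Is a person continuously enrolled for a calendar year?
#'
#' True when the person's merged spans cover January 1 and December 31 of
#' the year and every interior coverage gap is at most `gap_days` long.
#'
#' @param spans Data frame of `start_date`/`end_date` for one person
#'   (merged internally).
#' @param year Calendar year.
#' @param gap_days Maximum permitted interior gap, default 0.
#' @return Logical scalar.
#' @export
continuously_enrolled <- function(spans, year, gap_days = 0L) {
  m <- merge_spans(spans)
  if (nrow(m) == 0) return(FALSE)
  ys <- as.Date(sprintf("%d-01-01", year))
  ye <- as.Date(sprintf("%d-12-31", year))
  m <- m[m$end_date >= ys & m$start_date <= ye, , drop = FALSE]
  if (nrow(m) == 0) return(FALSE)
  if (m$start_date[1] > ys) return(FALSE)
  if (m$end_date[nrow(m)] < ye) return(FALSE)
  if (nrow(m) > 1) {
    gaps <- as.integer(m$start_date[-1]) - as.integer(m$end_date[-nrow(m)]) - 1L
    if (any(gaps > gap_days)) return(FALSE)
  }
  TRUE
}

# person-year eligibility table: one row per (person_id, year) in which the
# person is continuously enrolled and at least min_age years old.
eligible_person_years <- function(bundle, years, config) {
  if (length(years) == 0 || nrow(bundle$persons) == 0) {
    return(tibble::tibble(person_id = character(), year = integer()))
  }
  merged <- merge_spans_all(bundle$enrollment)
  if (config$enrollment_gap_days == 0L) {
    # a year is fully covered iff one merged span contains it
    sy <- as.integer(format(merged$start_date, "%Y"))
    ey <- as.integer(format(merged$end_date, "%Y"))
    full_from <- sy + (merged$start_date > as.Date(sprintf("%d-01-01", sy)))
    full_to <- ey - (merged$end_date < as.Date(sprintf("%d-12-31", ey)))
    n_y <- pmax(full_to - full_from + 1L, 0L)
    keep <- n_y > 0L
    py <- tibble::tibble(
      person_id = rep(merged$person_id[keep], n_y[keep]),
      year = unlist(lapply(which(keep), function(i) seq(full_from[i], full_to[i])),
                    use.names = FALSE)
    )
    py <- py[py$year %in% years, , drop = FALSE]
  } else {
    parts <- split(merged[c("start_date", "end_date")], merged$person_id)
    rows <- lapply(names(parts), function(id) {
      ok <- years[vapply(years, function(y) {
        continuously_enrolled(parts[[id]], y, config$enrollment_gap_days)
      }, logical(1))]
      if (length(ok)) tibble::tibble(person_id = id, year = ok) else NULL
    })
    py <- dplyr::bind_rows(rows)
    if (nrow(py) == 0) py <- tibble::tibble(person_id = character(), year = integer())
  }
  py <- dplyr::inner_join(py, bundle$persons[c("person_id", "birth_year")],
                          by = "person_id")
  py <- py[py$year - py$birth_year >= config$min_age_years, , drop = FALSE]
  tibble::tibble(person_id = py$person_id, year = as.integer(py$year))
}

#' Is a claim's code valid for its era?
#'
#' ICD-9-CM codes are queried only before the era boundary and ICD-10-CM
#' codes only from the boundary onward; claims violating this carry overt
#' coding errors and are ignored. Vectorized.
#'
#' @param version Claim code version(s).
#' @param service_date Claim date(s).
#' @param config A [study_config()].
#' @return Logical vector.
#' @export
era_valid <- function(version, service_date, config = study_config()) {
  (version == "icd9cm" & service_date < config$era_boundary) |
    (version == "icd10cm" & service_date >= config$era_boundary)
}

# qualifying claims for a scope/period: era-valid, code-list-matching,
# in-scope setting, dated inside an eligible fully-enrolled calendar year.
qualifying_claims <- function(bundle, codelist, period, setting_scope, config,
                              eligible = NULL) {
  scope_settings <- switch(setting_scope,
    any_healthcare = config$any_setting,
    inpatient = config$inpatient_setting,
    stop("unknown setting_scope: ", setting_scope)
  )
  years <- period_years(period, config)
  if (is.null(eligible)) eligible <- eligible_person_years(bundle, years, config)
  d <- bundle$diagnoses
  d <- d[d$setting %in% scope_settings &
           d$service_date >= max(period$start, config$study_start) &
           d$service_date <= min(period$end, config$study_end), , drop = FALSE]
  if (nrow(d)) d <- d[era_valid(d$version, d$service_date, config), , drop = FALSE]
  if (nrow(d)) d <- d[code_matches(d$code, d$version, codelist), , drop = FALSE]
  if (nrow(d)) {
    d$year <- as.integer(format(d$service_date, "%Y"))
    d <- dplyr::semi_join(d, eligible, by = c("person_id", "year"))
  }
  list(claims = tibble::as_tibble(d), eligible = eligible)
}

#' Build an AMI cohort
#'
#' Applies the phenotyping algorithm under the study's inclusion rules. A
#' person enters the denominator when continuously enrolled for at least one
#' whole calendar year inside the period and at least `min_age_years` old in
#' that year. Their index event is the chronologically first era-valid,
#' code-list-matching diagnosis claim whose setting is in scope and whose
#' date falls inside one of their fully enrolled years; later qualifying
#' claims (readmissions, subsequent events) in the period are ignored.
#' Same-day ties prefer the inpatient setting, then principal position,
#' then lexicographic code order.
#'
#' @param bundle A [claims_bundle()].
#' @param codelist A [code_list()]; the packaged [ami_code_list()] is the
#'   usual choice.
#' @param period A [query_period()].
#' @param setting_scope `"any_healthcare"` (all nine settings) or
#'   `"inpatient"`.
#' @param config A [study_config()].
#' @return Object of class `cohort`: `events` (one row per indexed person:
#'   `person_id`, `index_date`, `code`, `version`, `setting`,
#'   `age_at_index`, `gender`), plus `period`, `setting_scope`,
#'   `denominator` and `config`.
#' @export
build_cohort <- function(bundle, codelist, period,
                         setting_scope = c("any_healthcare", "inpatient"),
                         config = study_config()) {
  stopifnot(inherits(bundle, "claims_bundle"), inherits(period, "query_period"))
  setting_scope <- match.arg(setting_scope)
  if (!inherits(codelist, "code_list") || nrow(codelist$patterns) == 0) {
    stop("build_cohort: a non-empty code_list is required")
  }
  q <- qualifying_claims(bundle, codelist, period, setting_scope, config)
  d <- q$claims
  if (nrow(d)) {
    d$setting_rank <- ifelse(d$setting == "inpatient", 0L, 1L)
    d$position_rank <- match(d$position, code_positions())
    d <- d[order(d$person_id, d$service_date, d$setting_rank,
                 d$position_rank, d$code), , drop = FALSE]
    d <- d[!duplicated(d$person_id), , drop = FALSE]
    events <- tibble::tibble(
      person_id = d$person_id,
      index_date = d$service_date,
      code = d$code,
      version = d$version,
      setting = d$setting
    )
    events <- dplyr::left_join(
      events, bundle$persons[c("person_id", "birth_year", "gender")],
      by = "person_id"
    )
    events$age_at_index <-
      as.integer(format(events$index_date, "%Y")) - events$birth_year
    events$birth_year <- NULL
  } else {
    events <- tibble::tibble(
      person_id = character(), index_date = as.Date(character()),
      code = character(), version = character(), setting = character(),
      gender = character(), age_at_index = integer()
    )
  }
  structure(
    list(
      events = events,
      period = period,
      setting_scope = setting_scope,
      denominator = dplyr::n_distinct(q$eligible$person_id),
      config = config
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", x$period$label, "/", x$setting_scope, "\n")
  cat("  cases:      ", nrow(x$events), "\n")
  cat("  denominator:", x$denominator, "\n")
  invisible(x)
}

#' Attribute cohort members to code versions
#'
#' For a period straddling the era boundary, counts cohort members whose
#' qualifying claims are ICD-9-CM only, ICD-10-CM only, or both. A person is
#' "both" when they hold at least one qualifying era-valid claim under each
#' version inside the period; such patients are counted once in the cohort,
#' so `icd9_only + icd10_only + both = cohort size` and the union obeys
#' inclusion-exclusion against per-version cohorts.
#'
#' @inheritParams build_cohort
#' @return Named list: `icd9_only`, `icd10_only`, `both`, `total`.
#' @export
version_attribution <- function(bundle, codelist, period,
                                setting_scope = c("any_healthcare", "inpatient"),
                                config = study_config()) {
  setting_scope <- match.arg(setting_scope)
  q <- qualifying_claims(bundle, codelist, period, setting_scope, config)
  d <- q$claims
  if (nrow(d) == 0) {
    return(list(icd9_only = 0L, icd10_only = 0L, both = 0L, total = 0L))
  }
  per <- dplyr::summarise(
    dplyr::group_by(d, .data$person_id),
    has9 = any(.data$version == "icd9cm"),
    has10 = any(.data$version == "icd10cm"),
    .groups = "drop"
  )
  both <- sum(per$has9 & per$has10)
  list(
    icd9_only = sum(per$has9 & !per$has10),
    icd10_only = sum(per$has10 & !per$has9),
    both = both,
    total = nrow(per)
  )
}

#' Restrict a code list to one ICD-CM version
#'
#' Used to build per-version cohort strata (e.g. the ICD-9-CM column of a
#' demographics table).
#'
#' @param codelist A [code_list()].
#' @param version `"icd9cm"` or `"icd10cm"`.
#' @return A [code_list()] containing only that version's patterns.
#' @export
restrict_codelist <- function(codelist, version = c("icd9cm", "icd10cm")) {
  version <- match.arg(version)
  pats <- codelist$patterns[codelist$patterns$version == version, , drop = FALSE]
  code_list(paste0(codelist$name, " (", version, ")"),
            pats[c("pattern", "version", "description")],
            provenance = codelist$provenance)
}

#' Write a cohort to CSV plus a JSON summary
#'
#' @param cohort A [build_cohort()] result.
#' @param dir Output directory.
#' @param attribution Optional [version_attribution()] list to embed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, attribution = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$events, file.path(dir, "cohort.csv"), progress = FALSE)
  summary <- list(
    period = cohort$period$label,
    setting_scope = cohort$setting_scope,
    size = nrow(cohort$events),
    denominator = cohort$denominator
  )
  if (!is.null(attribution)) summary$version_attribution <- attribution
  jsonlite::write_json(summary, file.path(dir, "cohort_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
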
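# Descriptive characterization of AMI cohorts: rounded proportions, annual
# series, windowed item frequencies, drug classes, multi-code queries,
# length-of-stay summaries, demographics and gender-age curves.

round_half_away <- function(x, digits) {
  # round half away from zero (printed tables use this, not banker's
  # rounding); tiny epsilon guards against representation error at .5
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Percentage with half-away-from-zero rounding
#'
#' Every printed percentage in the package flows through this.
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param decimals Decimal places (default 1, matching the tables).
#' @return `100 * numerator / denominator`, rounded.
#' @examples
#' pct(170147, 268424)  # 63.4
#' @export
pct <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) stop("pct: denominator must be positive")
  if (any(numerator < 0)) stop("pct: numerator must be non-negative")
  round_half_away(100 * numerator / denominator, decimals)
}

#' Per-1,000 proportion with half-away-from-zero rounding
#'
#' @inheritParams pct
#' @param decimals Decimal places (default 2, matching annual series output).
#' @return `1000 * numerator / denominator`, rounded.
#' @examples
#' per_thousand(80411, 28407959)  # 2.83
#' @export
per_thousand <- function(numerator, denominator, decimals = 2L) {
  if (any(denominator <= 0)) stop("per_thousand: denominator must be positive")
  round_half_away(1000 * numerator / denominator, decimals)
}

#' Event-relative query window
#'
#' Windows are closed on both ends and expressed in days relative to the
#' index date (negative = before). The packaged analysis windows are
#' [condition_window()] (-1, +1) for concurrent diagnoses and
#' [treatment_window()] (-1, +14) for drugs and procedures.
#'
#' @param rel_start,rel_end Integer day offsets, `rel_start <= rel_end`.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(rel_start, rel_end) {
  rel_start <- as.integer(rel_start); rel_end <- as.integer(rel_end)
  if (is.na(rel_start) || is.na(rel_end) || rel_start > rel_end) {
    stop("window_spec: require rel_start <= rel_end")
  }
  structure(list(rel_start = rel_start, rel_end = rel_end),
            class = "window_spec")
}

#' @rdname window_spec
#' @export
condition_window <- function() window_spec(-1L, 1L)

#' @rdname window_spec
#' @export
treatment_window <- function() window_spec(-1L, 14L)

# claims of cohort members with dates inside the window, one row per claim,
# with the item column standardized to `item`
window_claims <- function(cohort, claims, window, item_col, date_col) {
  stopifnot(inherits(cohort, "cohort"), inherits(window, "window_spec"))
  claims <- tibble::as_tibble(claims)
  x <- dplyr::inner_join(
    claims, cohort$events[c("person_id", "index_date")], by = "person_id",
    relationship = "many-to-many"
  )
  rel <- as.integer(x[[date_col]]) - as.integer(x$index_date)
  x <- x[rel >= window$rel_start & rel <= window$rel_end, , drop = FALSE]
  x$item <- x[[item_col]]
  x
}

#' Rank items observed around cohort index dates
#'
#' For each cohort member, collects the distinct items (diagnosis codes,
#' drug products, procedure codes, ...) whose claim date lies within the
#' closed window around the index date, then counts persons per item. A
#' person contributes at most once per item; the index event's own code is
#' not excluded, so additional AMI codes within the window are counted.
#' Rows are ranked by person count (descending), ties broken by item.
#'
#' @param cohort A [build_cohort()] result.
#' @param claims Claim table holding `person_id`, a date column and an item
#'   column.
#' @param window A [window_spec()].
#' @param item_col,date_col Column names in `claims`.
#' @param top_n Optional limit on the number of rows returned.
#' @return Object of class `frequency_table`: tibble of `item`,
#'   `person_count`, `pct_of_cohort`, with attribute `cohort_size`.
#' @export
windowed_items <- function(cohort, claims, window, item_col, date_col,
                           top_n = Inf) {
  x <- window_claims(cohort, claims, window, item_col, date_col)
  size <- nrow(cohort$events)
  if (nrow(x) == 0) {
    out <- tibble::tibble(item = character(), person_count = integer(),
                          pct_of_cohort = numeric())
  } else {
    pairs <- dplyr::distinct(x, .data$person_id, .data$item)
    out <- dplyr::count(pairs, .data$item, name = "person_count")
    out <- out[order(-out$person_count, out$item), , drop = FALSE]
    out$pct_of_cohort <- if (size > 0) pct(out$person_count, size) else NA_real_
    if (is.finite(top_n)) out <- utils::head(out, top_n)
  }
  structure(tibble::as_tibble(out), cohort_size = size,
            class = c("frequency_table", class(out)))
}

#' Person counts per category of windowed items
#'
#' Like [windowed_items()] but items are first mapped to categories (e.g.
#' condition organ systems, procedure groups); unmapped items fall into
#' `"other"`. A person counts once per category.
#'
#' @inheritParams windowed_items
#' @param category_map Data frame with columns `item` and `category`.
#' @return A `frequency_table` over categories.
#' @export
category_table <- function(cohort, claims, window, item_col, date_col,
                           category_map) {
  stopifnot(all(c("item", "category") %in% names(category_map)))
  x <- window_claims(cohort, claims, window, item_col, date_col)
  size <- nrow(cohort$events)
  if (nrow(x) == 0) {
    out <- tibble::tibble(category = character(), person_count = integer(),
                          pct_of_cohort = numeric())
  } else {
    x <- dplyr::left_join(x, tibble::as_tibble(category_map)[c("item", "category")],
                          by = "item")
    x$category[is.na(x$category)] <- "other"
    pairs <- dplyr::distinct(x, .data$person_id, .data$category)
    out <- dplyr::count(pairs, .data$category, name = "person_count")
    out <- out[order(-out$person_count, out$category), , drop = FALSE]
    out$pct_of_cohort <- if (size > 0) pct(out$person_count, size) else NA_real_
  }
  structure(tibble::as_tibble(out), cohort_size = size,
            class = c("frequency_table", class(out)))
}

#' Cardiac drug-class table from the top-ranked products
#'
#' Ranks drug products ordered in the treatment window by person count,
#' keeps the 100 most common products, maps each to its drug class, and
#' counts each person once per class (the union of that class's top-ranked
#' products). Products absent from the catalogue fall into `"other"`.
#'
#' @param cohort A [build_cohort()] result.
#' @param drug_claims Drug order table (`person_id`, `order_date`,
#'   `product_name`).
#' @param window A [window_spec()]; the packaged analysis uses
#'   [treatment_window()].
#' @param catalogue Data frame with columns `product_name` and `class`.
#' @param top_products Number of top products classes are computed from
#'   (default 100).
#' @return Tibble of `class`, `person_count`, `pct_of_cohort`, ranked by
#'   count; attribute `top_products` holds the product ranking used.
#' @export
drug_class_table <- function(cohort, drug_claims, window = treatment_window(),
                             catalogue, top_products = 100L) {
  stopifnot(all(c("product_name", "class") %in% names(catalogue)))
  x <- window_claims(cohort, drug_claims, window, "product_name", "order_date")
  size <- nrow(cohort$events)
  if (nrow(x) == 0) {
    out <- tibble::tibble(class = character(), person_count = integer(),
                          pct_of_cohort = numeric())
    return(structure(out, cohort_size = size,
                     top_products = tibble::tibble(item = character(),
                                                   person_count = integer())))
  }
  pairs <- dplyr::distinct(x, .data$person_id, .data$item)
  ranking <- dplyr::count(pairs, .data$item, name = "person_count")
  ranking <- ranking[order(-ranking$person_count, ranking$item), , drop = FALSE]
  top <- utils::head(ranking, top_products)
  pairs <- pairs[pairs$item %in% top$item, , drop = FALSE]
  pairs <- dplyr::left_join(
    pairs,
    tibble::as_tibble(catalogue)[c("product_name", "class")],
    by = c(item = "product_name")
  )
  pairs$class[is.na(pairs$class)] <- "other"
  per_class <- dplyr::distinct(pairs, .data$person_id, .data$class)
  out <- dplyr::count(per_class, .data$class, name = "person_count")
  out <- out[order(-out$person_count, out$class), , drop = FALSE]
  out$pct_of_cohort <- if (size > 0) pct(out$person_count, size) else NA_real_
  structure(tibble::as_tibble(out), cohort_size = size, top_products = top)
}

#' Persons receiving any code from a set within a window
#'
#' The "at least one of these codes" query, e.g. any of the three
#' electrocardiogram procedure codes in the 15-day treatment window.
#'
#' @param cohort A [build_cohort()] result.
#' @param claims Claim table.
#' @param window A [window_spec()].
#' @param code_set Non-empty character vector of codes.
#' @param code_col,date_col Column names in `claims`.
#' @return List with `person_count` and `pct` (of cohort size).
#' @export
multi_code_any <- function(cohort, claims, window, code_set,
                           code_col = "procedure_code", date_col = "service_date") {
  if (length(code_set) == 0) stop("multi_code_any: code_set must be non-empty")
  x <- window_claims(cohort, claims, window, code_col, date_col)
  x <- x[x$item %in% code_set, , drop = FALSE]
  n <- dplyr::n_distinct(x$person_id)
  size <- nrow(cohort$events)
  list(person_count = n, pct = if (size > 0) pct(n, size) else NA_real_)
}

# median-exclusive quartiles: median of the lower/upper half, excluding the
# middle observation when n is odd
quartiles_exclusive <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 2) return(c(q1 = x[1], q3 = x[1]))
  lower <- x[seq_len(floor(n / 2))]
  upper <- x[seq(ceiling(n / 2) + 1L, n)]
  c(q1 = stats::median(lower), q3 = stats::median(upper))
}

los_band_labels <- function() c("1-5", "6-10", "11-14", ">14")

los_band <- function(los) {
  cut(los, breaks = c(0, 5, 10, 14, Inf), labels = los_band_labels())
}

#' Length-of-stay summary for an inpatient cohort
#'
#' Links each cohort member to the inpatient admission containing (or
#' starting on) their index date — earliest admission wins when several
#' qualify — and summarizes one length of stay per person.
#' `LOS = max(1, discharge - admit)` in days, so same-day stays count as
#' one day. Quartiles are median-exclusive; band proportions cover
#' 1-5 / 6-10 / 11-14 / >14 days.
#'
#' @param cohort An inpatient-scope [build_cohort()] result.
#' @param admissions Admissions table (`person_id`, `admit_date`,
#'   `discharge_date`).
#' @return Object of class `los_summary`: `n` (persons with a linkable
#'   admission), `n_unlinked`, `mean`, `sd`, `median`, `iqr`, `range`,
#'   `band_props` (named proportions summing to 1) and the per-person `los`
#'   tibble.
#' @export
los_summary <- function(cohort, admissions) {
  stopifnot(inherits(cohort, "cohort"))
  if (cohort$setting_scope != "inpatient") {
    warning("los_summary: cohort scope is not 'inpatient'")
  }
  adm <- tibble::as_tibble(admissions)
  x <- dplyr::inner_join(
    cohort$events[c("person_id", "index_date")], adm, by = "person_id",
    relationship = "many-to-many"
  )
  x <- x[x$admit_date <= x$index_date & x$discharge_date >= x$index_date, ,
         drop = FALSE]
  x <- x[order(x$person_id, x$admit_date), , drop = FALSE]
  x <- x[!duplicated(x$person_id), , drop = FALSE]
  x$los <- pmax(1L, as.integer(x$discharge_date) - as.integer(x$admit_date))
  n_unlinked <- nrow(cohort$events) - nrow(x)
  if (nrow(x) == 0) {
    return(structure(
      list(n = 0L, n_unlinked = n_unlinked, mean = NA_real_, sd = NA_real_,
           median = NA_real_, iqr = c(NA_real_, NA_real_),
           range = c(NA_real_, NA_real_),
           band_props = stats::setNames(rep(NA_real_, 4), los_band_labels()),
           los = tibble::tibble(person_id = character(), los = integer())),
      class = "los_summary"
    ))
  }
  q <- quartiles_exclusive(x$los)
  bands <- table(los_band(x$los))
  structure(
    list(
      n = nrow(x),
      n_unlinked = n_unlinked,
      mean = mean(x$los),
      sd = stats::sd(x$los),
      median = stats::median(x$los),
      iqr = unname(q),
      range = range(x$los),
      band_props = stats::setNames(as.numeric(bands) / nrow(x),
                                   los_band_labels()),
      los = x[c("person_id", "los")]
    ),
    class = "los_summary"
  )
}

#' @export
print.los_summary <- function(x, ...) {
  cat("<los_summary>", x$n, "linked stays",
      if (x$n_unlinked > 0) paste0("(", x$n_unlinked, " unlinked)") else "", "\n")
  if (x$n > 0) {
    cat(sprintf("  mean %.1f (SD %.1f); median %g (IQR %g-%g; range %g-%g)\n",
                x$mean, x$sd, x$median, x$iqr[1], x$iqr[2],
                x$range[1], x$range[2]))
    cat("  bands:", paste(sprintf("%s: %.1f%%", names(x$band_props),
                                  100 * x$band_props), collapse = ", "), "\n")
  }
  invisible(x)
}

age_bin_labels <- function() c("0-17", "18-34", "35-44", "45-54", "55-64", "65+")

#' Assign ages to reporting bins
#'
#' @param age Integer ages in years.
#' @return Factor over the six bins 0-17, 18-34, 35-44, 45-54, 55-64, 65+.
#' @export
age_bin <- function(age) {
  cut(age, breaks = c(-Inf, 17, 34, 44, 54, 64, Inf),
      labels = age_bin_labels())
}

#' Demographic summary of a cohort
#'
#' Size, mean/SD of age at index, counts and percentages per age bin, and
#' male count/percentage. Bin counts always sum to the cohort size.
#'
#' @param cohort A [build_cohort()] result.
#' @return Object of class `demographics_summary`.
#' @export
demographics <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  ev <- cohort$events
  size <- nrow(ev)
  bins <- table(age_bin(ev$age_at_index))
  bin_tbl <- tibble::tibble(
    bin = age_bin_labels(),
    n = as.integer(bins),
    pct = if (size > 0) pct(as.integer(bins), size) else NA_real_
  )
  male_n <- sum(ev$gender == "male")
  structure(
    list(
      size = size,
      mean_age = if (size > 0) mean(ev$age_at_index) else NA_real_,
      sd_age = if (size > 1) stats::sd(ev$age_at_index) else NA_real_,
      age_bins = bin_tbl,
      male_n = male_n,
      male_pct = if (size > 0) pct(male_n, size) else NA_real_
    ),
    class = "demographics_summary"
  )
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat("<demographics_summary> n =", x$size, "\n")
  if (x$size > 0) {
    cat(sprintf("  mean age %.1f (SD %.1f); male %d (%.1f%%)\n",
                x$mean_age, x$sd_age, x$male_n, x$male_pct))
    print(x$age_bins)
  }
  invisible(x)
}

#' Demographics stratified by ICD-CM version
#'
#' Builds the ICD-9-CM, ICD-10-CM and combined cohorts for a period (a
#' person with qualifying claims under both versions appears in both
#' version strata but once in the combined cohort) and summarizes each.
#'
#' @inheritParams build_cohort
#' @return Named list of [demographics()] summaries: `icd9`, `icd10`,
#'   `combined`, plus `cohorts` holding the three cohorts.
#' @export
demographics_by_version <- function(bundle, codelist, period,
                                    setting_scope = c("any_healthcare", "inpatient"),
                                    config = study_config()) {
  setting_scope <- match.arg(setting_scope)
  c9 <- build_cohort(bundle, restrict_codelist(codelist, "icd9cm"), period,
                     setting_scope, config)
  c10 <- build_cohort(bundle, restrict_codelist(codelist, "icd10cm"), period,
                      setting_scope, config)
  call <- build_cohort(bundle, codelist, period, setting_scope, config)
  list(
    icd9 = demographics(c9),
    icd10 = demographics(c10),
    combined = demographics(call),
    cohorts = list(icd9 = c9, icd10 = c10, combined = call)
  )
}

#' Annual cohort series
#'
#' For each calendar year, builds the cohort and reports its size, the
#' continuously enrolled denominator and the per-1,000 proportion. For
#' years straddling the era boundary the ICD-9-only / ICD-10-only / both
#' attribution is included; era-pure years report their own version's count.
#'
#' @param bundle A [claims_bundle()].
#' @param codelist A [code_list()].
#' @param years Integer vector of calendar years.
#' @param config A [study_config()].
#' @param setting_scope Cohort scope, as in [build_cohort()].
#' @return Tibble with columns `year`, `cases`, `denominator`, `per_1000`,
#'   `icd9_cases`, `icd10_cases`, `both_versions`.
#' @export
annual_series <- function(bundle, codelist, years, config = study_config(),
                          setting_scope = "any_healthcare") {
  rows <- lapply(years, function(y) {
    period <- year_period(y)
    coh <- build_cohort(bundle, codelist, period, setting_scope, config)
    n <- nrow(coh$events)
    straddle <- period$start <= config$era_boundary &&
      config$era_boundary <= period$end
    if (straddle) {
      att <- version_attribution(bundle, codelist, period, setting_scope, config)
      icd9 <- att$icd9_only + att$both
      icd10 <- att$icd10_only + att$both
      both <- att$both
    } else if (period$end < config$era_boundary) {
      icd9 <- n; icd10 <- 0L; both <- 0L
    } else {
      icd9 <- 0L; icd10 <- n; both <- 0L
    }
    tibble::tibble(
      year = y, cases = n, denominator = coh$denominator,
      per_1000 = if (coh$denominator > 0) per_thousand(n, coh$denominator) else NA_real_,
      icd9_cases = icd9, icd10_cases = icd10, both_versions = both
    )
  })
  dplyr::bind_rows(rows)
}

#' Gender- and age-specific diagnosis proportions
#'
#' Per-1,000 proportions of cohort members by gender and age, over single
#' years of age and over the six reporting bins. Numerator ages are ages at
#' index; denominator ages are ages at the period's first calendar year.
#' Cells with zero denominator are suppressed.
#'
#' @param cohort A [build_cohort()] result.
#' @param bundle The [claims_bundle()] the cohort came from.
#' @return List of two tibbles, `by_age` (gender, age, cases, enrollees,
#'   per_1000) and `by_bin`.
#' @export
gender_age_curve <- function(cohort, bundle) {
  config <- cohort$config
  years <- period_years(cohort$period, config)
  eligible <- eligible_person_years(bundle, years, config)
  denom <- dplyr::distinct(eligible, .data$person_id)
  denom <- dplyr::inner_join(denom, bundle$persons, by = "person_id")
  ref_year <- min(years)
  denom$age <- ref_year - denom$birth_year

  num <- cohort$events
  num$age <- num$age_at_index

  count_cells <- function(df, agevar) {
    dplyr::count(df, .data$gender, age = {{ agevar }}, name = "n")
  }
  by_cell <- function(numcells, dencells) {
    out <- dplyr::full_join(dencells, numcells, by = c("gender", "age"),
                            suffix = c("_den", "_num"))
    out$cases <- ifelse(is.na(out$n_num), 0L, out$n_num)
    out$enrollees <- ifelse(is.na(out$n_den), 0L, out$n_den)
    out <- out[out$enrollees > 0, , drop = FALSE]
    out$per_1000 <- per_thousand(out$cases, out$enrollees)
    out <- out[order(out$gender, out$age), , drop = FALSE]
    tibble::as_tibble(out[c("gender", "age", "cases", "enrollees", "per_1000")])
  }
  by_age <- by_cell(count_cells(num, age), count_cells(denom, age))
  num$bin <- age_bin(num$age)
  denom$bin <- age_bin(denom$age)
  by_bin <- by_cell(count_cells(num, bin), count_cells(denom, bin))
  names(by_bin)[names(by_bin) == "age"] <- "age_bin"
  list(by_age = by_age, by_bin = by_bin)
}
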
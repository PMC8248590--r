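# Independent brute-force oracles and hand-built micro-bundles used across
# the suite. The oracles deliberately share no code with the package
# internals: wildcard matching is re-implemented character by character,
# enrollment coverage is checked day by day, and cohorts are built by a
# per-person scan.

# character-by-character wildcard match on undotted codes; a trailing 'x'
# may also match absence
oracle_pattern_match <- function(code, pattern) {
  p <- gsub(".", "", pattern, fixed = TRUE)
  pc <- strsplit(p, "")[[1]]
  cc <- strsplit(code, "")[[1]]
  if (length(cc) == length(pc)) {
    all(mapply(function(a, b) b == "x" || toupper(b) == a, cc, pc))
  } else if (length(cc) == length(pc) - 1 && pc[length(pc)] == "x") {
    pc <- pc[-length(pc)]
    all(mapply(function(a, b) b == "x" || toupper(b) == a, cc, pc))
  } else {
    FALSE
  }
}

oracle_matches <- function(code, version, codelist) {
  pats <- codelist$patterns
  any(vapply(seq_len(nrow(pats)), function(i) {
    pats$version[i] == version && oracle_pattern_match(code, pats$pattern[i])
  }, logical(1)))
}

# day-by-day full-year coverage
oracle_year_covered <- function(spans, year) {
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  covered <- rep(FALSE, length(days))
  for (i in seq_len(nrow(spans))) {
    covered <- covered |
      (days >= spans$start_date[i] & days <= spans$end_date[i])
  }
  all(covered)
}

# per-person scan reproducing the cohort rules
oracle_cohort <- function(bundle, codelist, period, scope, config) {
  years <- seq(as.integer(format(period$start, "%Y")),
               as.integer(format(period$end, "%Y")))
  years <- years[vapply(years, function(y) {
    as.Date(sprintf("%d-01-01", y)) >= max(period$start, config$study_start) &&
      as.Date(sprintf("%d-12-31", y)) <= min(period$end, config$study_end)
  }, logical(1))]
  scope_settings <- if (scope == "inpatient") "inpatient" else claim_settings()
  events <- list()
  denom <- character(0)
  for (i in seq_len(nrow(bundle$persons))) {
    pid <- bundle$persons$person_id[i]
    by <- bundle$persons$birth_year[i]
    spans <- bundle$enrollment[bundle$enrollment$person_id == pid, ]
    ok_years <- years[vapply(years, function(y) {
      (y - by) >= config$min_age_years && oracle_year_covered(spans, y)
    }, logical(1))]
    if (length(ok_years) == 0) next
    denom <- c(denom, pid)
    cl <- bundle$diagnoses[bundle$diagnoses$person_id == pid, ]
    if (nrow(cl) == 0) next
    keep <- vapply(seq_len(nrow(cl)), function(j) {
      d <- cl$service_date[j]
      era_ok <- if (cl$version[j] == "icd9cm") d < config$era_boundary
      else d >= config$era_boundary
      cl$setting[j] %in% scope_settings &&
        as.integer(format(d, "%Y")) %in% ok_years &&
        era_ok &&
        oracle_matches(cl$code[j], cl$version[j], codelist)
    }, logical(1))
    cl <- cl[keep, ]
    if (nrow(cl) == 0) next
    cl <- cl[order(cl$service_date,
                   cl$setting != "inpatient",
                   match(cl$position, c("principal", "secondary", "unspecified")),
                   cl$code), ]
    events[[pid]] <- cl[1, c("person_id", "service_date", "code", "version",
                             "setting")]
  }
  list(
    events = if (length(events)) dplyr::bind_rows(events) else NULL,
    denominator = length(unique(denom))
  )
}

# naive per-person window filter
oracle_windowed_items <- function(cohort, claims, window, item_col, date_col) {
  rows <- list()
  for (i in seq_len(nrow(cohort$events))) {
    pid <- cohort$events$person_id[i]
    idx <- cohort$events$index_date[i]
    cl <- claims[claims$person_id == pid, ]
    items <- character(0)
    for (j in seq_len(nrow(cl))) {
      rel <- as.integer(cl[[date_col]][j]) - as.integer(idx)
      if (rel >= window$rel_start && rel <= window$rel_end) {
        items <- c(items, cl[[item_col]][j])
      }
    }
    for (it in unique(items)) rows[[length(rows) + 1L]] <- c(pid, it)
  }
  if (length(rows) == 0) {
    return(tibble::tibble(item = character(), person_count = integer()))
  }
  m <- do.call(rbind, rows)
  tab <- table(m[, 2])
  out <- tibble::tibble(item = names(tab), person_count = as.integer(tab))
  out[order(-out$person_count, out$item), ]
}

# brute-force reachability closure over a pair of toy GEMs
oracle_closure <- function(seed, forward, backward) {
  src <- sort(unique(seed))
  tgt <- character(0)
  step <- function(codes, gem) {
    e <- gem$entries
    sort(unique(e$target[e$source %in% codes & e$no_map == 0]))
  }
  repeat {
    new_tgt <- union(tgt, step(src, forward))
    new_src <- union(src, step(new_tgt, backward))
    if (setequal(new_src, src) && setequal(new_tgt, tgt)) break
    src <- sort(new_src); tgt <- sort(new_tgt)
  }
  list(source_set = src, target_set = tgt)
}

# hand-built micro-bundle: one fully enrolled adult, extensible
mini_person <- function(pid = "A", birth_year = 1950L, gender = "male") {
  tibble::tibble(person_id = pid, birth_year = birth_year, gender = gender)
}

mini_span <- function(pid = "A", start = "2014-01-01", end = "2017-12-31") {
  tibble::tibble(person_id = pid, start_date = as.Date(start),
                 end_date = as.Date(end), plan = "commercial")
}

mini_dx <- function(pid, date, code, version, position = "principal",
                    setting = "inpatient") {
  tibble::tibble(person_id = pid, service_date = as.Date(date), code = code,
                 version = version, position = position, setting = setting)
}

combined_period <- function() query_period("2014-01-01", "2017-12-31")

# a moderately sized generated bundle reused by several tests
shared_test_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_persons = 150L, annual_ami_rate = 80,
                              enrollment_gap_prob = 0.15)
      cache <<- generate_bundle(cfg, 7L)
    }
    cache
  }
})
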
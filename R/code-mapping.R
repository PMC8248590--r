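# Wildcard code lists and the GEM forward-backward crosswalk.
#
# Wildcard rule: a lowercase 'x' in a pattern matches exactly one character;
# when the 'x' is the final character of the (undotted) pattern it may also
# match nothing, so "I21.xx" covers 4- and 5-character I21 codes and
# "I22.x" covers I22 with or without a fourth character.

#' Compile a wildcard code pattern to a regular expression
#'
#' @param pattern Pattern string, possibly dotted, with lowercase `x`
#'   wildcards (e.g. `"410.x1"`, `"I21.xx"`).
#' @return A full-anchor regular expression matching normalized codes.
#' @keywords internal
pattern_regex <- function(pattern) {
  p <- gsub(".", "", trimws(pattern), fixed = TRUE)
  if (nchar(p) == 0) stop("empty code pattern")
  chars <- strsplit(p, "")[[1]]
  n <- length(chars)
  rx <- vapply(seq_len(n), function(i) {
    ch <- chars[i]
    if (ch == "x") {
      if (i == n) ".?" else "."
    } else {
      ch <- toupper(ch)
      if (grepl("[A-Z0-9]", ch)) ch else stop("invalid pattern character: ", ch)
    }
  }, character(1))
  paste0("^", paste(rx, collapse = ""), "$")
}

#' Construct a code list
#'
#' A code list names a phenotyping algorithm: a set of wildcard diagnosis
#' code patterns, each tied to an ICD-CM version.
#'
#' @param name Short name for the list.
#' @param patterns Data frame with columns `pattern`, `version` and
#'   optionally `description`.
#' @param provenance Free-text notes on where the list comes from.
#' @return Object of class `code_list`.
#' @export
code_list <- function(name, patterns, provenance = "") {
  patterns <- tibble::as_tibble(patterns)
  stopifnot(all(c("pattern", "version") %in% names(patterns)))
  if (nrow(patterns) == 0) stop("code_list: empty pattern set")
  if (!all(patterns$version %in% icd_versions())) {
    stop("code_list: version must be one of ", paste(icd_versions(), collapse = ", "))
  }
  if (!"description" %in% names(patterns)) patterns$description <- ""
  patterns$regex <- vapply(patterns$pattern, pattern_regex, character(1))
  structure(
    list(name = name, patterns = patterns, provenance = provenance),
    class = "code_list"
  )
}

#' @export
print.code_list <- function(x, ...) {
  cat("<code_list>", x$name, "\n")
  print(x$patterns[c("pattern", "version", "description")])
  invisible(x)
}

#' The packaged AMI code list
#'
#' Four pattern families identify acute myocardial infarction: ICD-9-CM
#' 410.x0 (episode of care unspecified) and 410.x1 (initial episode of
#' care), and ICD-10-CM I21.xx (acute myocardial infarction) and I22.x
#' (subsequent STEMI/NSTEMI). Codes for subsequent episodes of care
#' (410.x2), old myocardial infarction, angina and chronic ischemic heart
#' disease are deliberately absent.
#'
#' @param path Optional path to an alternative code-list CSV
#'   (columns `name`, `version`, `pattern`, `description`).
#' @return A [code_list()].
#' @export
ami_code_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ami_codelist.csv", package = "amiclaims",
                        mustWork = TRUE)
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  code_list(df$name[1], df[c("pattern", "version", "description")],
            provenance = paste0("loaded from ", path))
}

#' Expand a wildcard pattern against a code universe
#'
#' @param pattern A single pattern string (dotted or undotted).
#' @param universe Character vector of normalized codes.
#' @return The subset of `universe` matched by `pattern`, sorted.
#' @examples
#' expand_pattern("410.x1", c("41001", "41071", "41072", "I214"))
#' @export
expand_pattern <- function(pattern, universe) {
  if (length(universe) == 0) return(character(0))
  sort(unique(universe[grepl(pattern_regex(pattern), universe)]))
}

#' Does a code match a code list?
#'
#' Vectorized over `code`/`version`. A code matches when any pattern of the
#' same ICD-CM version matches it; one matching code on a claim is what the
#' cohort engine treats as a positive identification.
#'
#' @param code Normalized code(s).
#' @param version `"icd9cm"` or `"icd10cm"`, recycled against `code`.
#' @param codelist A [code_list()].
#' @return Logical vector.
#' @export
code_matches <- function(code, version, codelist) {
  stopifnot(inherits(codelist, "code_list"))
  n <- max(length(code), length(version))
  code <- rep_len(code, n)
  version <- rep_len(version, n)
  out <- logical(n)
  for (v in unique(version)) {
    rx <- codelist$patterns$regex[codelist$patterns$version == v]
    if (length(rx) == 0) next
    sel <- version == v
    out[sel] <- grepl(paste(rx, collapse = "|"), code[sel])
  }
  out
}

gem_directions <- function() c("icd9_to_icd10", "icd10_to_icd9")

#' Parse a General Equivalence Mappings flat file
#'
#' GEM files are whitespace-separated text: source code, target code, and a
#' five-digit flag string read positionally as approximate / no-map /
#' combination / scenario / choice-list. No-map entries carry a placeholder
#' target and never contribute to crosswalk sets.
#'
#' @param path Path to a GEM flat file.
#' @param direction `"icd9_to_icd10"` or `"icd10_to_icd9"`.
#' @return Object of class `gem_table`: `direction` plus an `entries` tibble.
#' @export
parse_gem <- function(path, direction = c("icd9_to_icd10", "icd10_to_icd9")) {
  direction <- match.arg(direction)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    entries <- tibble::tibble(
      source = character(), target = character(), approximate = integer(),
      no_map = integer(), combination = integer(), scenario = integer(),
      choice_list = integer()
    )
    return(structure(list(direction = direction, entries = entries),
                     class = "gem_table"))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 3)
  if (length(bad)) {
    stop("parse_gem: expected 'source target flags' on line ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  m <- do.call(rbind, parts)
  flags <- m[, 3]
  bad <- which(!grepl("^[0-9]{5}$", flags))
  if (length(bad)) {
    stop("parse_gem: malformed 5-digit flag string on line ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  dig <- function(i) as.integer(substr(flags, i, i))
  entries <- tibble::tibble(
    source = toupper(m[, 1]),
    target = toupper(m[, 2]),
    approximate = dig(1),
    no_map = dig(2),
    combination = dig(3),
    scenario = dig(4),
    choice_list = dig(5)
  )
  structure(list(direction = direction, entries = entries), class = "gem_table")
}

#' @export
print.gem_table <- function(x, ...) {
  cat("<gem_table>", x$direction, "-", nrow(x$entries), "entries\n")
  invisible(x)
}

gem_targets <- function(codes, gem) {
  e <- gem$entries
  sort(unique(e$target[e$source %in% codes & e$no_map == 0L]))
}

gem_flags_for <- function(codes, gem) {
  e <- gem$entries[gem$entries$source %in% codes, , drop = FALSE]
  e <- dplyr::arrange(e, .data$source, .data$target)
  e$direction <- rep(gem$direction, nrow(e))
  e
}

#' Forward-backward crosswalk through GEM tables
#'
#' Translates a seed set of codes to the other ICD-CM version (forward
#' mapping) and the result back again (backward mapping) to surface codes
#' without one-to-one mappings and related codes a seed list may have
#' missed. One pass is the published procedure; `iterations > 1` feeds
#' newly discovered source-version codes back through the forward step until
#' the requested number of passes (or a fixed point) is reached. No-map
#' entries contribute nothing to the sets but appear in `flags_per_code`
#' for review.
#'
#' @param seed Character vector of normalized source-version codes.
#' @param forward,backward [parse_gem()] tables with opposite directions;
#'   `forward` maps the seed's version to the other version.
#' @param iterations Number of forward-backward passes (>= 1).
#' @return Object of class `mapping_report` with elements `seed_codes`,
#'   `forward_set`, `backward_set`, `newly_discovered` (backward set minus
#'   seed) and `flags_per_code` (the GEM entries traversed, with provenance).
#' @export
forward_backward <- function(seed, forward, backward, iterations = 1L) {
  stopifnot(inherits(forward, "gem_table"), inherits(backward, "gem_table"))
  if (forward$direction == backward$direction) {
    stop("forward_backward: forward and backward tables must have opposite directions")
  }
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop("forward_backward: iterations must be a positive integer")
  }
  seed <- sort(unique(toupper(seed)))
  current <- seed
  fwd_all <- character(0)
  bwd_all <- character(0)
  for (i in seq_len(iterations)) {
    fwd <- gem_targets(current, forward)
    bwd <- gem_targets(fwd, backward)
    fwd_all <- sort(union(fwd_all, fwd))
    bwd_all <- sort(union(bwd_all, bwd))
    new <- setdiff(bwd, current)
    if (length(new) == 0 && i < iterations) break  # fixed point
    current <- sort(union(current, new))
  }
  flags <- dplyr::bind_rows(
    gem_flags_for(current, forward),
    gem_flags_for(fwd_all, backward)
  )
  structure(
    list(
      seed_codes = seed,
      forward_set = fwd_all,
      backward_set = bwd_all,
      newly_discovered = setdiff(bwd_all, seed),
      flags_per_code = flags
    ),
    class = "mapping_report"
  )
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("<mapping_report>\n")
  cat("  seed:            ", length(x$seed_codes), "codes\n")
  cat("  forward set:     ", length(x$forward_set), "codes\n")
  cat("  backward set:    ", length(x$backward_set), "codes\n")
  cat("  newly discovered:", length(x$newly_discovered), "codes",
      if (length(x$newly_discovered)) paste0("(", paste(x$newly_discovered, collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}

#' Write a mapping report to CSV + JSON
#'
#' @param report A [forward_backward()] report.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_mapping_report <- function(report, dir) {
  stopifnot(inherits(report, "mapping_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$flags_per_code, file.path(dir, "mapping_flags.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    report[c("seed_codes", "forward_set", "backward_set", "newly_discovered")],
    file.path(dir, "mapping_report.json"),
    pretty = TRUE
  )
  invisible(dir)
}
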
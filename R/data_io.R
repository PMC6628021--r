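# Reading, validating and writing encounter-level records, and linking
# prescriptions to the diagnosis registered in the same consultation.

ENCOUNTER_COLUMNS <- c("site_id", "encounter_id", "date", "age_years",
                       "sex", "icpc", "atc")

split_codes <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

#' Read encounter-level records from delimited text
#'
#' Expects one row per consultation with columns `site_id`, `encounter_id`,
#' `date` (ISO-8601), `age_years`, `sex` (`F`/`M`/`U`), `icpc`
#' (semicolon-separated ICPC-2 diagnosis codes, empty = diagnosis missing)
#' and `atc` (semicolon-separated ATC prescription codes, empty = none).
#' Rows that fail validation are excluded and recorded, field by field, in
#' the issue table attached to the result; nothing is silently coerced.
#' Only consultations at the cooperative itself should be supplied: home
#' visits are not special-cased and must be filtered out by the caller.
#'
#' @param path Path to a comma- or tab-delimited text file with a header.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A tibble with columns `site_id`, `encounter_id`, `date` (Date),
#'   `age_years` (numeric), `sex`, and list-columns `diagnoses` and
#'   `prescriptions` (character vectors, possibly empty). Attributes:
#'   `issues` (tibble of excluded rows: `row`, `field`, `value`, `reason`)
#'   and `n_input` (rows read before validation).
#' @seealso [validation_report()], [write_encounters()]
#' @export
read_encounters <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("File not found: %s", path), call. = FALSE)
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  missing_cols <- setdiff(ENCOUNTER_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("Missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  n_input <- nrow(df)
  issues <- list()
  note <- function(row, field, value, reason) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      row = row, field = field,
      value = ifelse(is.na(value), "NA", as.character(value)),
      reason = reason)
  }

  keep <- rep(TRUE, n_input)
  date <- as.Date(rep(NA, n_input))
  age <- rep(NA_real_, n_input)
  diagnoses <- vector("list", n_input)
  prescriptions <- vector("list", n_input)

  for (i in seq_len(n_input)) {
    r <- df[i, ]
    ok <- TRUE
    d <- suppressWarnings(as.Date(r$date, format = "%Y-%m-%d"))
    if (is.na(d)) { note(i, "date", r$date, "unparseable ISO-8601 date"); ok <- FALSE }
    a <- suppressWarnings(as.numeric(r$age_years))
    if (is.na(a) || a < 0 || a > 120) {
      note(i, "age_years", r$age_years, "age not a number in [0, 120]")
      ok <- FALSE
    }
    if (is.na(r$sex) || !r$sex %in% c("F", "M", "U")) {
      note(i, "sex", r$sex, "sex not one of F/M/U"); ok <- FALSE
    }
    dx <- split_codes(r$icpc)
    bad_dx <- dx[!icpc_is_valid(dx)]
    if (length(bad_dx)) {
      note(i, "icpc", paste(bad_dx, collapse = ";"), "invalid ICPC-2 code")
      ok <- FALSE
    }
    rx <- split_codes(r$atc)
    bad_rx <- rx[!atc_is_valid(rx)]
    if (length(bad_rx)) {
      note(i, "atc", paste(bad_rx, collapse = ";"), "invalid ATC code")
      ok <- FALSE
    }
    if (is.na(r$site_id) || !nzchar(r$site_id)) {
      note(i, "site_id", r$site_id, "empty site_id"); ok <- FALSE
    }
    if (is.na(r$encounter_id) || !nzchar(r$encounter_id)) {
      note(i, "encounter_id", r$encounter_id, "empty encounter_id"); ok <- FALSE
    }
    keep[i] <- ok
    if (ok) {
      date[i] <- d; age[i] <- a
      diagnoses[[i]] <- dx; prescriptions[[i]] <- rx
    }
  }

  out <- tibble::tibble(
    site_id = df$site_id, encounter_id = df$encounter_id,
    date = date, age_years = age, sex = df$sex,
    diagnoses = diagnoses, prescriptions = prescriptions)[keep, ]

  dup <- duplicated(paste(out$site_id, out$encounter_id, sep = "\r"))
  if (any(dup)) {
    for (i in which(dup)) {
      note(which(keep)[i], "encounter_id", out$encounter_id[i],
           "duplicate encounter_id within site")
    }
    out <- out[!dup, ]
  }

  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(row = integer(), field = character(),
                   value = character(), reason = character())
  attr(out, "issues") <- issues
  attr(out, "n_input") <- n_input
  out
}

#' Validation report for a set of encounter records
#'
#' @param records Output of [read_encounters()].
#' @return A list: `n_input`, `n_valid`, `n_excluded`, `issues` (tibble),
#'   `reasons` (named counts of exclusion reasons).
#' @export
validation_report <- function(records) {
  issues <- attr(records, "issues") %||%
    tibble::tibble(row = integer(), field = character(),
                   value = character(), reason = character())
  n_input <- attr(records, "n_input") %||% nrow(records)
  list(
    n_input = n_input,
    n_valid = nrow(records),
    n_excluded = n_input - nrow(records),
    issues = issues,
    reasons = as.list(table(issues$reason))
  )
}

#' Write encounter records to delimited text
#'
#' Inverse of [read_encounters()]: list-columns are collapsed to
#' semicolon-separated code strings, dates to ISO-8601.
#'
#' @param records Encounter tibble as returned by [read_encounters()] or
#'   [generate_encounters()].
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_encounters <- function(records, path, delim = ",") {
  flat <- tibble::tibble(
    site_id = records$site_id,
    encounter_id = records$encounter_id,
    date = format(records$date, "%Y-%m-%d"),
    age_years = records$age_years,
    sex = records$sex,
    icpc = vapply(records$diagnoses, paste, character(1), collapse = ";"),
    atc = vapply(records$prescriptions, paste, character(1), collapse = ";"))
  readr::write_delim(flat, path, delim = delim, na = "")
  invisible(path)
}

#' Link each prescription to the diagnosis of its consultation
#'
#' Produces one row per prescription, carrying the diagnosis registered in
#' the same consultation. When a consultation lists several diagnoses the
#' prescription is linked to the first-listed one and flagged
#' (`multi_diagnosis`), which preserves the identity "number of links =
#' number of prescriptions" that the descriptive tables rely on; set
#' `to_all_diagnoses = TRUE` for a sensitivity variant that duplicates the
#' link to every diagnosis. Consultations without any diagnosis yield links
#' with `icpc = NA` (diagnosis missing).
#'
#' @param records Validated encounter tibble.
#' @param to_all_diagnoses Duplicate each prescription across all diagnoses
#'   of its consultation instead of linking to the first (default `FALSE`).
#' @return A tibble with one row per prescription (x diagnosis when
#'   `to_all_diagnoses`): `site_id`, `encounter_id`, `date`, `age_years`,
#'   `sex`, `atc`, `icpc` (`NA` = missing) and `multi_diagnosis`.
#' @export
link_prescriptions <- function(records, to_all_diagnoses = FALSE) {
  n_dx <- lengths(records$diagnoses)
  base <- tibble::tibble(
    site_id = records$site_id,
    encounter_id = records$encounter_id,
    date = records$date,
    age_years = records$age_years,
    sex = records$sex,
    multi_diagnosis = n_dx > 1L,
    atc = records$prescriptions)
  if (to_all_diagnoses) {
    base$icpc <- lapply(records$diagnoses, function(d) {
      if (length(d)) unique(d) else NA_character_
    })
    out <- tidyr::unnest(base, "atc")
    out <- tidyr::unnest(out, "icpc")
  } else {
    base$icpc <- vapply(records$diagnoses, function(d) {
      if (length(d)) d[[1]] else NA_character_
    }, character(1))
    out <- tidyr::unnest(base, "atc")
  }
  dplyr::relocate(out, "atc", "icpc", .after = "sex")
}

#' Antibiotic prescription links
#'
#' Restricts a link table to antibacterials for systemic use (ATC J01),
#' the single source of truth for antibiotic-prescription counts used by
#' the indicator and coverage modules.
#'
#' @param links Output of [link_prescriptions()].
#' @return The subset of rows whose `atc` falls under J01.
#' @export
antibiotic_links <- function(links) {
  links[is_antibiotic(links$atc), , drop = FALSE]
}

#' Write a machine-readable validation or analysis report as JSON
#'
#' @param x A report list (e.g. from [validation_report()] or
#'   [build_report()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  if (inherits(x$issues, "data.frame")) x$issues <- as.data.frame(x$issues)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
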
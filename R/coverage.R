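# Antibiotic prescribing by indication and chapter, and the DU90%-style
# indication-coverage appraisal.

MISSING_KEY <- "MISSING"

# Full ranking of antibiotic links by linked diagnosis, one row per
# distinct diagnosis plus a MISSING row; no collapsing. Sorted by count
# descending, ties by ICPC code ascending, MISSING ordered by its count
# like any diagnosis.
rank_all <- function(ab) {
  key <- ifelse(is.na(ab$icpc), MISSING_KEY, ab$icpc)
  total <- nrow(ab)
  counts <- dplyr::count(tibble::tibble(icpc = key), .data$icpc,
                         name = "n_prescriptions")
  counts <- counts[order(-counts$n_prescriptions, counts$icpc), ]
  counts$share <- 100 * counts$n_prescriptions / total
  counts
}

#' Rank indications by number of linked antibiotic prescriptions
#'
#' One row per diagnosis whose share of all antibiotic prescriptions is at
#' or above `threshold` percent, a `MISSING` row for prescriptions without
#' a diagnosis, and (when anything falls below the threshold) an `OTHER`
#' row aggregating the rest. Rows are ordered by count descending (ties by
#' ICPC code), with `OTHER` last; `cumulative_share` accumulates in that
#' order. Counts conserve the total number of antibiotic links.
#'
#' @param links Prescription links from [link_prescriptions()]
#'   (non-antibiotic rows are ignored).
#' @param threshold Minimum share in percent for a diagnosis to keep its
#'   own row (default 3; 0 disables grouping).
#' @param apqi_set Codes flagged in the `in_apqi_set` column
#'   (default [apqi_codes()]`("apqi7")`).
#' @return A tibble: `icpc` (code, `"MISSING"` or `"OTHER"`),
#'   `n_prescriptions`, `share`, `cumulative_share`, `in_apqi_set`,
#'   `n_diagnoses` (diagnoses aggregated in the row, 1 for named rows).
#' @export
rank_indications <- function(links, threshold = 3,
                             apqi_set = apqi_codes("apqi7")) {
  ab <- antibiotic_links(links)
  if (!nrow(ab)) {
    return(tibble::tibble(icpc = character(), n_prescriptions = integer(),
                          share = numeric(), cumulative_share = numeric(),
                          in_apqi_set = logical(), n_diagnoses = integer()))
  }
  counts <- rank_all(ab)
  named <- counts$share >= threshold | counts$icpc == MISSING_KEY
  out <- counts[named, ]
  out$n_diagnoses <- 1L
  if (any(!named)) {
    rest <- counts[!named, ]
    out <- dplyr::bind_rows(out, tibble::tibble(
      icpc = "OTHER",
      n_prescriptions = sum(rest$n_prescriptions),
      share = sum(rest$share),
      n_diagnoses = nrow(rest)))
  }
  out$cumulative_share <- cumsum(out$share)
  out$in_apqi_set <- out$icpc %in% apqi_set
  out[, c("icpc", "n_prescriptions", "share", "cumulative_share",
          "in_apqi_set", "n_diagnoses")]
}

#' Antibiotic prescriptions by ICPC-2 chapter
#'
#' Groups antibiotic links by the chapter of the linked diagnosis, keeping
#' prescriptions without a diagnosis as a separate `MISSING` row. Chapters
#' whose share falls below `collapse_below` percent are aggregated into an
#' `OTHER` row (set it to 0 to keep every chapter). Counts sum to the
#' total number of antibiotic links.
#'
#' @param links Prescription links from [link_prescriptions()].
#' @param collapse_below Share in percent under which chapters are grouped
#'   (default 5).
#' @return A tibble: `chapter`, `n_prescriptions`, `share`, ordered by
#'   count descending with `MISSING` in rank order and `OTHER` last.
#' @export
chapter_table <- function(links, collapse_below = 5) {
  ab <- antibiotic_links(links)
  if (!nrow(ab)) {
    return(tibble::tibble(chapter = character(), n_prescriptions = integer(),
                          share = numeric()))
  }
  chap <- ifelse(is.na(ab$icpc), MISSING_KEY, substr(ab$icpc, 1, 1))
  total <- nrow(ab)
  counts <- dplyr::count(tibble::tibble(chapter = chap), .data$chapter,
                         name = "n_prescriptions")
  counts <- counts[order(-counts$n_prescriptions, counts$chapter), ]
  counts$share <- 100 * counts$n_prescriptions / total
  keep <- counts$share >= collapse_below | counts$chapter == MISSING_KEY
  out <- counts[keep, ]
  if (any(!keep)) {
    rest <- counts[!keep, ]
    out <- dplyr::bind_rows(out, tibble::tibble(
      chapter = "OTHER",
      n_prescriptions = sum(rest$n_prescriptions),
      share = sum(rest$share)))
  }
  out
}

#' Indication coverage of antibiotic prescribing (DU90%-style appraisal)
#'
#' Measures how much of all antibiotic prescribing a set of indications
#' describes: the count and share of antibiotic prescriptions whose linked
#' diagnosis belongs to `set` (the denominator includes prescriptions with
#' a missing diagnosis), together with a drug-utilization-90% adaptation:
#' the minimal number of top-ranked diagnoses whose cumulative share
#' reaches 90% of all antibiotic prescriptions (`NA` when even all
#' observed diagnoses stay below 90%, e.g. because of missing-diagnosis
#' mass). Also reports the share linked to symptom/complaint rubrics and
#' the chapter breakdown.
#'
#' @param links Prescription links from [link_prescriptions()].
#' @param set Character vector of ICPC-2 codes (default the classic
#'   seven-indication APQI set); may include `"MISSING"` to count
#'   missing-diagnosis prescriptions as covered. Syntactically invalid
#'   codes are dropped with a warning.
#' @return An object of class `apqi_coverage`: a list with
#'   `total_prescriptions`, `covered_count`, `covered_share`,
#'   `n_diagnoses_for_90pct`, `symptom_count`, `symptom_share`,
#'   `missing_count`, `missing_share`, `set`, `chapter_table`, `ranking`
#'   (full, ungrouped).
#' @export
coverage_of_set <- function(links, set = apqi_codes("apqi7")) {
  keep_missing <- MISSING_KEY %in% set
  codes <- setdiff(set, MISSING_KEY)
  bad <- codes[!icpc_is_valid(codes)]
  if (length(bad)) {
    warning(sprintf("Ignoring invalid ICPC-2 code(s) in set: %s",
                    paste(bad, collapse = ", ")), call. = FALSE)
    codes <- setdiff(codes, bad)
  }
  ab <- antibiotic_links(links)
  total <- nrow(ab)
  covered <- sum(!is.na(ab$icpc) & ab$icpc %in% codes) +
    if (keep_missing) sum(is.na(ab$icpc)) else 0L
  n_missing <- sum(is.na(ab$icpc))
  linked_dx <- ab$icpc[!is.na(ab$icpc)]
  n_symptom <- if (length(linked_dx)) sum(is_symptom_code(linked_dx)) else 0L
  ranking <- if (total) rank_all(ab) else
    tibble::tibble(icpc = character(), n_prescriptions = integer(),
                   share = numeric())
  dx_rank <- ranking[ranking$icpc != MISSING_KEY, ]
  cum <- cumsum(dx_rank$share)
  n90 <- if (length(cum) && max(cum) >= 90) which(cum >= 90)[1] else NA_integer_
  pct <- function(n) if (total) 100 * n / total else 0
  structure(list(
    total_prescriptions = total,
    covered_count = covered,
    covered_share = pct(covered),
    n_diagnoses_for_90pct = n90,
    symptom_count = n_symptom,
    symptom_share = pct(n_symptom),
    missing_count = n_missing,
    missing_share = pct(n_missing),
    set = set,
    chapter_table = chapter_table(links),
    ranking = ranking
  ), class = "apqi_coverage")
}

#' @export
print.apqi_coverage <- function(x, ...) {
  cat(sprintf(
    "<apqi_coverage> %d antibiotic prescriptions; set {%s} covers %d (%.1f%%)\n",
    x$total_prescriptions, paste(x$set, collapse = ", "),
    x$covered_count, x$covered_share))
  if (is.na(x$n_diagnoses_for_90pct)) {
    cat("  90% of prescriptions is not reached by observed diagnoses\n")
  } else {
    cat(sprintf("  %d top diagnoses needed to cover 90%% of prescriptions\n",
                x$n_diagnoses_for_90pct))
  }
  cat(sprintf("  missing diagnosis: %.1f%%; symptom diagnosis: %.1f%%\n",
              x$missing_share, x$symptom_share))
  invisible(x)
}

#' Expand an aggregated prescription count table into link rows
#'
#' Utility for working from published aggregate tables: turns a table of
#' per-diagnosis antibiotic prescription counts into one link row per
#' prescription (a generic J01 code is attached), so the coverage and
#' ranking functions can run on printed counts exactly as on record-level
#' data.
#'
#' @param counts A data frame with columns `icpc` (ICPC-2 code or `NA` for
#'   missing diagnosis) and `n_prescriptions`.
#' @param atc ATC code attached to each expanded row (default amoxicillin,
#'   `"J01CA04"`).
#' @return A link tibble compatible with [coverage_of_set()] etc.
#' @export
counts_to_links <- function(counts, atc = "J01CA04") {
  stopifnot(all(c("icpc", "n_prescriptions") %in% names(counts)))
  ok <- is.na(counts$icpc) | icpc_is_valid(counts$icpc)
  if (!all(ok)) {
    stop(sprintf("Invalid ICPC-2 code(s) in counts: %s",
                 paste(unique(counts$icpc[!ok]), collapse = ", ")),
         call. = FALSE)
  }
  n <- counts$n_prescriptions
  stopifnot(all(n >= 0), all(n == as.integer(n)))
  icpc <- rep(counts$icpc, n)
  total <- sum(n)
  tibble::tibble(
    site_id = "pooled",
    encounter_id = sprintf("X%07d", seq_len(total)),
    date = as.Date("2017-07-01"),
    age_years = NA_real_,
    sex = "U",
    atc = atc,
    icpc = icpc,
    multi_diagnosis = FALSE)
}

#' Published out-of-hours reference prescription counts
#'
#' Antibiotic prescription counts by linked diagnosis from a two-year
#' (July 2016 -- June 2018) appraisal of five Belgian out-of-hours general
#' practitioner cooperatives: 26,436 antibiotic prescriptions in 111,600
#' consultations. The per-indication rows (the nine indicator diagnoses
#' and the missing-diagnosis row) are published counts; the breakdown of
#' the published per-chapter remainders into individual sub-3% diagnoses
#' is a synthetic disaggregation (consistent with the published chapter
#' totals and symptom-diagnosis share) shipped so that the full table
#' machinery can be exercised.
#'
#' @return A list: `counts` (tibble `icpc`, `label`, `n_prescriptions`),
#'   `total_prescriptions`, `total_encounters` (111,600).
#' @export
ooh_reference_counts <- function() {
  path <- system.file("extdata", "ooh-counts-synthetic-breakdown.csv",
                      package = "apqi")
  counts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                            col_types = "cci")
  list(counts = counts,
       total_prescriptions = sum(counts$n_prescriptions),
       total_encounters = 111600L)
}
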
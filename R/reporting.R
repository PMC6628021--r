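# Benchmark feedback reports: indicator values vs acceptable ranges and an
# optional external reference table, plus the coverage appraisal.

#' Read a reference value table
#'
#' A reference table supplies earlier or external indicator values to
#' benchmark against (for instance a previous appraisal period). Expected
#' CSV columns: `icpc`, `a_ref`, `b_ref`, `c_ref` (percent, may be empty)
#' and `source` (free-text label).
#'
#' @param path Path to a CSV file.
#' @return A tibble with those columns.
#' @export
read_reference_values <- function(path) {
  ref <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           icpc = readr::col_character(),
                           a_ref = readr::col_double(),
                           b_ref = readr::col_double(),
                           c_ref = readr::col_double(),
                           source = readr::col_character()))
  vals <- unlist(ref[, c("a_ref", "b_ref", "c_ref")])
  if (any(!is.na(vals) & (vals < 0 | vals > 100))) {
    stop("Reference percentages must lie in [0, 100]", call. = FALSE)
  }
  ref
}

#' Assemble a benchmark feedback report
#'
#' Combines indicator results and the coverage appraisal into one
#' structured report: per indication the pooled a/b/c values, between-site
#' brackets, acceptable-range classification and, when a reference table
#' is given, the delta against the reference; plus the chapter table, the
#' ranked indication table and the coverage statement. The structure is
#' the single source of truth: the markdown rendering prints exactly the
#' numbers it contains.
#'
#' @param results Output of [compute_indicators()] with `by_site = TRUE`.
#' @param coverage An `apqi_coverage` object from [coverage_of_set()].
#' @param reference Optional reference tibble from
#'   [read_reference_values()]; rows whose `icpc` is not among the results
#'   are dropped with a warning.
#' @return An object of class `apqi_report` (a nested list, JSON-ready).
#' @export
build_report <- function(results, coverage, reference = NULL) {
  stopifnot(inherits(coverage, "apqi_coverage"))
  if (!is.null(reference)) {
    unknown <- setdiff(reference$icpc, results$icpc)
    if (length(unknown)) {
      warning(sprintf("Reference rows for unknown indication(s) omitted: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
      reference <- reference[reference$icpc %in% results$icpc, ]
    }
  }
  measure <- function(row, m) {
    val <- row[[m]]
    out <- list(
      value = val,
      bracket = c(row[[paste0(m, "_min")]], row[[paste0(m, "_max")]]),
      classification = row[[paste0("class_", m)]])
    if (!is.null(reference)) {
      i <- match(row$icpc, reference$icpc)
      refv <- if (is.na(i)) NA_real_ else reference[[paste0(m, "_ref")]][i]
      if (!is.na(refv)) {
        out$reference <- refv
        out$delta <- if (is.na(val)) NA_real_ else round(val - refv, 1)
        out$reference_source <- reference$source[i]
      }
    }
    out
  }
  indicators <- lapply(seq_len(nrow(results)), function(i) {
    row <- results[i, ]
    list(icpc = row$icpc,
         label = row$label,
         n_eligible = row$n_eligible,
         n_ab = row$n_ab,
         prescribed = measure(row, "a"),
         recommended = measure(row, "b"),
         quinolones = measure(row, "c"))
  })
  names(indicators) <- results$icpc
  structure(list(
    indicators = indicators,
    coverage = list(
      total_prescriptions = coverage$total_prescriptions,
      set = coverage$set,
      covered_count = coverage$covered_count,
      covered_share = round(coverage$covered_share, 1),
      n_diagnoses_for_90pct = coverage$n_diagnoses_for_90pct,
      missing_share = round(coverage$missing_share, 1),
      symptom_share = round(coverage$symptom_share, 1)),
    chapter_table = as.data.frame(coverage$chapter_table),
    ranking = as.data.frame(coverage$ranking)
  ), class = "apqi_report")
}

fmt_measure <- function(m, unit = "%") {
  if (is.na(m$value)) return("undefined")
  s <- sprintf("%.0f%s [%.0f-%.0f] %s", m$value, unit,
               m$bracket[1], m$bracket[2], m$classification)
  if (!is.null(m$reference)) {
    s <- sprintf("%s (ref %s: %.0f%s, delta %+.1f)", s,
                 m$reference_source, m$reference, unit, m$delta)
  }
  s
}

#' Render a report as markdown text
#'
#' Plain-text classification markers (WITHIN / ABOVE / BELOW) keep the
#' rendering diff-able; every number equals the corresponding field of the
#' report object.
#'
#' @param report An `apqi_report` from [build_report()].
#' @return Character vector of markdown lines.
#' @export
render_report_markdown <- function(report) {
  lines <- c("# Antibiotic prescribing quality feedback", "")
  for (ind in report$indicators) {
    lines <- c(lines,
      sprintf("## %s -- %s", ind$icpc, ind$label),
      sprintf("- eligible encounters: %d; antibiotic-treated: %d",
              ind$n_eligible, ind$n_ab),
      sprintf("- prescribed an antibiotic: %s", fmt_measure(ind$prescribed)),
      sprintf("- recommended antibiotic: %s", fmt_measure(ind$recommended)),
      sprintf("- quinolones: %s", fmt_measure(ind$quinolones)),
      "")
  }
  cov <- report$coverage
  cov90 <- if (is.na(cov$n_diagnoses_for_90pct))
    "90% coverage is not reached by the observed diagnoses" else
    sprintf("%d top diagnoses cover 90%% of prescriptions",
            cov$n_diagnoses_for_90pct)
  lines <- c(lines,
    "## Indication coverage",
    sprintf("- %d antibiotic prescriptions in total", cov$total_prescriptions),
    sprintf("- indication set {%s} covers %d (%.1f%%)",
            paste(cov$set, collapse = ", "), cov$covered_count,
            cov$covered_share),
    sprintf("- %s", cov90),
    sprintf("- missing diagnosis: %.1f%%; symptom diagnosis: %.1f%%",
            cov$missing_share, cov$symptom_share),
    "")
  lines
}

#' Write a report to JSON (and optionally markdown)
#'
#' @param report An `apqi_report`.
#' @param json_path Output path for the JSON serialization.
#' @param md_path Optional output path for the markdown rendering.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, md_path = NULL) {
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  if (!is.null(md_path)) {
    writeLines(render_report_markdown(report), md_path)
  }
  invisible(json_path)
}
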
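# The APQI indicator engine: eligibility, the a/b/c triple, acceptable-range
# classification and per-site variation.

#' Eligibility of encounters for an indicator
#'
#' An encounter is eligible when the indicator's ICPC-2 code appears among
#' its diagnoses, the patient's age lies within the indicator's age window,
#' and the sex matches any restriction. Under the default
#' `age_boundary = "inclusive"` convention "older than N years" counts
#' completed age >= N; `"strict"` requires age > N. Upper bounds
#' ("between 18 and 75") are always inclusive.
#'
#' @param records Encounter tibble ([read_encounters()] /
#'   [generate_encounters()]).
#' @param definition One indicator definition ([get_definition()]).
#' @param config An `apqi_config` object (for the boundary option).
#' @return Logical vector, one element per encounter.
#' @export
is_eligible <- function(records, definition, config = apqi_config()) {
  target <- definition$icpc
  has_dx <- vapply(records$diagnoses, function(d) target %in% d, logical(1))
  age <- records$age_years
  min_age <- definition$min_age
  max_age <- definition$max_age
  lower_ok <- if (is.na(min_age)) TRUE else if
    (config$options$age_boundary == "inclusive") age >= min_age else age > min_age
  upper_ok <- if (is.na(max_age)) TRUE else age <= max_age
  sex_ok <- if (is.na(definition$sex)) TRUE else records$sex == definition$sex
  has_dx & lower_ok & upper_ok & sex_ok
}

#' Classify an indicator value against its acceptable range
#'
#' Ranges are closed intervals in percent; a value equal to a stated bound
#' is WITHIN. `NA` (undefined value, zero denominator) passes through as
#' UNDEFINED. Classification always uses the unrounded value.
#'
#' @param value Numeric vector of percentages (or `NA`).
#' @param range Length-2 numeric `c(lo, hi)` within `[0, 100]`.
#' @return Character vector in `{"WITHIN","ABOVE","BELOW","UNDEFINED"}`.
#' @examples
#' classify_value(77, c(0, 20))   # ABOVE
#' classify_value(1, c(0, 5))     # WITHIN
#' @export
classify_value <- function(value, range) {
  stopifnot(length(range) == 2L, !any(is.na(range)), range[1] <= range[2])
  out <- rep("WITHIN", length(value))
  out[!is.na(value) & value < range[1]] <- "BELOW"
  out[!is.na(value) & value > range[2]] <- "ABOVE"
  out[is.na(value)] <- "UNDEFINED"
  out
}

encounter_flags <- function(records, definition) {
  rx <- records$prescriptions
  has_ab <- vapply(rx, function(p) any(startsWith(p, "J01")), logical(1))
  rec_set <- definition$recommended[[1]]
  has_rec <- vapply(rx, function(p) {
    any(vapply(p, function(x) any(startsWith(x, rec_set)), logical(1)))
  }, logical(1))
  has_qui <- vapply(rx, function(p) any(startsWith(p, "J01M")), logical(1))
  tibble::tibble(has_ab = has_ab,
                 has_rec = has_rec & has_ab,
                 has_qui = has_qui & has_ab)
}

#' Compute one disease-specific indicator
#'
#' For the eligible encounters of one indication, computes
#' `a = 100 * n_ab / n_eligible` (percentage prescribed >= 1 antibiotic),
#' `b = 100 * n_recommended / n_ab` and `c = 100 * n_quinolone / n_ab`
#' (percentages of the antibiotic-treated receiving a guideline-recommended
#' antibiotic, respectively a quinolone; with
#' `options$bc_denominator = "eligible"` the denominators of b and c become
#' `n_eligible`). Percentages are classified against the configured
#' acceptable ranges before rounding and then stored to one decimal; zero
#' denominators give `NA` values classified UNDEFINED. Encounter counts
#' stand in for patient counts (no stable patient identifier crosses
#' sites).
#'
#' @param records Encounter tibble.
#' @param indication A single ICPC-2 code configured in `config`.
#' @param config An `apqi_config` object.
#' @return A one-row tibble: `icpc`, `label`, `n_eligible`, `n_ab`,
#'   `n_recommended`, `n_quinolone`, `a`, `b`, `c`, `class_a`, `class_b`,
#'   `class_c`.
#' @export
compute_indicator <- function(records, indication, config = apqi_config()) {
  def <- get_definition(config, indication)
  elig <- records[is_eligible(records, def, config), , drop = FALSE]
  n_eligible <- nrow(elig)
  fl <- encounter_flags(elig, def)
  n_ab <- sum(fl$has_ab)
  n_rec <- sum(fl$has_rec)
  n_qui <- sum(fl$has_qui)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  a_raw <- pct(n_ab, n_eligible)
  bc_den <- if (config$options$bc_denominator == "treated") n_ab else n_eligible
  b_raw <- pct(n_rec, bc_den)
  c_raw <- pct(n_qui, bc_den)
  tibble::tibble(
    icpc = def$icpc, label = def$label,
    n_eligible = n_eligible, n_ab = n_ab,
    n_recommended = n_rec, n_quinolone = n_qui,
    a = round(a_raw, 1), b = round(b_raw, 1), c = round(c_raw, 1),
    class_a = classify_value(a_raw, def$range_a[[1]]),
    class_b = classify_value(b_raw, def$range_b[[1]]),
    class_c = classify_value(c_raw, def$range_c[[1]]))
}

#' Per-site indicator values and variation brackets
#'
#' Computes the indicator separately for every site (general practitioner
#' cooperative) and summarizes the between-site variation as the min--max
#' bracket over sites with a defined value. Sites without eligible
#' encounters are excluded from the brackets and listed.
#'
#' @inheritParams compute_indicator
#' @return A list: `per_site` (tibble with one row per site), `brackets`
#'   (tibble `measure`, `min`, `max`), `excluded_sites` (character).
#' @export
per_site_ranges <- function(records, indication, config = apqi_config()) {
  sites <- sort(unique(records$site_id))
  per_site <- purrr::map_dfr(sites, function(s) {
    res <- compute_indicator(records[records$site_id == s, , drop = FALSE],
                             indication, config)
    dplyr::bind_cols(tibble::tibble(site_id = s), res)
  })
  bracket <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) c(NA_real_, NA_real_) else range(v)
  }
  brackets <- tibble::tibble(
    measure = c("a", "b", "c"),
    min = c(bracket(per_site$a)[1], bracket(per_site$b)[1], bracket(per_site$c)[1]),
    max = c(bracket(per_site$a)[2], bracket(per_site$b)[2], bracket(per_site$c)[2]))
  list(per_site = per_site,
       brackets = brackets,
       excluded_sites = per_site$site_id[per_site$n_eligible == 0L])
}

#' Compute all configured indicators, with per-site variation
#'
#' The workhorse for a full quality appraisal: one row per configured
#' indication with pooled counts, the a/b/c percentages, acceptable-range
#' classifications and (with `by_site = TRUE`) the min--max brackets over
#' sites plus a nested per-site table.
#'
#' @param records Encounter tibble.
#' @param config An `apqi_config` object.
#' @param by_site Also compute per-site values and brackets
#'   (default `TRUE`).
#' @return A tibble, one row per indicator. With `by_site` it gains
#'   `a_min`, `a_max`, `b_min`, `b_max`, `c_min`, `c_max` and a `per_site`
#'   list-column.
#' @export
compute_indicators <- function(records, config = apqi_config(),
                               by_site = TRUE) {
  out <- purrr::map_dfr(config$indicators$icpc, function(code) {
    res <- compute_indicator(records, code, config)
    if (by_site) {
      ps <- per_site_ranges(records, code, config)
      res$a_min <- ps$brackets$min[1]; res$a_max <- ps$brackets$max[1]
      res$b_min <- ps$brackets$min[2]; res$b_max <- ps$brackets$max[2]
      res$c_min <- ps$brackets$min[3]; res$c_max <- ps$brackets$max[3]
      res$per_site <- list(ps$per_site)
    }
    res
  })
  out
}

#' Format an indicator table for display
#'
#' Renders pooled values to whole percent with the per-site bracket and
#' acceptable-range classification, mirroring the usual APQI presentation
#' (e.g. `"77 [65-87] ABOVE"`).
#'
#' @param results Output of [compute_indicators()] with `by_site = TRUE`.
#' @return A tibble of display strings, one row per indicator.
#' @export
format_indicator_table <- function(results) {
  fmt <- function(v, lo, hi, cls) {
    ifelse(is.na(v), "-",
           sprintf("%.0f [%.0f-%.0f] %s", v, lo, hi, cls))
  }
  tibble::tibble(
    icpc = results$icpc,
    label = results$label,
    prescribed = fmt(results$a, results$a_min, results$a_max, results$class_a),
    recommended = fmt(results$b, results$b_min, results$b_max, results$class_b),
    quinolones = fmt(results$c, results$c_min, results$c_max, results$class_c))
}
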
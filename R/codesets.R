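# ICPC-2 diagnosis codes, ATC drug codes, and the configurable
# indication -> recommended-antibiotic mapping.

#' ICPC-2 chapter letters
#'
#' The seventeen chapter letters of the International Classification of
#' Primary Care, 2nd edition (e.g. R respiratory, U urinary, S skin,
#' H ear, D digestive).
#'
#' @format Character vector of length 17.
#' @export
ICPC_CHAPTERS <- c("A", "B", "D", "F", "H", "K", "L", "N", "P",
                   "R", "S", "T", "U", "W", "X", "Y", "Z")

#' Validate ICPC-2 codes
#'
#' An ICPC-2 code is a chapter letter followed by a two-digit rubric
#' 01--99 (e.g. `"R74"`). `NA` is not valid.
#'
#' @param code Character vector of candidate codes.
#' @return Logical vector, `TRUE` where the code is syntactically valid.
#' @examples
#' icpc_is_valid(c("R74", "u71", "R00", "R7"))
#' @export
icpc_is_valid <- function(code) {
  !is.na(code) &
    grepl("^[A-Z][0-9]{2}$", code) &
    substr(code, 1, 1) %in% ICPC_CHAPTERS &
    substr(code, 2, 3) != "00"
}

assert_icpc <- function(code, arg = "code") {
  bad <- unique(code[!icpc_is_valid(code)])
  if (length(bad)) {
    stop(sprintf("Invalid ICPC-2 %s: %s", arg,
                 paste(ifelse(is.na(bad), "NA", bad), collapse = ", ")),
         call. = FALSE)
  }
  invisible(code)
}

#' ICPC-2 chapter of a diagnosis code
#'
#' @param code Character vector of valid ICPC-2 codes.
#' @return The chapter letter (first character) of each code.
#' @examples
#' icpc_chapter(c("R74", "U71", "D82"))
#' @export
icpc_chapter <- function(code) {
  assert_icpc(code)
  substr(code, 1, 1)
}

#' Rubric number of an ICPC-2 code
#'
#' @inheritParams icpc_chapter
#' @return Integer rubric 1--99.
#' @export
icpc_rubric <- function(code) {
  assert_icpc(code)
  as.integer(substr(code, 2, 3))
}

#' Is an ICPC-2 code a symptom / complaint diagnosis?
#'
#' ICPC-2 component-1 rubrics (01--29) code symptoms and complaints such
#' as fever (A03) or cough (R05) rather than disease entities. Indicator
#' denominators never use symptom codes; the coverage module reports the
#' share of antibiotic prescriptions linked to them descriptively.
#'
#' @inheritParams icpc_chapter
#' @return Logical vector.
#' @examples
#' is_symptom_code(c("R05", "R74", "A03"))
#' @export
is_symptom_code <- function(code) {
  icpc_rubric(code) <= 29L
}

#' Validate ATC codes
#'
#' Valid Anatomical Therapeutic Chemical codes have 1, 3, 4, 5 or 7
#' characters following the standard level structure (anatomical letter,
#' two-digit therapeutic subgroup, pharmacological letter, chemical letter,
#' two-digit substance), e.g. `"J"`, `"J01"`, `"J01C"`, `"J01CA"`,
#' `"J01CA04"`.
#'
#' @param code Character vector of candidate codes.
#' @return Logical vector.
#' @export
atc_is_valid <- function(code) {
  !is.na(code) &
    grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", code)
}

assert_atc <- function(code, arg = "code") {
  bad <- unique(code[!atc_is_valid(code)])
  if (length(bad)) {
    stop(sprintf("Invalid ATC %s: %s", arg,
                 paste(ifelse(is.na(bad), "NA", bad), collapse = ", ")),
         call. = FALSE)
  }
  invisible(code)
}

#' Is an ATC code an antibacterial for systemic use?
#'
#' `TRUE` iff the code falls under ATC group J01.
#'
#' @param code Character vector of valid ATC codes.
#' @return Logical vector.
#' @examples
#' is_antibiotic(c("J01CA04", "N02BE01", "J01"))
#' @export
is_antibiotic <- function(code) {
  assert_atc(code)
  startsWith(code, "J01")
}

#' Is an ATC code a quinolone antibacterial?
#'
#' `TRUE` iff the code falls under ATC group J01M (quinolone
#' antibacterials, including fluoroquinolones).
#'
#' @inheritParams is_antibiotic
#' @return Logical vector.
#' @examples
#' is_quinolone(c("J01MA02", "J01CA04"))
#' @export
is_quinolone <- function(code) {
  assert_atc(code)
  startsWith(code, "J01M")
}

# Prefix-set membership: a code matches when it starts with any member of
# `set`, so sets can be written at any ATC level ("J01CE" covers J01CE02).
atc_matches <- function(code, set) {
  assert_atc(code)
  assert_atc(set, arg = "set member")
  vapply(code, function(x) any(startsWith(x, set)), logical(1),
         USE.NAMES = FALSE)
}

#' Is a prescription the guideline-recommended antibiotic for an indication?
#'
#' Membership is by ATC prefix against the indication's configured
#' recommended set, so configurations can name a whole chemical subgroup
#' (`"J01CE"`, narrow-spectrum penicillins) or a single substance
#' (`"J01CA04"`, amoxicillin).
#'
#' @param code Character vector of valid ATC codes.
#' @param indication A single ICPC-2 indication code present in `config`.
#' @param config An indicator configuration from [apqi_config()].
#' @return Logical vector parallel to `code`.
#' @examples
#' cfg <- apqi_config()
#' is_recommended("J01CE02", "R76", cfg)
#' is_recommended("J01MA02", "R76", cfg)
#' @export
is_recommended <- function(code, indication, config) {
  def <- get_definition(config, indication)
  atc_matches(code, def$recommended[[1]])
}

#' Load an indicator configuration
#'
#' Reads a YAML configuration describing each indicator: ICPC-2 code,
#' label, age window (years, inclusive), sex restriction, recommended
#' antibiotic set (ATC prefixes) and acceptable ranges for the three
#' indicator values a/b/c in percent. With `path = NULL` the default
#' configuration shipped with the package is loaded; its recommended sets
#' follow Belgian first-line guidance (see the package vignette) and every
#' entry can be overridden by supplying an edited file.
#'
#' @param path Path to a YAML file, or `NULL` for the package default.
#' @return An object of class `apqi_config`: a list with
#'   `$indicators` (a tibble, one row per indication, with list-columns
#'   `recommended`, `range_a`, `range_b`, `range_c`) and `$options`
#'   (`age_boundary`: `"inclusive"` treats "older than N" as age >= N,
#'   `"strict"` as age > N; `bc_denominator`: `"treated"` or `"eligible"`).
#' @export
apqi_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "apqi-indicators.yaml", package = "apqi")
  }
  if (!file.exists(path)) {
    stop(sprintf("Configuration file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$indicators) || !length(raw$indicators)) {
    stop("Configuration contains no indicators", call. = FALSE)
  }
  parse_range <- function(x, name, icpc) {
    r <- c(x[[1]] %||% 0, x[[2]] %||% 100)
    r <- as.numeric(r)
    if (any(is.na(r)) || r[1] > r[2] || r[1] < 0 || r[2] > 100) {
      stop(sprintf("Indicator %s: %s must be an interval within [0, 100]",
                   icpc, name), call. = FALSE)
    }
    r
  }
  defs <- purrr::map_dfr(raw$indicators, function(d) {
    icpc <- d$icpc %||% stop("Indicator entry without an 'icpc' field",
                             call. = FALSE)
    assert_icpc(icpc, arg = "indicator code")
    rec <- unlist(d$recommended)
    if (!length(rec)) {
      stop(sprintf("Indicator %s: recommended set is empty", icpc),
           call. = FALSE)
    }
    assert_atc(rec, arg = sprintf("recommended set for %s", icpc))
    if (!all(startsWith(rec, "J01"))) {
      stop(sprintf("Indicator %s: recommended set must fall under J01", icpc),
           call. = FALSE)
    }
    min_age <- if (is.null(d$min_age)) NA_real_ else as.numeric(d$min_age)
    max_age <- if (is.null(d$max_age)) NA_real_ else as.numeric(d$max_age)
    if (!is.na(min_age) && !is.na(max_age) && min_age > max_age) {
      stop(sprintf("Indicator %s: min_age exceeds max_age", icpc),
           call. = FALSE)
    }
    sex <- d$sex %||% NA_character_
    if (!is.na(sex) && !sex %in% c("F", "M")) {
      stop(sprintf("Indicator %s: sex restriction must be 'F', 'M' or null",
                   icpc), call. = FALSE)
    }
    tibble::tibble(
      icpc = icpc,
      label = d$label %||% icpc,
      min_age = min_age,
      max_age = max_age,
      sex = sex,
      recommended = list(rec),
      range_a = list(parse_range(d$range_a, "range_a", icpc)),
      range_b = list(parse_range(d$range_b, "range_b", icpc)),
      range_c = list(parse_range(d$range_c, "range_c", icpc)),
      proposed = isTRUE(d$proposed)
    )
  })
  if (anyDuplicated(defs$icpc)) {
    stop("Duplicate indicator codes in configuration", call. = FALSE)
  }
  opts <- raw$options %||% list()
  age_boundary <- opts$age_boundary %||% "inclusive"
  if (!age_boundary %in% c("inclusive", "strict")) {
    stop("options$age_boundary must be 'inclusive' or 'strict'",
         call. = FALSE)
  }
  bc_denominator <- opts$bc_denominator %||% "treated"
  if (!bc_denominator %in% c("treated", "eligible")) {
    stop("options$bc_denominator must be 'treated' or 'eligible'",
         call. = FALSE)
  }
  structure(
    list(indicators = defs,
         options = list(age_boundary = age_boundary,
                        bc_denominator = bc_denominator)),
    class = "apqi_config"
  )
}

#' @export
print.apqi_config <- function(x, ...) {
  cat(sprintf("<apqi_config> %d indicators (age boundary: %s, b/c denominator: %s)\n",
              nrow(x$indicators), x$options$age_boundary,
              x$options$bc_denominator))
  for (i in seq_len(nrow(x$indicators))) {
    d <- x$indicators[i, ]
    cat(sprintf("  %s %-38s recommended: %s\n", d$icpc, d$label,
                paste(d$recommended[[1]], collapse = ", ")))
  }
  invisible(x)
}

#' Retrieve one indicator definition from a configuration
#'
#' @param config An `apqi_config` object.
#' @param indication A single ICPC-2 code.
#' @return A one-row tibble (the matching row of `config$indicators`).
#' @export
get_definition <- function(config, indication) {
  stopifnot(inherits(config, "apqi_config"), length(indication) == 1L)
  i <- match(indication, config$indicators$icpc)
  if (is.na(i)) {
    stop(sprintf("Indication '%s' is not configured. Available: %s",
                 indication,
                 paste(config$indicators$icpc, collapse = ", ")),
         call. = FALSE)
  }
  config$indicators[i, ]
}

#' ICPC-2 codes of the APQI indication sets
#'
#' `"apqi7"` is the classic ESAC seven-indication set (acute bronchitis
#' R78, upper respiratory tract infection R74, cystitis U71, tonsillitis
#' R76, sinusitis R75, otitis media H71, pneumonia R81). `"apqi9"` adds
#' the two disease entities proposed for out-of-hours care: erysipelas
#' (S76) and teeth/gum disease (D82).
#'
#' @param set `"apqi7"` or `"apqi9"`.
#' @return Character vector of ICPC-2 codes.
#' @export
apqi_codes <- function(set = c("apqi7", "apqi9")) {
  set <- match.arg(set)
  seven <- c("R78", "R74", "U71", "R76", "R75", "H71", "R81")
  if (set == "apqi7") seven else c(seven, "S76", "D82")
}
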
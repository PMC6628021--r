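# Seed-reproducible synthetic out-of-hours encounter generator, with a
# default scenario calibrated to published Belgian OOH prescribing values.

AGE_STRATA <- rbind(child = c(0, 18), adult = c(18, 65), elderly = c(65, 90))

#' Default synthetic scenario
#'
#' A fully parameterized generator scenario emulating two years of Belgian
#' out-of-hours primary-care encounters across five general practitioner
#' cooperatives. Calibration, all derived from published aggregates:
#' \itemize{
#'   \item Per-indication prescribing probability `p_prescribe`,
#'     recommended fraction `r_recommended` and quinolone fraction
#'     `q_quinolone` equal the published pooled indicator values a/b/c (as
#'     probabilities) for the nine indicator diagnoses.
#'   \item Encounter shares of the indicator diagnoses are back-computed as
#'     (published prescription count) / (p * 111,600 encounters), so the
#'     generated prescription mix reproduces the published indication mix.
#'   \item 6% of encounters carry no diagnosis; ~4% carry a
#'     symptom/complaint rubric; the remaining mass is spread over common
#'     non-indicator infections so chapter shares resemble the published
#'     chapter table. Overall ~23.7% of encounters yield an antibiotic.
#'   \item Five sites weighted by the published catchment populations,
#'     with multiplicative odds adjustments on the prescribing probability
#'     (0.6--1.6) spanning roughly the published between-site brackets.
#' }
#' Age is drawn from per-diagnosis child/adult/elderly mixtures that
#' deliberately cross every eligibility boundary, and sexes violating a
#' restriction (e.g. male cystitis) occur, so eligibility filters are
#' exercised on both sides.
#'
#' @param config Indicator configuration supplying the representative
#'   recommended ATC code per indication.
#' @return An object of class `apqi_scenario` (a named list; see
#'   [generate_encounters()]).
#' @export
default_scenario <- function(config = apqi_config()) {
  ref <- ooh_reference_counts()
  n_total <- ref$total_encounters
  counts <- setNames(ref$counts$n_prescriptions,
                     ifelse(is.na(ref$counts$icpc), "MISSING", ref$counts$icpc))

  # published pooled indicator values as probabilities
  tab <- tibble::tibble(
    icpc = c("H71", "R74", "R75", "R76", "R78", "R81", "U71", "S76", "D82"),
    p = c(.64, .30, .51, .77, .69, .80, .91, .80, .67),
    r = c(.74, .03, .40, .06, .42, .46, .69, .44, .42),
    q = c(.01, .02, .07, .01, .11, .15, .25, .01, .01))
  tab$share <- counts[tab$icpc] / (tab$p * n_total)
  rep_atc <- vapply(tab$icpc, function(code) {
    first <- get_definition(config, code)$recommended[[1]][1]
    # concrete level-5 representative for prefix-level sets
    switch(first, J01CE = "J01CE02", J01XE = "J01XE01", J01CF = "J01CF05",
           first)
  }, character(1))
  # broad-spectrum alternatives chosen so they never prefix-match the
  # recommended set of the same indication
  oth_atc <- ifelse(rep_atc %in% c("J01CE02"), "J01CA04", "J01CR02")

  ind <- tibble::tibble(
    icpc = tab$icpc, share = tab$share, p_prescribe = tab$p,
    r_recommended = tab$r, q_quinolone = tab$q,
    rec_atc = rep_atc, oth_atc = oth_atc)

  miss_share <- 0.06
  miss <- tibble::tibble(
    icpc = NA_character_, share = miss_share,
    p_prescribe = counts[["MISSING"]] / (miss_share * n_total),
    r_recommended = 0, q_quinolone = 0.05,
    rec_atc = NA_character_, oth_atc = "J01CA04")

  sym <- tibble::tibble(
    icpc = c("R05", "A03", "H01"),
    share = c(0.028, 0.008, 0.004),
    r_recommended = 0, q_quinolone = 0.02,
    rec_atc = NA_character_, oth_atc = "J01CA04")
  sym$p_prescribe <- counts[sym$icpc] / (sym$share * n_total)

  oth_codes <- c("R77", "U70", "S84", "S97", "H70", "D83", "A78",
                 "F70", "X84", "L70", "Y75", "B70", "W71", "N71", "T70")
  p_other <- 0.095
  oth <- tibble::tibble(
    icpc = oth_codes,
    share = counts[oth_codes] / (p_other * n_total),
    p_prescribe = p_other,
    r_recommended = 0,
    q_quinolone = ifelse(oth_codes == "U70", 0.25, 0.02),
    rec_atc = NA_character_, oth_atc = "J01CR02")

  dx <- dplyr::bind_rows(ind, miss, sym, oth)
  # filler: well-person contacts, almost never prescribed antibiotics
  dx <- dplyr::bind_rows(dx, tibble::tibble(
    icpc = "A97", share = 1 - sum(dx$share), p_prescribe = 0.01,
    r_recommended = 0, q_quinolone = 0,
    rec_atc = NA_character_, oth_atc = "J01CA04"))

  age_w <- matrix(c(0.30, 0.50, 0.20), nrow(dx), 3, byrow = TRUE,
                  dimnames = list(NULL, c("child", "adult", "elderly")))
  rownames(age_w) <- NULL
  set_w <- function(code, w) {
    age_w[which(dx$icpc %in% code), ] <<- matrix(w, length(which(dx$icpc %in% code)), 3, byrow = TRUE)
  }
  set_w("H71", c(0.70, 0.25, 0.05))
  set_w(c("R74", "R76", "R05", "A03", "H01"), c(0.40, 0.45, 0.15))
  set_w("R75", c(0.10, 0.75, 0.15))
  set_w(c("R78", "S76"), c(0.10, 0.55, 0.35))
  set_w("R81", c(0.10, 0.50, 0.40))
  set_w(c("U71", "D82", "X84"), c(0.05, 0.75, 0.20))
  dx$age_child <- age_w[, 1]; dx$age_adult <- age_w[, 2]
  dx$age_elderly <- age_w[, 3]
  dx$p_female <- 0.5
  dx$p_female[dx$icpc %in% c("U71", "X84", "W71")] <- 0.85
  dx$p_female[dx$icpc %in% "Y75"] <- 0

  structure(list(
    name = "ooh-flanders-default",
    n_encounters = 20000L,
    seed = 20160701L,
    sites = tibble::tibble(
      site_id = c("GPC-AE", "GPC-AN", "GPC-AC", "GPC-TI", "GPC-ZK"),
      weight = c(148366, 141110, 185358, 84430, 251833) / 811097,
      odds_multiplier = c(0.6, 0.8, 1.0, 1.25, 1.6)),
    diagnoses = dx,
    quinolone_atc = "J01MA02",
    p_extra_rx = 0.30,       # non-antibiotic co-prescription (paracetamol)
    p_second_diagnosis = 0.02,
    p_sex_unknown = 0.01,
    start_date = as.Date("2016-07-01"),
    n_days = 731L
  ), class = "apqi_scenario")
}

#' Validate a synthetic scenario
#'
#' Checks the probability structure of a scenario before any sampling:
#' site weights and diagnosis shares on the simplex, probabilities in
#' `[0, 1]`, `r + q <= 1` per diagnosis, ATC/ICPC codes syntactically
#' valid.
#'
#' @param scenario An `apqi_scenario` list.
#' @return `scenario`, invisibly; errors on the first violation.
#' @export
validate_scenario <- function(scenario) {
  s <- scenario
  err <- function(msg) stop(sprintf("Invalid scenario: %s", msg), call. = FALSE)
  if (!all(c("sites", "diagnoses", "seed", "n_encounters") %in% names(s)))
    err("missing required fields")
  if (abs(sum(s$sites$weight) - 1) > 1e-9 || any(s$sites$weight < 0))
    err("site weights must be a probability simplex")
  if (any(s$sites$odds_multiplier <= 0))
    err("site odds multipliers must be positive")
  d <- s$diagnoses
  if (abs(sum(d$share) - 1) > 1e-9 || any(d$share < 0))
    err("diagnosis shares must be a probability simplex")
  if (any(d$p_prescribe < 0 | d$p_prescribe > 1))
    err("prescribing probabilities must lie in [0, 1]")
  if (any(d$r_recommended < 0 | d$q_quinolone < 0 |
          d$r_recommended + d$q_quinolone > 1))
    err("per-diagnosis r + q must lie in [0, 1]")
  aw <- as.matrix(d[, c("age_child", "age_adult", "age_elderly")])
  if (any(abs(rowSums(aw) - 1) > 1e-9) || any(aw < 0))
    err("age-stratum weights must be probability simplexes")
  if (any(d$p_female < 0 | d$p_female > 1))
    err("p_female must lie in [0, 1]")
  dx <- d$icpc[!is.na(d$icpc)]
  if (!all(icpc_is_valid(dx))) err("invalid ICPC-2 code in diagnosis mix")
  atc <- c(d$rec_atc, d$oth_atc, s$quinolone_atc)
  atc <- atc[!is.na(atc)]
  if (!all(atc_is_valid(atc))) err("invalid ATC code in drug mapping")
  for (p in c("p_extra_rx", "p_second_diagnosis", "p_sex_unknown")) {
    if (s[[p]] < 0 || s[[p]] > 1) err(sprintf("%s must lie in [0, 1]", p))
  }
  invisible(scenario)
}

#' Generate synthetic encounter records
#'
#' Draws `n` encounters from a scenario: site, diagnosis (or none), age,
#' sex, then an antibiotic prescription with the diagnosis's prescribing
#' probability adjusted by the site's odds multiplier, and finally the
#' drug class (recommended / quinolone / other broad-spectrum) mapped to a
#' representative ATC code. A fraction of encounters additionally receive
#' a non-antibiotic prescription or a secondary symptom diagnosis.
#'
#' Each encounter consumes a fixed block of nine uniform draws from a
#' single Mersenne-Twister stream seeded with `seed`, so output is
#' byte-identical across runs and generating fewer encounters yields a
#' prefix of the longer run.
#'
#' @param scenario An `apqi_scenario`, e.g. [default_scenario()].
#' @param n Number of encounters (default `scenario$n_encounters`).
#' @param seed Integer seed (default `scenario$seed`).
#' @return An encounter tibble with the same schema as
#'   [read_encounters()].
#' @export
generate_encounters <- function(scenario, n = scenario$n_encounters,
                                seed = scenario$seed) {
  validate_scenario(scenario)
  stopifnot(length(n) == 1L, n >= 0, n == as.integer(n))
  empty <- tibble::tibble(
    site_id = character(), encounter_id = character(),
    date = as.Date(character()), age_years = numeric(), sex = character(),
    diagnoses = list(), prescriptions = list())
  if (n == 0) return(empty)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  u <- matrix(runif(n * 9L), ncol = 9L, byrow = TRUE)

  sites <- scenario$sites
  d <- scenario$diagnoses
  site_idx <- findInterval(u[, 1], cumsum(sites$weight),
                           rightmost.closed = TRUE) + 1L
  site_idx[site_idx > nrow(sites)] <- nrow(sites)
  dx_idx <- findInterval(u[, 2], cumsum(d$share), rightmost.closed = TRUE) + 1L
  dx_idx[dx_idx > nrow(d)] <- nrow(d)

  aw <- as.matrix(d[, c("age_child", "age_adult", "age_elderly")])
  cw1 <- aw[dx_idx, 1]
  cw2 <- cw1 + aw[dx_idx, 2]
  stratum <- 1L + (u[, 3] > cw1) + (u[, 3] > cw2)
  lo <- AGE_STRATA[stratum, 1]
  hi <- AGE_STRATA[stratum, 2]
  age <- round(lo + u[, 4] * (hi - lo), 1)

  pu <- scenario$p_sex_unknown
  pf <- d$p_female[dx_idx]
  v <- (u[, 5] - pu) / (1 - pu)
  sex <- ifelse(u[, 5] < pu, "U", ifelse(v < pf, "F", "M"))

  p <- d$p_prescribe[dx_idx]
  m <- sites$odds_multiplier[site_idx]
  p_adj <- plogis(qlogis(p) + log(m))
  p_adj[p == 0] <- 0
  p_adj[p == 1] <- 1
  has_rx <- u[, 6] < p_adj

  r <- d$r_recommended[dx_idx]
  q <- d$q_quinolone[dx_idx]
  atc1 <- ifelse(u[, 7] < r, d$rec_atc[dx_idx],
                 ifelse(u[, 7] < r + q, scenario$quinolone_atc,
                        d$oth_atc[dx_idx]))
  atc1[!has_rx] <- NA_character_

  extra <- u[, 8] < scenario$p_extra_rx
  dx1 <- d$icpc[dx_idx]
  second <- u[, 9] < scenario$p_second_diagnosis & !is.na(dx1) & dx1 != "R05"

  diagnoses <- vector("list", n)
  prescriptions <- vector("list", n)
  for (i in seq_len(n)) {
    diagnoses[[i]] <- if (is.na(dx1[i])) character(0)
      else if (second[i]) c(dx1[i], "R05") else dx1[i]
    rx <- character(0)
    if (has_rx[i]) rx <- atc1[i]
    if (extra[i]) rx <- c(rx, "N02BE01")
    prescriptions[[i]] <- rx
  }

  idx <- seq_len(n)
  tibble::tibble(
    site_id = sites$site_id[site_idx],
    encounter_id = sprintf("%s-%07d", sites$site_id[site_idx], idx),
    date = scenario$start_date + ((idx - 1L) %% scenario$n_days),
    age_years = age,
    sex = sex,
    diagnoses = diagnoses,
    prescriptions = prescriptions)
}

#' Single-indication scenario for parameter-recovery checks
#'
#' A degenerate variant of a scenario in which every encounter carries one
#' given diagnosis and all sites prescribe identically (odds multipliers
#' 1), optionally overriding the prescribing probability and drug-class
#' fractions. Used to verify that the indicator engine recovers the
#' generator's parameters.
#'
#' @param icpc Diagnosis code (must be present in the base scenario mix).
#' @param base Scenario to specialize (default [default_scenario()]).
#' @param p,r,q Optional overrides for the prescribing probability,
#'   recommended fraction and quinolone fraction.
#' @return An `apqi_scenario`.
#' @export
single_indication_scenario <- function(icpc, base = default_scenario(),
                                       p = NULL, r = NULL, q = NULL) {
  i <- match(icpc, base$diagnoses$icpc)
  if (is.na(i)) stop(sprintf("'%s' not in scenario mix", icpc), call. = FALSE)
  s <- base
  s$diagnoses <- s$diagnoses[i, ]
  s$diagnoses$share <- 1
  if (!is.null(p)) s$diagnoses$p_prescribe <- p
  if (!is.null(r)) s$diagnoses$r_recommended <- r
  if (!is.null(q)) s$diagnoses$q_quinolone <- q
  s$sites$odds_multiplier <- rep(1, nrow(s$sites))
  s$name <- sprintf("single-%s", icpc)
  s
}
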
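# Shared fixtures and an independent brute-force oracle for the
# indicator computation.

# Build an encounter tibble from parallel vectors; diagnoses/prescriptions
# given as semicolon-separated strings ("" = none).
make_encounters <- function(site = "S1", id = NULL, age = 30, sex = "F",
                            dx = "", rx = "", date = as.Date("2017-01-15")) {
  n <- max(length(site), length(id %||% character()), length(age),
           length(sex), length(dx), length(rx))
  split1 <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";")[[1]]
  }
  tibble::tibble(
    site_id = rep_len(site, n),
    encounter_id = if (is.null(id)) sprintf("E%03d", seq_len(n))
      else rep_len(id, n),
    date = rep_len(date, n),
    age_years = rep_len(age, n),
    sex = rep_len(sex, n),
    diagnoses = lapply(rep_len(dx, n), split1),
    prescriptions = lapply(rep_len(rx, n), split1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent oracle: nested loops and substr() prefix checks only, no
# shared code with the package implementation.
brute_force_indicator <- function(records, def,
                                  bc_treated = TRUE, inclusive = TRUE) {
  n_elig <- 0L; n_ab <- 0L; n_rec <- 0L; n_qui <- 0L
  for (i in seq_len(nrow(records))) {
    age <- records$age_years[i]
    sex <- records$sex[i]
    found <- FALSE
    for (dcode in records$diagnoses[[i]]) if (dcode == def$icpc) found <- TRUE
    if (!found) next
    if (!is.na(def$min_age)) {
      if (inclusive) { if (age < def$min_age) next }
      else if (age <= def$min_age) next
    }
    if (!is.na(def$max_age)) if (age > def$max_age) next
    if (!is.na(def$sex)) if (sex != def$sex) next
    n_elig <- n_elig + 1L
    ab <- FALSE; rec <- FALSE; qui <- FALSE
    for (p in records$prescriptions[[i]]) {
      if (substr(p, 1, 3) == "J01") ab <- TRUE
      if (substr(p, 1, 4) == "J01M") qui <- TRUE
      for (m in def$recommended[[1]]) {
        if (substr(p, 1, nchar(m)) == m) rec <- TRUE
      }
    }
    if (ab) {
      n_ab <- n_ab + 1L
      if (rec) n_rec <- n_rec + 1L
      if (qui) n_qui <- n_qui + 1L
    }
  }
  den_bc <- if (bc_treated) n_ab else n_elig
  list(n_eligible = n_elig, n_ab = n_ab,
       n_recommended = n_rec, n_quinolone = n_qui,
       a = if (n_elig > 0) round(100 * n_ab / n_elig, 1) else NA_real_,
       b = if (den_bc > 0) round(100 * n_rec / den_bc, 1) else NA_real_,
       c = if (den_bc > 0) round(100 * n_qui / den_bc, 1) else NA_real_)
}

# Small random record sets for property tests; independent of the
# package's generator.
random_records <- function(n, seed) {
  set.seed(seed)
  dx_pool <- c("R76", "R78", "U71", "H71", "R74", "D82", "S76", "R05", "A03")
  rx_pool <- c("J01CE02", "J01CA04", "J01MA02", "J01CR02", "J01XE01",
               "N02BE01", "J01CF05")
  make_encounters(
    site = sample(c("S1", "S2", "S3"), n, replace = TRUE),
    id = sprintf("E%04d", seq_len(n)),
    age = round(runif(n, 0, 95), 1),
    sex = sample(c("F", "M", "U"), n, replace = TRUE, prob = c(.48, .48, .04)),
    dx = vapply(seq_len(n), function(i) {
      paste(sample(dx_pool, sample(0:2, 1)), collapse = ";")
    }, character(1)),
    rx = vapply(seq_len(n), function(i) {
      paste(sample(rx_pool, sample(0:2, 1)), collapse = ";")
    }, character(1)))
}
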
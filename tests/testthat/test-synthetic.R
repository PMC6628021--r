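test_that("the default scenario is a valid parameterization", {
  sc <- default_scenario()
  expect_s3_class(sc, "apqi_scenario")
  expect_silent(validate_scenario(sc))
  expect_equal(sum(sc$diagnoses$share), 1, tolerance = 1e-9)
  expect_equal(sum(sc$sites$weight), 1, tolerance = 1e-9)
  expect_true(all(sc$diagnoses$r_recommended + sc$diagnoses$q_quinolone <= 1))
  expect_true(all(apqi_codes("apqi9") %in% sc$diagnoses$icpc))
  # expected overall prescribing rate close to the published 23.7%
  expect_equal(sum(sc$diagnoses$share * sc$diagnoses$p_prescribe),
               0.237, tolerance = 0.005)
})

test_that("invalid scenarios are rejected before sampling", {
  sc <- default_scenario()
  sc$diagnoses$share[1] <- sc$diagnoses$share[1] + 0.5
  expect_error(generate_encounters(sc, 10), "simplex")
  sc2 <- default_scenario()
  sc2$diagnoses$r_recommended[1] <- 0.9
  sc2$diagnoses$q_quinolone[1] <- 0.9
  expect_error(generate_encounters(sc2, 10), "r \\+ q")
  sc3 <- default_scenario()
  sc3$sites$weight <- rev(sc3$sites$weight) * c(1, 1, 1, 1, 2)
  expect_error(generate_encounters(sc3, 10), "simplex")
})

test_that("generation is byte-identical under a fixed seed and prefix-stable", {
  sc <- default_scenario()
  a <- generate_encounters(sc, 500, seed = 11)
  b <- generate_encounters(sc, 500, seed = 11)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_encounters(a, f1); write_encounters(b, f2)
  expect_identical(readLines(f1), readLines(f2))

  # a shorter run is a prefix of a longer one (counter-based draws)
  short <- generate_encounters(sc, 100, seed = 11)
  expect_identical(short, a[1:100, ])

  # different seeds differ
  expect_false(identical(generate_encounters(sc, 500, seed = 12), a))

  # the caller's RNG state is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_encounters(sc, 50, seed = 3))
  expect_identical(runif(1), before)
})

test_that("n = 0 yields an empty, schema-compatible collection", {
  rec <- generate_encounters(default_scenario(), 0)
  expect_identical(nrow(rec), 0L)
  expect_named(rec, c("site_id", "encounter_id", "date", "age_years",
                      "sex", "diagnoses", "prescriptions"))
})

test_that("degenerate probabilities hit their limits exactly", {
  sc <- single_indication_scenario("R76", p = 1, r = 1, q = 0)
  rec <- generate_encounters(sc, 300, seed = 2)
  expect_true(all(vapply(rec$diagnoses, function(d) "R76" %in% d, logical(1))))
  res <- compute_indicator(rec, "R76", apqi_config())
  expect_equal(res$a, 100)
  expect_equal(res$b, 100)
  expect_equal(res$c, 0)

  sc0 <- single_indication_scenario("R76", p = 0)
  rec0 <- generate_encounters(sc0, 300, seed = 2)
  expect_equal(compute_indicator(rec0, "R76", apqi_config())$a, 0)
})

test_that("written and re-read synthetic data give identical indicator results", {
  sc <- default_scenario()
  rec <- generate_encounters(sc, 2000, seed = 31)
  path <- tempfile(fileext = ".csv")
  write_encounters(rec, path)
  rec2 <- read_encounters(path)
  expect_identical(validation_report(rec2)$n_excluded, 0L)
  cfg <- apqi_config()
  expect_equal(compute_indicators(rec2, cfg, by_site = FALSE),
               compute_indicators(rec, cfg, by_site = FALSE))
  expect_identical(nrow(link_prescriptions(rec2)),
                   nrow(link_prescriptions(rec)))
})

test_that("realized diagnosis shares track the scenario mix", {
  sc <- default_scenario()
  mads <- vapply(1:10, function(seed) {
    rec <- generate_encounters(sc, 50000, seed = 1000 + seed)
    first <- vapply(rec$diagnoses,
                    function(d) if (length(d)) d[[1]] else "MISSING",
                    character(1))
    key <- ifelse(is.na(sc$diagnoses$icpc), "MISSING", sc$diagnoses$icpc)
    realized <- as.numeric(table(factor(first, levels = key))) / nrow(rec)
    mean(abs(realized - sc$diagnoses$share)) * 100
  }, numeric(1))
  expect_lt(mean(mads), 0.5)
})

test_that("site weights and heterogeneity are realized in the output", {
  sc <- default_scenario()
  rec <- generate_encounters(sc, 50000, seed = 77)
  realized_w <- as.numeric(table(factor(rec$site_id,
                                        levels = sc$sites$site_id))) / nrow(rec)
  expect_lt(max(abs(realized_w - sc$sites$weight)), 0.01)
  # the low-multiplier site prescribes less than the high-multiplier site
  ps <- per_site_ranges(rec, "R76", apqi_config())$per_site
  lo <- ps$a[ps$site_id == "GPC-AE"]
  hi <- ps$a[ps$site_id == "GPC-ZK"]
  expect_lt(lo, hi)
})
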
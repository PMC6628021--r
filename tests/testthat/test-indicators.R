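cfg <- apqi_config()

test_that("eligibility honours diagnosis, age window and sex restriction", {
  cyst <- get_definition(cfg, "U71")
  expect_true(is_eligible(make_encounters(age = 30, sex = "F", dx = "U71"),
                          cyst, cfg))
  expect_false(is_eligible(make_encounters(age = 30, sex = "M", dx = "U71"),
                           cyst, cfg))
  expect_false(is_eligible(make_encounters(age = 30, sex = "F", dx = "R76"),
                           cyst, cfg))
  bron <- get_definition(cfg, "R78")
  expect_false(is_eligible(make_encounters(age = 80, dx = "R78"), bron, cfg))
  expect_true(is_eligible(make_encounters(age = 75, dx = "R78"), bron, cfg))

  # boundary convention: inclusive counts age == min_age, strict does not
  oti <- get_definition(cfg, "H71")
  two <- make_encounters(age = 2, dx = "H71")
  expect_true(is_eligible(two, oti, cfg))
  strict <- cfg
  strict$options$age_boundary <- "strict"
  expect_false(is_eligible(two, oti, strict))
})

test_that("the indicator triple matches a hand count on a printed fixture", {
  rec <- make_encounters(
    age = c(0.5, 5, 30, 40),
    dx = "R76",
    rx = c("", "J01CE02", "J01CA04", ""))
  res <- compute_indicator(rec, "R76", cfg)
  expect_identical(res$n_eligible, 3L)   # the 6-month-old is below min_age 1
  expect_identical(res$n_ab, 2L)
  expect_identical(res$n_recommended, 1L)
  expect_identical(res$n_quinolone, 0L)
  expect_equal(res$a, 66.7)
  expect_equal(res$b, 50.0)
  expect_equal(res$c, 0.0)
})

test_that("degenerate inputs give undefined values, not errors", {
  res <- compute_indicator(make_encounters(dx = "")[0, ], "R76", cfg)
  expect_identical(res$n_eligible, 0L)
  expect_true(is.na(res$a) && is.na(res$b) && is.na(res$c))
  expect_identical(res$class_a, "UNDEFINED")

  # eligible encounters but none treated: b and c undefined, a defined
  res2 <- compute_indicator(make_encounters(age = 30, dx = "R76", rx = ""),
                            "R76", cfg)
  expect_equal(res2$a, 0)
  expect_identical(res2$class_b, "UNDEFINED")
})

test_that("classification against acceptable ranges uses closed bounds", {
  expect_identical(classify_value(77, c(0, 20)), "ABOVE")
  expect_identical(classify_value(1, c(0, 5)), "WITHIN")
  expect_identical(classify_value(5, c(0, 5)), "WITHIN")
  expect_identical(classify_value(80, c(80, 100)), "WITHIN")
  expect_identical(classify_value(79.9, c(80, 100)), "BELOW")
  expect_identical(classify_value(NA_real_, c(0, 5)), "UNDEFINED")
  vals <- runif(50, 0, 100)
  cls <- classify_value(vals, c(20, 60))
  expect_identical(cls == "WITHIN", vals >= 20 & vals <= 60)
})

test_that("per-site values bracket the pooled value", {
  rec <- dplyr::bind_rows(
    make_encounters(site = "S1", id = sprintf("A%d", 1:4), age = 30,
                    dx = "R76", rx = c("J01CA04", "J01CA04", "", "")),
    make_encounters(site = "S2", id = sprintf("B%d", 1:2), age = 30,
                    dx = "R76", rx = "J01CA04"))
  ps <- per_site_ranges(rec, "R76", cfg)
  expect_equal(ps$per_site$a, c(50, 100))
  expect_equal(ps$brackets$min[1], 50)
  expect_equal(ps$brackets$max[1], 100)
  pooled <- compute_indicator(rec, "R76", cfg)
  expect_true(pooled$a >= 50 && pooled$a <= 100)

  # identical sites give zero-width brackets; a single site equals pooled
  twin <- dplyr::bind_rows(
    make_encounters(site = "S1", id = "A1", age = 30, dx = "R76", rx = "J01CA04"),
    make_encounters(site = "S2", id = "B1", age = 30, dx = "R76", rx = "J01CA04"))
  pt <- per_site_ranges(twin, "R76", cfg)
  expect_equal(pt$brackets$min, pt$brackets$max)

  # sites with no eligible encounters are excluded and listed
  rec2 <- dplyr::bind_rows(rec,
    make_encounters(site = "S3", id = "C1", age = 30, dx = "H71", rx = ""))
  ps2 <- per_site_ranges(rec2, "R76", cfg)
  expect_identical(ps2$excluded_sites, "S3")
  expect_equal(ps2$brackets$min[1], 50)
})

test_that("compute_indicator agrees exactly with the brute-force oracle", {
  for (seed in 1:8) {
    rec <- random_records(sample(5:50, 1), seed = seed)
    for (code in cfg$indicators$icpc) {
      def <- get_definition(cfg, code)
      bf <- brute_force_indicator(rec, def)
      res <- compute_indicator(rec, code, cfg)
      expect_identical(res$n_eligible, bf$n_eligible)
      expect_identical(res$n_ab, bf$n_ab)
      expect_identical(res$n_recommended, bf$n_recommended)
      expect_identical(res$n_quinolone, bf$n_quinolone)
      expect_equal(res$a, bf$a)
      expect_equal(res$b, bf$b)
      expect_equal(res$c, bf$c)
    }
  }
})

test_that("count invariants hold on random record sets", {
  for (seed in 1:5) {
    rec <- random_records(40, seed = 100 + seed)
    res <- compute_indicators(rec, cfg, by_site = FALSE)
    expect_true(all(res$n_recommended <= res$n_ab))
    expect_true(all(res$n_quinolone <= res$n_ab))
    expect_true(all(res$n_ab <= res$n_eligible))
  }
})

test_that("indicator a is monotone under adding treated or untreated eligible encounters", {
  rec <- random_records(30, seed = 9)
  base <- compute_indicator(rec, "R76", cfg)
  plus_treated <- dplyr::bind_rows(
    rec, make_encounters(id = "Z1", age = 20, dx = "R76", rx = "J01CA04"))
  plus_untreated <- dplyr::bind_rows(
    rec, make_encounters(id = "Z2", age = 20, dx = "R76", rx = ""))
  a_t <- compute_indicator(plus_treated, "R76", cfg)$a
  a_u <- compute_indicator(plus_untreated, "R76", cfg)$a
  expect_true(is.na(base$a) || a_t >= base$a)
  expect_true(is.na(base$a) || a_u <= base$a)
})

test_that("the engine recovers generator parameters for all nine indications", {
  for (code in apqi_codes("apqi9")) {
    sc <- single_indication_scenario(code)
    rec <- generate_encounters(sc, n = 50000, seed = 271828)
    res <- compute_indicator(rec, code, cfg)
    d <- sc$diagnoses
    expect_lt(abs(res$a - 100 * d$p_prescribe), 1.5)
    expect_lt(abs(res$b - 100 * d$r_recommended), 1.5)
    expect_lt(abs(res$c - 100 * d$q_quinolone), 1.5)
  }
})

test_that("the unconditional b/c denominator variant divides by eligible encounters", {
  cfg2 <- cfg
  cfg2$options$bc_denominator <- "eligible"
  rec <- make_encounters(age = 30, dx = "R76",
                         rx = c("J01CE02", "", "", ""))
  res <- compute_indicator(rec, "R76", cfg2)
  expect_equal(res$b, 25)   # 1 recommended / 4 eligible
  expect_equal(compute_indicator(rec, "R76", cfg)$b, 100)
})
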
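# Frozen expected values below were hand-evaluated from the published
# coefficients (5-decimal precision, exact arithmetic) independently of the
# implementation.

test_that("derived predictors follow their definitions", {
  r <- test_records(tibble::tibble(
    sex = c("male", "male"), age = 40, po_standard = 30,
    po_high = c(130, 140), hr_standard = c(90, 85), hr_high = c(140, 151)))
  d <- derive_predictors(r)
  expect_equal(d$delta_hr, c(50, 66))
  expect_equal(d$delta_po, c(100, 110))
  expect_equal(d$hr_per_po, c(0.5, 0.6))

  flat <- tibble::tibble(sex = "male", age = 40, po_standard = 30,
                         po_high = 130, hr_standard = 100, hr_high = 100)
  expect_error(derive_predictors(flat), "delta_hr")
})

test_that("sex-specific log-linear equations match hand evaluation", {
  r <- test_records(tibble::tibble(
    sex = c("male", "female"), age = 40, po_standard = 30, po_high = 150,
    hr_standard = 90, hr_high = 150))  # hr_per_po 0.5, delta_po 120
  est <- eb_new_estimate(r)
  expect_equal(est$vo2max_abs[1], exp(1.20469), tolerance = 1e-10)
  expect_equal(est$vo2max_abs[1], 3.3357248, tolerance = 1e-6)
  expect_equal(est$vo2max_abs[2], exp(1.04791), tolerance = 1e-10)
  expect_equal(est$vo2max_abs[2], 2.8516849, tolerance = 1e-6)
  expect_true(all(est$in_valid_range))
  # ln round-trip reproduces the linear predictor
  expect_equal(log(est$vo2max_abs[1]), 1.20469, tolerance = 1e-12)
})

test_that("2012 pooled linear equation matches hand evaluation", {
  r <- test_records(tibble::tibble(
    sex = c("male", "female"), age = 40, po_standard = 30, po_high = 150,
    hr_standard = 90, hr_high = 150))
  est <- eb_2012_estimate(r)
  expect_equal(est$vo2max_abs, c(3.50422, 2.85407), tolerance = 1e-10)
})

test_that("equation signs: estimates move the right way with each predictor", {
  base <- list(sex = "male", age = 40, po_standard = 30, po_high = 150,
               hr_standard = 90, hr_high = 150)
  mk <- function(...) {
    args <- utils::modifyList(base, list(...))
    test_records(tibble::as_tibble(args))
  }
  v0 <- function(rec) eb_new_estimate(rec)$vo2max_abs
  for (sex in c("male", "female")) {
    b <- mk(sex = sex)
    expect_lt(v0(mk(sex = sex, age = 50)), v0(b))             # age down
    expect_lt(v0(mk(sex = sex, hr_high = 160)), v0(b))        # hr_per_po down
    expect_lt(v0(mk(sex = sex, hr_standard = 100,
                    hr_high = 160)), v0(b))                   # hr_std down
    # larger delta_po at fixed hr_per_po: up
    expect_gt(v0(mk(sex = sex, po_high = 190, hr_high = 170)), v0(b))
  }
  # always positive by construction (exp form), even absurd inputs
  extreme <- suppressWarnings(mk(age = 95, hr_standard = 140, hr_high = 200,
                                 po_high = 60))
  expect_gt(v0(extreme), 0)
})

test_that("2012 linear form can go non-positive and is flagged", {
  r <- suppressWarnings(test_records(tibble::tibble(
    sex = "female", age = 80, po_standard = 30, po_high = 80,
    hr_standard = 90, hr_high = 190)))  # hr_per_po = 2.0
  est <- eb_2012_estimate(r)
  expect_lt(est$vo2max_abs, 0)
  expect_false(est$in_valid_range)
  expect_match(est$warnings, "non-positive")
})

test_that("validity gating warns without rejecting", {
  expect_warning(
    r <- test_records(tibble::tibble(
      sex = "male", age = 90, po_standard = 30, po_high = 150,
      hr_standard = 90, hr_high = 150)),
    "age outside 20-86")
  est <- eb_new_estimate(r)
  expect_false(est$in_valid_range)
  expect_match(est$warnings, "age outside")
  # 2012 range is narrower (21-65)
  r2 <- test_records(tibble::tibble(
    sex = "male", age = 70, po_standard = 30, po_high = 150,
    hr_standard = 90, hr_high = 150))
  expect_true(eb_new_estimate(r2)$in_valid_range)
  expect_false(eb_2012_estimate(r2)$in_valid_range)
})

test_that("relative estimates require body mass and scale by it", {
  r <- fixture_records()
  est <- eb_new_estimate(r)
  expect_equal(est$vo2max_rel, est$vo2max_abs * 1000 / r$body_mass)
  r$body_mass <- NA_real_
  expect_true(all(is.na(eb_new_estimate(r)$vo2max_rel)))
})

test_that("prediction half-widths reproduce the published worked examples", {
  expect_equal(round(prediction_halfwidth(0.084, 3.0), 2), 0.49)
  expect_equal(round(prediction_halfwidth(0.092, 3.0), 2), 0.54)
  expect_equal(round(prediction_halfwidth(0.084, 2.0), 2), 0.33)
  expect_equal(round(prediction_halfwidth(0.092, 2.0), 2), 0.36)
  expect_equal(prediction_halfwidth(0.1, 0), 0)
  expect_error(prediction_halfwidth(-0.1, 3), "invalid argument")
  expect_error(prediction_halfwidth(0.1, -3), "invalid argument")
})

test_that("estimate_vo2max dispatches and row-binds all methods", {
  r <- fixture_records()
  all3 <- estimate_vo2max(r, "all")
  expect_setequal(unique(all3$method), c("eb-new", "eb-2012", "astrand"))
  expect_equal(nrow(all3), 3 * nrow(r))
  one <- estimate_vo2max(r, "eb-new")
  expect_equal(one$vo2max_abs, all3$vo2max_abs[all3$method == "eb-new"])
})
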
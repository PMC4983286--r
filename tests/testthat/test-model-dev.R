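# Noise-free generative round trips are the primary check: a cohort built
# exactly from a published equation must give the printed coefficients back.

coef_of <- function(fit, term) {
  fit$coefficients$estimate[fit$coefficients$term == term]
}

test_that("forward selection recovers the published sex equations exactly", {
  for (sex in c("male", "female")) {
    spec <- cohort_spec(n_male = if (sex == "male") 300 else 0,
                        n_female = if (sex == "female") 300 else 0,
                        ln_noise_sd = 0)
    coh <- generate_cohort(spec, seed = 42)
    fit <- suppressWarnings(fit_eb_model(coh, sex))
    published <- eb_coefficients()$eb_new[[sex]]
    expect_setequal(fit$entry_order,
                    c("age", "hr_per_po", "delta_po", "hr_standard"))
    expect_equal(coef_of(fit, "(Intercept)"), unname(published["intercept"]),
                 tolerance = 1e-6)
    for (term in c("age", "hr_per_po", "delta_po", "hr_standard")) {
      expect_equal(coef_of(fit, term), unname(published[term]),
                   tolerance = 1e-6)
    }
    expect_true(all(fit$tolerances > 0.2))
  }
})

test_that("a single qualifying candidate reduces to plain OLS", {
  set.seed(8)
  d <- data.frame(x = runif(60))
  d$y <- 1 + 2 * d$x + rnorm(60, 0, 0.1)
  fs <- forward_select(d, "y", "x")
  ols <- lm(y ~ x, data = d)
  expect_equal(fs$coefficients$estimate, unname(coef(ols)), tolerance = 1e-12)
  expect_equal(fs$entry_order, "x")
})

test_that("p_enter = 1 admits every candidate: full-model OLS", {
  set.seed(10)
  d <- data.frame(a = runif(50), b = runif(50), c = runif(50))
  d$y <- rnorm(50)
  fs <- forward_select(d, "y", c("a", "b", "c"), p_enter = 1, p_remove = 1)
  full <- lm(y ~ a + b + c, data = d)
  expect_setequal(fs$entry_order, c("a", "b", "c"))
  co <- setNames(fs$coefficients$estimate, fs$coefficients$term)
  expect_equal(co[names(coef(full))], coef(full), tolerance = 1e-12)
})

test_that("perfectly collinear candidates raise a degenerate-design error", {
  set.seed(12)
  d <- data.frame(a = runif(40))
  d$b <- 2 * d$a          # exact copy up to scale
  d$y <- d$a + rnorm(40, 0, 0.05)
  expect_error(forward_select(d, "y", c("a", "b"), p_enter = 1, p_remove = 1),
               "degenerate design.*'b'")
})

test_that("null candidates enter at about the nominal rate", {
  set.seed(77)
  entered <- logical(500)
  for (i in 1:500) {
    n <- 60
    d <- data.frame(age = runif(n, 20, 80), noise = rnorm(n))
    d$y <- 3 - 0.01 * d$age + rnorm(n, 0, 0.05)
    fit <- forward_select(d, "y", c("age", "noise"))
    entered[i] <- "noise" %in% fit$entry_order
  }
  rate <- mean(entered)
  # binomial 95% band around p_enter = 0.05 at 500 replicates
  half <- 1.96 * sqrt(0.05 * 0.95 / 500)
  expect_gte(rate, 0.05 - half)
  expect_lte(rate, 0.05 + half)
})

test_that("coefficient error shrinks with sample size under ln-scale noise", {
  published <- eb_coefficients()$eb_new$male
  terms <- c("(Intercept)" = "intercept", age = "age",
             hr_per_po = "hr_per_po", delta_po = "delta_po",
             hr_standard = "hr_standard")
  rmse_at <- function(n) {
    # average over replicate cohorts; a single draw is too noisy for a
    # monotonicity check
    per_seed <- vapply(101:110, function(seed) {
      spec <- cohort_spec(n_male = n, n_female = 0, ln_noise_sd = 0.085)
      fit <- fit_eb_model(generate_cohort(spec, seed = seed), "male")
      err <- vapply(names(terms), function(t) {
        est <- coef_of(fit, t)
        if (length(est) == 0) return(NA_real_)
        est - unname(published[terms[t]])
      }, numeric(1))
      sqrt(mean(err^2, na.rm = TRUE))
    }, numeric(1))
    mean(per_seed)
  }
  r <- vapply(c(100, 400, 1600), rmse_at, numeric(1))
  expect_gt(r[1], r[2])
  expect_gt(r[2], r[3])
})

test_that("sex interactions are detected when sexes follow different equations", {
  spec <- cohort_spec(n_male = 100, n_female = 100, ln_noise_sd = 0.03)
  coh <- generate_cohort(spec, seed = 31)  # exact-model uses both sex equations
  scr <- interaction_screen(coh)
  expect_lt(scr$p_values[["sex:hr_standard"]], 0.05)
  expect_lt(scr$p_values[["sex:hr_per_po"]], 0.05)
  expect_equal(scr$recommendation, "split")
  expect_error(interaction_screen(coh[coh$sex == "male", ]),
               "not applicable")
})

test_that("no interaction is flagged in most null cohorts", {
  set.seed(55)
  pooled <- logical(200)
  male_eq <- eb_coefficients()$eb_new$male
  for (i in 1:200) {
    n <- 120
    d <- tibble::tibble(
      sex = rep(c("male", "female"), each = n / 2),
      age = runif(n, 20, 86),
      hr_per_po = runif(n, 0.25, 1),
      delta_po = runif(n, 60, 220),
      hr_standard = runif(n, 70, 115))
    lp <- male_eq["intercept"] + male_eq["age"] * d$age +
      male_eq["hr_per_po"] * d$hr_per_po +
      male_eq["delta_po"] * d$delta_po +
      male_eq["hr_standard"] * d$hr_standard
    d$measured_vo2max <- exp(lp + rnorm(n, 0, 0.085))
    d$po_standard <- 30
    d$po_high <- 30 + d$delta_po
    d$hr_high <- d$hr_standard + d$hr_per_po * d$delta_po
    pooled[i] <- interaction_screen(d)$recommendation == "pooled"
  }
  # two interaction terms each tested at 0.05: the null pooled rate is about
  # 0.95^2 = 0.9025; allow the binomial 95% band at 200 replicates
  null_rate <- 0.95^2
  half <- 1.96 * sqrt(null_rate * (1 - null_rate) / 200)
  expect_gte(mean(pooled), null_rate - half)
})

test_that("duplicating every record leaves the fitted coefficients unchanged", {
  spec <- cohort_spec(n_male = 80, n_female = 0, ln_noise_sd = 0.085)
  coh <- generate_cohort(spec, seed = 4)
  doubled <- dplyr::bind_rows(coh, coh)
  f1 <- fit_eb_model(coh, "male")
  f2 <- fit_eb_model(doubled, "male")
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("tolerance equals one minus the auxiliary-regression R2", {
  # mutually orthogonal (factorial) design: all tolerances 1
  X <- as.matrix(expand.grid(x1 = c(-1, 1), x2 = c(-1, 1),
                             x3 = c(-1, 1), x4 = c(-1, 1)))
  tc <- tolerance_check(X)
  expect_equal(unname(tc$tolerance), rep(1, 4), tolerance = 1e-12)
  expect_length(tc$flagged, 0)
  # duplicated predictor: tolerance collapses to 0 and is flagged
  set.seed(2)
  Y <- cbind(a = rnorm(30), b = rnorm(30))
  Y <- cbind(Y, c = Y[, "a"])
  tc2 <- tolerance_check(Y)
  expect_lt(tc2$tolerance[["a"]], 1e-10)
  expect_true(all(c("a", "c") %in% tc2$flagged))
  # random Gaussian design against the direct auxiliary-regression oracle
  set.seed(3)
  Z <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(NULL, c("p", "q", "r")))
  Z[, 3] <- Z[, 1] * 0.8 + rnorm(40, 0, 0.5)
  tc3 <- tolerance_check(Z)
  for (j in 1:3) {
    o <- ols_oracle(Z[, j], Z[, -j])
    r2 <- 1 - (o$sigma^2 * (40 - 3)) / sum((Z[, j] - mean(Z[, j]))^2)
    expect_equal(unname(tc3$tolerance[j]), 1 - r2, tolerance = 1e-10)
  }
})
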
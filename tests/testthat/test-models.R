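# Association models: standardization, OLS oracle equivalence, per-unit
# ratios, stratified fits, interactions.

test_that("standardize centres and scales, and is location invariant", {
  df <- tibble::tibble(x = rnorm(50, 10, 3), y = rnorm(50))
  s <- standardize(df, c("x", "y"))
  expect_equal(mean(s$x), 0, tolerance = 1e-12)
  expect_equal(sd(s$x), 1, tolerance = 1e-12)
  s2 <- standardize(dplyr::mutate(df, x = x + 1000), c("x", "y"))
  expect_equal(s2$x, s$x, tolerance = 1e-9)
  expect_error(standardize(dplyr::mutate(df, x = 1), "x"), "zero variance")
  expect_error(standardize(df, "nope"), "Unknown variable")
})

test_that("standardized simple regression slope equals Pearson r", {
  withr::local_seed(42)
  df <- manual_analysis(tibble::tibble(
    sbp = rnorm(80, 135, 15),
    wmh_load = plogis(rnorm(80, -5.2, 0.8))
  ))
  fit <- fit_wmh_model(df, exposures = "sbp", adjustment = "unadjusted",
                       standardized = TRUE)
  expect_equal(tidy(fit)$estimate, cor(df$sbp_followup, df$wmh_logit),
               tolerance = 1e-10)
})

test_that("noiseless fit returns the exact slope with zero-width CI", {
  df <- manual_analysis(tibble::tibble(
    sbp = seq(100, 179, by = 1),
    wmh_load = plogis(-7 + 2 * 0.01 * seq(100, 179, by = 1))
  ))
  df$wmh_logit <- 2 * 0.01 * df$sbp_followup - 7
  df$wmh_load <- plogis(df$wmh_logit)
  fit <- fit_wmh_model(df, exposures = "sbp", adjustment = "unadjusted",
                       standardized = FALSE)
  td <- suppressWarnings(tidy(fit))  # "essentially perfect fit"
  expect_equal(td$estimate, 0.02, tolerance = 1e-12)
  expect_equal(td$conf.high - td$conf.low, 0, tolerance = 1e-10)
})

test_that("coefficients match an independent normal-equations oracle", {
  withr::local_seed(7)
  n <- 50
  raw <- tibble::tibble(
    sbp = rnorm(n, 135, 16), dbp = rnorm(n, 80, 9),
    age = runif(n, 55, 75), asi = rnorm(n, 9, 2),
    sex = sample(c("male", "female"), n, replace = TRUE),
    diabetes = runif(n) < 0.2,
    smoking = sample(c("never", "ex", "active"), n, replace = TRUE),
    time_diff = runif(n, 5, 13),
    wmh_load = plogis(rnorm(n, -5, 1))
  )
  df <- manual_analysis(raw)

  fit <- fit_wmh_model(df, adjustment = "full", timing = "past",
                       standardized = FALSE)
  td <- tidy(fit)

  # oracle: hand-built design matrix, beta = (X'X)^{-1} X'y
  X <- cbind(
    1, raw$sbp, raw$dbp, raw$age - 9, as.numeric(raw$sex == "female"),
    raw$asi, as.numeric(raw$smoking == "ex"),
    as.numeric(raw$smoking == "active"), as.numeric(raw$diabetes),
    raw$time_diff
  )
  beta <- solve(t(X) %*% X, t(X) %*% df$wmh_logit)[, 1]
  got <- setNames(td$estimate, td$term)
  expect_equal(unname(got["sbp"]), beta[2], tolerance = 1e-8)
  expect_equal(unname(got["dbp"]), beta[3], tolerance = 1e-8)
  expect_equal(unname(got["age"]), beta[4], tolerance = 1e-8)
  expect_equal(unname(got["sex_female"]), beta[5], tolerance = 1e-8)
  expect_equal(unname(got["asi"]), beta[6], tolerance = 1e-8)
  expect_equal(unname(got["smoking_ex"]), beta[7], tolerance = 1e-8)
  expect_equal(unname(got["smoking_active"]), beta[8], tolerance = 1e-8)
  expect_equal(unname(got["diabetes"]), beta[9], tolerance = 1e-8)
  expect_equal(unname(got["time_diff"]), beta[10], tolerance = 1e-8)
})

test_that("standardized and per-mmHg fits are consistent", {
  a <- synth_analysis(1200, seed = 31)
  f_std <- fit_wmh_model(a, adjustment = "full", standardized = TRUE)
  f_raw <- fit_wmh_model(a, adjustment = "full", standardized = FALSE)
  td_s <- tidy(f_std); td_r <- tidy(f_raw)
  for (term in c("sbp", "dbp", "age", "asi")) {
    suffix <- "followup"
    sd_x <- sd(a[[paste0(term, "_", suffix)]])
    sd_y <- sd(a$wmh_logit)
    expect_equal(td_s$estimate[td_s$term == term],
                 td_r$estimate[td_r$term == term] * sd_x / sd_y,
                 tolerance = 1e-10)
  }
})

test_that("an orthogonal covariate leaves the exposure beta unchanged", {
  x <- rep(c(-1, 0, 1), each = 4)
  z <- rep(c(-1, 1), 6)  # orthogonal to x by construction
  stopifnot(sum(x * z) == 0)
  y <- 0.5 * x + 0.25 * z + rep(c(0.1, -0.1), 6)
  df <- manual_analysis(tibble::tibble(sbp = 130 + 10 * x,
                                       wmh_load = plogis(-5 + y)))
  df$asi_followup <- z; df$asi_baseline <- z
  f1 <- fit_wmh_model(df, exposures = "sbp", adjustment = "unadjusted",
                      standardized = FALSE)
  # joint fit with the orthogonal covariate, via an independent lm
  mf <- tibble::tibble(y = df$wmh_logit, x = df$sbp_followup, z = z)
  joint <- coef(lm(y ~ x + z, mf))[["x"]]
  alone <- tidy(f1)$estimate
  expect_equal(alone, joint, tolerance = 1e-10)
})

test_that("per-unit ratios exponentiate the per-mmHg coefficients", {
  expect_equal(effect_ratio_per_unit(0, 10), 1)
  expect_equal(effect_ratio_per_unit(0.00402, 10), exp(0.0402))
  expect_equal(round(effect_ratio_per_unit(0.00402, 10), 4), 1.0410)
  betas <- seq(-0.01, 0.01, by = 0.002)
  expect_true(all(diff(effect_ratio_per_unit(betas, 10)) > 0))

  a <- synth_analysis(1500, seed = 41)
  f <- fit_wmh_model(a, adjustment = "full", standardized = FALSE)
  r <- per_unit_ratios(f)
  td <- tidy(f)
  expect_equal(r$ratio[r$term == "sbp"],
               exp(10 * td$estimate[td$term == "sbp"]), tolerance = 1e-12)
  expect_equal(r$conf.low[r$term == "dbp"],
               exp(5 * td$conf.low[td$term == "dbp"]), tolerance = 1e-12)
  expect_error(per_unit_ratios(fit_wmh_model(a, adjustment = "full")),
               "unstandardized")
})

test_that("identical strata give identical estimates", {
  a <- synth_analysis(800, seed = 51)
  a$sex <- factor(rep(c("male", "female"), length.out = nrow(a)),
                  levels = c("male", "female"))
  # make both sexes literally the same data
  half <- a[seq_len(400), ]
  m <- dplyr::mutate(half, sex = factor("male", levels = levels(a$sex)),
                     participant_id = paste0(participant_id, "m"))
  f <- dplyr::mutate(half, sex = factor("female", levels = levels(a$sex)),
                     participant_id = paste0(participant_id, "f"))
  both <- dplyr::bind_rows(m, f)
  sf <- fit_stratified(both, by = "sex", timing = "concurrent")
  td <- tidy(sf)
  male <- td[td$stratum == "male", c("term", "estimate")]
  female <- td[td$stratum == "female", c("term", "estimate")]
  expect_equal(male, female, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("duration strata split at the sample median of time_diff", {
  a <- synth_analysis(1000, seed = 61)
  sf <- fit_stratified(a, by = "duration", timing = "past")
  td <- tidy(sf)
  expect_setequal(unique(td$stratum), c("short", "long"))
  med <- median(a$time_diff)
  expect_equal(sum(td$n[td$stratum == "short"][1]), sum(a$time_diff <= med))
})

test_that("tiny strata are skipped with a warning", {
  a <- synth_analysis(600, seed = 71)
  # push almost everyone into one age group
  a$age_group_followup <- factor(
    c("<60", rep(">=70", nrow(a) - 1)),
    levels = levels(a$age_group_followup), ordered = TRUE
  )
  w <- testthat::capture_warnings(
    sf <- fit_stratified(a, by = "age_group", timing = "concurrent")
  )
  expect_true(any(grepl("skipped", w)))
  expect_true("<60" %in% sf$skipped)
})

test_that("sex interaction is exactly zero for mirrored data", {
  a <- synth_analysis(500, seed = 81)
  m <- dplyr::mutate(a, sex = factor("male", levels = c("male", "female")),
                     participant_id = paste0(participant_id, "m"))
  f <- dplyr::mutate(a, sex = factor("female", levels = c("male", "female")),
                     participant_id = paste0(participant_id, "f"))
  both <- dplyr::bind_rows(m, f)
  it <- interaction_test(both, exposure = "sbp", timing = "concurrent")
  expect_equal(it$estimate, 0, tolerance = 1e-10)

  expect_error(interaction_test(m, exposure = "sbp"), "Both sexes")
})

test_that("rank-deficient designs raise a collinearity error", {
  a <- synth_analysis(300, seed = 91)
  a$asi_followup <- a$sbp_followup  # aliased with sbp
  expect_error(
    fit_wmh_model(a, adjustment = "full", timing = "concurrent"),
    "collinear|Rank"
  )
})
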
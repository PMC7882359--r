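# Usual-BP stratified analysis: stratum summaries, log-ratio regression,
# bootstrap, and the regression-dilution correction itself.

# hand-built analysis table: participants per (baseline age group x SBP
# band) cell with chosen follow-up BP and loads
strata_fixture <- function(cells) {
  purrr::list_rbind(purrr::map(cells, function(cell) {
    k <- length(cell$loads)
    manual_analysis(tibble::tibble(
      sbp = cell$fu_sbp,
      sbp_baseline = cell$base_sbp,
      age_baseline = cell$age,
      age = cell$age + 9,
      wmh_load = cell$loads
    ))
  }))
}

test_that("stratum summaries: usual BP is the mean follow-up BP", {
  cells <- list(
    list(base_sbp = 110, age = 45, fu_sbp = c(rep(130, 1), rep(140, 1)),
         loads = c(0.004, 0.006)),
    list(base_sbp = 150, age = 45, fu_sbp = rep(148, 2),
         loads = c(0.009, 0.011))
  )
  # expand each cell to satisfy min_n
  cells <- purrr::map(cells, function(c_) {
    c_$fu_sbp <- rep(c_$fu_sbp, 15); c_$loads <- rep(c_$loads, 15); c_
  })
  st <- build_strata(strata_fixture(cells), which = "sbp", min_n = 20)
  ref <- st[st$bp_band == "<120", ]
  expect_equal(ref$usual_bp, 135)
  expect_equal(ref$ratio_to_reference, 1)
  expect_identical(ref$log_ratio, 0)
  hi <- st[st$bp_band == ">=140", ]
  expect_equal(hi$usual_bp, 148)
  expect_equal(hi$median_wmh, 0.010)
  expect_equal(hi$ratio_to_reference, 0.010 / 0.005)
})

test_that("empty reference stratum is an error", {
  cells <- list(list(base_sbp = 150, age = 45, fu_sbp = rep(150, 30),
                     loads = rep(0.01, 30)))
  expect_error(build_strata(strata_fixture(cells), "sbp"),
               "Reference stratum")
})

test_that("two strata give an exact two-point fit", {
  cells <- list(
    list(base_sbp = 110, age = 45, fu_sbp = rep(115, 25),
         loads = rep(0.005, 25)),
    list(base_sbp = 150, age = 45, fu_sbp = rep(145, 25),
         loads = rep(0.005 * exp(0.36), 25))
  )
  st <- build_strata(strata_fixture(cells), "sbp")
  fit <- fit_log_ratio_regression(st, "overall")
  expect_equal(fit$slope_per_mmHg, 0.36 / 30, tolerance = 1e-12)
  expect_equal(fit$ratio_per_unit, exp(0.12), tolerance = 1e-12)
})

test_that("noiseless log-linear strata recover the exact slope", {
  # median load m0 * exp(0.012 * (BP - BP0)) across four bands
  bp0 <- 110
  cells <- purrr::map(
    list(c(110, "<120"), c(125, "120-130"), c(135, "130-140"), c(150, ">=140")),
    function(x) {
      bp <- as.numeric(x[1])
      list(base_sbp = bp, age = 45, fu_sbp = rep(bp, 30),
           loads = rep(0.004 * exp(0.012 * (bp - bp0)), 30))
    }
  )
  st <- build_strata(strata_fixture(cells), "sbp")
  fit <- fit_log_ratio_regression(st, "overall")
  expect_equal(fit$slope_per_mmHg, 0.012, tolerance = 1e-12)
  expect_equal(fit$ratio_per_unit, exp(0.12), tolerance = 1e-12)
  expect_equal(fit$ratio_per_unit, 1.1275, tolerance = 1e-4)

  expect_error(fit_log_ratio_regression(st[1, ], "overall"),
               "at least two strata")
})

test_that("slope is invariant to BP shifts and load rescaling", {
  a <- synth_analysis(3000, seed = 23)
  st <- build_strata(a, "sbp")
  fit <- fit_log_ratio_regression(st, "overall")

  sh <- dplyr::mutate(a, sbp_followup = sbp_followup + 7)
  st_sh <- build_strata(sh, "sbp")
  expect_equal(st_sh$usual_bp, st$usual_bp + 7, tolerance = 1e-10)
  expect_equal(fit_log_ratio_regression(st_sh, "overall")$slope_per_mmHg,
               fit$slope_per_mmHg, tolerance = 1e-10)

  sc <- dplyr::mutate(a, wmh_load = wmh_load * 3)  # still interior
  st_sc <- build_strata(sc, "sbp")
  expect_equal(st_sc$log_ratio, st$log_ratio, tolerance = 1e-10)
  expect_equal(fit_log_ratio_regression(st_sc, "overall")$slope_per_mmHg,
               fit$slope_per_mmHg, tolerance = 1e-10)
})

test_that("baseline-banded usual BP shows regression to the mean", {
  cfg <- cohort_config(n_participants = 6000, seed = 29,
                       bp_within_person_sd = c(sbp = 12, dbp = 8))
  a <- derive_analysis(generate_cohort(cfg))$analysis
  top_band <- a$bp_band_sbp_baseline == ">=140"
  mean_base <- mean(a$sbp_baseline[top_band])
  st <- build_strata(a, "sbp")
  usual_top <- st$usual_bp[st$bp_band == ">=140"]
  expect_true(all(usual_top < mean_base))
})

test_that("bootstrap CIs are deterministic given the seed", {
  a <- synth_analysis(1500, seed = 37)
  u1 <- usual_bp_analysis(a, "sbp", n_boot = 50, seed = 9)
  u2 <- usual_bp_analysis(a, "sbp", n_boot = 50, seed = 9)
  expect_identical(tidy(u1), tidy(u2))
  u3 <- usual_bp_analysis(a, "sbp", n_boot = 50, seed = 10)
  expect_false(identical(tidy(u1)$ci_low, tidy(u3)$ci_low))
})

test_that("degenerate within-stratum data give a zero-width CI", {
  # every stratum's members are identical clones: resampling cannot move
  # the stratum mean or median, so every replicate refits the same line
  cells <- purrr::map(
    list(c(110, 45), c(125, 45), c(150, 45), c(110, 55), c(150, 55)),
    function(x) list(base_sbp = x[1], age = x[2], fu_sbp = rep(x[1], 60),
                     loads = rep(0.004 * exp(0.01 * (x[1] - 110)), 60))
  )
  a <- strata_fixture(cells)
  u <- usual_bp_analysis(a, "sbp", n_boot = 40, seed = 4, min_n = 5)
  ov <- tidy(u)[tidy(u)$scope == "overall", ]
  expect_equal(ov$ci_low, ov$ci_high, tolerance = 1e-12)
  expect_equal(ov$ci_low, ov$ratio_per_unit, tolerance = 1e-12)
})

test_that("usual-BP slope undoes dilution; naive baseline slope is attenuated", {
  b <- log(1.126) / 10
  # noise off, perfect tracking: naive and usual agree to numerical precision
  # age-related BP drift is also off so the two visits differ by a pure
  # constant shift, making the naive and usual analyses exactly comparable
  cfg0 <- clean_config(8000, seed = 43, b_sbp = b,
                       bp_within_person_sd = c(sbp = 0, dbp = 0),
                       bp_tracking_corr = 1,
                       bp_age_slope_per_year = c(sbp = 0, dbp = 0))
  a0 <- derive_analysis(generate_cohort(cfg0))$analysis
  s_usual0 <- fit_log_ratio_regression(build_strata(a0, "sbp"), "overall")
  s_naive0 <- fit_log_ratio_regression(
    build_strata(a0, "sbp", bp = "baseline"), "overall"
  )
  expect_equal(s_naive0$slope_per_mmHg, s_usual0$slope_per_mmHg,
               tolerance = 1e-6)

  # noise on: the naive slope is attenuated relative to the usual-BP slope
  cfg1 <- clean_config(8000, seed = 43, b_sbp = b,
                       bp_within_person_sd = c(sbp = 12, dbp = 8))
  a1 <- derive_analysis(generate_cohort(cfg1))$analysis
  s_usual1 <- fit_log_ratio_regression(build_strata(a1, "sbp"), "overall")
  s_naive1 <- fit_log_ratio_regression(
    build_strata(a1, "sbp", bp = "baseline"), "overall"
  )
  expect_lt(s_naive1$slope_per_mmHg, s_usual1$slope_per_mmHg)
})
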
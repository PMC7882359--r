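# BP harmonization, WMH load, band assignment, eligibility audit.

test_that("automated readings are preferred, then manual, then PWA", {
  v_both <- visit_with_readings(
    sbp_automated_1 = 135, dbp_automated_1 = 82,
    sbp_manual_1 = 130, dbp_manual_1 = 80
  )
  expect_equal(select_bp_source(v_both),
               list(sbp = 135, dbp = 82, source = "automated"))

  v_man <- visit_with_readings(
    sbp_manual_1 = 130, dbp_manual_1 = 80,
    sbp_pwa_1 = 128, dbp_pwa_1 = 79
  )
  expect_equal(select_bp_source(v_man),
               list(sbp = 130, dbp = 80, source = "manual"))
})

test_that("PWA is only used when no other source exists", {
  # exhaustive over the 7 non-empty presence patterns
  sources <- c("automated", "manual", "pwa")
  for (mask in 1:7) {
    present <- sources[as.logical(bitwAnd(mask, c(1, 2, 4)))]
    args <- list()
    for (s in present) {
      args[[paste0("sbp_", s, "_1")]] <- 120
      args[[paste0("dbp_", s, "_1")]] <- 75
    }
    got <- do.call(visit_with_readings, args)
    sel <- select_bp_source(got)
    expected <- present[which.min(match(present, sources))]
    expect_identical(sel$source, expected)
    if (length(setdiff(present, "pwa"))) expect_false(sel$source == "pwa")
  }
})

test_that("readings are averaged within a visit; singles used as-is", {
  v <- visit_with_readings(sbp_automated_1 = 120, sbp_automated_2 = 124,
                           dbp_automated_1 = 70, dbp_automated_2 = 80)
  sel <- select_bp_source(v)
  expect_equal(sel$sbp, 122)
  expect_equal(sel$dbp, 75)

  # one SBP reading, two DBP readings: still valid, single used as-is
  v1 <- visit_with_readings(sbp_manual_1 = 141,
                            dbp_manual_1 = 88, dbp_manual_2 = 92)
  expect_equal(select_bp_source(v1), list(sbp = 141, dbp = 90, source = "manual"))

  # a source with SBP but no DBP does not count as present
  v2 <- visit_with_readings(sbp_automated_1 = 130,
                            sbp_pwa_1 = 125, dbp_pwa_1 = 78)
  expect_identical(select_bp_source(v2)$source, "pwa")

  expect_error(select_bp_source(empty_reading_cols(1)), "No BP source")
})

test_that("exclude_pwa drops PWA-only visits", {
  v <- visit_with_readings(sbp_pwa_1 = 125, dbp_pwa_1 = 78)
  expect_identical(select_bp_source(v)$source, "pwa")
  expect_error(select_bp_source(v, exclude_pwa = TRUE), "No BP source")
})

test_that("WMH load is the volume ratio, strictly inside (0,1)", {
  expect_equal(compute_wmh_load(2796, 559200), 0.005)
  for (V in c(1, 5e5, 2e6)) {
    expect_equal(compute_wmh_load(0.01 * V, V), 0.01)
  }
  expect_error(compute_wmh_load(-1, 100), "positive")
  expect_error(compute_wmh_load(100, 100), "smaller")
  expect_error(compute_wmh_load(150, 100), "smaller")
})

test_that("logit matches its closed form and is monotone", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.0052), log(0.0052 / 0.9948))
  expect_equal(logit(0.0052), -5.2538, tolerance = 1e-4)
  p <- runif(200, 0.001, 0.999)
  expect_equal(logit(p) + logit(1 - p), rep(0, 200), tolerance = 1e-10)
  p <- sort(p)
  expect_true(all(diff(logit(p)) > 0))
  expect_error(logit(0), "open interval")
  expect_error(logit(1), "open interval")
  expect_error(logit(-0.1), "open interval")
})

test_that("BP bands are left-closed and partition the line", {
  expect_identical(as.character(assign_bp_band(70, "dbp")), "70-80")
  expect_identical(as.character(assign_bp_band(139.9, "sbp")), "130-140")
  expect_identical(as.character(assign_bp_band(140, "sbp")), ">=140")
  expect_identical(as.character(assign_bp_band(119.999, "sbp")), "<120")

  # every threshold, one ulp either side
  for (which in c("sbp", "dbp")) {
    cuts <- if (which == "sbp") c(120, 130, 140) else c(70, 80, 90)
    for (thr in cuts) {
      below <- assign_bp_band(thr * (1 - 1e-15), which)
      at <- assign_bp_band(thr, which)
      above <- assign_bp_band(thr * (1 + 1e-15), which)
      expect_identical(at, above)
      expect_true(as.integer(below) + 1L == as.integer(at))
    }
  }

  # partition: exactly one band per random value
  vals <- runif(10000, 1, 250)
  bands <- assign_bp_band(vals, "sbp")
  expect_false(anyNA(bands))
  expect_identical(nlevels(bands), 4L)
})

test_that("age groups use the scheme-specific left-closed cuts", {
  expect_identical(as.character(assign_age_group(49.9, "baseline")), "<50")
  expect_identical(as.character(assign_age_group(50, "baseline")), "50-60")
  expect_identical(as.character(assign_age_group(70, "followup")), ">=70")
  expect_identical(as.character(assign_age_group(59.99, "followup")), "<60")
  expect_error(assign_age_group(20, "baseline"), "30")
})

test_that("eligibility filters run in fixed order with a correct audit", {
  visits <- dplyr::bind_rows(lapply(1:10, function(i) {
    basic_visit_pair(id = sprintf("P%02d", i), excl = i %in% c(1, 2))
  }))
  # participant 3: no BP at baseline (blank automated readings)
  idx <- which(visits$participant_id == "P03" & visits$visit == "baseline")
  visits$sbp_automated_1[idx] <- NA

  out <- derive_analysis(visits)
  expect_equal(nrow(out$analysis), 7)
  audit <- setNames(out$audit$n_removed, out$audit$step)
  expect_equal(unname(audit[c("exclusion_flag", "missing_baseline_bp")]),
               c(2, 1))
  expect_equal(sum(audit), 3)

  # no filters triggered: audit all zeros, everyone kept
  clean <- dplyr::bind_rows(lapply(1:5, function(i) {
    basic_visit_pair(id = sprintf("Q%02d", i))
  }))
  out2 <- derive_analysis(clean)
  expect_equal(sum(out2$audit$n_removed), 0)
  expect_equal(nrow(out2$analysis), 5)
})

test_that("cross-sectional set is a superset of the longitudinal set", {
  cfg <- cohort_config(n_participants = 1500, seed = 13,
                       missingness_rates = c(automated = 0.15))
  v <- inject_missingness(generate_cohort(cfg), cfg)
  n_long <- nrow(derive_analysis(v, cohort = "longitudinal")$analysis)
  n_cross <- nrow(derive_analysis(v, cohort = "cross_sectional")$analysis)
  expect_gte(n_cross, n_long)
})

test_that("brain-volume denominator variant scales the load down", {
  v <- basic_visit_pair()
  a_wm <- derive_analysis(v)$analysis
  a_bv <- derive_analysis(v, denominator = "brain")$analysis
  expect_equal(a_wm$wmh_load, 2796 / 559200)
  expect_equal(a_bv$wmh_load, 2796 / (559200 + 600000 + 350000))
  expect_lt(a_bv$wmh_load, a_wm$wmh_load)
  expect_equal(a_wm$wmh_load_brainvol, a_bv$wmh_load)
  expect_equal(a_wm$wmh_logit, logit(a_wm$wmh_load))
})

test_that("time_diff comes from visit dates in exact days / 365.25", {
  v <- basic_visit_pair()
  a <- derive_analysis(v)$analysis
  expect_equal(a$time_diff,
               as.numeric(as.Date("2017-06-01") - as.Date("2008-06-01")) / 365.25)
})
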
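# Fixture builders: all test inputs are constructed in code.

empty_reading_cols <- function(n) {
  cols <- as.vector(outer(c("sbp", "dbp"),
                          as.vector(outer(c("automated", "manual", "pwa"),
                                          c("1", "2"), paste, sep = "_")),
                          paste, sep = "_"))
  out <- lapply(cols, function(x) rep(NA_real_, n))
  names(out) <- cols
  tibble::as_tibble(out)
}

# one-row visit with chosen readings filled in
visit_with_readings <- function(...) {
  v <- empty_reading_cols(1)
  vals <- list(...)
  for (nm in names(vals)) v[[nm]] <- vals[[nm]]
  v
}

# minimal visit table: one participant, both visits, automated readings
basic_visit_pair <- function(id = "P1", sbp_b = 130, dbp_b = 80,
                             sbp_f = 135, dbp_f = 78,
                             wmh = 2796, wm = 559200, gm = 600000,
                             csf = 350000, excl = FALSE) {
  base <- tibble::tibble(
    participant_id = id, visit = c("baseline", "followup"),
    visit_date = as.Date(c("2008-06-01", "2017-06-01")),
    age = c(50, 59), sex = "female", asi = c(9, 9.5),
    smoking = "never", diabetes = FALSE, antihypertensive = FALSE,
    centre = "C1",
    wmh_volume = c(NA, wmh), wm_volume = c(NA, wm),
    gm_volume = c(NA, gm), csf_volume = c(NA, csf),
    exclusion_flag = excl
  )
  rd <- empty_reading_cols(2)
  rd$sbp_automated_1 <- c(sbp_b, sbp_f)
  rd$dbp_automated_1 <- c(dbp_b, dbp_f)
  dplyr::bind_cols(base, rd)
}

# analysis-shaped tibble from plain per-participant columns; baseline and
# follow-up copies are identical unless *_baseline overrides are given
manual_analysis <- function(df) {
  n <- nrow(df)
  pick <- function(nm, default) if (nm %in% names(df)) df[[nm]] else default
  sbp <- pick("sbp", 130); dbp <- pick("dbp", 80)
  sbp_b <- pick("sbp_baseline", sbp); dbp_b <- pick("dbp_baseline", dbp)
  age <- pick("age", 62); age_b <- pick("age_baseline", age - 9)
  load <- pick("wmh_load", 0.005)
  tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    sex = factor(pick("sex", "female"), levels = c("male", "female")),
    centre = pick("centre", "C1"),
    wmh_volume = load * 5e5, wm_volume = 5e5, gm_volume = 6e5,
    csf_volume = 3.5e5,
    wmh_load = load, wmh_logit = logit(load),
    wmh_load_brainvol = load * 5e5 / 14.5e5,
    sbp_baseline = sbp_b, dbp_baseline = dbp_b,
    sbp_followup = sbp, dbp_followup = dbp,
    bp_source_baseline = pick("bp_source", "automated"),
    bp_source_followup = pick("bp_source", "automated"),
    age_baseline = age_b, age_followup = age,
    asi_baseline = pick("asi", 9), asi_followup = pick("asi", 9),
    smoking_baseline = factor(pick("smoking", "never"),
                              levels = c("never", "ex", "active")),
    smoking_followup = factor(pick("smoking", "never"),
                              levels = c("never", "ex", "active")),
    diabetes_baseline = pick("diabetes", FALSE),
    diabetes_followup = pick("diabetes", FALSE),
    antihypertensive_baseline = pick("antihypertensive", FALSE),
    antihypertensive_followup = pick("antihypertensive", FALSE),
    time_diff = pick("time_diff", 9),
    bp_band_sbp_baseline = assign_bp_band(sbp_b, "sbp"),
    bp_band_dbp_baseline = assign_bp_band(dbp_b, "dbp"),
    bp_band_sbp_followup = assign_bp_band(sbp, "sbp"),
    bp_band_dbp_followup = assign_bp_band(dbp, "dbp"),
    age_group_baseline = assign_age_group(age_b, "baseline"),
    age_group_followup = assign_age_group(age, "followup")
  )
}

# small synthetic analysis set via the real pipeline
synth_analysis <- function(n = 2000, seed = 1, ...) {
  cfg <- cohort_config(n_participants = n, seed = seed, ...)
  derive_analysis(inject_missingness(generate_cohort(cfg), cfg))$analysis
}

# generator config with every nuisance pathway off and a known BP slope
clean_config <- function(n, seed, b_sbp = 0, b_dbp = 0, ...) {
  cohort_config(
    n_participants = n, seed = seed,
    true_log_ratio_sbp_per_mmHg = b_sbp,
    true_log_ratio_dbp_per_mmHg = b_dbp,
    covariate_effects = list(),
    medication = list(baseline_rate = 0, followup_rate = 0,
                      indication_slope = 0, effect = c(sbp = 0, dbp = 0)),
    exclusion_rate = 0,
    ...
  )
}
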
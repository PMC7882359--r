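# Synthetic cohort generator: two visit rows per participant with latent
# BP tracking, within-person measurement noise, and WMH load generated on
# the logit scale from latent ("usual") follow-up BP.

visit_schema <- function() {
  tibble::tibble(
    participant_id = character(), visit = character(),
    visit_date = as.Date(character()), age = numeric(), sex = character(),
    sbp_automated_1 = numeric(), sbp_automated_2 = numeric(),
    dbp_automated_1 = numeric(), dbp_automated_2 = numeric(),
    sbp_manual_1 = numeric(), sbp_manual_2 = numeric(),
    dbp_manual_1 = numeric(), dbp_manual_2 = numeric(),
    sbp_pwa_1 = numeric(), sbp_pwa_2 = numeric(),
    dbp_pwa_1 = numeric(), dbp_pwa_2 = numeric(),
    asi = numeric(), smoking = character(), diabetes = logical(),
    antihypertensive = logical(), centre = character(),
    wmh_volume = numeric(), wm_volume = numeric(), gm_volume = numeric(),
    csf_volume = numeric(), exclusion_flag = logical(),
    latent_sbp = numeric(), latent_dbp = numeric()
  )
}

# inverse-CDF truncated normal (deterministic given the RNG state)
rtnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

# intercept of a logistic assignment model calibrated so the sample mean
# probability hits `rate` given linear score `slope * (x - mean(x))`
calibrate_logistic_intercept <- function(x, slope, rate) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  xc <- x - mean(x)
  if (slope == 0 || sd(xc) == 0) return(qlogis(rate))
  stats::uniroot(function(a) mean(plogis(a + slope * xc)) - rate,
                 interval = c(-50, 50), tol = 1e-10)$root
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a UK-Biobank-shaped visit table: one baseline and one follow-up
#' row per participant, with per-source paired BP readings, covariates,
#' and follow-up brain volumes. Participant-level latent (SBP, DBP) are
#' bivariate normal and track between visits at `bp_tracking_corr`;
#' observed readings add independent normal within-person noise, so
#' cross-visit correlation of *observed* BP is attenuated below the latent
#' tracking correlation (regression dilution). WMH load is drawn so that
#'
#' `logit(load) = logit(median) + b_sbp (uSBP - mean) + b_dbp (uDBP - mean)
#'                + covariate effects (centred) + Normal(0, noise_sd)`
#'
#' where `uSBP`/`uDBP` are the latent untreated follow-up pressures and
#' `b_*` the configured ground-truth log median-ratio slopes per mmHg.
#' Covariates are centred at their sample means so the configured median
#' load is attained at the centre of the cohort. The latent pressures are
#' returned in `latent_sbp` / `latent_dbp` columns (follow-up rows carry
#' the untreated values that drive WMH) so tests can check recovery
#' against ground truth; real data would not have them.
#'
#' Deterministic given `config$seed`; each generation stage uses its own
#' derived sub-stream so adding a stage never perturbs earlier draws.
#'
#' @param config A [cohort_config()].
#' @return A tibble with two rows per participant (visit `"baseline"` then
#'   `"followup"`); imaging volumes only on follow-up rows; BP reading
#'   columns per source with `NA` for sources not used at that visit.
#' @examples
#' visits <- generate_cohort(cohort_config(n_participants = 100, seed = 7))
#' dplyr::count(visits, visit)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config().")
  }
  n <- config$n_participants
  if (n == 0) return(visit_schema())
  seed <- config$seed

  # --- latent BP (between-person, bivariate, tracking across visits) ---
  lat <- withr::with_seed(stage_seed(seed, "latent"), {
    rho <- config$bp_sbp_dbp_corr
    z_s <- rnorm(n)
    z_d <- rho * z_s + sqrt(1 - rho^2) * rnorm(n)
    r <- config$bp_tracking_corr
    e_s <- rnorm(n); e_d <- rnorm(n)
    z_s_f <- r * z_s + sqrt(1 - r^2) * e_s
    z_d_f <- r * z_d + sqrt(1 - r^2) * e_d
    list(
      sbp_b = config$bp_baseline_mean[["sbp"]] + config$bp_latent_sd[["sbp"]] * z_s,
      dbp_b = config$bp_baseline_mean[["dbp"]] + config$bp_latent_sd[["dbp"]] * z_d,
      sbp_f = config$bp_baseline_mean[["sbp"]] + config$bp_followup_shift[["sbp"]] +
        config$bp_latent_sd[["sbp"]] * z_s_f,
      dbp_f = config$bp_baseline_mean[["dbp"]] + config$bp_followup_shift[["dbp"]] +
        config$bp_latent_sd[["dbp"]] * z_d_f
    )
  })

  # --- follow-up interval and visit dates ---
  interval <- withr::with_seed(
    stage_seed(seed, "interval"),
    rtnorm(n, config$follow_up_years_mean, config$follow_up_years_sd,
           config$follow_up_years_bounds[1], config$follow_up_years_bounds[2])
  )
  baseline_date <- withr::with_seed(stage_seed(seed, "dates"), {
    span <- as.numeric(as.Date("2010-10-31") - as.Date("2006-03-01"))
    as.Date("2006-03-01") + floor(runif(n, 0, span + 1))
  })
  followup_date <- baseline_date + round(interval * 365.25)

  # --- covariates ---
  cov <- withr::with_seed(stage_seed(seed, "covariates"), {
    age_b <- runif(n, config$age_range_years[1], config$age_range_years[2])
    sex <- ifelse(runif(n) < config$female_rate, "female", "male")
    smoking_b <- sample(names(config$smoking_baseline_probs), n,
                        replace = TRUE, prob = config$smoking_baseline_probs)
    quit <- runif(n) < config$smoking_quit_rate
    smoking_f <- ifelse(smoking_b == "active" & quit, "ex", smoking_b)
    diab_b <- runif(n) < config$diabetes_baseline_rate
    diab_f <- diab_b | (runif(n) < config$diabetes_incident_rate)
    asi_person <- rnorm(n, 0, config$asi_person_sd)
    asi_b <- config$asi_mean[["baseline"]] + asi_person +
      rnorm(n, 0, config$asi_visit_sd)
    asi_f <- config$asi_mean[["followup"]] + asi_person +
      rnorm(n, 0, config$asi_visit_sd)
    centre <- paste0("C", sample.int(config$n_centres, n, replace = TRUE))
    list(age_b = age_b, sex = sex, smoking_b = smoking_b, smoking_f = smoking_f,
         diab_b = diab_b, diab_f = diab_f, asi_b = asi_b, asi_f = asi_f,
         centre = centre)
  })
  age_f <- cov$age_b + interval

  # latent BP rises with age (centred, so configured means are preserved)
  slope <- config$bp_age_slope_per_year
  lat$sbp_b <- lat$sbp_b + slope[["sbp"]] * (cov$age_b - mean(cov$age_b))
  lat$dbp_b <- lat$dbp_b + slope[["dbp"]] * (cov$age_b - mean(cov$age_b))
  lat$sbp_f <- lat$sbp_f + slope[["sbp"]] * (age_f - mean(age_f))
  lat$dbp_f <- lat$dbp_f + slope[["dbp"]] * (age_f - mean(age_f))

  # --- antihypertensive medication (confounding by indication) ---
  med <- withr::with_seed(stage_seed(seed, "medication"), {
    slope <- config$medication$indication_slope
    a_b <- calibrate_logistic_intercept(lat$sbp_b, slope,
                                        config$medication$baseline_rate)
    p_b <- plogis(a_b + slope * (lat$sbp_b - mean(lat$sbp_b)))
    med_b <- runif(n) < p_b
    target_f <- config$medication$followup_rate
    med_f <- med_b
    if (mean(med_b) < target_f && any(!med_b)) {
      # initiation among the untreated, again indication-weighted
      new_rate <- (target_f - mean(med_b)) / mean(!med_b)
      x_new <- lat$sbp_f[!med_b]
      a_f <- calibrate_logistic_intercept(x_new, slope, min(new_rate, 1))
      p_new <- plogis(a_f + slope * (x_new - mean(x_new)))
      med_f[!med_b] <- runif(sum(!med_b)) < p_new
    }
    list(b = med_b, f = med_f)
  })

  # measured (treated) pressures: medication lowers what the cuff sees,
  # not the long-term exposure that drives WMH
  eff <- config$medication$effect
  meas <- list(
    sbp_b = lat$sbp_b - ifelse(med$b, eff[["sbp"]], 0),
    dbp_b = lat$dbp_b - ifelse(med$b, eff[["dbp"]], 0),
    sbp_f = lat$sbp_f - ifelse(med$f, eff[["sbp"]], 0),
    dbp_f = lat$dbp_f - ifelse(med$f, eff[["dbp"]], 0)
  )

  # --- per-visit readings by source ---
  readings <- withr::with_seed(stage_seed(seed, "readings"), {
    draw_visit <- function(sbp_true, dbp_true) {
      src <- sample(c("automated", "manual", "pwa"), n, replace = TRUE,
                    prob = config$source_probabilities[c("automated", "manual", "pwa")])
      second <- runif(n) < config$second_reading_rate
      s_sd <- config$bp_within_person_sd[["sbp"]]
      d_sd <- config$bp_within_person_sd[["dbp"]]
      out <- list(source = src)
      for (which in c("sbp", "dbp")) {
        true <- if (which == "sbp") sbp_true else dbp_true
        nsd <- if (which == "sbp") s_sd else d_sd
        r1 <- true + rnorm(n, 0, nsd)
        r2 <- ifelse(second, true + rnorm(n, 0, nsd), NA_real_)
        for (s in c("automated", "manual", "pwa")) {
          out[[paste0(which, "_", s, "_1")]] <- ifelse(src == s, r1, NA_real_)
          out[[paste0(which, "_", s, "_2")]] <- ifelse(src == s, r2, NA_real_)
        }
      }
      out
    }
    list(b = draw_visit(meas$sbp_b, meas$dbp_b),
         f = draw_visit(meas$sbp_f, meas$dbp_f))
  })

  # --- brain volumes (follow-up only) ---
  vols <- withr::with_seed(stage_seed(seed, "volumes"), {
    list(
      wm = pmax(rnorm(n, config$volume_mean[["wm"]], config$volume_sd[["wm"]]), 1e4),
      gm = pmax(rnorm(n, config$volume_mean[["gm"]], config$volume_sd[["gm"]]), 1e4),
      csf = pmax(rnorm(n, config$volume_mean[["csf"]], config$volume_sd[["csf"]]), 1e4)
    )
  })

  # --- WMH load on the logit scale ---
  wmh_load <- withr::with_seed(stage_seed(seed, "wmh"), {
    ce <- config$covariate_effects
    centred <- function(x) x - mean(x)
    lp <- config$true_log_ratio_sbp_per_mmHg * centred(lat$sbp_f) +
      config$true_log_ratio_dbp_per_mmHg * centred(lat$dbp_f) +
      (ce$age_per_year %||% 0) * centred(age_f) +
      (ce$female %||% 0) * centred(as.numeric(cov$sex == "female")) +
      (ce$diabetes %||% 0) * centred(as.numeric(cov$diab_f)) +
      (ce$smoking_ex %||% 0) * centred(as.numeric(cov$smoking_f == "ex")) +
      (ce$smoking_active %||% 0) * centred(as.numeric(cov$smoking_f == "active")) +
      (ce$asi %||% 0) * centred(cov$asi_f)
    centre_idx <- as.integer(sub("^C", "", cov$centre))
    ctr_eff <- config$centre_effects[centre_idx]
    lp <- lp + ctr_eff - mean(ctr_eff)
    noise <- if (config$wmh_logit_noise_sd > 0) {
      rnorm(n, 0, config$wmh_logit_noise_sd)
    } else rep(0, n)
    plogis(qlogis(config$wmh_median_load) + lp + noise)
  })
  wmh_volume <- wmh_load * vols$wm

  id <- sprintf("P%07d", seq_len(n))
  row_for <- function(visit) {
    b <- visit == "baseline"
    rd <- if (b) readings$b else readings$f
    tibble::tibble(
      participant_id = id, visit = visit,
      visit_date = if (b) baseline_date else followup_date,
      age = if (b) cov$age_b else age_f,
      sex = cov$sex,
      sbp_automated_1 = rd$sbp_automated_1, sbp_automated_2 = rd$sbp_automated_2,
      dbp_automated_1 = rd$dbp_automated_1, dbp_automated_2 = rd$dbp_automated_2,
      sbp_manual_1 = rd$sbp_manual_1, sbp_manual_2 = rd$sbp_manual_2,
      dbp_manual_1 = rd$dbp_manual_1, dbp_manual_2 = rd$dbp_manual_2,
      sbp_pwa_1 = rd$sbp_pwa_1, sbp_pwa_2 = rd$sbp_pwa_2,
      dbp_pwa_1 = rd$dbp_pwa_1, dbp_pwa_2 = rd$dbp_pwa_2,
      asi = if (b) cov$asi_b else cov$asi_f,
      smoking = if (b) cov$smoking_b else cov$smoking_f,
      diabetes = if (b) cov$diab_b else cov$diab_f,
      antihypertensive = if (b) med$b else med$f,
      centre = cov$centre,
      wmh_volume = if (b) NA_real_ else wmh_volume,
      wm_volume = if (b) NA_real_ else vols$wm,
      gm_volume = if (b) NA_real_ else vols$gm,
      csf_volume = if (b) NA_real_ else vols$csf,
      exclusion_flag = FALSE,
      latent_sbp = if (b) lat$sbp_b else lat$sbp_f,
      latent_dbp = if (b) lat$dbp_b else lat$dbp_f
    )
  }
  dplyr::arrange(
    dplyr::bind_rows(row_for("baseline"), row_for("followup")),
    .data$participant_id, .data$visit
  )
}

#' Blank fields at configured rates and set the exclusion flag
#'
#' Applies the missingness model of a [cohort_config()] to a visit table:
#' each named field is blanked independently at its configured rate, and
#' `exclusion_flag` (a WMH-confounding diagnosis) is set at
#' `exclusion_rate`. Names in `missingness_rates` may be visit-table
#' columns, or one of the source groups `"automated"`, `"manual"`,
#' `"pwa"`, which blank all four reading columns of that source jointly
#' (a missing source, not a missing single reading). Deterministic given
#' `config$seed`; uses its own RNG sub-stream.
#'
#' @param visits A visit table from [generate_cohort()].
#' @param config The [cohort_config()] carrying `missingness_rates`,
#'   `exclusion_rate`, and `seed`.
#' @return The visit table with fields blanked and flags set.
#' @export
inject_missingness <- function(visits, config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config().")
  }
  rates <- config$missingness_rates
  src_groups <- c("automated", "manual", "pwa")
  unknown <- setdiff(names(rates), c(names(visits), src_groups))
  if (length(unknown)) {
    abort(paste0("Unknown field(s) in missingness_rates: ",
                 paste(unknown, collapse = ", ")))
  }
  n <- nrow(visits)
  if (n == 0) return(visits)
  withr::with_seed(stage_seed(config$seed, "missingness"), {
    for (field in names(rates)) {
      rate <- rates[[field]]
      if (rate == 0) next
      hit <- runif(n) < rate
      cols <- if (field %in% src_groups) {
        paste0(rep(c("sbp_", "dbp_"), each = 2), field, "_", c(1, 2))
      } else field
      for (cl in cols) visits[[cl]][hit] <- NA
    }
    if (config$exclusion_rate > 0) {
      # flag is per participant: same draw applied to both visit rows
      ids <- unique(visits$participant_id)
      flagged <- ids[runif(length(ids)) < config$exclusion_rate]
      visits$exclusion_flag <- visits$exclusion_flag |
        visits$participant_id %in% flagged
    }
    visits
  })
}
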
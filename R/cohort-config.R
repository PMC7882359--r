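#' Configuration for the synthetic longitudinal cohort generator
#'
#' Builds the parameter object consumed by [generate_cohort()] and
#' [inject_missingness()]. Defaults emulate a UK-Biobank-shaped imaging
#' cohort: participants aged 40-69 at baseline, re-assessed with MRI about
#' nine years later, with blood pressure measured twice per visit by one of
#' three sources (automated sphygmomanometer preferred, then manual, then
#' pulse-wave analysis). Participant-level latent (SBP, DBP) are bivariate
#' normal; observed readings add independent within-person visit noise, so
#' a single baseline measurement is a diluted proxy for long-term BP — the
#' phenomenon the usual-BP analysis corrects. WMH load is generated on the
#' logit scale as a linear function of latent ("usual") follow-up BP plus
#' covariate effects and normal noise, so the median WMH load follows a
#' log-linear dose-response in usual BP (logit and log coincide closely at
#' small loads).
#'
#' Antihypertensive medication is assigned with probability increasing in
#' latent SBP (confounding by indication); medicated participants have
#' their *measured* BP lowered by `medication$effect` while WMH continues
#' to track untreated latent BP, reproducing the higher WMH seen in
#' treated people even at normotensive measured values.
#'
#' @param n_participants Number of participants (two visit rows each).
#' @param seed Integer seed; every stage derives its own sub-stream from it.
#' @param age_range_years Baseline age interval (uniform), years.
#' @param follow_up_years_mean,follow_up_years_sd Mean and SD of the
#'   between-visit interval (normal, truncated at `follow_up_years_bounds`).
#' @param follow_up_years_bounds Truncation bounds for the interval, years.
#' @param bp_baseline_mean Named vector `c(sbp=, dbp=)`, latent means at
#'   baseline, mmHg.
#' @param bp_followup_shift Named vector, added to the latent means at
#'   follow-up (population BP drift), mmHg.
#' @param bp_latent_sd Named vector, between-person SD of latent BP, mmHg.
#' @param bp_sbp_dbp_corr Correlation between latent SBP and DBP.
#' @param bp_age_slope_per_year Named vector: mmHg added to latent BP per
#'   year of age (centred at the cohort mean age), making BP rise with
#'   age as in real cohorts; this is what makes age a confounder of the
#'   marginal usual-BP dose-response.
#' @param bp_tracking_corr Correlation of latent BP across visits in [0, 1].
#' @param bp_within_person_sd Named vector, SD of reading-level
#'   measurement/biological noise, mmHg.
#' @param true_log_ratio_sbp_per_mmHg,true_log_ratio_dbp_per_mmHg Ground
#'   truth: log median-WMH-load ratio per 1 mmHg of usual SBP / DBP.
#' @param wmh_median_load Target median WMH load (proportion of white
#'   matter volume) at the centre of the covariate distribution.
#' @param wmh_logit_noise_sd SD of residual noise on the logit-load scale.
#' @param covariate_effects Named list of logit-scale effects:
#'   `age_per_year`, `female`, `diabetes`, `smoking_ex`, `smoking_active`,
#'   `asi` (covariates are centred, so these do not move the median load).
#' @param female_rate,diabetes_baseline_rate,diabetes_incident_rate,
#'   smoking_baseline_probs,smoking_quit_rate Covariate distribution
#'   parameters; smoking probabilities are `c(never=, ex=, active=)`.
#' @param asi_mean Named vector `c(baseline=, followup=)`, arterial
#'   stiffness index means; `asi_person_sd` / `asi_visit_sd` split its
#'   variance into a stable person effect and visit noise.
#' @param asi_person_sd,asi_visit_sd See `asi_mean`.
#' @param medication List: `baseline_rate`, `followup_rate` (population
#'   prevalence targets), `indication_slope` (logit of medication per mmHg
#'   latent SBP), `effect` (named vector, mmHg subtracted from measured
#'   SBP/DBP while medicated).
#' @param source_probabilities Named probabilities `c(automated=, manual=,
#'   pwa=)` that a visit's BP comes from each source; must sum to 1.
#' @param second_reading_rate Probability the second within-visit reading
#'   pair is recorded.
#' @param volume_mean,volume_sd Named vectors `c(wm=, gm=, csf=)`:
#'   white-matter, grey-matter, CSF volume distribution, mm^3.
#' @param missingness_rates Named probabilities used by
#'   [inject_missingness()]; names are visit-table columns or the source
#'   groups `"automated"`, `"manual"`, `"pwa"` (blanking all four reading
#'   columns of that source jointly).
#' @param exclusion_rate Probability of a WMH-confounding diagnosis flag.
#' @param n_centres Number of assessment centres (uniform assignment).
#' @param centre_effects Optional numeric vector of logit-scale centre
#'   effects (length `n_centres`); defaults to zeros.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [inject_missingness()]
#' @export
cohort_config <- function(n_participants = 5000,
                          seed = 1L,
                          age_range_years = c(40, 69),
                          follow_up_years_mean = 9.0,
                          follow_up_years_sd = 2.0,
                          follow_up_years_bounds = c(4, 13.5),
                          bp_baseline_mean = c(sbp = 134.8, dbp = 81.4),
                          bp_followup_shift = c(sbp = 3.5, dbp = -3.7),
                          bp_latent_sd = c(sbp = 15.7, dbp = 7.9),
                          bp_sbp_dbp_corr = 0.6,
                          bp_age_slope_per_year = c(sbp = 0.5, dbp = 0.1),
                          bp_tracking_corr = 0.7,
                          bp_within_person_sd = c(sbp = 8, dbp = 6),
                          true_log_ratio_sbp_per_mmHg = log(1.041) / 10,
                          true_log_ratio_dbp_per_mmHg = log(1.031) / 5,
                          wmh_median_load = 0.0052,
                          wmh_logit_noise_sd = 1.1,
                          covariate_effects = list(
                            age_per_year = 0.06, female = 0.10,
                            diabetes = 0.30, smoking_ex = 0.07,
                            smoking_active = 0.25, asi = 0.02
                          ),
                          female_rate = 0.53,
                          diabetes_baseline_rate = 0.025,
                          diabetes_incident_rate = 0.027,
                          smoking_baseline_probs = c(never = 0.612, ex = 0.326, active = 0.062),
                          smoking_quit_rate = 0.45,
                          asi_mean = c(baseline = 9.07, followup = 9.61),
                          asi_person_sd = 2.3,
                          asi_visit_sd = 1.8,
                          medication = list(
                            baseline_rate = 0.146, followup_rate = 0.261,
                            indication_slope = 0.05,
                            effect = c(sbp = 10, dbp = 6)
                          ),
                          source_probabilities = c(automated = 0.90, manual = 0.08, pwa = 0.02),
                          second_reading_rate = 0.97,
                          volume_mean = c(wm = 540000, gm = 600000, csf = 350000),
                          volume_sd = c(wm = 30000, gm = 35000, csf = 40000),
                          missingness_rates = c(),
                          exclusion_rate = 0.0128,
                          n_centres = 3,
                          centre_effects = NULL) {
  if (length(n_participants) != 1 || is.na(n_participants) ||
      !is.finite(n_participants) || n_participants < 0 ||
      n_participants != floor(n_participants)) {
    abort("`n_participants` must be a single nonnegative integer.")
  }
  check_finite(seed, "seed")
  check_finite(age_range_years, "age_range_years")
  check_finite(c(follow_up_years_mean, follow_up_years_sd), "follow_up_years")
  check_nonneg(follow_up_years_sd, "follow_up_years_sd")
  check_finite(bp_baseline_mean, "bp_baseline_mean")
  check_finite(bp_followup_shift, "bp_followup_shift")
  check_nonneg(bp_latent_sd, "bp_latent_sd")
  check_nonneg(bp_within_person_sd, "bp_within_person_sd")
  check_prob(bp_tracking_corr, "bp_tracking_corr")
  check_finite(bp_age_slope_per_year, "bp_age_slope_per_year")
  if (abs(bp_sbp_dbp_corr) > 1) abort("`bp_sbp_dbp_corr` must lie in [-1, 1].")
  check_finite(true_log_ratio_sbp_per_mmHg, "true_log_ratio_sbp_per_mmHg")
  check_finite(true_log_ratio_dbp_per_mmHg, "true_log_ratio_dbp_per_mmHg")
  if (wmh_median_load <= 0 || wmh_median_load >= 1) {
    abort("`wmh_median_load` must be in (0, 1).")
  }
  check_nonneg(wmh_logit_noise_sd, "wmh_logit_noise_sd")
  if (length(covariate_effects)) {
    check_finite(unlist(covariate_effects), "covariate_effects")
  }
  check_prob(c(female_rate, diabetes_baseline_rate, diabetes_incident_rate,
               smoking_quit_rate, second_reading_rate, exclusion_rate),
             "rates")
  check_prob(smoking_baseline_probs, "smoking_baseline_probs")
  if (abs(sum(smoking_baseline_probs) - 1) > 1e-8) {
    abort("`smoking_baseline_probs` must sum to 1.")
  }
  check_prob(source_probabilities, "source_probabilities")
  if (!setequal(names(source_probabilities), c("automated", "manual", "pwa"))) {
    abort("`source_probabilities` must be named automated/manual/pwa.")
  }
  if (abs(sum(source_probabilities) - 1) > 1e-8) {
    abort("`source_probabilities` must sum to 1.")
  }
  if (length(missingness_rates)) check_prob(missingness_rates, "missingness_rates")
  check_prob(c(medication$baseline_rate, medication$followup_rate), "medication rates")
  if (medication$followup_rate < medication$baseline_rate) {
    abort("medication follow-up prevalence cannot be below baseline prevalence.")
  }
  check_nonneg(volume_sd, "volume_sd")
  if (is.null(centre_effects)) centre_effects <- rep(0, n_centres)
  if (length(centre_effects) != n_centres) {
    abort("`centre_effects` must have one entry per centre.")
  }

  structure(
    list(
      n_participants = as.integer(n_participants), seed = as.integer(seed),
      age_range_years = age_range_years,
      follow_up_years_mean = follow_up_years_mean,
      follow_up_years_sd = follow_up_years_sd,
      follow_up_years_bounds = follow_up_years_bounds,
      bp_baseline_mean = bp_baseline_mean,
      bp_followup_shift = bp_followup_shift,
      bp_latent_sd = bp_latent_sd,
      bp_sbp_dbp_corr = bp_sbp_dbp_corr,
      bp_age_slope_per_year = bp_age_slope_per_year,
      bp_tracking_corr = bp_tracking_corr,
      bp_within_person_sd = bp_within_person_sd,
      true_log_ratio_sbp_per_mmHg = true_log_ratio_sbp_per_mmHg,
      true_log_ratio_dbp_per_mmHg = true_log_ratio_dbp_per_mmHg,
      wmh_median_load = wmh_median_load,
      wmh_logit_noise_sd = wmh_logit_noise_sd,
      covariate_effects = covariate_effects,
      female_rate = female_rate,
      diabetes_baseline_rate = diabetes_baseline_rate,
      diabetes_incident_rate = diabetes_incident_rate,
      smoking_baseline_probs = smoking_baseline_probs,
      smoking_quit_rate = smoking_quit_rate,
      asi_mean = asi_mean, asi_person_sd = asi_person_sd,
      asi_visit_sd = asi_visit_sd,
      medication = medication,
      source_probabilities = source_probabilities,
      second_reading_rate = second_reading_rate,
      volume_mean = volume_mean, volume_sd = volume_sd,
      missingness_rates = missingness_rates,
      exclusion_rate = exclusion_rate,
      n_centres = as.integer(n_centres),
      centre_effects = centre_effects
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  participants: %d   seed: %d\n", x$n_participants, x$seed))
  cat(sprintf("  true log median-WMH ratio: %.5f /mmHg SBP, %.5f /mmHg DBP\n",
              x$true_log_ratio_sbp_per_mmHg, x$true_log_ratio_dbp_per_mmHg))
  cat(sprintf("  BP tracking %.2f, within-person SD %.1f/%.1f mmHg\n",
              x$bp_tracking_corr, x$bp_within_person_sd[["sbp"]],
              x$bp_within_person_sd[["dbp"]]))
  invisible(x)
}
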
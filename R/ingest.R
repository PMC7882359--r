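# Cohort ingest: harmonize BP sources, derive WMH load and category
# assignments, apply eligibility filters with an explicit audit trail.

bp_band_breaks <- list(
  sbp = c(120, 130, 140),
  dbp = c(70, 80, 90)
)
bp_band_labels <- list(
  sbp = c("<120", "120-130", "130-140", ">=140"),
  dbp = c("<70", "70-80", "80-90", ">=90")
)
age_group_breaks <- list(baseline = c(50, 60), followup = c(60, 70))
age_group_labels <- list(
  baseline = c("<50", "50-60", ">=60"),
  followup = c("<60", "60-70", ">=70")
)

#' Harmonize multi-source BP readings for a table of visits
#'
#' Each visit may carry up to two SBP/DBP readings from each of three
#' sources. The harmonized visit BP uses the automated sphygmomanometer
#' readings when present, falling back to manual readings, then to
#' pulse-wave-analysis (PWA) readings; the available readings of the
#' chosen source are averaged within the visit. A source counts as
#' present when it has at least one SBP and one DBP reading; a single
#' available reading is used as-is.
#'
#' @param visits Visit table with `sbp_<source>_<1|2>` /
#'   `dbp_<source>_<1|2>` columns for sources automated, manual, pwa.
#' @param exclude_pwa If `TRUE`, PWA readings are ignored (sensitivity
#'   analysis); visits with only PWA data then have missing BP.
#' @return A tibble with one row per input row: `sbp`, `dbp` (mmHg) and
#'   `bp_source`; all `NA` when no source is available.
#' @export
harmonize_bp <- function(visits, exclude_pwa = FALSE) {
  sources <- c("automated", "manual", if (!exclude_pwa) "pwa")
  n <- nrow(visits)
  sbp <- rep(NA_real_, n); dbp <- rep(NA_real_, n)
  src <- rep(NA_character_, n)
  pair_mean <- function(a, b) {
    m <- rowMeans(cbind(a, b), na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }
  for (s in sources) {
    s_m <- pair_mean(visits[[paste0("sbp_", s, "_1")]],
                     visits[[paste0("sbp_", s, "_2")]])
    d_m <- pair_mean(visits[[paste0("dbp_", s, "_1")]],
                     visits[[paste0("dbp_", s, "_2")]])
    use <- is.na(src) & !is.na(s_m) & !is.na(d_m)
    sbp[use] <- s_m[use]; dbp[use] <- d_m[use]; src[use] <- s
  }
  tibble::tibble(sbp = sbp, dbp = dbp, bp_source = src)
}

#' Select the preferred BP source for a single visit
#'
#' Scalar counterpart of [harmonize_bp()]: automated readings preferred,
#' then manual, then PWA, averaging available readings within the visit.
#'
#' @param visit A one-row visit table (see [harmonize_bp()]).
#' @inheritParams harmonize_bp
#' @return A list with `sbp`, `dbp`, and `source`.
#' @examples
#' v <- tibble::tibble(
#'   sbp_automated_1 = 135, sbp_automated_2 = NA, dbp_automated_1 = 82,
#'   dbp_automated_2 = NA, sbp_manual_1 = 130, sbp_manual_2 = NA,
#'   dbp_manual_1 = 80, dbp_manual_2 = NA, sbp_pwa_1 = NA, sbp_pwa_2 = NA,
#'   dbp_pwa_1 = NA, dbp_pwa_2 = NA
#' )
#' select_bp_source(v)  # automated wins: 135/82
#' @export
select_bp_source <- function(visit, exclude_pwa = FALSE) {
  if (nrow(visit) != 1) abort("`visit` must be a single row.")
  h <- harmonize_bp(visit, exclude_pwa = exclude_pwa)
  if (is.na(h$bp_source)) {
    abort("No BP source with both SBP and DBP readings is available.")
  }
  list(sbp = h$sbp, dbp = h$dbp, source = h$bp_source)
}

#' WMH load: lesion volume as a proportion of a reference volume
#'
#' The primary outcome normalizes WMH volume by total white matter
#' volume; the sensitivity variant normalizes by total brain volume
#' (grey + white + CSF). The result must lie strictly inside (0, 1).
#'
#' @param wmh_volume WMH volume, mm^3 (> 0).
#' @param denom_volume Reference volume, mm^3 (> `wmh_volume`).
#' @return Numeric vector of proportions in (0, 1).
#' @examples
#' compute_wmh_load(2796, 559200)  # 0.005
#' @export
compute_wmh_load <- function(wmh_volume, denom_volume) {
  ok <- !is.na(wmh_volume) & !is.na(denom_volume)
  if (any(wmh_volume[ok] <= 0) || any(denom_volume[ok] <= 0)) {
    abort("Volumes must be strictly positive.")
  }
  if (any(wmh_volume[ok] >= denom_volume[ok])) {
    abort("WMH volume must be smaller than the reference volume.")
  }
  wmh_volume / denom_volume
}

#' Assign a blood pressure to its category band
#'
#' Standard clinic thresholds with left-closed intervals `[lo, hi)`:
#' SBP <120, 120-130, 130-140, >=140 mmHg; DBP <70, 70-80, 80-90,
#' >=90 mmHg. A value on a boundary belongs to the upper band (so
#' DBP 70 is "70-80" and SBP 140 is ">=140").
#'
#' @param value BP values, mmHg (finite, positive; `NA` passes through).
#' @param which `"sbp"` or `"dbp"`.
#' @return Ordered factor over the four bands.
#' @examples
#' assign_bp_band(c(119, 120, 140), "sbp")
#' @export
assign_bp_band <- function(value, which = c("sbp", "dbp")) {
  which <- match.arg(which)
  ok <- !is.na(value)
  if (any(!is.finite(value[ok])) || any(value[ok] <= 0)) {
    abort("BP values must be finite and positive.")
  }
  cut(value, breaks = c(-Inf, bp_band_breaks[[which]], Inf),
      labels = bp_band_labels[[which]], right = FALSE, ordered_result = TRUE)
}

#' Assign an age to its analysis age group
#'
#' Left-closed groups: `<50, 50-60, >=60` years for baseline ages and
#' `<60, 60-70, >=70` years for follow-up ages (the cohort is about a
#' decade older at the imaging visit).
#'
#' @param age Ages in years (plausible range 30-100; `NA` passes through).
#' @param scheme `"baseline"` or `"followup"`.
#' @return Ordered factor over the three groups.
#' @examples
#' assign_age_group(c(49.9, 50), "baseline")
#' @export
assign_age_group <- function(age, scheme = c("baseline", "followup")) {
  scheme <- match.arg(scheme)
  ok <- !is.na(age)
  if (any(!is.finite(age[ok])) || any(age[ok] < 30 | age[ok] > 100)) {
    abort("Ages must lie in [30, 100] years.")
  }
  cut(age, breaks = c(-Inf, age_group_breaks[[scheme]], Inf),
      labels = age_group_labels[[scheme]], right = FALSE,
      ordered_result = TRUE)
}

required_visit_cols <- c(
  "participant_id", "visit", "visit_date", "age", "sex", "asi", "smoking",
  "diabetes", "antihypertensive", "centre", "wmh_volume", "wm_volume",
  "gm_volume", "csf_volume", "exclusion_flag",
  as.vector(outer(c("sbp", "dbp"),
                  as.vector(outer(c("automated", "manual", "pwa"),
                                  c("1", "2"), paste, sep = "_")),
                  paste, sep = "_"))
)

#' Derive the per-participant analysis dataset from a visit table
#'
#' Harmonizes BP per visit ([harmonize_bp()]), reshapes to one row per
#' participant, derives WMH load / logit load / category assignments /
#' follow-up interval, and applies the eligibility filters in a fixed,
#' audited order:
#'
#' 1. missing WMH or white-matter volume at follow-up;
#' 2. exclusion flag (diagnosis confounding WMH assessment);
#' 3. missing harmonized follow-up BP;
#' 4. missing harmonized baseline BP (longitudinal set only).
#'
#' The cross-sectional set stops after step 3, so it is always a superset
#' of the longitudinal set.
#'
#' @param visits Visit table (two rows per participant) in the
#'   [generate_cohort()] schema.
#' @param cohort `"longitudinal"` (default) or `"cross_sectional"`.
#' @param denominator `"wm"` (primary: WMH / white matter volume) or
#'   `"brain"` (sensitivity: WMH / (grey + white + CSF)); selects which
#'   load feeds `wmh_load` and `wmh_logit`. Both loads are always
#'   returned (`wmh_load_brainvol` holds the brain-volume variant).
#' @param exclude_pwa Drop pulse-wave-analysis BP (sensitivity analysis).
#' @return A list with `analysis` (one tibble row per eligible
#'   participant, including `wmh_load`, `wmh_logit`, BP bands and age
#'   groups for both visits, and `time_diff` in years) and `audit` (a
#'   tibble of filter steps with participants removed and remaining).
#' @export
derive_analysis <- function(visits,
                            cohort = c("longitudinal", "cross_sectional"),
                            denominator = c("wm", "brain"),
                            exclude_pwa = FALSE) {
  cohort <- match.arg(cohort)
  denominator <- match.arg(denominator)
  missing_cols <- setdiff(required_visit_cols, names(visits))
  if (length(missing_cols)) {
    abort(paste0("Visit table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_visit <- which(!visits$visit %in% c("baseline", "followup"))
  if (length(bad_visit)) {
    abort(paste0("Invalid `visit` value at row(s): ",
                 paste(head(bad_visit, 5), collapse = ", ")))
  }

  h <- harmonize_bp(visits, exclude_pwa = exclude_pwa)
  visits <- dplyr::bind_cols(visits, h)

  per_visit <- c("visit_date", "age", "sbp", "dbp", "bp_source", "asi",
                 "smoking", "diabetes", "antihypertensive",
                 intersect(c("latent_sbp", "latent_dbp"), names(visits)))
  suffix_cols <- function(df, suffix) {
    df <- df[, c("participant_id", per_visit)]
    names(df)[-1] <- paste0(per_visit, "_", suffix)
    df
  }
  b <- suffix_cols(visits[visits$visit == "baseline", ], "baseline")
  fu_rows <- visits[visits$visit == "followup", ]
  f <- suffix_cols(fu_rows, "followup")
  shared <- fu_rows[, c("participant_id", "sex", "centre", "wmh_volume",
                        "wm_volume", "gm_volume", "csf_volume",
                        "exclusion_flag")]
  # exclusion flag counts if set at either visit
  excl_b <- visits$exclusion_flag[visits$visit == "baseline"]
  excl_b <- excl_b[match(shared$participant_id,
                         visits$participant_id[visits$visit == "baseline"])]
  shared$exclusion_flag <- shared$exclusion_flag | (excl_b %in% TRUE)
  wide <- shared |>
    dplyr::left_join(b, by = "participant_id") |>
    dplyr::left_join(f, by = "participant_id")

  n0 <- nrow(wide)
  miss_wmh <- is.na(wide$wmh_volume) | is.na(wide$wm_volume)
  wide <- wide[!miss_wmh, ]
  flagged <- wide$exclusion_flag
  wide <- wide[!flagged, ]
  miss_fu_bp <- is.na(wide$sbp_followup) | is.na(wide$dbp_followup)
  wide <- wide[!miss_fu_bp, ]
  n_miss_base <- 0L
  if (cohort == "longitudinal") {
    miss_b_bp <- is.na(wide$sbp_baseline) | is.na(wide$dbp_baseline)
    n_miss_base <- sum(miss_b_bp)
    wide <- wide[!miss_b_bp, ]
  }

  audit <- tibble::tibble(
    step = c("input", "missing_wmh", "exclusion_flag",
             "missing_followup_bp",
             if (cohort == "longitudinal") "missing_baseline_bp"),
    n_removed = c(0L, sum(miss_wmh), sum(flagged), sum(miss_fu_bp),
                  if (cohort == "longitudinal") n_miss_base)
  )
  audit$n_remaining <- n0 - cumsum(audit$n_removed)

  load_wm <- compute_wmh_load(wide$wmh_volume, wide$wm_volume)
  brain_vol <- wide$wm_volume + wide$gm_volume + wide$csf_volume
  load_brain <- compute_wmh_load(wide$wmh_volume, brain_vol)
  primary <- if (denominator == "wm") load_wm else load_brain

  analysis <- wide |>
    dplyr::mutate(
      wmh_load = primary,
      wmh_logit = logit(primary),
      wmh_load_brainvol = load_brain,
      time_diff = as.numeric(.data$visit_date_followup -
                               .data$visit_date_baseline) / 365.25,
      bp_band_sbp_baseline = assign_bp_band(.data$sbp_baseline, "sbp"),
      bp_band_dbp_baseline = assign_bp_band(.data$dbp_baseline, "dbp"),
      bp_band_sbp_followup = assign_bp_band(.data$sbp_followup, "sbp"),
      bp_band_dbp_followup = assign_bp_band(.data$dbp_followup, "dbp"),
      age_group_baseline = assign_age_group(.data$age_baseline, "baseline"),
      age_group_followup = assign_age_group(.data$age_followup, "followup"),
      smoking_baseline = factor(.data$smoking_baseline,
                                levels = c("never", "ex", "active")),
      smoking_followup = factor(.data$smoking_followup,
                                levels = c("never", "ex", "active")),
      sex = factor(.data$sex, levels = c("male", "female"))
    ) |>
    dplyr::select(-"exclusion_flag")

  if (cohort == "longitudinal" && any(analysis$time_diff <= 0)) {
    abort("Non-positive follow-up interval: check visit dates.")
  }

  list(analysis = analysis, audit = audit)
}

#' @rdname derive_analysis
#' @export
apply_eligibility <- derive_analysis
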
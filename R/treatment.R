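# Hypertension/treatment categories: stratify by BP severity category
# crossed with antihypertensive medication, and contrast each category's
# logit WMH load against unmedicated participants in the lowest category.

severity_levels <- c("low_range_nt", "high_range_nt", "pre_ht", "ht")

treatment_levels <- as.vector(outer(severity_levels,
                                    c("unmedicated", "medicated"),
                                    paste, sep = ":"))

#' Assign the hypertension/treatment category
#'
#' BP severity is graded on both pressures with the standard left-closed
#' bands and resolved by the *maximum* severity (an "or" rule): lowest
#' category requires SBP <120 *and* DBP <70 mmHg; SBP 120-130 or DBP
#' 70-80 is high-range normotensive (or well-controlled hypertensive if
#' medicated); SBP 130-140 or DBP 80-90 is pre-hypertensive (or
#' controlled); SBP >=140 or DBP >=90 is hypertensive (untreated or
#' uncontrolled). The severity grade is crossed with the medication flag.
#'
#' @param sbp,dbp Pressures, mmHg (positive, finite; `NA` propagates).
#' @param medicated Logical, on antihypertensive medication.
#' @return Factor over the eight `severity:medication` categories.
#' @examples
#' assign_treatment_category(118, 68, FALSE)  # low_range_nt:unmedicated
#' assign_treatment_category(125, 92, FALSE)  # ht:unmedicated (DBP >= 90)
#' @export
assign_treatment_category <- function(sbp, dbp, medicated) {
  sev <- pmax(as.integer(assign_bp_band(sbp, "sbp")),
              as.integer(assign_bp_band(dbp, "dbp")))
  med <- ifelse(medicated, "medicated", "unmedicated")
  factor(ifelse(is.na(sev) | is.na(med), NA,
                paste(severity_levels[sev], med, sep = ":")),
         levels = treatment_levels)
}

#' Contrast treatment categories against unmedicated normotensives
#'
#' Computes per-category (and per age group) medians and interquartile
#' ranges of logit WMH load, and formally contrasts each category against
#' the reference — unmedicated participants with SBP <120 and DBP <70
#' mmHg — with a multivariable linear model adjusted for decade of age
#' (`floor(age / 10)`), sex, arterial stiffness index, smoking status,
#' diabetes, assessment centre, and the between-visit interval for the
#' longitudinal (`timing = "past"`) analysis. Categories and medication
#' are taken from the visit matching `timing`.
#'
#' @param data Analysis tibble from [derive_analysis()].
#' @param timing `"past"` (baseline BP and medication; the primary
#'   longitudinal view) or `"concurrent"` (follow-up visit).
#' @return A `treatment_contrasts` object with `medians` (category x age
#'   group: `n`, `median`, `q25`, `q75` of logit load) and `contrasts`
#'   (per category vs. reference: estimate, 95% CI, `n`). [tidy()]
#'   returns the contrasts; [autoplot()] draws the category boxes.
#' @export
compare_to_reference <- function(data, timing = c("past", "concurrent")) {
  timing <- match.arg(timing)
  suffix <- if (timing == "past") "baseline" else "followup"
  col <- function(stem) data[[paste0(stem, "_", suffix)]]
  df <- tibble::tibble(
    wmh_logit = data$wmh_logit,
    category = assign_treatment_category(col("sbp"), col("dbp"),
                                         col("antihypertensive")),
    age = col("age"), sex = data$sex, asi = col("asi"),
    smoking = col("smoking"), diabetes = col("diabetes"),
    centre = data$centre,
    age_group = data[[paste0("age_group_", suffix)]]
  )
  if (timing == "past") df$time_diff <- data$time_diff
  covs <- c("age_decade", "sex", "asi", "smoking", "diabetes", "centre",
            if (timing == "past") "time_diff")
  df$age_decade <- floor(df$age / 10)
  use <- complete.cases(df[, c("wmh_logit", "category", covs)])
  df <- df[use, , drop = FALSE]
  if (!any(df$category == treatment_levels[1], na.rm = TRUE)) {
    abort("Reference category (unmedicated, SBP <120 and DBP <70) is empty.")
  }

  medians <- df |>
    dplyr::group_by(.data$age_group, .data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$wmh_logit),
      q25 = quantile(.data$wmh_logit, 0.25, names = FALSE),
      q75 = quantile(.data$wmh_logit, 0.75, names = FALSE),
      .groups = "drop"
    )

  df$category <- factor(as.character(df$category), levels = treatment_levels)
  covs_kept <- drop_constant_terms(df, covs)
  fit <- lm(as.formula(paste("wmh_logit ~",
                             paste(c("category", covs_kept),
                                   collapse = " + "))),
            data = df)
  check_not_aliased(fit)
  cf <- coef(fit); ci <- confint(fit)
  idx <- grep("^category", names(cf))
  contrasts <- tibble::tibble(
    category = sub("^category", "", names(cf)[idx]),
    estimate = unname(cf[idx]), conf.low = ci[idx, 1], conf.high = ci[idx, 2],
    n = length(fit$residuals)
  )
  structure(
    list(timing = timing, medians = medians, contrasts = contrasts,
         reference = treatment_levels[1],
         category_counts = dplyr::count(df, .data$category)),
    class = "treatment_contrasts"
  )
}

#' @export
print.treatment_contrasts <- function(x, ...) {
  cat(sprintf("<treatment_contrasts> timing = %s, reference = %s\n",
              x$timing, x$reference))
  print(x$contrasts)
  invisible(x)
}

#' @describeIn compare_to_reference Adjusted contrasts of each category
#'   against the unmedicated lowest-BP reference.
#' @param x A `treatment_contrasts`.
#' @param ... Unused.
#' @export
tidy.treatment_contrasts <- function(x, ...) x$contrasts
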
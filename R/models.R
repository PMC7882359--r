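# Linear models of logit WMH load on concurrent or past BP:
# unadjusted, age-sex adjusted, and fully adjusted, with standardized
# and per-mmHg effects, stratified fits and sex interactions.

#' Z-score continuous variables on the analysis sample
#'
#' Replaces each listed variable by `(x - mean) / sd`, with moments taken
#' on the rows of `data` itself (the fitted sample). Binary and
#' categorical variables should not be listed: indicator coefficients are
#' left in outcome-SD units per level.
#'
#' @param data A data frame.
#' @param variables Character vector of continuous column names.
#' @return `data` with the listed columns standardized.
#' @export
standardize <- function(data, variables) {
  for (v in variables) {
    if (!v %in% names(data)) abort(sprintf("Unknown variable `%s`.", v))
    x <- data[[v]]
    if (!is.numeric(x)) abort(sprintf("Variable `%s` is not numeric.", v))
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      abort(sprintf("Variable `%s` has zero variance; cannot standardize.", v))
    }
    data[[v]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  data
}

# timing-specific model frame with generic column names
model_frame_for_timing <- function(data, timing) {
  suffix <- if (timing == "concurrent") "followup" else "baseline"
  col <- function(stem) data[[paste0(stem, "_", suffix)]]
  mf <- tibble::tibble(
    wmh_logit = data$wmh_logit,
    sbp = col("sbp"), dbp = col("dbp"), age = col("age"),
    sex = data$sex, asi = col("asi"),
    smoking = col("smoking"), diabetes = col("diabetes"),
    bp_source = col("bp_source"), centre = data$centre
  )
  if (timing == "past") mf$time_diff <- data$time_diff
  mf
}

continuous_model_vars <- function(timing) {
  c("wmh_logit", "sbp", "dbp", "age", "asi",
    if (timing == "past") "time_diff")
}

# most frequent level as reference for unordered categoricals
relevel_mode <- function(x) {
  f <- factor(as.character(x))
  stats::relevel(f, ref = names(sort(table(f), decreasing = TRUE))[1])
}

check_not_aliased <- function(fit) {
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(aliased)) {
    abort(paste0("Rank-deficient design; collinear term(s): ",
                 paste(aliased, collapse = ", ")))
  }
  invisible(fit)
}

pretty_terms <- function(terms) {
  terms <- sub("^sexfemale$", "sex_female", terms)
  terms <- sub("^smokingex$", "smoking_ex", terms)
  terms <- sub("^smokingactive$", "smoking_active", terms)
  terms <- sub("^diabetesTRUE$", "diabetes", terms)
  terms <- gsub(":sexfemale$", ":sex_female", terms)
  terms
}

estimates_from_lm <- function(fit, terms = NULL, conf_level = 0.95) {
  check_not_aliased(fit)
  cf <- coef(fit)
  ci <- suppressMessages(confint(fit, level = conf_level))
  keep <- setdiff(names(cf), "(Intercept)")
  if (!is.null(terms)) keep <- intersect(names(cf), terms)
  tibble::tibble(
    term = pretty_terms(keep),
    estimate = unname(cf[keep]),
    conf.low = ci[keep, 1],
    conf.high = ci[keep, 2],
    n = length(fit$residuals)
  )
}

full_adjustment_rhs <- function(timing, drop = character()) {
  rhs <- c("sbp", "dbp", "age", "sex", "asi", "smoking", "diabetes",
           "bp_source", "centre", if (timing == "past") "time_diff")
  setdiff(rhs, drop)
}

# drop constant factors (e.g. a single centre) so lm keeps full rank
drop_constant_terms <- function(mf, rhs) {
  keep <- vapply(rhs, function(v) {
    x <- mf[[v]]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))
  rhs[keep]
}

fit_one <- function(mf, rhs, standardized, timing) {
  base_vars <- unique(unlist(strsplit(rhs, ":", fixed = TRUE)))
  use <- complete.cases(mf[, c("wmh_logit", base_vars)])
  mfc <- mf[use, , drop = FALSE]
  kept <- drop_constant_terms(mfc, base_vars)
  rhs <- rhs[vapply(strsplit(rhs, ":", fixed = TRUE),
                    function(v) all(v %in% kept), logical(1))]
  if (standardized) {
    cont <- intersect(continuous_model_vars(timing), c("wmh_logit", rhs))
    mfc <- standardize(mfc, cont)
  }
  for (v in intersect(c("bp_source", "centre"), rhs)) {
    mfc[[v]] <- relevel_mode(mfc[[v]])
  }
  p <- length(rhs) + 1
  if (nrow(mfc) <= p) {
    abort(sprintf("Too few rows (%d) for %d model terms.", nrow(mfc), p))
  }
  fit <- lm(as.formula(paste("wmh_logit ~", paste(rhs, collapse = " + "))),
            data = mfc)
  check_not_aliased(fit)
  fit
}

#' Fit linear models of logit WMH load on blood pressure
#'
#' Reproduces the three adjustment tiers of the analysis. With
#' `adjustment = "unadjusted"` each exposure is fit alone; with
#' `"age_sex"` each exposure is fit with age and sex; with `"full"` a
#' single model enters SBP and DBP jointly together with age, sex,
#' arterial stiffness index, smoking (never/ex/active indicators),
#' diabetes, BP source, and assessment centre — plus the between-visit
#' interval when `timing = "past"`. `timing` selects which visit supplies
#' the exposures and covariates: `"concurrent"` uses the imaging
#' (follow-up) visit, `"past"` the baseline visit.
#'
#' When `standardized = TRUE` the outcome and continuous predictors are
#' z-scored on the fitted sample, so coefficients are in outcome-SD per
#' predictor-SD units; binary and categorical indicators are left
#' unscaled (their coefficients are outcome-SDs per level). Fits are
#' ordinary least squares with normal-theory 95% confidence intervals,
#' complete-case on the model's variables.
#'
#' @param data Analysis tibble from [derive_analysis()].
#' @param exposures Exposure terms to report; any of `"sbp"`, `"dbp"`,
#'   `"asi"`, `"age"`, `"sex"`, `"diabetes"`, `"smoking"` (the latter
#'   four only for `adjustment = "unadjusted"`).
#' @param adjustment `"unadjusted"`, `"age_sex"`, or `"full"`.
#' @param timing `"concurrent"` or `"past"`.
#' @param standardized Z-score outcome and continuous predictors.
#' @return A `wmh_fit` object; use [tidy()] for term estimates with 95%
#'   CIs, [glance()] for fit-level summaries, [per_unit_ratios()] (on an
#'   unstandardized full fit) for multiplicative per-10/per-5 mmHg
#'   effects.
#' @export
fit_wmh_model <- function(data,
                          exposures = c("sbp", "dbp"),
                          adjustment = c("full", "age_sex", "unadjusted"),
                          timing = c("concurrent", "past"),
                          standardized = TRUE) {
  adjustment <- match.arg(adjustment)
  timing <- match.arg(timing)
  mf <- model_frame_for_timing(data, timing)
  allowed <- c("sbp", "dbp", "asi", "age", "sex", "diabetes", "smoking",
               if (timing == "past") "time_diff")
  bad <- setdiff(exposures, allowed)
  if (length(bad)) {
    abort(paste0("Unknown exposure(s): ", paste(bad, collapse = ", ")))
  }

  if (adjustment == "full") {
    rhs <- union(full_adjustment_rhs(timing), exposures)
    fits <- list(full = fit_one(mf, rhs, standardized, timing))
  } else {
    fits <- lapply(setNames(exposures, exposures), function(x) {
      rhs <- if (adjustment == "unadjusted") x else union(x, c("age", "sex"))
      if (adjustment == "age_sex" && x %in% c("age", "sex")) {
        abort("Age and sex are the adjustment itself; use adjustment = 'unadjusted'.")
      }
      fit_one(mf, rhs, standardized, timing)
    })
  }
  structure(
    list(fits = fits, exposures = exposures, adjustment = adjustment,
         timing = timing, standardized = standardized),
    class = "wmh_fit"
  )
}

#' @export
print.wmh_fit <- function(x, ...) {
  cat(sprintf("<wmh_fit> %s, %s, %s coefficients\n", x$timing, x$adjustment,
              if (x$standardized) "standardized" else "per-mmHg"))
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_wmh_model Term-level estimates: `term`, `estimate`,
#'   `conf.low`, `conf.high`, `scale`, `n`. For single-exposure tiers,
#'   one row per exposure from its own model; for the full tier, all
#'   model terms.
#' @param x,object A `wmh_fit`.
#' @param ... Unused.
#' @export
tidy.wmh_fit <- function(x, ...) {
  scale_lab <- if (x$standardized) "standardized" else "per_mmHg"
  out <- if (x$adjustment == "full") {
    estimates_from_lm(x$fits$full)
  } else {
    purrr::list_rbind(purrr::imap(x$fits, function(f, nm) {
      term_map <- c(sex = "sexfemale", diabetes = "diabetesTRUE",
                    smoking = "smoking")
      want <- if (nm == "smoking") c("smokingex", "smokingactive")
              else c(nm, unname(term_map[nm]))
      estimates_from_lm(f, terms = want[!is.na(want)])
    }))
  }
  out$scale <- scale_lab
  out[, c("term", "estimate", "conf.low", "conf.high", "scale", "n")]
}

#' @describeIn fit_wmh_model One row per fitted model: adjustment,
#'   timing, scale, `n`, `r.squared`, `sigma`.
#' @export
glance.wmh_fit <- function(x, ...) {
  purrr::list_rbind(purrr::imap(x$fits, function(f, nm) {
    s <- summary(f)
    tibble::tibble(
      model = nm, adjustment = x$adjustment, timing = x$timing,
      standardized = x$standardized, n = length(f$residuals),
      r.squared = s$r.squared, sigma = s$sigma
    )
  }))
}

#' Multiplicative WMH-load ratio per BP unit
#'
#' Converts a per-mmHg coefficient from the logit-load model into a
#' multiplicative load ratio per conventional reporting unit: 10 mmHg
#' for SBP, 5 mmHg for DBP. At small loads the logit and log scales
#' coincide, so `exp(beta * unit)` is the multiplicative change in WMH
#' load per unit of BP.
#'
#' @param beta_per_mmHg Coefficient(s) per mmHg on the logit-load scale.
#' @param unit mmHg per reporting unit (10 for SBP, 5 for DBP).
#' @return `exp(beta_per_mmHg * unit)`.
#' @examples
#' effect_ratio_per_unit(0.00402, 10)  # about 1.041
#' @export
effect_ratio_per_unit <- function(beta_per_mmHg, unit) {
  check_finite(beta_per_mmHg, "beta_per_mmHg")
  check_finite(unit, "unit")
  exp(beta_per_mmHg * unit)
}

#' @describeIn effect_ratio_per_unit Per-unit ratios with CIs from an
#'   unstandardized full [fit_wmh_model()] fit: SBP per 10 mmHg, DBP per
#'   5 mmHg, CI endpoints transformed the same way.
#' @param fit An unstandardized (`standardized = FALSE`) full `wmh_fit`.
#' @export
per_unit_ratios <- function(fit) {
  if (!inherits(fit, "wmh_fit") || fit$standardized ||
      fit$adjustment != "full") {
    abort("`fit` must be an unstandardized full-adjustment wmh_fit.")
  }
  est <- tidy(fit)
  est <- est[est$term %in% c("sbp", "dbp"), ]
  unit <- ifelse(est$term == "sbp", 10, 5)
  tibble::tibble(
    term = est$term,
    unit_mmHg = unit,
    ratio = effect_ratio_per_unit(est$estimate, unit),
    conf.low = effect_ratio_per_unit(est$conf.low, unit),
    conf.high = effect_ratio_per_unit(est$conf.high, unit),
    scale = ifelse(est$term == "sbp", "ratio_per_10mmHg_sbp",
                   "ratio_per_5mmHg_dbp"),
    n = est$n
  )
}

#' Stratified fully adjusted fits
#'
#' Refits the fully adjusted model independently within strata of age
#' group (the timing-matched scheme), sex, or follow-up duration (median
#' split of `time_diff` into `<= median` vs `> median`). The stratifying
#' variable is removed from that fit's adjustment set (age for age-group
#' strata, sex for sex strata, the interval for duration strata). Strata
#' too small to support the model are skipped with a warning and listed
#' in the result.
#'
#' @inheritParams fit_wmh_model
#' @param by `"age_group"`, `"sex"`, or `"duration"`.
#' @return A `wmh_fit_stratified` object; [tidy()] gives estimates with a
#'   `stratum` column.
#' @export
fit_stratified <- function(data,
                           by = c("age_group", "sex", "duration"),
                           exposures = c("sbp", "dbp"),
                           timing = c("concurrent", "past"),
                           standardized = TRUE) {
  by <- match.arg(by)
  timing <- match.arg(timing)
  strat_var <- switch(
    by,
    age_group = if (timing == "concurrent") data$age_group_followup
                else data$age_group_baseline,
    sex = data$sex,
    duration = {
      med <- median(data$time_diff, na.rm = TRUE)
      factor(ifelse(data$time_diff <= med, "short", "long"),
             levels = c("short", "long"))
    }
  )
  drop <- switch(by, age_group = "age", sex = "sex", duration = "time_diff")
  levels_ <- levels(strat_var)
  fits <- list(); skipped <- character()
  for (lev in levels_) {
    sub <- data[!is.na(strat_var) & strat_var == lev, , drop = FALSE]
    mf <- model_frame_for_timing(sub, timing)
    rhs <- union(full_adjustment_rhs(timing, drop = drop), exposures)
    rhs <- setdiff(rhs, drop)
    res <- tryCatch(fit_one(mf, rhs, standardized, timing),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("Stratum '%s' skipped: %s", lev, conditionMessage(res)))
      skipped <- c(skipped, lev)
    } else {
      fits[[lev]] <- res
    }
  }
  structure(
    list(fits = fits, by = by, skipped = skipped, exposures = exposures,
         timing = timing, standardized = standardized),
    class = "wmh_fit_stratified"
  )
}

#' @describeIn fit_stratified Estimates per stratum for the exposure
#'   terms.
#' @param x A `wmh_fit_stratified`.
#' @param ... Unused.
#' @export
tidy.wmh_fit_stratified <- function(x, ...) {
  scale_lab <- if (x$standardized) "standardized" else "per_mmHg"
  purrr::list_rbind(purrr::imap(x$fits, function(f, lev) {
    est <- estimates_from_lm(f, terms = x$exposures)
    est$stratum <- lev
    est$scale <- scale_lab
    est[, c("stratum", "term", "estimate", "conf.low", "conf.high",
            "scale", "n")]
  }))
}

#' Test an exposure-by-sex interaction in the fully adjusted model
#'
#' Adds an exposure x sex product term to the fully adjusted model and
#' reports its coefficient with a 95% CI. A nonzero interaction means the
#' BP-WMH slope differs between men and women.
#'
#' @inheritParams fit_wmh_model
#' @param exposure `"sbp"` or `"dbp"`.
#' @return One-row tibble: `term`, `estimate`, `conf.low`, `conf.high`,
#'   `scale`, `n`.
#' @export
interaction_test <- function(data,
                             exposure = c("sbp", "dbp"),
                             timing = c("concurrent", "past"),
                             standardized = TRUE) {
  exposure <- match.arg(exposure)
  timing <- match.arg(timing)
  if (length(unique(stats::na.omit(as.character(data$sex)))) < 2) {
    abort("Both sexes must be present for an interaction test.")
  }
  mf <- model_frame_for_timing(data, timing)
  rhs <- c(full_adjustment_rhs(timing), paste0(exposure, ":sex"))
  fit <- fit_one(mf, rhs, standardized, timing)
  est <- estimates_from_lm(fit)
  est <- est[grepl(":", est$term), ]
  est$scale <- if (standardized) "standardized" else "per_mmHg"
  est[, c("term", "estimate", "conf.low", "conf.high", "scale", "n")]
}
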
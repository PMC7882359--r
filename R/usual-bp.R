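# Usual-BP analysis: stratify by baseline BP band and age group, estimate
# each stratum's long-term ("usual") BP from the mean follow-up BP of its
# members, and regress log median-WMH ratios on usual BP. Because strata
# are defined at baseline but characterized by a later measurement, the
# stratum means shrink toward the population mean exactly as the
# participants' long-term pressures do, correcting the regression
# dilution that attenuates naive single-measurement slopes.

# integer stratum key: age_idx * 10 + band_idx (both 1-based)
stratum_key <- function(age_group, band) {
  as.integer(age_group) * 10L + as.integer(band)
}

# per-stratum n / mean follow-up BP / median load, dropping strata below
# min_n except the reference, which must be present (NULL when absent)
stratum_stats <- function(key, fu_bp, load, min_n, ref_key) {
  counts <- table(key)
  keys <- as.integer(names(counts))
  n <- as.integer(counts)
  keep <- n >= min_n | keys == ref_key
  if (!(ref_key %in% keys)) return(NULL)
  keys <- keys[keep]; n <- n[keep]
  grp <- split(seq_along(key), key)[as.character(keys)]
  usual <- vapply(grp, function(i) mean(fu_bp[i]), numeric(1))
  med <- vapply(grp, function(i) median(load[i]), numeric(1))
  list(key = keys, n = n, usual_bp = unname(usual), median_wmh = unname(med),
       log_ratio = unname(log(med) - log(med[keys == ref_key])))
}

# unweighted (or n-weighted) slope of log_ratio on usual_bp; NA when
# fewer than two strata or no spread
slope_of <- function(st, sel, weighted) {
  x <- st$usual_bp[sel]; y <- st$log_ratio[sel]
  if (length(x) < 2 || sd(x) == 0) return(NA_real_)
  if (weighted) {
    w <- st$n[sel]
    xm <- sum(w * x) / sum(w); ym <- sum(w * y) / sum(w)
    sum(w * (x - xm) * (y - ym)) / sum(w * (x - xm)^2)
  } else {
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
}

# slopes for every scope: overall plus each baseline age group
scope_slopes <- function(st, age_levels, weighted) {
  ages <- st$key %/% 10L
  out <- c(overall = slope_of(st, rep(TRUE, length(st$key)), weighted))
  for (a in seq_along(age_levels)) {
    out[age_levels[a]] <- slope_of(st, ages == a, weighted)
  }
  out
}

#' Build age-by-BP strata with usual BP and median WMH load
#'
#' Participants are stratified by baseline age group and baseline BP band
#' (see [assign_bp_band()], [assign_age_group()]). Each stratum's usual
#' BP is the mean follow-up BP of its members — a less biased estimate of
#' the stratum's long-term pressure than the baseline value that defined
#' it. Median WMH load per stratum is expressed as a ratio to the
#' reference stratum: normotensive participants (lowest band, SBP <120 or
#' DBP <70 mmHg) in the youngest baseline age group (<50 years).
#'
#' @param data Analysis tibble from [derive_analysis()] (longitudinal).
#' @param which `"sbp"` or `"dbp"`: which pressure defines the bands and
#'   the usual value.
#' @param min_n Minimum stratum size; smaller strata are dropped (the
#'   reference stratum is always retained and must be non-empty).
#' @param exclude_medicated Drop participants on antihypertensive
#'   medication at baseline (sensitivity analysis).
#' @param bp `"usual"` (default: stratum mean *follow-up* BP) or
#'   `"baseline"` (stratum mean baseline BP — the naive, dilution-biased
#'   variant used for comparison).
#' @return A tibble of stratum summaries: `age_group`, `bp_band`,
#'   `which`, `n`, `usual_bp`, `median_wmh`, `ratio_to_reference`,
#'   `log_ratio`.
#' @export
build_strata <- function(data, which = c("sbp", "dbp"), min_n = 20,
                         exclude_medicated = FALSE,
                         bp = c("usual", "baseline")) {
  which <- match.arg(which)
  bp <- match.arg(bp)
  if (exclude_medicated) data <- data[!data$antihypertensive_baseline, ]
  band <- data[[paste0("bp_band_", which, "_baseline")]]
  age <- data$age_group_baseline
  ok <- !is.na(band) & !is.na(age) & !is.na(data$wmh_load)
  data <- data[ok, ]; band <- band[ok]; age <- age[ok]
  fu <- data[[paste0(which, "_", if (bp == "usual") "followup" else "baseline")]]
  key <- stratum_key(age, band)
  ref_key <- stratum_key(factor(levels(age)[1], levels = levels(age)),
                         factor(levels(band)[1], levels = levels(band)))
  st <- stratum_stats(key, fu, data$wmh_load, min_n, ref_key)
  if (is.null(st)) {
    abort("Reference stratum (youngest age group, lowest BP band) is empty.")
  }
  tibble::tibble(
    age_group = factor(levels(age)[st$key %/% 10L], levels = levels(age)),
    bp_band = factor(levels(band)[st$key %% 10L], levels = levels(band)),
    which = which, n = st$n, usual_bp = st$usual_bp,
    median_wmh = st$median_wmh,
    ratio_to_reference = exp(st$log_ratio), log_ratio = st$log_ratio
  )
}

#' Regress log median-WMH ratios on usual BP across strata
#'
#' Unweighted least squares of each stratum's log median-load ratio on
#' its usual BP, either across all strata (`scope = "overall"`) or within
#' one baseline age group. The slope is a log median-load ratio per mmHg;
#' it is reported multiplicatively per 10 mmHg for SBP and per 5 mmHg for
#' DBP.
#'
#' @param strata Stratum table from [build_strata()].
#' @param scope `"overall"` or one of the baseline age-group labels.
#' @param weighted Weight strata by size (off by default; the primary
#'   analysis treats strata as equal observations).
#' @return One-row tibble: `which`, `scope`, `n_strata`,
#'   `slope_per_mmHg`, `ratio_per_unit`, `unit_mmHg`.
#' @export
fit_log_ratio_regression <- function(strata, scope = "overall",
                                     weighted = FALSE) {
  which <- strata$which[1]
  unit <- if (which == "sbp") 10 else 5
  sel <- if (identical(scope, "overall")) rep(TRUE, nrow(strata))
         else strata$age_group == scope
  if (sum(sel) < 2) abort("Need at least two strata in scope.")
  st <- list(usual_bp = strata$usual_bp, log_ratio = strata$log_ratio,
             n = strata$n)
  slope <- slope_of(st, sel, weighted)
  if (is.na(slope)) abort("No spread in usual BP across strata in scope.")
  tibble::tibble(
    which = which, scope = as.character(scope), n_strata = sum(sel),
    slope_per_mmHg = slope, ratio_per_unit = exp(slope * unit),
    unit_mmHg = unit
  )
}

#' Usual-BP analysis with non-parametric bootstrap confidence intervals
#'
#' Runs the full regression-dilution-corrected pipeline: build baseline
#' age x BP strata, estimate usual BP and median-load ratios, fit the
#' log-ratio regression overall and within each age group, and bootstrap
#' the whole procedure — participants resampled with replacement, strata
#' and medians recomputed each replicate — to percentile 95% intervals on
#' the per-unit ratio scale. Replicates whose reference stratum comes up
#' empty are redrawn (the count is reported); the run errors if more than
#' 10% of replicates fail to yield a slope for the overall scope.
#'
#' @inheritParams build_strata
#' @param n_boot Number of bootstrap replicates (>= 2; use >= 1000 for
#'   reporting).
#' @param seed Integer seed; the analysis is deterministic given it.
#' @param weighted Weight strata by size in the regression.
#' @return A `usual_bp_fit`: `strata` (the point-estimate stratum table)
#'   and `fits` (per scope: slope, per-unit ratio with bootstrap CI,
#'   `n_boot`, redraw count). [tidy()] returns `fits`; [autoplot()]
#'   draws the stratum ratios on a log scale with fitted lines.
#' @export
usual_bp_analysis <- function(data, which = c("sbp", "dbp"),
                              n_boot = 1000, seed = 1, min_n = 20,
                              exclude_medicated = FALSE, weighted = FALSE,
                              bp = c("usual", "baseline")) {
  which <- match.arg(which)
  bp <- match.arg(bp)
  if (n_boot < 2) abort("`n_boot` must be at least 2.")
  if (exclude_medicated) data <- data[!data$antihypertensive_baseline, ]

  band <- data[[paste0("bp_band_", which, "_baseline")]]
  age <- data$age_group_baseline
  ok <- !is.na(band) & !is.na(age) & !is.na(data$wmh_load)
  band <- band[ok]; age <- age[ok]
  fu <- data[[paste0(which, "_", if (bp == "usual") "followup" else "baseline")]][ok]
  load <- data$wmh_load[ok]
  key <- stratum_key(age, band)
  ref_key <- stratum_key(factor(levels(age)[1], levels = levels(age)),
                         factor(levels(band)[1], levels = levels(band)))
  age_levels <- levels(age)
  unit <- if (which == "sbp") 10 else 5

  st0 <- stratum_stats(key, fu, load, min_n, ref_key)
  if (is.null(st0)) {
    abort("Reference stratum (youngest age group, lowest BP band) is empty.")
  }
  point <- scope_slopes(st0, age_levels, weighted)

  n <- length(key)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = length(point),
                 dimnames = list(NULL, names(point)))
  n_redrawn <- 0L
  withr::with_seed(stage_seed(seed, "usualbp_boot"), {
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      st <- stratum_stats(key[idx], fu[idx], load[idx], min_n, ref_key)
      if (is.null(st)) {
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 10L * n_boot) {
          abort("Reference stratum empty in too many bootstrap replicates.")
        }
        next
      }
      boot[b, ] <- scope_slopes(st, age_levels, weighted)
      b <- b + 1L
    }
  })
  fail_rate <- mean(is.na(boot[, "overall"]))
  if (fail_rate > 0.10) {
    abort(sprintf(
      "Usual-BP estimator failed in %.0f%% of bootstrap replicates.",
      100 * fail_rate
    ))
  }

  fits <- purrr::list_rbind(purrr::map(names(point), function(sc) {
    reps <- boot[, sc]
    ci <- if (all(is.na(reps))) c(NA_real_, NA_real_) else {
      quantile(exp(reps * unit), c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    }
    tibble::tibble(
      which = which, scope = sc, slope_per_mmHg = point[[sc]],
      ratio_per_unit = exp(point[[sc]] * unit), unit_mmHg = unit,
      ci_low = ci[1], ci_high = ci[2],
      n_boot = n_boot, n_boot_failed = sum(is.na(reps))
    )
  }))

  strata <- tibble::tibble(
    age_group = factor(age_levels[st0$key %/% 10L], levels = age_levels),
    bp_band = factor(levels(band)[st0$key %% 10L], levels = levels(band)),
    which = which, n = st0$n, usual_bp = st0$usual_bp,
    median_wmh = st0$median_wmh,
    ratio_to_reference = exp(st0$log_ratio), log_ratio = st0$log_ratio
  )
  structure(
    list(which = which, unit_mmHg = unit, strata = strata, fits = fits,
         n = n, n_boot = n_boot, n_redrawn = n_redrawn, seed = seed,
         bp = bp),
    class = "usual_bp_fit"
  )
}

#' @export
print.usual_bp_fit <- function(x, ...) {
  cat(sprintf("<usual_bp_fit> %s, %d participants, %d strata, %d bootstrap replicates\n",
              toupper(x$which), x$n, nrow(x$strata), x$n_boot))
  print(x$fits)
  invisible(x)
}

#' @describeIn usual_bp_analysis Per-scope slope and per-unit ratio with
#'   bootstrap CI.
#' @param x,object A `usual_bp_fit`.
#' @param ... Unused.
#' @export
tidy.usual_bp_fit <- function(x, ...) x$fits

#' @describeIn usual_bp_analysis One-row summary of the overall fit.
#' @export
glance.usual_bp_fit <- function(x, ...) {
  ov <- x$fits[x$fits$scope == "overall", ]
  tibble::tibble(
    which = x$which, n = x$n, n_strata = nrow(x$strata),
    ratio_per_unit = ov$ratio_per_unit, ci_low = ov$ci_low,
    ci_high = ov$ci_high, n_boot = x$n_boot, n_redrawn = x$n_redrawn
  )
}
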
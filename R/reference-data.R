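#' Published baseline characteristics of the UK Biobank WMH cohort
#'
#' The printed summary table of the UK Biobank imaging substudy used
#' throughout this package as a calibration target for the synthetic
#' generator and as an internal-consistency input: means (SD in the
#' source, not carried here) for continuous measures and counts for
#' binary ones, at the baseline and imaging (follow-up) visits of the
#' longitudinal set, the printed between-visit difference, and the
#' cross-sectional set.
#'
#' Means are as printed (2 decimal places), so derived identities such as
#' pulse pressure = SBP - DBP hold only to printed precision (about 0.015
#' after two roundings). Count differences are exact integers.
#'
#' @return A tibble with columns `variable`, `baseline`, `followup`,
#'   `difference` (printed between-visit change, `NA` where the source
#'   prints none), `cross_sectional`, and `type` (`"mean"` or `"count"`).
#' @export
ukb_baseline_characteristics <- function() {
  tibble::tribble(
    ~variable,            ~baseline, ~followup, ~difference, ~cross_sectional, ~type,
    "n",                      37026,     37026,          NA,            37041, "count",
    "age_years",              55.29,     64.12,        8.84,            64.12, "mean",
    "female_n",               19624,        NA,          NA,            19635, "count",
    "height_cm",              169.6,    169.07,       -0.54,           169.07, "mean",
    "weight_kg",              76.57,     75.93,       -0.69,            75.94, "mean",
    "bmi",                    26.53,     26.47,       -0.06,            26.48, "mean",
    "diabetes_n",               908,        NA,          NA,             1855, "count",
    "ex_smoker_n",            12057,     12332,         275,            12334, "count",
    "active_smoker_n",         2278,      1255,       -1023,             1256, "count",
    "sbp_mmHg",              134.81,    138.26,        3.45,           138.26, "mean",
    "dbp_mmHg",               81.39,     77.66,       -3.72,            77.66, "mean",
    "pulse_pressure_mmHg",    53.42,      60.6,        7.17,            60.59, "mean",
    "asi",                     9.07,      9.61,        0.48,             9.61, "mean",
    "antihypertensive_n",      4757,      8264,        3507,             8269, "count"
  )
}
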
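# End-to-end orchestration: simulate -> ingest -> all analyses, from one
# config, with a reproducibility manifest.

# tiny FNV-1a over a string, for config fingerprinting (not cryptographic)
fnv1a <- function(s) {
  h <- 2166136261
  for (cp in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), cp)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed for every stage.
#' @param n_participants Cohort size for the simulation stage.
#' @param n_boot Bootstrap replicates for the usual-BP stage.
#' @param min_n Minimum usual-BP stratum size.
#' @param stages Named logical list toggling `fit`, `paf`, `usual_bp`,
#'   `treatment` (simulation and ingest always run).
#' @param cohort_args Extra arguments forwarded to [cohort_config()].
#' @param write_cohort Also write the simulated visit table
#'   (`cohort.csv`).
#' @return A `run_config` list.
#' @seealso [run_pipeline()]
#' @export
run_config <- function(out_dir, seed = 1, n_participants = 5000,
                       n_boot = 200, min_n = 20,
                       stages = list(), cohort_args = list(),
                       write_cohort = FALSE) {
  stages <- utils::modifyList(
    list(fit = TRUE, paf = TRUE, usual_bp = TRUE, treatment = TRUE),
    stages
  )
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_participants = n_participants, n_boot = n_boot, min_n = min_n,
         stages = stages, cohort_args = cohort_args,
         write_cohort = write_cohort),
    class = "run_config"
  )
}

#' Run the full analysis pipeline from one configuration
#'
#' Simulates a cohort, ingests it, and runs the association models,
#' PAF, usual-BP, and treatment-category stages, writing one artifact
#' per stage into `config$out_dir`:
#'
#' * `estimates.csv` — standardized coefficients for every timing x
#'   adjustment tier plus per-unit ratios from the unstandardized full
#'   fits;
#' * `paf.json` — fully adjusted PAFs for SBP >120 and DBP >70 mmHg,
#'   concurrent and past;
#' * `usualbp.csv` and `usualbp_strata.csv` — usual-BP fits per scope
#'   and the stratum table behind them;
#' * `treatment.csv` and `treatment_medians.csv` — category contrasts
#'   and per-category medians;
#' * `audit.json` — the eligibility filter audit;
#' * `manifest.json` — seed, config echo and fingerprint, package
#'   version, and row counts, sufficient to reproduce every artifact.
#'
#' Deterministic given `config$seed`; artifacts contain no timestamps, so
#' a rerun with the same config is byte-identical.
#'
#' @param config A [run_config()], or a path to a YAML file with its
#'   fields.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    config <- do.call(run_config, cfg)
  }
  if (!inherits(config, "run_config")) {
    abort("`config` must be a run_config() or a YAML path.")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  written <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  ccfg <- stage("simulate", do.call(cohort_config, c(
    list(n_participants = config$n_participants, seed = config$seed),
    config$cohort_args
  )))
  visits <- stage("simulate", inject_missingness(generate_cohort(ccfg), ccfg))
  message(sprintf("[simulate] %d visit rows", nrow(visits)))
  if (isTRUE(config$write_cohort)) {
    written$cohort <- write_cohort_csv(visits, out("cohort.csv"))
  }

  ingest <- stage("ingest", derive_analysis(visits))
  analysis <- ingest$analysis
  message(sprintf("[ingest] %d eligible participants", nrow(analysis)))
  jsonlite::write_json(ingest$audit, out("audit.json"), dataframe = "rows",
                       pretty = TRUE)
  written$audit <- out("audit.json")

  if (isTRUE(config$stages$fit)) {
    grid <- tidyr::expand_grid(
      timing = c("concurrent", "past"),
      adjustment = c("unadjusted", "age_sex", "full")
    )
    est <- purrr::list_rbind(purrr::pmap(grid, function(timing, adjustment) {
      td <- tidy(fit_wmh_model(analysis, adjustment = adjustment,
                               timing = timing))
      td$timing <- timing; td$adjustment <- adjustment
      td
    }))
    ratios <- purrr::list_rbind(purrr::map(c("concurrent", "past"), function(tm) {
      r <- per_unit_ratios(fit_wmh_model(analysis, adjustment = "full",
                                         timing = tm, standardized = FALSE))
      tibble::tibble(term = r$term, estimate = r$ratio, conf.low = r$conf.low,
                     conf.high = r$conf.high, scale = r$scale, n = r$n,
                     timing = tm, adjustment = "full")
    }))
    readr::write_csv(dplyr::bind_rows(est, ratios), out("estimates.csv"))
    written$estimates <- out("estimates.csv")
    message(sprintf("[fit] %d estimate rows", nrow(est) + nrow(ratios)))
  }

  if (isTRUE(config$stages$paf)) {
    pafs <- tidyr::expand_grid(exposure = c("sbp", "dbp"),
                               timing = c("concurrent", "past")) |>
      purrr::pmap(function(exposure, timing) {
        estimate_paf(analysis, exposure = exposure, timing = timing,
                     adjustment = "full")
      }) |>
      purrr::list_rbind()
    jsonlite::write_json(pafs, out("paf.json"), dataframe = "rows",
                         pretty = TRUE, digits = NA)
    written$paf <- out("paf.json")
    message(sprintf("[paf] %d estimates", nrow(pafs)))
  }

  if (isTRUE(config$stages$usual_bp)) {
    ub <- purrr::map(c("sbp", "dbp"), function(w) {
      usual_bp_analysis(analysis, which = w, n_boot = config$n_boot,
                        seed = config$seed, min_n = config$min_n)
    })
    readr::write_csv(purrr::list_rbind(purrr::map(ub, tidy)), out("usualbp.csv"))
    readr::write_csv(purrr::list_rbind(purrr::map(ub, `[[`, "strata")),
                     out("usualbp_strata.csv"))
    written$usualbp <- out("usualbp.csv")
    message("[usualbp] fits for sbp and dbp written")
  }

  if (isTRUE(config$stages$treatment)) {
    tc <- compare_to_reference(analysis, timing = "past")
    readr::write_csv(tidy(tc), out("treatment.csv"))
    readr::write_csv(tc$medians, out("treatment_medians.csv"))
    written$treatment <- out("treatment.csv")
    message(sprintf("[treatment] %d contrasts", nrow(tc$contrasts)))
  }

  cfg_plain <- unclass(config)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "bpwmh",
    version = as.character(utils::packageVersion("bpwmh")),
    seed = config$seed,
    config = cfg_plain,
    config_fingerprint = fnv1a(as.character(cfg_json)),
    n_visit_rows = nrow(visits),
    n_analysis_rows = nrow(analysis),
    artifacts = names(written)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  written$manifest <- out("manifest.json")
  invisible(written)
}
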
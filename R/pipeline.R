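# End-to-end orchestration: simulate (or load) -> filter -> phase -> icc ->
# signatures -> report, with a manifest for exact re-runs.

#' Run the full analysis pipeline
#'
#' Executes the stages simulate (or load) -> healthy-visit filter -> cycle
#' phase -> variance components/ICC -> signature scans -> descriptive
#' report, writing each stage's output as CSV into `outdir` together with a
#' `manifest.json` (seed, configuration summary, package version and
#' per-stage row counts) that enables exact re-runs. Any stage failure
#' aborts with the stage name.
#'
#' @param config A [sim_config()]; used when `input_dir` is `NULL`.
#' @param input_dir Directory with `women.csv`, `visits.csv`,
#'   `measurements.csv` to analyse instead of simulating.
#' @param outdir Output directory.
#' @param seed Integer seed for the simulation stage.
#' @param exposures Exposure names to scan (see [exposure_spec()]).
#' @param adjusted Fit covariate-adjusted signature models?
#' @param normalize Normalisation for the ICC table (see [icc_scan()]).
#' @param verbose Log row counts at stage boundaries.
#' @return Invisibly, a list with the in-memory stage outputs.
#' @export
run_pipeline <- function(config = sim_config(), input_dir = NULL,
                         outdir = tempfile("cvl_run_"), seed = 1,
                         exposures = c("phase", "dmpa", "coc", "psa"),
                         adjusted = FALSE,
                         normalize = "none", verbose = TRUE) {
  say <- function(...) if (verbose) inform(paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline failed at stage '", name, "': ",
                   conditionMessage(e)))
    })
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  cohort <- if (is.null(input_dir)) {
    stage("simulate", simulate_cohort(config, seed = seed))
  } else {
    stage("load", {
      cc <- read_cohort(file.path(input_dir, "visits.csv"),
                        file.path(input_dir, "women.csv"),
                        file.path(input_dir, "measurements.csv"))
      cc$panel <- config$panel
      cc
    })
  }
  write_cohort(cohort, file.path(outdir, "cohort"))
  say("cohort: ", nrow(cohort$women), " women, ", nrow(cohort$visits),
      " scheduled visits, ", nrow(cohort$measurements), " measurements")

  flags <- stage("filter", flag_healthy_visits(cohort$visits, cohort$women))
  report <- filter_report(flags)
  readr::write_csv(report, file.path(outdir, "filter_cascade.csv"))
  say("filter cascade: ", paste(report$step, report$n, collapse = " -> "))

  phases <- stage("phase", call_cycle_phases(cohort$visits, cohort$women))
  readr::write_csv(phases, file.path(outdir, "cycle_phases.csv"))
  say("phase-assigned visits: ", sum(phases$phase != "unassigned"))

  vc <- stage("icc", icc_scan(cohort$measurements, flags, cohort$panel,
                              normalize = normalize))
  readr::write_csv(vc, file.path(outdir, "icc_table.csv"))
  isum <- icc_summary(vc$icc)
  say(sprintf("ICC: median %.3f, IQR %.3f-%.3f over %d analytes",
              isum$median, isum$q1, isum$q3, isum$n))

  scans <- stage("signatures", {
    map(exposures, function(e) {
      signature_scan(cohort, e, adjusted = adjusted, phases = phases,
                     flags = flags)
    }) %>% setNames(exposures)
  })
  for (e in exposures) {
    readr::write_csv(scans[[e]],
                     file.path(outdir, paste0("signature_", e, ".csv")))
  }

  summary_tbl <- stage("report", summarize_analytes(cohort$measurements,
                                                    flags, cohort$panel))
  readr::write_csv(summary_tbl, file.path(outdir, "analyte_summary.csv"))
  t1 <- stage("report", table1_report(cohort$women, cohort$visits,
                                      flags = flags, phases = phases))
  readr::write_csv(t1, file.path(outdir, "table1.csv"))

  manifest <- list(
    seed = seed,
    simulated = is.null(input_dir),
    input_dir = if (is.null(input_dir)) NA else input_dir,
    package_version = as.character(utils::packageVersion("cvimmune")),
    exposures = exposures,
    adjusted = adjusted,
    normalize = normalize,
    rows = list(women = nrow(cohort$women), visits = nrow(cohort$visits),
                measurements = nrow(cohort$measurements),
                healthy_visits = sum(flags$healthy),
                phase_assigned = sum(phases$phase != "unassigned"),
                analytes = nrow(vc))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, flags = flags, phases = phases, vc = vc,
                 scans = scans, summary = summary_tbl, table1 = t1,
                 cascade = report, outdir = outdir))
}
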
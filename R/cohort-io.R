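# Cohort tables: schema constants, CSV readers/writers, validation.

#' @rdname cohort_schema
#' @export
ph_strip_values <- c(3.6, 4.1, 4.4, 4.7, 5.0, 5.3, 5.6, 6.1)

.psa_levels <- c("none", "low", "high")
.hb_levels <- c("none", "25", "80", "200")
.neut_levels <- c("0", "1-10", "11-50", ">50")
.contraception_levels <- c("none", "condom", "dmpa", "coc", "other")
.censor_levels <- c("below_lloq", "quantified", "above_uloq")

.women_logical <- c("ct_pos", "ng_pos", "tv_pos")
.visit_logical <- c("attended", "menstruating", "hsv_shedding", "bv", "yeast",
                    "lymphocytes_present", "sex_past_3_days",
                    "ivp_soap", "ivp_cloth", "ivp_insert_other",
                    "ivp_insert_med", "ectopy", "colposcopy")

#' Cohort table schema
#'
#' The pipeline works on three long-format tables:
#'
#' * `women`: one row per participant — `woman_id`, `age`, `contraception`
#'   (none / condom / dmpa / coc / other), and `ct_pos`, `ng_pos`, `tv_pos`
#'   (STI tests performed at visits 1 and 12; `NA` = untested).
#' * `visits`: one row per scheduled visit — `woman_id`, `visit_index`,
#'   `study_day`, `attended`, `menstruating`, infection flags
#'   (`hsv_shedding`, `bv`, `yeast`), `psa_category`, `ph_value` (one of the
#'   pH strip colour-zone values `r toString(ph_strip_values)`),
#'   `hb_category` (ery/uL: none/25/80/200), `neutrophil_category`
#'   (per 100 WBCs: 0 / 1-10 / 11-50 / >50), `lymphocytes_present`,
#'   `sex_past_3_days`, intravaginal-practice flags (`ivp_soap`,
#'   `ivp_cloth`, `ivp_insert_other`, `ivp_insert_med`), `ectopy` and
#'   `colposcopy` (assessed at visits 1 and 12 only), and urinary `pdg` and
#'   `crt` concentrations.
#' * `measurements`: one row per (woman, visit, analyte) — `value`
#'   (concentration in the analyte's units) and `censor`
#'   (below_lloq / quantified / above_uloq).
#'
#' Files are comma-separated UTF-8 with one header row; booleans are written
#' as 0/1 and missing values as empty fields.
#'
#' @name cohort_schema
NULL

.check_tokens <- function(x, allowed, what, table) {
  bad <- which(!is.na(x) & !x %in% allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown ", what, " value(s) in ", table, " row(s) ",
                 paste(head(bad, 10), collapse = ", "), ": ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
}

#' Validate a cohort's tables
#'
#' Checks category tokens against their closed sets, pH against the strip
#' values, referential integrity of measurements (no orphan rows), and that
#' menstruating visits carry no measurement rows (no genital samples are
#' obtained during menstruation).
#'
#' @param women,visits,measurements Cohort tables (see [cohort_schema]).
#' @return `TRUE`, invisibly, or an error listing the offending rows.
#' @export
validate_cohort <- function(women, visits, measurements) {
  .check_tokens(women$contraception, .contraception_levels, "contraception", "women")
  .check_tokens(visits$psa_category, .psa_levels, "psa_category", "visits")
  .check_tokens(visits$hb_category, .hb_levels, "hb_category", "visits")
  .check_tokens(visits$neutrophil_category, .neut_levels, "neutrophil_category", "visits")
  .check_tokens(measurements$censor, .censor_levels, "censor", "measurements")
  bad_ph <- which(!is.na(visits$ph_value) &
                    !visits$ph_value %in% ph_strip_values)
  if (length(bad_ph) > 0) {
    abort(paste0("pH value(s) not on the test strip (",
                 paste(ph_strip_values, collapse = ", "),
                 ") in visits row(s): ", paste(head(bad_ph, 10), collapse = ", ")))
  }
  if (any(!women$woman_id == unique(women$woman_id)) ||
      anyDuplicated(women$woman_id) > 0) {
    abort("duplicate woman_id in women table")
  }
  orphan_w <- setdiff(visits$woman_id, women$woman_id)
  if (length(orphan_w) > 0) {
    abort(paste0("visits reference unknown woman_id: ",
                 paste(head(orphan_w, 5), collapse = ", ")))
  }
  vkey <- paste(visits$woman_id, visits$visit_index)
  mkey <- paste(measurements$woman_id, measurements$visit_index)
  orphan_m <- which(!mkey %in% vkey)
  if (length(orphan_m) > 0) {
    abort(paste0("measurement row(s) reference a visit that does not exist: rows ",
                 paste(head(orphan_m, 10), collapse = ", ")))
  }
  mens_key <- vkey[!is.na(visits$menstruating) & visits$menstruating]
  bad_mens <- which(mkey %in% mens_key)
  if (length(bad_mens) > 0) {
    abort(paste0("measurement rows exist for menstruating visits ",
                 "(no genital samples are collected during menstruation): rows ",
                 paste(head(bad_mens, 10), collapse = ", ")))
  }
  invisible(TRUE)
}

.logical_out <- function(df, cols) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- as.integer(df[[cl]])
  df
}

.logical_in <- function(df, cols) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- as.logical(df[[cl]])
  df
}

#' Read a cohort from delimited text
#'
#' Reads and cross-validates the three cohort tables (see [cohort_schema]).
#'
#' @param visits_path,women_path,measurements_path CSV file paths.
#' @return A list with elements `women`, `visits`, `measurements` (tibbles).
#' @export
read_cohort <- function(visits_path, women_path, measurements_path) {
  for (p in c(visits_path, women_path, measurements_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  women <- readr::read_csv(women_path, show_col_types = FALSE) %>%
    .logical_in(.women_logical)
  visits <- readr::read_csv(visits_path, show_col_types = FALSE) %>%
    .logical_in(.visit_logical)
  measurements <- readr::read_csv(measurements_path, show_col_types = FALSE)
  validate_cohort(women, visits, measurements)
  list(women = as_tibble(women), visits = as_tibble(visits),
       measurements = as_tibble(measurements))
}

#' Write a cohort to delimited text
#'
#' Writes `women.csv`, `visits.csv` and `measurements.csv` (and, when
#' present, the simulation truth tables) into a directory, using the file
#' dialect of [cohort_schema] (booleans as 0/1, missing as empty).
#'
#' @param cohort A list with `women`, `visits`, `measurements` (and
#'   optionally `truth`), e.g. from [simulate_cohort()] or [read_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(.logical_out(cohort$women, .women_logical),
                   file.path(dir, "women.csv"), na = "")
  readr::write_csv(.logical_out(cohort$visits, .visit_logical),
                   file.path(dir, "visits.csv"), na = "")
  readr::write_csv(cohort$measurements, file.path(dir, "measurements.csv"), na = "")
  if (!is.null(cohort$truth)) {
    readr::write_csv(.logical_out(cohort$truth$women,
                                  c("ovulatory", "has_menses")),
                     file.path(dir, "truth_women.csv"), na = "")
    readr::write_csv(.logical_out(cohort$truth$visits, "menstruating"),
                     file.path(dir, "truth_visits.csv"), na = "")
    readr::write_csv(cohort$truth$intercepts,
                     file.path(dir, "truth_intercepts.csv"), na = "")
  }
  invisible(dir)
}
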
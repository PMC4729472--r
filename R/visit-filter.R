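# Healthy-visit filter cascade and intravaginal-practice comparison sets.

.exclusion_order <- c("not_attended", "menstruating", "woman_sti",
                      "woman_sti_indeterminate", "hsv_shedding", "bv", "yeast")

#' Flag healthy visits
#'
#' A visit is *healthy* iff it was attended, the woman was not menstruating,
#' the visit was negative for HSV shedding, bacterial vaginosis and yeast,
#' and the woman tested negative for C. trachomatis, N. gonorrhoeae and
#' T. vaginalis at both the first and last visit (a positive at either visit
#' excludes all of the woman's visits). Women with missing STI results are
#' excluded conservatively and flagged indeterminate.
#'
#' The first matching exclusion reason is recorded in the fixed order:
#' attendance, menstruation, woman-level STI, HSV, BV, yeast. The order
#' affects only the report, not the healthy set.
#'
#' @param visits,women Cohort tables (see [cohort_schema]).
#' @param nugent Optional numeric vector of Nugent scores aligned with
#'   `visits`; when supplied, `bv` is defined as Nugent >= 7.
#' @return `visits` with added columns `healthy` (logical) and
#'   `exclusion_reason` (`NA` for healthy visits).
#' @export
flag_healthy_visits <- function(visits, women, nugent = NULL) {
  bv <- visits$bv
  if (!is.null(nugent)) {
    if (length(nugent) != nrow(visits)) {
      abort("nugent must have one score per visit row")
    }
    bv <- nugent >= 7
  }
  sti <- women %>%
    mutate(woman_sti = .data$ct_pos | .data$ng_pos | .data$tv_pos) %>%
    select("woman_id", "woman_sti")
  indeterminate <- is.na(sti$woman_sti)
  if (any(indeterminate)) {
    inform(paste0(sum(indeterminate),
                  " woman/women with indeterminate STI results excluded: ",
                  paste(sti$woman_id[indeterminate], collapse = ", ")))
  }
  v <- visits %>%
    mutate(.bv = !!bv) %>%
    left_join(sti, by = "woman_id") %>%
    mutate(
      exclusion_reason = case_when(
        !.data$attended ~ "not_attended",
        .data$menstruating ~ "menstruating",
        is.na(.data$woman_sti) ~ "woman_sti_indeterminate",
        .data$woman_sti ~ "woman_sti",
        .data$hsv_shedding ~ "hsv_shedding",
        .data$.bv ~ "bv",
        .data$yeast ~ "yeast",
        TRUE ~ NA_character_
      ),
      healthy = is.na(.data$exclusion_reason)
    ) %>%
    select(-".bv", -"woman_sti")
  v
}

#' Build an intravaginal-practice comparison set
#'
#' For a given practice, the analysis subset is the union of healthy visits
#' at which the practice was reported (exposure arm) and healthy reference
#' visits at which no cleansing, or cleansing with fingers and water only,
#' was reported. Visits reporting insertion of prescribed medications are
#' excluded from every subset. A visit reporting several practices appears
#' in each corresponding exposure arm.
#'
#' @param visits Flagged visits (from [flag_healthy_visits()]).
#' @param practice One of `"soap"`, `"cloth"`, `"insertion"`.
#' @return The subset tibble with an added `ivp_arm` column
#'   (`"exposed"`/`"reference"`).
#' @export
build_ivp_comparison <- function(visits, practice = c("soap", "cloth", "insertion")) {
  practice <- tryCatch(match.arg(practice),
                       error = function(e) abort(paste0(
                         "unknown practice label: ", practice[1],
                         " (expected soap, cloth or insertion)")))
  if (!"healthy" %in% names(visits)) abort("run flag_healthy_visits() first")
  flag <- switch(practice,
                 soap = "ivp_soap", cloth = "ivp_cloth",
                 insertion = "ivp_insert_other")
  v <- visits %>%
    filter(.data$healthy, !.data$ivp_insert_med) %>%
    mutate(
      .reference = !.data$ivp_soap & !.data$ivp_cloth &
        !.data$ivp_insert_other,
      ivp_arm = case_when(.data[[flag]] ~ "exposed",
                          .data$.reference ~ "reference",
                          TRUE ~ NA_character_)
    ) %>%
    filter(!is.na(.data$ivp_arm)) %>%
    select(-".reference")
  v
}

#' Percentage cascade from raw step counts
#'
#' Computes each step's percentage of the preceding step, with percentages
#' rounded half-away-from-zero to integers.
#'
#' @param counts Named integer vector of monotone non-increasing step counts,
#'   e.g. `c(scheduled = 1200, attended = 1108, non_menstruating = 956,
#'   healthy = 370)`.
#' @return A tibble with `step`, `n`, `pct_of_previous`.
#' @export
cascade_table <- function(counts) {
  if (is.null(names(counts)) || any(names(counts) == "")) {
    abort("counts must be a named vector")
  }
  if (any(diff(counts) > 0)) abort("cascade counts must be non-increasing")
  pct <- c(NA_real_, unname(round_half_up(
    100 * counts[-1] / counts[-length(counts)])))
  tibble(step = names(counts), n = as.integer(counts), pct_of_previous = pct)
}

#' Healthy-visit cascade report
#'
#' Tabulates the filter cascade scheduled -> attended -> non-menstruating ->
#' healthy, with each step's percentage of the previous one, plus the number
#' of women contributing at least one healthy visit.
#'
#' @param flags Flagged visits from [flag_healthy_visits()].
#' @return A tibble as in [cascade_table()], with an attribute
#'   `n_women_healthy`.
#' @export
filter_report <- function(flags) {
  counts <- c(
    scheduled = nrow(flags),
    attended = sum(flags$attended),
    non_menstruating = sum(flags$attended & !flags$menstruating),
    healthy = sum(flags$healthy)
  )
  out <- cascade_table(counts)
  attr(out, "n_women_healthy") <-
    length(unique(flags$woman_id[flags$healthy]))
  out
}

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero (the
#' convention of published percentage tables), unlike base [round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers.
#' @examples
#' round_half_up(c(92.5, 86.3, -0.5))
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
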
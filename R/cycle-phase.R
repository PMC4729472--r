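# Menstrual cycle-phase classification from urinary PDG/CRT (modified
# Kassam method): per-woman ratio indexing, the 4.0 ovulation threshold,
# and pre-/post-ovulation segmentation between the observed menstruation
# and the sustained PDG rise.

#' Per-visit PDG/CRT ratios indexed to the woman's study minimum
#'
#' Each visit's PDG concentration is divided by the same sample's creatinine
#' (adjusting for urine dilution), and the series is indexed to the woman's
#' study minimum, so the minimum ratio is exactly 1. The result is invariant
#' to rescaling the whole PDG series.
#'
#' @param pdg,crt Paired positive vectors (>= 2 visits).
#' @return Numeric vector of ratios, minimum exactly 1.
#' @export
compute_cycle_ratios <- function(pdg, crt) {
  if (length(pdg) != length(crt)) abort("pdg and crt must be the same length")
  if (length(pdg) < 2) abort("need at least two visits to index a series")
  if (any(crt <= 0 | pdg <= 0, na.rm = TRUE)) {
    abort("pdg and crt must be positive")
  }
  raw <- pdg / crt
  raw / min(raw, na.rm = TRUE)
}

#' Classify a woman's cycle as ovulatory
#'
#' Ovulation is signalled when any indexed PDG/CRT ratio strictly exceeds
#' 4.0 (modified Kassam method). A maximum ratio of exactly 4.0 does not
#' qualify.
#'
#' @param ratios Ratios from [compute_cycle_ratios()].
#' @param threshold Ratio threshold (default 4.0).
#' @return Logical.
#' @export
classify_ovulatory <- function(ratios, threshold = 4.0) {
  any(ratios > threshold, na.rm = TRUE)
}

#' Assign pre-/post-ovulation phases to one woman's visits
#'
#' Phases are assigned only when the cycle is ovulatory, exactly one
#' menstruation episode (a run of consecutive menstruating visits) was
#' observed, and a sustained PDG rise is found. "Day 1" is the first
#' menstruating visit; visits after the menstruation episode ends are
#' pre-ovulation until the rise, and from the rise visit onward visits are
#' post-ovulation until the next menstruation or the end of the study.
#' Visits before Day 1, menstruating visits, and everything in a
#' non-assignable series are `unassigned`.
#'
#' The rise visit is the first visit whose ratio exceeds the threshold and
#' is *sustained*: with `min_sustained = 2` (default) the next visit must
#' also exceed the threshold (or the rise visit is the last visit); a lone
#' one-visit spike is not a rise. `min_sustained = 1` accepts single-visit
#' crossings.
#'
#' @param ratios Ratios from [compute_cycle_ratios()], in visit order.
#' @param menstruating Logical vector aligned with `ratios`.
#' @param hormonal Is the woman using hormonal contraception? If so, no
#'   phases are assigned.
#' @param threshold Ovulation ratio threshold (default 4.0).
#' @param min_sustained 1 or 2 (see above).
#' @return A list with `phase` (character vector:
#'   pre_ovulation/post_ovulation/unassigned), `ovulatory`, `day1_visit`,
#'   `rise_visit`, and `reason` (why nothing was assigned, or `NA`).
#' @export
assign_phase <- function(ratios, menstruating, hormonal = FALSE,
                         threshold = 4.0, min_sustained = 2) {
  if (!min_sustained %in% c(1, 2)) abort("min_sustained must be 1 or 2")
  n <- length(ratios)
  if (length(menstruating) != n) {
    abort("ratios and menstruating must be the same length")
  }
  unassigned <- rep("unassigned", n)
  ovulatory <- classify_ovulatory(ratios, threshold)
  base <- list(phase = unassigned, ovulatory = ovulatory,
               day1_visit = NA_integer_, rise_visit = NA_integer_)
  if (hormonal) return(c(base, reason = "hormonal_contraception"))
  if (!ovulatory) return(c(base, reason = "not_ovulatory"))

  mens <- !is.na(menstruating) & menstruating
  episodes <- rle(mens)
  n_episodes <- sum(episodes$values)
  if (n_episodes == 0) return(c(base, reason = "no_observed_menstruation"))
  if (n_episodes > 1) return(c(base, reason = "multiple_menstruations"))

  day1 <- which(mens)[1]
  base$day1_visit <- day1
  episode_end <- day1 + episodes$lengths[which(episodes$values)[1]] - 1

  candidates <- which(seq_len(n) > episode_end & !is.na(ratios) &
                        ratios > threshold)
  rise <- NA_integer_
  for (v in candidates) {
    sustained <- min_sustained == 1 || v == n ||
      (!is.na(ratios[v + 1]) && ratios[v + 1] > threshold)
    if (sustained) { rise <- v; break }
  }
  if (is.na(rise)) return(c(base, reason = "no_rise"))
  base$rise_visit <- rise

  phase <- unassigned
  idx <- seq_len(n)
  phase[idx > episode_end & idx < rise] <- "pre_ovulation"
  phase[idx >= rise] <- "post_ovulation"
  base$phase <- phase
  c(base, reason = NA_character_)
}

#' Classify cycle phases for a whole cohort
#'
#' Applies [compute_cycle_ratios()], [classify_ovulatory()] and
#' [assign_phase()] to each woman's attended visits in visit order. Women
#' using hormonal contraception (DMPA or COC) are never phase-assigned.
#'
#' @param visits,women Cohort tables.
#' @param threshold,min_sustained See [assign_phase()].
#' @return A tibble with one row per attended visit: `woman_id`,
#'   `visit_index`, `ratio`, `ovulatory`, `phase`, `phase_reason`.
#' @export
call_cycle_phases <- function(visits, women, threshold = 4.0,
                              min_sustained = 2) {
  hormonal <- women %>%
    transmute(.data$woman_id,
              hormonal = .data$contraception %in% c("dmpa", "coc"))
  attended <- visits %>%
    filter(.data$attended, !is.na(.data$pdg), !is.na(.data$crt)) %>%
    arrange(.data$woman_id, .data$visit_index) %>%
    left_join(hormonal, by = "woman_id")
  attended %>%
    group_by(.data$woman_id) %>%
    group_modify(function(d, key) {
      if (nrow(d) < 2) {
        return(tibble(visit_index = d$visit_index, ratio = NA_real_,
                      ovulatory = NA, phase = "unassigned",
                      phase_reason = "single_visit"))
      }
      r <- compute_cycle_ratios(d$pdg, d$crt)
      res <- assign_phase(r, d$menstruating, hormonal = d$hormonal[1],
                          threshold = threshold,
                          min_sustained = min_sustained)
      tibble(visit_index = d$visit_index, ratio = r,
             ovulatory = res$ovulatory, phase = res$phase,
             phase_reason = res$reason)
    }) %>%
    ungroup()
}
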
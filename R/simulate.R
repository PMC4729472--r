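# Synthetic cohort generator: emulates a 100-woman, 12-visit (thrice weekly,
# 4 weeks) longitudinal CVL study with ovulatory cycles, assay censoring and
# woman-level random intercepts calibrated to published summary statistics.

#' Simulation configuration
#'
#' Builds the configuration for [simulate_cohort()]. Defaults reproduce the
#' study conditions of the cohort the analysis machinery was designed for:
#' 100 women followed thrice weekly for four weeks (12 visits) with ~92%
#' attendance, contraception frequencies from the published demographics
#' table, ovulatory cycles in 96% of women not using hormonal contraception,
#' a 6-fold luteal rise of the urinary PDG/CRT ratio, and per-analyte
#' log-normal concentrations with woman-level random intercepts whose means
#' and variance components come from the published analyte summary table.
#'
#' @param n_women Number of participants.
#' @param n_visits Scheduled visits per woman.
#' @param attendance_prob Per-visit attendance probability.
#' @param contraception_probs Named probabilities for
#'   none/condom/dmpa/coc/other; must be in `[0,1]` and sum to 1.
#' @param ovulatory_prob Probability that a woman not using hormonal
#'   contraception has ovulatory cycles.
#' @param cycle_length,menses_length Menstrual cycle and menses duration in
#'   days.
#' @param visit_spacing Candidate gaps (days) between consecutive visits.
#' @param pdg_fold_rise Luteal / follicular fold-rise of the PDG/CRT ratio
#'   (must be positive).
#' @param pdg_noise_bound Multiplicative noise bound `B` for the PDG/CRT
#'   ratio: per-visit noise factors lie in `[1/sqrt(B), sqrt(B)]`, so a flat
#'   (anovulatory) series has max/min ratio at most `B`. Must satisfy
#'   `B < 4` so anovulatory women are never called ovulatory, and
#'   `pdg_fold_rise / B > 4` so ovulatory women always are. Set to 1 for
#'   noise-free series.
#' @param crt_meanlog,crt_sdlog Log-normal urine creatinine parameters
#'   (urine dilution varies independently of PDG).
#' @param sti_probs Named per-woman positivity probabilities for ct/ng/tv.
#' @param hsv_prob,bv_prob,yeast_prob Per-visit infection probabilities.
#' @param sex_prob Per-visit probability of reported sex in the past 3 days.
#' @param psa_given_sex,psa_given_nosex Probabilities of (none, low, high)
#'   PSA category conditional on recent sex.
#' @param ivp_probs Per-visit probabilities of soap cleansing, cloth use,
#'   insertion of a non-medication substance, and insertion of a prescribed
#'   medication.
#' @param ph_probs Probabilities over the eight pH strip values.
#' @param hb_probs,neutrophil_probs Category probabilities for haemoglobin
#'   (none/25/80/200 ery/uL) and neutrophils (0/1-10/11-50/>50 per 100 WBCs).
#' @param lymphocytes_prob Per-visit probability of lymphocytes present.
#' @param ectopy_prob,colposcopy_prob Probabilities of ectopy/colposcopic
#'   findings at the two examination visits (1 and 12).
#' @param effects Named list mapping an exposure to a named numeric vector of
#'   per-analyte shifts in log10 concentration, e.g.
#'   `list(dmpa = c("IL-8" = 0.3))`. Supported exposures: `dmpa`, `coc`,
#'   `phase_post`, `psa` (per trend score 0/1/2), `soap`, `cloth`,
#'   `insertion`, `haemoglobin` (per score 0..3), `neutrophils` (per score),
#'   `ph` (per score 0/1/2), `lymphocytes`, `sex`.
#' @param censor_at_assay Apply LLOQ/ULOQ censoring to the generated
#'   concentrations.
#' @param panel Analyte panel providing `mu`, `sd_b`, `sd_w`, `lloq`, `uloq`
#'   per analyte (default [default_panel()]).
#' @return A validated list of class `cvl_sim_config`.
#' @export
sim_config <- function(n_women = 100,
                       n_visits = 12,
                       attendance_prob = 0.92,
                       contraception_probs = c(none = 0.28, condom = 0.34,
                                               dmpa = 0.19, coc = 0.09,
                                               other = 0.10),
                       ovulatory_prob = 0.96,
                       cycle_length = 28,
                       menses_length = 4,
                       visit_spacing = c(2, 3),
                       pdg_fold_rise = 6,
                       pdg_noise_bound = 1.4,
                       crt_meanlog = 0,
                       crt_sdlog = 0.25,
                       sti_probs = c(ct = 0.12, ng = 0.08, tv = 0.15),
                       hsv_prob = 0.07,
                       bv_prob = 0.33,
                       yeast_prob = 0.07,
                       sex_prob = 0.45,
                       psa_given_sex = c(0.10, 0.55, 0.35),
                       psa_given_nosex = c(0.95, 0.04, 0.01),
                       ivp_probs = c(soap = 0.50, cloth = 0.08,
                                     insert_other = 0.04, insert_med = 0.01),
                       ph_probs = c(0.05, 0.14, 0.20, 0.25, 0.22, 0.08, 0.04, 0.02),
                       hb_probs = c(0.33, 0.33, 0.16, 0.18),
                       neutrophil_probs = c(0.49, 0.25, 0.16, 0.10),
                       lymphocytes_prob = 0.20,
                       ectopy_prob = 0.39,
                       colposcopy_prob = 0.21,
                       effects = list(),
                       censor_at_assay = TRUE,
                       panel = default_panel()) {
  cfg <- as.list(environment())
  probs <- c(attendance_prob, ovulatory_prob, contraception_probs,
             sti_probs, hsv_prob, bv_prob, yeast_prob, sex_prob,
             ivp_probs, lymphocytes_prob, ectopy_prob, colposcopy_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (abs(sum(contraception_probs) - 1) > 1e-8) {
    abort("contraception_probs must sum to 1")
  }
  if (pdg_fold_rise <= 0) abort("pdg_fold_rise must be positive")
  if (pdg_noise_bound < 1) abort("pdg_noise_bound must be >= 1")
  if (n_women < 1 || n_visits < 2) abort("need n_women >= 1 and n_visits >= 2")
  if (!all(c("sd_b", "sd_w", "mu") %in% names(panel))) {
    abort("panel must carry mu, sd_b and sd_w columns for simulation")
  }
  if (any(panel$sd_b < 0) || any(panel$sd_w <= 0)) {
    abort("panel requires sd_b >= 0 and sd_w > 0")
  }
  known_exp <- c("dmpa", "coc", "phase_post", "psa", "soap", "cloth",
                 "insertion", "haemoglobin", "neutrophils", "ph",
                 "lymphocytes", "sex")
  bad <- setdiff(names(effects), known_exp)
  if (length(bad) > 0) abort(paste0("unknown effect exposure(s): ",
                                    paste(bad, collapse = ", ")))
  for (e in effects) {
    missing_a <- setdiff(names(e), panel$analyte)
    if (length(missing_a) > 0) {
      abort(paste0("effect refers to analyte(s) absent from the panel: ",
                   paste(missing_a, collapse = ", ")))
    }
  }
  structure(cfg, class = "cvl_sim_config")
}

#' Generate a urinary PDG and creatinine series for one woman
#'
#' The PDG/CRT ratio follows a piecewise trajectory: follicular baseline, a
#' step rise to `fold_rise` x baseline at the ovulation day, a luteal
#' plateau, and a fall back to baseline two days before the next menses.
#' Anovulatory series stay at baseline. Creatinine varies independently
#' (urine dilution) and multiplies both numerator and denominator of the
#' underlying ratio, so it carries no phase signal. Multiplicative ratio
#' noise is bounded: factors lie in `[1/sqrt(B), sqrt(B)]`.
#'
#' @param study_days Visit days (within the follow-up window).
#' @param cycle_day0 Cycle day (0-based; menses begins at day 0) at study
#'   day 0.
#' @param ovulatory Does this woman ovulate during the study?
#' @param ovulation_day Cycle day of ovulation.
#' @param fold_rise Luteal fold-rise of PDG/CRT (> 0).
#' @param noise_bound Multiplicative noise bound `B >= 1` (1 = noise-free).
#' @param cycle_length,fall_lead Cycle length and days before menses at
#'   which PDG returns to baseline.
#' @param baseline Follicular PDG/CRT baseline value.
#' @param crt_meanlog,crt_sdlog Log-normal creatinine parameters.
#' @return A tibble with columns `study_day`, `cycle_day`, `pdg`, `crt`.
#' @export
generate_pdg_series <- function(study_days, cycle_day0 = 0, ovulatory = TRUE,
                                ovulation_day = 14, fold_rise = 6,
                                noise_bound = 1, cycle_length = 28,
                                fall_lead = 2, baseline = 1,
                                crt_meanlog = 0, crt_sdlog = 0.25) {
  if (fold_rise <= 0) abort("fold_rise must be positive")
  if (noise_bound < 1) abort("noise_bound must be >= 1")
  cycle_day <- (study_days + cycle_day0) %% cycle_length
  ratio <- rep(baseline, length(study_days))
  if (ovulatory) {
    luteal <- cycle_day >= ovulation_day & cycle_day < (cycle_length - fall_lead)
    ratio[luteal] <- baseline * fold_rise
  }
  noise <- if (noise_bound > 1) {
    exp(runif(length(study_days), -log(noise_bound) / 2, log(noise_bound) / 2))
  } else {
    rep(1, length(study_days))
  }
  crt <- rlnorm(length(study_days), crt_meanlog, crt_sdlog)
  tibble(study_day = study_days, cycle_day = cycle_day,
         pdg = ratio * noise * crt, crt = crt)
}

# per-visit exposure scores used by the effect map and by the scan encoders
.exposure_scores <- function(visits, women, truth_visits) {
  women_small <- women %>% select("woman_id", "contraception")
  visits %>%
    left_join(women_small, by = "woman_id") %>%
    left_join(truth_visits %>% select("woman_id", "visit_index", "true_phase"),
              by = c("woman_id", "visit_index")) %>%
    transmute(
      .data$woman_id, .data$visit_index,
      dmpa = as.numeric(.data$contraception == "dmpa"),
      coc = as.numeric(.data$contraception == "coc"),
      phase_post = as.numeric(!is.na(.data$true_phase) &
                                .data$true_phase == "luteal"),
      psa = as.numeric(factor(.data$psa_category, levels = .psa_levels)) - 1,
      soap = as.numeric(.data$ivp_soap),
      cloth = as.numeric(.data$ivp_cloth),
      insertion = as.numeric(.data$ivp_insert_other),
      haemoglobin = as.numeric(factor(.data$hb_category, levels = .hb_levels)) - 1,
      neutrophils = as.numeric(factor(.data$neutrophil_category,
                                      levels = .neut_levels)) - 1,
      ph = .ph_score(.data$ph_value),
      lymphocytes = as.numeric(.data$lymphocytes_present),
      sex = as.numeric(.data$sex_past_3_days)
    )
}

#' Generate an uncensored analyte measurement table
#'
#' For each analyte, the log10 concentration at a sampled visit is
#' `mu + b_woman + sum(effect * exposure score) + e`, with
#' `b ~ N(0, sd_b^2)` and `e ~ N(0, sd_w^2)`, so the large-sample intraclass
#' correlation is `sd_b^2 / (sd_b^2 + sd_w^2)`. Analytes measured on assay
#' subsets (`n_measured < max`) have rows thinned proportionally.
#'
#' @param truth Truth tables from [simulate_cohort()] (woman intercepts and
#'   per-visit exposure scores are taken from here).
#' @param visits,women Cohort tables.
#' @param config A [sim_config()].
#' @return An uncensored measurement tibble (all rows `quantified`).
#' @export
generate_analyte_matrix <- function(truth, visits, women, config) {
  panel <- config$panel
  sampled <- visits %>% filter(.data$attended, !.data$menstruating)
  scores <- .exposure_scores(sampled, women, truth$visits)
  n_s <- nrow(sampled)
  eff <- config$effects
  max_n <- if ("n_measured" %in% names(panel)) max(panel$n_measured) else NA
  rows <- map(seq_len(nrow(panel)), function(i) {
    an <- panel$analyte[i]
    b <- truth$intercepts %>% filter(.data$analyte == an)
    b_vec <- setNames(b$intercept, b$woman_id)[sampled$woman_id]
    shift <- rep(0, n_s)
    for (ex in names(eff)) {
      if (an %in% names(eff[[ex]])) {
        shift <- shift + eff[[ex]][[an]] * scores[[ex]]
      }
    }
    log_val <- panel$mu[i] + b_vec + shift + rnorm(n_s, 0, panel$sd_w[i])
    out <- tibble(woman_id = sampled$woman_id,
                  visit_index = sampled$visit_index,
                  analyte = an, value = 10^log_val,
                  censor = "quantified")
    if (!is.na(max_n) && panel$n_measured[i] < max_n) {
      keep <- runif(n_s) < panel$n_measured[i] / max_n
      out <- out[keep, ]
    }
    out
  })
  list_rbind(rows)
}

#' Apply assay quantification limits to a measurement table
#'
#' Values below the analyte's LLOQ are flagged `below_lloq`, values above
#' the ULOQ `above_uloq`; quantified values are untouched. The original
#' (uncensored) values are retained only in the simulation truth tables.
#'
#' @param measurements Measurement tibble.
#' @param panel Panel with `lloq`/`uloq` per analyte.
#' @return The censored measurement tibble.
#' @export
apply_assay_censoring <- function(measurements, panel) {
  lim <- panel %>% select("analyte", "lloq", "uloq")
  missing_a <- setdiff(unique(measurements$analyte), lim$analyte)
  if (length(missing_a) > 0) {
    abort(paste0("panel lacks limits for analyte(s): ",
                 paste(missing_a, collapse = ", ")))
  }
  measurements %>%
    left_join(lim, by = "analyte") %>%
    mutate(censor = case_when(.data$value < .data$lloq ~ "below_lloq",
                              .data$value > .data$uloq ~ "above_uloq",
                              TRUE ~ "quantified"),
           value = case_when(.data$censor == "below_lloq" ~ .data$lloq,
                             .data$censor == "above_uloq" ~ .data$uloq,
                             TRUE ~ .data$value)) %>%
    select(-"lloq", -"uloq")
}

#' Simulate a longitudinal CVL cohort
#'
#' Generates women, visits (attendance, menstruation from each woman's cycle
#' position, infection flags, exposures, urinary PDG/CRT), analyte
#' measurements with woman-level random intercepts, and — unless disabled —
#' assay censoring at the panel's limits. The returned `truth` tables record
#' the latent random intercepts, the true per-visit cycle phase and the true
#' ovulation status, for parameter-recovery testing.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   `(config, seed)`.
#' @return A list of class `cvl_cohort` with elements `women`, `visits`,
#'   `measurements`, `truth` (list: `women`, `visits`, `intercepts`),
#'   `panel`, `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_women = 10), seed = 1)
#' nrow(cohort$women)
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  if (!inherits(config, "cvl_sim_config")) abort("config must come from sim_config()")
  set.seed(seed)
  nw <- config$n_women
  nv <- config$n_visits
  panel <- config$panel

  women <- tibble(
    woman_id = sprintf("W%03d", seq_len(nw)),
    age = pmin(pmax(round(rnorm(nw, 26, 6)), 18), 44),
    contraception = sample(names(config$contraception_probs), nw,
                           replace = TRUE, prob = config$contraception_probs),
    ct_pos = runif(nw) < config$sti_probs[["ct"]],
    ng_pos = runif(nw) < config$sti_probs[["ng"]],
    tv_pos = runif(nw) < config$sti_probs[["tv"]]
  )

  hormonal <- women$contraception %in% c("dmpa", "coc")
  truth_women <- tibble(
    woman_id = women$woman_id,
    ovulatory = ifelse(hormonal, FALSE,
                       runif(nw) < config$ovulatory_prob),
    has_menses = women$contraception != "dmpa",
    cycle_day0 = sample(0:(config$cycle_length - 1), nw, replace = TRUE),
    ovulation_day = sample(13:15, nw, replace = TRUE)
  )

  per_woman <- map(seq_len(nw), function(i) {
    gaps <- sample(config$visit_spacing, nv - 1, replace = TRUE)
    study_day <- cumsum(c(1, gaps))
    attended <- runif(nv) < config$attendance_prob
    pser <- generate_pdg_series(
      study_day, cycle_day0 = truth_women$cycle_day0[i],
      ovulatory = truth_women$ovulatory[i],
      ovulation_day = truth_women$ovulation_day[i],
      fold_rise = config$pdg_fold_rise,
      noise_bound = config$pdg_noise_bound,
      cycle_length = config$cycle_length,
      crt_meanlog = config$crt_meanlog, crt_sdlog = config$crt_sdlog
    )
    menstruating <- truth_women$has_menses[i] &
      pser$cycle_day < config$menses_length
    true_phase <- rep(NA_character_, nv)
    if (truth_women$ovulatory[i]) {
      true_phase <- case_when(
        menstruating ~ "menses",
        pser$cycle_day < truth_women$ovulation_day[i] ~ "follicular",
        TRUE ~ "luteal"
      )
    }
    sex <- runif(nv) < config$sex_prob
    psa <- vapply(sex, function(s) {
      sample(.psa_levels, 1,
             prob = if (s) config$psa_given_sex else config$psa_given_nosex)
    }, character(1))
    exam <- seq_len(nv) %in% c(1L, nv)
    tibble(
      woman_id = women$woman_id[i],
      visit_index = seq_len(nv),
      study_day = study_day,
      attended = attended,
      menstruating = menstruating,
      hsv_shedding = runif(nv) < config$hsv_prob,
      bv = runif(nv) < config$bv_prob,
      yeast = runif(nv) < config$yeast_prob,
      psa_category = psa,
      ph_value = sample(ph_strip_values, nv, replace = TRUE,
                        prob = config$ph_probs),
      hb_category = sample(.hb_levels, nv, replace = TRUE,
                           prob = config$hb_probs),
      neutrophil_category = sample(.neut_levels, nv, replace = TRUE,
                                   prob = config$neutrophil_probs),
      lymphocytes_present = runif(nv) < config$lymphocytes_prob,
      sex_past_3_days = sex,
      ivp_soap = runif(nv) < config$ivp_probs[["soap"]],
      ivp_cloth = runif(nv) < config$ivp_probs[["cloth"]],
      ivp_insert_other = runif(nv) < config$ivp_probs[["insert_other"]],
      ivp_insert_med = runif(nv) < config$ivp_probs[["insert_med"]],
      ectopy = ifelse(exam, runif(nv) < config$ectopy_prob, NA),
      colposcopy = ifelse(exam, runif(nv) < config$colposcopy_prob, NA),
      pdg = pser$pdg,
      crt = pser$crt,
      cycle_day = pser$cycle_day,
      true_phase = true_phase
    )
  })
  visits_full <- list_rbind(per_woman)

  truth_visits <- visits_full %>%
    select("woman_id", "visit_index", "study_day", "cycle_day",
           "true_phase", "menstruating")
  truth_intercepts <- tidyr::expand_grid(woman_id = women$woman_id,
                                         analyte = panel$analyte) %>%
    arrange(match(.data$analyte, panel$analyte), .data$woman_id) %>%
    left_join(panel %>% select("analyte", "sd_b"), by = "analyte") %>%
    mutate(intercept = rnorm(n(), 0, .data$sd_b)) %>%
    select(-"sd_b")

  visits <- visits_full %>% select(-"cycle_day", -"true_phase")
  # clinical flags are only observed at attended visits
  obs_cols <- c("menstruating", "hsv_shedding", "bv", "yeast", "psa_category",
                "ph_value", "hb_category", "neutrophil_category",
                "lymphocytes_present", "sex_past_3_days", "ivp_soap",
                "ivp_cloth", "ivp_insert_other", "ivp_insert_med",
                "ectopy", "colposcopy", "pdg", "crt")
  for (cl in obs_cols) visits[[cl]][!visits$attended] <- NA
  # no genital samples are obtained at menstruating visits
  genital_cols <- c("hsv_shedding", "bv", "yeast", "psa_category", "ph_value",
                    "hb_category", "neutrophil_category", "lymphocytes_present")
  mens <- !is.na(visits$menstruating) & visits$menstruating
  for (cl in genital_cols) visits[[cl]][mens] <- NA

  truth <- list(women = truth_women, visits = truth_visits,
                intercepts = truth_intercepts)
  measurements <- generate_analyte_matrix(truth, visits, women, config)
  if (isTRUE(config$censor_at_assay)) {
    measurements <- apply_assay_censoring(measurements, panel)
  }
  validate_cohort(women, visits, measurements)
  structure(list(women = women, visits = visits, measurements = measurements,
                 truth = truth, panel = panel, config = config),
            class = "cvl_cohort")
}

#' @export
print.cvl_cohort <- function(x, ...) {
  cat("<cvl_cohort> ", nrow(x$women), " women, ",
      sum(x$visits$attended), "/", nrow(x$visits), " attended visits, ",
      nrow(x$measurements), " measurements of ",
      length(unique(x$measurements$analyte)), " analytes\n", sep = "")
  invisible(x)
}
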
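# Shared fixtures, built once per test run.

suppressPackageStartupMessages({
  library(dplyr)
  library(tidyr)
  library(tibble)
})

.cache <- new.env(parent = emptyenv())

# default study conditions, fixed seed
shared_cohort <- function() {
  if (is.null(.cache$cohort)) {
    .cache$cohort <- simulate_cohort(sim_config(), seed = 101)
  }
  .cache$cohort
}

shared_flags <- function() {
  if (is.null(.cache$flags)) {
    co <- shared_cohort()
    .cache$flags <- flag_healthy_visits(co$visits, co$women)
  }
  .cache$flags
}

# tiny single-analyte panel for focused simulations
mini_panel <- function(sd_b = 0.35, sd_w = 0.35, mu = 1.5,
                       lloq = 1e-6, uloq = 1e9) {
  tibble::tibble(
    analyte = "IL-X", class = "inflammatory cytokine", units = "pg/ml",
    panel = "a", n_measured = 370, median_ref = 10^mu, sd_b = sd_b,
    icc_ref = sd_b^2 / (sd_b^2 + sd_w^2), sd_w = sd_w, detect_ref = 1,
    mu = mu, lloq = lloq, uloq = uloq
  )
}

# hand-built three-woman cohort used by the filter/io tests
toy_cohort <- function() {
  women <- tibble::tibble(
    woman_id = c("W1", "W2", "W3"),
    age = c(25L, 30L, 35L),
    contraception = c("none", "dmpa", "condom"),
    ct_pos = c(FALSE, FALSE, FALSE),
    ng_pos = c(FALSE, FALSE, FALSE),
    tv_pos = c(TRUE, FALSE, FALSE)
  )
  visits <- tidyr::expand_grid(woman_id = women$woman_id, visit_index = 1:4) %>%
    dplyr::mutate(
      study_day = visit_index * 2L,
      attended = TRUE,
      menstruating = woman_id == "W3" & visit_index == 1,
      hsv_shedding = FALSE,
      bv = woman_id == "W2" & visit_index == 2,
      yeast = FALSE,
      psa_category = "none",
      ph_value = 4.4,
      hb_category = "none",
      neutrophil_category = "0",
      lymphocytes_present = FALSE,
      sex_past_3_days = FALSE,
      ivp_soap = woman_id == "W2" & visit_index == 3,
      ivp_cloth = woman_id == "W2" & visit_index == 3,
      ivp_insert_other = FALSE,
      ivp_insert_med = woman_id == "W3" & visit_index == 2,
      ectopy = NA,
      colposcopy = NA,
      pdg = 1, crt = 1
    )
  measurements <- visits %>%
    dplyr::filter(!menstruating) %>%
    dplyr::transmute(woman_id, visit_index, analyte = "IL-X",
                     value = 10, censor = "quantified")
  list(women = women, visits = visits, measurements = measurements)
}
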
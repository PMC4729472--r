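# Descriptive outputs: per-analyte summary table, within-panel Spearman
# cross-reactivity screen, and the cohort demographics/exposure table.

#' Per-analyte summary of healthy-visit concentrations
#'
#' For each analyte: the percentage of measurements above the LLOQ, the
#' median and range of *quantified* values (within assay limits), the mean
#' and SD of *imputed* values (below-LLOQ rows at half the LLOQ, above-ULOQ
#' rows at twice the ULOQ) — both variants are emitted because published
#' summary tables are ambiguous about which base they use — and the REML
#' variance components, ICC and F test of the log10 imputed values.
#'
#' @param measurements Measurement tibble.
#' @param flags Flagged visits from [flag_healthy_visits()].
#' @param panel Analyte panel.
#' @return A tibble, one row per analyte in panel order.
#' @export
summarize_analytes <- function(measurements, flags, panel) {
  healthy_key <- flags %>% filter(.data$healthy) %>%
    select("woman_id", "visit_index")
  m <- measurements %>%
    inner_join(healthy_key, by = c("woman_id", "visit_index"))
  vc <- icc_scan(measurements, flags, panel)
  desc <- m %>%
    group_by(.data$analyte) %>%
    group_modify(function(d, key) {
      quantified <- d$value[d$censor == "quantified"]
      imputed <- impute_censored(d %>% mutate(analyte = key$analyte), panel)$value
      tibble(
        n = nrow(d),
        pct_detected = 100 * mean(d$censor != "below_lloq"),
        median_quantified = if (length(quantified)) median(quantified) else NA_real_,
        min_quantified = if (length(quantified)) min(quantified) else NA_real_,
        max_quantified = if (length(quantified)) max(quantified) else NA_real_,
        mean_imputed = mean(imputed),
        sd_imputed = sd(imputed)
      )
    }) %>%
    ungroup()
  panel %>%
    select("analyte", "class", "units") %>%
    inner_join(desc, by = "analyte") %>%
    left_join(vc %>% select("analyte", "sigma_b2", "sigma_w2", "icc",
                            "f_stat", "f_p"),
              by = "analyte")
}

#' Within-panel Spearman cross-reactivity screen
#'
#' Pairwise Spearman rank correlations between analytes measured on the same
#' Luminex panel, computed on log10 imputed concentrations with average
#' ranks for ties. A constant series yields an `NA` (undefined) cell.
#'
#' @param measurements Measurement tibble (healthy subset recommended).
#' @param panel Analyte panel (its `panel` column defines the groups).
#' @param min_pairs Minimum paired observations per analyte pair.
#' @return A tibble with `panel`, `analyte_1`, `analyte_2`, `rho`, `n_pairs`.
#' @export
crossreactivity_spearman <- function(measurements, panel, min_pairs = 3) {
  m <- measurements %>%
    impute_censored(panel) %>%
    log10_transform() %>%
    left_join(panel %>% select("analyte", panel_label = "panel"),
              by = "analyte")
  out <- m %>%
    group_by(.data$panel_label) %>%
    group_modify(function(d, key) {
      wide <- d %>%
        select("woman_id", "visit_index", "analyte", "value") %>%
        pivot_wider(names_from = "analyte", values_from = "value")
      analytes <- setdiff(names(wide), c("woman_id", "visit_index"))
      if (length(analytes) < 2) return(tibble())
      pairs <- utils::combn(analytes, 2, simplify = FALSE)
      map_dfr(pairs, function(p) {
        x <- wide[[p[1]]]; y <- wide[[p[2]]]
        ok <- complete.cases(x, y)
        rho <- if (sum(ok) < min_pairs || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
          NA_real_
        } else {
          cor(x[ok], y[ok], method = "spearman")
        }
        tibble(analyte_1 = p[1], analyte_2 = p[2], rho = rho,
               n_pairs = sum(ok))
      })
    }) %>%
    ungroup() %>%
    rename(panel = "panel_label")
  out
}

.pct_block <- function(x, label) {
  tb <- table(x, useNA = "no")
  tibble(block = label, level = names(tb), n = as.integer(tb),
         pct = round_half_up(100 * as.integer(tb) / sum(tb)),
         denominator = sum(tb))
}

#' Cohort demographics and exposure frequency table
#'
#' Counts and percentages (rounded half-away-from-zero to integers, with the
#' denominator stated per block) for contraception, intravaginal practices
#' reported at least once, cycle classification, and per-visit PSA, pH and
#' haemoglobin categories on healthy visits.
#'
#' @param women,visits Cohort tables.
#' @param flags Optional flagged visits (computed if omitted).
#' @param phases Optional phase calls from [call_cycle_phases()].
#' @return A long tibble with `block`, `level`, `n`, `pct`, `denominator`.
#' @export
table1_report <- function(women, visits, flags = NULL, phases = NULL) {
  if (nrow(women) == 0) {
    return(tibble(block = character(), level = character(), n = integer(),
                  pct = numeric(), denominator = integer()))
  }
  if (is.null(flags)) flags <- flag_healthy_visits(visits, women)
  healthy <- flags %>% filter(.data$healthy)
  ever <- visits %>%
    filter(.data$attended) %>%
    group_by(.data$woman_id) %>%
    summarise(sex = any(.data$sex_past_3_days, na.rm = TRUE),
              soap = any(.data$ivp_soap, na.rm = TRUE),
              cloth = any(.data$ivp_cloth, na.rm = TRUE),
              insertion = any(.data$ivp_insert_other | .data$ivp_insert_med,
                              na.rm = TRUE))
  blocks <- list(
    .pct_block(women$contraception, "contraception"),
    .pct_block(ifelse(ever$sex, "yes", "no"), "reported sex during study"),
    .pct_block(ifelse(ever$soap, "yes", "no"), "cleansing with soap"),
    .pct_block(ifelse(ever$cloth, "yes", "no"), "cleansing with cloth"),
    .pct_block(ifelse(ever$insertion, "yes", "no"), "any insertion"),
    .pct_block(healthy$psa_category, "PSA category (healthy visits)"),
    .pct_block(.ph_score(healthy$ph_value), "pH category (healthy visits)"),
    .pct_block(healthy$hb_category, "haemoglobin category (healthy visits)"),
    .pct_block(healthy$neutrophil_category,
               "neutrophil category (healthy visits)")
  )
  if (!is.null(phases)) {
    nh <- phases %>%
      group_by(.data$woman_id) %>%
      summarise(ovulatory = any(.data$ovulatory, na.rm = TRUE))
    blocks <- c(blocks, list(
      .pct_block(ifelse(nh$ovulatory, "ovulatory", "not ovulatory"),
                 "cycle classification (non-hormonal women)"),
      .pct_block(phases$phase[phases$phase != "unassigned"],
                 "assigned cycle phase (visits)")
    ))
  }
  list_rbind(blocks)
}
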
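# Per-analyte exposure signature scans: random-intercept linear models for
# well-detected analytes (>85% above LLOQ), random-intercept logistic models
# (adaptive Gauss-Hermite quadrature) for the rest, with per-exposure
# analysis subsets and a priori confounder adjustment sets.

# pH trend score: 3.6-4.1 normal (0), 4.4-4.7 high normal (1), >=5.0 abnormal (2)
.ph_score <- function(ph_value) {
  case_when(is.na(ph_value) ~ NA_real_,
            ph_value <= 4.1 ~ 0,
            ph_value <= 4.7 ~ 1,
            TRUE ~ 2)
}

.exposure_names <- c("phase", "dmpa", "coc", "psa", "soap", "cloth",
                     "insertion", "ectopy", "colposcopy", "ph",
                     "neutrophils", "lymphocytes", "haemoglobin")

#' Exposure specification
#'
#' Returns the built-in definition of one of the thirteen exposures: its
#' coding (binary or ordered trend with integer scores), reference level,
#' analysis-subset rule, and adjustment set. The a priori confounders are
#' age, reported sex in the past three days, and presence of haemoglobin;
#' PSA is adjusted for age and haemoglobin only (recent sex lies on its
#' causal path), and the haemoglobin exposure is adjusted for age and sex.
#'
#' @param name One of `r toString(.exposure_names)`.
#' @return A list with `name`, `coding`, `reference`, `covariates`, `subset`.
#' @export
exposure_spec <- function(name) {
  name <- match.arg(name, .exposure_names)
  covars_full <- c("age", "sex_past_3_days", "hb_present")
  spec <- switch(
    name,
    phase = list(coding = "binary", reference = "pre_ovulation",
                 covariates = covars_full,
                 subset = "healthy visits with an assigned cycle phase"),
    dmpa = list(coding = "binary", reference = "no hormonal contraception",
                covariates = covars_full,
                subset = "healthy visits of DMPA users and women using no hormonal contraception"),
    coc = list(coding = "binary", reference = "no hormonal contraception",
               covariates = covars_full,
               subset = "healthy visits of COC users and women using no hormonal contraception"),
    psa = list(coding = "ordered-trend", reference = "none",
               covariates = c("age", "hb_present"),
               subset = "healthy visits", scores = 0:2),
    soap = list(coding = "binary", reference = "no cleansing or water only",
                covariates = covars_full,
                subset = "healthy visits, medication-insertion visits excluded"),
    cloth = list(coding = "binary", reference = "no cleansing or water only",
                 covariates = covars_full,
                 subset = "healthy visits, medication-insertion visits excluded"),
    insertion = list(coding = "binary", reference = "no cleansing or water only",
                     covariates = covars_full,
                     subset = "healthy visits, medication-insertion visits excluded"),
    ectopy = list(coding = "binary", reference = "absent",
                  covariates = covars_full,
                  subset = "healthy examination visits (1 and 12)"),
    colposcopy = list(coding = "binary", reference = "absent",
                      covariates = covars_full,
                      subset = "healthy examination visits (1 and 12)"),
    ph = list(coding = "ordered-trend", reference = "3.6-4.1",
              covariates = covars_full, subset = "healthy visits",
              scores = 0:2),
    neutrophils = list(coding = "ordered-trend", reference = "0",
                       covariates = covars_full, subset = "healthy visits",
                       scores = 0:3),
    lymphocytes = list(coding = "binary", reference = "absent",
                       covariates = covars_full, subset = "healthy visits"),
    haemoglobin = list(coding = "ordered-trend", reference = "none",
                       covariates = c("age", "sex_past_3_days"),
                       subset = "healthy visits", scores = 0:3)
  )
  c(list(name = name), spec)
}

#' Encode an exposure into a design subset
#'
#' Restricts to the exposure's analysis subset of healthy visits and returns
#' a numeric exposure column (0/1 for binary codings, integer scores for
#' ordered trends) plus the covariate columns `age`, `sex_past_3_days` and
#' `hb_present`.
#'
#' @param flags Flagged visits from [flag_healthy_visits()].
#' @param women Women table.
#' @param exposure Exposure name (see [exposure_spec()]).
#' @param phases Phase calls from [call_cycle_phases()]; required for the
#'   `phase` exposure.
#' @return A tibble with `woman_id`, `visit_index`, `exposure`, `age`,
#'   `sex_past_3_days`, `hb_present`.
#' @export
encode_exposure <- function(flags, women, exposure, phases = NULL) {
  spec <- exposure_spec(exposure)
  base <- flags %>%
    filter(.data$healthy) %>%
    left_join(women %>% select("woman_id", "age", "contraception"),
              by = "woman_id")
  d <- switch(
    spec$name,
    phase = {
      if (is.null(phases)) abort("the phase exposure requires phase calls")
      base %>%
        inner_join(phases %>% select("woman_id", "visit_index", "phase"),
                   by = c("woman_id", "visit_index")) %>%
        filter(.data$phase %in% c("pre_ovulation", "post_ovulation")) %>%
        mutate(exposure = as.numeric(.data$phase == "post_ovulation"))
    },
    dmpa = base %>%
      filter(.data$contraception != "coc") %>%
      mutate(exposure = as.numeric(.data$contraception == "dmpa")),
    coc = base %>%
      filter(.data$contraception != "dmpa") %>%
      mutate(exposure = as.numeric(.data$contraception == "coc")),
    psa = base %>%
      filter(!is.na(.data$psa_category)) %>%
      mutate(exposure = as.numeric(factor(.data$psa_category,
                                          levels = .psa_levels)) - 1),
    soap = ,
    cloth = ,
    insertion = build_ivp_comparison(flags, spec$name) %>%
      left_join(women %>% select("woman_id", "age"), by = "woman_id") %>%
      mutate(exposure = as.numeric(.data$ivp_arm == "exposed")),
    ectopy = base %>%
      filter(!is.na(.data$ectopy)) %>%
      mutate(exposure = as.numeric(.data$ectopy)),
    colposcopy = base %>%
      filter(!is.na(.data$colposcopy)) %>%
      mutate(exposure = as.numeric(.data$colposcopy)),
    ph = base %>%
      filter(!is.na(.data$ph_value)) %>%
      mutate(exposure = .ph_score(.data$ph_value)),
    neutrophils = base %>%
      filter(!is.na(.data$neutrophil_category)) %>%
      mutate(exposure = as.numeric(factor(.data$neutrophil_category,
                                          levels = .neut_levels)) - 1),
    lymphocytes = base %>%
      filter(!is.na(.data$lymphocytes_present)) %>%
      mutate(exposure = as.numeric(.data$lymphocytes_present)),
    haemoglobin = base %>%
      filter(!is.na(.data$hb_category)) %>%
      mutate(exposure = as.numeric(factor(.data$hb_category,
                                          levels = .hb_levels)) - 1)
  )
  d %>%
    mutate(hb_present = as.numeric(.data$hb_category != "none"),
           sex_past_3_days = as.numeric(.data$sex_past_3_days)) %>%
    select("woman_id", "visit_index", "exposure", "age",
           "sex_past_3_days", "hb_present")
}

.skip_row <- function(reason) {
  tibble(estimate = NA_real_, se = NA_real_, ci_lo = NA_real_,
         ci_hi = NA_real_, p_value = NA_real_, sigma_b = NA_real_,
         loglik = NA_real_, skipped = TRUE, skip_reason = reason)
}

.wald_row <- function(est, se, sigma_b, ll) {
  z <- qnorm(0.975)
  tibble(estimate = est, se = se, ci_lo = est - z * se, ci_hi = est + z * se,
         p_value = 2 * pnorm(-abs(est / se)), sigma_b = sigma_b,
         loglik = ll, skipped = FALSE, skip_reason = NA_character_)
}

.model_formula <- function(response, covariates, adjusted) {
  rhs <- "exposure"
  if (adjusted && length(covariates) > 0) {
    rhs <- paste(c(rhs, covariates), collapse = " + ")
  }
  as.formula(paste0(response, " ~ ", rhs, " + (1 | woman_id)"))
}

#' Random-intercept linear model for one analyte
#'
#' Fits `value ~ exposure (+ covariates) + (1 | woman)` by REML through
#' lme4 and reports the exposure coefficient (difference in log10
#' concentration), its Wald 95% CI and p-value. A constant exposure or
#' fewer than two women yields a structured skip record.
#'
#' @param data Tibble with columns `value` (log10 concentration),
#'   `exposure`, `woman_id` and any covariates.
#' @param covariates Covariate column names.
#' @param adjusted Include the covariates?
#' @return A one-row tibble (see [signature_scan()] columns).
#' @export
fit_lmm <- function(data, covariates = character(), adjusted = FALSE) {
  if (length(unique(data$woman_id)) < 2) return(.skip_row("fewer than two women"))
  if (length(unique(data$exposure)) < 2) {
    return(.skip_row("exposure constant in subset"))
  }
  f <- .model_formula("value", covariates, adjusted)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(f, data = data, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) NULL)
  if (is.null(fit)) return(.skip_row("linear mixed model failed to fit"))
  est <- lme4::fixef(fit)[["exposure"]]
  se <- sqrt(diag(as.matrix(vcov(fit)))[["exposure"]])
  .wald_row(est, se, sqrt(unlist(lme4::VarCorr(fit))[[1]]),
            as.numeric(logLik(fit)))
}

#' Random-intercept logistic model for one analyte
#'
#' Fits `detected ~ exposure (+ covariates) + (1 | woman)` by maximum
#' likelihood with adaptive Gauss-Hermite quadrature (default 15 nodes) and
#' reports the exposure log odds-ratio with Wald 95% CI. Degenerate designs
#' — constant outcome, or a binary-exposure arm in which every visit is
#' detected or undetected (the odds ratio is then inestimable) — yield
#' structured skip records rather than silent omission.
#'
#' @param data Tibble with columns `detected` (0/1), `exposure`, `woman_id`
#'   and any covariates.
#' @param covariates,adjusted As in [fit_lmm()].
#' @param nAGQ Number of adaptive quadrature nodes.
#' @param keep_fit Attach the fitted lme4 model as attribute `"fit"` (for
#'   diagnostics such as quadrature-refinement checks).
#' @return A one-row tibble (see [signature_scan()] columns).
#' @export
fit_relogit <- function(data, covariates = character(), adjusted = FALSE,
                        nAGQ = 15, keep_fit = FALSE) {
  if (length(unique(data$woman_id)) < 2) return(.skip_row("fewer than two women"))
  if (length(unique(data$exposure)) < 2) {
    return(.skip_row("exposure constant in subset"))
  }
  if (length(unique(data$detected)) < 2) {
    return(.skip_row(if (all(data$detected == 1)) "all visits detected"
                     else "no visits detected"))
  }
  if (all(data$exposure %in% c(0, 1))) {
    arm_var <- tapply(data$detected, data$exposure, function(y) {
      length(unique(y))
    })
    if (any(arm_var < 2)) {
      return(.skip_row("odds ratio inestimable: an exposure arm is all detected or all undetected"))
    }
  }
  f <- .model_formula("detected", covariates, adjusted)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(f, data = data, family = binomial(), nAGQ = nAGQ)
    )),
    error = function(e) NULL)
  if (is.null(fit)) return(.skip_row("logistic mixed model failed to fit"))
  est <- lme4::fixef(fit)[["exposure"]]
  se <- sqrt(diag(as.matrix(vcov(fit)))[["exposure"]])
  if (!is.finite(se) || se > 15) return(.skip_row("separation (unstable estimate)"))
  out <- .wald_row(est, se, sqrt(unlist(lme4::VarCorr(fit))[[1]]),
                   as.numeric(logLik(fit)))
  if (keep_fit) attr(out, "fit") <- fit
  out
}

#' Scan all analytes for association with one exposure
#'
#' For every analyte: compute the detection proportion on the exposure's
#' analysis subset, route the model accordingly ([select_route()]; strict
#' >85% for the continuous route), fit the random-intercept model, and
#' collect the estimates. Degenerate fits propagate as skip records; the
#' scan never aborts. No multiple-testing correction is applied by default
#' (set `p_adjust = TRUE` for Benjamini-Hochberg adjusted p-values in an
#' extra column).
#'
#' @param cohort A `cvl_cohort` (or list with `women`, `visits`,
#'   `measurements`).
#' @param exposure Exposure name (see [exposure_spec()]).
#' @param panel Analyte panel; defaults to the cohort's.
#' @param adjusted Adjust for the exposure's a priori confounder set?
#' @param phases Optional precomputed phase calls (computed on demand for
#'   the `phase` exposure).
#' @param flags Optional precomputed healthy-visit flags.
#' @param nAGQ Quadrature nodes for logistic fits.
#' @param alpha Significance flag threshold.
#' @param p_adjust Add Benjamini-Hochberg adjusted p-values?
#' @return A tibble of class `cvl_signature_scan`, one row per analyte,
#'   ordered by panel analyte class: `analyte`, `class`, `exposure`,
#'   `route`, `detection`, `estimate` (log10-concentration difference or
#'   log odds-ratio), `ci_lo`, `ci_hi`, `p_value`, `significant`,
#'   `n_visits`, `n_women`, `adjusted`, `covariates`, `skipped`,
#'   `skip_reason`.
#' @export
signature_scan <- function(cohort, exposure, panel = NULL, adjusted = FALSE,
                           phases = NULL, flags = NULL, nAGQ = 15,
                           alpha = 0.05, p_adjust = FALSE) {
  if (is.null(panel)) panel <- cohort$panel
  if (is.null(panel)) abort("no panel supplied and cohort carries none")
  spec <- exposure_spec(exposure)
  if (is.null(flags)) flags <- flag_healthy_visits(cohort$visits, cohort$women)
  if (spec$name == "phase" && is.null(phases)) {
    phases <- call_cycle_phases(cohort$visits, cohort$women)
  }
  design <- encode_exposure(flags, cohort$women, exposure, phases = phases)
  m <- cohort$measurements %>%
    mutate(detected = as.numeric(.data$censor != "below_lloq")) %>%
    impute_censored(panel) %>%
    log10_transform() %>%
    inner_join(design, by = c("woman_id", "visit_index"))
  covars <- spec$covariates
  res <- map(panel$analyte, function(an) {
    d <- m %>% filter(.data$analyte == an)
    if (nrow(d) == 0) {
      row <- .skip_row("no measurements in analysis subset") %>%
        mutate(route = NA_character_, detection = NA_real_,
               n_visits = 0L, n_women = 0L)
    } else {
      det <- mean(d$detected)
      route <- select_route(det)
      fit_row <- if (route == "linear") {
        fit_lmm(d, covars, adjusted)
      } else {
        fit_relogit(d, covars, adjusted, nAGQ = nAGQ)
      }
      row <- fit_row %>%
        mutate(route = route, detection = det, n_visits = nrow(d),
               n_women = length(unique(d$woman_id)))
    }
    row %>% mutate(analyte = an)
  }) %>% list_rbind()
  out <- res %>%
    left_join(panel %>% select("analyte", "class"), by = "analyte") %>%
    mutate(exposure = spec$name,
           covariates = if (isTRUE(adjusted)) paste(covars, collapse = ", ") else "",
           adjusted = adjusted,
           significant = !.data$skipped & .data$p_value <= alpha) %>%
    select("analyte", "class", "exposure", "route", "detection", "estimate",
           "ci_lo", "ci_hi", "p_value", "significant", "n_visits",
           "n_women", "adjusted", "covariates", "skipped", "skip_reason") %>%
    arrange(match(.data$analyte, panel$analyte))
  if (p_adjust) {
    out <- out %>% mutate(p_adj = stats::p.adjust(.data$p_value, "BH"))
  }
  class(out) <- c("cvl_signature_scan", class(out))
  out
}
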
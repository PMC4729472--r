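# Quantification-limit handling: substitution imputation, detection
# proportions, model routing, log10 transform.

#' Impute censored concentrations
#'
#' Rows flagged `below_lloq` are assigned half the analyte's LLOQ; rows
#' flagged `above_uloq` twice the ULOQ. Quantified rows are unchanged and
#' censor flags are preserved, so imputation is idempotent.
#'
#' @param measurements Measurement tibble with a `censor` column.
#' @param panel Panel with `lloq`/`uloq` per analyte.
#' @return The measurement tibble with imputed `value`s.
#' @export
impute_censored <- function(measurements, panel) {
  lim <- panel %>% select("analyte", "lloq", "uloq")
  out <- measurements %>% left_join(lim, by = "analyte")
  if (anyNA(out$lloq)) {
    abort(paste0("panel lacks limits for analyte(s): ",
                 paste(unique(out$analyte[is.na(out$lloq)]), collapse = ", ")))
  }
  bad <- which(out$censor == "quantified" &
                 (out$value < out$lloq | out$value > out$uloq))
  if (length(bad) > 0) {
    abort(paste0("quantified value(s) outside [lloq, uloq] in row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  out %>%
    mutate(value = case_when(.data$censor == "below_lloq" ~ .data$lloq / 2,
                             .data$censor == "above_uloq" ~ 2 * .data$uloq,
                             TRUE ~ .data$value)) %>%
    select(-"lloq", -"uloq")
}

#' Proportion of measurements above the LLOQ
#'
#' The detection proportion counts rows whose censor flag is not
#' `below_lloq` (values above the ULOQ are quantifiable signal and count as
#' detected). It depends only on the flags, never on (possibly imputed)
#' values.
#'
#' @param measurements Measurement tibble (typically already restricted to
#'   the analysis subset).
#' @param analyte Optional single analyte name to restrict to.
#' @return A fraction in `[0, 1]`; errors on zero rows.
#' @export
detection_proportion <- function(measurements, analyte = NULL) {
  m <- measurements
  if (!is.null(analyte)) m <- m %>% filter(.data$analyte == !!analyte)
  if (nrow(m) == 0) abort("no measurement rows in the requested subset")
  mean(m$censor != "below_lloq")
}

#' Select the model route for an analyte
#'
#' Analytes detected in more than 85% of samples of the analysis subset are
#' modelled on the continuous (log10) scale with a random-intercept linear
#' model; analytes at or below 85% are modelled as detected/undetected with
#' a random-intercept logistic model. The inequality is strict: a detection
#' fraction of exactly 0.85 routes to logistic.
#'
#' @param detection Detection fraction(s) in `[0, 1]`.
#' @return `"linear"` or `"logistic"` (vectorised).
#' @export
select_route <- function(detection) {
  if (any(detection < 0 | detection > 1, na.rm = TRUE)) {
    abort("detection fractions must lie in [0, 1]")
  }
  ifelse(detection > 0.85, "linear", "logistic")
}

#' Log10-transform a measurement table
#'
#' @param measurements Measurement tibble; every value must be positive
#'   (guaranteed after [impute_censored()]).
#' @return The tibble with `value <- log10(value)` and, when a `units`
#'   column is present, units prefixed `log10 `.
#' @export
log10_transform <- function(measurements) {
  if (any(measurements$value <= 0, na.rm = TRUE)) {
    abort("nonpositive concentration encountered; run impute_censored() first")
  }
  out <- measurements %>% mutate(value = log10(.data$value))
  if ("units" %in% names(out)) {
    out <- out %>% mutate(units = paste0("log10 ", .data$units))
  }
  out
}
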
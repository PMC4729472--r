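# broom-style tidiers for fitted objects.

#' Tidy a variance-components fit
#'
#' @param x A `cvl_vc` from [reml_fit()].
#' @param ... Unused.
#' @return A tibble with one row per component (`sigma_b2`, `sigma_w2`,
#'   `icc`).
#' @export
tidy.cvl_vc <- function(x, ...) {
  tibble(term = c("sigma_b2", "sigma_w2", "icc"),
         estimate = c(x$sigma_b2, x$sigma_w2, x$icc),
         conf.low = c(NA, NA, x$icc_ci[1]),
         conf.high = c(NA, NA, x$icc_ci[2]))
}

#' One-row summary of a variance-components fit
#'
#' @inheritParams tidy.cvl_vc
#' @return A one-row tibble: ICC, F test, sample sizes, boundary flag.
#' @export
glance.cvl_vc <- function(x, ...) {
  tibble(icc = x$icc, sigma_b2 = x$sigma_b2, sigma_w2 = x$sigma_w2,
         f_stat = x$f_stat, f_p = x$f_p, logLik = x$loglik,
         n_obs = x$n_obs, n_groups = x$n_groups, boundary = x$boundary)
}

#' Tidy a signature scan
#'
#' @param x A `cvl_signature_scan` from [signature_scan()].
#' @param ... Unused.
#' @return The scan as a plain tibble with broom-style column names.
#' @export
tidy.cvl_signature_scan <- function(x, ...) {
  as_tibble(x) %>%
    select(term = "analyte", "class", "exposure", "route",
           "estimate", conf.low = "ci_lo", conf.high = "ci_hi",
           p.value = "p_value", "n_visits", "n_women", "skipped")
}

#' One-row summary of a signature scan
#'
#' @inheritParams tidy.cvl_signature_scan
#' @return A one-row tibble with counts of fitted, skipped and significant
#'   analytes per route.
#' @export
glance.cvl_signature_scan <- function(x, ...) {
  tibble(exposure = x$exposure[1],
         n_analytes = nrow(x),
         n_linear = sum(x$route == "linear", na.rm = TRUE),
         n_logistic = sum(x$route == "logistic", na.rm = TRUE),
         n_skipped = sum(x$skipped),
         n_significant = sum(x$significant, na.rm = TRUE))
}
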
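# One-way random-effects variance decomposition of log10 concentrations:
# method-of-moments (ANOVA) estimator, profile-REML estimator, ICC, and the
# F test of between-/within-woman variation.

.group_stats <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- as.character(group[keep])
  if (length(values) == 0) abort("no non-missing observations")
  ni <- tapply(values, group, length)
  if (length(ni) < 2) abort("need at least two groups (women)")
  if (all(ni < 2)) abort("all groups are singletons; within-group variance is undefined")
  ybar <- tapply(values, group, mean)
  ssw_i <- tapply(values, group, function(y) sum((y - mean(y))^2))
  list(ni = as.numeric(ni), ybar = as.numeric(ybar),
       ssw = sum(ssw_i), N = length(values), k = length(ni),
       grand = mean(values))
}

#' ANOVA (method-of-moments) variance components
#'
#' One-way decomposition of values grouped by woman: `sigma_w2` is the
#' pooled within-group mean square, `sigma_b2 = max(0, (MSB - MSW) / n0)`
#' with `n0 = (N - sum(n_i^2)/N) / (k - 1)` the average group size for
#' unbalanced designs, and the F statistic `MSB/MSW` on `(k-1, N-k)` degrees
#' of freedom tests between- versus within-woman variation.
#'
#' @param values Numeric vector (typically log10 concentrations).
#' @param group Grouping vector (woman identifiers).
#' @return A list with `sigma_b2`, `sigma_w2`, `icc`, `f_stat`, `f_p`,
#'   `msb`, `msw`, `n_obs`, `n_groups`.
#' @examples
#' anova_components(c(1, 3, 5, 7), c("a", "a", "b", "b"))
#' @export
anova_components <- function(values, group) {
  gs <- .group_stats(values, group)
  msb <- sum(gs$ni * (gs$ybar - gs$grand)^2) / (gs$k - 1)
  msw <- gs$ssw / (gs$N - gs$k)
  n0 <- (gs$N - sum(gs$ni^2) / gs$N) / (gs$k - 1)
  sigma_b2 <- max(0, (msb - msw) / n0)
  f_stat <- msb / msw
  f_p <- pf(f_stat, gs$k - 1, gs$N - gs$k, lower.tail = FALSE)
  list(sigma_b2 = sigma_b2, sigma_w2 = msw,
       icc = icc(sigma_b2, msw),
       f_stat = f_stat, f_p = f_p, msb = msb, msw = msw,
       n_obs = gs$N, n_groups = gs$k)
}

# profiled REML criterion pieces at variance ratio lambda = sigma_b2/sigma_w2
.reml_profile <- function(lambda, gs) {
  w <- gs$ni / (1 + lambda * gs$ni)
  mu <- sum(w * gs$ybar) / sum(w)
  q <- gs$ssw + sum(w * (gs$ybar - mu)^2)
  list(w = w, mu = mu, q = q,
       # restricted log-likelihood profiled over mu and sigma_w2, up to a
       # constant not involving lambda
       ll = -0.5 * ((gs$N - 1) * log(q) + sum(log1p(lambda * gs$ni)) +
                      log(sum(w))))
}

# analytic gradient of the profiled restricted log-likelihood in lambda
.reml_gradient <- function(lambda, gs) {
  p <- .reml_profile(lambda, gs)
  dq <- -sum(p$w^2 * (gs$ybar - p$mu)^2)
  -0.5 * ((gs$N - 1) * dq / p$q + sum(p$w) - sum(p$w^2) / sum(p$w))
}

#' REML variance components for a one-way random-intercept model
#'
#' Maximises the restricted log-likelihood of `y_ij = mu + b_i + e_ij`
#' (`b ~ N(0, sigma_b2)`, `e ~ N(0, sigma_w2)`) over `sigma_b2 >= 0`,
#' `sigma_w2 > 0`. The problem is profiled to a one-dimensional search in
#' the variance ratio `lambda = sigma_b2/sigma_w2` (Brent bracketing on
#' `log(lambda)` followed by a root solve of the analytic gradient), so
#' boundary solutions `sigma_b2 = 0` are handled exactly. The ANOVA F test
#' of [anova_components()] is attached.
#'
#' @param values,group As in [anova_components()].
#' @param analyte Optional label carried into the result.
#' @param tol Convergence tolerance on the variance ratio.
#' @param max_iter Iteration cap for the gradient root solve.
#' @return An object of class `cvl_vc`: a list with `analyte`, `sigma_b2`,
#'   `sigma_w2`, `icc`, `icc_ci` (Wald 95% interval on the ICC, delta
#'   method; `NA` at the boundary), `f_stat`, `f_p`, `loglik` (profiled,
#'   up to a constant), `n_obs`, `n_groups`, `boundary`.
#' @export
reml_fit <- function(values, group, analyte = NA_character_,
                     tol = 1e-10, max_iter = 500) {
  gs <- .group_stats(values, group)
  an <- anova_components(values, group)

  lambda_hat <- 0
  if (.reml_gradient(0, gs) > 0) {
    # interior optimum: bracket on log(lambda), then solve the gradient
    obj <- function(t) -.reml_profile(exp(t), gs)$ll
    br <- optimize(obj, interval = c(-30, 30), tol = 1e-8)
    lo <- exp(br$minimum) / 4
    hi <- exp(br$minimum) * 4
    it <- 0
    while (.reml_gradient(hi, gs) > 0 && it < max_iter) { hi <- hi * 4; it <- it + 1 }
    while (.reml_gradient(lo, gs) < 0 && lo > 1e-300 && it < max_iter) {
      lo <- lo / 4; it <- it + 1
    }
    if (it >= max_iter) {
      abort(paste0("REML bracketing did not converge within ", max_iter,
                   " iterations (lambda bracket [", lo, ", ", hi, "])"))
    }
    root <- uniroot(.reml_gradient, gs = gs, lower = lo, upper = hi,
                    tol = tol, maxiter = max_iter)
    lambda_hat <- root$root
  }
  prof <- .reml_profile(lambda_hat, gs)
  sigma_w2 <- prof$q / (gs$N - 1)
  sigma_b2 <- lambda_hat * sigma_w2
  icc_hat <- icc(sigma_b2, sigma_w2)
  boundary <- lambda_hat == 0

  ci <- c(NA_real_, NA_real_)
  if (!boundary) {
    se <- .icc_wald_se(sigma_b2, sigma_w2, gs)
    if (is.finite(se)) {
      ci <- pmin(pmax(icc_hat + c(-1, 1) * qnorm(0.975) * se, 0), 1)
    }
  }

  structure(list(analyte = analyte, sigma_b2 = sigma_b2, sigma_w2 = sigma_w2,
                 icc = icc_hat, icc_ci = ci,
                 f_stat = an$f_stat, f_p = an$f_p,
                 loglik = prof$ll - 0.5 * (gs$N - 1) *
                   (1 + log(2 * pi) - log(gs$N - 1)),
                 n_obs = gs$N, n_groups = gs$k, boundary = boundary),
            class = "cvl_vc")
}

# full restricted log-likelihood in (sigma_b2, sigma_w2), up to a constant
.reml_ll2 <- function(sb2, sw2, gs) {
  vi <- sw2 + gs$ni * sb2
  w <- gs$ni / vi
  mu <- sum(gs$ni * gs$ybar / vi) / sum(gs$ni / vi)
  -0.5 * (sum((gs$ni - 1) * log(sw2) + log(vi)) + log(sum(w)) +
            gs$ssw / sw2 + sum(gs$ni * (gs$ybar - mu)^2 / vi))
}

# Wald SE of the ICC by the delta method from the numerical observed
# information of the restricted likelihood in (sigma_b2, sigma_w2)
.icc_wald_se <- function(sb2, sw2, gs) {
  h <- matrix(NA_real_, 2, 2)
  d <- c(max(sb2, 1e-4) * 1e-3, max(sw2, 1e-4) * 1e-3)
  f <- function(p) .reml_ll2(p[1], p[2], gs)
  p0 <- c(sb2, sw2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- d[i]; ej[j] <- d[j]
    h[i, j] <- (f(p0 + ei + ej) - f(p0 + ei - ej) -
                  f(p0 - ei + ej) + f(p0 - ei - ej)) / (4 * d[i] * d[j])
  }
  vc <- tryCatch(solve(-h), error = function(e) NULL)
  if (is.null(vc)) return(NA_real_)
  s <- sb2 + sw2
  grad <- c(sw2 / s^2, -sb2 / s^2)
  v <- drop(t(grad) %*% vc %*% grad)
  if (v < 0) return(NA_real_)
  sqrt(v)
}

#' @export
print.cvl_vc <- function(x, ...) {
  cat("<cvl_vc>", if (!is.na(x$analyte)) x$analyte else "", "\n",
      sprintf("  sigma_b2 = %.4f, sigma_w2 = %.4f, ICC = %.3f%s\n",
              x$sigma_b2, x$sigma_w2, x$icc,
              if (x$boundary) " (boundary)" else ""),
      sprintf("  F = %.2f, p = %.3g (%d women, %d obs)\n",
              x$f_stat, x$f_p, x$n_groups, x$n_obs))
  invisible(x)
}

#' Intraclass correlation coefficient
#'
#' `icc = sigma_b2 / (sigma_b2 + sigma_w2)`: the share of total variance of
#' log-transformed concentration attributable to between-woman differences.
#'
#' @param sigma_b2 Between-woman variance (>= 0).
#' @param sigma_w2 Within-woman variance (> 0).
#' @return A value in `[0, 1)` (vectorised); 0 iff `sigma_b2 = 0`.
#' @export
icc <- function(sigma_b2, sigma_w2) {
  if (any(sigma_b2 < 0)) abort("sigma_b2 must be >= 0")
  if (any(sigma_w2 <= 0)) {
    abort("sigma_w2 must be > 0 (both components zero leaves the ICC undefined)")
  }
  sigma_b2 / (sigma_b2 + sigma_w2)
}

#' Median and interquartile range of a set of ICCs
#'
#' Summarises per-analyte ICCs with the `(n+1)p` interpolation quantile
#' convention (R quantile type 6).
#'
#' @param iccs Numeric vector of ICC values.
#' @return A tibble with `median`, `q1`, `q3`, `n`.
#' @export
icc_summary <- function(iccs) {
  iccs <- iccs[!is.na(iccs)]
  if (length(iccs) < 1) abort("need at least one ICC value")
  q <- quantile(iccs, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  tibble(median = q[2], q1 = q[1], q3 = q[3], n = length(iccs))
}

#' Per-analyte variance components across a cohort
#'
#' For each analyte: restrict to healthy visits, impute censored values,
#' optionally normalise by a reference analyte measured at the same visit
#' (total protein or involucrin, to account for the CVL dilution factor),
#' log10-transform, and fit the one-way REML decomposition.
#'
#' @param measurements Measurement tibble.
#' @param flags Flagged visits from [flag_healthy_visits()].
#' @param panel Analyte panel.
#' @param normalize `"none"`, `"total_protein"` or `"involucrin"`.
#' @return A tibble with one row per analyte: variance components, ICC with
#'   CI, F test, and sample sizes; ordered by panel analyte class.
#' @export
icc_scan <- function(measurements, flags, panel,
                     normalize = c("none", "total_protein", "involucrin")) {
  normalize <- match.arg(normalize)
  healthy_key <- flags %>% filter(.data$healthy) %>%
    select("woman_id", "visit_index")
  m <- measurements %>%
    inner_join(healthy_key, by = c("woman_id", "visit_index")) %>%
    impute_censored(panel)
  if (normalize != "none") {
    ref_name <- c(total_protein = "Total protein",
                  involucrin = "Involucrin")[[normalize]]
    ref <- m %>% filter(.data$analyte == ref_name) %>%
      select("woman_id", "visit_index", ref_value = "value")
    m <- m %>%
      filter(.data$analyte != ref_name) %>%
      inner_join(ref, by = c("woman_id", "visit_index")) %>%
      mutate(value = .data$value / .data$ref_value) %>%
      select(-"ref_value")
  }
  m <- m %>% log10_transform()
  m %>%
    group_by(.data$analyte) %>%
    group_modify(function(d, key) {
      fit <- reml_fit(d$value, d$woman_id, analyte = key$analyte)
      tibble(sigma_b2 = fit$sigma_b2, sigma_w2 = fit$sigma_w2,
             icc = fit$icc, icc_ci_lo = fit$icc_ci[1],
             icc_ci_hi = fit$icc_ci[2], f_stat = fit$f_stat, f_p = fit$f_p,
             n_visits = fit$n_obs, n_women = fit$n_groups,
             boundary = fit$boundary)
    }) %>%
    ungroup() %>%
    left_join(panel %>% select("analyte", "class"), by = "analyte") %>%
    arrange(match(.data$analyte, panel$analyte)) %>%
    relocate("class", .after = "analyte")
}
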
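test_that("the ANOVA estimator reproduces a hand-computed example", {
  # groups {1,3} and {5,7}: MSB = 16, MSW = 2, n0 = 2
  a <- anova_components(c(1, 3, 5, 7), c("a", "a", "b", "b"))
  expect_equal(a$sigma_b2, 7)
  expect_equal(a$sigma_w2, 2)
  expect_equal(a$icc, 7 / 9)
  expect_equal(a$f_stat, 8)
  expect_equal(a$f_p, pf(8, 1, 2, lower.tail = FALSE))
})

test_that("degenerate groupings are rejected with clear errors", {
  expect_error(anova_components(numeric(0), character(0)), "no non-missing")
  expect_error(anova_components(1:4, rep("a", 4)), "two groups")
  expect_error(anova_components(1:3, c("a", "b", "c")), "singletons")
  expect_error(icc(-1, 1), ">= 0")
  expect_error(icc(1, 0), "> 0")
})

test_that("REML agrees with ANOVA on balanced designs at interior optima", {
  set.seed(31)
  for (rep in 1:25) {
    k <- sample(5:20, 1)
    n <- sample(3:8, 1)
    g <- rep(sprintf("g%02d", 1:k), each = n)
    y <- rnorm(k, 0, 1)[rep(1:k, each = n)] + rnorm(k * n, 0, 0.7)
    a <- anova_components(y, g)
    if (a$sigma_b2 == 0) next  # boundary: estimators legitimately differ
    r <- reml_fit(y, g)
    expect_equal(r$sigma_b2, a$sigma_b2, tolerance = 1e-8)
    expect_equal(r$sigma_w2, a$sigma_w2, tolerance = 1e-8)
    expect_equal(r$icc, a$icc, tolerance = 1e-8)
  }
})

test_that("REML matches lme4 on an unbalanced design", {
  set.seed(32)
  ni <- sample(2:9, 12, replace = TRUE)
  g <- rep(sprintf("g%02d", seq_along(ni)), times = ni)
  y <- rnorm(length(ni), 0, 0.8)[rep(seq_along(ni), times = ni)] +
    rnorm(sum(ni), 0, 0.5)
  r <- reml_fit(y, g)
  fit <- lme4::lmer(y ~ 1 + (1 | g),
                    data = data.frame(y = y, g = g), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(r$sigma_b2, vc$vcov[1], tolerance = 1e-6)
  expect_equal(r$sigma_w2, vc$vcov[2], tolerance = 1e-6)
  # absolute restricted log-likelihoods agree (constants included)
  expect_equal(r$loglik, as.numeric(logLik(fit)), tolerance = 1e-6)
})

test_that("boundary data pin sigma_b2 at zero and flag it", {
  # identical group means, pure within-group noise
  y <- rep(c(-1, 1), 10)
  g <- rep(sprintf("g%d", 1:10), each = 2)
  r <- reml_fit(y, g)
  expect_true(r$boundary)
  expect_equal(r$sigma_b2, 0)
  expect_equal(r$icc, 0)
  expect_true(all(is.na(r$icc_ci)))
})

test_that("the Wald interval covers and is ordered on a well-powered fit", {
  set.seed(33)
  g <- rep(sprintf("g%03d", 1:150), each = 8)
  y <- rnorm(150, 0, 1)[rep(1:150, each = 8)] + rnorm(1200, 0, 1)
  r <- reml_fit(y, g)
  expect_false(r$boundary)
  expect_true(r$icc_ci[1] < r$icc & r$icc < r$icc_ci[2])
  expect_true(r$icc_ci[1] <= 0.5 && 0.5 <= r$icc_ci[2])
  expect_lt(r$icc_ci[2] - r$icc_ci[1], 0.25)
})

test_that("icc_summary uses the (n+1)p quantile convention", {
  x <- (1:10) / 20
  s <- icc_summary(x)
  expect_equal(s$n, 10)
  expect_equal(s$median, quantile(x, 0.5, type = 6, names = FALSE))
  expect_equal(s$q1, 2.75 / 20)  # (n+1)*0.25 = 2.75th order statistic
  expect_equal(s$q3, 8.25 / 20)
  expect_error(icc_summary(NA_real_), "at least one")
})

test_that("icc_scan decomposes every analyte on the healthy subset", {
  co <- shared_cohort()
  flags <- shared_flags()
  p <- default_panel()
  scan <- icc_scan(co$measurements, flags, p)
  expect_equal(nrow(scan), 46)
  expect_equal(scan$analyte, p$analyte)
  expect_true(all(scan$icc >= 0 & scan$icc < 1))
  expect_true(all(scan$n_women <= 100))

  # one analyte checked against a direct fit on the same subset
  healthy <- flags %>% filter(healthy) %>% select(woman_id, visit_index)
  d <- co$measurements %>%
    filter(analyte == "IL-8") %>%
    inner_join(healthy, by = c("woman_id", "visit_index")) %>%
    impute_censored(p) %>%
    log10_transform()
  direct <- reml_fit(d$value, d$woman_id)
  expect_equal(scan$icc[scan$analyte == "IL-8"], direct$icc)
})

test_that("normalised scans divide by the reference analyte", {
  co <- shared_cohort()
  flags <- shared_flags()
  p <- default_panel()
  norm <- icc_scan(co$measurements, flags, p, normalize = "total_protein")
  expect_false("Total protein" %in% norm$analyte)
  expect_equal(nrow(norm), 45)

  healthy <- flags %>% filter(healthy) %>% select(woman_id, visit_index)
  m <- co$measurements %>%
    inner_join(healthy, by = c("woman_id", "visit_index")) %>%
    impute_censored(p)
  tp <- m %>% filter(analyte == "Total protein") %>%
    select(woman_id, visit_index, tp = value)
  d <- m %>% filter(analyte == "IL-8") %>%
    inner_join(tp, by = c("woman_id", "visit_index"))
  direct <- reml_fit(log10(d$value / d$tp), d$woman_id)
  expect_equal(norm$icc[norm$analyte == "IL-8"], direct$icc)
})
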
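test_that("exposure specs encode the a priori adjustment sets", {
  expect_equal(exposure_spec("dmpa")$covariates,
               c("age", "sex_past_3_days", "hb_present"))
  expect_equal(exposure_spec("psa")$covariates, c("age", "hb_present"))
  expect_equal(exposure_spec("haemoglobin")$covariates,
               c("age", "sex_past_3_days"))
  expect_equal(exposure_spec("neutrophils")$scores, 0:3)
  expect_error(exposure_spec("smoking"))
})

test_that("the pH trend score bins the strip values", {
  expect_equal(.ph_score(ph_strip_values),
               c(0, 0, 1, 1, 2, 2, 2, 2))
  expect_true(is.na(.ph_score(NA)))
})

test_that("exposure encoders restrict to the right analysis subsets", {
  co <- shared_cohort()
  flags <- shared_flags()

  dmpa <- encode_exposure(flags, co$women, "dmpa")
  coc_users <- co$women$woman_id[co$women$contraception == "coc"]
  expect_false(any(dmpa$woman_id %in% coc_users))
  expect_true(all(dmpa$exposure %in% 0:1))

  soap <- encode_exposure(flags, co$women, "soap")
  med <- flags %>% filter(ivp_insert_med) %>%
    mutate(key = paste(woman_id, visit_index))
  expect_false(any(paste(soap$woman_id, soap$visit_index) %in% med$key))

  ect <- encode_exposure(flags, co$women, "ectopy")
  expect_true(all(ect$visit_index %in% c(1, 12)))

  hb <- encode_exposure(flags, co$women, "haemoglobin")
  expect_true(all(hb$exposure %in% 0:3))

  expect_error(encode_exposure(flags, co$women, "phase"),
               "requires phase calls")
})

test_that("fit_lmm recovers a planted shift and skips degenerate designs", {
  set.seed(11)
  n_w <- 60
  d <- tidyr::expand_grid(woman_id = sprintf("W%02d", 1:n_w),
                          visit_index = 1:6) %>%
    mutate(exposure = rep(rep(0:1, each = 3), n_w),
           value = rnorm(n_w, 0, 0.4)[match(woman_id, unique(woman_id))] +
             0.5 * exposure + rnorm(n(), 0, 0.3))
  r <- fit_lmm(d)
  expect_false(r$skipped)
  expect_lt(abs(r$estimate - 0.5), 0.1)
  expect_true(r$ci_lo < 0.5 & 0.5 < r$ci_hi)
  expect_lt(r$p_value, 1e-6)

  expect_equal(fit_lmm(d %>% mutate(exposure = 1))$skip_reason,
               "exposure constant in subset")
  expect_equal(fit_lmm(d %>% filter(woman_id == "W01"))$skip_reason,
               "fewer than two women")
})

test_that("fit_relogit recovers a planted odds ratio and flags inestimable arms", {
  set.seed(12)
  n_w <- 120
  b <- rnorm(n_w, 0, 0.8)
  d <- tidyr::expand_grid(woman_id = sprintf("W%03d", 1:n_w),
                          visit_index = 1:8) %>%
    mutate(exposure = rep(rep(0:1, each = 4), n_w),
           eta = b[match(woman_id, unique(woman_id))] + 1 * exposure,
           detected = as.numeric(runif(n()) < plogis(eta)))
  r <- fit_relogit(d)
  expect_false(r$skipped)
  expect_lt(abs(r$estimate - 1), 0.4)
  expect_true(r$ci_lo < 1 & 1 < r$ci_hi)

  allone <- d %>% mutate(detected = ifelse(exposure == 1, 1, detected))
  expect_match(fit_relogit(allone)$skip_reason, "inestimable")
  expect_equal(fit_relogit(d %>% mutate(detected = 1))$skip_reason,
               "all visits detected")
  expect_equal(fit_relogit(d %>% mutate(detected = 0))$skip_reason,
               "no visits detected")

  kept <- fit_relogit(d, keep_fit = TRUE)
  expect_s4_class(attr(kept, "fit"), "glmerMod")
})

test_that("signature_scan routes by detection and returns one row per analyte", {
  co <- shared_cohort()
  flags <- shared_flags()
  p <- default_panel()
  scan <- signature_scan(co, "dmpa", flags = flags)
  expect_s3_class(scan, "cvl_signature_scan")
  expect_equal(nrow(scan), 46)
  expect_equal(scan$analyte, p$analyte)
  expect_true(all(scan$exposure == "dmpa"))
  ok <- !scan$skipped
  expect_true(all(scan$route[ok] ==
                    select_route(scan$detection[ok])))
  expect_true(all(scan$ci_lo[ok] < scan$ci_hi[ok]))
  expect_equal(scan$significant[ok], scan$p_value[ok] <= 0.05)
  expect_true(all(is.na(scan$estimate[scan$skipped])))
  expect_true(all(!is.na(scan$skip_reason[scan$skipped])))
  expect_true(all(scan$covariates == ""))
})

test_that("adjusted scans carry the exposure's covariate string", {
  co <- shared_cohort()
  flags <- shared_flags()
  adj <- signature_scan(co, "psa", flags = flags, adjusted = TRUE)
  expect_true(all(adj$adjusted))
  expect_true(all(adj$covariates == "age, hb_present"))
})

test_that("a planted DMPA effect is detected by the scan", {
  cfg <- sim_config(effects = list(dmpa = c("IL-8" = 0.6)))
  co <- simulate_cohort(cfg, seed = 21)
  scan <- signature_scan(co, "dmpa")
  row <- scan %>% filter(analyte == "IL-8")
  expect_false(row$skipped)
  expect_equal(row$route, "linear")
  expect_true(row$ci_lo < 0.6 & 0.6 < row$ci_hi)
  expect_true(row$significant)
})

test_that("Benjamini-Hochberg adjustment is optional and monotone", {
  co <- shared_cohort()
  flags <- shared_flags()
  scan <- signature_scan(co, "lymphocytes", flags = flags, p_adjust = TRUE)
  expect_true("p_adj" %in% names(scan))
  ok <- !scan$skipped
  expect_true(all(scan$p_adj[ok] >= scan$p_value[ok]))
})
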
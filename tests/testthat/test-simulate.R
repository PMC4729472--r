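test_that("the generator is a deterministic function of (config, seed)", {
  cfg <- sim_config(n_women = 15)
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a$women, b$women)
  expect_identical(a$visits, b$visits)
  expect_identical(a$measurements, b$measurements)
  c <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(a$measurements, c$measurements))
})

test_that("cohort dimensions and attendance match the study design", {
  co <- shared_cohort()
  expect_equal(nrow(co$women), 100)
  expect_equal(nrow(co$visits), 1200)
  # attended ~ Binomial(1200, 0.92); allow 4 SD
  att <- sum(co$visits$attended)
  expect_lt(abs(att - 0.92 * 1200), 4 * sqrt(1200 * 0.92 * 0.08))
  expect_silent(validate_cohort(co$women, co$visits, co$measurements))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(attendance_prob = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(contraception_probs = c(none = 0.5, condom = 0.1,
                                                  dmpa = 0.1, coc = 0.1,
                                                  other = 0.1)), "sum to 1")
  expect_error(sim_config(pdg_fold_rise = -1), "positive")
  expect_error(sim_config(effects = list(dmpa = c("NOPE" = 1))), "absent")
})

test_that("PDG series has the configured fold-rise and bounded flat noise", {
  days <- seq(1, 28, by = 3)
  set.seed(1)
  ov <- generate_pdg_series(days, cycle_day0 = 0, ovulatory = TRUE,
                            fold_rise = 6, noise_bound = 1, crt_sdlog = 0.4)
  r <- compute_cycle_ratios(ov$pdg, ov$crt)
  expect_equal(max(r) / min(r), 6)

  an <- generate_pdg_series(days, ovulatory = FALSE, noise_bound = 1.4)
  ra <- compute_cycle_ratios(an$pdg, an$crt)
  expect_lt(max(ra), 1.4 + 1e-12)
  expect_false(classify_ovulatory(ra))

  expect_error(generate_pdg_series(days, fold_rise = 0), "positive")
})

test_that("assay censoring flags exactly the out-of-limit values", {
  m <- tibble(woman_id = "W1", visit_index = 1:4, analyte = "IL-X",
              value = c(0.5, 2, 50, 200), censor = "quantified")
  p <- mini_panel(lloq = 1, uloq = 100)
  cen <- apply_assay_censoring(m, p)
  expect_equal(cen$censor, c("below_lloq", "quantified", "quantified",
                             "above_uloq"))
  none <- apply_assay_censoring(m, mini_panel(lloq = 0.1, uloq = 1000))
  expect_true(all(none$censor == "quantified"))
  all_bel <- apply_assay_censoring(m, mini_panel(lloq = 1e6, uloq = 1e7))
  expect_true(all(all_bel$censor == "below_lloq"))
  expect_error(apply_assay_censoring(m %>% mutate(analyte = "OTHER"), p),
               "lacks limits")
})

test_that("sample ICC of the uncensored matrix converges to the target", {
  for (icc_t in c(0.2, 0.5)) {
    sd_b <- sqrt(icc_t)
    sd_w <- sqrt(1 - icc_t)
    cfg <- sim_config(n_women = 500, panel = mini_panel(sd_b, sd_w),
                      censor_at_assay = FALSE)
    co <- simulate_cohort(cfg, seed = round(1000 * icc_t))
    fit <- reml_fit(log10(co$measurements$value), co$measurements$woman_id)
    expect_lt(abs(fit$icc - icc_t), 0.03)
  }
})

test_that("zero between-woman variance yields near-zero downstream ICC", {
  cfg <- sim_config(n_women = 120, panel = mini_panel(sd_b = 0, sd_w = 0.4),
                    censor_at_assay = FALSE)
  co <- simulate_cohort(cfg, seed = 2)
  fit <- reml_fit(log10(co$measurements$value), co$measurements$woman_id)
  expect_lt(fit$icc, 0.03)
})
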
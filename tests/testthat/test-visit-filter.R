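test_that("the healthy flag applies every exclusion, in report order", {
  toy <- toy_cohort()
  flags <- flag_healthy_visits(toy$visits, toy$women)

  # W1 is TV-positive: all her visits are excluded at the woman level
  w1 <- flags %>% filter(woman_id == "W1")
  expect_true(all(!w1$healthy))
  expect_true(all(w1$exclusion_reason == "woman_sti"))

  # W2: one BV visit excluded, the rest healthy (IVPs do not exclude)
  w2 <- flags %>% filter(woman_id == "W2")
  expect_equal(w2$exclusion_reason, c(NA, "bv", NA, NA))

  # W3: menstruating visit excluded, others healthy
  w3 <- flags %>% filter(woman_id == "W3")
  expect_equal(w3$exclusion_reason, c("menstruating", NA, NA, NA))

  # attendance outranks menstruation in the reported reason
  v <- toy$visits
  v$attended[v$woman_id == "W3" & v$visit_index == 1] <- FALSE
  expect_equal(flag_healthy_visits(v, toy$women)$exclusion_reason[
    v$woman_id == "W3" & v$visit_index == 1], "not_attended")
})

test_that("indeterminate STI results exclude the woman with a message", {
  toy <- toy_cohort()
  w <- toy$women
  w$ct_pos[2] <- NA
  expect_message(flags <- flag_healthy_visits(toy$visits, w), "W2")
  expect_true(all(flags$exclusion_reason[flags$woman_id == "W2"] ==
                    "woman_sti_indeterminate"))
})

test_that("a Nugent override redefines BV", {
  toy <- toy_cohort()
  nugent <- rep(3, nrow(toy$visits))
  nugent[toy$visits$woman_id == "W2" & toy$visits$visit_index == 3] <- 8
  flags <- flag_healthy_visits(toy$visits, toy$women, nugent = nugent)
  w2 <- flags %>% filter(woman_id == "W2")
  expect_equal(w2$exclusion_reason, c(NA, NA, "bv", NA))
  expect_error(flag_healthy_visits(toy$visits, toy$women, nugent = 1:3),
               "one score per visit")
})

test_that("IVP comparison sets pair exposed visits with clean references", {
  toy <- toy_cohort()
  flags <- flag_healthy_visits(toy$visits, toy$women)
  soap <- build_ivp_comparison(flags, "soap")
  expect_true(all(soap$healthy))
  # W2 visit 3 reports soap AND cloth: it lands in both exposure arms
  expect_equal(soap$ivp_arm[soap$woman_id == "W2" & soap$visit_index == 3],
               "exposed")
  cloth <- build_ivp_comparison(flags, "cloth")
  expect_equal(cloth$ivp_arm[cloth$woman_id == "W2" & cloth$visit_index == 3],
               "exposed")
  # the medication-insertion visit (W3 v2) is in no subset
  expect_false(any(soap$woman_id == "W3" & soap$visit_index == 2))
  # all other healthy visits are references
  expect_true(all(soap$ivp_arm[!(soap$woman_id == "W2" &
                                   soap$visit_index == 3)] == "reference"))
  expect_error(build_ivp_comparison(flags, "douche"), "unknown practice")
  expect_error(build_ivp_comparison(toy$visits, "soap"),
               "flag_healthy_visits")
})

test_that("cascade percentages are of the previous step, half rounded up", {
  tab <- cascade_table(c(scheduled = 1200, attended = 1108,
                         non_menstruating = 956, healthy = 370))
  expect_equal(tab$pct_of_previous, c(NA, 92, 86, 39))
  # 925/1000 = 92.5 rounds away from zero to 93, not banker's 92
  expect_equal(cascade_table(c(a = 1000, b = 925))$pct_of_previous[2], 93)
  expect_error(cascade_table(c(10, 5)), "named")
  expect_error(cascade_table(c(a = 10, b = 12)), "non-increasing")
})

test_that("filter_report counts the simulated cohort consistently", {
  flags <- shared_flags()
  rep <- filter_report(flags)
  expect_equal(rep$step, c("scheduled", "attended", "non_menstruating",
                           "healthy"))
  expect_equal(rep$n[1], 1200)
  expect_true(all(diff(rep$n) <= 0))
  manual <- sum(flags$healthy)
  expect_equal(rep$n[4], manual)
  expect_lte(attr(rep, "n_women_healthy"), 100)
  expect_gt(attr(rep, "n_women_healthy"), 0)
})
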
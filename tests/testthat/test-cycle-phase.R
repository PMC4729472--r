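test_that("ratios are indexed to the study minimum and scale invariant", {
  pdg <- c(2, 1, 6, 12)
  crt <- c(1, 1, 1, 2)
  r <- compute_cycle_ratios(pdg, crt)
  expect_equal(min(r), 1)
  expect_equal(r, c(2, 1, 6, 6))
  expect_equal(compute_cycle_ratios(pdg * 1000, crt), r)
  expect_error(compute_cycle_ratios(pdg, crt[1:3]), "same length")
  expect_error(compute_cycle_ratios(c(1, -1), c(1, 1)), "positive")
  expect_error(compute_cycle_ratios(1, 1), "two visits")
})

test_that("the ovulation threshold is strictly greater than 4.0", {
  expect_false(classify_ovulatory(c(1, 2, 4.0)))
  expect_true(classify_ovulatory(c(1, 2, 4.0 + 1e-9)))
  expect_false(classify_ovulatory(c(NA, 1)))
})

test_that("phase assignment segments the cycle around menses and the rise", {
  ratios <- c(1, 1, 1.2, 2, 5, 6, 6, 5)
  mens <- c(TRUE, TRUE, rep(FALSE, 6))
  res <- assign_phase(ratios, mens)
  expect_equal(res$day1_visit, 1L)
  expect_equal(res$rise_visit, 5L)
  expect_equal(res$phase,
               c("unassigned", "unassigned", "pre_ovulation", "pre_ovulation",
                 rep("post_ovulation", 4)))
  expect_true(is.na(res$reason))

  # visits before day 1 stay unassigned
  res2 <- assign_phase(c(1, 5, 5, 1, 1, 5, 5, 5),
                       c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                         FALSE))
  expect_equal(res2$phase[1:4], rep("unassigned", 4))
  expect_equal(res2$rise_visit, 6L)
})

test_that("a lone spike is not a sustained rise, unless min_sustained = 1", {
  ratios <- c(1, 1, 6, 1, 1, 1)
  mens <- c(TRUE, rep(FALSE, 5))
  strict <- assign_phase(ratios, mens, min_sustained = 2)
  expect_equal(strict$reason, "no_rise")
  expect_true(all(strict$phase == "unassigned"))
  lax <- assign_phase(ratios, mens, min_sustained = 1)
  expect_equal(lax$rise_visit, 3L)

  # a crossing at the final visit counts even under the sustained rule
  tail <- assign_phase(c(1, 1, 1, 6), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(tail$rise_visit, 4L)
  expect_error(assign_phase(ratios, mens, min_sustained = 3), "1 or 2")
})

test_that("non-assignable series carry an explicit reason", {
  expect_equal(assign_phase(c(1, 6, 6), rep(FALSE, 3),
                            hormonal = TRUE)$reason,
               "hormonal_contraception")
  expect_equal(assign_phase(c(1, 2, 3), c(TRUE, FALSE, FALSE))$reason,
               "not_ovulatory")
  expect_equal(assign_phase(c(1, 6, 6), rep(FALSE, 3))$reason,
               "no_observed_menstruation")
  expect_equal(assign_phase(c(1, 6, 6, 1, 6, 6),
                            c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))$reason,
               "multiple_menstruations")
})

test_that("cohort-level calls respect contraception and agree with truth", {
  cfg <- sim_config(n_women = 60, attendance_prob = 1, pdg_noise_bound = 1)
  co <- simulate_cohort(cfg, seed = 7)
  phases <- call_cycle_phases(co$visits, co$women)

  hormonal_ids <- co$women$woman_id[co$women$contraception %in%
                                      c("dmpa", "coc")]
  hp <- phases %>% filter(woman_id %in% hormonal_ids)
  expect_true(all(hp$phase == "unassigned"))
  expect_true(all(hp$phase_reason == "hormonal_contraception"))

  # with noiseless PDG the ovulatory call equals the generator's truth
  called <- phases %>% distinct(woman_id, ovulatory)
  truth <- co$truth$women %>% select(woman_id, ovulatory)
  j <- inner_join(called, truth, by = "woman_id",
                  suffix = c("_called", "_true"))
  expect_equal(j$ovulatory_called, j$ovulatory_true)

  # assigned phases never contradict the generator's phase truth
  tp <- co$truth$visits %>% select(woman_id, visit_index, true_phase)
  cmp <- phases %>%
    inner_join(tp, by = c("woman_id", "visit_index")) %>%
    filter(phase != "unassigned")
  expect_gt(nrow(cmp), 0)
  expect_true(all(cmp$true_phase[cmp$phase == "pre_ovulation"] ==
                    "follicular"))
  expect_true(all(cmp$true_phase[cmp$phase == "post_ovulation"] == "luteal"))
})
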
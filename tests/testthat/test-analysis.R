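test_that("compliance summary reproduces the double-70% rule arithmetic", {
  cs <- compliance_summary(records_with_compliance(c(89)))
  expect_equal(round(100 * cs$mean_rate, 2), 70.63)
  expect_true(tidy(cs)$meets_threshold[1])

  cs_full <- compliance_summary(records_with_compliance(c(126, 126)))
  expect_equal(cs_full$mean_rate, 1)
  expect_true(cs_full$feasible)

  expect_error(compliance_summary(records_with_compliance(1)[0, ]))
})

test_that("careless rate counts non-5 answers among shown checks", {
  mk <- function(n_shown, n_careless, n_total = 1000) {
    tibble::tibble(
      person_id = "p001", day = 1, slot = 1,
      completed = TRUE,
      attention_check_shown = c(rep(TRUE, n_shown), rep(FALSE, n_total - n_shown)),
      attention_check_value = c(rep(3L, n_careless), rep(5L, n_shown - n_careless),
                                rep(NA_integer_, n_total - n_shown))
    )
  }
  out <- careless_rate(mk(389, 6))
  expect_equal(round(100 * out$rate, 1), 1.5)
  expect_true(out$high_quality)

  clean <- careless_rate(mk(100, 0))
  expect_equal(clean$rate, 0)
  expect_true(clean$high_quality)

  noisy <- careless_rate(mk(389, 20))
  expect_equal(round(100 * noisy$rate, 2), 5.14)
  expect_false(noisy$high_quality)

  none <- careless_rate(mk(0, 0))
  expect_true(is.na(none$rate))
})

test_that("descriptive decomposition handles degenerate groupings", {
  rec <- tibble::tibble(
    person_id = rep(c("a", "b"), each = 3),
    completed = TRUE,
    stress = c(2, 2, 2, 4, 4, 4)
  )
  d <- descriptives(rec, "stress")
  expect_equal(d$grand_mean, 3)
  expect_equal(d$between_sd, stats::sd(c(2, 4)))
  expect_equal(d$mean_within_sd, 0)

  single <- descriptives(rec[rec$person_id == "a", ], "stress")
  expect_true(is.na(single$between_sd))
  expect_equal(single$mean_within_sd, 0)

  expect_error(descriptives(rec[0, ], "stress"), "no completed")
})

test_that("the decomposition recovers known population components", {
  pop <- population_config(mu_mean = 3, mu_sd = 0.8, sd_within_mean = 1,
                           sd_within_sd = 0, ar_mean = 0, ar_sd = 0,
                           compliance_mean = 1, compliance_sd = 0)
  cohort <- generate_cohort(500, pop, seed = 33)
  records <- simulate_ema(cohort, seed = 33)
  # analyze the latent trajectories to isolate the decomposition itself
  truth <- ground_truth(records)
  truth$completed <- TRUE
  d <- descriptives(truth, "latent_stress")
  n_per <- 126
  exp_between <- sqrt(pop$mu_sd^2 + pop$sd_within_mean^2 / n_per)
  se_between <- exp_between / sqrt(2 * (500 - 1))
  expect_lt(abs(d$between_sd - exp_between), 3 * se_between)
  sd_person_sd <- pop$sd_within_mean / sqrt(2 * (n_per - 1))
  expect_lt(abs(d$mean_within_sd - pop$sd_within_mean),
            3 * sd_person_sd / sqrt(500) + 0.005)  # + small-sample sd bias bound
  expect_lt(abs(d$grand_mean - pop$mu_mean), 3 * 0.8 / sqrt(500))
})

test_that("Welch contrasts match hand arithmetic and are antisymmetric", {
  same <- welch_contrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_equal(same$p, 1)

  a <- c(1, 2, 3, 4, 5); b <- c(3, 4, 5, 6, 7)
  ct <- glance(welch_contrast(a, b))
  or <- oracle_welch(a, b)
  expect_equal(ct$t, or$t, tolerance = 1e-10)
  expect_equal(ct$df, or$df, tolerance = 1e-10)
  expect_equal(ct$p, or$p, tolerance = 1e-10)
  expect_equal(ct$d, or$d, tolerance = 1e-10)

  rev <- glance(welch_contrast(b, a))
  expect_equal(rev$t, -ct$t)
  expect_equal(rev$d, -ct$d)
  expect_equal(rev$p, ct$p)

  expect_error(welch_contrast(1, c(1, 2)), "insufficient")
  expect_error(welch_contrast(c(2, 2), c(2, 2)), "degenerate")
})

test_that("change scores use the results sign convention and drop overnight lags", {
  rec <- make_records(c(rep(3, 24), 5, 3, rep(3, 3), 4, rep(3, 6)),
                      days = rep(1:6, each = 6), slots = rep(1:6, 6))
  attr(rec, "ground_truth") <- tibble::tibble(person_id = rec$person_id,
                                              day = rec$day, slot = rec$slot)
  trial <- run_trial(rec, trigger_config(probs = c(1, 0, 0, 0)), seed = 1)
  cs <- change_scores(rec, trial)
  # T = day 5 slot 1 (stress 5), T+1 = day 5 slot 2 (stress 3): delta -2
  row <- cs[cs$day == 5 & cs$slot == 1 & cs$variable == "stress", ]
  expect_equal(row$delta, -2)
  expect_equal(row$trigger_status, "delivered")
  # the last slot of day 5 (value 4) pairs only overnight: excluded
  expect_false(any(cs$day == 5 & cs$slot == 6))
  expect_gte(attr(cs, "n_dropped_overnight"), 1)
  # pairing never crosses persons or days
  expect_true(all(cs$day %in% 4:6))
})

test_that("a null cohort shows no delivered vs omitted change-score effect", {
  cfg <- null_calibration_config(n_persons = 500)
  cohort <- generate_cohort(cfg$n_persons, cfg$population, cfg$effects, seed = 55)
  records <- simulate_ema(cohort, cfg$schedule, seed = 55)
  trial <- run_trial(records, cfg$trigger, seed = 55)
  cs <- change_scores(records, trial)
  a <- cs$delta[cs$variable == "stress" & cs$trigger_status == "delivered"]
  b <- cs$delta[cs$variable == "stress" & cs$trigger_status == "omitted_control"]
  d <- glance(welch_contrast(a, b))$d
  expect_lt(abs(d), 0.05)
})

test_that("degenerate outcome cells are flagged not estimable", {
  rec <- make_records(rep(6, 12), days = rep(4:5, each = 6),
                      slots = rep(1:6, 2))
  attr(rec, "ground_truth") <- tibble::tibble(person_id = rec$person_id,
                                              day = rec$day, slot = rec$slot)
  trial <- run_trial(rec, trigger_config(probs = c(1, 0, 0, 0)), seed = 2)
  rec$behavior_adoption[2] <- "no"  # lone observation in one condition
  out <- condition_outcome_contrasts(rec, trial, "behavior_adoption")
  expect_true(all(!out$estimable))
  expect_equal(nrow(out), 3)
})

test_that("helpfulness contrasts use only single-delivery days", {
  rec <- make_records(rep(6, 6), days = rep(4, 6), slots = 1:6)
  attr(rec, "evening") <- tibble::tibble(
    person_id = c("p001", "p001", "p002", "p002", "p003"),
    day = c(4L, 5L, 4L, 5L, 4L),
    n_delivered = c(1L, 2L, 1L, 1L, 1L),
    condition = c("fixed_cutoff", "fixed_cutoff", "spc", "fixed_cutoff", "spc"),
    helpfulness = c(4L, 7L, 3L, 5L, 2L)
  )
  trial <- run_trial(rec, trigger_config(probs = c(1, 0, 0, 0)), seed = 3)
  out <- condition_outcome_contrasts(rec, trial, "helpfulness")
  fc_spc <- out[out$group_a == "fixed_cutoff" & out$group_b == "spc", ]
  # the 2-delivery day (rating 7) must not contribute
  expect_equal(fc_spc$n_a, 2)
  expect_equal(fc_spc$mean_a, mean(c(4, 5)))
  expect_equal(fc_spc$n_b, 2)
  expect_equal(fc_spc$mean_b, mean(c(3, 2)))
})
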
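test_that("a null effect configuration leaves the stream untouched", {
  cohort <- generate_cohort(4, effects = effect_config(effect_delta = 0,
                                                       support_seek_shift = 0),
                            seed = 21)
  records <- simulate_ema(cohort, seed = 21)
  trial <- run_trial(records, seed = 21)
  out <- apply_intervention_effects(records, trial, cohort, seed = 21)
  for (v in c(distress_items(), "support_seeking", "support_need")) {
    expect_identical(out[[v]], dplyr::arrange(records, person_id, day, slot)[[v]],
                     label = v)
  }
  # post-intervention items are still attached after deliveries
  if (glance(trial)$n_delivered > 0) {
    expect_gt(sum(!is.na(out$appropriate_timing)), 0)
  }
})

test_that("guaranteed adoption marks the next completed prompt", {
  cohort <- fixed_params(mu = 7, sd_within = 0, ar = 0, compliance = 1) |>
    dplyr::mutate(adoption_fixed_cutoff = 1, adoption_spc = 1,
                  adoption_support_need = 1)
  records <- simulate_ema(cohort, seed = 22)
  trial <- run_trial(records, trigger_config(probs = c(1, 0, 0, 0)), seed = 22)
  out <- apply_intervention_effects(records, trial, cohort, seed = 22)
  del <- attr(out, "deliveries")
  expect_true(all(del$adopted))
  expect_true(all(del$behavior_adoption == "yes"))
  attached <- out$behavior_adoption[del$next_idx[!is.na(del$next_idx)]]
  expect_true(all(attached == "yes"))
  expect_true(all(out$appropriate_timing[del$next_idx[!is.na(del$next_idx)]] %in% 1:7))
})

test_that("adopted deliveries reduce next same-day distress and raise support seeking", {
  cohort <- fixed_params(mu = 6, sd_within = 0.4, ar = 0, compliance = 1) |>
    dplyr::mutate(adoption_fixed_cutoff = 1, effect_delta = 1.5,
                  support_seek_shift = 2)
  records <- simulate_ema(cohort, seed = 23)
  trial <- run_trial(records, trigger_config(probs = c(1, 0, 0, 0)), seed = 23)
  out <- apply_intervention_effects(records, trial, cohort, seed = 23)
  del <- attr(out, "deliveries")
  tgt <- del$next_sameday_idx[!is.na(del$next_sameday_idx)]
  before <- dplyr::arrange(records, person_id, day, slot)
  expect_true(all(out$stress[tgt] <= before$stress[tgt]))
  expect_true(all(out$support_seeking[tgt] >= before$support_seeking[tgt]))
  # untouched rows are identical
  untouched <- setdiff(seq_len(nrow(out)), tgt)
  expect_identical(out$stress[untouched], before$stress[untouched])
})

test_that("post-intervention items attach across missed prompts", {
  # person completes slots 1 and 4 on day 5; delivery at slot 1 must attach
  # its items to slot 4 despite the two missed prompts in between
  rec <- make_records(rep(6, 30), days = rep(1:5, each = 6),
                      slots = rep(1:6, 5))
  rec$completed[rec$day == 5 & rec$slot %in% 2:3] <- FALSE
  rec$stress[!rec$completed] <- NA
  rec$negative_affect[!rec$completed] <- NA
  rec$loneliness[!rec$completed] <- NA
  rec$rumination[!rec$completed] <- NA
  attr(rec, "ground_truth") <- tibble::tibble(
    person_id = rec$person_id, day = rec$day, slot = rec$slot,
    latent_negative_affect = 6, latent_stress = 6, latent_loneliness = 6,
    latent_rumination = 6, latent_support_seeking = 2, seed = 1L
  )
  decisions <- tibble::tibble(
    person_id = "p001", day = 5L, slot = 1L, completed = TRUE,
    assigned_condition = "fixed_cutoff", delivered = TRUE
  )
  out <- apply_intervention_effects(rec, decisions, fixed_params(), seed = 1)
  del <- attr(out, "deliveries")
  expect_equal(del$target_day, 5L)
  expect_equal(del$target_slot, 4L)
  expect_false(is.na(out$appropriate_timing[out$day == 5 & out$slot == 4]))
})

test_that("deliveries referencing nonexistent records raise a consistency error", {
  cohort <- generate_cohort(2, seed = 24)
  records <- simulate_ema(cohort, seed = 24)
  bogus <- tibble::tibble(person_id = "p999", day = 5L, slot = 1L,
                          completed = TRUE, assigned_condition = "spc",
                          delivered = TRUE)
  expect_error(apply_intervention_effects(records, bogus, cohort, seed = 1),
               "consistency error")
})
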
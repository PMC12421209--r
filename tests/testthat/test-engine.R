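test_that("condition randomization is degenerate, calibrated and reproducible", {
  set.seed(1)
  expect_true(all(randomize_condition(500, c(1, 0, 0, 0)) == "fixed_cutoff"))
  set.seed(2)
  a <- randomize_condition(1000, c(0.25, 0.25, 0.25, 0.25))
  set.seed(2)
  b <- randomize_condition(1000, c(0.25, 0.25, 0.25, 0.25))
  expect_identical(a, b)
  expect_error(randomize_condition(1, c(0.3, 0.3, 0.3, 0.3)), "probs")
})

test_that("the fixed-cutoff rule is disjunctive and non-strict at 5", {
  rec <- function(na, st, lo, ru) {
    list(completed = TRUE, negative_affect = na, stress = st,
         loneliness = lo, rumination = ru)
  }
  expect_false(evaluate_fixed_cutoff(rec(4, 4, 4, 4))$met)
  out <- evaluate_fixed_cutoff(rec(2, 5, 1, 3))
  expect_true(out$met)
  expect_equal(out$variables, "stress")
  out4 <- evaluate_fixed_cutoff(rec(5, 5, 5, 5))
  expect_true(out4$met)
  expect_equal(sort(out4$variables), sort(distress_items()))
  expect_true(is.na(evaluate_fixed_cutoff(list(completed = FALSE))$met))
})

test_that("the SPC rule flags strict exceedances and honors the baseline floor", {
  charts <- lapply(stats::setNames(distress_items(), distress_items()),
                   function(v) shewhart_chart(3, 1.75, L = 2, variable = v,
                                              n_baseline = 10))
  rec <- list(completed = TRUE, negative_affect = 7, stress = 1,
              loneliness = 1, rumination = 1)
  out <- evaluate_spc(charts, rec)
  expect_true(out$evaluable)
  expect_true(out$met)
  expect_equal(out$variables, "negative_affect")

  caps <- lapply(charts, function(ch) shewhart_chart(5, 1, L = 2,
                                                     n_baseline = 10))
  rec7 <- list(completed = TRUE, negative_affect = 7, stress = 7,
               loneliness = 7, rumination = 7)
  expect_false(evaluate_spc(caps, rec7)$met)  # UCL 7: nothing on a 1-7 scale exceeds

  short <- lapply(charts, function(ch) shewhart_chart(3, 1, n_baseline = 6))
  out_short <- evaluate_spc(short, rec)
  expect_false(out_short$evaluable)
  expect_true(is.na(out_short$met))
})

test_that("support need triggers only on an explicit yes", {
  mk <- function(x) list(completed = TRUE, support_need = x)
  expect_true(evaluate_support_need(mk("yes"))$met)
  expect_false(evaluate_support_need(mk("would_not_help"))$met)
  expect_false(evaluate_support_need(mk("no_worries"))$met)
})

test_that("single-EMA decisions cover omitted control, cap, and unmet criteria", {
  charts <- lapply(stats::setNames(distress_items(), distress_items()),
                   function(v) shewhart_chart(3, 1.75, L = 2, n_baseline = 10))
  rec <- list(person_id = "p001", day = 5, slot = 2, completed = TRUE,
              negative_affect = 6, stress = 2, loneliness = 2, rumination = 2,
              support_need = "would_not_help")
  d1 <- decide(rec, charts, deliveries_today = 0,
               assigned_condition = "no_intervention")
  expect_false(d1$delivered)
  expect_true(d1$omitted_control)
  expect_equal(d1$suppressed_reason, "condition4")

  d2 <- decide(rec, charts, deliveries_today = 2,
               assigned_condition = "fixed_cutoff")
  expect_false(d2$delivered)
  expect_equal(d2$suppressed_reason, "daily_cap")

  d3 <- decide(rec, charts, deliveries_today = 0,
               assigned_condition = "support_need")
  expect_false(d3$delivered)
  expect_equal(d3$suppressed_reason, "criterion_not_met")

  d4 <- decide(rec, charts, deliveries_today = 1,
               assigned_condition = "fixed_cutoff")
  expect_true(d4$delivered)
  expect_equal(d4$suppressed_reason, "none")

  expect_error(decide(modifyList(rec, list(day = 2)), charts), "phase error")
})

test_that("a cohort that never meets any criterion yields zero deliveries", {
  cohort <- fixed_params(mu = 1, sd_within = 0, ar = 0, compliance = 1,
                         no_worries = 10)
  records <- simulate_ema(cohort, seed = 3)
  expect_true(all(records$support_need == "no_worries"))
  trial <- run_trial(records, seed = 3)
  expect_equal(glance(trial)$n_delivered, 0)
  expect_true(all(trial$decisions$suppressed_reason %in%
                    c("criterion_not_met", "condition4")))
})

test_that("a saturated stream is capped at exactly two deliveries per day", {
  cohort <- fixed_params(mu = 7, sd_within = 0, ar = 0, compliance = 1)
  records <- simulate_ema(cohort, seed = 4)
  trial <- run_trial(records, trigger_config(probs = c(1, 0, 0, 0)), seed = 4)
  per_day <- trial$decisions |>
    dplyr::group_by(day) |>
    dplyr::summarise(n = sum(delivered))
  expect_true(all(per_day$n == 2))
  expect_equal(min(trial$decisions$day), 4)  # intervention phase start
  # cap suppressions recorded for the remaining saturated prompts
  expect_equal(sum(trial$decisions$suppressed_reason == "daily_cap"),
               sum(per_day$n > 0) * 4)
})

test_that("trial accounting conserves and zero-probability conditions never deliver", {
  records <- generate_cohort(8, seed = 6) |> simulate_ema(seed = 6)
  trial <- run_trial(records, trigger_config(probs = c(0.5, 0, 0.25, 0.25)),
                     seed = 6)
  g <- glance(trial)
  expect_equal(g$delivered_fixed_cutoff + g$delivered_spc +
                 g$delivered_support_need, g$n_delivered)
  expect_equal(g$delivered_spc, 0)
  acc <- trigger_accounting(trial)
  expect_equal(acc$n_delivered[acc$condition == "total"],
               sum(acc$n_delivered[acc$condition != "total"]))
  # every completed intervention-phase EMA has exactly one decision
  comp <- records[records$completed & records$day >= 4, ]
  expect_equal(sum(trial$decisions$completed), nrow(comp))
})

test_that("the vectorized trial matches per-record decisions replayed in order", {
  records <- generate_cohort(3, seed = 12) |> simulate_ema(seed = 12)
  cfg <- trigger_config()
  trial <- run_trial(records, cfg, seed = 12)
  dec <- trial$decisions
  rec <- dplyr::arrange(records, person_id, day, slot)

  for (i in seq_len(nrow(dec))) {
    row <- dec[i, ]
    r <- rec[rec$person_id == row$person_id & rec$day == row$day &
               rec$slot == row$slot, ]
    if (!row$completed) next
    prev_slot <- row$slot - 1
    as_of <- if (prev_slot >= 1) c(row$day, prev_slot) else c(row$day - 1, 99)
    charts <- fit_charts(rec[rec$person_id == row$person_id, ],
                         L = cfg$L, baseline_end_day = cfg$baseline_end_day,
                         as_of = as_of)
    replay <- decide(r, charts, deliveries_today = row$deliveries_today_before,
                     config = cfg, assigned_condition = row$assigned_condition)
    expect_equal(replay$delivered, row$delivered,
                 label = paste("delivered at", row$person_id, row$day, row$slot))
    expect_equal(replay$suppressed_reason, row$suppressed_reason,
                 label = paste("reason at", row$person_id, row$day, row$slot))
    expect_equal(replay$omitted_control, row$omitted_control)
    expect_equal(replay$fixed_cutoff_met, row$fixed_cutoff_met)
    expect_equal(replay$support_need_met, row$support_need_met)
  }
})

test_that("criterion evaluation is side-effect free", {
  charts <- lapply(stats::setNames(distress_items(), distress_items()),
                   function(v) shewhart_chart(3, 1, L = 2, n_baseline = 10))
  rec <- list(person_id = "p001", day = 5, slot = 1, completed = TRUE,
              negative_affect = 6, stress = 6, loneliness = 6, rumination = 6,
              support_need = "yes")
  before <- lapply(charts, function(ch) ch$ucl)
  invisible(evaluate_fixed_cutoff(rec))
  invisible(evaluate_spc(charts, rec))
  invisible(evaluate_support_need(rec))
  expect_identical(lapply(charts, function(ch) ch$ucl), before)
})
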
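# Pre-specified study configurations for calibration and recovery checks.

#' Null configuration for type-I-error calibration of the lagged contrast
#'
#' A configuration under which the delivered vs omitted-control contrast is
#' exactly null by design, so its rejection rate at a given alpha estimates
#' the type-I error of the analysis machinery.
#'
#' Randomization-based exchangeability needs care here: with several active
#' trigger criteria, delivered prompts (assigned condition's criterion met)
#' and omitted controls (no-intervention condition, any criterion met)
#' condition on different momentary-state distributions, and the
#' autoregressive regression-to-the-mean then differs systematically between
#' the groups even without any intervention effect. This configuration
#' therefore isolates a single active criterion (support need), assigns it
#' and the no-intervention condition with probability 1/2 each, disables the
#' fixed-cutoff and SPC rules (cutoff at the scale ceiling plus a
#' low-variance distress process, and a large `L`), removes the daily cap
#' (which would truncate the delivered group only), and sets all injected
#' effects to zero. Delivered and omitted prompts are then an exact random
#' split of the same state distribution.
#'
#' @param n_persons Cohort size per replicate (default 12).
#' @return A [jitai_config()].
#' @export
null_calibration_config <- function(n_persons = 12) {
  jitai_config(
    n_persons = n_persons,
    population = population_config(
      mu_mean = 3, mu_sd = 0.5,
      sd_within_mean = 0.6, sd_within_sd = 0,
      support_need_intercept = -2.5, support_need_slope = 0.6,
      no_worries_threshold = 2.0
    ),
    trigger = trigger_config(probs = c(0, 0, 0.5, 0.5), cutoff = 7, L = 12,
                             max_per_day = 1e6),
    effects = effect_config(effect_delta = 0, support_seek_shift = 0)
  )
}

#' Configuration for recovering an injected support-seeking effect
#'
#' Sets up a cohort in which every delivered intervention is adopted and the
#' latent support-seeking rating at the next same-day prompt is shifted by
#' `target_d` latent SDs, so the delivered vs omitted-control contrast at
#' T+1 carries a standardized effect of about `target_d` (slightly
#' attenuated by Likert discretization). Because the support-seeking rating
#' is generated independently of momentary distress, the criterion-selection
#' asymmetry described in [null_calibration_config()] does not bias this
#' particular contrast, and the default mixed-criteria design can be used.
#'
#' @param n_persons Cohort size (default 500).
#' @param target_d Injected standardized effect on the latent scale
#'   (default 0.24).
#' @return A [jitai_config()].
#' @export
seek_effect_config <- function(n_persons = 500, target_d = 0.24) {
  pop <- population_config()
  jitai_config(
    n_persons = n_persons,
    population = pop,
    effects = effect_config(
      adoption_prob = c(fixed_cutoff = 1, spc = 1, support_need = 1),
      effect_delta = 0,
      support_seek_shift = target_d * pop$support_seek_sd
    )
  )
}

#' Empirical type-I error of the delivered vs omitted lagged contrast
#'
#' Runs `n_reps` independent replicates of the null design of
#' [null_calibration_config()], each time simulating a cohort, running the
#' trigger engine, computing the lagged change scores of one distress item
#' and the Welch contrast of delivered vs omitted-control, and returns the
#' share of replicates with `p < alpha`. Replicates where either group has
#' fewer than two change scores are skipped (and not counted).
#'
#' @param n_reps Number of replicates (default 1000).
#' @param alpha Nominal level (default 0.05).
#' @param seed Master seed.
#' @param n_persons Persons per replicate (default 12).
#' @param variable Distress item contrasted (default `"negative_affect"`).
#' @return A list with `rate`, `n_valid`, `n_reps`.
#' @export
null_rejection_rate <- function(n_reps = 1000, alpha = 0.05, seed = 1L,
                                n_persons = 12, variable = "negative_affect") {
  cfg <- null_calibration_config(n_persons)
  rej <- 0L
  valid <- 0L
  for (r in seq_len(n_reps)) {
    rseed <- child_seed(seed, r, salt = 5)
    cohort <- generate_cohort(cfg$n_persons, cfg$population, cfg$effects,
                              seed = child_seed(rseed, 1))
    rec <- simulate_ema(cohort, cfg$schedule, seed = child_seed(rseed, 2))
    tr <- run_trial(rec, cfg$trigger, seed = child_seed(rseed, 3))
    cs <- change_scores(rec, tr)
    a <- cs$delta[cs$variable == variable & cs$trigger_status == "delivered"]
    b <- cs$delta[cs$variable == variable & cs$trigger_status == "omitted_control"]
    if (length(a) < 2 || length(b) < 2) next
    valid <- valid + 1L
    if (glance(welch_contrast(a, b))$p < alpha) rej <- rej + 1L
  }
  list(rate = rej / valid, n_valid = valid, n_reps = n_reps)
}
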
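#' EMA sampling schedule
#'
#' Defines the prompting schedule of the study design: `slots_per_day`
#' disjoint two-hour windows per day (by default six windows between 08:00
#' and 20:00) over `n_days` days, with interventions available from
#' `intervention_start_day` onward.
#'
#' @param n_days Number of study days (default 21).
#' @param slots_per_day Number of scheduled prompts per day (default 6).
#' @param first_hour Hour (0--23) at which the first window opens (default 8).
#' @param window_hours Width of each prompting window in hours (default 2).
#' @param intervention_start_day First day (1-based) on which an intervention
#'   may be delivered (default 4).
#' @return A list of class `ema_schedule`.
#' @examples
#' sched <- ema_schedule()
#' sched$n_days * sched$slots_per_day  # scheduled prompts per person
#' @export
ema_schedule <- function(n_days = 21, slots_per_day = 6, first_hour = 8,
                         window_hours = 2, intervention_start_day = 4) {
  if (n_days < 1) stop_config("n_days", "must be >= 1")
  if (slots_per_day < 1) stop_config("slots_per_day", "must be >= 1")
  if (first_hour < 0 || first_hour + slots_per_day * window_hours > 24) {
    stop_config("first_hour/window_hours", "windows must fit within one calendar day")
  }
  if (intervention_start_day < 1 || intervention_start_day > n_days) {
    stop_config("intervention_start_day", "must lie within 1..n_days")
  }
  structure(
    list(
      n_days = as.integer(n_days),
      slots_per_day = as.integer(slots_per_day),
      first_hour = first_hour,
      window_hours = window_hours,
      intervention_start_day = as.integer(intervention_start_day)
    ),
    class = "ema_schedule"
  )
}

#' Population distribution settings for the synthetic cohort
#'
#' Describes the population from which person-specific generative parameters
#' are drawn. Person-level baseline means of each distress item are Gaussian
#' (truncated to the 1--7 scale), within-person SDs are log-normal, the
#' first-order autoregressive coefficient is Gaussian clipped to `[0, 0.95]`,
#' and compliance probabilities are Beta with the given mean and SD.
#'
#' @param mu_mean,mu_sd Population mean and between-person SD of the
#'   person-level distress means (1--7 scale).
#' @param sd_within_mean,sd_within_sd Mean and SD of the within-person
#'   (stationary) latent SD.
#' @param ar_mean,ar_sd Mean and SD of the serial-dependence (AR(1))
#'   coefficient; draws are clipped to `[0, 0.95]`.
#' @param compliance_mean,compliance_sd Mean and SD of the per-person
#'   probability of completing a scheduled prompt. `compliance_sd = 0` makes
#'   compliance constant across persons.
#' @param support_need_intercept,support_need_slope Parameters of the
#'   logistic link from momentary mean latent distress to the probability of
#'   answering "yes" to the support-need item.
#' @param no_worries_threshold Mean latent distress below which the
#'   "I have no worries" category is produced.
#' @param careless_prob Probability that a shown attention check is answered
#'   carelessly (uniform draw from the other scale points).
#' @param support_seek_mu,support_seek_sd Mean and SD of the latent
#'   support-seeking rating (1--7 scale after discretization).
#' @return A list of class `population_config`.
#' @export
population_config <- function(mu_mean = 3.0, mu_sd = 0.8,
                              sd_within_mean = 1.0, sd_within_sd = 0.25,
                              ar_mean = 0.4, ar_sd = 0.15,
                              compliance_mean = 0.85, compliance_sd = 0.16,
                              support_need_intercept = -4,
                              support_need_slope = 0.8,
                              no_worries_threshold = 2.5,
                              careless_prob = 0.015,
                              support_seek_mu = 2.7, support_seek_sd = 2.0) {
  if (mu_mean < 1 || mu_mean > 7) stop_config("mu_mean", "must lie in [1, 7]")
  if (mu_sd < 0) stop_config("mu_sd", "must be >= 0")
  if (sd_within_mean < 0) stop_config("sd_within_mean", "must be >= 0")
  if (sd_within_sd < 0) stop_config("sd_within_sd", "must be >= 0")
  if (ar_mean < 0 || ar_mean >= 1) stop_config("ar_mean", "must lie in [0, 1)")
  if (!is_prob(compliance_mean)) stop_config("compliance_mean", "must lie in [0, 1]")
  if (compliance_sd < 0) stop_config("compliance_sd", "must be >= 0")
  if (compliance_sd > 0 &&
      compliance_sd^2 >= compliance_mean * (1 - compliance_mean)) {
    stop_config("compliance_sd", "is too large for a Beta distribution with this mean")
  }
  if (!is_prob(careless_prob)) stop_config("careless_prob", "must lie in [0, 1]")
  if (support_seek_sd < 0) stop_config("support_seek_sd", "must be >= 0")
  structure(
    list(
      mu_mean = mu_mean, mu_sd = mu_sd,
      sd_within_mean = sd_within_mean, sd_within_sd = sd_within_sd,
      ar_mean = ar_mean, ar_sd = ar_sd,
      compliance_mean = compliance_mean, compliance_sd = compliance_sd,
      support_need_intercept = support_need_intercept,
      support_need_slope = support_need_slope,
      no_worries_threshold = no_worries_threshold,
      careless_prob = careless_prob,
      support_seek_mu = support_seek_mu, support_seek_sd = support_seek_sd
    ),
    class = "population_config"
  )
}

#' Intervention-effect settings for the synthetic cohort
#'
#' Governs what happens after a delivered intervention in the generator:
#' whether the prompt is adopted (support is actually sought), how much the
#' next same-day latent distress is reduced, how much the support-seeking
#' rating at the following prompt is shifted, and the rating distributions of
#' the post-intervention appropriateness and evening helpfulness items.
#'
#' @param adoption_prob Named numeric vector of per-condition adoption
#'   probabilities for `fixed_cutoff`, `spc` and `support_need`.
#' @param effect_delta Mean reduction of next-EMA latent distress (all four
#'   items) when the intervention is adopted; `>= 0`, on the latent 1--7
#'   scale.
#' @param support_seek_shift Mean increase of the latent support-seeking
#'   rating at the next same-day prompt when adopted.
#' @param timing_mu,timing_sd Per-condition mean (named as `adoption_prob`)
#'   and common SD of the "right time" rating attached to the next completed
#'   prompt.
#' @param helpfulness_mu,helpfulness_sd Per-condition mean and common SD of
#'   the evening helpfulness rating on days with a delivery.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(adoption_prob = c(fixed_cutoff = 0.23, spc = 0.22,
                                            support_need = 0.43),
                          effect_delta = 0.2,
                          support_seek_shift = 1.0,
                          timing_mu = c(fixed_cutoff = 4.0, spc = 4.4,
                                        support_need = 5.3),
                          timing_sd = 1.8,
                          helpfulness_mu = c(fixed_cutoff = 3.5, spc = 3.6,
                                             support_need = 4.7),
                          helpfulness_sd = 1.8) {
  for (cond in CONDITIONS[1:3]) {
    if (!cond %in% names(adoption_prob)) {
      stop_config("adoption_prob", paste0("must name condition `", cond, "`"))
    }
    if (!is_prob(unname(adoption_prob[cond]))) {
      stop_config(paste0("adoption_prob[", cond, "]"), "must lie in [0, 1]")
    }
    if (!cond %in% names(timing_mu)) stop_config("timing_mu", paste0("must name `", cond, "`"))
    if (!cond %in% names(helpfulness_mu)) stop_config("helpfulness_mu", paste0("must name `", cond, "`"))
  }
  if (effect_delta < 0) stop_config("effect_delta", "must be >= 0")
  structure(
    list(
      adoption_prob = adoption_prob[CONDITIONS[1:3]],
      effect_delta = effect_delta,
      support_seek_shift = support_seek_shift,
      timing_mu = timing_mu[CONDITIONS[1:3]], timing_sd = timing_sd,
      helpfulness_mu = helpfulness_mu[CONDITIONS[1:3]],
      helpfulness_sd = helpfulness_sd
    ),
    class = "effect_config"
  )
}

#' Trigger-engine settings
#'
#' @param probs Randomization probabilities for the four conditions
#'   (fixed cutoff, SPC, support need, no intervention); must be
#'   non-negative and sum to 1 within `1e-12`.
#' @param cutoff Fixed disjunctive cutoff on the 1--7 distress items
#'   (non-strict, default `>= 5`).
#' @param L Control-limit multiplier of the Shewhart chart (default 2).
#' @param baseline_end_day Last day of the chart learning phase (default 7);
#'   control limits are frozen afterwards.
#' @param min_baseline Minimum number of completed baseline observations
#'   before the SPC rule is evaluable (default 7).
#' @param max_per_day Daily cap on delivered interventions per person
#'   (default 2).
#' @return A list of class `trigger_config`.
#' @export
trigger_config <- function(probs = c(0.25, 0.25, 0.25, 0.25), cutoff = 5,
                           L = 2, baseline_end_day = 7, min_baseline = 7,
                           max_per_day = 2) {
  check_probs(probs)
  if (cutoff < 1 || cutoff > 7) stop_config("cutoff", "must lie in [1, 7]")
  if (L < 0) stop_config("L", "must be >= 0")
  if (baseline_end_day < 1) stop_config("baseline_end_day", "must be >= 1")
  if (min_baseline < 2) stop_config("min_baseline", "must be >= 2")
  if (max_per_day < 0) stop_config("max_per_day", "must be >= 0")
  structure(
    list(
      probs = stats::setNames(as.numeric(probs), CONDITIONS),
      cutoff = cutoff, L = L,
      baseline_end_day = as.integer(baseline_end_day),
      min_baseline = as.integer(min_baseline),
      max_per_day = max_per_day
    ),
    class = "trigger_config"
  )
}

check_probs <- function(probs) {
  if (length(probs) != 4 || any(!is.finite(probs)) || any(probs < 0)) {
    stop_config("probs", "must be four finite non-negative numbers")
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop_config("probs", "must sum to 1 (within 1e-12)")
  }
  invisible(probs)
}

#' Analysis settings
#'
#' @param person_rate_threshold Per-person compliance threshold (default 0.70).
#' @param cohort_share_threshold Required share of persons meeting the
#'   per-person threshold (default 0.70).
#' @param careless_threshold Careless-response rate below which data quality
#'   is considered high (default 0.05).
#' @param digits Decimal places used for percentages in reports (default 2).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(person_rate_threshold = 0.70,
                            cohort_share_threshold = 0.70,
                            careless_threshold = 0.05,
                            digits = 2) {
  if (!is_prob(person_rate_threshold)) stop_config("person_rate_threshold", "must lie in [0, 1]")
  if (!is_prob(cohort_share_threshold)) stop_config("cohort_share_threshold", "must lie in [0, 1]")
  if (!is_prob(careless_threshold)) stop_config("careless_threshold", "must lie in [0, 1]")
  structure(
    list(
      person_rate_threshold = person_rate_threshold,
      cohort_share_threshold = cohort_share_threshold,
      careless_threshold = careless_threshold,
      digits = as.integer(digits)
    ),
    class = "analysis_config"
  )
}

#' Full run configuration
#'
#' Bundles all settings of a simulation-and-analysis run: cohort size,
#' population distributions, schedule, trigger engine, intervention effects,
#' analysis thresholds, and the master seed.
#'
#' @param n_persons Cohort size (default 25).
#' @param population A [population_config()].
#' @param schedule An [ema_schedule()].
#' @param trigger A [trigger_config()].
#' @param effects An [effect_config()].
#' @param analysis An [analysis_config()].
#' @param seed Master seed (integer).
#' @return A list of class `jitai_config`.
#' @seealso [load_config()], [run_pipeline()]
#' @export
jitai_config <- function(n_persons = 25,
                         population = population_config(),
                         schedule = ema_schedule(),
                         trigger = trigger_config(),
                         effects = effect_config(),
                         analysis = analysis_config(),
                         seed = 1L) {
  if (n_persons < 1) stop_config("n_persons", "must be >= 1")
  stopifnot(inherits(population, "population_config"),
            inherits(schedule, "ema_schedule"),
            inherits(trigger, "trigger_config"),
            inherits(effects, "effect_config"),
            inherits(analysis, "analysis_config"))
  structure(
    list(
      n_persons = as.integer(n_persons),
      population = population, schedule = schedule, trigger = trigger,
      effects = effects, analysis = analysis, seed = as.integer(seed)
    ),
    class = "jitai_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected with an error naming the key; missing keys fall
#' back to the package defaults, so an empty file yields the default design
#' (25 persons, 21 days, 6 slots/day, cutoff 5, L = 2, daily cap 2).
#'
#' @param path Path to a YAML file (possibly empty).
#' @return A validated [jitai_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

#' Build a run configuration from a nested list
#'
#' @param raw Nested list with optional sections `population`, `schedule`,
#'   `trigger`, `effects`, `analysis`, and scalars `n_persons`, `seed`.
#' @return A validated [jitai_config()].
#' @export
config_from_list <- function(raw) {
  known_top <- c("n_persons", "seed", "population", "schedule", "trigger",
                 "effects", "analysis")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop_config(unknown[1], "is not a recognized configuration key")
  }
  section <- function(name, ctor) {
    args <- raw[[name]]
    if (is.null(args)) return(ctor())
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad)) stop_config(paste0(name, ".", bad[1]), "is not a recognized configuration key")
    # named vectors arrive from YAML as named lists
    args <- lapply(args, function(x) if (is.list(x)) unlist(x) else x)
    do.call(ctor, args)
  }
  jitai_config(
    n_persons = raw$n_persons %||% 25,
    population = section("population", population_config),
    schedule = section("schedule", ema_schedule),
    trigger = section("trigger", trigger_config),
    effects = section("effects", effect_config),
    analysis = section("analysis", analysis_config),
    seed = raw$seed %||% 1L
  )
}

#' Write a run configuration to a YAML file
#'
#' [save_config()] followed by [load_config()] reproduces the configuration
#' exactly.
#'
#' @param config A [jitai_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "jitai_config"))
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(el) {
      if (is.list(el)) strip(el)
      else if (!is.null(names(el))) as.list(el)  # keep names in the YAML map
      else el
    })
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' Stable hash of a run configuration
#'
#' Used for provenance stamps in written outputs.
#'
#' @param config A [jitai_config()].
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}
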
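#' Draw person-specific generative parameters for a synthetic cohort
#'
#' Samples one parameter set per person from the population distributions in
#' `population` (see [population_config()]). Each row fully determines one
#' person's EMA stream given a schedule and seed: baseline means and
#' within-person SDs of the four distress items, the AR(1) serial-dependence
#' coefficient, the compliance probability, the support-need link, the
#' careless-response rate, and the intervention-response parameters taken
#' from `effects`.
#'
#' @param n_persons Number of persons (default 25).
#' @param population A [population_config()].
#' @param effects An [effect_config()]; its adoption probabilities,
#'   distress-reduction `effect_delta` and `support_seek_shift` are copied
#'   into the cohort table.
#' @param seed Integer seed; identical `(config, seed)` yields an identical
#'   cohort.
#' @return A tibble with one row per person and class `jitai_cohort`.
#' @examples
#' cohort <- generate_cohort(5, seed = 1)
#' dplyr::select(cohort, person_id, mu_stress, compliance_prob)
#' @export
generate_cohort <- function(n_persons = 25,
                            population = population_config(),
                            effects = effect_config(),
                            seed = 1L) {
  if (n_persons < 1) stop_config("n_persons", "must be >= 1")
  stopifnot(inherits(population, "population_config"),
            inherits(effects, "effect_config"))
  p <- population
  n <- as.integer(n_persons)

  draws <- with_seed(child_seed(seed, 0, salt = 1), {
    mu <- lapply(DISTRESS_VARS, function(v) {
      pmin(pmax(stats::rnorm(n, p$mu_mean, p$mu_sd), 1), 7)
    })
    names(mu) <- paste0("mu_", DISTRESS_VARS)
    sdw <- lapply(DISTRESS_VARS, function(v) rlnorm_meansd(n, p$sd_within_mean, p$sd_within_sd))
    names(sdw) <- paste0("sd_", DISTRESS_VARS)
    ar <- pmin(pmax(stats::rnorm(n, p$ar_mean, p$ar_sd), 0), 0.95)
    compliance <- rbeta_meansd(n, p$compliance_mean, p$compliance_sd)
    c(mu, sdw, list(ar_coef = ar, compliance_prob = compliance))
  })

  out <- tibble::tibble(
    person_id = sprintf("p%03d", seq_len(n)),
    !!!draws,
    support_need_intercept = p$support_need_intercept,
    support_need_slope = p$support_need_slope,
    no_worries_threshold = p$no_worries_threshold,
    careless_prob = p$careless_prob,
    support_seek_mu = p$support_seek_mu,
    support_seek_sd = p$support_seek_sd,
    adoption_fixed_cutoff = unname(effects$adoption_prob["fixed_cutoff"]),
    adoption_spc = unname(effects$adoption_prob["spc"]),
    adoption_support_need = unname(effects$adoption_prob["support_need"]),
    effect_delta = effects$effect_delta,
    support_seek_shift = effects$support_seek_shift
  )
  class(out) <- c("jitai_cohort", class(out))
  attr(out, "seed") <- as.integer(seed)
  out
}

# Log-normal draws parameterized by mean and SD; sd = 0 collapses to the mean.
rlnorm_meansd <- function(n, mean, sd) {
  if (mean == 0) return(rep(0, n))
  if (sd == 0) return(rep(mean, n))
  sigma2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Beta draws parameterized by mean and SD; sd = 0 collapses to the mean.
rbeta_meansd <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  nu <- mean * (1 - mean) / sd^2 - 1
  stats::rbeta(n, shape1 = mean * nu, shape2 = (1 - mean) * nu)
}
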
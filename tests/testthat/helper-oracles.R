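# Independent brute-force oracles and small fixture builders.

# Chart oracle: explicit element-wise loop over the three defining formulas,
# kept independent of the package's fit_chart() path.
oracle_chart <- function(x, L = 2) {
  n <- length(x)
  mr <- numeric(0)
  if (n >= 2) {
    for (j in 2:n) mr <- c(mr, abs(x[j] - x[j - 1]))
  }
  m <- sum(x) / n
  mr_mean <- sum(mr) / length(mr)
  sigma <- mr_mean / 1.128
  list(mean = m, mr = mr, mr_mean = mr_mean, sigma = sigma,
       ucl = m + L * sigma)
}

# Welch/Satterthwaite oracle from the textbook formulas.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  va <- sum((a - ma)^2) / (na - 1)
  vb <- sum((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  list(t = t, df = df, p = p, d = (ma - mb) / sp)
}

# Minimal single-person records table for chart and engine tests: one
# completed observation per (day, slot) with all four distress items equal
# to `values` unless per-item columns are supplied.
make_records <- function(values, days = NULL, slots = NULL, person = "p001",
                         completed = TRUE, support_need = "would_not_help") {
  n <- length(values)
  if (is.null(days)) days <- rep(seq_len(ceiling(n / 6)), each = 6)[seq_len(n)]
  if (is.null(slots)) slots <- (seq_len(n) - 1) %% 6 + 1
  tibble::tibble(
    person_id = person,
    day = as.integer(days), slot = as.integer(slots),
    timestamp = as.POSIXct("2024-01-01", tz = "UTC") + days * 86400 + slots * 3600,
    completed = rep_len(completed, n),
    negative_affect = ifelse(rep_len(completed, n), as.integer(values), NA_integer_),
    stress = ifelse(rep_len(completed, n), as.integer(values), NA_integer_),
    loneliness = ifelse(rep_len(completed, n), as.integer(values), NA_integer_),
    rumination = ifelse(rep_len(completed, n), as.integer(values), NA_integer_),
    support_need = ifelse(rep_len(completed, n), support_need, NA_character_),
    support_seeking = ifelse(rep_len(completed, n), 2L, NA_integer_),
    attention_check_shown = FALSE,
    attention_check_value = NA_integer_,
    appropriate_timing = NA_integer_,
    behavior_adoption = NA_character_
  )
}

# A deterministic cohort row with fully controlled parameters.
fixed_params <- function(person = "p001", mu = 3, sd_within = 1, ar = 0.4,
                         compliance = 0.85, careless = 0.015,
                         sn_intercept = -4, sn_slope = 0.8,
                         no_worries = 2.5) {
  tibble::tibble(
    person_id = person,
    mu_negative_affect = mu, mu_stress = mu, mu_loneliness = mu,
    mu_rumination = mu,
    sd_negative_affect = sd_within, sd_stress = sd_within,
    sd_loneliness = sd_within, sd_rumination = sd_within,
    ar_coef = ar, compliance_prob = compliance,
    support_need_intercept = sn_intercept, support_need_slope = sn_slope,
    no_worries_threshold = no_worries, careless_prob = careless,
    support_seek_mu = 2.7, support_seek_sd = 2,
    adoption_fixed_cutoff = 0.23, adoption_spc = 0.22,
    adoption_support_need = 0.43,
    effect_delta = 0.2, support_seek_shift = 1
  )
}

# 99% binomial confidence interval half-width around p0 for n draws.
binom99_halfwidth <- function(p0, n) {
  stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
}

# helper: a records table with prescribed per-person completion counts
records_with_compliance <- function(completed_counts, scheduled = 126) {
  purrr::imap_dfr(completed_counts, function(k, i) {
    tibble::tibble(
      person_id = sprintf("p%03d", i),
      day = rep(1:(scheduled / 6), each = 6),
      slot = rep(1:6, scheduled / 6),
      completed = c(rep(TRUE, k), rep(FALSE, scheduled - k)),
      attention_check_shown = FALSE,
      attention_check_value = NA_integer_
    )
  })
}

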
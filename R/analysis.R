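# Feasibility and proximal-outcome analyses: compliance, careless
# responding, variance decomposition, Welch contrasts with Cohen's d, and
# lagged change scores of delivered vs omitted triggers.

#' Compliance summary with the double-70% feasibility rule
#'
#' Per-person compliance is completed prompts divided by scheduled prompts
#' (every row of `records` is one scheduled prompt). The design is feasible
#' when at least `cohort_share_threshold` of persons complete at least
#' `person_rate_threshold` of their prompts (both default 70%).
#'
#' @param records EMA records covering the full schedule of every person.
#' @param person_rate_threshold Per-person compliance threshold (default 0.70).
#' @param cohort_share_threshold Required share of persons at or above the
#'   person threshold (default 0.70).
#' @return An object of class `compliance_summary`; `tidy()` gives the
#'   per-person table, `glance()` the one-row cohort summary with
#'   `mean_rate` (mean of person rates), `pooled_rate`
#'   (total completed / total scheduled), `sd_rate`, `share_meeting` and the
#'   `feasible` flag.
#' @examples
#' records <- generate_cohort(5, seed = 1) |> simulate_ema(seed = 1)
#' glance(compliance_summary(records))
#' @export
compliance_summary <- function(records, person_rate_threshold = 0.70,
                               cohort_share_threshold = 0.70) {
  if (nrow(records) == 0) {
    stop("consistency error: no scheduled prompts in the records", call. = FALSE)
  }
  persons <- records |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      scheduled = dplyr::n(),
      completed = sum(.data$completed),
      rate = .data$completed / .data$scheduled,
      .groups = "drop"
    ) |>
    dplyr::mutate(meets_threshold = .data$rate >= person_rate_threshold)
  if (any(persons$scheduled == 0)) {
    stop("consistency error: person with zero scheduled prompts", call. = FALSE)
  }
  share <- mean(persons$meets_threshold)
  structure(
    list(
      persons = persons,
      mean_rate = mean(persons$rate),
      sd_rate = stats::sd(persons$rate),
      pooled_rate = sum(persons$completed) / sum(persons$scheduled),
      share_meeting = share,
      person_rate_threshold = person_rate_threshold,
      cohort_share_threshold = cohort_share_threshold,
      feasible = share >= cohort_share_threshold
    ),
    class = "compliance_summary"
  )
}

#' @rdname tidy.jitai_trial
#' @method tidy compliance_summary
#' @export
tidy.compliance_summary <- function(x, ...) x$persons

#' @rdname tidy.jitai_trial
#' @method glance compliance_summary
#' @export
glance.compliance_summary <- function(x, ...) {
  tibble::tibble(
    n_persons = nrow(x$persons),
    scheduled = sum(x$persons$scheduled),
    completed = sum(x$persons$completed),
    mean_rate = x$mean_rate,
    sd_rate = x$sd_rate,
    pooled_rate = x$pooled_rate,
    share_meeting = x$share_meeting,
    feasible = x$feasible
  )
}

#' @export
print.compliance_summary <- function(x, ...) {
  cat(sprintf(
    "Compliance: %d/%d completed (pooled %.2f%%; person mean %.2f%%, SD %.2f%%)\n%.0f%% of persons at or above the %.0f%% threshold -> %s\n",
    sum(x$persons$completed), sum(x$persons$scheduled), 100 * x$pooled_rate,
    100 * x$mean_rate, 100 * x$sd_rate, 100 * x$share_meeting,
    100 * x$person_rate_threshold,
    if (x$feasible) "feasible" else "not feasible"
  ))
  invisible(x)
}

#' Careless-responding rate from the attention checks
#'
#' A careless response is a shown attention check answered with anything
#' other than the instructed value 5. Data quality is considered high when
#' the rate is below `threshold` (default 5%).
#'
#' @param records EMA records.
#' @param threshold Careless-rate threshold for the quality flag.
#' @return A one-row tibble with `n_shown`, `n_careless`, `rate` and
#'   `high_quality`. When no attention check was shown the rate is `NA`.
#' @export
careless_rate <- function(records, threshold = 0.05) {
  shown <- records$attention_check_shown %in% TRUE & records$completed
  n_shown <- sum(shown)
  n_careless <- sum(shown & records$attention_check_value != 5, na.rm = TRUE)
  rate <- if (n_shown == 0) NA_real_ else n_careless / n_shown
  tibble::tibble(
    n_shown = n_shown, n_careless = n_careless, rate = rate,
    high_quality = if (n_shown == 0) NA else rate < threshold
  )
}

#' Descriptive decomposition of an EMA item
#'
#' The four summary statistics of intensive longitudinal data: the grand
#' mean over all completed observations, person-specific means, the
#' between-person SD (SD of the person means) and the mean within-person SD
#' (mean of the per-person SDs; persons with fewer than two observations
#' contribute to the means but not to the within-person SD).
#'
#' @param records EMA records.
#' @param item Column name of the item (e.g. `"stress"`).
#' @return A one-row tibble with `item`, `n_obs`, `n_persons`, `grand_mean`,
#'   `between_sd` (`NA` with a single person) and `mean_within_sd`, carrying
#'   the person-level table as attribute `"persons"`.
#' @export
descriptives <- function(records, item) {
  stopifnot(item %in% names(records))
  obs <- records[records$completed & !is.na(records[[item]]), ]
  if (nrow(obs) == 0) stop("no completed observations for item ", item, call. = FALSE)
  persons <- obs |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      person_mean = mean(.data[[item]]),
      person_sd = if (dplyr::n() >= 2) stats::sd(.data[[item]]) else NA_real_,
      .groups = "drop"
    )
  out <- tibble::tibble(
    item = item,
    n_obs = nrow(obs),
    n_persons = nrow(persons),
    grand_mean = mean(obs[[item]]),
    between_sd = if (nrow(persons) >= 2) stats::sd(persons$person_mean) else NA_real_,
    mean_within_sd = mean(persons$person_sd, na.rm = TRUE)
  )
  attr(out, "persons") <- persons
  out
}

#' Welch two-sample contrast with Cohen's d
#'
#' Two-tailed Welch (unequal-variances) t test with Satterthwaite degrees of
#' freedom, plus the pooled-SD Cohen's d with sign convention
#' `mean(a) - mean(b)`.
#'
#' @param a,b Numeric vectors (each of length >= 2 with non-degenerate
#'   combined variance).
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `welch_contrast`; `glance()` gives the one-row
#'   summary (`t`, `df`, `p`, `d`, group means/SDs/ns), `tidy()` the
#'   per-group descriptives.
#' @examples
#' ct <- welch_contrast(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7))
#' glance(ct)
#' @export
welch_contrast <- function(a, b, labels = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient data: each group needs at least 2 observations", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    stop("degenerate variance: both groups are constant", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  structure(
    list(
      labels = labels,
      n = c(na, nb), mean = c(mean(a), mean(b)), sd = c(sqrt(va), sqrt(vb)),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = unname(tt$p.value),
      d = (mean(a) - mean(b)) / sp
    ),
    class = "welch_contrast"
  )
}

#' @rdname tidy.jitai_trial
#' @method tidy welch_contrast
#' @export
tidy.welch_contrast <- function(x, ...) {
  tibble::tibble(group = x$labels, n = x$n, mean = x$mean, sd = x$sd)
}

#' @rdname tidy.jitai_trial
#' @method glance welch_contrast
#' @export
glance.welch_contrast <- function(x, ...) {
  tibble::tibble(
    group_a = x$labels[1], group_b = x$labels[2],
    n_a = x$n[1], n_b = x$n[2],
    mean_a = x$mean[1], mean_b = x$mean[2],
    sd_a = x$sd[1], sd_b = x$sd[2],
    t = x$t, df = x$df, p = x$p, d = x$d
  )
}

#' @export
print.welch_contrast <- function(x, ...) {
  cat(sprintf(
    "Welch contrast %s vs %s: t(%.2f) = %.3f, p = %.4g, Cohen's d = %.3f\n  %s: n %d, mean %.3f (SD %.3f) | %s: n %d, mean %.3f (SD %.3f)\n",
    x$labels[1], x$labels[2], x$df, x$t, x$p, x$d,
    x$labels[1], x$n[1], x$mean[1], x$sd[1],
    x$labels[2], x$n[2], x$mean[2], x$sd[2]
  ))
  invisible(x)
}

#' Lagged change scores of the distress items
#'
#' For every intervention-phase completed prompt T whose next completed
#' prompt T+1 falls on the same calendar day, emits one row per distress
#' item with `delta = value(T+1) - value(T)` (negative values are
#' reductions) and T's trigger status: `delivered`, `omitted_control`
#' (no-intervention condition with at least one criterion met), or
#' `not_triggered` (no criterion met anywhere). Prompts where a criterion
#' was met but no delivery or omitted-control applied (e.g. cap-suppressed,
#' or the assigned condition's criterion unmet while another was met) do not
#' fit any of the three strata and are excluded; their count is reported in
#' attribute `"n_excluded_other"`. Overnight lags are excluded, with the
#' count in attribute `"n_dropped_overnight"`.
#'
#' @param records EMA records (post [apply_intervention_effects()], or raw).
#' @param trial A [run_trial()] object.
#' @return A tibble with columns `person_id`, `day`, `slot`, `variable`,
#'   `value_t`, `value_t1`, `delta`, `trigger_status`.
#' @export
change_scores <- function(records, trial) {
  stopifnot(inherits(trial, "jitai_trial"))
  dec <- trial$decisions
  rec <- dplyr::arrange(records, .data$person_id, .data$day, .data$slot)
  nxt <- next_completed_index(rec)

  key <- paste(rec$person_id, rec$day, rec$slot)
  dkey <- paste(dec$person_id, dec$day, dec$slot)
  t_idx <- match(dkey, key)
  if (anyNA(t_idx)) {
    stop("trial log does not align with the records", call. = FALSE)
  }

  status <- dplyr::case_when(
    dec$delivered ~ "delivered",
    dec$omitted_control ~ "omitted_control",
    dec$completed & !dec$any_criterion_met ~ "not_triggered",
    .default = "other"
  )
  usable <- dec$completed & status != "other"
  n_excluded_other <- sum(dec$completed & status == "other")

  has_next_any <- usable & !is.na(nxt$any_day[t_idx])
  same_day <- usable & !is.na(nxt$same_day[t_idx])
  n_overnight <- sum(has_next_any & !same_day)

  keep <- which(same_day)
  t1_idx <- nxt$same_day[t_idx[keep]]
  base <- tibble::tibble(
    person_id = dec$person_id[keep],
    day = dec$day[keep], slot = dec$slot[keep],
    trigger_status = status[keep],
    t1_row = t1_idx, t_row = t_idx[keep]
  )
  out <- purrr::map_dfr(DISTRESS_VARS, function(v) {
    tibble::tibble(
      person_id = base$person_id, day = base$day, slot = base$slot,
      variable = v,
      value_t = rec[[v]][base$t_row],
      value_t1 = rec[[v]][base$t1_row],
      delta = rec[[v]][base$t1_row] - rec[[v]][base$t_row],
      trigger_status = base$trigger_status
    )
  })
  attr(out, "n_dropped_overnight") <- n_overnight
  attr(out, "n_excluded_other") <- n_excluded_other
  out
}

#' Pairwise condition and delivery contrasts of proximal outcomes
#'
#' Computes the Welch/Cohen-d contrasts of the feasibility analyses:
#'
#' * `outcome = "appropriate_timing"` or `"behavior_adoption"`: pairwise
#'   contrasts between the three triggering conditions, using the rating
#'   attached to the next completed same-day prompt after each delivery
#'   (overnight attachments are excluded from analysis). Binary adoption is
#'   analyzed as 0/1 means.
#' * `outcome = "helpfulness"`: the same pairwise contrasts on the evening
#'   helpfulness rating, restricted to days with exactly one delivered
#'   intervention (so the rating is attributable to one condition).
#' * `outcome = "support_seeking"`: delivered vs omitted-control contrast of
#'   the support-seeking rating at T+1 (next completed same-day prompt).
#' * `outcome` one of the four distress items: delivered vs omitted-control
#'   contrast of the T to T+1 change score.
#'
#' @param records EMA records after [apply_intervention_effects()] (for
#'   helpfulness, the records must carry the `"evening"` attribute).
#' @param trial A [run_trial()] object.
#' @param outcome Outcome name (see Details).
#' @return A tibble with one row per pairwise contrast: group labels, group
#'   sizes, means and SDs, Welch `t`, `df`, `p`, Cohen's `d`, and an
#'   `estimable` flag (contrasts with a group below 2 observations or fully
#'   degenerate variance are flagged, not errors).
#' @export
condition_outcome_contrasts <- function(records, trial, outcome) {
  stopifnot(inherits(trial, "jitai_trial"))
  if (outcome %in% c("appropriate_timing", "behavior_adoption")) {
    post_jitai_contrasts(records, trial, outcome)
  } else if (outcome == "helpfulness") {
    helpfulness_contrasts(records, trial)
  } else if (outcome == "support_seeking") {
    delivered_vs_omitted_seek(records, trial)
  } else if (outcome %in% DISTRESS_VARS) {
    delta <- change_scores(records, trial)
    delta <- delta[delta$variable == outcome, ]
    contrast_row(outcome,
                 delta$delta[delta$trigger_status == "delivered"],
                 delta$delta[delta$trigger_status == "omitted_control"],
                 c("delivered", "omitted_control"))
  } else {
    stop("unknown outcome: ", outcome, call. = FALSE)
  }
}

post_jitai_contrasts <- function(records, trial, outcome) {
  per <- post_jitai_values(records, trial)
  vals <- if (outcome == "behavior_adoption") {
    as.numeric(per$behavior_adoption == "yes")
  } else {
    per$appropriate_timing
  }
  pairwise_condition_contrasts(outcome, vals, per$condition)
}

# one row per delivery with a completed same-day follow-up prompt,
# reconstructed from the records and the trial log
post_jitai_values <- function(records, trial) {
  rec <- dplyr::arrange(records, .data$person_id, .data$day, .data$slot)
  nxt <- next_completed_index(rec)
  dec <- trial$decisions
  del <- dec[dec$delivered, ]
  key <- paste(rec$person_id, rec$day, rec$slot)
  idx <- match(paste(del$person_id, del$day, del$slot), key)
  target <- nxt$same_day[idx]
  ok <- !is.na(target)
  tibble::tibble(
    person_id = del$person_id[ok],
    day = del$day[ok], slot = del$slot[ok],
    condition = del$assigned_condition[ok],
    appropriate_timing = rec$appropriate_timing[target[ok]],
    behavior_adoption = rec$behavior_adoption[target[ok]]
  )
}

helpfulness_contrasts <- function(records, trial) {
  evening <- attr(records, "evening")
  if (is.null(evening)) {
    stop("records carry no evening helpfulness ratings; run apply_intervention_effects() first",
         call. = FALSE)
  }
  single <- evening[evening$n_delivered == 1, ]
  pairwise_condition_contrasts("helpfulness", single$helpfulness, single$condition)
}

pairwise_condition_contrasts <- function(outcome, values, condition) {
  pairs <- utils::combn(CONDITIONS[1:3], 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    contrast_row(outcome, values[condition == pr[1]], values[condition == pr[2]], pr)
  })
}

delivered_vs_omitted_seek <- function(records, trial) {
  rec <- dplyr::arrange(records, .data$person_id, .data$day, .data$slot)
  nxt <- next_completed_index(rec)
  dec <- trial$decisions
  key <- paste(rec$person_id, rec$day, rec$slot)
  idx <- match(paste(dec$person_id, dec$day, dec$slot), key)
  target <- nxt$same_day[idx]
  status <- dplyr::case_when(
    dec$delivered ~ "delivered",
    dec$omitted_control ~ "omitted_control",
    .default = "other"
  )
  ok <- status != "other" & !is.na(target)
  seek_t1 <- rec$support_seeking[target[ok]]
  contrast_row("support_seeking_t1",
               seek_t1[status[ok] == "delivered"],
               seek_t1[status[ok] == "omitted_control"],
               c("delivered", "omitted_control"))
}

contrast_row <- function(outcome, a, b, labels) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  ct <- tryCatch(welch_contrast(a, b, labels), error = function(e) NULL)
  if (is.null(ct)) {
    return(tibble::tibble(
      outcome = outcome, group_a = labels[1], group_b = labels[2],
      n_a = length(a), n_b = length(b),
      mean_a = if (length(a)) mean(a) else NA_real_,
      mean_b = if (length(b)) mean(b) else NA_real_,
      sd_a = NA_real_, sd_b = NA_real_,
      t = NA_real_, df = NA_real_, p = NA_real_, d = NA_real_,
      estimable = FALSE
    ))
  }
  dplyr::bind_cols(tibble::tibble(outcome = outcome), glance(ct),
                   tibble::tibble(estimable = TRUE))
}
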
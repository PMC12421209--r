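# Microrandomized trigger engine: per-EMA condition randomization,
# evaluation of the three trigger criteria, delivery under the daily cap,
# and omitted-control bookkeeping.

#' Randomize the triggering condition
#'
#' Draws `n` independent condition assignments with the given probabilities.
#' Reproducible under a fixed RNG seed set by the caller.
#'
#' @param n Number of draws.
#' @param probs Probabilities for (fixed cutoff, SPC, support need,
#'   no intervention); non-negative, summing to 1 within `1e-12`.
#' @return Character vector of condition names.
#' @examples
#' set.seed(1)
#' table(randomize_condition(1000))
#' @export
randomize_condition <- function(n = 1, probs = c(0.25, 0.25, 0.25, 0.25)) {
  check_probs(probs)
  CONDITIONS[sample.int(4, n, replace = TRUE, prob = probs)]
}

#' Fixed-cutoff trigger criterion
#'
#' Disjunctive rule over the four distress items: met when any item is at or
#' above `cutoff` (non-strict). Not evaluable on an incomplete record.
#'
#' @param record A one-row EMA record (list or data frame row) with the four
#'   distress items and `completed`.
#' @param cutoff Threshold on the 1--7 scale (default 5).
#' @return A list with `met` (logical, `NA` when not evaluable) and
#'   `variables` (character vector of qualifying items).
#' @export
evaluate_fixed_cutoff <- function(record, cutoff = 5) {
  if (!isTRUE(record$completed[[1]])) {
    return(list(met = NA, variables = character(0)))
  }
  vals <- vapply(DISTRESS_VARS, function(v) as.numeric(record[[v]][[1]]), numeric(1))
  hit <- !is.na(vals) & vals >= cutoff
  list(met = any(hit), variables = DISTRESS_VARS[hit])
}

#' SPC trigger criterion
#'
#' Disjunctive strict exceedance of the personalized upper control limits.
#' Not evaluable when any of the four charts lacks the minimum baseline.
#'
#' @param charts A named list of `shewhart_chart` objects (one per distress
#'   item) or a [fit_charts()] tibble for one person.
#' @param record A one-row completed EMA record.
#' @param min_baseline Minimum completed baseline observations required for
#'   evaluation (default 7).
#' @return A list with `evaluable`, `met` (`NA` when not evaluable) and
#'   `variables`.
#' @export
evaluate_spc <- function(charts, record, min_baseline = 7) {
  if (!isTRUE(record$completed[[1]])) {
    return(list(evaluable = FALSE, met = NA, variables = character(0)))
  }
  get_chart <- function(v) {
    if (inherits(charts, "data.frame")) {
      row <- charts[charts$variable == v, ]
      if (nrow(row) != 1 || is.na(row$ucl)) return(NULL)
      shewhart_chart(row$phase1_mean, row$sigma_hat, L = row$L,
                     person_id = row$person_id, variable = v,
                     n_baseline = row$n_baseline, frozen = isTRUE(row$frozen))
    } else {
      charts[[v]]
    }
  }
  hits <- logical(0)
  vars <- character(0)
  for (v in DISTRESS_VARS) {
    ch <- get_chart(v)
    if (is.null(ch) || is.na(ch$n_baseline) || ch$n_baseline < min_baseline) {
      return(list(evaluable = FALSE, met = NA, variables = character(0)))
    }
    val <- as.numeric(record[[v]][[1]])
    hit <- !is.na(val) && exceeds_ucl(ch, val)
    if (hit) vars <- c(vars, v)
    hits <- c(hits, hit)
  }
  list(evaluable = TRUE, met = any(hits), variables = vars)
}

#' Support-need trigger criterion
#'
#' Met only when the trinary support-need item was answered "yes"; the
#' "would not help" and "no worries" categories do not trigger.
#'
#' @param record A one-row completed EMA record with `support_need`.
#' @return A list with `met` (`NA` when not evaluable).
#' @export
evaluate_support_need <- function(record) {
  if (!isTRUE(record$completed[[1]])) return(list(met = NA))
  list(met = identical(record$support_need[[1]], "yes"))
}

#' Decide delivery for a single EMA
#'
#' Evaluates all three trigger criteria (needed for omitted-control and
#' overlap accounting), randomizes the condition from the current RNG
#' stream, and delivers if and only if the assigned condition's criterion is
#' met and fewer than `max_per_day` interventions were already delivered to
#' this person today. A no-intervention assignment with at least one
#' criterion met is logged as an omitted control.
#'
#' @param record A one-row EMA record in the intervention phase.
#' @param charts Per-variable charts for this person (see [evaluate_spc()]).
#' @param deliveries_today Number of interventions already delivered to this
#'   person on this calendar day.
#' @param config A [trigger_config()].
#' @param assigned_condition Optional pre-drawn condition (skips
#'   randomization), for replaying logged assignments.
#' @param intervention_start_day First day of the intervention phase
#'   (default 4); records before it are a phase error.
#' @return A one-row tibble with the decision fields (see [run_trial()]).
#' @export
decide <- function(record, charts, deliveries_today = 0,
                   config = trigger_config(), assigned_condition = NULL,
                   intervention_start_day = 4) {
  if (record$day[[1]] < intervention_start_day) {
    stop("phase error: record precedes the intervention phase (day ",
         record$day[[1]], " < ", intervention_start_day, ")", call. = FALSE)
  }
  if (!isTRUE(record$completed[[1]])) {
    return(decision_row(record, NA_character_, fc = list(met = NA, variables = character(0)),
                        spc = list(evaluable = FALSE, met = NA, variables = character(0)),
                        sn = list(met = NA), delivered = FALSE,
                        reason = "ema_missing", omitted = FALSE,
                        before = deliveries_today))
  }
  fc <- evaluate_fixed_cutoff(record, cutoff = config$cutoff)
  spc <- evaluate_spc(charts, record, min_baseline = config$min_baseline)
  sn <- evaluate_support_need(record)
  cond <- assigned_condition %||% randomize_condition(1, config$probs)

  any_met <- isTRUE(fc$met) || isTRUE(spc$met) || isTRUE(sn$met)
  criterion_met <- switch(cond,
    fixed_cutoff = isTRUE(fc$met),
    spc = isTRUE(spc$evaluable) && isTRUE(spc$met),
    support_need = isTRUE(sn$met),
    no_intervention = FALSE
  )
  delivered <- criterion_met && deliveries_today < config$max_per_day
  reason <- if (delivered) {
    "none"
  } else if (cond == "no_intervention") {
    "condition4"
  } else if (cond == "spc" && !isTRUE(spc$evaluable)) {
    "insufficient_baseline"
  } else if (!criterion_met) {
    "criterion_not_met"
  } else {
    "daily_cap"
  }
  omitted <- cond == "no_intervention" && any_met
  decision_row(record, cond, fc, spc, sn, delivered, reason, omitted,
               deliveries_today)
}

decision_row <- function(record, cond, fc, spc, sn, delivered, reason,
                         omitted, before) {
  tibble::tibble(
    person_id = record$person_id[[1]],
    day = record$day[[1]], slot = record$slot[[1]],
    completed = isTRUE(record$completed[[1]]),
    assigned_condition = cond,
    fixed_cutoff_met = fc$met,
    fixed_cutoff_vars = paste(fc$variables, collapse = ";"),
    spc_evaluable = isTRUE(spc$evaluable),
    spc_met = spc$met,
    spc_vars = paste(spc$variables, collapse = ";"),
    support_need_met = sn$met,
    any_criterion_met = isTRUE(fc$met) || isTRUE(spc$met) || isTRUE(sn$met),
    delivered = delivered,
    suppressed_reason = reason,
    omitted_control = omitted,
    deliveries_today_before = as.integer(before)
  )
}

#' Run the microrandomized trial over simulated EMA streams
#'
#' Iterates all scheduled prompts in chronological order per person.
#' For every intervention-phase prompt (day `>= intervention_start_day`) it
#' evaluates the three trigger criteria against the state of knowledge at
#' that moment -- the SPC charts use only strictly prior completed
#' observations, growing until the end of the learning phase and frozen
#' afterwards -- randomizes the condition, and applies the delivery rule
#' with the daily cap. Missing prompts yield placeholder decisions with
#' `suppressed_reason = "ema_missing"`.
#'
#' @param records A [simulate_ema()] table (any table with the same
#'   columns works).
#' @param config A [trigger_config()].
#' @param seed Integer seed for the condition randomization stream.
#' @param intervention_start_day First day interventions may be delivered;
#'   defaults to the schedule attached to `records`, else 4.
#' @return An object of class `jitai_trial`: a list with `decisions` (one
#'   row per intervention-phase prompt), `config`, `seed`,
#'   `intervention_start_day`. Use [tidy()] for the decision log and
#'   [glance()] for the trigger accounting.
#' @examples
#' records <- generate_cohort(3, seed = 1) |> simulate_ema(seed = 1)
#' trial <- run_trial(records, seed = 1)
#' glance(trial)
#' @export
run_trial <- function(records, config = trigger_config(), seed = 1L,
                      intervention_start_day = NULL) {
  stopifnot(inherits(config, "trigger_config"))
  sched <- attr(records, "schedule")
  start_day <- intervention_start_day %||%
    (if (!is.null(sched)) sched$intervention_start_day else 4L)

  rec <- dplyr::arrange(records, .data$person_id, .data$day, .data$slot)
  if (any(duplicated(rec[c("person_id", "day", "slot")]))) {
    stop("inconsistent stream: duplicated (person_id, day, slot)", call. = FALSE)
  }

  # SPC exceedance per variable, evaluated against the chart fitted on
  # strictly prior completed observations (growing to day baseline_end_day,
  # frozen after).
  spc <- spc_flags(rec, config)

  phase <- rec$day >= start_day
  dec <- rec[phase, c("person_id", "day", "slot", "completed")]
  dec$fixed_cutoff_met <- fixed_cutoff_flags(rec, config$cutoff)[phase]
  dec$fixed_cutoff_vars <- fixed_cutoff_vars(rec, config$cutoff)[phase]
  dec$spc_evaluable <- spc$evaluable[phase]
  dec$spc_met <- ifelse(spc$evaluable[phase], spc$met[phase], NA)
  dec$spc_vars <- spc$vars[phase]
  dec$support_need_met <- ifelse(dec$completed, rec$support_need[phase] == "yes", NA)

  # condition randomization: one draw per completed intervention-phase EMA,
  # in chronological order (mirrors randomization at EMA completion)
  dec$assigned_condition <- NA_character_
  n_draw <- sum(dec$completed)
  dec$assigned_condition[dec$completed] <-
    with_seed(child_seed(seed, 0, salt = 3), randomize_condition(n_draw, config$probs))

  dec$any_criterion_met <- dec$completed & (
    dec$fixed_cutoff_met %in% TRUE | dec$spc_met %in% TRUE |
      dec$support_need_met %in% TRUE
  )
  criterion_met <- dplyr::case_when(
    !dec$completed ~ FALSE,
    dec$assigned_condition == "fixed_cutoff" ~ dec$fixed_cutoff_met %in% TRUE,
    dec$assigned_condition == "spc" ~ dec$spc_evaluable & dec$spc_met %in% TRUE,
    dec$assigned_condition == "support_need" ~ dec$support_need_met %in% TRUE,
    .default = FALSE
  )
  candidate <- criterion_met & dec$assigned_condition != "no_intervention"
  candidate[is.na(candidate)] <- FALSE

  # Daily cap: within each person-day (slot order) candidates deliver until
  # `max_per_day` deliveries are reached. Suppressions never count toward
  # the cap because only delivered interventions increment it, and
  # candidates convert to deliveries in order until the cap binds, so the
  # grouped cumulative sum over candidates is exactly the cap rule.
  grp <- factor(paste(dec$person_id, dec$day))
  cand_cum <- stats::ave(as.integer(candidate), grp, FUN = cumsum)
  dec$delivered <- candidate & cand_cum <= config$max_per_day
  before <- stats::ave(as.integer(dec$delivered), grp,
                       FUN = function(x) cumsum(x) - x)
  dec$deliveries_today_before <- as.integer(before)

  dec$suppressed_reason <- dplyr::case_when(
    dec$delivered ~ "none",
    !dec$completed ~ "ema_missing",
    dec$assigned_condition == "no_intervention" ~ "condition4",
    dec$assigned_condition == "spc" & !dec$spc_evaluable ~ "insufficient_baseline",
    !criterion_met ~ "criterion_not_met",
    .default = "daily_cap"
  )
  dec$omitted_control <- dec$completed &
    dec$assigned_condition %in% "no_intervention" & dec$any_criterion_met

  dec <- dec[, c("person_id", "day", "slot", "completed", "assigned_condition",
                 "fixed_cutoff_met", "fixed_cutoff_vars", "spc_evaluable",
                 "spc_met", "spc_vars", "support_need_met",
                 "any_criterion_met", "delivered", "suppressed_reason",
                 "omitted_control", "deliveries_today_before")]

  structure(
    list(decisions = dec, config = config, seed = as.integer(seed),
         intervention_start_day = as.integer(start_day)),
    class = "jitai_trial"
  )
}

# vectorized disjunctive fixed-cutoff flag (NA for incomplete records)
fixed_cutoff_flags <- function(rec, cutoff) {
  m <- as.matrix(rec[DISTRESS_VARS])
  hit <- rowSums(m >= cutoff, na.rm = TRUE) > 0
  ifelse(rec$completed, hit, NA)
}

fixed_cutoff_vars <- function(rec, cutoff) {
  m <- as.matrix(rec[DISTRESS_VARS])
  hits <- !is.na(m) & m >= cutoff
  out <- character(nrow(m))
  any_hit <- which(rowSums(hits) > 0)
  out[any_hit] <- apply(hits[any_hit, , drop = FALSE], 1,
                        function(h) paste(DISTRESS_VARS[h], collapse = ";"))
  out
}

# For every record of every person, the SPC evaluation state based on the
# chart fitted from strictly prior completed baseline observations.
spc_flags <- function(rec, config) {
  n <- nrow(rec)
  evaluable <- logical(n)
  met <- logical(n)
  vars <- vector("list", n)
  for (i in seq_len(n)) vars[[i]] <- character(0)

  person_rows <- split(seq_len(n), rec$person_id)
  for (rows in person_rows) {
    comp <- rows[rec$completed[rows]]
    if (length(comp) == 0) next
    bday <- rec$day[comp] <= config$baseline_end_day
    m <- sum(bday)
    brank <- cumsum(bday)
    prior_n <- ifelse(bday, brank - 1L, m)
    ev <- prior_n >= config$min_baseline
    evaluable[comp] <- ev
    if (!any(ev)) next
    for (v in DISTRESS_VARS) {
      x <- rec[[v]][comp]
      xb <- x[bday]
      if (m < 2) next
      csum <- cumsum(xb)
      cmr <- cumsum(abs(diff(xb)))
      pn <- prior_n
      ok <- ev & pn >= 2
      mean_p <- rep(NA_real_, length(comp))
      mrbar <- rep(NA_real_, length(comp))
      mean_p[ok] <- csum[pn[ok]] / pn[ok]
      mrbar[ok] <- cmr[pn[ok] - 1L] / (pn[ok] - 1L)
      ucl <- mean_p + config$L * (mrbar / D2_PAIR)
      hit <- ok & !is.na(x) & x > ucl
      met[comp] <- met[comp] | hit
      for (j in which(hit)) vars[[comp[j]]] <- c(vars[[comp[j]]], v)
    }
  }
  list(evaluable = evaluable, met = met,
       vars = vapply(vars, paste, character(1), collapse = ";"))
}

#' @export
print.jitai_trial <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Microrandomized trial log: %d decision points, %d delivered (fixed cutoff %d, SPC %d, support need %d)\n  omitted controls %d | cap suppressions %d | persons %d\n",
    g$n_decisions, g$n_delivered, g$delivered_fixed_cutoff, g$delivered_spc,
    g$delivered_support_need, g$n_omitted_control, g$n_cap_suppressed,
    g$n_persons
  ))
  invisible(x)
}

#' Tidy and summarize trial, chart and contrast objects
#'
#' `tidy()` returns the row-level table behind an object (the decision log
#' of a trial, the component table of a chart, per-group descriptives of a
#' contrast, per-person rates of a compliance summary); `glance()` returns a
#' one-row summary.
#'
#' @param x A `jitai_trial`, `shewhart_chart`, `welch_contrast` or
#'   `compliance_summary` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy jitai_trial
#' @export
tidy.jitai_trial <- function(x, ...) x$decisions

#' @rdname tidy.jitai_trial
#' @method glance jitai_trial
#' @export
glance.jitai_trial <- function(x, ...) {
  d <- x$decisions
  delivered <- d[d$delivered, ]
  per_cond <- vapply(CONDITIONS[1:3], function(cc) sum(delivered$assigned_condition == cc),
                     integer(1))
  tibble::tibble(
    n_persons = length(unique(d$person_id)),
    n_decisions = nrow(d),
    n_completed = sum(d$completed),
    n_delivered = nrow(delivered),
    delivered_fixed_cutoff = per_cond[["fixed_cutoff"]],
    delivered_spc = per_cond[["spc"]],
    delivered_support_need = per_cond[["support_need"]],
    n_omitted_control = sum(d$omitted_control),
    n_cap_suppressed = sum(d$suppressed_reason == "daily_cap"),
    n_insufficient_baseline = sum(d$suppressed_reason == "insufficient_baseline")
  )
}

#' Trigger accounting of a trial log
#'
#' Per-condition delivered counts with their shares of all deliveries and of
#' all completed decision points -- the accounting the study design reports.
#'
#' @param trial A `jitai_trial` object or its decision tibble.
#' @return A tibble with one row per triggering condition plus a `total`
#'   row.
#' @export
trigger_accounting <- function(trial) {
  d <- if (inherits(trial, "jitai_trial")) trial$decisions else trial
  delivered <- d[d$delivered, ]
  total <- nrow(delivered)
  counts <- vapply(CONDITIONS[1:3], function(cc) sum(delivered$assigned_condition == cc),
                   integer(1))
  tibble::tibble(
    condition = c(CONDITIONS[1:3], "total"),
    n_delivered = c(unname(counts), total),
    share_of_delivered = c(unname(counts) / total, 1),
    share_of_completed = c(unname(counts), total) / sum(d$completed)
  )
}
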
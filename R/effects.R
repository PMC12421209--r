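#' Inject post-delivery intervention effects into a simulated stream
#'
#' For every delivered intervention in `trial`, draws a condition-specific
#' adoption indicator (did the person actually seek support). When adopted,
#' the next completed same-day prompt has its latent distress (all four
#' items) reduced by the person's `effect_delta` and its latent
#' support-seeking rating shifted up by `support_seek_shift`, both before
#' re-discretization to the 1--7 scale. Independently of adoption, the two
#' post-intervention items -- the "right time" rating and the yes/no
#' behavior-adoption report -- are attached to the next completed prompt
#' (even across missed prompts); an evening helpfulness rating is generated
#' for every person-day with at least one delivery.
#'
#' A null configuration (`effect_delta = 0`, `support_seek_shift = 0`)
#' leaves all distress and support-seeking fields unchanged.
#'
#' @param records A [simulate_ema()] table (must carry ground truth).
#' @param trial A [run_trial()] object, or its decision tibble.
#' @param cohort The [generate_cohort()] table the records were simulated
#'   from (provides adoption probabilities and effect sizes).
#' @param effects An [effect_config()] (rating distributions of the
#'   post-intervention items).
#' @param seed Integer seed for adoption and rating draws.
#' @return The records tibble with effects applied; attributes
#'   `"deliveries"` (one row per delivered intervention: condition, adoption
#'   draw, attachment targets) and `"evening"` (per person-day helpfulness)
#'   are added, and the ground truth gains the realized adoption indicators.
#' @export
apply_intervention_effects <- function(records, trial, cohort,
                                       effects = effect_config(), seed = 1L) {
  dec <- if (inherits(trial, "jitai_trial")) trial$decisions else trial
  stopifnot(inherits(effects, "effect_config"))
  truth <- ground_truth(records)

  rec <- dplyr::arrange(records, .data$person_id, .data$day, .data$slot)
  key <- paste(rec$person_id, rec$day, rec$slot)
  del <- dec[dec$delivered, c("person_id", "day", "slot", "assigned_condition")]
  if (nrow(del) == 0) {
    attr(rec, "deliveries") <- empty_deliveries()
    attr(rec, "evening") <- empty_evening()
    return(restore_attrs(rec, records, truth))
  }
  del_idx <- match(paste(del$person_id, del$day, del$slot), key)
  if (anyNA(del_idx)) {
    stop("consistency error: trial log references records absent from the stream",
         call. = FALSE)
  }
  if (any(!rec$completed[del_idx])) {
    stop("consistency error: delivery at a non-completed record", call. = FALSE)
  }

  # next completed record (any day) and next completed same-day record
  nxt <- next_completed_index(rec)
  del$next_idx <- nxt$any_day[del_idx]
  del$next_sameday_idx <- nxt$same_day[del_idx]

  adoption_prob <- cohort_adoption(cohort, del$person_id, del$assigned_condition)
  person_row <- match(del$person_id, cohort$person_id)

  rec_out <- rec
  truth_key <- paste(truth$person_id, truth$day, truth$slot)

  with_seed(child_seed(seed, 0, salt = 4), {
    del$adopted <- stats::runif(nrow(del)) < adoption_prob
    timing_raw <- stats::rnorm(nrow(del),
                               effects$timing_mu[del$assigned_condition],
                               effects$timing_sd)
    del$appropriate_timing <- as.integer(discretize_likert(timing_raw))
    del$behavior_adoption <- ifelse(del$adopted, "yes", "no")

    # distress + support-seeking effect at the next completed same-day EMA
    eff <- which(del$adopted & !is.na(del$next_sameday_idx))
    if (length(eff)) {
      tgt <- del$next_sameday_idx[eff]
      t_idx <- match(key[tgt], truth_key)
      delta <- cohort$effect_delta[person_row[eff]]
      shift <- cohort$support_seek_shift[person_row[eff]]
      for (v in DISTRESS_VARS) {
        lat <- truth[[paste0("latent_", v)]][t_idx] - delta
        truth[[paste0("latent_", v)]][t_idx] <- lat
        rec_out[[v]][tgt] <- as.integer(discretize_likert(lat))
      }
      seek <- truth$latent_support_seeking[t_idx] + shift
      truth$latent_support_seeking[t_idx] <- seek
      rec_out$support_seeking[tgt] <- as.integer(discretize_likert(seek))
    }

    # post-intervention items attach to the next completed EMA, if any
    att <- which(!is.na(del$next_idx))
    rec_out$appropriate_timing[del$next_idx[att]] <- del$appropriate_timing[att]
    rec_out$behavior_adoption[del$next_idx[att]] <- del$behavior_adoption[att]

    # evening helpfulness on each person-day with >= 1 delivery, rated for
    # the day's first delivered intervention
    first_del <- del |>
      dplyr::group_by(.data$person_id, .data$day) |>
      dplyr::summarise(
        n_delivered = dplyr::n(),
        condition = dplyr::first(.data$assigned_condition),
        .groups = "drop"
      )
    help_raw <- stats::rnorm(nrow(first_del),
                             effects$helpfulness_mu[first_del$condition],
                             effects$helpfulness_sd)
    first_del$helpfulness <- as.integer(discretize_likert(help_raw))
    attr(rec_out, "evening") <- first_del
  })

  del$target_day <- rec$day[del$next_idx]
  del$target_slot <- rec$slot[del$next_idx]
  attr(rec_out, "deliveries") <- del
  restore_attrs(rec_out, records, truth)
}

restore_attrs <- function(rec, records, truth) {
  attr(rec, "ground_truth") <- truth
  attr(rec, "schedule") <- attr(records, "schedule")
  attr(rec, "seed") <- attr(records, "seed")
  rec
}

empty_deliveries <- function() {
  tibble::tibble(person_id = character(0), day = integer(0), slot = integer(0),
                 assigned_condition = character(0), next_idx = integer(0),
                 next_sameday_idx = integer(0), adopted = logical(0),
                 appropriate_timing = integer(0),
                 behavior_adoption = character(0),
                 target_day = integer(0), target_slot = integer(0))
}

empty_evening <- function() {
  tibble::tibble(person_id = character(0), day = integer(0),
                 n_delivered = integer(0), condition = character(0),
                 helpfulness = integer(0))
}

cohort_adoption <- function(cohort, person_id, condition) {
  row <- match(person_id, cohort$person_id)
  col <- paste0("adoption_", condition)
  vapply(seq_along(row), function(i) cohort[[col[i]]][row[i]], numeric(1))
}

# For each row of a (person, day, slot)-sorted record table: the index of
# the next completed record of the same person (any day) and restricted to
# the same calendar day. NA when none exists.
next_completed_index <- function(rec) {
  n <- nrow(rec)
  any_day <- rep(NA_integer_, n)
  same_day <- rep(NA_integer_, n)
  person_rows <- split(seq_len(n), rec$person_id)
  for (rows in person_rows) {
    comp <- rows[rec$completed[rows]]
    # next completed at or after each position, then step one completed ahead
    nxt_comp <- rep(NA_integer_, length(rows))
    if (length(comp)) {
      pos <- findInterval(rows, comp) + 1L  # index into comp of next strictly-after
      ok <- pos <= length(comp)
      nxt_comp[ok] <- comp[pos[ok]]
    }
    any_day[rows] <- nxt_comp
    sd_ok <- !is.na(nxt_comp) & rec$day[nxt_comp] == rec$day[rows]
    same_day[rows] <- ifelse(sd_ok, nxt_comp, NA_integer_)
  }
  list(any_day = any_day, same_day = same_day)
}
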
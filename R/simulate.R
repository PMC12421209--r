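#' Simulate EMA streams for a synthetic cohort
#'
#' Generates one record per scheduled prompt for every person in `cohort`.
#' Latent distress follows a person-specific stationary AR(1) process per
#' item, discretized to the 1--7 Likert scale by round-half-up and clipping.
#' Completion is an independent Bernoulli draw per prompt; the trinary
#' support-need item is produced from a logistic link on momentary mean
#' latent distress, with the "no worries" category below a threshold; the
#' attention check is shown with probability 1/7 and answered 5 unless a
#' careless event occurs.
#'
#' The returned table carries the latent ground truth as attribute
#' `"ground_truth"` (see [ground_truth()]) and the schedule as attribute
#' `"schedule"`.
#'
#' @param cohort A [generate_cohort()] table (or any tibble with the same
#'   columns).
#' @param schedule An [ema_schedule()].
#' @param seed Integer master seed. Per-person child streams are derived
#'   deterministically from it, so a person's stream does not depend on the
#'   rest of the cohort.
#' @return A tibble of EMA records, one row per scheduled prompt, ordered by
#'   person, day and slot, with columns `person_id`, `day`, `slot`,
#'   `timestamp`, `completed`, the four distress items, `support_need`,
#'   `support_seeking`, `attention_check_shown`, `attention_check_value`,
#'   `appropriate_timing`, `behavior_adoption`.
#' @examples
#' records <- generate_cohort(2, seed = 1) |> simulate_ema(seed = 1)
#' dplyr::count(records, completed)
#' @export
simulate_ema <- function(cohort, schedule = ema_schedule(), seed = 1L) {
  stopifnot(inherits(schedule, "ema_schedule"))
  check_cohort(cohort)
  pieces <- lapply(seq_len(nrow(cohort)), function(i) {
    generate_ema_stream(cohort[i, ], schedule,
                        seed = child_seed(seed, i, salt = 2))
  })
  records <- dplyr::bind_rows(lapply(pieces, `[[`, "records"))
  truth <- dplyr::bind_rows(lapply(pieces, `[[`, "truth"))
  attr(records, "ground_truth") <- truth
  attr(records, "schedule") <- schedule
  attr(records, "seed") <- as.integer(seed)
  records
}

#' Simulate a single person's EMA stream
#'
#' Workhorse behind [simulate_ema()]; exposed for tests and for building
#' streams person by person.
#'
#' @param params One row of a [generate_cohort()] table.
#' @param schedule An [ema_schedule()].
#' @param seed Integer seed for this person's stream.
#' @return A list with elements `records` (tibble, one row per scheduled
#'   prompt) and `truth` (tibble of latent values per prompt).
#' @export
generate_ema_stream <- function(params, schedule = ema_schedule(), seed = 1L) {
  stopifnot(inherits(schedule, "ema_schedule"), nrow(params) == 1)
  n_days <- schedule$n_days
  spd <- schedule$slots_per_day
  n <- n_days * spd

  day <- rep(seq_len(n_days), each = spd)
  slot <- rep(seq_len(spd), times = n_days)

  with_seed(seed, {
    # timestamps: uniform within each slot's window, on a fixed origin date
    window_start <- schedule$first_hour + (slot - 1) * schedule$window_hours
    hour <- window_start + stats::runif(n) * schedule$window_hours
    timestamp <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
      (day - 1) * 86400 + hour * 3600

    # latent AR(1) per distress item, stationary start
    latent <- matrix(NA_real_, nrow = n, ncol = 4,
                     dimnames = list(NULL, DISTRESS_VARS))
    for (v in DISTRESS_VARS) {
      mu <- params[[paste0("mu_", v)]]
      sdw <- params[[paste0("sd_", v)]]
      ar <- params$ar_coef
      e <- stats::rnorm(n)
      x <- numeric(n)
      x[1] <- mu + sdw * e[1]
      innov_sd <- sdw * sqrt(1 - ar^2)
      for (t in seq_len(n)[-1]) {
        x[t] <- mu + ar * (x[t - 1] - mu) + innov_sd * e[t]
      }
      latent[, v] <- x
    }

    completed <- stats::runif(n) < params$compliance_prob

    latent_mean <- rowMeans(latent)
    p_yes <- stats::plogis(params$support_need_intercept +
                             params$support_need_slope * latent_mean)
    u_need <- stats::runif(n)
    support_need <- ifelse(latent_mean < params$no_worries_threshold,
                           "no_worries",
                           ifelse(u_need < p_yes, "yes", "would_not_help"))

    seek_latent <- stats::rnorm(n, params$support_seek_mu, params$support_seek_sd)

    shown <- stats::runif(n) < 1 / 7
    careless <- stats::runif(n) < params$careless_prob
    check_value <- ifelse(careless, sample(c(1:4, 6:7), n, replace = TRUE), 5)

    records <- tibble::tibble(
      person_id = params$person_id,
      day = as.integer(day),
      slot = as.integer(slot),
      timestamp = timestamp,
      completed = completed,
      negative_affect = mask(as.integer(discretize_likert(latent[, "negative_affect"])), completed),
      stress = mask(as.integer(discretize_likert(latent[, "stress"])), completed),
      loneliness = mask(as.integer(discretize_likert(latent[, "loneliness"])), completed),
      rumination = mask(as.integer(discretize_likert(latent[, "rumination"])), completed),
      support_need = ifelse(completed, support_need, NA_character_),
      support_seeking = mask(as.integer(discretize_likert(seek_latent)), completed),
      attention_check_shown = completed & shown,
      attention_check_value = mask(as.integer(check_value), completed & shown),
      appropriate_timing = NA_integer_,
      behavior_adoption = NA_character_
    )
    truth <- tibble::tibble(
      person_id = params$person_id,
      day = as.integer(day),
      slot = as.integer(slot),
      latent_negative_affect = latent[, "negative_affect"],
      latent_stress = latent[, "stress"],
      latent_loneliness = latent[, "loneliness"],
      latent_rumination = latent[, "rumination"],
      latent_support_seeking = seek_latent,
      seed = as.integer(seed)
    )
    list(records = records, truth = truth)
  })
}

mask <- function(x, keep) {
  x[!keep] <- NA
  x
}

#' Latent ground truth of a simulated EMA table
#'
#' @param records A table produced by [simulate_ema()] (and possibly
#'   modified by [apply_intervention_effects()]).
#' @return The ground-truth tibble stored on the records, or an error when
#'   absent.
#' @export
ground_truth <- function(records) {
  gt <- attr(records, "ground_truth")
  if (is.null(gt)) stop("records carry no ground truth; were they simulated by simulate_ema()?",
                        call. = FALSE)
  gt
}

check_cohort <- function(cohort) {
  needed <- c("person_id", paste0("mu_", DISTRESS_VARS), paste0("sd_", DISTRESS_VARS),
              "ar_coef", "compliance_prob", "support_need_intercept",
              "support_need_slope", "no_worries_threshold", "careless_prob",
              "support_seek_mu", "support_seek_sd")
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(cohort)
}

#' Write simulated records and ground truth as CSV
#'
#' Long-format delimited output with stable snake_case headers; missing
#' values are written as empty fields. Ground truth goes to a companion file
#' keyed by `(person_id, day, slot)`.
#'
#' @param records A [simulate_ema()] table.
#' @param path Output CSV path for the records.
#' @param truth_path Optional path for the ground-truth CSV.
#' @return `path`, invisibly.
#' @export
write_ema_csv <- function(records, path, truth_path = NULL) {
  out <- dplyr::mutate(records,
                       timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S"))
  readr::write_csv(out, path, na = "")
  if (!is.null(truth_path)) {
    readr::write_csv(ground_truth(records), truth_path, na = "")
  }
  invisible(path)
}
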
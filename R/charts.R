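# Shewhart individuals control charts with moving-range sigma estimation.
#
# The chart for person i and one distress item uses the phase-1 (baseline)
# observations x_ij: moving ranges MR_ij = |x_ij - x_i(j-1)| between
# successive completed observations, sigma_hat = mean(MR) / d2 with
# d2 = 1.128 (the unbiasing constant for ranges of successive pairs,
# 2/sqrt(pi) to three decimals), and UCL = phase-1 mean + L * sigma_hat.

D2_PAIR <- 1.128

#' The d2 unbiasing constant for moving ranges of successive pairs
#'
#' Converts a mean moving range into an estimate of the process SD:
#' `sigma_hat = mean(MR) / d2`. For subgroups of size 2 the constant equals
#' the expected range of two independent standard normal variates,
#' `2/sqrt(pi)`, conventionally rounded to 1.128.
#'
#' @return The numeric constant 1.128.
#' @export
shewhart_d2 <- function() D2_PAIR

#' Moving ranges of an ordered series
#'
#' Absolute differences between successive observations. With fewer than two
#' observations the series is empty (insufficient for sigma estimation).
#'
#' @param x Numeric vector ordered in time (completed observations only).
#' @return Numeric vector of length `length(x) - 1` (or length 0).
#' @examples
#' moving_ranges(c(1, 4, 2))  # 3 2
#' @export
moving_ranges <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) return(numeric(0))
  abs(diff(x))
}

#' Moving-range estimate of the process SD
#'
#' `mean(mr) / d2` with `d2 = 1.128`. Unlike the sample SD this estimate is
#' based on changes between subsequent observations and so is robust to slow
#' level shifts within the baseline.
#'
#' @param mr Numeric vector of moving ranges (see [moving_ranges()]).
#' @return Non-negative numeric scalar.
#' @export
estimate_sigma <- function(mr) {
  if (length(mr) < 1 || all(is.na(mr))) {
    stop("insufficient data: at least one moving range is required", call. = FALSE)
  }
  mean(mr) / D2_PAIR
}

#' Construct a Shewhart individuals chart from known parameters
#'
#' Mainly useful for calibration studies where the process mean and SD are
#' known rather than estimated; [fit_chart()] builds the chart from data.
#'
#' @param center Process mean (chart center line).
#' @param sigma Process SD.
#' @param L Control-limit multiplier (default 2, a one-sided Gaussian tail
#'   of about 2.28% per observation).
#' @param person_id,variable Optional labels.
#' @param mr_mean Optional mean moving range the sigma was derived from.
#' @param n_baseline Number of baseline observations (NA when known-parameter).
#' @param frozen Whether the learning phase has ended.
#' @return An object of class `shewhart_chart`.
#' @examples
#' ch <- shewhart_chart(center = 0, sigma = 1, L = 2)
#' exceeds_ucl(ch, c(1.9, 2.1))
#' @export
shewhart_chart <- function(center, sigma, L = 2, person_id = NA_character_,
                           variable = NA_character_, mr_mean = NA_real_,
                           n_baseline = NA_integer_, frozen = TRUE) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(
    list(
      person_id = person_id, variable = variable,
      phase1_mean = center, mr_mean = mr_mean, d2_constant = D2_PAIR,
      sigma_hat = sigma, L = L, ucl = center + L * sigma,
      n_baseline = n_baseline, frozen = frozen
    ),
    class = "shewhart_chart"
  )
}

#' Fit a personalized control chart from one person's EMA records
#'
#' Two-phase design: during the learning phase (days 1 to
#' `baseline_end_day`) the chart is fitted on all completed observations up
#' to `as_of` (a growing window); once `as_of` passes the end of the
#' learning phase the chart uses all completed observations of days 1 to
#' `baseline_end_day` and is frozen. The upper control limit is
#' `phase-1 mean + L * sigma_hat` with the moving-range sigma estimate.
#'
#' @param records EMA records of a single person (see [simulate_ema()] for
#'   the column layout); rows must be ordered by day and slot.
#' @param variable One of the four distress items.
#' @param L Control-limit multiplier (default 2).
#' @param baseline_end_day Last learning-phase day (default 7).
#' @param as_of Optional `c(day, slot)` giving the time up to which (and
#'   including) observations may be used; defaults to the end of the data.
#' @return An object of class `shewhart_chart`.
#' @examples
#' rec <- tibble::tibble(
#'   person_id = "p001", day = rep(1:2, each = 4), slot = rep(1:4, 2),
#'   completed = TRUE,
#'   stress = c(2, 5, 3, 6, 2, 5, 3, 4)
#' )
#' fit_chart(rec, "stress", L = 2)
#' @export
fit_chart <- function(records, variable, L = 2, baseline_end_day = 7,
                      as_of = NULL) {
  stopifnot(variable %in% names(records))
  if (length(unique(records$person_id)) > 1) {
    stop("fit_chart() expects records of a single person", call. = FALSE)
  }
  ord <- order(records$day, records$slot)
  records <- records[ord, ]
  if (is.null(as_of)) {
    as_of <- c(max(records$day), max(records$slot[records$day == max(records$day)]))
  }
  in_window <- records$completed &
    records$day <= baseline_end_day &
    (records$day < as_of[1] | (records$day == as_of[1] & records$slot <= as_of[2])) &
    !is.na(records[[variable]])
  x <- records[[variable]][in_window]
  if (length(x) < 2) {
    stop("insufficient data: fewer than 2 completed baseline observations",
         call. = FALSE)
  }
  mr <- moving_ranges(x)
  sigma <- estimate_sigma(mr)
  shewhart_chart(
    center = mean(x), sigma = sigma, L = L,
    person_id = records$person_id[1], variable = variable,
    mr_mean = mean(mr), n_baseline = length(x),
    frozen = as_of[1] > baseline_end_day
  )
}

#' Fit personalized charts for every person and distress item
#'
#' @param records EMA records of one or more persons.
#' @param variables Distress items to chart (default all four).
#' @inheritParams fit_chart
#' @return A tibble with one row per person and variable and the chart
#'   components (`phase1_mean`, `mr_mean`, `sigma_hat`, `L`, `ucl`,
#'   `n_baseline`, `frozen`), suitable for CSV audit export. Person-variable
#'   pairs with fewer than 2 completed baseline observations are returned
#'   with `NA` chart fields.
#' @export
fit_charts <- function(records, variables = distress_items(), L = 2,
                       baseline_end_day = 7, as_of = NULL) {
  grid <- tidyr::expand_grid(person_id = unique(records$person_id),
                             variable = variables)
  rows <- purrr::pmap(grid, function(person_id, variable) {
    rec <- records[records$person_id == person_id, ]
    ch <- tryCatch(
      fit_chart(rec, variable, L = L, baseline_end_day = baseline_end_day,
                as_of = as_of),
      error = function(e) NULL
    )
    if (is.null(ch)) {
      tibble::tibble(person_id = person_id, variable = variable,
                     n_baseline = NA_integer_, phase1_mean = NA_real_,
                     mr_mean = NA_real_, sigma_hat = NA_real_, L = L,
                     ucl = NA_real_, frozen = NA)
    } else {
      tidy.shewhart_chart(ch)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("shewhart_chart_tbl", class(out))
  out
}

#' Does an observation exceed the upper control limit?
#'
#' Strict exceedance: a value exactly at the limit does not signal.
#'
#' @param chart A `shewhart_chart`.
#' @param value Numeric vector of observations.
#' @return Logical vector.
#' @export
exceeds_ucl <- function(chart, value) {
  stopifnot(inherits(chart, "shewhart_chart"))
  value > chart$ucl
}

#' @export
print.shewhart_chart <- function(x, ...) {
  cat(sprintf(
    "Shewhart individuals chart%s%s\n  center %.4f | sigma_hat %.4f (d2 = %.3f) | L = %g | UCL %.4f\n  n_baseline %s | %s\n",
    if (!is.na(x$person_id)) paste0(" for ", x$person_id) else "",
    if (!is.na(x$variable)) paste0(" [", x$variable, "]") else "",
    x$phase1_mean, x$sigma_hat, x$d2_constant, x$L, x$ucl,
    ifelse(is.na(x$n_baseline), "?", x$n_baseline),
    if (isTRUE(x$frozen)) "frozen" else "learning"
  ))
  invisible(x)
}

#' @rdname tidy.jitai_trial
#' @method tidy shewhart_chart
#' @export
tidy.shewhart_chart <- function(x, ...) {
  tibble::tibble(
    person_id = x$person_id, variable = x$variable,
    n_baseline = x$n_baseline, phase1_mean = x$phase1_mean,
    mr_mean = x$mr_mean, sigma_hat = x$sigma_hat, L = x$L, ucl = x$ucl,
    frozen = x$frozen
  )
}
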
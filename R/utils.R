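# Internal helpers shared across modules.

# The four momentary distress indicators, in canonical order.
DISTRESS_VARS <- c("negative_affect", "stress", "loneliness", "rumination")

# Triggering conditions of the microrandomized design, in canonical order.
CONDITIONS <- c("fixed_cutoff", "spc", "support_need", "no_intervention")

SUPPORT_NEED_LEVELS <- c("yes", "would_not_help", "no_worries")

SUPPRESSED_REASONS <- c(
  "none", "criterion_not_met", "condition4", "daily_cap",
  "insufficient_baseline", "ema_missing"
)

#' Distress item names
#'
#' The four momentary distress indicators monitored by the trigger engine:
#' negative affect, stress, loneliness, and rumination, each rated on a
#' 1--7 Likert scale.
#'
#' @return Character vector of length four.
#' @export
distress_items <- function() DISTRESS_VARS

#' Trigger condition names
#'
#' The four microrandomized triggering conditions: a fixed disjunctive
#' cutoff over the distress items, a personalized statistical-process-control
#' (SPC) exceedance, a momentary support-need report, and a no-intervention
#' control condition.
#'
#' @return Character vector of length four.
#' @export
trigger_conditions <- function() CONDITIONS

# Round-half-up then clip to the 1..7 Likert range. Monotone by construction.
discretize_likert <- function(x) {
  pmin(pmax(floor(x + 0.5), 1), 7)
}

# Deterministic 31-bit child seed for per-person / per-stage RNG streams.
# All intermediates stay below 2^53 so double arithmetic is exact.
child_seed <- function(master, index, salt = 0) {
  m <- as.double(master) %% 2147483647
  s <- (m * 69621 + as.double(index) * 1013904 + as.double(salt) * 7919)
  as.integer(s %% 2147483629) + 1L
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

stop_config <- function(field, constraint) {
  stop(sprintf("invalid configuration: `%s` %s", field, constraint), call. = FALSE)
}
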
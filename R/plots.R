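# ggplot2 displays for the main result types.

#' Plot a person's distress series against the personalized control limit
#'
#' Shows the completed observations of one distress item over the study
#' days, the frozen chart's center line and upper control limit, the
#' learning/monitoring phase boundary, and marks exceedances.
#'
#' @param records EMA records.
#' @param person A `person_id` present in `records`.
#' @param variable One of the four distress items.
#' @param L Control-limit multiplier (default 2).
#' @param baseline_end_day Last learning-phase day (default 7).
#' @return A ggplot object.
#' @export
plot_control_chart <- function(records, person, variable = "stress", L = 2,
                               baseline_end_day = 7) {
  rec <- records[records$person_id == person & records$completed &
                   !is.na(records[[variable]]), ]
  if (nrow(rec) == 0) stop("no completed observations for ", person, call. = FALSE)
  chart <- fit_chart(rec, variable, L = L, baseline_end_day = baseline_end_day)
  rec <- dplyr::arrange(rec, .data$day, .data$slot)
  rec$t <- rec$day + (rec$slot - 1) / max(rec$slot)
  rec$exceeds <- exceeds_ucl(chart, rec[[variable]])
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$t, y = .data[[variable]])) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$exceeds), size = 1.6) +
    ggplot2::geom_hline(yintercept = chart$ucl, linetype = "dashed", color = "firebrick") +
    ggplot2::geom_hline(yintercept = chart$phase1_mean, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = baseline_end_day + 1, color = "grey40") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::scale_y_continuous(limits = c(1, 7), breaks = 1:7) +
    ggplot2::labs(
      x = "study day", y = variable,
      title = sprintf("%s: %s (UCL = %.2f, center = %.2f, L = %g)",
                      person, variable, chart$ucl, chart$phase1_mean, chart$L),
      subtitle = "dashed: upper control limit | dotted: phase-1 mean | vertical: limit freeze"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_control_chart Delivered-intervention counts per condition
#'   with suppression reasons, from a trial log.
#' @param object A `jitai_trial` (autoplot method).
#' @param ... Unused.
#' @method autoplot jitai_trial
#' @export
autoplot.jitai_trial <- function(object, ...) {
  d <- object$decisions[object$decisions$completed, ]
  d$outcome <- ifelse(d$delivered, "delivered", d$suppressed_reason)
  counts <- dplyr::count(d, .data$assigned_condition, .data$outcome)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$assigned_condition,
                                       y = .data$n, fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "assigned condition", y = "decision points",
                  title = "Microrandomized decision points by condition and outcome") +
    ggplot2::theme_minimal()
}

#' Distribution of lagged change scores by trigger status
#'
#' Violin/box display of the T to T+1 change per distress item, split by
#' whether the prompt at T led to a delivery, an omitted control, or met no
#' criterion. Negative changes are distress reductions.
#'
#' @param scores A [change_scores()] tibble.
#' @return A ggplot object.
#' @export
plot_change_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$trigger_status, y = .data$delta,
                                       fill = .data$trigger_status)) +
    ggplot2::geom_violin(alpha = 0.4, color = NA) +
    ggplot2::geom_boxplot(width = 0.2, outlier.size = 0.5) +
    ggplot2::facet_wrap(~variable) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "change T+1 - T (negative = reduction)",
                  title = "Lagged distress change by trigger status") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' @describeIn plot_control_chart Per-person compliance bars with the
#'   double-70% feasibility thresholds (autoplot method).
#' @method autoplot compliance_summary
#' @export
autoplot.compliance_summary <- function(object, ...) {
  p <- object$persons
  ggplot2::ggplot(p, ggplot2::aes(x = stats::reorder(.data$person_id, .data$rate),
                                  y = .data$rate, fill = .data$meets_threshold)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$person_rate_threshold,
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "completed / scheduled",
                  title = sprintf("Compliance: %.0f%% of persons at or above %.0f%%",
                                  100 * object$share_meeting,
                                  100 * object$person_rate_threshold)) +
    ggplot2::guides(fill = "none") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
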
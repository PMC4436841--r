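# S3 methods: print, broom-style tidiers, and plots.

#' @export
print.or_schedule <- function(x, ...) {
  asg <- x$assignments
  cat("<or_schedule>\n")
  cat(sprintf("  %d patients: %d planned, %d postponed, %d cancelled, %d unscheduled\n",
              nrow(asg), sum(asg$status == "planned"),
              sum(asg$status == "postponed"), sum(asg$status == "cancelled"),
              sum(asg$status == "unscheduled")))
  if (is.finite(x$objective %||% NA)) {
    cat(sprintf("  objective (NAWD): %.1f\n", x$objective))
  }
  cat(sprintf("  solver: %s\n", x$solver$backend %||% "?"))
  invisible(x)
}

#' @export
print.three_phase_plan <- function(x, ...) {
  cat("<three_phase_plan> target week starting", format(x$target_week), "\n")
  print(x$schedule)
  cat(sprintf("  changelog: %d postponement(s), %d cancellation(s)\n",
              sum(x$changelog$event == "postponed"),
              sum(x$changelog$event == "cancelled")))
  invisible(x)
}

#' @export
print.utilization_report <- function(x, ...) {
  cat("<utilization_report>\n")
  s <- x$summary
  cat(sprintf("  planned %d | unscheduled %d | postponed %d | cancelled %d\n",
              s$n_planned, s$n_unscheduled, s$n_postponed, s$n_cancelled))
  cat(sprintf("  blocks open %d/%d | mean open-block utilisation %.1f%%\n",
              s$blocks_open, s$blocks_total, 100 * s$mean_utilization))
  invisible(x)
}

#' Tidy a schedule into its assignment table
#'
#' @param x An `or_schedule` or `three_phase_plan`.
#' @param ... Unused.
#' @return A tibble with one row per patient considered.
#' @method tidy or_schedule
#' @export
tidy.or_schedule <- function(x, ...) x$assignments

#' @rdname tidy.or_schedule
#' @method tidy three_phase_plan
#' @export
tidy.three_phase_plan <- function(x, ...) x$schedule$assignments

#' One-row summary of a schedule
#'
#' @param x An `or_schedule` or `three_phase_plan`.
#' @param ... Unused.
#' @return A one-row tibble (counts by status, objective, mean open-block
#'   utilisation).
#' @method glance or_schedule
#' @export
glance.or_schedule <- function(x, ...) {
  rep <- utilization_report(x)
  dplyr::bind_cols(rep$summary, tibble(objective = x$objective))
}

#' @rdname glance.or_schedule
#' @method glance three_phase_plan
#' @export
glance.three_phase_plan <- function(x, ...) {
  rep <- utilization_report(x)
  rep$summary
}

#' Plot block utilisation
#'
#' One bar per OR block (faceted by room) showing occupied minutes against
#' the block duration, coloured by specialty.
#'
#' @param object An `or_schedule`, `three_phase_plan` or
#'   `utilization_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot utilization_report
#' @export
autoplot.utilization_report <- function(object, ...) {
  bb <- object$by_block
  bb$slot <- paste(format(bb$date, "%a"), substr(bb$session, 1, 2))
  ggplot2::ggplot(bb, ggplot2::aes(x = .data$slot)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$duration_min),
                      fill = "grey85", width = 0.8) +
    ggplot2::geom_col(ggplot2::aes(y = .data$occupied_min,
                                   fill = .data$specialty), width = 0.8) +
    ggplot2::facet_wrap(~room, ncol = 1) +
    ggplot2::labs(x = NULL, y = "minutes", fill = "specialty",
                  title = "OR block occupation") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.utilization_report
#' @method autoplot or_schedule
#' @export
autoplot.or_schedule <- function(object, ...) {
  autoplot(utilization_report(object), ...)
}

#' @rdname autoplot.utilization_report
#' @method autoplot three_phase_plan
#' @export
autoplot.three_phase_plan <- function(object, ...) {
  autoplot(utilization_report(object), ...)
}

#' Plot a waiting-list profile
#'
#' Elapsed waiting days by URG class at the list's reference date, with
#' each class's maximum acceptable wait marked.
#'
#' @param wl A [waiting_list()].
#' @param urg_table URG class table.
#' @return A ggplot object.
#' @export
plot_waiting_list <- function(wl, urg_table = default_urg_classes()) {
  df <- nawd(as_tibble(wl), reference_date(wl), urg_table)
  df$urg <- factor(df$urg, levels = urg_table$code)
  lim <- tibble(urg = factor(urg_table$code, levels = urg_table$code),
                max_wait_days = urg_table$max_wait_days)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$urg, y = .data$elapsed_days)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.4, size = 0.8) +
    ggplot2::geom_crossbar(data = lim,
                           ggplot2::aes(y = .data$max_wait_days,
                                        ymin = .data$max_wait_days,
                                        ymax = .data$max_wait_days),
                           color = "red", width = 0.6, linewidth = 0.3) +
    ggplot2::labs(x = "URG class", y = "elapsed waiting days",
                  title = "Waiting list by urgency class") +
    ggplot2::theme_minimal()
}
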
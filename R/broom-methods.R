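#' Tidiers and plots for SLE results
#'
#' `tidy()` returns per-observation tibbles, `glance()` one-row summaries,
#' and `autoplot()` ggplot2 figures, following the broom conventions.
#'
#' @param x An `sle_curve`, `dnb_result` or `dnb_condition_report`.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot object (`autoplot`).
#' @name sle-tidiers
NULL

#' @rdname sle-tidiers
#' @method tidy sle_curve
#' @export
tidy.sle_curve <- function(x, ...) x$scores

#' @rdname sle-tidiers
#' @method glance sle_curve
#' @export
glance.sle_curve <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_times = nrow(x$summary),
    n_case = sum(x$summary$n_case),
    critical_time = x$critical_time,
    peak_score = max(x$summary$mean),
    reference_spec = x$reference_spec,
    divisor = x$divisor
  )
}

#' @rdname sle-tidiers
#' @param object An `sle_curve`.
#' @method autoplot sle_curve
#' @export
autoplot.sle_curve <- function(object, ...) {
  sm <- dplyr::mutate(object$summary,
                      time = factor(.data$time, levels = object$time_levels))
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$time, y = .data$mean, group = 1)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0.15) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$time == object$critical_time),
                        size = 2.5, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey20")) +
    ggplot2::labs(x = "time point", y = "global SLE score (mean ± SEM)",
                  title = "Single-sample landscape entropy curve",
                  subtitle = paste("peak at", object$critical_time)) +
    ggplot2::theme_minimal()
}

#' @export
print.sle_curve <- function(x, ...) {
  cat(sprintf("<sle_curve> %d time point(s), K = %d scoreable locals; peak at %s\n",
              nrow(x$summary), x$k, x$critical_time))
  print(x$summary)
  invisible(x)
}

#' @rdname sle-tidiers
#' @method tidy dnb_result
#' @export
tidy.dnb_result <- function(x, ...) x$members

#' @rdname sle-tidiers
#' @method glance dnb_result
#' @export
glance.dnb_result <- function(x, ...) {
  tibble::tibble(
    n_members = nrow(x$members),
    rule = x$rule,
    parameter = x$parameter,
    critical_time = x$critical_time %||% NA_character_,
    top_score = if (nrow(x$members) > 0) max(x$members$score) else NA_real_
  )
}

#' @rdname sle-tidiers
#' @method tidy dnb_condition_report
#' @export
tidy.dnb_condition_report <- function(x, ...) {
  dplyr::mutate(x$stats, is_critical = .data$time == x$t_star)
}

#' @rdname sle-tidiers
#' @method glance dnb_condition_report
#' @export
glance.dnb_condition_report <- function(x, ...) {
  wide <- setNames(as.list(x$conditions$passed), x$conditions$condition)
  tibble::tibble(t_star = x$t_star, cohort = x$cohort,
                 !!!wide, passed = x$passed)
}

#' @rdname sle-tidiers
#' @method autoplot dnb_condition_report
#' @export
autoplot.dnb_condition_report <- function(object, ...) {
  long <- object$stats |>
    dplyr::select("time", "sd_in", "pcc_in", "pcc_out") |>
    tidyr::pivot_longer(-"time", names_to = "statistic", values_to = "value") |>
    dplyr::mutate(
      time = factor(.data$time, levels = unique(object$stats$time)),
      statistic = factor(.data$statistic, levels = c("sd_in", "pcc_in", "pcc_out")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value, group = 1)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$time == object$t_star),
                        size = 2, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey20")) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "time point", y = NULL,
                  title = "DNB condition statistics over time",
                  subtitle = paste("candidate critical time:", object$t_star)) +
    ggplot2::theme_minimal()
}
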
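# ggplot2 visualisations of simulation results.

#' Boxplot of per-cycle dismissal ratios
#'
#' @param object A `ward_sim_log`.
#' @param by `"collective_size"` bins the cycles by collective size (width
#'   10); `"none"` draws a single box.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ward_sim_log
#' @export
autoplot.ward_sim_log <- function(object, by = c("collective_size", "none"),
                                  ...) {
  by <- match.arg(by)
  d <- tidy(object)
  if (by == "collective_size") {
    d$size_bin <- size_bin(d$collective_size)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$size_bin,
                                    y = .data$dismissal_ratio)) +
      ggplot2::geom_boxplot() +
      ggplot2::stat_summary(fun = mean, geom = "point", colour = "red") +
      ggplot2::labs(x = "collective size", y = "dismissal ratio",
                    title = object$config$strategy$name) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$strategy,
                                    y = .data$dismissal_ratio)) +
      ggplot2::geom_boxplot() +
      ggplot2::stat_summary(fun = mean, geom = "point", colour = "red") +
      ggplot2::labs(x = NULL, y = "dismissal ratio") +
      ggplot2::theme_minimal()
  }
}

#' Boxplot comparing strategies of a sweep
#'
#' @param object A `ward_sweep`.
#' @param what `"dismissal"`, `"cost"` (per assigned patient) or
#'   `"seconds"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ward_sweep
#' @export
autoplot.ward_sweep <- function(object,
                                what = c("dismissal", "cost", "seconds"),
                                ...) {
  what <- match.arg(what)
  d <- tidy(object)
  y <- switch(what,
    dismissal = d$dismissal_ratio,
    cost = ifelse(d$assigned_count > 0, d$total_sum / d$assigned_count,
                  NA_real_),
    seconds = d$compute_seconds
  )
  d$y <- y
  lab <- switch(what, dismissal = "dismissal ratio",
                cost = "mean cost per assigned patient",
                seconds = "computation time [s]")
  ggplot2::ggplot(d[!is.na(d$y), ], ggplot2::aes(x = .data$strategy,
                                                 y = .data$y)) +
    ggplot2::geom_boxplot() +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red") +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
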
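# broom-style accessors for the package's result objects.

#' Tidy a simulation log
#'
#' @param x A `ward_sim_log`.
#' @param ... Unused.
#' @return The per-cycle tibble with a `strategy` column prepended.
#' @method tidy ward_sim_log
#' @export
tidy.ward_sim_log <- function(x, ...) {
  dplyr::bind_cols(tibble(strategy = x$config$strategy$name), x$cycles)
}

#' Glance at a simulation log
#'
#' @param x A `ward_sim_log`.
#' @param ... Unused.
#' @return A one-row tibble with run-level summaries.
#' @method glance ward_sim_log
#' @export
glance.ward_sim_log <- function(x, ...) {
  d <- dismissal_summary(x)
  tibble(
    strategy = x$config$strategy$name,
    cycles = nrow(x$cycles),
    patients = x$total_patients,
    mean_dismissal = d$mean,
    median_dismissal = d$median,
    mean_dismissal_adjusted = d$mean_adjusted,
    timeout_cycles = d$timeout_cycles,
    mean_seconds = mean(x$cycles$compute_seconds)
  )
}

#' Tidy a strategy sweep
#'
#' @param x A `ward_sweep`.
#' @param ... Unused.
#' @return Stacked per-cycle tibbles of all swept strategies.
#' @method tidy ward_sweep
#' @export
tidy.ward_sweep <- function(x, ...) {
  bind_rows(lapply(unclass(x), tidy))
}

#' Glance at a strategy sweep
#' @param x A `ward_sweep`.
#' @param ... Unused.
#' @method glance ward_sweep
#' @export
glance.ward_sweep <- function(x, ...) {
  bind_rows(lapply(unclass(x), glance))
}

#' Tidy a solved assignment program
#'
#' @param x A `ward_solution`.
#' @param ... Unused.
#' @return The decision tibble (one row per patient).
#' @method tidy ward_solution
#' @export
tidy.ward_solution <- function(x, ...) {
  x$decisions %||% tibble()
}

#' Glance at a solved assignment program
#' @param x A `ward_solution`.
#' @param ... Unused.
#' @method glance ward_solution
#' @export
glance.ward_solution <- function(x, ...) {
  tibble(
    status = x$status,
    objective_value = x$objective_value,
    assigned = if (is.null(x$decisions)) NA_integer_ else
      sum(x$decisions$status == "assigned"),
    dismissed = if (is.null(x$decisions)) NA_integer_ else
      sum(x$decisions$status == "dismissed"),
    solve_seconds = x$solve_seconds
  )
}
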
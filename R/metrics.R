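# Descriptive statistics over simulation logs: dismissal ratios, cost
# decompositions, runtimes, and strategy comparison tables. Quantiles use
# linear interpolation between order statistics (R's default type 7).

summary_stats <- function(x) {
  if (!length(x)) abort("cannot summarise an empty vector")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(mean = mean(x), median = q[2], sd = if (length(x) > 1) sd(x) else 0,
         q1 = q[1], q3 = q[3], min = min(x), max = max(x), n = length(x))
}

size_bin <- function(size, width = 10L) {
  lo <- (ceiling(size / width) - 1L) * width + 1L
  factor(sprintf("%d-%d", lo, lo + width - 1L),
         levels = sprintf("%d-%d", seq(1L, max(lo), by = width),
                          seq(1L, max(lo), by = width) + width - 1L))
}

#' Summarise per-cycle dismissal ratios
#'
#' Mean, median, sd, quartiles and range of the per-cycle dismissal ratio,
#' optionally refined into collective-size bins of width 10 (1-10, 11-20,
#' ...). The `mean_adjusted` column recomputes the mean disregarding the
#' cycles whose dismissals were caused by a solver timeout (relevant for
#' EXACT logs; equal to `mean` when no timeout occurred).
#'
#' @param log A `ward_sim_log`.
#' @param by `"none"` or `"collective_size"`.
#' @return A tibble of summary statistics (one row, or one per size bin).
#' @export
dismissal_summary <- function(log, by = c("none", "collective_size")) {
  by <- match.arg(by)
  stopifnot(inherits(log, "ward_sim_log"))
  cy <- log$cycles
  if (!nrow(cy)) abort("empty simulation log")
  one <- function(d) {
    s <- summary_stats(d$dismissal_ratio)
    keep <- d$solver_status != "timeout"
    s$mean_adjusted <- if (any(keep)) mean(d$dismissal_ratio[keep]) else
      NA_real_
    s$timeout_cycles <- sum(!keep)
    s
  }
  if (by == "none") {
    one(cy)
  } else {
    cy$size_bin <- size_bin(cy$collective_size)
    out <- cy |>
      dplyr::group_split(.data$size_bin) |>
      purrr::map(function(d) {
        dplyr::bind_cols(tibble(size_bin = d$size_bin[1]), one(d))
      })
    bind_rows(out)
  }
}

#' Summarise assignment costs
#'
#' Per-cycle mean cost per assigned patient, dismissals excluded (their
#' penalties would swamp the factor structure). Cycles without any assigned
#' patient contribute nothing. With `per_factor = TRUE` the summary is
#' decomposed into the four partial factors plus the total, and each
#' factor's share of the summed total cost is reported.
#'
#' @param log A `ward_sim_log`.
#' @param per_factor Decompose into the four partial cost factors.
#' @return A tibble; `empty` is `TRUE` (with zero rows of statistics) when
#'   no cycle had an assigned patient.
#' @export
cost_summary <- function(log, per_factor = TRUE) {
  stopifnot(inherits(log, "ward_sim_log"))
  cy <- log$cycles[log$cycles$assigned_count > 0, ]
  if (!nrow(cy)) {
    return(tibble(factor = character(), mean = numeric(), median = numeric(),
                  sd = numeric(), q1 = numeric(), q3 = numeric(),
                  min = numeric(), max = numeric(), n = integer(),
                  share = numeric(), empty = logical()))
  }
  factors <- if (per_factor) c("alpha", "beta", "gamma", "delta", "total")
  else "total"
  grand_total <- sum(cy$total_sum)
  out <- purrr::map(factors, function(f) {
    per_patient <- cy[[paste0(f, "_sum")]] / cy$assigned_count
    s <- summary_stats(per_patient)
    s$factor <- f
    s$share <- if (f == "total") 1 else sum(cy[[paste0(f, "_sum")]]) /
      grand_total
    s
  })
  out <- bind_rows(out)
  out$empty <- FALSE
  out[c("factor", setdiff(names(out), "factor"))]
}

#' Compare strategies across paired simulation logs
#'
#' One row per strategy with dismissal, runtime and cost summaries, plus the
#' difference of each strategy's mean dismissal ratio from the first
#' (baseline) log in percentage points.
#'
#' @param logs A `ward_sweep` or named list of `ward_sim_log` objects
#'   (at least two).
#' @return A tibble with one row per strategy.
#' @export
compare_strategies <- function(logs) {
  if (inherits(logs, "ward_sweep")) logs <- unclass(logs)
  if (length(logs) < 2L) abort("need at least two logs to compare")
  seeds <- vapply(logs, function(l) l$config$seed, integer(1))
  if (length(unique(seeds)) > 1L) {
    warn("logs were produced with different master seeds; comparison is unpaired")
  }
  rows <- purrr::imap(logs, function(l, nm) {
    d <- dismissal_summary(l)
    cs <- cost_summary(l, per_factor = FALSE)
    tibble(
      strategy = nm,
      cycles = nrow(l$cycles),
      patients = l$total_patients,
      mean_dismissal = d$mean,
      median_dismissal = d$median,
      sd_dismissal = d$sd,
      mean_dismissal_adjusted = d$mean_adjusted,
      mean_cost = if (nrow(cs)) cs$mean else NA_real_,
      mean_seconds = mean(l$cycles$compute_seconds)
    )
  })
  out <- bind_rows(rows)
  out$diff_vs_baseline_pp <- (out$mean_dismissal[1] - out$mean_dismissal) *
    100
  out
}

#' Render a comparison table as Markdown
#'
#' @param tab A data frame, e.g. from [compare_strategies()].
#' @param digits Significant digits for numeric columns.
#' @return A character vector of Markdown lines (one per table row).
#' @export
as_markdown_table <- function(tab, digits = 4) {
  cells <- lapply(tab, function(col) {
    if (is.numeric(col)) format(signif(col, digits)) else as.character(col)
  })
  m <- rbind(names(tab), rep("---", ncol(tab)),
             do.call(cbind, cells))
  apply(m, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
}
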
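# build a synthetic simulation log directly from a cycle table
fake_log <- function(cycles, strategy = "RAND", seed = 1L) {
  cfg <- list(strategy = list(name = strategy), seed = seed)
  structure(list(config = cfg, cycles = cycles,
                 total_patients = sum(cycles$collective_size)),
            class = "ward_sim_log")
}

fake_cycles <- function(ratios, sizes = 10L, status = "ok",
                        alpha = 0, beta = 0, gamma = 0, delta = 0) {
  n <- length(ratios)
  sizes <- rep_len(sizes, n)
  dismissed <- as.integer(round(ratios * sizes))
  assigned <- sizes - dismissed
  tibble::tibble(
    cycle_index = seq_len(n), day = seq_len(n), collective_size = sizes,
    dismissed_count = dismissed, dismissal_ratio = dismissed / sizes,
    assigned_count = assigned,
    alpha_sum = rep_len(alpha, n) * assigned,
    beta_sum = rep_len(beta, n) * assigned,
    gamma_sum = rep_len(gamma, n) * assigned,
    delta_sum = rep_len(delta, n) * assigned,
    total_sum = (rep_len(alpha, n) + rep_len(beta, n) + rep_len(gamma, n) +
                   rep_len(delta, n)) * assigned,
    solver_status = rep_len(status, n), compute_seconds = 0.01,
    expected_occupied_before = 0, expected_occupied_after = 0,
    realized_occupied = 0L, overflow_beds = 0L
  )
}

test_that("dismissal summaries report the standard descriptive statistics", {
  log <- fake_log(fake_cycles(c(0, 0.5, 1), sizes = 10L))
  s <- dismissal_summary(log)
  expect_equal(s$mean, 0.5)
  expect_equal(s$median, 0.5)
  expect_equal(s$q1, 0.25)
  expect_equal(s$q3, 0.75)
  expect_equal(s$min, 0)
  expect_equal(s$max, 1)
  expect_equal(s$n, 3L)
  expect_true(s$q1 <= s$median && s$median <= s$q3)
  # all-zero ratios give all-zero statistics
  s0 <- dismissal_summary(fake_log(fake_cycles(rep(0, 5))))
  expect_true(all(unlist(s0[c("mean", "median", "sd", "q1", "q3", "min",
                              "max")]) == 0))
  # quartiles agree with linear interpolation between order statistics
  x <- withr::with_seed(4, runif(37))
  sr <- dismissal_summary(fake_log(fake_cycles(x, sizes = 1000L)))
  ratios <- round(x * 1000) / 1000
  ref <- function(v, p) {
    v <- sort(v)
    hpos <- (length(v) - 1) * p + 1
    lo <- floor(hpos)
    v[lo] + (hpos - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  expect_equal(sr$q1, ref(ratios, 0.25), tolerance = 1e-12)
  expect_equal(sr$median, ref(ratios, 0.5), tolerance = 1e-12)
  expect_equal(sr$q3, ref(ratios, 0.75), tolerance = 1e-12)
})

test_that("summaries are invariant under cycle order and refinable by size", {
  x <- withr::with_seed(9, runif(40))
  sizes <- withr::with_seed(10, sample(c(5L, 15L, 25L), 40, replace = TRUE))
  cy <- fake_cycles(x, sizes = sizes)
  log <- fake_log(cy)
  perm <- withr::with_seed(11, sample(40))
  log_perm <- fake_log(cy[perm, ])
  expect_equal(dismissal_summary(log)[c("mean", "median", "sd", "q1", "q3")],
               dismissal_summary(log_perm)[c("mean", "median", "sd", "q1",
                                             "q3")])
  by_size <- dismissal_summary(log, by = "collective_size")
  expect_equal(as.character(unique(by_size$size_bin)),
               c("1-10", "11-20", "21-30"))
  expect_equal(sum(by_size$n), 40L)
})

test_that("the adjusted mean strips timeout cycles only", {
  cy <- fake_cycles(c(0.2, 1, 0.4), status = c("optimal", "timeout",
                                               "optimal"))
  s <- dismissal_summary(fake_log(cy, strategy = "EXACT"))
  expect_equal(s$mean, mean(c(0.2, 1, 0.4)))
  expect_equal(s$mean_adjusted, mean(c(0.2, 0.4)))
  expect_equal(s$timeout_cycles, 1L)
  expect_lte(s$mean_adjusted, s$mean)
})

test_that("cost summaries exclude dismissals and normalise shares", {
  # one assigned patient per cycle with breakdown (0, 2, 0, 0.5)
  log <- fake_log(fake_cycles(rep(0, 4), sizes = 1L, beta = 2, delta = 0.5))
  cs <- cost_summary(log)
  expect_equal(cs$share[cs$factor == "beta"], 0.8)
  expect_equal(cs$share[cs$factor == "delta"], 0.2)
  expect_equal(sum(cs$share[cs$factor != "total"]), 1, tolerance = 1e-12)
  expect_equal(cs$mean[cs$factor == "total"], 2.5)
  # cycles that assigned nobody contribute nothing
  log2 <- fake_log(fake_cycles(c(0, 1), sizes = 2L, beta = 1))
  cs2 <- cost_summary(log2)
  expect_equal(cs2$n[cs2$factor == "total"], 1L)
  # an all-dismissal log yields an explicitly empty summary
  log3 <- fake_log(fake_cycles(rep(1, 3)))
  cs3 <- cost_summary(log3)
  expect_equal(nrow(cs3), 0L)
})

test_that("strategy comparisons are tabulated against the baseline", {
  a <- fake_log(fake_cycles(rep(0.5, 6)), strategy = "STATQUO")
  b <- fake_log(fake_cycles(rep(0, 6), beta = 1), strategy = "RAND")
  tab <- compare_strategies(list(STATQUO = a, RAND = b))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$diff_vs_baseline_pp, c(0, 50))
  tab2 <- compare_strategies(list(A = a, B = a))
  expect_equal(tab2$diff_vs_baseline_pp, c(0, 0))
  expect_error(compare_strategies(list(A = a)), "at least two")
})

test_that("tidiers expose logs as flat tibbles", {
  log <- fake_log(fake_cycles(c(0.1, 0.2)))
  td <- tidy(log)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$strategy, c("RAND", "RAND"))
  g <- glance(log)
  expect_equal(g$mean_dismissal, 0.15)
  expect_equal(g$cycles, 2L)
})

test_that("markdown rendering keeps one line per table row", {
  a <- fake_log(fake_cycles(rep(0.5, 3)), strategy = "STATQUO")
  b <- fake_log(fake_cycles(rep(0.1, 3)), strategy = "RAND")
  md <- as_markdown_table(compare_strategies(list(STATQUO = a, RAND = b)))
  expect_length(md, 4L) # header + separator + 2 strategies
  expect_true(all(startsWith(md, "| ")))
})
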
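test_that("moment matching round-trips natural-scale moments", {
  for (m in c(0.5, 1, 5, 20)) {
    for (s in c(0.1, 1, 4)) {
      d <- los_estimate(m, s)
      mean_back <- exp(d$meanlog + d$sdlog^2 / 2)
      var_back <- (exp(d$sdlog^2) - 1) * exp(2 * d$meanlog + d$sdlog^2)
      expect_equal(mean_back, m, tolerance = 1e-9)
      expect_equal(var_back, s^2, tolerance = 1e-9)
    }
  }
  expect_error(los_estimate(0, 1), "> 0")
  expect_error(los_estimate(5, -1), "> 0")
})

test_that("elicited mean and sd are recovered by Monte Carlo", {
  d <- los_estimate(5, 2)
  x <- withr::with_seed(99, rlnorm(1e6, d$meanlog, d$sdlog))
  expect_equal(mean(x), 5, tolerance = 0.01)
  expect_equal(sd(x), 2, tolerance = 0.01)
})

test_that("survival is a proper non-increasing curve", {
  d <- los_estimate(5, 2)
  expect_equal(los_survival(d, 0), 1)
  med <- exp(d$meanlog)
  expect_equal(los_survival(d, med), 0.5, tolerance = 1e-9)
  # agrees with the closed-form normal-cdf expression
  for (t in c(0.5, 1, 3, 7, 20)) {
    expect_equal(los_survival(d, t),
                 1 - pnorm((log(t) - d$meanlog) / d$sdlog),
                 tolerance = 1e-12)
  }
  expect_error(los_survival(d, -1), "non-negative")
  # property over random distributions: bounds and monotonicity
  withr::with_seed(11, {
    for (i in 1:20) {
      di <- los_estimate(runif(1, 0.5, 30), runif(1, 0.1, 10))
      p <- los_survival(di, 0:60)
      expect_true(all(p >= 0 & p <= 1))
      expect_true(all(diff(p) <= 1e-12))
    }
  })
})

test_that("a near-zero uncertainty degenerates to a step at the mean", {
  d <- los_estimate(1, 1e-9) # capped at the 1e-3 floor
  expect_gt(los_survival(d, 0.99), 0.999)
  expect_lt(los_survival(d, 1.01), 0.001)
})

test_that("expected usage is the sum of survival probabilities", {
  h <- tiny_hospital(n_wards = 1L, single = 16L)
  led <- new_ledger(h)
  expect_equal(expected_usage(led, 1L, "single", 0:5), rep(0, 6))
  # two occupants that are certainly present -> 2.0
  lp <- wardopt:::los_params(c(50, 50), c(0.01, 0.01))
  led2 <- add_stays(led, tibble::tibble(
    patient_id = c("a", "b"), ward_id = 1L, preference = "single",
    admission_day = 0L, mean_days = 50, variance_days2 = 1e-4,
    meanlog = lp$meanlog, sdlog = lp$sdlog, realized_los = 50L
  ))
  expect_equal(expected_usage(led2, 1L, "single", 3), 2)
  # stays admitted in the future contribute nothing before admission
  expect_equal(expected_usage(led2, 1L, "single", -1), 0)
  expect_error(expected_usage(led2, 99L, "single", 0), "unknown ward")
})

test_that("expected usage equals the Poisson-binomial mean exactly", {
  h <- tiny_hospital(n_wards = 1L, single = 40L)
  led <- new_ledger(h)
  stays <- tiny_patients(20, h, seed = 5)
  led <- add_stays(led, tibble::tibble(
    patient_id = stays$patient_id, ward_id = 1L, preference = "single",
    admission_day = rep(0:3, 5), mean_days = stays$mean_days,
    variance_days2 = stays$variance_days2, meanlog = stays$meanlog,
    sdlog = stays$sdlog, realized_los = stays$realized_los
  ))
  for (day in c(1, 3, 6)) {
    p <- wardopt:::surv_vec(day - led$stays$admission_day,
                            led$stays$meanlog, led$stays$sdlog)
    expect_equal(expected_usage(led, 1L, "single", day), sum(p),
                 tolerance = 1e-12)
  }
})

test_that("expected usage matches a Monte-Carlo occupancy simulation", {
  h <- tiny_hospital(n_wards = 1L, single = 40L)
  stays <- tiny_patients(20, h, seed = 8)
  adm <- rep(0:4, 4)
  led <- add_stays(new_ledger(h), tibble::tibble(
    patient_id = stays$patient_id, ward_id = 1L, preference = "single",
    admission_day = adm, mean_days = stays$mean_days,
    variance_days2 = stays$variance_days2, meanlog = stays$meanlog,
    sdlog = stays$sdlog, realized_los = stays$realized_los
  ))
  day <- 4
  n_rep <- 1e5
  occ <- withr::with_seed(21, {
    # each replicate draws one continuous LoS per stay; the stay occupies
    # day `day` iff admission <= day and LoS >= day - admission
    draws <- matrix(rlnorm(20 * n_rep, stays$meanlog, stays$sdlog),
                    nrow = 20)
    colSums(draws >= (day - adm))
  })
  mc_mean <- mean(occ)
  mc_se <- sd(occ) / sqrt(n_rep)
  expect_lt(abs(expected_usage(led, 1L, "single", day) - mc_mean),
            3 * mc_se + 1e-9)
})

test_that("usage rate and free capacity are consistent with capacity", {
  h <- tiny_hospital(n_wards = 1L, single = 16L, double_male = 0L)
  led <- new_ledger(h)
  expect_equal(usage_rate(led, 1L, "single", 0), 0)
  expect_equal(free_capacity(led, 1L, "single", 0), 16)
  expect_error(usage_rate(led, 1L, "double_male", 0), "no beds")
  lp <- wardopt:::los_params(30, 0.01)
  led <- add_stays(led, tibble::tibble(
    patient_id = sprintf("x%d", 1:8), ward_id = 1L, preference = "single",
    admission_day = 0L, mean_days = 30, variance_days2 = 1e-4,
    meanlog = lp$meanlog, sdlog = lp$sdlog, realized_los = 30L
  ))
  expect_equal(usage_rate(led, 1L, "single", 2), 0.5)
  expect_equal(free_capacity(led, 1L, "single", 2) +
                 expected_usage(led, 1L, "single", 2), 16)
  # adding one more stay never decreases the usage rate anywhere
  before <- usage_rate(led, 1L, "single", 0:20)
  led2 <- add_stays(led, tibble::tibble(
    patient_id = "y1", ward_id = 1L, preference = "single",
    admission_day = 4L, mean_days = 3, variance_days2 = 1,
    meanlog = wardopt:::los_params(3, 1)$meanlog,
    sdlog = wardopt:::los_params(3, 1)$sdlog, realized_los = 3L
  ))
  expect_true(all(usage_rate(led2, 1L, "single", 0:20) >= before - 1e-12))
  # removing it restores the original curve exactly
  led3 <- remove_stay(led2, "y1")
  expect_equal(usage_rate(led3, 1L, "single", 0:20), before)
})

test_that("normal approximation tracks the exact Poisson-binomial pmf", {
  # stays engineered so the survival probabilities at the evaluation day are
  # uniform random draws: survival(day) = 1 - Phi((log(day) - mu)/s) = p
  # when mu = log(day) - s * qnorm(1 - p)
  make_led <- function(p_target, day = 3) {
    h <- tiny_hospital(n_wards = 1L, single = 60L)
    sdlog <- 0.8
    meanlog <- log(day) - sdlog * qnorm(1 - p_target)
    add_stays(new_ledger(h), tibble::tibble(
      patient_id = sprintf("u%03d", seq_along(p_target)), ward_id = 1L,
      preference = "single", admission_day = 0L,
      mean_days = exp(meanlog + sdlog^2 / 2),
      variance_days2 = (exp(sdlog^2) - 1) * exp(2 * meanlog + sdlog^2),
      meanlog = meanlog, sdlog = sdlog,
      realized_los = pmax(1L, as.integer(ceiling(exp(meanlog))))
    ))
  }
  tv_for <- function(n, seed, day = 3) {
    p_target <- withr::with_seed(seed, runif(n, 0.02, 0.98))
    led <- make_led(p_target, day)
    ap <- occupancy_normal_approx(led, 1L, "single", day)
    p <- wardopt:::surv_vec(day - led$stays$admission_day,
                            led$stays$meanlog, led$stays$sdlog)
    expect_equal(p, p_target, tolerance = 1e-9)
    expect_equal(ap$mean, expected_usage(led, 1L, "single", day))
    expect_equal(ap$variance, sum(p * (1 - p)), tolerance = 1e-12)
    tv_dist(ap$pmf$prob, poisbin_pmf(p))
  }
  tv30 <- tv_for(30, seed = 31)
  expect_lt(tv30, 0.05)
  # the approximation improves with the number of stays
  tv5 <- tv_for(5, seed = 13)
  tv50 <- tv_for(50, seed = 13)
  expect_lt(tv50, tv5)
  # degenerate cases
  h <- tiny_hospital(n_wards = 1L, single = 3L)
  empty <- occupancy_normal_approx(new_ledger(h), 1L, "single", 0)
  expect_equal(empty$pmf$prob, c(1, 0, 0, 0))
  lp <- wardopt:::los_params(40, 0.001)
  led1 <- add_stays(new_ledger(h), tibble::tibble(
    patient_id = c("a", "b"), ward_id = 1L, preference = "single",
    admission_day = 0L, mean_days = 40, variance_days2 = 1e-6,
    meanlog = lp$meanlog, sdlog = lp$sdlog, realized_los = 40L
  ))
  sure <- occupancy_normal_approx(led1, 1L, "single", 1)
  expect_equal(sure$variance, 0, tolerance = 1e-9)
  expect_equal(sure$pmf$prob[sure$pmf$k == 2], 1, tolerance = 1e-9)
})

test_that("LoS revision updates one stay and is invertible", {
  h <- tiny_hospital(n_wards = 1L, single = 10L)
  s <- tiny_patients(4, h, seed = 3)
  led <- add_stays(new_ledger(h), tibble::tibble(
    patient_id = s$patient_id, ward_id = 1L, preference = "single",
    admission_day = 0:3, mean_days = s$mean_days,
    variance_days2 = s$variance_days2, meanlog = s$meanlog,
    sdlog = s$sdlog, realized_los = s$realized_los
  ))
  base <- expected_usage(led, 1L, "single", 0:15)
  orig <- los_estimate(s$mean_days[2], s$sd_days[2])
  # revising to the identical law changes nothing
  expect_equal(expected_usage(revise_los(led, s$patient_id[2], orig),
                              1L, "single", 0:15), base)
  # revising the mean upward never decreases usage from admission onwards
  up <- revise_los(led, s$patient_id[2],
                   los_estimate(s$mean_days[2] * 2, s$sd_days[2]))
  expect_true(all(expected_usage(up, 1L, "single", 1:15) >= base[-1] - 1e-12))
  # revise then revert restores the original curve
  back <- revise_los(up, s$patient_id[2], orig)
  expect_equal(expected_usage(back, 1L, "single", 0:15), base)
  expect_error(revise_los(led, "nobody", orig), "not in ledger")
})

test_that("ledger snapshots round-trip through CSV", {
  h <- tiny_hospital(n_wards = 2L)
  s <- tiny_patients(5, h, seed = 17)
  led <- add_stays(new_ledger(h), tibble::tibble(
    patient_id = s$patient_id, ward_id = c(1L, 1L, 2L, 2L, 1L),
    preference = s$preference, admission_day = 0:4,
    mean_days = s$mean_days, variance_days2 = s$variance_days2,
    meanlog = s$meanlog, sdlog = s$sdlog, realized_los = s$realized_los
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger(led, path)
  led2 <- read_ledger(path, h)
  expect_equal(led2$stays, led$stays, tolerance = 1e-12)
})
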
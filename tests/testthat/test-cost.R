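test_that("affinity cost respects the chosen direction", {
  w <- cost_weights()
  expect_equal(alpha_cost(1, w, "inverted"), 0)
  expect_equal(alpha_cost(1, w, "literal"), 1)
  expect_equal(alpha_cost(0.5, w, "inverted"), 0.5)
  expect_equal(alpha_cost(0.5, cost_weights(alpha = 2), "inverted"), 1)
  expect_error(alpha_cost(0, w), "infeasible")
  expect_error(cost_weights(alpha = -1), ">= 0")
})

test_that("delay cost follows the priority-discounted formula", {
  w <- cost_weights()
  expect_equal(delta_cost(0, 1, w), 0.5)
  expect_equal(delta_cost(3, 1, w), 0.125)
  expect_equal(delta_cost(2, 3, w), (1 / 3) * (1 - 1 / 4))
  # strictly increasing in t, decreasing in priority
  expect_true(all(diff(delta_cost(3, 1:40, w)) > 0))
  expect_true(all(diff(vapply(0:3, delta_cost, numeric(1), t = 5,
                              weights = w)) < 0))
  # limit for large delays
  expect_equal(delta_cost(1, 1e9, w), 0.5, tolerance = 1e-6)
  expect_error(delta_cost(4, 1, w), "priority")
  expect_error(delta_cost(2, 0, w), ">= 1")
})

with_occupied_ward <- function() {
  h <- tiny_hospital(n_wards = 1L, single = 2L)
  lp <- wardopt:::los_params(50, 0.01)
  led <- add_stays(new_ledger(h), tibble::tibble(
    patient_id = "occ", ward_id = 1L, preference = "single",
    admission_day = 0L, mean_days = 50, variance_days2 = 1e-4,
    meanlog = lp$meanlog, sdlog = lp$sdlog, realized_los = 50L
  ))
  list(h = h, led = led)
}

test_that("occupancy cost sums the usage rate over the stay window", {
  f <- with_occupied_ward() # c = 0.5 on every day of the horizon
  expect_equal(beta_cost(f$led, 1L, "single", t = 1, expected_los = 1), 0.5)
  expect_equal(beta_cost(f$led, 1L, "single", t = 3, expected_los = 4), 2)
  # empty ward costs nothing
  h2 <- tiny_hospital(n_wards = 1L)
  expect_equal(beta_cost(new_ledger(h2), 1L, "single", 1, 5), 0)
  # matches direct summation on a random ledger
  h <- tiny_hospital(n_wards = 2L, single = 4L)
  s <- tiny_patients(6, h, seed = 23)
  led <- add_stays(new_ledger(h), tibble::tibble(
    patient_id = s$patient_id, ward_id = rep(1:2, 3),
    preference = "single", admission_day = c(0L, 0L, 1L, 2L, 3L, 5L),
    mean_days = s$mean_days, variance_days2 = s$variance_days2,
    meanlog = s$meanlog, sdlog = s$sdlog, realized_los = s$realized_los
  ))
  for (t in c(1, 2, 5)) {
    len <- 4
    direct <- sum(usage_rate(led, 1L, "single", (t - 1) + 0:(len - 1)))
    expect_equal(beta_cost(led, 1L, "single", t, expected_los = len),
                 direct, tolerance = 1e-12)
    dg <- sum(abs(diff(usage_rate(led, 1L, "single", (t - 1) + 0:len))))
    expect_equal(gamma_cost(led, 1L, "single", t, expected_los = len),
                 dg, tolerance = 1e-12)
  }
})

test_that("occupancy-change cost vanishes on a flat profile", {
  f <- with_occupied_ward() # constant c = 0.5 over the stay window
  expect_equal(gamma_cost(f$led, 1L, "single", t = 2, expected_los = 5), 0,
               tolerance = 1e-9)
})

test_that("assignment cost composes the four factors", {
  h <- tiny_hospital(n_wards = 1L, aff = data.frame(clinic_id = 1:2,
                                                    ward_id = 1L,
                                                    affinity = c(1, 0.5)))
  led <- new_ledger(h)
  p <- list(clinic_id = 1L, preference = "single", priority = 3L,
            mean_days = 4)
  cb <- assignment_cost(p, 1L, 1, led)
  # empty hospital, affinity 1: only the delay factor remains
  expect_equal(cb$total, 0.125)
  expect_equal(cb$alpha + cb$beta + cb$gamma + cb$delta, cb$total)
  # dummy candidates carry the dismissal penalty with zero partials
  dummy <- h$wards$id[h$wards$is_dummy]
  cbd <- assignment_cost(p, dummy, 1, led, penalty = 123)
  expect_equal(cbd$total, 123)
  expect_equal(cbd$alpha + cbd$beta + cbd$gamma + cbd$delta, 0)
  # infeasible candidates are signalled, not costed
  p2 <- list(clinic_id = 2L, preference = "single", priority = 1L,
             mean_days = 2)
  h0 <- tiny_hospital(n_wards = 1L,
                      aff = data.frame(clinic_id = 1L, ward_id = 1L,
                                       affinity = 1))
  expect_error(assignment_cost(p2, 1L, 1, new_ledger(h0)), "affinity 0")
  # compositional check on an occupied ledger
  f <- with_occupied_ward()
  p3 <- list(clinic_id = 1L, preference = "single", priority = 2L,
             mean_days = 3.2)
  cb3 <- assignment_cost(p3, 1L, 2, f$led)
  expect_equal(cb3$alpha, alpha_cost(1, cost_weights()))
  expect_equal(cb3$beta, beta_cost(f$led, 1L, "single", 2, 3.2))
  expect_equal(cb3$gamma, gamma_cost(f$led, 1L, "single", 2, 3.2))
  expect_equal(cb3$delta, delta_cost(2, 2))
  expect_equal(cb3$total, sum(cb3$alpha, cb3$beta, cb3$gamma, cb3$delta))
})

test_that("the vectorised cost curve agrees with the single-candidate path", {
  checked <- 0L
  for (seed in c(404, 505, 909)) {
    inst <- random_instance(seed)
    h <- inst$hospital
    led <- inst$ledger
    k <- inst$query$timeframe_days
    nd <- h$wards[!h$wards$is_dummy, ]
    eu <- wardopt:::usage_matrix(led, led$current_day +
                                   0:(k + inst$query$l_max + 1))
    caps <- wardopt:::capacity_vector(h)
    for (pi in seq_len(nrow(inst$query$patients))) {
      p <- inst$query$patients[pi, ]
      for (w in nd$id) {
        if (nd[[p$preference]][match(w, nd$id)] == 0) next
        aff <- affinity(h, p$clinic_id, w)
        if (aff == 0) next
        key <- wardopt:::key_wb(w, p$preference)
        cc <- wardopt:::candidate_cost_curve(eu[key, ] / caps[key], k,
                                             p$mean_days, p$priority, aff,
                                             cost_weights())
        for (t in seq_len(k)) {
          slow <- assignment_cost(p, w, t, led)
          expect_equal(unname(cc["total", t]), slow$total,
                       tolerance = 1e-10)
          expect_equal(unname(cc["beta", t]), slow$beta, tolerance = 1e-10)
          expect_equal(unname(cc["gamma", t]), slow$gamma,
                       tolerance = 1e-10)
          checked <- checked + 1L
        }
      }
    }
  }
  expect_gt(checked, 10L)
})

test_that("raising existing occupancy never lowers the occupancy cost", {
  h <- tiny_hospital(n_wards = 1L, single = 6L)
  s <- tiny_patients(4, h, seed = 31)
  led <- add_stays(new_ledger(h), tibble::tibble(
    patient_id = s$patient_id, ward_id = 1L, preference = "single",
    admission_day = 0:3, mean_days = s$mean_days,
    variance_days2 = s$variance_days2, meanlog = s$meanlog,
    sdlog = s$sdlog, realized_los = s$realized_los
  ))
  led_hot <- led
  for (i in seq_len(4)) {
    led_hot <- revise_los(led_hot, s$patient_id[i],
                          los_estimate(s$mean_days[i] * 3, s$sd_days[i]))
  }
  for (t in c(1, 2, 4)) {
    expect_gte(beta_cost(led_hot, 1L, "single", t, 5),
               beta_cost(led, 1L, "single", t, 5) - 1e-12)
  }
})

test_that("STATQUO weights drop the change and delay factors exactly", {
  s <- strategy_config("STATQUO", seed = 1)
  expect_equal(s$weights$gamma, 0)
  expect_equal(s$weights$delta, 0)
  expect_equal(s$weights$alpha, 1)
  expect_equal(s$weights$beta, 1)
  f <- with_occupied_ward()
  p <- list(clinic_id = 1L, preference = "single", priority = 3L,
            mean_days = 4)
  cb <- assignment_cost(p, 1L, 2, f$led, weights = s$weights)
  ref <- assignment_cost(p, 1L, 2, f$led)
  expect_equal(cb$total, ref$alpha + ref$beta)
})
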
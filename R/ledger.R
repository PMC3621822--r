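# Occupancy ledger: the set of admitted stays per (ward, preference class),
# carrying each occupant's survival curve and realized discharge day.
# Expected usage of a contingent is the Poisson-binomial mean: the sum of the
# occupants' survival probabilities at the day in question.

#' Create an empty occupancy ledger
#'
#' @param hospital A `ward_hospital` the stays must refer to.
#' @param horizon Number of days tracked ahead of `current_day`.
#' @param current_day Integer index of "today" (day 0 of planning queries).
#' @return An object of class `ward_ledger`.
#' @export
new_ledger <- function(hospital, horizon = 160L, current_day = 0L) {
  stopifnot(inherits(hospital, "ward_hospital"), is_count(horizon))
  structure(
    list(
      stays = empty_stays(),
      hospital = hospital,
      horizon = as.integer(horizon),
      current_day = as.integer(current_day)
    ),
    class = "ward_ledger"
  )
}

empty_stays <- function() {
  tibble(
    patient_id = character(), ward_id = integer(), preference = character(),
    admission_day = integer(), mean_days = numeric(),
    variance_days2 = numeric(), meanlog = numeric(), sdlog = numeric(),
    realized_los = integer()
  )
}

#' @export
print.ward_ledger <- function(x, ...) {
  cat(sprintf(
    "<ward_ledger> day %d, %d active stays, horizon %d d\n",
    x$current_day, nrow(x$stays), x$horizon
  ))
  invisible(x)
}

#' Add stays to a ledger
#'
#' @param ledger A `ward_ledger`.
#' @param stays Tibble with the columns of the ledger's stay table
#'   (`patient_id`, `ward_id`, `preference`, `admission_day`, `mean_days`,
#'   `variance_days2`, `meanlog`, `sdlog`, `realized_los`).
#' @return The updated ledger.
#' @export
add_stays <- function(ledger, stays) {
  stopifnot(inherits(ledger, "ward_ledger"))
  stays <- as_tibble(stays)[names(empty_stays())]
  if (any(!stays$ward_id %in% ledger$hospital$wards$id)) {
    abort("stay refers to unknown ward id")
  }
  if (any(!stays$preference %in% pref_labels())) {
    abort("stay refers to unknown preference class")
  }
  if (any(stays$admission_day < 0) || any(stays$realized_los < 1)) {
    abort("stays need admission_day >= 0 and realized_los >= 1")
  }
  if (any(stays$patient_id %in% ledger$stays$patient_id)) {
    abort("duplicate patient_id in ledger")
  }
  ledger$stays <- bind_rows(ledger$stays, stays)
  ledger
}

#' Remove a stay from the ledger
#' @param ledger A `ward_ledger`.
#' @param patient_id Id of the stay to drop.
#' @export
remove_stay <- function(ledger, patient_id) {
  stopifnot(inherits(ledger, "ward_ledger"))
  keep <- ledger$stays$patient_id != patient_id
  if (all(keep)) abort(sprintf("patient '%s' not in ledger", patient_id))
  ledger$stays <- ledger$stays[keep, ]
  ledger
}

#' Revise the length-of-stay estimate of an admitted patient
#'
#' Replaces the survival curve used in all subsequent expected-usage
#' calculations; every other stay is untouched.
#'
#' @param ledger A `ward_ledger`.
#' @param patient_id Id of the stay to update.
#' @param new_dist A [los_estimate()] object.
#' @export
revise_los <- function(ledger, patient_id, new_dist) {
  stopifnot(inherits(ledger, "ward_ledger"), inherits(new_dist, "los_dist"))
  i <- which(ledger$stays$patient_id == patient_id)
  if (!length(i)) abort(sprintf("patient '%s' not in ledger", patient_id))
  ledger$stays$mean_days[i] <- new_dist$mean_days
  ledger$stays$variance_days2[i] <- new_dist$variance_days2
  ledger$stays$meanlog[i] <- new_dist$meanlog
  ledger$stays$sdlog[i] <- new_dist$sdlog
  ledger
}

stays_for <- function(ledger, ward_id, preference) {
  s <- ledger$stays
  s[s$ward_id == ward_id & s$preference == preference, ]
}

#' Expected number of used beds
#'
#' Expected occupancy of the contingent (`ward_id`, `preference`) at day
#' `day`: the sum over its stays of the survival probability at offset
#' `day - admission_day` (stays admitted after `day` contribute 0).
#'
#' @param ledger A `ward_ledger`.
#' @param ward_id Ward id.
#' @param preference Preference class label.
#' @param day Absolute day index (vectorised).
#' @return Non-negative expected bed counts.
#' @export
expected_usage <- function(ledger, ward_id, preference, day) {
  stopifnot(inherits(ledger, "ward_ledger"))
  if (!ward_id %in% ledger$hospital$wards$id) abort("unknown ward id")
  if (!preference %in% pref_labels()) abort("unknown preference class")
  s <- stays_for(ledger, ward_id, preference)
  if (!nrow(s)) return(rep(0, length(day)))
  vapply(day, function(d) {
    sum(surv_vec(d - s$admission_day, s$meanlog, s$sdlog))
  }, numeric(1))
}

#' Expected usage rate of a contingent
#'
#' `expected_usage / K_jb`; the cost coefficient attached to admitting a
#' patient with preference `preference` to `ward_id` at `day`. May exceed 1
#' when the contingent is expected to be overbooked.
#'
#' @inheritParams expected_usage
#' @export
usage_rate <- function(ledger, ward_id, preference, day) {
  k <- contingent_capacity(ledger$hospital, ward_id, preference)
  if (k == 0) {
    abort("usage rate undefined: ward has no beds of this preference class")
  }
  expected_usage(ledger, ward_id, preference, day) / k
}

#' Expected free capacity of a contingent
#'
#' `K_jb - expected_usage`; may be negative when the contingent is expected
#' to be overbooked.
#'
#' @inheritParams expected_usage
#' @export
free_capacity <- function(ledger, ward_id, preference, day) {
  k <- contingent_capacity(ledger$hospital, ward_id, preference)
  if (k == 0) {
    abort("free capacity undefined: ward has no beds of this preference class")
  }
  k - expected_usage(ledger, ward_id, preference, day)
}

contingent_capacity <- function(hospital, ward_id, preference) {
  i <- match(ward_id, hospital$wards$id)
  if (is.na(i)) abort("unknown ward id")
  hospital$wards[[preference]][i]
}

#' Normal approximation of the occupancy distribution
#'
#' The occupancy count of a contingent is a sum of independent Bernoulli
#' variables with success probabilities \eqn{p_{it}} (a Poisson-binomial
#' variable). Its mean \eqn{\sum p_{it}} and variance
#' \eqn{\sum p_{it}(1-p_{it})} are exact; the probability mass function is
#' approximated by a continuity-corrected normal, renormalised over
#' \eqn{k = 0, \dots, K_{jb}}.
#'
#' @inheritParams expected_usage
#' @return A list with `mean`, `variance` and `pmf` (a tibble with columns
#'   `k`, `prob`). An empty contingent yields a point mass at 0.
#' @export
occupancy_normal_approx <- function(ledger, ward_id, preference, day) {
  stopifnot(length(day) == 1L)
  s <- stays_for(ledger, ward_id, preference)
  kmax <- contingent_capacity(ledger$hospital, ward_id, preference)
  if (!nrow(s)) {
    return(list(mean = 0, variance = 0,
                pmf = tibble(k = 0:kmax, prob = c(1, rep(0, kmax)))))
  }
  p <- surv_vec(day - s$admission_day, s$meanlog, s$sdlog)
  mu <- sum(p)
  v <- sum(p * (1 - p))
  ks <- 0:kmax
  if (v < 1e-12) {
    prob <- as.numeric(ks == round(mu))
    if (!any(prob > 0)) prob <- as.numeric(ks == kmax)
  } else {
    prob <- pnorm(ks + 0.5, mu, sqrt(v)) - pnorm(ks - 0.5, mu, sqrt(v))
  }
  prob <- prob / sum(prob)
  list(mean = mu, variance = v, pmf = tibble(k = ks, prob = prob))
}

# Expected-usage matrix over all (ward, preference) contingents and a vector
# of absolute days; rows keyed by key_wb(). Fast path used by the cost model,
# the BIP builder and the simulation.
usage_matrix <- function(ledger, days) {
  h <- ledger$hospital
  keys <- as.vector(outer(h$wards$id, pref_labels(), key_wb))
  eu <- matrix(0, nrow = length(keys), ncol = length(days),
               dimnames = list(keys, NULL))
  s <- ledger$stays
  if (nrow(s)) {
    off <- outer(s$admission_day, days, function(a, d) d - a)
    p <- matrix(plnorm(pmax(off, 0), meanlog = s$meanlog, sdlog = s$sdlog,
                       lower.tail = FALSE),
                nrow = nrow(s))
    p[off < 0] <- 0
    grp <- key_wb(s$ward_id, s$preference)
    agg <- rowsum(p, group = grp, reorder = FALSE)
    eu[rownames(agg), ] <- agg
  }
  eu
}

#' Advance simulated time
#'
#' Shifts the ledger's current day forward and removes the stays whose
#' realized occupancy interval has ended (`admission_day + realized_los <=`
#' new current day). A patient admitted on day `d` with realized stay `L`
#' occupies days `d` to `d + L - 1`.
#'
#' @param ledger A `ward_ledger`.
#' @param days Positive integer number of days to advance.
#' @export
advance_time <- function(ledger, days) {
  stopifnot(inherits(ledger, "ward_ledger"))
  if (!is_count(days, min = 1L)) abort("`days` must be a positive integer")
  ledger$current_day <- ledger$current_day + as.integer(days)
  keep <- ledger$stays$admission_day + ledger$stays$realized_los >
    ledger$current_day
  ledger$stays <- ledger$stays[keep, ]
  ledger
}

# realized occupancy counts (0/1 per stay) per contingent at a single day
realized_occupancy <- function(ledger, day) {
  s <- ledger$stays
  occ <- s$admission_day <= day & day < s$admission_day + s$realized_los
  out <- tibble(ward_id = s$ward_id[occ], preference = s$preference[occ])
  dplyr::count(out, .data$ward_id, .data$preference, name = "occupied")
}

#' Read / write a ledger snapshot
#'
#' CSV snapshot of the stay table (columns `patient_id`, `ward_id`,
#' `preference`, `admission_day`, `mean_days`, `variance_days2`,
#' `realized_los`); log-scale parameters are re-derived on read.
#'
#' @param ledger A `ward_ledger`.
#' @param path CSV file path.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "ward_ledger"))
  out <- ledger$stays[c("patient_id", "ward_id", "preference",
                        "admission_day", "mean_days", "variance_days2",
                        "realized_los")]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @param hospital,horizon,current_day Passed to [new_ledger()].
#' @export
read_ledger <- function(path, hospital, horizon = 160L, current_day = 0L) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  p <- los_params(df$mean_days, sqrt(df$variance_days2))
  df$meanlog <- p$meanlog
  df$sdlog <- p$sdlog
  df$patient_id <- as.character(df$patient_id)
  df$ward_id <- as.integer(df$ward_id)
  df$admission_day <- as.integer(df$admission_day)
  df$realized_los <- as.integer(df$realized_los)
  add_stays(new_ledger(hospital, horizon, current_day), df)
}
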
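# Four-factor assignment cost model. A candidate is a triple
# (patient, ward, admission day t); its cost is the weighted sum of
#   alpha: clinic-ward affinity,
#   beta:  expected usage rate summed over the expected stay window,
#   gamma: absolute day-to-day change of the usage rate over that window,
#   delta: admission delay discounted by treatment priority.
# All usage rates are evaluated on the ledger as it stands before the
# candidate is added, so the costs double as constant BIP coefficients.

#' Cost weights
#'
#' Non-negative weight factors for the four partial assignment costs. The
#' reference configuration fixes all four at 1.
#'
#' @param alpha,beta,gamma,delta Non-negative weights.
#' @return A `cost_weights` object.
#' @export
cost_weights <- function(alpha = 1, beta = 1, gamma = 1, delta = 1) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(!is.finite(w)) || any(w < 0)) abort("weights must be finite and >= 0")
  structure(as.list(w), class = "cost_weights")
}

#' Affinity cost factor
#'
#' In the default `"inverted"` mode the cost of an assignment with affinity
#' `aff` is `alpha * (1 - aff)`, so the most preferred ward (affinity 1)
#' costs nothing under the minimising objective. The `"literal"` mode charges
#' `alpha * aff` instead. Affinity 0 is an infeasible assignment, not a cost,
#' and raises an error.
#'
#' @param aff Affinity in (0, 1].
#' @param weights A [cost_weights()] object.
#' @param mode `"inverted"` (default) or `"literal"`.
#' @export
alpha_cost <- function(aff, weights = cost_weights(),
                       mode = c("inverted", "literal")) {
  mode <- match.arg(mode)
  if (any(aff <= 0) || any(aff > 1)) {
    abort("affinity must lie in (0, 1]; 0 marks an infeasible assignment")
  }
  if (mode == "inverted") weights$alpha * (1 - aff) else weights$alpha * aff
}

#' Ward occupancy cost factor
#'
#' Sum of the expected usage rate `c_jmb` of the target contingent over the
#' patient's expected stay window, the `ceiling(expected_los)` days starting
#' at admission day `t` (day indices relative to the ledger's current day,
#' `t = 1` meaning admission today).
#'
#' @param ledger A `ward_ledger` (state before adding the candidate).
#' @param ward_id,preference Target contingent.
#' @param t Admission day index (>= 1).
#' @param expected_los Expected length of stay in days.
#' @param weights A [cost_weights()] object.
#' @export
beta_cost <- function(ledger, ward_id, preference, t, expected_los,
                      weights = cost_weights()) {
  check_scalar_number(t, "t", min = 1)
  len <- max(1L, as.integer(ceiling(expected_los)))
  days <- ledger$current_day + (t - 1) + seq_len(len) - 1
  weights$beta * sum(usage_rate(ledger, ward_id, preference, days))
}

#' Occupancy change cost factor
#'
#' Sum of the absolute successive differences of the usage rate across the
#' expected stay window, penalising admissions into volatile occupancy
#' profiles (a proxy for ward changes during the stay).
#'
#' @inheritParams beta_cost
#' @export
gamma_cost <- function(ledger, ward_id, preference, t, expected_los,
                       weights = cost_weights()) {
  check_scalar_number(t, "t", min = 1)
  len <- max(1L, as.integer(ceiling(expected_los)))
  days <- ledger$current_day + (t - 1) + seq_len(len + 1L) - 1
  cs <- usage_rate(ledger, ward_id, preference, days)
  weights$gamma * sum(abs(diff(cs)))
}

#' Admission delay cost factor
#'
#' `delta / (1 + priority) * (1 - 1 / (1 + t))`: strictly increasing in the
#' admission day index `t` and decreasing in the treatment priority (0 is the
#' most urgent class, 3 the least).
#'
#' @param priority Integer treatment priority in 0..3.
#' @param t Admission day index (>= 1, vectorised).
#' @param weights A [cost_weights()] object.
#' @export
delta_cost <- function(priority, t, weights = cost_weights()) {
  if (any(!priority %in% 0:3)) abort("priority must be one of 0, 1, 2, 3")
  if (any(t < 1)) abort("`t` must be >= 1")
  weights$delta * (1 / (1 + priority)) * (1 - 1 / (1 + t))
}

#' Full assignment cost of a candidate
#'
#' Evaluates the four partial factors for admitting `patient` to `ward_id`
#' at day `t` (relative to the ledger's current day) and returns the
#' weighted breakdown. A dummy-ward candidate returns the dismissal penalty
#' as `total` with all partial factors zero.
#'
#' @param patient A one-row tibble or list with at least `clinic_id`,
#'   `preference`, `priority` and `mean_days`.
#' @param ward_id Target ward.
#' @param t Admission day index (>= 1).
#' @param ledger A `ward_ledger` (state before adding the candidate).
#' @param weights A [cost_weights()] object.
#' @param mode Affinity cost mode, see [alpha_cost()].
#' @param penalty Dismissal penalty charged for dummy-ward assignments.
#' @return A one-row tibble with columns `alpha`, `beta`, `gamma`, `delta`
#'   and `total`.
#' @export
assignment_cost <- function(patient, ward_id, t, ledger,
                            weights = cost_weights(),
                            mode = c("inverted", "literal"),
                            penalty = 1e6) {
  mode <- match.arg(mode)
  h <- ledger$hospital
  i <- match(ward_id, h$wards$id)
  if (is.na(i)) abort("unknown ward id")
  if (h$wards$is_dummy[i]) {
    return(tibble(alpha = 0, beta = 0, gamma = 0, delta = 0, total = penalty))
  }
  aff <- affinity(h, patient$clinic_id, ward_id)
  if (aff == 0) abort("infeasible candidate: affinity 0")
  if (h$wards[[patient$preference]][i] == 0) {
    abort("infeasible candidate: ward has no beds of this preference class")
  }
  a <- alpha_cost(aff, weights, mode)
  b <- beta_cost(ledger, ward_id, patient$preference, t, patient$mean_days,
                 weights)
  g <- gamma_cost(ledger, ward_id, patient$preference, t, patient$mean_days,
                  weights)
  d <- delta_cost(patient$priority, t, weights)
  tibble(alpha = a, beta = b, gamma = g, delta = d, total = a + b + g + d)
}

# Vectorised candidate costing over all admission days 1..k for one
# (patient, contingent) pair, given the contingent's usage-rate curve over
# days current_day .. current_day + H - 1 (column 1 = current day = t 1).
# Returns a matrix with rows alpha, beta, gamma, delta, total and k columns.
candidate_cost_curve <- function(c_curve, k, expected_los, priority, aff,
                                 weights, mode = "inverted") {
  len <- max(1L, as.integer(ceiling(expected_los)))
  stopifnot(length(c_curve) >= k + len)
  a <- if (mode == "inverted") weights$alpha * (1 - aff) else weights$alpha * aff
  cs <- c(0, cumsum(c_curve))
  beta <- weights$beta * (cs[(1:k) + len] - cs[1:k])
  dd <- c(0, cumsum(abs(diff(c_curve))))
  gamma <- weights$gamma * (dd[(1:k) + len] - dd[1:k])
  delta <- weights$delta * (1 / (1 + priority)) * (1 - 1 / (1 + (1:k)))
  rbind(alpha = rep(a, k), beta = beta, gamma = gamma, delta = delta,
        total = a + beta + gamma + delta)
}

# Admission-day window allowed by a treatment priority within a k-day frame:
# priorities 0 and 1 must be admitted today (t = 1), priority 2 within a
# week, priority 3 anywhere in the frame.
priority_window <- function(priority, k) {
  switch(as.character(priority),
    "0" = 1L,
    "1" = 1L,
    "2" = seq_len(min(7L, k)),
    "3" = seq_len(k),
    abort("priority must be one of 0, 1, 2, 3")
  )
}
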
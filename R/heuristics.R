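# List-scheduling heuristics: order the collective (LEPT / SEPT / random),
# then place each patient greedily at the feasible (ward, day) with minimal
# assignment cost, committing placements against the same windowed capacity
# rows the BIP uses. STATQUO is the status-quo baseline: random order and
# only the affinity and occupancy cost factors.

#' Strategy configuration
#'
#' @param name One of `"EXACT"`, `"LEPT"`, `"SEPT"`, `"RAND"`, `"STATQUO"`.
#' @param seed Seed for the strategy's own randomness (patient order for
#'   RAND/STATQUO).
#' @param weights A [cost_weights()]. STATQUO forces the occupancy-change
#'   and delay weights to zero, mirroring what human planners neglect.
#' @param time_limit Solver time limit in seconds (EXACT only).
#' @param mode Affinity cost mode, see [alpha_cost()].
#' @param backend MILP backend for EXACT, see [solve_bip()].
#' @param penalty Dismissal penalty constant.
#' @return A `strategy_config` object.
#' @export
strategy_config <- function(name = c("RAND", "LEPT", "SEPT", "STATQUO",
                                     "EXACT"),
                            seed = NULL, weights = cost_weights(),
                            time_limit = 300, mode = "inverted",
                            backend = "auto", penalty = 1e6) {
  name <- match.arg(name)
  if (name == "STATQUO") {
    weights <- cost_weights(alpha = weights$alpha, beta = weights$beta,
                            gamma = 0, delta = 0)
  }
  structure(
    list(name = name, seed = seed, weights = weights,
         time_limit = time_limit, mode = mode, backend = backend,
         penalty = penalty),
    class = "strategy_config"
  )
}

#' Order a planning collective for list scheduling
#'
#' LEPT sorts by non-increasing rounded-up expected LoS, SEPT by
#' non-decreasing (ties broken by patient id); RAND and STATQUO shuffle
#' uniformly using the strategy seed.
#'
#' @param patients Patient tibble.
#' @param strategy A [strategy_config()] (or a strategy name).
#' @param seed Optional seed overriding the strategy's.
#' @return The reordered patient tibble.
#' @export
order_patients <- function(patients, strategy, seed = NULL) {
  if (is.character(strategy)) strategy <- strategy_config(strategy)
  seed <- seed %||% strategy$seed
  lep <- ceiling(patients$mean_days)
  switch(strategy$name,
    LEPT = patients[order(-lep, patients$patient_id), ],
    SEPT = patients[order(lep, patients$patient_id), ],
    EXACT = patients,
    local_seed(seed, patients[sample.int(nrow(patients)), ])
  )
}

# Mutable per-cycle state shared by the greedy placements: expected-usage
# curves (constant within the cycle, as in the BIP), floored capacity
# right-hand sides, and the windowed admission counts W of the placements
# committed so far this cycle.
cycle_state <- function(query, hospital, ledger, strategy) {
  k <- query$timeframe_days
  l_max <- query$l_max
  if (ledger$horizon < k + l_max + 2L) {
    abort(sprintf(
      "ledger horizon (%d) too short: need at least k + l_max + 2 = %d days",
      ledger$horizon, k + l_max + 2L))
  }
  H <- k + l_max + 2L
  eu <- usage_matrix(ledger, ledger$current_day + 0:(H - 1L))
  caps <- capacity_vector(hospital)[rownames(eu)]
  st <- new.env(parent = emptyenv())
  st$k <- k
  st$l_max <- l_max
  st$cmat <- eu / pmax(caps, 1L)
  st$rhs <- pmax(caps - eu[, seq_len(k), drop = FALSE], 0)
  st$W <- matrix(0L, nrow = nrow(eu), ncol = k,
                 dimnames = list(rownames(eu), NULL))
  st$caps <- caps
  st
}

# cheapest feasible (ward, day) for one patient given the cycle state;
# ties broken by earlier day, then smaller ward id
place_one <- function(patient, hospital, st, strategy) {
  k <- st$k
  nd <- hospital$wards[!hospital$wards$is_dummy, ]
  ok <- nd[[patient$preference]] > 0
  wids <- nd$id[ok]
  affs <- affinity(hospital, patient$clinic_id, wids)
  keep <- affs > 0
  wids <- wids[keep]
  affs <- affs[keep]
  if (!length(wids)) {
    return(NULL)
  }
  tt <- priority_window(patient$priority, k)
  nt <- length(tt)
  nw <- length(wids)
  al <- be <- ga <- de <- tot <- numeric(nw * nt)
  for (wi in seq_len(nw)) {
    key <- key_wb(wids[wi], patient$preference)
    cc <- candidate_cost_curve(st$cmat[key, ], k, patient$mean_days,
                               patient$priority, affs[wi],
                               strategy$weights, strategy$mode)
    idx <- (wi - 1L) * nt + seq_len(nt)
    al[idx] <- cc["alpha", tt]
    be[idx] <- cc["beta", tt]
    ga[idx] <- cc["gamma", tt]
    de[idx] <- cc["delta", tt]
    tot[idx] <- cc["total", tt]
  }
  wvec <- rep(wids, each = nt)
  tvec <- rep.int(tt, nw)
  for (i in order(tot, tvec, wvec)) {
    key <- key_wb(wvec[i], patient$preference)
    t0 <- tvec[i]
    rows <- t0:min(t0 + st$l_max, k)
    if (all(st$W[key, rows] + 1 <= st$rhs[key, rows] + 1e-9)) {
      return(list(ward_id = wvec[i], key = key, t = t0, alpha = al[i],
                  beta = be[i], gamma = ga[i], delta = de[i],
                  total = tot[i]))
    }
  }
  NULL
}

commit_placement <- function(st, key, t0) {
  rows <- t0:min(t0 + st$l_max, st$k)
  st$W[key, rows] <- st$W[key, rows] + 1L
  invisible(st)
}

#' Greedy minimum-cost placement of a single patient
#'
#' Evaluates every feasible candidate (preference satisfied, positive
#' affinity, admission day inside the priority window, no windowed capacity
#' row violated, counting the `pending` same-cycle placements) and returns
#' the cheapest one, or a dismissal when none is feasible.
#'
#' @param patient One-row patient tibble.
#' @param hospital A `ward_hospital`.
#' @param ledger A `ward_ledger` (pre-cycle state).
#' @param pending Optional tibble of placements already made this cycle
#'   (`ward_id`, `preference`, `t`).
#' @param timeframe_days Planning frame length `k`.
#' @param l_max Capacity look-back window; defaults to the rounded-up
#'   expected LoS of `patient` and `pending` combined.
#' @param strategy A [strategy_config()].
#' @return A one-row tibble (`ward_id`, `t`, cost breakdown) or `NULL` for a
#'   dismissal.
#' @export
greedy_place <- function(patient, hospital, ledger, pending = NULL,
                         timeframe_days = 40L, l_max = NULL,
                         strategy = strategy_config("RAND")) {
  patient <- as_tibble(patient)
  stopifnot(nrow(patient) == 1L)
  l_max <- as.integer(l_max %||% max(ceiling(patient$mean_days)))
  query <- structure(
    list(patients = patient, timeframe_days = as.integer(timeframe_days),
         current_day = ledger$current_day, l_max = l_max),
    class = "ward_query"
  )
  st <- cycle_state(query, hospital, ledger, strategy)
  if (!is.null(pending) && nrow(pending)) {
    for (i in seq_len(nrow(pending))) {
      commit_placement(st, key_wb(pending$ward_id[i], pending$preference[i]),
                       pending$t[i])
    }
  }
  res <- place_one(patient, hospital, st, strategy)
  if (is.null(res)) NULL else as_tibble(res[c("ward_id", "t", "alpha",
                                              "beta", "gamma", "delta",
                                              "total")])
}

#' Plan a collective with one strategy
#'
#' Runs the configured strategy against a frozen ledger state: EXACT builds
#' and solves the BIP; the list-scheduling strategies order the collective
#' and place patients greedily one by one, each committed placement counting
#' against the capacity rows seen by the next. Decisions do not modify the
#' ledger; committing accepted stays is the caller's (the simulation's)
#' responsibility.
#'
#' @param query A [planning_query()].
#' @param hospital A `ward_hospital`.
#' @param ledger A `ward_ledger`.
#' @param strategy A [strategy_config()].
#' @return A list with `decisions` (one row per patient), `status`
#'   (`"ok"` or the solver status for EXACT) and `seconds`.
#' @export
assign_collective <- function(query, hospital, ledger, strategy) {
  stopifnot(inherits(query, "ward_query"), inherits(strategy,
                                                    "strategy_config"))
  t0 <- proc.time()[["elapsed"]]
  if (strategy$name == "EXACT") {
    model <- build_bip(query, hospital, ledger, weights = strategy$weights,
                       mode = strategy$mode, penalty = strategy$penalty)
    sol <- solve_bip(model, time_limit = strategy$time_limit,
                     backend = strategy$backend)
    if (sol$status == "error") {
      abort("MILP backend failed; no assignment computed")
    }
    return(list(decisions = sol$decisions, status = sol$status,
                seconds = proc.time()[["elapsed"]] - t0))
  }
  ordered <- order_patients(query$patients, strategy)
  st <- cycle_state(query, hospital, ledger, strategy)
  n <- nrow(ordered)
  status <- character(n)
  wid <- t_sel <- rep(NA_integer_, n)
  al <- be <- ga <- de <- numeric(n)
  tot <- rep(strategy$penalty, n)
  for (i in seq_len(n)) {
    p <- list(preference = ordered$preference[i],
              clinic_id = ordered$clinic_id[i],
              mean_days = ordered$mean_days[i],
              priority = ordered$priority[i])
    res <- place_one(p, hospital, st, strategy)
    if (is.null(res)) {
      status[i] <- "dismissed"
    } else {
      commit_placement(st, res$key, res$t)
      status[i] <- "assigned"
      wid[i] <- res$ward_id
      t_sel[i] <- res$t
      al[i] <- res$alpha
      be[i] <- res$beta
      ga[i] <- res$gamma
      de[i] <- res$delta
      tot[i] <- res$total
    }
  }
  decisions <- tibble(
    patient_id = ordered$patient_id, status = status, ward_id = wid,
    t = t_sel, alpha = al, beta = be, gamma = ga, delta = de, total = tot
  )
  decisions <- decisions[match(query$patients$patient_id,
                               decisions$patient_id), ]
  list(decisions = decisions, status = "ok",
       seconds = proc.time()[["elapsed"]] - t0)
}
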
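# Discrete-event simulation of the virtual hospital. Events are planning
# cycles: a collective of random size arrives, the configured strategy plans
# it against the current occupancy, accepted stays are committed, and after
# CPD cycles the planning frame shifts by SPF days, discharging the stays
# whose realized occupancy interval has ended. Dismissed patients are
# dropped for good; each admission request is planned exactly once.

#' Simulation configuration
#'
#' @param hospital A `ward_hospital`.
#' @param strategy A [strategy_config()] (or strategy name).
#' @param pop A [population_config()]; its `mxp` is overridden by the `mxp`
#'   argument.
#' @param ppy Total number of patients to generate before stopping.
#' @param mxp Maximum collective size per cycle.
#' @param cpd Assignment cycles per day.
#' @param spf Planning-frame shift in days after each day's cycles.
#' @param timeframe_days Planning frame length `k` in days.
#' @param seed Master seed; population, strategy and realization randomness
#'   are derived from it per cycle, so runs are reproducible and sweeps over
#'   strategies see identical patient streams.
#' @param warmup_days Number of initial days whose cycles are run but
#'   neither logged nor counted towards `ppy`. The simulation starts from an
#'   empty hospital; with a 40-day planning frame the fill transient lasts
#'   roughly the frame length plus the LoS tail, so stationary summaries at
#'   reduced `ppy` should discard it. Seed streams advance identically
#'   during warm-up, keeping strategy sweeps paired.
#' @param horizon Ledger horizon in days (must cover
#'   `timeframe_days + l_max + 2`).
#' @return A `ward_sim_config` object.
#' @export
simulation_config <- function(hospital, strategy, pop = population_config(),
                              ppy = 45000L, mxp = 110L, cpd = 5L, spf = 1L,
                              timeframe_days = 40L, seed = 1L,
                              warmup_days = 0L, horizon = 160L) {
  if (is.character(strategy)) strategy <- strategy_config(strategy)
  stopifnot(inherits(hospital, "ward_hospital"),
            inherits(strategy, "strategy_config"),
            inherits(pop, "population_config"))
  if (!is_count(ppy) || !is_count(mxp) || !is_count(cpd) || !is_count(spf) ||
      !is_count(timeframe_days)) {
    abort("ppy, mxp, cpd, spf and timeframe_days must be positive integers")
  }
  if (!is_count(warmup_days, min = 0L)) {
    abort("warmup_days must be a non-negative integer")
  }
  pop$mxp <- as.integer(mxp)
  structure(
    list(hospital = hospital, strategy = strategy, pop = pop,
         ppy = as.integer(ppy), mxp = as.integer(mxp), cpd = as.integer(cpd),
         spf = as.integer(spf), timeframe_days = as.integer(timeframe_days),
         seed = as.integer(seed), warmup_days = as.integer(warmup_days),
         horizon = as.integer(horizon)),
    class = "ward_sim_config"
  )
}

#' Run the discrete-event simulation
#'
#' Loops over days with `cpd` planning cycles each: a collective is sampled,
#' ward states are snapshot, the strategy plans the collective against the
#' current ledger, accepted stays are committed, and a cycle record is
#' logged. After each day's cycles the clock advances by `spf` days and
#' stays whose realized occupancy has ended are discharged. The run stops
#' once `ppy` patients have been generated. Fully deterministic given the
#' configuration seed.
#'
#' @param config A [simulation_config()].
#' @param keep_ledger Keep the final ledger in the returned log.
#' @return A `ward_sim_log`: list with the `config`, the per-cycle tibble
#'   `cycles` and `total_patients`.
#' @export
run_simulation <- function(config, keep_ledger = FALSE) {
  stopifnot(inherits(config, "ward_sim_config"))
  hospital <- config$hospital
  strategy <- config$strategy
  ledger <- new_ledger(hospital, horizon = config$horizon)
  total <- 0L
  cycle <- 0L
  day_idx <- 0L
  records <- list()
  done <- FALSE
  while (!done) {
    day_idx <- day_idx + 1L
    warm <- day_idx <= (config$warmup_days %||% 0L)
    for (cy in seq_len(config$cpd)) {
      cycle <- cycle + 1L
      query <- sample_collective(
        hospital, config$pop, current_day = ledger$current_day,
        timeframe_days = config$timeframe_days,
        seed = derive_seed(config$seed, cycle, stream_id("population")),
        id_prefix = sprintf("c%05d-", cycle)
      )
      strategy$seed <- derive_seed(config$seed, cycle, stream_id("strategy"))
      before <- if (!warm) occupancy_snapshot(ledger)
      res <- assign_collective(query, hospital, ledger, strategy)
      ledger <- commit_decisions(ledger, query, res$decisions)
      if (warm) next
      after <- occupancy_snapshot(ledger)
      n <- nrow(query$patients)
      dism <- sum(res$decisions$status == "dismissed")
      assigned <- res$decisions[res$decisions$status == "assigned", ]
      records[[length(records) + 1L]] <- tibble(
        cycle_index = cycle,
        day = ledger$current_day,
        collective_size = n,
        dismissed_count = dism,
        dismissal_ratio = dism / n,
        assigned_count = n - dism,
        alpha_sum = sum(assigned$alpha), beta_sum = sum(assigned$beta),
        gamma_sum = sum(assigned$gamma), delta_sum = sum(assigned$delta),
        total_sum = sum(assigned$total),
        solver_status = res$status,
        compute_seconds = res$seconds,
        expected_occupied_before = before$expected,
        expected_occupied_after = after$expected,
        realized_occupied = after$realized,
        overflow_beds = after$overflow
      )
      total <- total + n
      if (total >= config$ppy) {
        done <- TRUE
        break
      }
    }
    if (!done) ledger <- advance_time(ledger, config$spf)
  }
  structure(
    list(config = config, cycles = bind_rows(records),
         total_patients = total,
         ledger = if (keep_ledger) ledger else NULL),
    class = "ward_sim_log"
  )
}

# commit accepted decisions as stays (realized LoS was sampled with the
# patient, so planning never sees it)
commit_decisions <- function(ledger, query, decisions) {
  acc <- decisions[decisions$status == "assigned", ]
  if (!nrow(acc)) return(ledger)
  p <- query$patients[match(acc$patient_id, query$patients$patient_id), ]
  add_stays(ledger, tibble(
    patient_id = p$patient_id,
    ward_id = as.integer(acc$ward_id),
    preference = p$preference,
    admission_day = as.integer(query$current_day + acc$t - 1L),
    mean_days = p$mean_days,
    variance_days2 = p$variance_days2,
    meanlog = p$meanlog,
    sdlog = p$sdlog,
    realized_los = p$realized_los
  ))
}

# expected, realized and overflowing occupancy at the ledger's current day
occupancy_snapshot <- function(ledger) {
  d <- ledger$current_day
  eu <- usage_matrix(ledger, d)
  ro <- realized_occupancy(ledger, d)
  caps <- capacity_vector(ledger$hospital)
  over <- 0L
  if (nrow(ro)) {
    kk <- key_wb(ro$ward_id, ro$preference)
    over <- sum(pmax(0L, ro$occupied - caps[kk]))
  }
  list(expected = sum(eu), realized = sum(ro$occupied), overflow = over)
}

#' @export
print.ward_sim_log <- function(x, ...) {
  cat(sprintf(
    "<ward_sim_log> %s: %d cycles, %d patients, mean dismissal ratio %.3f\n",
    x$config$strategy$name, nrow(x$cycles), x$total_patients,
    mean(x$cycles$dismissal_ratio)
  ))
  invisible(x)
}

#' Paired strategy sweep
#'
#' Runs the same simulation configuration once per strategy under common
#' random numbers: population seeds depend only on the master seed and the
#' cycle index, so every strategy plans an identical stream of collectives
#' and the comparison is paired.
#'
#' @param config A [simulation_config()]; its `strategy` slot is replaced by
#'   each swept strategy in turn.
#' @param strategies Character vector of strategy names or a list of
#'   [strategy_config()] objects.
#' @return A named list of `ward_sim_log` objects, class `ward_sweep`.
#' @export
strategy_sweep <- function(config,
                           strategies = c("STATQUO", "LEPT", "SEPT",
                                          "RAND")) {
  logs <- lapply(strategies, function(s) {
    cfg <- config
    cfg$strategy <- if (is.character(s)) strategy_config(s) else s
    run_simulation(cfg)
  })
  names(logs) <- vapply(logs, function(l) l$config$strategy$name,
                        character(1))
  structure(logs, class = "ward_sweep")
}

#' @export
print.ward_sweep <- function(x, ...) {
  for (l in x) print(l)
  invisible(x)
}
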
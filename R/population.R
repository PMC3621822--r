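# Synthetic patient population: clinic, gender, priority, bed preference and
# a log-normal LoS estimate per admission request.

#' Population generator configuration
#'
#' @param male_share Probability that a sampled patient is male.
#' @param priority_probs Probabilities of treatment priorities 0..3 (must sum
#'   to 1).
#' @param los_cv Coefficient of variation of the length-of-stay estimate: a
#'   patient treated by clinic `c` gets LoS mean `avg_los[c]` and standard
#'   deviation `los_cv * avg_los[c]`.
#' @param mxp Maximum planning-collective size; collective sizes are drawn
#'   uniformly from `{1, ..., mxp}`.
#' @return A `population_config` object.
#' @export
population_config <- function(male_share = 0.56,
                              priority_probs = c(0.1, 0.2, 0.3, 0.4),
                              los_cv = 0.5, mxp = 110L) {
  if (length(priority_probs) != 4L || any(priority_probs < 0) ||
      abs(sum(priority_probs) - 1) > 1e-9) {
    abort("priority_probs must be 4 non-negative values summing to 1")
  }
  check_scalar_number(male_share, "male_share", min = 0)
  check_scalar_number(los_cv, "los_cv", min = 0, strict = TRUE)
  if (!is_count(mxp)) abort("mxp must be a positive integer")
  structure(
    list(male_share = male_share,
         priority_probs = stats::setNames(priority_probs, 0:3),
         los_cv = los_cv, mxp = as.integer(mxp)),
    class = "population_config"
  )
}

# hospital-wide bed share per preference class (non-dummy wards); a
# bed-less hospital degenerates to equal shares so preferences stay defined
bed_shares <- function(hospital) {
  w <- hospital$wards[!hospital$wards$is_dummy, ]
  s <- vapply(pref_labels(), function(b) sum(w[[b]]), numeric(1))
  if (sum(s) == 0) s[] <- 1
  s / sum(s)
}

#' Sample synthetic patients
#'
#' Each patient gets a treating clinic (categorical on the clinics' annual
#' case shares), a gender (Bernoulli on `male_share`), a treatment priority
#' (categorical on `priority_probs`), a bed preference drawn from the
#' hospital-wide bed shares restricted to the classes open to the gender
#' (males: single or male double; females: single or female double,
#' renormalised), a log-normal LoS estimate with mean equal to the clinic's
#' average LoS and coefficient of variation `los_cv`, and a hidden realized
#' integer LoS sampled from that law. Clinic and gender are sampled
#' independently, so clinically implausible combinations (e.g. male
#' gynecology patients) can occur; only the room-type/gender coupling is
#' enforced.
#'
#' @param n Number of patients.
#' @param hospital A `ward_hospital`.
#' @param pop A [population_config()].
#' @param seed Optional seed; when given, the draw neither reads nor
#'   disturbs the caller's RNG state.
#' @param id_prefix Prefix for generated patient ids.
#' @return A tibble with one row per patient.
#' @export
sample_patients <- function(n, hospital, pop = population_config(),
                            seed = NULL, id_prefix = "p") {
  stopifnot(inherits(hospital, "ward_hospital"),
            inherits(pop, "population_config"))
  local_seed(seed, {
    cl <- hospital$clinics
    share <- cl$case_share / sum(cl$case_share)
    clinic_idx <- sample.int(nrow(cl), n, replace = TRUE, prob = share)
    gender <- ifelse(runif(n) < pop$male_share, "male", "female")
    priority <- sample(0:3, n, replace = TRUE, prob = pop$priority_probs)
    bs <- bed_shares(hospital)
    pref <- character(n)
    male <- gender == "male"
    p_single_m <- bs[["single"]] / (bs[["single"]] + bs[["double_male"]])
    p_single_f <- bs[["single"]] / (bs[["single"]] + bs[["double_female"]])
    u <- runif(n)
    pref[male] <- ifelse(u[male] < p_single_m, "single", "double_male")
    pref[!male] <- ifelse(u[!male] < p_single_f, "single", "double_female")
    mean_days <- cl$avg_los[clinic_idx]
    sd_days <- pmax(pop$los_cv * mean_days, 1e-3)
    lp <- los_params(mean_days, sd_days)
    tibble(
      patient_id = sprintf("%s%05d", id_prefix, seq_len(n)),
      clinic_id = cl$id[clinic_idx],
      gender = gender,
      priority = as.integer(priority),
      preference = pref,
      mean_days = mean_days,
      sd_days = sd_days,
      variance_days2 = sd_days^2,
      meanlog = lp$meanlog,
      sdlog = lp$sdlog,
      realized_los = sample_realized_los(lp$meanlog, lp$sdlog)
    )
  })
}

#' Planning query
#'
#' A batch of admission requests to be planned together in one assignment
#' cycle, with the planning frame length and the current day. `l_max` is the
#' largest rounded-up expected LoS in the collective; it sizes the look-back
#' window of the capacity constraints.
#'
#' @param patients Patient tibble as produced by [sample_patients()].
#' @param timeframe_days Number of admission days in the planning frame, `k`.
#' @param current_day Absolute day index of "today".
#' @return A `ward_query` object.
#' @export
planning_query <- function(patients, timeframe_days = 40L, current_day = 0L) {
  patients <- as_tibble(patients)
  if (!nrow(patients)) abort("planning collective must not be empty")
  if (!is_count(timeframe_days)) abort("timeframe_days must be >= 1")
  if (anyDuplicated(patients$patient_id)) abort("duplicate patient ids")
  structure(
    list(
      patients = patients,
      timeframe_days = as.integer(timeframe_days),
      current_day = as.integer(current_day),
      l_max = as.integer(max(ceiling(patients$mean_days)))
    ),
    class = "ward_query"
  )
}

#' @export
print.ward_query <- function(x, ...) {
  cat(sprintf(
    "<ward_query> %d patients, frame %d d, day %d, l_max %d\n",
    nrow(x$patients), x$timeframe_days, x$current_day, x$l_max
  ))
  invisible(x)
}

#' Sample a planning collective
#'
#' Draws a collective size uniformly from `{1, ..., mxp}` and fills it with
#' i.i.d. patients from [sample_patients()].
#'
#' @inheritParams sample_patients
#' @param current_day Absolute day index of the cycle.
#' @param timeframe_days Planning frame length in days.
#' @param size Optional fixed collective size (skips the uniform draw).
#' @return A `ward_query`.
#' @export
sample_collective <- function(hospital, pop = population_config(),
                              current_day = 0L, timeframe_days = 40L,
                              seed = NULL, size = NULL,
                              id_prefix = "p") {
  local_seed(seed, {
    n <- if (is.null(size)) sample.int(pop$mxp, 1L) else as.integer(size)
    planning_query(
      sample_patients(n, hospital, pop, seed = NULL, id_prefix = id_prefix),
      timeframe_days = timeframe_days, current_day = current_day
    )
  })
}

#' Read / write a planning query
#'
#' JSON round-trip of a planning query, preserving all patient fields
#' including the hidden realized LoS.
#'
#' @param query A `ward_query`.
#' @param path JSON file path.
#' @export
write_query <- function(query, path) {
  stopifnot(inherits(query, "ward_query"))
  doc <- list(
    timeframe_days = query$timeframe_days,
    current_day = query$current_day,
    patients = purrr::transpose(as.list(query$patients))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_query
#' @export
read_query <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (k in c("timeframe_days", "current_day", "patients")) {
    if (is.null(raw[[k]])) abort(sprintf("query file misses key '%s'", k))
  }
  pats <- bind_rows(purrr::map(raw$patients, function(e) {
    miss <- setdiff(c("patient_id", "clinic_id", "priority", "preference",
                      "mean_days", "variance_days2", "realized_los"),
                    names(e))
    if (length(miss)) {
      abort(sprintf("patient entry missing field(s): %s",
                    paste(miss, collapse = ", ")))
    }
    if (!e$preference %in% pref_labels()) {
      abort(sprintf("unknown preference token '%s'", e$preference))
    }
    as_tibble(e)
  }))
  lp <- los_params(pats$mean_days, sqrt(pats$variance_days2))
  pats$meanlog <- lp$meanlog
  pats$sdlog <- lp$sdlog
  pats$priority <- as.integer(pats$priority)
  pats$realized_los <- as.integer(pats$realized_los)
  pats$clinic_id <- as.integer(pats$clinic_id)
  planning_query(pats, timeframe_days = as.integer(raw$timeframe_days),
                 current_day = as.integer(raw$current_day))
}
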
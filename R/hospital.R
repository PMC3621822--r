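# Hospital model: clinics, wards with per-preference bed contingents, and
# clinic-ward affinities.

#' Preference classes for beds
#'
#' Beds are aggregated into contingents per preference class rather than
#' tracked individually: single-room beds, beds in female double rooms and
#' beds in male double rooms.
#'
#' @return A tibble with columns `id` and `label`.
#' @export
preference_classes <- function() {
  tibble(id = 1:3, label = c("single", "double_female", "double_male"))
}

pref_labels <- function() c("single", "double_female", "double_male")

# Annual case distribution over the 27 clinics of a German university
# hospital (relative frequency of inpatient cases and mean LoS in days).
clinic_table <- function() {
  tibble::tribble(
    ~name, ~cases, ~case_share, ~avg_los,
    "Ophthalmic clinic", 2040L, 0.0465, 4.1,
    "Surgical clinic", 2704L, 0.0615, 8.9,
    "Gynecological clinic (Breast)", 183L, 0.0042, 7.3,
    "Gynecological clinic (Endocrinology)", 88L, 0.0020, 3.8,
    "Gynecological clinic", 2458L, 0.0559, 5.4,
    "Dermatology", 1234L, 0.0281, 6.6,
    "Vascular surgery", 661L, 0.0150, 9.6,
    "Otolaryngology", 2093L, 0.0476, 5.9,
    "Pediatrics", 4674L, 0.1063, 5.5,
    "Pediatric psychology", 408L, 0.0093, 31.2,
    "Child cardiology", 403L, 0.0092, 6.5,
    "Nuclear medicine", 237L, 0.0054, 3.4,
    "Orthopedics", 1515L, 0.0345, 9.0,
    "Accident surgery", 1160L, 0.0264, 10.1,
    "Palliative medicine", 212L, 0.0048, 12.6,
    "Plastic surgery", 901L, 0.0205, 11.6,
    "Psychiatry", 1693L, 0.0385, 18.4,
    "Radiation therapy", 782L, 0.0178, 13.8,
    "Cardiac surgery", 1296L, 0.0295, 18.4,
    "Med. Clinic I", 7040L, 0.1602, 6.3,
    "Med. Clinic II", 1453L, 0.0331, 11.9,
    "Med. Clinic III", 3116L, 0.0709, 8.0,
    "Med. Clinic IV", 1677L, 0.0382, 7.6,
    "Neurosurgery", 1227L, 0.0279, 12.5,
    "Neurology", 2697L, 0.0614, 8.6,
    "Urology", 1323L, 0.0301, 7.7,
    "Facial surgery", 676L, 0.0154, 6.4
  )
}

# Ward types with bed contingents per preference class. Loaded as reported by
# the hospital's controllers; several rows have contingents that do not sum
# to the printed overall bed count and are flagged by validation, not fixed.
ward_type_table <- function() {
  tibble::tribble(
    ~type_name, ~total_beds, ~single, ~double_female, ~double_male,
    "Ward_G", 30L, 8L, 10L, 12L,
    "Ward_K", 16L, 2L, 7L, 9L,
    "Ward_SC01", 30L, 4L, 11L, 15L,
    "Ward_SC02", 32L, 8L, 10L, 14L,
    "Ward_SC03", 14L, 2L, 6L, 8L,
    "Ward_SC04", 30L, 8L, 10L, 12L,
    "Ward_SC06", 32L, 8L, 10L, 14L,
    "Ward_SC07", 27L, 6L, 9L, 12L,
    "Ward_SC08", 14L, 2L, 6L, 8L,
    "Ward_SC09", 32L, 8L, 10L, 14L,
    "Ward_SC10", 32L, 8L, 10L, 14L,
    "Ward_SC11", 16L, 2L, 7L, 9L,
    "Ward_SC12", 32L, 8L, 10L, 14L,
    "Ward_SC15", 4L, 2L, 2L, 2L
  )
}

dummy_ward_row <- function(id) {
  tibble(
    id = as.integer(id), type_name = "DUMMY",
    total_beds = 1000L, single = 300L,
    double_female = 350L, double_male = 350L,
    is_dummy = TRUE
  )
}

# How many wards of each type the default virtual hospital contains. The
# counts sum to 43 and are weighted toward the large interdisciplinary
# Standard Care (SC) types, which carry the shared-bed pool the model is
# about; every type stays represented at least once.
default_replication <- function() {
  tibble::tribble(
    ~type_name, ~count,
    "Ward_G", 2L,
    "Ward_K", 1L,
    "Ward_SC01", 2L,
    "Ward_SC02", 6L,
    "Ward_SC03", 1L,
    "Ward_SC04", 2L,
    "Ward_SC06", 6L,
    "Ward_SC07", 2L,
    "Ward_SC08", 1L,
    "Ward_SC09", 6L,
    "Ward_SC10", 6L,
    "Ward_SC11", 1L,
    "Ward_SC12", 6L,
    "Ward_SC15", 1L
  )
}

#' Construct and validate a hospital configuration
#'
#' @param clinics Tibble with `id`, `name`, `case_share`, `avg_los`.
#' @param wards Tibble with `id`, `type_name`, `total_beds`, one column per
#'   preference class (`single`, `double_female`, `double_male`) and
#'   `is_dummy` (exactly one dummy ward).
#' @param affinities Tibble with `clinic_id`, `ward_id`, `affinity` holding
#'   the non-zero clinic-ward affinities in (0, 1]. Pairs absent from the
#'   table have affinity 0 and are infeasible; the dummy ward implicitly has
#'   affinity 1 to every clinic.
#' @param replication Optional tibble `type_name`, `count` recording how ward
#'   types were replicated into wards (kept so a fixture round-trips).
#' @return A validated object of class `ward_hospital`. Non-fatal findings
#'   (e.g. bed contingents that do not sum to the ward total) are kept in
#'   `$validation_warnings` and signalled as warnings.
#' @export
hospital_config <- function(clinics, wards, affinities,
                            replication = NULL) {
  h <- structure(
    list(
      clinics = as_tibble(clinics),
      wards = as_tibble(wards),
      affinities = as_tibble(affinities),
      preference_classes = preference_classes(),
      replication = if (is.null(replication)) NULL else as_tibble(replication),
      validation_warnings = character()
    ),
    class = "ward_hospital"
  )
  validate_hospital(h)
}

validate_hospital <- function(h) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(sprintf("hospital config: %s missing field(s): %s",
                    what, paste(miss, collapse = ", ")))
    }
  }
  need(h$clinics, c("id", "name", "case_share", "avg_los"), "clinics")
  need(h$wards, c("id", "type_name", "total_beds", pref_labels(), "is_dummy"),
       "wards")
  need(h$affinities, c("clinic_id", "ward_id", "affinity"), "affinities")

  if (anyDuplicated(h$clinics$id)) abort("duplicate clinic ids")
  if (anyDuplicated(h$wards$id)) abort("duplicate ward ids")
  if (any(h$clinics$avg_los <= 0)) abort("clinic avg_los must be > 0")
  if (any(h$clinics$case_share < 0 | h$clinics$case_share > 1)) {
    abort("clinic case_share must lie in [0, 1]")
  }
  if (abs(sum(h$clinics$case_share) - 1) > 0.01) {
    abort("clinic case shares must sum to 1 within 0.01")
  }
  if (sum(h$wards$is_dummy) != 1L) {
    abort("hospital config must contain exactly one dummy ward")
  }
  if (nrow(h$wards) - sum(h$wards$is_dummy) < 1L) {
    abort("hospital config must contain at least one non-dummy ward")
  }
  caps <- as.matrix(h$wards[pref_labels()])
  if (any(caps < 0)) abort("bed contingents must be non-negative")
  if (any(!h$affinities$ward_id %in% h$wards$id) ||
      any(!h$affinities$clinic_id %in% h$clinics$id)) {
    abort("affinity refers to unknown clinic or ward id")
  }
  if (any(h$affinities$affinity < 0 | h$affinities$affinity > 1)) {
    abort("affinities must lie in [0, 1]")
  }
  warnings <- character()
  zero <- h$affinities$affinity == 0
  if (any(zero)) {
    warnings <- c(warnings, sprintf(
      "%d affinity entries with value 0 dropped (absence already means 0)",
      sum(zero)))
    h$affinities <- h$affinities[!zero, , drop = FALSE]
  }
  dummy_id <- h$wards$id[h$wards$is_dummy]
  if (any(h$affinities$ward_id == dummy_id)) {
    warnings <- c(warnings,
                  "explicit dummy-ward affinities dropped (always 1)")
    h$affinities <- h$affinities[h$affinities$ward_id != dummy_id, ,
                                 drop = FALSE]
  }
  if (anyDuplicated(h$affinities[c("clinic_id", "ward_id")])) {
    abort("duplicate clinic-ward affinity entries")
  }
  bad <- !h$wards$is_dummy & rowSums(caps) != h$wards$total_beds
  if (any(bad)) {
    warnings <- c(warnings, sprintf(
      "ward %s (%s): bed contingents sum to %d, not the stated total of %d",
      h$wards$id[bad], h$wards$type_name[bad],
      rowSums(caps)[bad], h$wards$total_beds[bad]))
  }
  h$validation_warnings <- warnings
  for (w in warnings) warn(w)
  h
}

#' @export
print.ward_hospital <- function(x, ...) {
  cat(sprintf(
    "<ward_hospital> %d clinics, %d wards (+1 dummy), %d affinities, %d contingent beds\n",
    nrow(x$clinics), sum(!x$wards$is_dummy), nrow(x$affinities),
    sum(as.matrix(x$wards[!x$wards$is_dummy, pref_labels()]))
  ))
  invisible(x)
}

#' Default synthetic hospital fixture
#'
#' Builds the virtual hospital used throughout: 27 clinics with their annual
#' case shares and mean lengths of stay, 43 wards obtained by replicating the
#' ward types according to [default_replication()], one high-capacity dummy
#' ward, and exactly 72 non-zero clinic-ward affinities. Ward capacity
#' reachable by a clinic is balanced against the clinic's expected bed-day
#' demand (case share times mean LoS): clinics are processed in decreasing
#' demand order and greedily pick the wards with the most spare capacity per
#' unit of demand already routed to them. The nine clinics with the lowest
#' demand get two candidate wards, all others three; the first, second and
#' third choices receive affinities 1.0, 0.8 and 0.5.
#'
#' @param seed Integer seed; the construction is deterministic given `seed`
#'   (used only to jitter ties in the ward-matching step).
#' @return A `ward_hospital` object.
#' @examples
#' h <- default_hospital(1)
#' nrow(h$affinities) # 72
#' @export
default_hospital <- function(seed = 1L) {
  clinics <- clinic_table()
  clinics$id <- seq_len(nrow(clinics))
  clinics <- clinics[c("id", "name", "case_share", "avg_los")]

  repl <- default_replication()
  types <- ward_type_table()
  idx <- rep(match(repl$type_name, types$type_name), repl$count)
  wards <- types[idx, ]
  wards$id <- seq_len(nrow(wards))
  wards$is_dummy <- FALSE
  wards <- bind_rows(wards, dummy_ward_row(nrow(wards) + 1L))
  wards <- wards[c("id", "type_name", "total_beds", pref_labels(),
                   "is_dummy")]

  affinities <- local_seed(
    derive_seed(seed, stream = stream_id("fixture")),
    build_affinities(clinics, wards)
  )
  suppressWarnings(hospital_config(clinics, wards, affinities,
                                   replication = repl))
}

# Demand-balanced matching of clinics to candidate wards (see
# default_hospital). Deterministic given the RNG state.
build_affinities <- function(clinics, wards) {
  nd <- wards[!wards$is_dummy, ]
  beds <- rowSums(as.matrix(nd[pref_labels()]))
  demand <- clinics$case_share * clinics$avg_los
  demand <- demand / sum(demand)
  ord <- order(demand, decreasing = TRUE)
  n_choices <- rep(3L, nrow(clinics))
  n_choices[ord[(nrow(clinics) - 8):nrow(clinics)]] <- 2L
  aff_values <- c(1.0, 0.8, 0.5)
  load <- stats::setNames(rep(0, nrow(nd)), nd$id)
  jitter <- runif(nrow(nd), 0, 1e-9)
  out <- vector("list", nrow(clinics))
  for (ci in ord) {
    k <- n_choices[ci]
    w <- aff_values[seq_len(k)]
    share <- demand[ci] * w / sum(w)
    picked <- integer(0)
    for (r in seq_len(k)) {
      # load per bed if this clinic's r-th slice were routed to ward j
      score <- (load + share[r]) / beds + jitter
      score[match(picked, nd$id)] <- Inf
      j <- which.min(score)
      load[j] <- load[j] + share[r]
      picked <- c(picked, nd$id[j])
    }
    out[[ci]] <- tibble(clinic_id = clinics$id[ci], ward_id = picked,
                        affinity = aff_values[seq_len(k)])
  }
  arrange(bind_rows(out), .data$clinic_id, desc(.data$affinity))
}

#' Clinic-ward affinity lookup
#'
#' @param hospital A `ward_hospital`.
#' @param clinic_id,ward_id Ids to look up (vectorised, recycled).
#' @return Affinity values; 0 for pairs not in the table (assignment
#'   forbidden), 1 for the dummy ward regardless of clinic.
#' @export
affinity <- function(hospital, clinic_id, ward_id) {
  stopifnot(inherits(hospital, "ward_hospital"))
  n <- max(length(clinic_id), length(ward_id))
  clinic_id <- rep_len(clinic_id, n)
  ward_id <- rep_len(ward_id, n)
  key <- paste(clinic_id, ward_id)
  tab <- hospital$affinities
  m <- match(key, paste(tab$clinic_id, tab$ward_id))
  out <- ifelse(is.na(m), 0, tab$affinity[m])
  dummy_id <- hospital$wards$id[hospital$wards$is_dummy]
  out[ward_id == dummy_id] <- 1
  out
}

#' Wards able to satisfy a preference class
#'
#' Returns the wards with a positive bed contingent for preference class `b`
#' (the dummy ward included).
#'
#' @param hospital A `ward_hospital`.
#' @param preference One of `"single"`, `"double_female"`, `"double_male"`.
#' @return The matching rows of `hospital$wards`.
#' @export
wards_for_preference <- function(hospital, preference) {
  stopifnot(inherits(hospital, "ward_hospital"))
  if (!preference %in% pref_labels()) {
    abort(sprintf("unknown preference class '%s'", preference))
  }
  hospital$wards[hospital$wards[[preference]] > 0, ]
}

# named capacity vector over all (ward, preference) pairs
capacity_vector <- function(hospital) {
  w <- hospital$wards
  caps <- unlist(lapply(pref_labels(), function(b) {
    stats::setNames(w[[b]], key_wb(w$id, b))
  }))
  caps
}

#' Read / write a hospital configuration
#'
#' The on-disk schema is a JSON or YAML document with the top-level keys
#' `preference_classes`, `clinics`, `wards`, `affinities` and (optionally)
#' `replication`; unknown keys are rejected. Ward capacities are nested under
#' a `capacity` object keyed by preference class.
#'
#' @param path File path; `.yaml`/`.yml` selects YAML, anything else JSON.
#' @return `read_hospital()` returns a validated `ward_hospital`;
#'   `write_hospital()` returns `path` invisibly.
#' @export
read_hospital <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  allowed <- c("preference_classes", "clinics", "wards", "affinities",
               "replication")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown top-level config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  for (k in c("clinics", "wards", "affinities")) {
    if (is.null(raw[[k]])) abort(sprintf("config misses required key '%s'", k))
  }
  grab <- function(entries, fields, what, coerce = identity) {
    purrr::map(entries, function(e) {
      miss <- setdiff(fields, names(e))
      if (length(miss)) {
        abort(sprintf("%s entry missing field(s): %s", what,
                      paste(miss, collapse = ", ")))
      }
      e
    })
  }
  clinics <- bind_rows(purrr::map(
    grab(raw$clinics, c("id", "name", "case_share", "avg_los"), "clinic"),
    function(e) tibble(id = as.integer(e$id), name = e$name,
                       case_share = as.numeric(e$case_share),
                       avg_los = as.numeric(e$avg_los))
  ))
  wards <- bind_rows(purrr::map(
    grab(raw$wards, c("id", "type_name", "total_beds", "capacity",
                      "is_dummy"), "ward"),
    function(e) {
      cap <- e$capacity
      miss <- setdiff(pref_labels(), names(cap))
      if (length(miss)) {
        abort(sprintf("ward %s capacity missing class(es): %s", e$id,
                      paste(miss, collapse = ", ")))
      }
      tibble(id = as.integer(e$id), type_name = e$type_name,
             total_beds = as.integer(e$total_beds),
             single = as.integer(cap$single),
             double_female = as.integer(cap$double_female),
             double_male = as.integer(cap$double_male),
             is_dummy = isTRUE(e$is_dummy))
    }
  ))
  affinities <- bind_rows(purrr::map(
    grab(raw$affinities, c("clinic_id", "ward_id", "affinity"), "affinity"),
    function(e) tibble(clinic_id = as.integer(e$clinic_id),
                       ward_id = as.integer(e$ward_id),
                       affinity = as.numeric(e$affinity))
  ))
  replication <- if (!is.null(raw$replication)) {
    bind_rows(purrr::map(
      grab(raw$replication, c("type_name", "count"), "replication"),
      function(e) tibble(type_name = e$type_name, count = as.integer(e$count))
    ))
  }
  hospital_config(clinics, wards, affinities, replication = replication)
}

#' @rdname read_hospital
#' @param hospital A `ward_hospital` to serialise.
#' @export
write_hospital <- function(hospital, path) {
  stopifnot(inherits(hospital, "ward_hospital"))
  wards <- purrr::pmap(hospital$wards, function(id, type_name, total_beds,
                                                single, double_female,
                                                double_male, is_dummy) {
    list(id = id, type_name = type_name, total_beds = total_beds,
         capacity = list(single = single, double_female = double_female,
                         double_male = double_male),
         is_dummy = is_dummy)
  })
  doc <- list(
    preference_classes = purrr::pmap(hospital$preference_classes,
                                     function(id, label) list(id = id, label = label)),
    clinics = purrr::pmap(hospital$clinics,
                          function(id, name, case_share, avg_los) {
                            list(id = id, name = name, case_share = case_share,
                                 avg_los = avg_los)
                          }),
    wards = wards,
    affinities = purrr::pmap(hospital$affinities,
                             function(clinic_id, ward_id, affinity) {
                               list(clinic_id = clinic_id, ward_id = ward_id,
                                    affinity = affinity)
                             })
  )
  if (!is.null(hospital$replication)) {
    doc$replication <- purrr::pmap(hospital$replication,
                                   function(type_name, count) {
                                     list(type_name = type_name, count = count)
                                   })
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
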
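# Small hospitals and random instances built in code for the tests.

# A minimal hospital: `n_wards` identical wards plus the dummy, every clinic
# affine to every ward (affinity 1 by default).
tiny_hospital <- function(n_wards = 2L, single = 2L, double_female = 2L,
                          double_male = 2L, n_clinics = 2L,
                          avg_los = c(3, 5), aff = NULL) {
  clinics <- tibble::tibble(
    id = seq_len(n_clinics),
    name = paste0("Clinic ", LETTERS[seq_len(n_clinics)]),
    case_share = rep(1 / n_clinics, n_clinics),
    avg_los = rep_len(avg_los, n_clinics)
  )
  wards <- tibble::tibble(
    id = seq_len(n_wards + 1L),
    type_name = c(rep("Ward_T", n_wards), "DUMMY"),
    total_beds = c(rep(single + double_female + double_male, n_wards),
                   1000L),
    single = c(rep(single, n_wards), 300L),
    double_female = c(rep(double_female, n_wards), 350L),
    double_male = c(rep(double_male, n_wards), 350L),
    is_dummy = c(rep(FALSE, n_wards), TRUE)
  )
  if (is.null(aff)) {
    aff <- expand.grid(clinic_id = clinics$id, ward_id = seq_len(n_wards))
    aff$affinity <- 1
  }
  suppressWarnings(hospital_config(clinics, wards, tibble::as_tibble(aff)))
}

# One random patient tibble for a given hospital (small LoS means so the
# enumeration oracle stays tractable).
tiny_patients <- function(n, hospital, seed) {
  withr::with_seed(seed, {
    genders <- sample(c("male", "female"), n, replace = TRUE)
    pref <- ifelse(genders == "male",
                   sample(c("single", "double_male"), n, replace = TRUE),
                   sample(c("single", "double_female"), n, replace = TRUE))
    mean_days <- round(runif(n, 1.2, 5.8), 2)
    sd_days <- pmax(0.3 * mean_days, 0.2)
    lp <- wardopt:::los_params(mean_days, sd_days)
    tibble::tibble(
      patient_id = sprintf("t%03d", seq_len(n)),
      clinic_id = sample(hospital$clinics$id, n, replace = TRUE),
      gender = genders,
      priority = sample(0:3, n, replace = TRUE),
      preference = pref,
      mean_days = mean_days,
      sd_days = sd_days,
      variance_days2 = sd_days^2,
      meanlog = lp$meanlog,
      sdlog = lp$sdlog,
      realized_los = pmax(1L, as.integer(ceiling(mean_days)))
    )
  })
}

# A random small planning instance: hospital with random small contingents
# and affinities, a ledger with a few pre-existing stays, and a collective
# small enough for exhaustive enumeration.
random_instance <- function(seed) {
  withr::with_seed(seed, {
    n_wards <- sample(1:3, 1)
    h <- tiny_hospital(
      n_wards = n_wards,
      single = sample(0:2, 1), double_female = sample(1:2, 1),
      double_male = sample(1:2, 1), n_clinics = 2L
    )
    aff_vals <- sample(c(0, 0.5, 0.8, 1), 2L * n_wards, replace = TRUE,
                       prob = c(0.2, 0.3, 0.2, 0.3))
    aff <- expand.grid(clinic_id = 1:2, ward_id = seq_len(n_wards))
    aff$affinity <- aff_vals
    aff <- aff[aff$affinity > 0, ]
    if (nrow(aff) == 0) aff <- data.frame(clinic_id = 1L, ward_id = 1L,
                                          affinity = 1)
    h <- suppressWarnings(hospital_config(h$clinics, h$wards,
                                          tibble::as_tibble(aff)))
    k <- sample(1:3, 1)
    n_pat <- sample(2:5, 1)
    pats <- tiny_patients(n_pat, h, seed = seed + 1000L)
    led <- new_ledger(h, horizon = 40L)
    n_stays <- sample(0:3, 1)
    if (n_stays > 0) {
      occ <- tiny_patients(n_stays, h, seed = seed + 2000L)
      led <- add_stays(led, tibble::tibble(
        patient_id = paste0("s", occ$patient_id),
        ward_id = sample(h$wards$id[!h$wards$is_dummy], n_stays,
                         replace = TRUE),
        preference = occ$preference,
        admission_day = sample(0:2, n_stays, replace = TRUE),
        mean_days = occ$mean_days, variance_days2 = occ$variance_days2,
        meanlog = occ$meanlog, sdlog = occ$sdlog,
        realized_los = occ$realized_los
      ))
    }
    list(hospital = h, ledger = led,
         query = planning_query(pats, timeframe_days = k))
  })
}
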
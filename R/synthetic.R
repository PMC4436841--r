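#' Case-mix specification for the synthetic generator
#'
#' Describes the statistical structure of the elective case load from which
#' synthetic waiting lists and arrival streams are drawn.  The default
#' weights reproduce one year of the studied unit's activity: 3112 elective
#' cases across nine specialties, five URG classes and six expected-
#' operating-time bins.  Specialty, URG and EOT are drawn independently by
#' weight (the source data publishes only the marginals); EOT is uniform
#' within its bin, and the open-ended ">150" bin is sampled uniformly on
#' (150, `eot_cap`] with `eot_cap` = 360 (a 12-hour block bound).
#'
#' Anesthesia-type shares, per-risk prevalences and the logistics
#' probabilities are synthetic conventions — the source publishes none —
#' and are plainly configurable here.
#'
#' @param specialty_weights Named nonnegative weights per specialty.
#' @param urg_weights Named nonnegative weights per URG class.
#' @param eot_bins Tibble with columns `lo`, `hi`, `weight`; contiguous
#'   increasing bins of EOT minutes.
#' @param anesthesia_weights Named probabilities for codes A-D.
#' @param risk_prevalence Named per-risk marginal probabilities
#'   (independent draws).
#' @param same_building_p Probability the ward is in the theatre's building.
#' @param prep_room_p Probability a C/D case elects the preparation room.
#' @param destination_p Named probabilities over exit destinations.
#' @param eot_cap Upper bound of the open-ended EOT bin, minutes.
#' @return A list of class `case_mix_spec`.
#' @export
case_mix_spec <- function(
    specialty_weights = c(
      "Maxillo-Facial Plastic" = 551, "Otolaryngology" = 29, "General" = 286,
      "Neurosurgery" = 89, "Urology" = 1447, "Neonatal" = 82,
      "Orthopedy" = 106, "Gastrointestinal" = 457, "Hepatobiliary" = 65),
    urg_weights = c(AA = 173, A = 660, B = 736, C = 583, D = 960),
    eot_bins = tibble(
      lo = c(0, 30, 60, 90, 120, 150),
      hi = c(30, 60, 90, 120, 150, NA),
      weight = c(383, 769, 593, 435, 273, 659)),
    anesthesia_weights = c(A = 0.25, B = 0.40, C = 0.25, D = 0.10),
    risk_prevalence = setNames(rep(0.05, 8), default_risk_table()$name),
    same_building_p = 0.75,
    prep_room_p = 0.5,
    destination_p = c(ward = 0.15, recovery_room = 0.75, intensive_care = 0.10),
    eot_cap = 360) {
  spec <- list(specialty_weights = specialty_weights,
               urg_weights = urg_weights,
               eot_bins = as_tibble(eot_bins),
               anesthesia_weights = anesthesia_weights,
               risk_prevalence = risk_prevalence,
               same_building_p = same_building_p,
               prep_room_p = prep_room_p,
               destination_p = destination_p,
               eot_cap = eot_cap)
  validate_case_mix(spec)
  structure(spec, class = "case_mix_spec")
}

validate_case_mix <- function(spec) {
  check_weights <- function(w, what) {
    if (length(w) == 0 || anyNA(w) || any(w < 0) || sum(w) <= 0) {
      abort(sprintf("%s must be nonnegative with at least one positive entry", what))
    }
  }
  check_weights(spec$specialty_weights, "specialty_weights")
  check_weights(spec$urg_weights, "urg_weights")
  check_weights(spec$anesthesia_weights, "anesthesia_weights")
  check_weights(spec$eot_bins$weight, "eot bin weights")
  bins <- spec$eot_bins
  hi <- ifelse(is.na(bins$hi), spec$eot_cap, bins$hi)
  if (any(hi <= bins$lo)) abort("eot bins must be increasing")
  if (nrow(bins) > 1 && any(bins$lo[-1] != hi[-nrow(bins)])) {
    abort("eot bins must be contiguous")
  }
  if (any(spec$risk_prevalence < 0 | spec$risk_prevalence > 1)) {
    abort("risk prevalences must be probabilities")
  }
  check_weights(spec$destination_p, "destination_p")
  invisible(spec)
}

#' Generate synthetic patients
#'
#' Draws `n` patients from a case-mix specification: specialty, URG class
#' and EOT bin independently by weight, EOT uniform (integer minutes)
#' within its bin, anesthesia type by weight, each risk independently by
#' prevalence, and logistics flags by their probabilities.  Preparation-room
#' use is only ever drawn for anesthesia C/D.  Reproducible for a fixed
#' seed.
#'
#' @param n Number of patients (>= 0).
#' @param spec A [case_mix_spec()].
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param id_prefix Prefix for generated patient ids.
#' @return A tibble of patients with case-profile columns (no registration
#'   dates; see [generate_waiting_list()]).
#' @export
generate_patients <- function(n, spec = case_mix_spec(), seed = NULL,
                              id_prefix = "P") {
  validate_case_mix(spec)
  if (n == 0) {
    return(tibble(patient_id = character(0), specialty = character(0),
                  urg = character(0), eot_min = numeric(0),
                  anesthesia = character(0), risks = list(),
                  same_building = logical(0), use_prep_room = logical(0),
                  destination = character(0)))
  }
  with_seed_if(seed, {
    bins <- spec$eot_bins
    hi <- ifelse(is.na(bins$hi), spec$eot_cap, bins$hi)
    bin_idx <- sample.int(nrow(bins), n, replace = TRUE, prob = bins$weight)
    # integer minutes uniform in (lo, hi]
    width <- hi - bins$lo
    eot <- bins$lo[bin_idx] + floor(runif(n) * width[bin_idx]) + 1L
    anesthesia <- sample(names(spec$anesthesia_weights), n, replace = TRUE,
                         prob = spec$anesthesia_weights)
    risk_names <- names(spec$risk_prevalence)
    risk_draw <- matrix(runif(n * length(risk_names)) < rep(spec$risk_prevalence,
                                                            each = n),
                        nrow = n)
    risks <- lapply(seq_len(n), function(i) risk_names[risk_draw[i, ]])
    tibble(
      patient_id = sprintf("%s%05d", id_prefix, seq_len(n)),
      specialty = sample(names(spec$specialty_weights), n, replace = TRUE,
                         prob = spec$specialty_weights),
      urg = sample(names(spec$urg_weights), n, replace = TRUE,
                   prob = spec$urg_weights),
      eot_min = as.numeric(eot),
      anesthesia = anesthesia,
      risks = risks,
      same_building = runif(n) < spec$same_building_p,
      use_prep_room = anesthesia %in% c("C", "D") & runif(n) < spec$prep_room_p,
      destination = sample(names(spec$destination_p), n, replace = TRUE,
                           prob = spec$destination_p)
    )
  })
}

#' Generate a synthetic waiting list
#'
#' Draws `size` patients and back-dates each registration uniformly over
#' `[0, max_wait_days]` of the patient's URG class, so that no patient has
#' yet exceeded the class's maximum acceptable wait at the reference date.
#'
#' @param size Number of patients on the list.
#' @param reference_date The list's "as of" date.
#' @inheritParams generate_patients
#' @param urg_table URG class table (maximum waits).
#' @return A [waiting_list()].
#' @export
#' @examples
#' wl <- generate_waiting_list(50, "2026-06-15", seed = 1)
#' nrow(wl)
generate_waiting_list <- function(size, reference_date,
                                  spec = case_mix_spec(), seed = NULL,
                                  urg_table = default_urg_classes()) {
  reference_date <- as.Date(reference_date)
  with_seed_if(seed, {
    patients <- generate_patients(size, spec)
    if (size > 0) {
      max_wait <- urg_table$max_wait_days[match(patients$urg, urg_table$code)]
      patients$registration_date <-
        reference_date - as.integer(floor(runif(size) * (max_wait + 1L)))
    } else {
      patients$registration_date <- as.Date(character(0))
    }
    waiting_list(patients, reference_date, urg_table = urg_table)
  })
}

#' Generate a weekly arrival stream
#'
#' New registrations arriving after a reference date: weekly counts are
#' Poisson at `rate_per_week` (default the annual case load spread evenly,
#' 3112/52 ~ 60 per week) and registration dates are uniform within each
#' week.
#'
#' @param rate_per_week Mean arrivals per week (>= 0).
#' @param n_weeks Number of weeks to generate.
#' @param start_date First day of the first week.
#' @inheritParams generate_patients
#' @return A patient tibble with `registration_date`, sorted by date.
#' @export
generate_arrivals <- function(rate_per_week = 3112 / 52, n_weeks,
                              start_date, spec = case_mix_spec(),
                              seed = NULL, id_prefix = "N") {
  start_date <- as.Date(start_date)
  with_seed_if(seed, {
    counts <- rpois(n_weeks, rate_per_week)
    total <- sum(counts)
    patients <- generate_patients(total, spec, id_prefix = id_prefix)
    if (total > 0) {
      week_of <- rep(seq_len(n_weeks), counts)
      patients$registration_date <- start_date + 7L * (week_of - 1L) +
        as.integer(floor(runif(total) * 7))
      patients <- patients[order(patients$registration_date,
                                 patients$patient_id), ]
    } else {
      patients$registration_date <- as.Date(character(0))
    }
    patients
  })
}
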
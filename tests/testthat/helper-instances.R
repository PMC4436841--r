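# Builders for small scheduling instances used across tests.

# A dated block table built directly (no weekly template), one block per
# (date, room) pair given.
make_blocks <- function(dates, specialties, rooms = NULL, duration = 360,
                        session = "morning") {
  dates <- as.Date(dates)
  n <- length(dates)
  rooms <- rooms %||% paste0("OR", seq_len(n))
  tibble::tibble(
    block_id = sprintf("%s_%s_%s", format(dates), rooms,
                       ifelse(session == "morning", "AM", "PM")),
    room = rooms,
    date = dates,
    week_start = dates - (as.integer(format(dates, "%u")) - 1L),
    weekday = format(dates, "%a"),
    session = session,
    start_time = "08:00",
    duration_min = duration,
    specialty = rep_len(specialties, n)
  )
}

# Patients with explicit control over the scheduling-relevant fields; the
# pathway fields default to a plain case (anesthesia A, no risks) so that
# occupation load = eot + 50.
make_patients <- function(eot, specialty = "General", urg = "B",
                          registration_date = "2026-06-01",
                          anesthesia = "A", destination = "recovery_room",
                          ids = NULL) {
  n <- length(eot)
  tibble::tibble(
    patient_id = ids %||% sprintf("T%03d", seq_len(n)),
    specialty = rep_len(specialty, n),
    urg = rep_len(urg, n),
    registration_date = as.Date(rep_len(registration_date, n)),
    eot_min = eot,
    anesthesia = rep_len(anesthesia, n),
    risks = replicate(n, character(0), simplify = FALSE),
    same_building = TRUE,
    use_prep_room = FALSE,
    destination = rep_len(destination, n)
  )
}

# Random tiny instance for oracle-equivalence checks: <= `max_pat` patients,
# <= `max_blk` blocks over at most two specialties.
random_tiny_instance <- function(seed, max_pat = 8, max_blk = 3) {
  withr::with_seed(seed, {
    n_pat <- sample(2:max_pat, 1)
    n_blk <- sample(1:max_blk, 1)
    specs <- c("General", "Urology")
    pts <- make_patients(
      eot = sample(30:240, n_pat, replace = TRUE),
      specialty = sample(specs, n_pat, replace = TRUE),
      urg = sample(c("AA", "A", "B", "C", "D"), n_pat, replace = TRUE),
      registration_date = as.Date("2026-06-01") +
        sample(0:20, n_pat, replace = TRUE)
    )
    blocks <- make_blocks(
      dates = as.Date("2026-07-20") + sample(0:4, n_blk, replace = TRUE),
      specialties = sample(specs, n_blk, replace = TRUE),
      rooms = paste0("OR", seq_len(n_blk))
    )
    cap <- sample(c(0.5, 0.75, 1), 1)
    list(patients = pts, blocks = blocks,
         phase = phase_config(1, 5, c("AA", "A", "B", "C", "D"),
                              cumulative_utilization_cap = cap))
  })
}
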
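#' Construct a waiting list
#'
#' A waiting list is a tibble of patients — one row per patient, with the
#' case-profile columns inlined — carrying a reference date as an attribute.
#' Registration dates may not lie after the reference date and patient ids
#' must be unique.
#'
#' @param patients A data frame with columns `patient_id`, `specialty`,
#'   `urg`, `registration_date` (Date), plus the case-profile columns
#'   `eot_min`, `anesthesia`, `risks`, `same_building`, `use_prep_room`,
#'   `destination`.
#' @param reference_date The "as of" date of the list.
#' @param specialties Allowed specialty names.
#' @param urg_table URG class table.
#' @return A tibble of class `waiting_list` with attribute `reference_date`.
#' @export
waiting_list <- function(patients, reference_date,
                         specialties = specialty_names(),
                         urg_table = default_urg_classes()) {
  patients <- as_tibble(patients)
  assert_columns(patients, c("patient_id", "specialty", "urg",
                             "registration_date"), "waiting list")
  reference_date <- as.Date(reference_date)
  patients$registration_date <- as.Date(patients$registration_date)
  if (anyDuplicated(patients$patient_id)) {
    abort("patient ids on a waiting list must be unique")
  }
  if (any(patients$registration_date > reference_date)) {
    abort("every registration_date must be on or before the reference date")
  }
  bad_spec <- setdiff(unique(patients$specialty), specialties)
  if (length(bad_spec) > 0) {
    abort(sprintf("unknown specialty name(s): %s", paste(bad_spec, collapse = ", ")))
  }
  bad_urg <- setdiff(unique(patients$urg), urg_table$code)
  if (length(bad_urg) > 0) {
    abort(sprintf("unknown URG class(es): %s", paste(bad_urg, collapse = ", ")))
  }
  patients$risks <- as_risk_list(patients$risks)
  validate_case_profiles(patients)
  structure(patients,
            reference_date = reference_date,
            class = c("waiting_list", class(patients)))
}

#' Reference date of a waiting list
#' @param x A `waiting_list`.
#' @return A Date.
#' @export
reference_date <- function(x) {
  rd <- attr(x, "reference_date")
  if (is.null(rd)) abort("object carries no reference_date attribute")
  rd
}

#' Need Adjusted Waiting Days
#'
#' The waiting cost of each patient at a given date: the urgency coefficient
#' of the patient's URG class multiplied by the elapsed waiting time in
#' whole calendar days.  NAWD is the objective currency of the block
#' assignment model.
#'
#' @param patients A patient tibble with `urg` and `registration_date`.
#' @param at_date Date at which to evaluate the waiting cost.
#' @param urg_table URG class table supplying the coefficients.
#' @return The input tibble with columns `elapsed_days` and `nawd` added.
#' @export
#' @examples
#' p <- tibble::tibble(patient_id = "P1", urg = "B",
#'                     registration_date = as.Date("2026-01-01"))
#' nawd(p, as.Date("2026-01-31"))  # 6 * 30 = 180 NAWD
nawd <- function(patients, at_date, urg_table = default_urg_classes()) {
  patients <- as_tibble(patients)
  assert_columns(patients, c("urg", "registration_date"), "patient table")
  validate_urg_table(urg_table)
  at_date <- as.Date(at_date)
  if (any(as.Date(patients$registration_date) > at_date)) {
    abort("at_date precedes a registration_date: elapsed wait would be negative")
  }
  coef <- urg_table$urgency_coefficient[match(patients$urg, urg_table$code)]
  patients$elapsed_days <- days_between(patients$registration_date, at_date)
  patients$nawd <- coef * patients$elapsed_days
  patients
}

#' Patients eligible for a planning phase
#'
#' Filters a waiting list to the URG classes admitted by a phase, ordered
#' stably by urgency (most urgent first), then registration date, then
#' patient id.
#'
#' @param patients A waiting list or patient tibble.
#' @param phase_urgs Character vector of admitted URG codes.
#' @param urg_table URG class table (defines the priority order).
#' @return The eligible subset, reordered.
#' @export
eligible_patients <- function(patients, phase_urgs,
                              urg_table = default_urg_classes()) {
  patients <- as_tibble(patients)
  assert_columns(patients, c("urg", "registration_date", "patient_id"),
                 "patient table")
  out <- patients[patients$urg %in% phase_urgs, , drop = FALSE]
  prio <- match(out$urg, urg_table$code)
  out[order(prio, as.Date(out$registration_date), out$patient_id), , drop = FALSE]
}

# ---- CSV interchange ------------------------------------------------------

#' Read or write a waiting list as CSV
#'
#' The interchange dialect has one row per patient and columns `patient_id`,
#' `specialty`, `urg`, `registration_date` (ISO-8601), `eot_min`,
#' `anesthesia`, `risks` (";"-separated names, empty for none),
#' `same_building`, `use_prep_room`, `destination`.  Reading is strict:
#' malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @param reference_date Reference date for the resulting list; defaults to
#'   the latest registration date in the file.
#' @return `read_waiting_list()` returns a `waiting_list`;
#'   `write_waiting_list()` returns `path` invisibly.
#' @export
read_waiting_list <- function(path, reference_date = NULL) {
  spec <- readr::cols(
    patient_id = readr::col_character(),
    specialty = readr::col_character(),
    urg = readr::col_character(),
    registration_date = readr::col_date(format = "%Y-%m-%d"),
    eot_min = readr::col_double(),
    anesthesia = readr::col_character(),
    risks = readr::col_character(),
    same_building = readr::col_logical(),
    use_prep_room = readr::col_logical(),
    destination = readr::col_character()
  )
  df <- suppressWarnings(readr::read_csv(path, col_types = spec,
                                         progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    msg <- paste(sprintf("line %d, column %s: expected %s, got %s",
                         probs$row, probs$col, probs$expected, probs$actual),
                 collapse = "\n")
    abort(paste0("malformed waiting-list CSV:\n", msg))
  }
  missing <- setdiff(names(spec$cols), names(df))
  if (length(missing) > 0) {
    abort(sprintf("waiting-list CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- which(is.na(df$registration_date) | is.na(df$eot_min) |
                 is.na(df$patient_id))
  if (length(bad) > 0) {
    abort(sprintf("waiting-list CSV has missing required values on line(s): %s",
                  paste(bad + 1L, collapse = ", ")))
  }
  waiting_list(df, reference_date %||% max(df$registration_date))
}

#' @rdname read_waiting_list
#' @param patients Patient tibble or `waiting_list` to serialise.
#' @export
write_waiting_list <- function(patients, path) {
  out <- as_tibble(patients)
  assert_columns(out, c("patient_id", "specialty", "urg", "registration_date",
                        "eot_min", "anesthesia", "risks", "same_building",
                        "use_prep_room", "destination"), "waiting list")
  out$risks <- risk_string(out$risks)
  cols <- c("patient_id", "specialty", "urg", "registration_date", "eot_min",
            "anesthesia", "risks", "same_building", "use_prep_room",
            "destination")
  readr::write_csv(out[cols], path)
  invisible(path)
}
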
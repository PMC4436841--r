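#' Validate a table of case profiles
#'
#' A case profile describes one patient's surgical characteristics: the
#' surgeon-declared Expected Operating Time (EOT), anesthesia type, systemic
#' risks, logistics (same-building ward, preparation-room use) and exit
#' destination.  All pathway durations derive from these fields.
#'
#' @param cases A data frame with columns `eot_min` (minutes, > 0),
#'   `anesthesia` ("A".."D"), `risks` (list-column of risk names or a
#'   ";"-separated string), `same_building` (logical), `use_prep_room`
#'   (logical; only allowed for anesthesia C/D), `destination` (one of
#'   "ward", "recovery_room", "intensive_care").
#' @param risk_table Risk incidence table; used to reject unknown risk names.
#' @return The input, invisibly, with `risks` normalised to a list-column.
#' @export
validate_case_profiles <- function(cases, risk_table = default_risk_table()) {
  assert_columns(cases, c("eot_min", "anesthesia", "risks", "same_building",
                          "use_prep_room", "destination"),
                 "case profile table")
  cases$risks <- as_risk_list(cases$risks)
  if (anyNA(cases$eot_min) || !all(cases$eot_min > 0)) {
    abort("eot_min must be positive for every case")
  }
  if (!all(cases$anesthesia %in% c("A", "B", "C", "D"))) {
    bad <- unique(setdiff(cases$anesthesia, c("A", "B", "C", "D")))
    abort(sprintf("unknown anesthesia code(s): %s", paste(bad, collapse = ", ")))
  }
  if (!all(cases$destination %in% c("ward", "recovery_room", "intensive_care"))) {
    abort("destination must be one of ward, recovery_room, intensive_care")
  }
  bad_prep <- cases$use_prep_room & !(cases$anesthesia %in% c("C", "D"))
  if (any(bad_prep)) {
    abort("use_prep_room is only allowed for anesthesia types C and D")
  }
  unknown <- setdiff(unique(unlist(cases$risks)), risk_table$name)
  if (length(unknown) > 0) {
    abort(sprintf("unknown risk name(s): %s", paste(unknown, collapse = ", ")))
  }
  invisible(cases)
}

# Phase multipliers for each case's risk set.  Returns a 3-column matrix
# (induction, operating, awakening).
risk_multipliers <- function(risk_list, risk_table,
                             combine = c("additive", "multiplicative")) {
  combine <- match.arg(combine)
  lut <- as.matrix(risk_table[c("induction_pct", "operating_pct", "awakening_pct")])
  rownames(lut) <- risk_table$name
  out <- vapply(risk_list, function(r) {
    if (length(r) == 0) return(c(1, 1, 1))
    frac <- lut[r, , drop = FALSE] / 100
    if (combine == "additive") 1 + colSums(frac) else apply(1 + frac, 2, prod)
  }, numeric(3))
  out <- t(out)
  dimnames(out) <- NULL
  out
}

#' Risk-adjusted induction, operating and awakening times
#'
#' Applies each case's risk incidences to the three risk-sensitive phase
#' durations.  The base times are the anesthesia-type induction and emergence
#' task durations and the surgeon's EOT; a risk with incidence p% inflates a
#' phase by p/100.  Multiple risks combine additively in the multiplier by
#' default, `time * (1 + sum(p_i)/100)`, an order-independent rule; a
#' compounding `multiplicative` rule, `time * prod(1 + p_i/100)`, is
#' available as an option.
#'
#' @param cases Case profile table (see [validate_case_profiles()]).
#' @param risk_table Risk incidence table; defaults to [default_risk_table()].
#' @param anesthesia_table Anesthesia parameter table.
#' @param combine Risk combination rule, "additive" (default) or
#'   "multiplicative".
#' @param adjust_eot If FALSE, operating-time incidences are ignored on the
#'   assumption that the surgeon's declared EOT already accounts for the
#'   patient's risks; induction and awakening are still adjusted.
#' @return The input tibble with columns `induction_min`, `operating_min`,
#'   `awakening_min` added (exact fractional minutes, no rounding).
#' @export
#' @examples
#' cases <- tibble::tibble(
#'   eot_min = 30, anesthesia = "A", risks = list("Premature"),
#'   same_building = TRUE, use_prep_room = FALSE, destination = "recovery_room"
#' )
#' adjusted_phase_times(cases)
adjusted_phase_times <- function(cases,
                                 risk_table = default_risk_table(),
                                 anesthesia_table = default_anesthesia_profiles(),
                                 combine = c("additive", "multiplicative"),
                                 adjust_eot = TRUE) {
  combine <- match.arg(combine)
  cases <- as_tibble(cases)
  cases$risks <- as_risk_list(cases$risks)
  validate_case_profiles(cases, risk_table)
  an <- anesthesia_table[match(cases$anesthesia, anesthesia_table$code), ]
  mult <- risk_multipliers(cases$risks, risk_table, combine)
  cases$induction_min <- an$anesthesia_task_min * mult[, 1]
  cases$operating_min <- cases$eot_min * (if (adjust_eot) mult[, 2] else 1)
  cases$awakening_min <- an$end_anesthesia_task_min * mult[, 3]
  cases
}

#' Operating-theatre occupation time
#'
#' The full interval a case holds the theatre: entering the theatre,
#' risk-adjusted induction, surgery and emergence, the exit transfer, and
#' the anesthesia-type-specific preparation-and-cleaning time.  This is the
#' duration charged against OR block capacity; it always exceeds the bare
#' EOT.  A direct-to-ward exit is charged the recovery-room exit time (the
#' smaller of the two printed exit transfers; configurable via
#' `ward_exit_min`).
#'
#' @inheritParams adjusted_phase_times
#' @param timings Ancillary task timing table ([default_task_timings()]).
#' @param ward_exit_min Exit-transfer minutes charged for destination
#'   "ward"; defaults to the recovery-room exit time.
#' @return The input tibble with an `occupation_min` column added (plus the
#'   adjusted phase-time columns).
#' @export
#' @examples
#' cases <- tibble::tibble(
#'   eot_min = 30, anesthesia = "A", risks = list(character(0)),
#'   same_building = TRUE, use_prep_room = FALSE, destination = "recovery_room"
#' )
#' or_occupation_time(cases)$occupation_min  # 80 minutes
or_occupation_time <- function(cases,
                               risk_table = default_risk_table(),
                               anesthesia_table = default_anesthesia_profiles(),
                               timings = default_task_timings(),
                               combine = c("additive", "multiplicative"),
                               adjust_eot = TRUE,
                               ward_exit_min = timings$exit_to_recovery_min) {
  validate_task_timings(timings)
  cases <- adjusted_phase_times(cases, risk_table, anesthesia_table,
                                combine, adjust_eot)
  an <- anesthesia_table[match(cases$anesthesia, anesthesia_table$code), ]
  exit_min <- dplyr::case_when(
    cases$destination == "intensive_care" ~ timings$exit_to_icu_min,
    cases$destination == "recovery_room"  ~ timings$exit_to_recovery_min,
    TRUE                                  ~ ward_exit_min
  )
  cases$occupation_min <- timings$enter_theatre_min +
    cases$induction_min + cases$operating_min + cases$awakening_min +
    exit_min + an$prep_cleaning_min
  cases
}

#' Total ward-to-ward pathway time
#'
#' The patient's elapsed time from leaving the ward to returning to a bed:
#' transport in (same- or different-building), entering the operating
#' sector, the optional preparation-room task (anesthesia C/D when elected),
#' entering the theatre, the three risk-adjusted phases, the exit transfer,
#' and the destination branch — recovery-room stay plus ward transport,
#' transport to intensive care, or direct ward transport.  Theatre cleaning
#' is excluded: it extends block occupancy, not the patient's pathway.
#'
#' @inheritParams or_occupation_time
#' @return The input tibble with a `pathway_min` column added.
#' @export
#' @examples
#' cases <- tibble::tibble(
#'   eot_min = 60, anesthesia = "B", risks = list(character(0)),
#'   same_building = TRUE, use_prep_room = FALSE, destination = "recovery_room"
#' )
#' total_pathway_time(cases)$pathway_min  # 165 minutes
total_pathway_time <- function(cases,
                               risk_table = default_risk_table(),
                               anesthesia_table = default_anesthesia_profiles(),
                               timings = default_task_timings(),
                               combine = c("additive", "multiplicative"),
                               adjust_eot = TRUE,
                               ward_exit_min = timings$exit_to_recovery_min) {
  validate_task_timings(timings)
  cases <- adjusted_phase_times(cases, risk_table, anesthesia_table,
                                combine, adjust_eot)
  an <- anesthesia_table[match(cases$anesthesia, anesthesia_table$code), ]

  transport_in <- ifelse(cases$same_building,
                         timings$transport_same_building_min,
                         timings$transport_diff_building_min)
  prep_room <- ifelse(cases$use_prep_room,
                      dplyr::coalesce(an$prep_room_task_min, 0), 0)
  exit_min <- dplyr::case_when(
    cases$destination == "intensive_care" ~ timings$exit_to_icu_min,
    cases$destination == "recovery_room"  ~ timings$exit_to_recovery_min,
    TRUE                                  ~ ward_exit_min
  )
  ward_transport <- ifelse(cases$same_building,
                           timings$transport_ward_same_min,
                           timings$transport_ward_diff_min)
  branch <- dplyr::case_when(
    cases$destination == "recovery_room"  ~ timings$recovery_stay_min + ward_transport,
    cases$destination == "intensive_care" ~ timings$transport_icu_min,
    TRUE                                  ~ ward_transport
  )

  cases$pathway_min <- transport_in + timings$enter_sector_min + prep_room +
    timings$enter_theatre_min +
    cases$induction_min + cases$operating_min + cases$awakening_min +
    exit_min + branch
  cases
}
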
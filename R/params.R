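#' Anesthesia type parameter table
#'
#' The four anesthesia types used throughout the pathway model.  Type A is
#' mask / no-intubation anesthesia; B is general anesthesia with intubation;
#' C adds one ancillary procedure (e.g. a central venous or epidural
#' catheter) and D more than one.  The preparation room is never used for
#' A and B and is optional (surgeon's decision) for C and D.
#'
#' Columns:
#' \describe{
#'   \item{code}{"A", "B", "C", "D".}
#'   \item{intubation}{logical; FALSE only for A.}
#'   \item{uses_prep_room}{"never" (A, B) or "optional" (C, D).}
#'   \item{induction_staff, operating_staff, recovery_staff}{anesthesiologist
#'     head counts during induction, surgery and recovery.}
#'   \item{anesthesia_task_min}{duration of the induction task (A = 10,
#'     B/C/D = 15 minutes).}
#'   \item{end_anesthesia_task_min}{duration of the emergence task (A = 10,
#'     B/C/D = 15 minutes).}
#'   \item{prep_room_task_min}{preparation-room task duration (C = 30,
#'     D = 45 minutes; NA for A and B, which never use it).}
#'   \item{prep_cleaning_min}{combined patient-preparation and theatre
#'     cleaning time charged to block occupancy (15/20/40/60 minutes).}
#'   \item{table6_induction_min}{the aggregate induction time printed in the
#'     staffing table (10/15/30/45); reference metadata only — pathway
#'     assembly uses the task-level decomposition.}
#' }
#'
#' @return A tibble with one row per anesthesia code.
#' @export
#' @examples
#' default_anesthesia_profiles()
default_anesthesia_profiles <- function() {
  tribble(
    ~code, ~intubation, ~uses_prep_room, ~induction_staff, ~operating_staff,
    ~recovery_staff, ~anesthesia_task_min, ~end_anesthesia_task_min,
    ~prep_room_task_min, ~prep_cleaning_min, ~table6_induction_min,
    "A", FALSE, "never",    1L, 1L, 1L, 10, 10, NA_real_, 15, 10,
    "B", TRUE,  "never",    1L, 1L, 1L, 15, 15, NA_real_, 20, 15,
    "C", TRUE,  "optional", 2L, 1L, 1L, 15, 15, 30,       40, 30,
    "D", TRUE,  "optional", 2L, 2L, 1L, 15, 15, 45,       60, 45
  )
}

#' Systemic risk incidence table
#'
#' Patient risk conditions and their percentage incidence on the induction,
#' operating and awakening phase durations.  A percentage p inflates the
#' phase time by a factor depending on the combination rule (see
#' [adjusted_phase_times()]).  Transport and ancillary task times are never
#' risk-adjusted.
#'
#' @return A tibble with columns `name`, `induction_pct`, `operating_pct`,
#'   `awakening_pct`.
#' @export
#' @examples
#' default_risk_table()
default_risk_table <- function() {
  tribble(
    ~name,                    ~induction_pct, ~operating_pct, ~awakening_pct,
    "Premature",              25,  0, 25,
    "Baby",                   25,  0,  0,
    "HeartDisease",          100,  0, 50,
    "Coagulopathy",           50, 50,  0,
    "PsychoMotorPathology",   50,  0, 50,
    "Allergies",              25,  0, 25,
    "ParticularSyndromes",    25,  0, 25,
    "NeuromuscularPathology", 25,  0, 25
  )
}

#' Ancillary task timing table
#'
#' Fixed execution times, in minutes, for the transport and transfer tasks of
#' the surgical pathway.  Anesthesia-dependent tasks (induction, emergence,
#' preparation room, cleaning) live in [default_anesthesia_profiles()].
#'
#' @return A one-row tibble of task durations in minutes.
#' @export
default_task_timings <- function() {
  tibble(
    transport_same_building_min = 10,
    transport_diff_building_min = 20,
    enter_sector_min            = 10,
    enter_theatre_min           = 10,
    exit_to_icu_min             = 10,
    exit_to_recovery_min        = 5,
    recovery_stay_min           = 30,
    transport_icu_min           = 10,
    transport_ward_same_min     = 10,
    transport_ward_diff_min     = 20
  )
}

#' Urgency Related Group (URG) table
#'
#' The five clinical priority classes, from most urgent (AA) to least (D).
#' Each class carries a maximum acceptable wait and an urgency coefficient;
#' a patient's waiting cost in Need Adjusted Waiting Days (NAWD) is
#' coefficient x elapsed waiting days.  The numeric coefficients are a
#' configuration convention — the inverse-of-maximum-wait construction,
#' coefficient = 360 / max_wait_days — not empirical estimates; every
#' scheduling property in the package is coefficient-agnostic.
#'
#' @return A tibble with columns `code`, `max_wait_days`,
#'   `urgency_coefficient`, ordered AA, A, B, C, D.
#' @export
#' @examples
#' default_urg_classes()
default_urg_classes <- function() {
  tibble(
    code = c("AA", "A", "B", "C", "D"),
    max_wait_days = c(15, 30, 60, 180, 360),
    urgency_coefficient = 360 / c(15, 30, 60, 180, 360)
  )
}

#' Surgical specialty names
#'
#' The nine subspecialties sharing the three-room elective operating area.
#'
#' @return A character vector of specialty names.
#' @export
specialty_names <- function() {
  c("Maxillo-Facial Plastic", "Otolaryngology", "General", "Neurosurgery",
    "Urology", "Neonatal", "Orthopedy", "Gastrointestinal", "Hepatobiliary")
}

# ---- validation -----------------------------------------------------------

validate_anesthesia_profiles <- function(profiles) {
  assert_columns(profiles, names(default_anesthesia_profiles()),
                 "anesthesia profile table")
  if (!setequal(profiles$code, c("A", "B", "C", "D"))) {
    abort("anesthesia profile table must define exactly codes A, B, C, D")
  }
  if (profiles$intubation[profiles$code == "A"]) {
    abort("anesthesia type A must not use intubation")
  }
  if (!all(profiles$intubation[profiles$code != "A"])) {
    abort("anesthesia types B, C, D must use intubation")
  }
  expected_prep <- c(A = "never", B = "never", C = "optional", D = "optional")
  if (!all(profiles$uses_prep_room == expected_prep[profiles$code])) {
    abort("preparation room use must be 'never' for A/B and 'optional' for C/D")
  }
  dur <- c("anesthesia_task_min", "end_anesthesia_task_min", "prep_cleaning_min")
  if (!all(as.matrix(profiles[dur]) > 0)) {
    abort("anesthesia task durations must all be positive")
  }
  prep <- profiles$prep_room_task_min[profiles$code %in% c("C", "D")]
  if (anyNA(prep) || !all(prep > 0)) {
    abort("preparation-room task durations for C and D must be positive")
  }
  staff <- c("induction_staff", "operating_staff", "recovery_staff")
  if (!all(as.matrix(profiles[staff]) >= 1)) {
    abort("staff head counts must be at least 1")
  }
  invisible(profiles)
}

validate_risk_table <- function(risks) {
  assert_columns(risks, c("name", "induction_pct", "operating_pct", "awakening_pct"),
                 "risk table")
  if (anyDuplicated(risks$name)) abort("risk names must be unique")
  pct <- as.matrix(risks[c("induction_pct", "operating_pct", "awakening_pct")])
  if (anyNA(pct) || !all(pct >= 0)) {
    abort("risk incidence percentages must be nonnegative")
  }
  invisible(risks)
}

validate_task_timings <- function(timings) {
  assert_columns(timings, names(default_task_timings()), "task timing table")
  if (!all(as.matrix(timings[names(default_task_timings())]) > 0)) {
    abort("task timings must all be positive")
  }
  invisible(timings)
}

validate_urg_table <- function(urg_table) {
  assert_columns(urg_table, c("code", "max_wait_days", "urgency_coefficient"),
                 "URG table")
  urg_table <- urg_table[match(c("AA", "A", "B", "C", "D"), urg_table$code), ]
  if (anyNA(urg_table$code)) {
    abort("URG table must define exactly classes AA, A, B, C, D")
  }
  if (any(diff(urg_table$urgency_coefficient) >= 0)) {
    abort("urgency coefficients must strictly decrease along AA > A > B > C > D")
  }
  if (any(diff(urg_table$max_wait_days) <= 0)) {
    abort("maximum waits must strictly increase along AA < A < B < C < D")
  }
  invisible(urg_table)
}

# ---- YAML round trip ------------------------------------------------------

#' Read a parameter table from YAML
#'
#' Parameter tables (anesthesia profiles, risk incidences, task timings, URG
#' classes) can be supplied as YAML documents; the copies shipped under
#' `inst/extdata/` reproduce the package defaults.  Each document is a list
#' of records (or a single mapping for the task-timing table) and is schema-
#' validated on load.
#'
#' @param path Path to a YAML file.
#' @param what One of "anesthesia", "risks", "task_timings", "urg_classes".
#' @return A validated tibble in the layout of the corresponding
#'   `default_*()` constructor.
#' @export
#' @examples
#' read_parameter_table(
#'   system.file("extdata", "risk_table.yaml", package = "theatreplan"),
#'   "risks"
#' )
read_parameter_table <- function(path,
                                 what = c("anesthesia", "risks",
                                          "task_timings", "urg_classes")) {
  what <- match.arg(what)
  raw <- yaml::read_yaml(path)
  df <- switch(what,
    task_timings = as_tibble(raw),
    {
      rows <- lapply(raw, function(r) {
        as_tibble(lapply(r, function(x) if (is.null(x)) NA else x))
      })
      bind_rows(rows)
    }
  )
  switch(what,
    anesthesia   = validate_anesthesia_profiles(df),
    risks        = validate_risk_table(df),
    task_timings = validate_task_timings(df),
    urg_classes  = validate_urg_table(df)
  )
  df
}
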
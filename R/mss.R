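#' Default weekly Master Surgical Schedule template
#'
#' The cyclic weekly grid assigning surgical specialties to OR block times:
#' three rooms, Monday to Friday, a 360-minute morning session (08:00-14:00)
#' and a 360-minute afternoon session (14:00-20:00), each labelled with
#' exactly one specialty (block booking: a block is never shared between
#' subspecialties).  The default reproduces the studied unit's weekly
#' assignment; 180 OR hours per week in total.
#'
#' @return A tibble with columns `room`, `weekday` ("Mon".."Fri"),
#'   `session` ("morning"/"afternoon"), `start_time`, `duration_min`,
#'   `specialty`.
#' @export
#' @examples
#' dplyr::count(default_mss_template(), specialty)
default_mss_template <- function() {
  grid <- tribble(
    ~room,  ~session,    ~Mon, ~Tue, ~Wed, ~Thu, ~Fri,
    "OR1", "morning",   "Maxillo-Facial Plastic", "Otolaryngology",
                        "Neurosurgery", "Neurosurgery", "Maxillo-Facial Plastic",
    "OR1", "afternoon", "Neurosurgery", "Urology",
                        "Neurosurgery", "Urology", "Maxillo-Facial Plastic",
    "OR2", "morning",   "General", "Neonatal",
                        "Hepatobiliary", "Urology", "Orthopedy",
    "OR2", "afternoon", "General", "Neonatal",
                        "Hepatobiliary", "Urology", "Urology",
    "OR3", "morning",   "Urology", "Gastrointestinal",
                        "Orthopedy", "Neonatal", "Urology",
    "OR3", "afternoon", "Urology", "Orthopedy",
                        "Orthopedy", "General", "Urology"
  )
  long <- tidyr::pivot_longer(grid, cols = c("Mon", "Tue", "Wed", "Thu", "Fri"),
                              names_to = "weekday", values_to = "specialty")
  long$start_time <- ifelse(long$session == "morning", "08:00", "14:00")
  long$duration_min <- 360
  long <- long[order(long$room, match(long$weekday, weekday_levels()),
                     match(long$session, c("morning", "afternoon"))), ]
  long[, c("room", "weekday", "session", "start_time", "duration_min", "specialty")]
}

weekday_levels <- function() c("Mon", "Tue", "Wed", "Thu", "Fri")

validate_mss_template <- function(template, specialties = specialty_names()) {
  assert_columns(template, c("room", "weekday", "session", "duration_min",
                             "specialty"), "MSS template")
  if (!all(template$weekday %in% weekday_levels())) {
    abort("MSS template weekdays must be Mon..Fri (weekend blocks are not opened)")
  }
  if (!all(template$session %in% c("morning", "afternoon"))) {
    abort("MSS sessions must be 'morning' or 'afternoon'")
  }
  key <- paste(template$room, template$weekday, template$session)
  if (anyDuplicated(key)) {
    abort("an OR block cannot be shared: duplicate (room, weekday, session) in template")
  }
  bad <- setdiff(unique(template$specialty), specialties)
  if (length(bad) > 0) {
    abort(sprintf("unknown specialty in MSS template: %s", paste(bad, collapse = ", ")))
  }
  if (!all(template$duration_min > 0)) abort("block durations must be positive")
  invisible(template)
}

#' Expand a weekly MSS template over a planning horizon
#'
#' Repeats the weekly grid across `n_weeks` consecutive weeks starting at
#' the Monday of the week containing `start_date`, producing dated OR
#' blocks (Monday-Friday only).
#'
#' @param template Weekly grid, as from [default_mss_template()].
#' @param start_date Any date inside the first week.
#' @param n_weeks Number of weeks (>= 1 for a non-empty template).
#' @param specialties Allowed specialty names (template validation).
#' @return A tibble of blocks with columns `block_id`, `room`, `date`,
#'   `week_start`, `weekday`, `session`, `start_time`, `duration_min`,
#'   `specialty`.
#' @export
#' @examples
#' blocks <- expand_template(default_mss_template(), "2026-10-05", 1)
#' nrow(blocks)  # 30 blocks: 3 rooms x 5 days x 2 sessions
expand_template <- function(template, start_date, n_weeks,
                            specialties = specialty_names()) {
  template <- as_tibble(template)
  if (nrow(template) == 0 || n_weeks < 1) {
    return(tibble(block_id = character(0), room = character(0),
                  date = as.Date(character(0)), week_start = as.Date(character(0)),
                  weekday = character(0), session = character(0),
                  start_time = character(0), duration_min = numeric(0),
                  specialty = character(0)))
  }
  validate_mss_template(template, specialties)
  monday <- week_start(start_date)
  weeks <- tibble(week = seq_len(n_weeks),
                  week_start = monday + 7 * (seq_len(n_weeks) - 1L))
  out <- tidyr::crossing(weeks, template)
  out$date <- out$week_start + (match(out$weekday, weekday_levels()) - 1L)
  out$block_id <- sprintf("%s_%s_%s", format(out$date), out$room,
                          ifelse(out$session == "morning", "AM", "PM"))
  out <- out[order(out$date, out$room, match(out$session, c("morning", "afternoon"))), ]
  out[, c("block_id", "room", "date", "week_start", "weekday", "session",
          "start_time", "duration_min", "specialty")]
}

#' Weekly OR capacity per specialty
#'
#' Sums, for each specialty and week, the duration of the OR blocks the MSS
#' assigns to it 'a priori'.  This is the denominator of the per-specialty
#' utilisation caps: the moving-target phases fill each specialty's own
#' block time progressively (50/75/100 %), which prevents one specialty
#' cannibalising another's blocks.
#'
#' @param blocks Dated block tibble from [expand_template()].
#' @param specialty Optional single specialty to filter to (must be known).
#' @param week Optional week start (Monday) date to filter to.
#' @param specialties Full specialty list; specialties with no blocks report
#'   zero capacity.
#' @return A tibble with columns `specialty`, `week_start`, `capacity_min`.
#' @export
#' @examples
#' blocks <- expand_template(default_mss_template(), "2026-10-05", 1)
#' specialty_capacity(blocks, specialty = "Urology")$capacity_min  # 3240
specialty_capacity <- function(blocks, specialty = NULL, week = NULL,
                               specialties = specialty_names()) {
  blocks <- as_tibble(blocks)
  if (!is.null(specialty) && !specialty %in% specialties) {
    abort(sprintf("unknown specialty: %s", specialty))
  }
  weeks <- unique(blocks$week_start)
  grid <- tidyr::crossing(specialty_ = specialties,
                          week_start = as.Date(weeks))
  have <- blocks %>%
    group_by(specialty_ = .data$specialty, week_start = .data$week_start) %>%
    summarise(capacity_min = sum(.data$duration_min), .groups = "drop")
  out <- grid %>%
    left_join(have, by = c("specialty_", "week_start")) %>%
    mutate(capacity_min = dplyr::coalesce(.data$capacity_min, 0)) %>%
    rename(specialty = "specialty_") %>%
    arrange(.data$week_start, .data$specialty)
  if (!is.null(specialty)) out <- out[out$specialty == specialty, ]
  if (!is.null(week)) out <- out[out$week_start == as.Date(week), ]
  out
}

#' Read an MSS template from YAML
#'
#' The YAML layout is a mapping room -> weekday -> session -> specialty,
#' with optional top-level `duration_min` and `start_times`.  The copy
#' shipped under `inst/extdata/mss_template.yaml` reproduces the default
#' weekly grid.
#'
#' @param path Path to a YAML file.
#' @param specialties Allowed specialty names.
#' @return A validated template tibble (see [default_mss_template()]).
#' @export
read_mss_template <- function(path, specialties = specialty_names()) {
  raw <- yaml::read_yaml(path)
  duration <- raw$duration_min %||% 360
  starts <- raw$start_times %||% list(morning = "08:00", afternoon = "14:00")
  rooms <- raw$rooms
  if (is.null(rooms)) abort("MSS YAML must have a top-level 'rooms' mapping")
  rows <- list()
  for (room in names(rooms)) {
    for (wd in names(rooms[[room]])) {
      for (sess in names(rooms[[room]][[wd]])) {
        rows[[length(rows) + 1L]] <- tibble(
          room = room, weekday = wd, session = sess,
          start_time = starts[[sess]] %||% NA_character_,
          duration_min = duration,
          specialty = rooms[[room]][[wd]][[sess]]
        )
      }
    }
  }
  template <- bind_rows(rows)
  template <- template[order(template$room,
                             match(template$weekday, weekday_levels()),
                             match(template$session, c("morning", "afternoon"))), ]
  validate_mss_template(template, specialties)
  template
}
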
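#' Utilisation and throughput report for a schedule
#'
#' Double-entry accounting of a solved schedule against the MSS blocks it
#' was planned into: per-block occupied minutes and utilisation fraction,
#' per-specialty weekly scheduled load against MSS capacity, planned-patient
#' counts by URG class and by planning phase, and postponement/cancellation
#' totals.  No overtime is allowed by construction, so every utilisation
#' fraction lies in [0, 1].
#'
#' @param schedule An `or_schedule` (from [solve_phase()] or the `schedule`
#'   element of [plan_three_phase()]), or a `three_phase_plan`.
#' @param blocks The dated block tibble the schedule was solved against;
#'   defaults to the blocks stored in the schedule.  Supplying a different
#'   block set than the one the schedule references is an error.
#' @param open_blocks_only If TRUE (default), the summary utilisation rate
#'   averages over blocks with at least one scheduled patient; idle blocks
#'   are still listed per block either way.
#' @return A list of class `utilization_report` with tibbles `by_block`,
#'   `by_specialty`, `by_urg`, `by_phase` and a one-row `summary`.
#' @export
utilization_report <- function(schedule, blocks = NULL,
                               open_blocks_only = TRUE) {
  changelog <- NULL
  if (inherits(schedule, "three_phase_plan")) {
    changelog <- schedule$changelog
    blocks <- blocks %||% schedule$blocks
    schedule <- schedule$schedule
  }
  if (!inherits(schedule, "or_schedule")) {
    abort("utilization_report() expects an or_schedule or three_phase_plan")
  }
  blocks <- as_tibble(blocks %||% schedule$blocks)
  asg <- schedule$assignments
  planned <- asg[asg$status %in% c("planned", "postponed") &
                   !is.na(asg$block_id), ]
  if (nrow(planned) > 0 &&
      !all(planned$block_id %in% blocks$block_id)) {
    abort("schedule references blocks absent from the supplied MSS")
  }

  occ <- planned %>%
    group_by(block_id = .data$block_id) %>%
    summarise(occupied_min = sum(.data$load_min),
              n_patients = dplyr::n(), .groups = "drop")
  by_block <- blocks %>%
    left_join(occ, by = "block_id") %>%
    mutate(occupied_min = dplyr::coalesce(.data$occupied_min, 0),
           n_patients = dplyr::coalesce(.data$n_patients, 0L),
           utilization = .data$occupied_min / .data$duration_min) %>%
    select("block_id", "room", "date", "session", "specialty",
           "duration_min", "occupied_min", "n_patients", "utilization")
  if (any(by_block$utilization > 1 + 1e-9)) {
    abort("internal error: block utilisation above 1 (overtime is forbidden)")
  }

  cap <- specialty_capacity(blocks,
                            specialties = unique(c(specialty_names(),
                                                   blocks$specialty)))
  wk <- blocks$week_start[match(planned$block_id, blocks$block_id)]
  spec_load <- tibble(specialty = planned$specialty, week_start = wk,
                      load = planned$load_min) %>%
    group_by(.data$specialty, .data$week_start) %>%
    summarise(scheduled_min = sum(.data$load), .groups = "drop")
  by_specialty <- cap %>%
    left_join(spec_load, by = c("specialty", "week_start")) %>%
    mutate(scheduled_min = dplyr::coalesce(.data$scheduled_min, 0),
           utilization = ifelse(.data$capacity_min > 0,
                                .data$scheduled_min / .data$capacity_min, NA))

  by_urg <- planned %>% count(urg = .data$urg, name = "n_planned")
  by_phase <- planned %>% count(phase = .data$phase, name = "n_planned")

  open <- if (open_blocks_only) by_block[by_block$n_patients > 0, ] else by_block
  summary <- tibble(
    n_planned = nrow(planned),
    n_unscheduled = sum(asg$status == "unscheduled"),
    n_postponed = if (!is.null(changelog)) {
      sum(changelog$event == "postponed")
    } else sum(asg$status == "postponed"),
    n_cancelled = if (!is.null(changelog)) {
      length(setdiff(changelog$patient_id[changelog$event == "cancelled"],
                     planned$patient_id))
    } else sum(asg$status == "cancelled"),
    blocks_open = nrow(open),
    blocks_total = nrow(by_block),
    mean_utilization = if (nrow(open) > 0) mean(open$utilization) else 0,
    total_occupied_min = sum(by_block$occupied_min),
    total_capacity_min = sum(by_block$duration_min)
  )
  structure(list(by_block = by_block, by_specialty = by_specialty,
                 by_urg = by_urg, by_phase = by_phase, summary = summary),
            class = "utilization_report")
}

#' First-come first-served baseline schedule
#'
#' The open-booking comparator: patients are taken in registration order
#' (ties by patient id) and each is placed in the earliest compatible block
#' — same specialty, ordered by date, session, room — that still has room
#' for the patient's load.  Patients who fit nowhere are left unscheduled.
#' Deterministic, no urgency information, no utilisation caps.
#'
#' @param patients A waiting list or patient tibble.
#' @param blocks Dated block tibble from [expand_template()].
#' @inheritParams build_model
#' @return An `or_schedule`.
#' @export
fcfs_baseline <- function(patients, blocks, load = c("occupation", "eot"),
                          ...) {
  patients <- as_tibble(patients)
  blocks <- as_tibble(blocks)
  ord <- order(as.Date(patients$registration_date), patients$patient_id)
  pts <- patients[ord, ]
  pts$load_min <- patient_loads(pts, load, ...)
  bl <- blocks[order(blocks$date, match(blocks$session,
                                        c("morning", "afternoon")),
                     blocks$room), ]
  remaining <- bl$duration_min
  assigned <- rep(NA_character_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ok <- which(bl$specialty == pts$specialty[i] &
                  remaining >= pts$load_min[i])
    if (length(ok) > 0) {
      assigned[i] <- bl$block_id[ok[1]]
      remaining[ok[1]] <- remaining[ok[1]] - pts$load_min[i]
    }
  }
  asg <- pts[, c("patient_id", "specialty", "urg", "registration_date",
                 "load_min")]
  asg$block_id <- assigned
  asg$status <- ifelse(is.na(assigned), "unscheduled", "planned")
  asg$phase <- NA_integer_
  asg$prior_block <- NA_character_
  extra <- bl[match(asg$block_id, bl$block_id), c("room", "date", "session")]
  asg <- dplyr::bind_cols(asg, extra)
  structure(list(assignments = as_tibble(asg), blocks = blocks,
                 objective = NA_real_, phase = NA_integer_,
                 solver = list(backend = "fcfs")),
            class = "or_schedule")
}

#' Compare an optimised schedule against a baseline
#'
#' Throughput gain is the relative increase in planned patients,
#' `(planned_opt - planned_base) / planned_base * 100`; the utilisation
#' delta is the difference in mean open-block utilisation, in percentage
#' points.  Both schedules must have been planned against the same blocks.
#'
#' @param optimized,baseline `or_schedule` (or `three_phase_plan`) objects
#'   over the same waiting list and MSS.
#' @param open_blocks_only Passed to [utilization_report()].
#' @return A one-row tibble with planned counts, `throughput_gain_pct`
#'   (NA with a warning when the baseline plans nobody) and
#'   `utilization_delta_pp`.
#' @export
compare_schedules <- function(optimized, baseline, open_blocks_only = TRUE) {
  rep_opt <- utilization_report(optimized, open_blocks_only = open_blocks_only)
  rep_base <- utilization_report(baseline, open_blocks_only = open_blocks_only)
  if (!setequal(rep_opt$by_block$block_id, rep_base$by_block$block_id)) {
    abort("schedules were planned against different block sets")
  }
  n_opt <- rep_opt$summary$n_planned
  n_base <- rep_base$summary$n_planned
  gain <- if (n_base == 0) {
    warn("baseline plans no patients: throughput gain is undefined")
    NA_real_
  } else {
    (n_opt - n_base) / n_base * 100
  }
  tibble(
    planned_optimized = n_opt,
    planned_baseline = n_base,
    throughput_gain_pct = gain,
    mean_utilization_optimized = rep_opt$summary$mean_utilization,
    mean_utilization_baseline = rep_base$summary$mean_utilization,
    utilization_delta_pp = 100 * (rep_opt$summary$mean_utilization -
                                    rep_base$summary$mean_utilization)
  )
}
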
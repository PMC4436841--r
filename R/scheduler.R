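#' Planning phase configuration
#'
#' One stage of the moving-target framework.  Each phase runs a fixed
#' number of weeks before the target surgery week, admits a set of URG
#' classes (optionally with less-urgent "fill" classes when block space
#' allows), and may use each specialty's block time only up to a cumulative
#' utilisation cap.  The defaults follow the three-stage design: 5 weeks
#' ahead, URG B/C/D, 50 %; 3 weeks ahead, URG A (B/C/D as fill), 75 %;
#' 1 week ahead, URG AA, 100 %.
#'
#' Disruption penalties price changes to previously planned patients:
#' moving a patient to a different block costs `postpone_penalty`, dropping
#' a patient back to the waiting list costs `cancel_penalty` (cancel >>
#' postpone).  `NULL` penalties are resolved at model-build time to 1x and
#' 5x the median per-patient NAWD of the phase's candidates.  `Inf` makes
#' the corresponding change a hard constraint.
#'
#' @param index Phase number, 1-3.
#' @param weeks_ahead Weeks between this run and the target week.
#' @param eligible_urgs URG codes admitted with priority.
#' @param fill_urgs URG codes admitted as fill-ins (lower waiting cost, so
#'   they yield to the eligible classes whenever capacity binds).
#' @param cumulative_utilization_cap Fraction of each specialty's weekly
#'   block time usable after this phase.
#' @param postpone_penalty,cancel_penalty Nonnegative reals, `Inf`, or
#'   `NULL` (resolve from the candidate NAWD distribution).
#' @return A list of class `phase_config`.
#' @export
phase_config <- function(index, weeks_ahead, eligible_urgs,
                         fill_urgs = character(0),
                         cumulative_utilization_cap,
                         postpone_penalty = NULL, cancel_penalty = NULL) {
  stopifnot(index %in% 1:3, weeks_ahead >= 1,
            cumulative_utilization_cap > 0, cumulative_utilization_cap <= 1)
  if (!is.null(postpone_penalty) && postpone_penalty < 0) {
    abort("postpone_penalty must be nonnegative")
  }
  if (!is.null(cancel_penalty) && cancel_penalty < 0) {
    abort("cancel_penalty must be nonnegative")
  }
  structure(list(index = index, weeks_ahead = weeks_ahead,
                 eligible_urgs = eligible_urgs, fill_urgs = fill_urgs,
                 cumulative_utilization_cap = cumulative_utilization_cap,
                 postpone_penalty = postpone_penalty,
                 cancel_penalty = cancel_penalty),
            class = "phase_config")
}

#' @rdname phase_config
#' @export
default_phase_configs <- function() {
  list(
    phase_config(1, 5, c("B", "C", "D"), character(0), 0.50),
    phase_config(2, 3, "A", c("B", "C", "D"), 0.75),
    phase_config(3, 1, "AA", character(0), 1.00)
  )
}

validate_phase_configs <- function(phases) {
  caps <- vapply(phases, `[[`, numeric(1), "cumulative_utilization_cap")
  if (any(diff(caps) < 0)) {
    abort("cumulative utilisation caps must be nondecreasing across phases")
  }
  ahead <- vapply(phases, `[[`, numeric(1), "weeks_ahead")
  if (any(diff(ahead) >= 0)) {
    abort("phases must be ordered by decreasing weeks_ahead")
  }
  invisible(phases)
}

#' Read phase configurations from YAML
#'
#' A YAML list of phase mappings with the fields of [phase_config()];
#' `.inf` may be used for infinite penalties.
#'
#' @param path Path to a YAML file.
#' @return A list of `phase_config` objects.
#' @export
read_phase_configs <- function(path) {
  raw <- yaml::read_yaml(path)
  phases <- lapply(raw, function(p) {
    phase_config(p$index, p$weeks_ahead,
                 as.character(p$eligible_urgs),
                 as.character(p$fill_urgs %||% character(0)),
                 p$cumulative_utilization_cap,
                 p$postpone_penalty, p$cancel_penalty)
  })
  validate_phase_configs(phases)
  phases
}

# Per-patient load entering the block capacity constraint: the full OR
# occupation time (default) or the bare surgeon-declared EOT.
patient_loads <- function(patients, load = c("occupation", "eot"), ...) {
  load <- match.arg(load)
  if (load == "eot") return(patients$eot_min)
  or_occupation_time(patients, ...)$occupation_min
}

#' Build the 0-1 patient-to-block assignment model
#'
#' Emits a declarative model with a binary variable x[i, b] for every
#' (patient, compatible block) pair — compatible meaning the block's MSS
#' specialty equals the patient's — under three constraint families:
#' each patient is assigned at most once; each block's summed load may not
#' exceed its duration (no overtime); each specialty's scheduled load per
#' week may not exceed the phase's cumulative cap times that specialty's
#' MSS capacity.  The objective minimises total waiting cost: a patient
#' left unscheduled is charged their NAWD at the horizon end (one week past
#' the target week's last block, i.e. the earliest next planning
#' opportunity); a scheduled patient is charged coefficient x wait-to-block
#' date; prior-planned patients add the phase's postpone/cancel penalty
#' when moved or dropped.  Patients enter the model in canonical order
#' (earlier registration, then smaller id), and the MILP solver is
#' deterministic, so repeated solves of the same data return the same
#' schedule; waiting costs are exact integers (coefficient x whole days),
#' which the solver exploits when closing optimality bounds.
#'
#' @param patients Candidate patients (rows must include prior-planned
#'   patients being carried as soft constraints).
#' @param blocks Dated OR blocks of the target week ([expand_template()]).
#' @param phase A [phase_config()].
#' @param prior Optional tibble (`patient_id`, `block_id`) of assignments
#'   from the previous phase.
#' @param urg_table URG class table.
#' @param load Capacity load definition: "occupation" (default) or "eot".
#' @param horizon_extra_days Days past the last block date at which
#'   unscheduled patients' NAWD is charged.
#' @param ... Passed to [or_occupation_time()] (parameter tables).
#' @return A list of class `model_spec` (variables, loads, caps, objective
#'   constant).
#' @export
build_model <- function(patients, blocks, phase, prior = NULL,
                        urg_table = default_urg_classes(),
                        load = c("occupation", "eot"),
                        horizon_extra_days = 7, ...) {
  patients <- as_tibble(patients)
  blocks <- as_tibble(blocks)
  validate_urg_table(urg_table)
  if (nrow(blocks) == 0) abort("cannot build a model with no OR blocks")
  if (!is.null(prior) && nrow(prior) > 0) {
    missing_prior <- setdiff(prior$patient_id, patients$patient_id)
    if (length(missing_prior) > 0) {
      abort("prior-planned patients must be included among the candidates")
    }
    if (!all(prior$block_id %in% blocks$block_id)) {
      abort("prior assignments reference unknown blocks")
    }
  }

  horizon_end <- max(blocks$date) + horizon_extra_days
  pts <- nawd(patients, horizon_end, urg_table)
  pts$coef <- urg_table$urgency_coefficient[match(pts$urg, urg_table$code)]
  pts$load_min <- patient_loads(patients, load, ...)
  pts$prior_block <- NA_character_
  if (!is.null(prior) && nrow(prior) > 0) {
    pts$prior_block <- prior$block_id[match(pts$patient_id, prior$patient_id)]
  }

  med_nawd <- median(pts$nawd)
  postpone_pen <- phase$postpone_penalty %||% med_nawd
  cancel_pen <- phase$cancel_penalty %||% (5 * med_nawd)

  # canonical variable order: earlier registration, then smaller id.  The
  # waiting costs are integers (coefficient x whole days), which MILP
  # solvers exploit to round dual bounds; costs are therefore left exact
  # and unperturbed, and reproducibility comes from the deterministic
  # solver on a canonically ordered model.
  ord <- order(as.Date(pts$registration_date), pts$patient_id)
  pts <- pts[ord, ]
  n_pat <- nrow(pts)

  pts$forced <- !is.na(pts$prior_block) & is.infinite(cancel_pen)
  pts$fixed <- !is.na(pts$prior_block) & is.infinite(postpone_pen)
  # unscheduled cost; forced patients cannot be unscheduled
  pts$u_cost <- pts$nawd +
    ifelse(!is.na(pts$prior_block) & !pts$forced & is.finite(cancel_pen),
           cancel_pen, 0)

  vars <- tidyr::crossing(pi = seq_len(n_pat), bi = seq_len(nrow(blocks)))
  vars <- vars[pts$specialty[vars$pi] == blocks$specialty[vars$bi], ]
  # a patient fixed to a prior block (infinite postpone penalty) keeps only
  # that variable
  keep <- !pts$fixed[vars$pi] |
    blocks$block_id[vars$bi] == pts$prior_block[vars$pi]
  vars <- vars[keep, ]
  vars$patient_id <- pts$patient_id[vars$pi]
  vars$block_id <- blocks$block_id[vars$bi]
  moved <- !is.na(pts$prior_block[vars$pi]) &
    vars$block_id != pts$prior_block[vars$pi]
  wait <- days_between(pts$registration_date[vars$pi], blocks$date[vars$bi])
  if (any(wait < 0)) {
    abort("a candidate patient registers after the target week: check phase dates")
  }
  vars$cost <- pts$coef[vars$pi] * wait +
    ifelse(moved & is.finite(postpone_pen), postpone_pen, 0)

  unassignable <- pts$forced & !pts$patient_id %in% vars$patient_id
  if (any(unassignable)) {
    abort(sprintf("infeasible: prior-planned patient(s) %s have no admissible block",
                  paste(pts$patient_id[unassignable], collapse = ", ")))
  }

  caps <- specialty_capacity(blocks,
                             specialties = unique(c(specialty_names(),
                                                    blocks$specialty)))
  caps <- caps[caps$capacity_min > 0, ]
  caps$cap_min <- phase$cumulative_utilization_cap * caps$capacity_min

  structure(list(
    vars = as_tibble(vars[, c("pi", "bi", "patient_id", "block_id", "cost")]),
    patients = pts,
    blocks = blocks,
    caps = caps,
    const = sum(pts$u_cost[!pts$forced]),
    phase = phase,
    horizon_end = horizon_end,
    penalties = c(postpone = postpone_pen, cancel = cancel_pen)
  ), class = "model_spec")
}

# Assemble the sparse constraint system of a model_spec for the MILP
# backend.  Returns the problem list consumed by milp_solve_batch().
model_matrices <- function(model, gap = 1e-4, time_limit = 60) {
  vars <- model$vars
  pts <- model$patients
  n <- nrow(vars)
  obj <- vars$cost - ifelse(pts$forced[vars$pi], 0, pts$u_cost[vars$pi])

  ti <- list(); tj <- list(); tv <- list(); bub <- numeric(0)
  ei <- list(); ej <- list(); ev <- list(); beq <- numeric(0)
  row <- 0L; erow <- 0L

  add_ub <- function(idx, coefs, rhs) {
    row <<- row + 1L
    ti[[length(ti) + 1L]] <<- rep(row, length(idx))
    tj[[length(tj) + 1L]] <<- idx
    tv[[length(tv) + 1L]] <<- coefs
    bub[row] <<- rhs
  }

  for (p in seq_len(nrow(pts))) {
    idx <- which(vars$pi == p)
    if (length(idx) == 0) next
    if (pts$forced[p]) {
      erow <- erow + 1L
      ei[[length(ei) + 1L]] <- rep(erow, length(idx))
      ej[[length(ej) + 1L]] <- idx
      ev[[length(ev) + 1L]] <- rep(1, length(idx))
      beq[erow] <- 1
    } else {
      add_ub(idx, rep(1, length(idx)), 1)
    }
  }
  for (b in seq_len(nrow(model$blocks))) {
    idx <- which(vars$bi == b)
    if (length(idx) == 0) next
    add_ub(idx, pts$load_min[vars$pi[idx]], model$blocks$duration_min[b])
  }
  if (model$phase$cumulative_utilization_cap < 1) {
    for (g in seq_len(nrow(model$caps))) {
      in_group <- model$blocks$specialty[vars$bi] == model$caps$specialty[g] &
        model$blocks$week_start[vars$bi] == model$caps$week_start[g]
      idx <- which(in_group)
      if (length(idx) == 0) next
      add_ub(idx, pts$load_min[vars$pi[idx]], model$caps$cap_min[g])
    }
  }

  list(n = n, obj = obj,
       aub = list(i = unlist(ti) %||% integer(0),
                  j = unlist(tj) %||% integer(0),
                  v = unlist(tv) %||% numeric(0)),
       bub = bub,
       aeq = list(i = unlist(ei) %||% integer(0),
                  j = unlist(ej) %||% integer(0),
                  v = unlist(ev) %||% numeric(0)),
       beq = beq,
       mip_rel_gap = gap, time_limit = time_limit)
}

# Exhaustive depth-first enumeration over per-patient choices (unassigned or
# one compatible block) with capacity pruning.  Exact, but exponential:
# only for tiny models and cross-checks.
enumerate_model <- function(model) {
  vars <- model$vars
  pts <- model$patients
  n_pat <- nrow(pts)
  choices <- lapply(seq_len(n_pat), function(p) which(vars$pi == p))
  block_cap <- model$blocks$duration_min
  cap_key <- paste(model$blocks$specialty, model$blocks$week_start)
  cap_idx <- match(cap_key, paste(model$caps$specialty, model$caps$week_start))
  use_caps <- model$phase$cumulative_utilization_cap < 1
  cap_rem <- model$caps$cap_min

  best <- list(obj = Inf, pick = NULL)
  pick <- integer(n_pat)  # 0 = unassigned, else var index

  # admissible lower bound on the cost still to come: each remaining patient
  # pays at least its cheapest option, capacities ignored
  min_choice <- vapply(seq_len(n_pat), function(p) {
    cand <- vars$cost[choices[[p]]]
    if (!pts$forced[p]) cand <- c(cand, pts$u_cost[p])
    min(cand)
  }, numeric(1))
  suffix_lb <- rev(cumsum(rev(c(min_choice, 0))))

  recurse <- function(p, cost, brem, crem) {
    if (cost + suffix_lb[p] >= best$obj) return()
    if (p > n_pat) {
      best <<- list(obj = cost, pick = pick)
      return()
    }
    if (!pts$forced[p]) {
      pick[p] <<- 0L
      recurse(p + 1L, cost + pts$u_cost[p], brem, crem)
    }
    for (v in choices[[p]]) {
      b <- vars$bi[v]
      ld <- pts$load_min[p]
      if (brem[b] < ld) next
      crem2 <- crem
      if (use_caps) {
        g <- cap_idx[b]
        if (!is.na(g)) {
          if (crem[g] < ld) next
          crem2[g] <- crem[g] - ld
        }
      }
      brem2 <- brem
      brem2[b] <- brem[b] - ld
      pick[p] <<- v
      recurse(p + 1L, cost + vars$cost[v], brem2, crem2)
    }
    pick[p] <<- 0L
  }
  recurse(1L, 0, block_cap, cap_rem)
  if (!is.finite(best$obj)) {
    abort("infeasible: forced prior assignments exceed block capacity",
          class = "theatreplan_infeasible")
  }
  x <- numeric(nrow(vars))
  x[best$pick[best$pick > 0]] <- 1
  list(success = TRUE, objective = best$obj, x = as.list(x),
       status = 0L, message = "enumeration")
}

#' Solve an assignment model into a schedule
#'
#' Solves the 0-1 model to optimality (within the relative gap tolerance)
#' and decodes the solution into per-patient assignments with status
#' `planned` (in a block), `postponed` (prior-planned, moved to a different
#' block), `cancelled` (prior-planned, dropped back to the list) or
#' `unscheduled`.  The result is deterministic for a fixed model: HiGHS is
#' deterministic and the tie-break perturbation makes optima unique.
#'
#' @param model A `model_spec` from [build_model()].
#' @param backend "highs" (default; scipy/HiGHS via the bundled helper) or
#'   "enumerate" (exact exhaustive search, tiny models only).
#' @param gap Relative MIP gap tolerance.
#' @param time_limit Solver wall-clock limit in seconds (per specialty
#'   sub-model under the "highs" backend).
#' @param on_timeout What to do when a sub-model hits the time limit with a
#'   feasible incumbent: "error" (default) raises a
#'   `theatreplan_infeasible` condition; "incumbent" keeps the best
#'   feasible schedule found and records `proven_optimal = FALSE` in the
#'   solver statistics.
#' @return An `or_schedule`: assignments tibble, blocks, objective value
#'   and solver statistics.
#' @export
solve_phase <- function(model, backend = c("highs", "enumerate"),
                        gap = 1e-4, time_limit = 60,
                        on_timeout = c("error", "incumbent")) {
  solve_models(list(model), backend = backend, gap = gap,
               time_limit = time_limit, on_timeout = on_timeout)[[1]]
}

# Solve several model_specs in one MILP backend invocation.  Every model is
# first split into its independent per-specialty sub-models (blocks carry a
# single specialty and the utilisation caps are per specialty, so the
# constraint matrix is block-diagonal); all sub-problems across all models
# are then solved in a single subprocess call and reassembled.
solve_models <- function(models, backend = c("highs", "enumerate"),
                         gap = 1e-4, time_limit = 60,
                         on_timeout = c("error", "incumbent")) {
  backend <- match.arg(backend)
  on_timeout <- match.arg(on_timeout)
  t0 <- Sys.time()
  if (backend == "enumerate") {
    return(lapply(models, function(model) {
      res <- enumerate_model(model)
      decode_solution(model, res,
                      solver = list(backend = "enumerate",
                                    n_vars = nrow(model$vars)))
    }))
  }
  probs <- list()
  index <- list()  # (model k, var indices in model k) per sub-problem
  for (k in seq_along(models)) {
    model <- models[[k]]
    block_spec <- model$blocks$specialty[model$vars$bi]
    for (sp in unique(block_spec)) {
      vidx <- which(block_spec == sp)
      probs[[length(probs) + 1L]] <-
        model_matrices(submodel(model, vidx), gap, time_limit)
      index[[length(index) + 1L]] <- list(k = k, vidx = vidx)
    }
  }
  results <- milp_solve_batch(probs)
  xs <- lapply(models, function(m) numeric(nrow(m$vars)))
  proven <- rep(TRUE, length(models))
  for (s in seq_along(results)) {
    res <- results[[s]]
    timed_out <- !isTRUE(res$success) &&
      isTRUE((res$status %||% -1) == 1) && !is.null(res$x)
    if (timed_out && on_timeout == "incumbent") {
      # feasible but not proven optimal within the time limit: keep the
      # incumbent and record it as such
      proven[index[[s]]$k] <- FALSE
    } else if (!isTRUE(res$success)) {
      abort(paste0("solver did not reach a feasible optimum (status ",
                   res$status %||% NA, "): ", res$message %||% ""),
            class = "theatreplan_infeasible")
    }
    xs[[index[[s]]$k]][index[[s]]$vidx] <- as.numeric(unlist(res$x))
  }
  wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  lapply(seq_along(models), function(k) {
    decode_solution(models[[k]], list(x = xs[[k]]),
                    solver = list(backend = "highs",
                                  n_vars = nrow(models[[k]]$vars),
                                  gap = gap, proven_optimal = proven[k],
                                  wall_s = wall))
  })
}

# Restrict a model_spec to a subset of its variables (with the patients and
# blocks they touch), remapping indices.  Patients and blocks outside the
# subset do not constrain it.
submodel <- function(model, vidx) {
  pidx <- sort(unique(model$vars$pi[vidx]))
  bidx <- sort(unique(model$vars$bi[vidx]))
  vars <- model$vars[vidx, ]
  vars$pi <- match(vars$pi, pidx)
  vars$bi <- match(vars$bi, bidx)
  list(vars = vars,
       patients = model$patients[pidx, ],
       blocks = model$blocks[bidx, ],
       caps = model$caps,
       phase = model$phase)
}

decode_solution <- function(model, res, solver = list()) {
  vars <- model$vars
  pts <- model$patients
  x <- as.numeric(unlist(res$x))
  chosen <- vars[x > 0.5, ]
  if (anyDuplicated(chosen$patient_id)) {
    abort("internal error: a patient was assigned to more than one block")
  }
  asg <- pts[, c("patient_id", "specialty", "urg", "registration_date",
                 "load_min", "prior_block")]
  asg$block_id <- chosen$block_id[match(asg$patient_id, chosen$patient_id)]
  asg$status <- dplyr::case_when(
    !is.na(asg$block_id) & !is.na(asg$prior_block) &
      asg$block_id != asg$prior_block ~ "postponed",
    !is.na(asg$block_id) ~ "planned",
    is.na(asg$block_id) & !is.na(asg$prior_block) ~ "cancelled",
    TRUE ~ "unscheduled"
  )
  asg$phase <- model$phase$index
  bl <- model$blocks[match(asg$block_id, model$blocks$block_id),
                     c("room", "date", "session")]
  asg <- dplyr::bind_cols(asg, bl)
  objective <- model$const + sum(vars$cost[x > 0.5]) -
    sum(ifelse(pts$forced, 0, pts$u_cost)[vars$pi[x > 0.5]])
  out <- structure(list(assignments = as_tibble(asg),
                        blocks = model$blocks,
                        objective = objective,
                        phase = model$phase$index,
                        solver = solver),
                   class = "or_schedule")
  check_schedule_feasible(out, model)
  out
}

# Defensive double-entry check: decoded schedules must satisfy every model
# constraint family.
check_schedule_feasible <- function(schedule, model) {
  asg <- schedule$assignments
  planned <- asg[asg$status %in% c("planned", "postponed"), ]
  if (nrow(planned) == 0) return(invisible(schedule))
  loads <- planned %>%
    group_by(block_id = .data$block_id) %>%
    summarise(load = sum(.data$load_min), .groups = "drop") %>%
    left_join(schedule$blocks[, c("block_id", "duration_min", "specialty")],
              by = "block_id")
  if (any(loads$load > loads$duration_min + 1e-6)) {
    abort("internal error: block capacity violated in decoded schedule")
  }
  spec_match <- schedule$blocks$specialty[match(planned$block_id,
                                                schedule$blocks$block_id)]
  if (any(spec_match != planned$specialty)) {
    abort("internal error: block/patient specialty mismatch")
  }
  if (!is.null(model) && model$phase$cumulative_utilization_cap < 1) {
    wk <- schedule$blocks$week_start[match(planned$block_id,
                                           schedule$blocks$block_id)]
    by_spec <- tibble(specialty = planned$specialty, week_start = wk,
                      load = planned$load_min) %>%
      group_by(.data$specialty, .data$week_start) %>%
      summarise(load = sum(.data$load), .groups = "drop") %>%
      left_join(model$caps, by = c("specialty", "week_start"))
    if (any(by_spec$load > by_spec$cap_min + 1e-6, na.rm = TRUE)) {
      abort("internal error: specialty utilisation cap violated")
    }
  }
  invisible(schedule)
}

#' Three-phase moving-target planning
#'
#' Plans one target surgery week by running the optimisation three times as
#' the week approaches.  Phase 1 (5 weeks ahead) schedules URG B/C/D
#' patients up to 50 % of each specialty's block time; the scheduled
#' patients are cleared from the waiting list.  Phase 2 (3 weeks ahead)
#' admits the URG A patients that have accumulated — filling residual space
#' with B/C/D when the priority load is low — up to a cumulative 75 %,
#' re-optimising with the phase-1 patients carried as soft constraints:
#' moving one costs the postpone penalty, dropping one the (much larger)
#' cancel penalty.  Phase 3 (1 week ahead) adds URG AA up to 100 %.
#'
#' @param wl A [waiting_list()]; its reference date is the phase-1 run date.
#' @param arrivals Optional patient tibble with `registration_date`: new
#'   registrations joining the list between phase runs.
#' @param template Weekly MSS grid ([default_mss_template()]).
#' @param phases List of three [phase_config()]s, decreasing `weeks_ahead`.
#' @param urg_table URG class table.
#' @inheritParams build_model
#' @inheritParams solve_phase
#' @return A list of class `three_phase_plan`: `schedule` (final
#'   `or_schedule` covering every patient considered), `phase_schedules`,
#'   `changelog` (postponements/cancellations per phase), `blocks`,
#'   `remaining` (patients still waiting).
#' @export
plan_three_phase <- function(wl, arrivals = NULL,
                             template = default_mss_template(),
                             phases = default_phase_configs(),
                             urg_table = default_urg_classes(),
                             load = c("occupation", "eot"),
                             horizon_extra_days = 7,
                             backend = c("highs", "enumerate"),
                             gap = 1e-4, time_limit = 60,
                             on_timeout = c("error", "incumbent"), ...) {
  validate_phase_configs(phases)
  load <- match.arg(load)
  backend <- match.arg(backend)
  on_timeout <- match.arg(on_timeout)
  t_ref <- reference_date(wl)
  target_monday <- week_start(t_ref) + 7L * phases[[1]]$weeks_ahead
  blocks <- expand_template(template, target_monday, 1)

  pool <- as_tibble(wl)
  assigned <- tibble(patient_id = character(0), block_id = character(0),
                     planned_in_phase = integer(0))
  all_seen <- pool
  changelog <- tibble(phase = integer(0), patient_id = character(0),
                      event = character(0), from_block = character(0),
                      to_block = character(0))
  phase_schedules <- vector("list", length(phases))
  prev_run <- t_ref

  for (k in seq_along(phases)) {
    ph <- phases[[k]]
    run_date <- target_monday - 7L * ph$weeks_ahead
    if (!is.null(arrivals) && k > 1) {
      newly <- arrivals[as.Date(arrivals$registration_date) > prev_run &
                          as.Date(arrivals$registration_date) <= run_date, ]
      if (nrow(newly) > 0) {
        newly$risks <- as_risk_list(newly$risks)
        pool <- bind_rows(pool, newly)
        all_seen <- bind_rows(all_seen, newly)
      }
    }
    prev_run <- run_date

    admit <- c(ph$eligible_urgs, ph$fill_urgs)
    candidates <- pool[pool$urg %in% admit &
                         as.Date(pool$registration_date) <= run_date, ]
    carried <- all_seen[all_seen$patient_id %in% assigned$patient_id, ]
    candidates <- bind_rows(carried,
                            candidates[!candidates$patient_id %in%
                                         carried$patient_id, ])
    if (nrow(candidates) == 0) next

    model <- build_model(candidates, blocks, ph,
                         prior = assigned[, c("patient_id", "block_id")],
                         urg_table = urg_table, load = load,
                         horizon_extra_days = horizon_extra_days, ...)
    sched <- solve_phase(model, backend = backend, gap = gap,
                         time_limit = time_limit, on_timeout = on_timeout)
    phase_schedules[[k]] <- sched
    asg <- sched$assignments

    moved <- asg[asg$status == "postponed", ]
    dropped <- asg[asg$status == "cancelled", ]
    if (nrow(moved) > 0 || nrow(dropped) > 0) {
      changelog <- bind_rows(
        changelog,
        tibble(phase = ph$index, patient_id = moved$patient_id,
               event = "postponed", from_block = moved$prior_block,
               to_block = moved$block_id),
        tibble(phase = ph$index, patient_id = dropped$patient_id,
               event = "cancelled", from_block = dropped$prior_block,
               to_block = NA_character_)
      )
    }

    in_block <- asg[!is.na(asg$block_id), ]
    first_phase <- assigned$planned_in_phase[match(in_block$patient_id,
                                                   assigned$patient_id)]
    assigned <- tibble(patient_id = in_block$patient_id,
                       block_id = in_block$block_id,
                       planned_in_phase = dplyr::coalesce(first_phase,
                                                          ph$index))
    # scheduled patients leave the list; cancelled ones return to it
    pool <- all_seen[!all_seen$patient_id %in% assigned$patient_id, ]
  }

  final <- finalize_plan(all_seen, assigned, changelog, blocks, phases,
                         urg_table, load, ...)
  structure(list(schedule = final, phase_schedules = phase_schedules,
                 changelog = changelog, blocks = blocks,
                 remaining = pool, target_week = target_monday),
            class = "three_phase_plan")
}

finalize_plan <- function(all_seen, assigned, changelog, blocks, phases,
                          urg_table, load, ...) {
  pts <- all_seen
  pts$load_min <- patient_loads(pts, load, ...)
  asg <- pts[, c("patient_id", "specialty", "urg", "registration_date",
                 "load_min")]
  m <- match(asg$patient_id, assigned$patient_id)
  asg$block_id <- assigned$block_id[m]
  asg$phase <- assigned$planned_in_phase[m]
  cancelled_ids <- changelog$patient_id[changelog$event == "cancelled"]
  cancelled_ids <- setdiff(cancelled_ids, assigned$patient_id)
  asg$status <- dplyr::case_when(
    !is.na(asg$block_id) ~ "planned",
    asg$patient_id %in% cancelled_ids ~ "cancelled",
    TRUE ~ "unscheduled"
  )
  asg$prior_block <- NA_character_
  bl <- blocks[match(asg$block_id, blocks$block_id),
               c("room", "date", "session")]
  asg <- dplyr::bind_cols(asg, bl)
  structure(list(assignments = as_tibble(asg), blocks = blocks,
                 objective = NA_real_, phase = phases[[length(phases)]]$index,
                 solver = list(backend = "three_phase")),
            class = "or_schedule")
}
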
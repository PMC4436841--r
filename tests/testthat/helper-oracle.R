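# Independent brute-force oracle for the 0-1 assignment problem.  Costs are
# recomputed from first principles and every assignment vector is
# enumerated and checked directly, with no use of the package's model
# builder or solver.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimum total cost over all feasible assignments.  Each patient is either
# unassigned (charged coefficient x days to horizon end, plus the cancel
# penalty if prior-planned) or placed in a same-specialty block (charged
# coefficient x days to the block date, plus the postpone penalty if moved
# off a prior block), subject to block capacity and the per-specialty
# utilisation cap.  Returns the optimum objective and one optimal pick.
oracle_optimum <- function(patients, blocks, phase,
                           urg_table = theatreplan::default_urg_classes(),
                           prior = NULL, postpone_pen = 0, cancel_pen = 0,
                           horizon_extra_days = 7) {
  n <- nrow(patients)
  B <- nrow(blocks)
  loads <- theatreplan::or_occupation_time(patients)$occupation_min
  coef <- urg_table$urgency_coefficient[match(patients$urg, urg_table$code)]
  horizon <- max(blocks$date) + horizon_extra_days
  reg <- as.Date(patients$registration_date)
  prior_block <- rep(NA_character_, n)
  if (!is.null(prior) && nrow(prior) > 0) {
    prior_block <- prior$block_id[match(patients$patient_id, prior$patient_id)]
  }

  # cost matrix W: column 1 = unassigned, column 1+b = block b (Inf when
  # incompatible)
  W <- matrix(Inf, n, B + 1)
  W[, 1] <- coef * as.numeric(horizon - reg) +
    ifelse(is.na(prior_block), 0, cancel_pen)
  for (b in seq_len(B)) {
    ok <- patients$specialty == blocks$specialty[b]
    moved <- !is.na(prior_block) & prior_block != blocks$block_id[b]
    W[ok, b + 1] <- coef[ok] * as.numeric(blocks$date[b] - reg[ok]) +
      ifelse(moved[ok], postpone_pen, 0)
  }

  combos <- as.matrix(expand.grid(rep(list(0:B), n)))
  cost <- numeric(nrow(combos))
  for (i in seq_len(n)) cost <- cost + W[i, combos[, i] + 1]

  feasible <- rep(TRUE, nrow(combos))
  for (b in seq_len(B)) {
    used <- numeric(nrow(combos))
    for (i in seq_len(n)) used <- used + loads[i] * (combos[, i] == b)
    feasible <- feasible & used <= blocks$duration_min[b] + 1e-9
  }
  cap_frac <- phase$cumulative_utilization_cap
  for (sp in unique(blocks$specialty)) {
    cap <- cap_frac * sum(blocks$duration_min[blocks$specialty == sp])
    used <- numeric(nrow(combos))
    for (i in seq_len(n)) {
      in_sp <- combos[, i] > 0 &
        blocks$specialty[pmax(combos[, i], 1)] == sp
      used <- used + loads[i] * in_sp
    }
    feasible <- feasible & used <= cap + 1e-9
  }

  cost[!feasible] <- Inf
  k <- which.min(cost)
  list(objective = cost[k], pick = combos[k, ],
       n_assigned = sum(combos[k, ] > 0))
}

# Feasibility audit of a decoded schedule, recomputed from the raw
# assignment table (double entry against the solver's own checks).
audit_schedule <- function(schedule, blocks, cap_frac = 1) {
  asg <- theatreplan::tidy(schedule)
  planned <- asg[asg$status %in% c("planned", "postponed"), ]
  ok_once <- !anyDuplicated(asg$patient_id)
  by_block <- tapply(planned$load_min, planned$block_id, sum)
  caps <- blocks$duration_min[match(names(by_block), blocks$block_id)]
  ok_cap <- length(by_block) == 0 || all(by_block <= caps + 1e-6)
  ok_spec <- all(blocks$specialty[match(planned$block_id, blocks$block_id)] ==
                   planned$specialty)
  by_sp <- tapply(planned$load_min, planned$specialty, sum)
  sp_cap <- vapply(names(by_sp), function(sp) {
    cap_frac * sum(blocks$duration_min[blocks$specialty == sp])
  }, numeric(1))
  ok_sp <- length(by_sp) == 0 || all(by_sp <= sp_cap + 1e-6)
  list(ok = ok_once && ok_cap && ok_spec && ok_sp,
       once = ok_once, capacity = ok_cap, specialty = ok_spec,
       specialty_cap = ok_sp)
}
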
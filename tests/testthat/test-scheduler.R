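test_that("model structure reflects compatibility and forced priors", {
  blocks <- make_blocks(c("2026-07-20", "2026-07-21"),
                        c("General", "Urology"), rooms = c("OR1", "OR1"))
  pts <- make_patients(eot = c(60, 60), specialty = c("General", "Neonatal"))
  ph <- phase_config(1, 5, c("B", "C", "D"), cumulative_utilization_cap = 1)
  m <- build_model(pts, blocks, ph)
  # one variable for the compatible pair, none for the blockless specialty
  expect_equal(nrow(m$vars), 1)
  expect_equal(m$vars$patient_id, "T001")
  sched <- solve_phase(m, backend = "enumerate")
  asg <- tidy(sched)
  expect_equal(asg$status[asg$patient_id == "T001"], "planned")
  expect_equal(asg$status[asg$patient_id == "T002"], "unscheduled")
})

test_that("no-overtime capacity admits at most one large case per block", {
  blocks <- make_blocks("2026-07-20", "General")
  pts <- make_patients(eot = rep(150, 3))  # occupation 200 each; 2 x 200 > 360
  ph <- phase_config(1, 5, c("B", "C", "D"), cumulative_utilization_cap = 1)
  sched <- solve_phase(build_model(pts, blocks, ph), backend = "enumerate")
  expect_equal(sum(tidy(sched)$status == "planned"), 1)
})

test_that("solver matches the brute-force oracle on random tiny instances", {
  insts <- lapply(1:60, random_tiny_instance)
  models <- lapply(insts, function(i) build_model(i$patients, i$blocks,
                                                  i$phase))
  scheds <- theatreplan:::solve_models(models, gap = 1e-9)
  for (k in seq_along(insts)) {
    opt <- oracle_optimum(insts[[k]]$patients, insts[[k]]$blocks,
                          insts[[k]]$phase)
    expect_equal(scheds[[k]]$objective, opt$objective, tolerance = 1e-6)
    # the package's own enumeration backend agrees too
    sched2 <- solve_phase(models[[k]], backend = "enumerate")
    expect_equal(sched2$objective, opt$objective, tolerance = 1e-6)
  }
})

test_that("when everything fits, every patient is planned", {
  blocks <- make_blocks(c("2026-07-20", "2026-07-21"), "General",
                        rooms = c("OR1", "OR1"))
  pts <- make_patients(eot = rep(60, 6))  # 6 x 110 = 660 <= 720
  ph <- phase_config(1, 5, c("B", "C", "D"), cumulative_utilization_cap = 1)
  sched <- solve_phase(build_model(pts, blocks, ph))
  expect_true(all(tidy(sched)$status == "planned"))
})

test_that("re-solving a schedule against itself with infinite penalties is a fixed point", {
  wl <- generate_waiting_list(30, "2026-06-15", seed = 41)
  blocks <- expand_template(default_mss_template(), "2026-07-20", 1)
  ph <- phase_config(1, 5, c("B", "C", "D"), cumulative_utilization_cap = 0.5)
  cand <- eligible_patients(wl, c("B", "C", "D"))
  s1 <- solve_phase(build_model(cand, blocks, ph))
  prior <- tidy(s1)
  prior <- prior[!is.na(prior$block_id), c("patient_id", "block_id")]
  ph2 <- phase_config(1, 5, c("B", "C", "D"), cumulative_utilization_cap = 0.5,
                      postpone_penalty = Inf, cancel_penalty = Inf)
  s2 <- solve_phase(build_model(cand, blocks, ph2, prior = prior))
  again <- tidy(s2)
  expect_equal(again$block_id[match(prior$patient_id, again$patient_id)],
               prior$block_id)
  expect_equal(sum(again$status %in% c("postponed", "cancelled")), 0)
})

test_that("an unscheduled patient never dominates a planned one", {
  # exchange argument: with the same compatible block, a smaller load and a
  # larger urgency coefficient, swapping in the unscheduled patient would
  # strictly improve -- so optima never leave one out
  urg <- default_urg_classes()
  insts <- lapply(101:130, random_tiny_instance)
  models <- lapply(insts, function(i) build_model(i$patients, i$blocks,
                                                  i$phase))
  scheds <- theatreplan:::solve_models(models, gap = 1e-9)
  for (k in seq_along(insts)) {
    inst <- insts[[k]]
    asg <- tidy(scheds[[k]])
    coef <- urg$urgency_coefficient[match(asg$urg, urg$code)]
    out <- which(asg$status == "unscheduled")
    on <- which(asg$status == "planned")
    for (i in out) for (j in on) {
      same_block_ok <- asg$specialty[i] ==
        inst$blocks$specialty[match(asg$block_id[j], inst$blocks$block_id)]
      if (same_block_ok && asg$load_min[i] <= asg$load_min[j]) {
        expect_lte(coef[i], coef[j])
      }
    }
  }
})

test_that("raising the utilisation cap never plans fewer patients", {
  wl <- generate_waiting_list(80, "2026-06-15", seed = 47)
  blocks <- expand_template(default_mss_template(), "2026-07-20", 1)
  cand <- eligible_patients(wl, c("A", "B", "C", "D", "AA"))
  planned <- vapply(c(0.3, 0.5, 0.7, 1.0), function(cap) {
    ph <- phase_config(1, 5, c("AA", "A", "B", "C", "D"),
                       cumulative_utilization_cap = cap)
    sum(tidy(solve_phase(build_model(cand, blocks, ph),
                         gap = 1e-6))$status == "planned")
  }, numeric(1))
  expect_true(all(diff(planned) >= 0))
})

test_that("infinite disruption penalties preserve phase-1 assignments to the end", {
  wl <- generate_waiting_list(120, "2026-06-15", seed = 53)
  phases <- list(
    phase_config(1, 5, c("B", "C", "D"), character(0), 0.50, Inf, Inf),
    phase_config(2, 3, "A", c("B", "C", "D"), 0.75, Inf, Inf),
    phase_config(3, 1, "AA", character(0), 1.00, Inf, Inf))
  arr <- generate_arrivals(40, 5, "2026-06-16", seed = 54)
  plan <- plan_three_phase(wl, arrivals = arr, phases = phases)
  expect_equal(nrow(plan$changelog), 0)
  p1 <- tidy(plan$phase_schedules[[1]])
  p1 <- p1[!is.na(p1$block_id), ]
  final <- tidy(plan)
  expect_equal(final$block_id[match(p1$patient_id, final$patient_id)],
               p1$block_id)
})

test_that("an urgent arrival can force a logged postponement", {
  # two one-block days; phase 1 parks a B case in the earlier block, then a
  # high-coefficient A case arrives whose only benefit is that early block
  tpl <- tibble::tibble(room = "OR1", weekday = c("Mon", "Fri"),
                        session = "morning", start_time = "08:00",
                        duration_min = 360,
                        specialty = "General")
  b_case <- make_patients(eot = 250, urg = "B",
                          registration_date = "2026-06-01", ids = "B1")
  wl <- waiting_list(b_case, "2026-06-15")
  a_case <- make_patients(eot = 250, urg = "A",
                          registration_date = "2026-06-20", ids = "A1")
  phases <- list(
    phase_config(1, 5, c("B", "C", "D"), character(0), 0.50),
    phase_config(2, 3, "A", c("B", "C", "D"), 1.00,
                 postpone_penalty = 10, cancel_penalty = 1e6),
    phase_config(3, 1, "AA", character(0), 1.00,
                 postpone_penalty = 10, cancel_penalty = 1e6))
  plan <- plan_three_phase(wl, arrivals = a_case, template = tpl,
                           phases = phases)
  expect_gte(sum(plan$changelog$event == "postponed"), 1)
  final <- tidy(plan)
  # the A patient takes the Monday block, the B patient moves to Friday
  expect_equal(final$date[final$patient_id == "A1"], as.Date("2026-07-20"))
  expect_equal(final$date[final$patient_id == "B1"], as.Date("2026-07-24"))
  expect_equal(sum(final$status == "cancelled"), 0)
})

test_that("forced prior loads beyond capacity are reported infeasible", {
  blocks <- make_blocks("2026-07-20", "General")
  pts <- make_patients(eot = c(250, 250))
  ph <- phase_config(1, 5, c("B", "C", "D"), cumulative_utilization_cap = 1,
                     postpone_penalty = Inf, cancel_penalty = Inf)
  prior <- tibble::tibble(patient_id = c("T001", "T002"),
                          block_id = rep(blocks$block_id, 2))
  m <- build_model(pts, blocks, ph, prior = prior)
  expect_error(solve_phase(m), class = "theatreplan_infeasible")
  expect_error(solve_phase(m, backend = "enumerate"),
               class = "theatreplan_infeasible")
})

test_that("feasibility holds on random synthetic weeks", {
  blocks <- expand_template(default_mss_template(), "2026-07-20", 1)
  caps <- c(0.5, 0.75, 1)[(1:20) %% 3 + 1]
  models <- lapply(1:20, function(seed) {
    wl <- generate_waiting_list(80, "2026-06-15", seed = seed)
    ph <- phase_config(1, 5, c("AA", "A", "B", "C", "D"),
                       cumulative_utilization_cap = caps[seed])
    build_model(wl, blocks, ph)
  })
  scheds <- theatreplan:::solve_models(models, gap = 5e-2, time_limit = 10,
                                       on_timeout = "incumbent")
  for (k in 1:20) {
    audit <- audit_schedule(scheds[[k]], blocks, cap_frac = caps[k])
    expect_true(audit$ok)
  }
})
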
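test_that("utilisation report computes direct ratios and empty schedules", {
  blocks <- make_blocks(c("2026-07-20", "2026-07-24"), "General",
                        rooms = c("OR1", "OR1"))
  # one patient of load 180 in a 360-minute block: utilisation 1/2
  pts <- make_patients(eot = 130)  # occupation = 130 + 50
  sched <- fcfs_baseline(pts, blocks)
  rep <- utilization_report(sched)
  expect_equal(rep$by_block$occupied_min, c(180, 0))
  expect_equal(rep$by_block$utilization, c(0.5, 0))
  expect_equal(rep$summary$mean_utilization, 0.5)  # open blocks only
  expect_equal(utilization_report(sched, open_blocks_only = FALSE)$
                 summary$mean_utilization, 0.25)
  # empty schedule: all utilisations zero
  none <- fcfs_baseline(make_patients(numeric(0), ids = character(0)), blocks)
  rep0 <- utilization_report(none)
  expect_true(all(rep0$by_block$utilization == 0))
  expect_equal(rep0$summary$n_planned, 0)
})

test_that("FCFS packs in registration order into earliest compatible blocks", {
  blocks <- make_blocks(c("2026-07-20", "2026-07-22", "2026-07-24"),
                        c("General", "Urology", "General"),
                        rooms = c("OR1", "OR1", "OR1"))
  pts <- make_patients(eot = c(250, 250), ids = c("late", "early"),
                       registration_date = c("2026-02-01", "2026-01-01"))
  sched <- fcfs_baseline(pts, blocks)
  asg <- tidy(sched)
  # the older registration gets the earliest block
  expect_equal(asg$block_id[asg$patient_id == "early"],
               blocks$block_id[1])
  expect_equal(asg$block_id[asg$patient_id == "late"],
               blocks$block_id[3])
  # a patient with no compatible block stays unscheduled
  uro <- make_patients(eot = 400, specialty = "Neurosurgery", ids = "nv")
  expect_equal(tidy(fcfs_baseline(uro, blocks))$status, "unscheduled")
})

test_that("greedy packing can strand capacity the optimiser recovers", {
  # single 360-minute block; arrival order 200, 100, 120, 120 (occupation
  # loads 250, 150, 170, 170 would not fit; use bare EOT loads instead)
  blocks <- make_blocks("2026-07-20", "General")
  pts <- make_patients(eot = c(200, 100, 120, 120),
                       registration_date = c("2026-01-01", "2026-01-02",
                                             "2026-01-03", "2026-01-04"))
  base <- fcfs_baseline(pts, blocks, load = "eot")
  expect_equal(sum(tidy(base)$status == "planned"), 2)  # 200 + 100
  ph <- phase_config(1, 5, c("B", "C", "D"), cumulative_utilization_cap = 1)
  opt <- solve_phase(build_model(pts, blocks, ph, load = "eot"),
                     backend = "enumerate")
  expect_equal(sum(tidy(opt)$status == "planned"), 3)  # 100 + 120 + 120
  cmp <- compare_schedules(opt, base)
  expect_equal(cmp$throughput_gain_pct, 50)
})

test_that("comparison metrics follow their definitions", {
  blocks <- make_blocks("2026-07-20", "General")
  pts <- make_patients(eot = c(100, 100))
  s <- fcfs_baseline(pts, blocks)
  same <- compare_schedules(s, s)
  expect_equal(same$throughput_gain_pct, 0)
  expect_equal(same$utilization_delta_pp, 0)
  # empty baseline: undefined gain, not a crash
  empty <- fcfs_baseline(make_patients(numeric(0), ids = character(0)), blocks)
  expect_warning(cmp <- compare_schedules(s, empty), "undefined")
  expect_true(is.na(cmp$throughput_gain_pct))
})

test_that("gain percentages are invariant to duplicating the instance", {
  blocks1 <- make_blocks("2026-07-20", "General")
  pts <- make_patients(eot = c(200, 100, 120, 120))
  ph <- phase_config(1, 5, c("B", "C", "D"), cumulative_utilization_cap = 1)
  g1 <- compare_schedules(
    solve_phase(build_model(pts, blocks1, ph, load = "eot"),
                backend = "enumerate"),
    fcfs_baseline(pts, blocks1, load = "eot"))
  blocks2 <- make_blocks(c("2026-07-20", "2026-07-20"), "General",
                         rooms = c("OR1", "OR2"))
  pts2 <- dplyr::bind_rows(pts, dplyr::mutate(
    pts, patient_id = paste0(patient_id, "b")))
  g2 <- compare_schedules(
    solve_phase(build_model(pts2, blocks2, ph, load = "eot"),
                backend = "enumerate"),
    fcfs_baseline(pts2, blocks2, load = "eot"))
  expect_equal(g1$throughput_gain_pct, g2$throughput_gain_pct)
})

test_that("report totals agree with independent recomputation", {
  wl <- generate_waiting_list(60, "2026-06-15", seed = 31)
  blocks <- expand_template(default_mss_template(), "2026-07-20", 1)
  sched <- fcfs_baseline(wl, blocks)
  rep <- utilization_report(sched)
  asg <- tidy(sched)
  planned <- asg[asg$status == "planned", ]
  expect_equal(rep$summary$n_planned, nrow(planned))
  expect_equal(rep$summary$total_occupied_min, sum(planned$load_min))
  by_sp <- tapply(planned$load_min, planned$specialty, sum)
  for (sp in names(by_sp)) {
    expect_equal(
      rep$by_specialty$scheduled_min[rep$by_specialty$specialty == sp],
      unname(by_sp[[sp]]))
  }
  audit <- audit_schedule(sched, blocks)
  expect_true(audit$ok)
})

test_that("plot builders return ggplot objects", {
  blocks <- make_blocks(c("2026-07-20", "2026-07-21"), "General",
                        rooms = c("OR1", "OR1"))
  sched <- fcfs_baseline(make_patients(eot = c(120, 90)), blocks)
  expect_s3_class(autoplot(sched), "ggplot")
  expect_s3_class(autoplot(utilization_report(sched)), "ggplot")
  wl <- generate_waiting_list(30, "2026-06-15", seed = 3)
  expect_s3_class(plot_waiting_list(wl), "ggplot")
})
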
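case <- function(eot, anesthesia = "A", risks = character(0),
                 same_building = TRUE, use_prep_room = FALSE,
                 destination = "recovery_room") {
  tibble::tibble(eot_min = eot, anesthesia = anesthesia,
                 risks = list(risks), same_building = same_building,
                 use_prep_room = use_prep_room, destination = destination)
}

test_that("risk adjustment reproduces hand-computed phase times", {
  # no risks: identity on the base task times
  t0 <- adjusted_phase_times(case(30, "A"))
  expect_equal(unlist(t0[c("induction_min", "operating_min", "awakening_min")]),
               c(induction_min = 10, operating_min = 30, awakening_min = 10))
  # Premature: 25 % on induction and awakening, none on operating
  t1 <- adjusted_phase_times(case(30, "A", "Premature"))
  expect_equal(t1$induction_min, 12.5)
  expect_equal(t1$operating_min, 30)
  expect_equal(t1$awakening_min, 12.5)
  # HeartDisease (100/0/50) + Coagulopathy (50/50/0), additive combination
  t2 <- adjusted_phase_times(case(100, "B", c("HeartDisease", "Coagulopathy")))
  expect_equal(t2$induction_min, 15 * 2.5)
  expect_equal(t2$operating_min, 100 * 1.5)
  expect_equal(t2$awakening_min, 15 * 1.5)
})

test_that("multiplicative combination compounds instead of summing", {
  t <- adjusted_phase_times(case(100, "B", c("HeartDisease", "Coagulopathy")),
                            combine = "multiplicative")
  expect_equal(t$induction_min, 15 * 2 * 1.5)
  expect_equal(t$operating_min, 100 * 1.5)
})

test_that("EOT inflation can be disabled for risk-aware surgeon estimates", {
  t <- adjusted_phase_times(case(100, "B", "Coagulopathy"), adjust_eot = FALSE)
  expect_equal(t$operating_min, 100)
  expect_equal(t$induction_min, 15 * 1.5)
})

test_that("unknown risk names are rejected by name", {
  expect_error(adjusted_phase_times(case(30, "A", "Rickets")), "Rickets")
})

test_that("occupation time matches the task-sum examples", {
  # A, EOT 30, recovery: 10 enter + 10 induction + 30 + 10 awaken + 5 exit
  # + 15 prep/cleaning
  expect_equal(or_occupation_time(case(30, "A"))$occupation_min, 80)
  # D, EOT 120, ICU: 10 + 15 + 120 + 15 + 10 + 60
  expect_equal(
    or_occupation_time(case(120, "D", destination = "intensive_care"))$occupation_min,
    230)
})

test_that("total pathway time matches the task-sum examples", {
  # B, EOT 60, same building, recovery:
  # 10 + 10 + 10 + 15 + 60 + 15 + 5 + 30 + 10
  expect_equal(total_pathway_time(case(60, "B"))$pathway_min, 165)
  # C with the preparation room adds its 30-minute task
  expect_equal(
    total_pathway_time(case(60, "C", use_prep_room = TRUE))$pathway_min, 195)
  # cleaning is charged to the block, not the patient: occupation - pathway
  # differs by cleaning for an ICU case with no recovery branch
  icu <- case(60, "B", destination = "intensive_care")
  occ <- or_occupation_time(icu)$occupation_min
  path <- total_pathway_time(icu)$pathway_min
  # pathway adds transport-in 10 + sector 10 + icu transport 10, occupation
  # adds cleaning 20
  expect_equal(path - occ, 30 - 20)
})

test_that("adding a risk never decreases any adjusted duration", {
  base <- case(90, "C", destination = "intensive_care")
  b0 <- or_occupation_time(base)
  for (r in default_risk_table()$name) {
    with_r <- or_occupation_time(case(90, "C", r,
                                      destination = "intensive_care"))
    expect_gte(with_r$induction_min, b0$induction_min)
    expect_gte(with_r$operating_min, b0$operating_min)
    expect_gte(with_r$awakening_min, b0$awakening_min)
    expect_gte(with_r$occupation_min, b0$occupation_min)
  }
  # Baby (25/0/0) strictly increases occupation via induction
  expect_gt(or_occupation_time(case(90, "C", "Baby"))$occupation_min,
            or_occupation_time(case(90, "C"))$occupation_min)
})

test_that("pathway and occupation totals equal their component sums on random cases", {
  pts <- generate_patients(1000, seed = 42)
  out <- total_pathway_time(pts)
  out <- or_occupation_time(out)
  tt <- default_task_timings()
  an <- default_anesthesia_profiles()
  ani <- an[match(out$anesthesia, an$code), ]
  transport_in <- ifelse(out$same_building, tt$transport_same_building_min,
                         tt$transport_diff_building_min)
  prep <- ifelse(out$use_prep_room,
                 ifelse(out$anesthesia == "C", 30, 45), 0)
  exit <- dplyr::case_when(
    out$destination == "intensive_care" ~ tt$exit_to_icu_min,
    TRUE ~ tt$exit_to_recovery_min)
  ward_t <- ifelse(out$same_building, tt$transport_ward_same_min,
                   tt$transport_ward_diff_min)
  branch <- dplyr::case_when(
    out$destination == "recovery_room" ~ tt$recovery_stay_min + ward_t,
    out$destination == "intensive_care" ~ tt$transport_icu_min,
    TRUE ~ ward_t)
  expect_equal(out$pathway_min,
               transport_in + tt$enter_sector_min + prep +
                 tt$enter_theatre_min + out$induction_min +
                 out$operating_min + out$awakening_min + exit + branch)
  expect_equal(out$occupation_min,
               tt$enter_theatre_min + out$induction_min + out$operating_min +
                 out$awakening_min + exit + ani$prep_cleaning_min)
  # occupation dominates the bare EOT everywhere
  expect_true(all(out$occupation_min > out$eot_min))
})
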
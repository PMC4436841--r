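test_that("NAWD is coefficient times elapsed days", {
  p <- make_patients(eot = c(60, 60, 60), urg = c("B", "AA", "D"),
                     registration_date = "2026-01-01")
  # zero elapsed time costs nothing regardless of class
  z <- nawd(p, "2026-01-01")
  expect_equal(z$nawd, c(0, 0, 0))
  # 10 days at coefficients 6 / 24 / 1
  d <- nawd(p, "2026-01-11")
  expect_equal(d$nawd, c(60, 240, 10))
  # unit coefficient gives elapsed days back (class D, coefficient 1)
  expect_equal(nawd(p[3, ], "2026-01-31")$nawd, 30)
  # future registration is rejected
  expect_error(nawd(p, "2025-12-31"), "negative")
})

test_that("NAWD is linear in elapsed days and ordered by urgency", {
  urg <- default_urg_classes()
  p <- make_patients(eot = rep(60, 5), urg = urg$code,
                     registration_date = "2026-01-01")
  n10 <- nawd(p, "2026-01-11")$nawd
  n25 <- nawd(p, "2026-01-26")$nawd
  expect_equal(n25 - n10, 15 * urg$urgency_coefficient)
  # same elapsed time: strictly decreasing cost AA > A > B > C > D
  expect_true(all(diff(n10) < 0))
})

test_that("phase eligibility filters and orders stably", {
  p <- make_patients(eot = rep(60, 6), urg = c("A", "B", "B", "B", "AA", "C"),
                     registration_date = c("2026-02-01", "2026-01-05",
                                           "2026-01-01", "2026-01-05",
                                           "2026-03-01", "2026-02-10"),
                     ids = sprintf("P%d", 1:6))
  wl <- waiting_list(p, "2026-06-15")
  sel <- eligible_patients(wl, c("B", "C", "D"))
  expect_equal(sel$patient_id, c("P3", "P2", "P4", "P6"))
  expect_equal(nrow(eligible_patients(wl, character(0))), 0)
  # the three phase URG sets partition the list
  sets <- list(c("B", "C", "D"), "A", "AA")
  ids <- unlist(lapply(sets, function(s) eligible_patients(wl, s)$patient_id))
  expect_setequal(ids, p$patient_id)
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("waiting lists enforce unique ids and registration before reference", {
  p <- make_patients(eot = c(60, 60), ids = c("X1", "X1"))
  expect_error(waiting_list(p, "2026-06-15"), "unique")
  p2 <- make_patients(eot = 60, registration_date = "2026-07-01")
  expect_error(waiting_list(p2, "2026-06-15"), "before")
  p3 <- make_patients(eot = 60, specialty = "Astrology")
  expect_error(waiting_list(p3, "2026-06-15"), "specialty")
})

test_that("waiting-list CSV round-trips and reports malformed lines", {
  wl <- generate_waiting_list(40, "2026-06-15", seed = 11)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_waiting_list(wl, tmp)
  back <- read_waiting_list(tmp, reference_date = "2026-06-15")
  expect_equal(as.data.frame(back)[order(back$patient_id),
                                   c("patient_id", "specialty", "urg",
                                     "eot_min", "anesthesia", "destination")],
               as.data.frame(wl)[order(wl$patient_id),
                                 c("patient_id", "specialty", "urg",
                                   "eot_min", "anesthesia", "destination")])
  expect_equal(lapply(back$risks, sort)[order(back$patient_id)],
               lapply(wl$risks, sort)[order(wl$patient_id)])

  txt <- readr::read_lines(tmp)
  txt[3] <- sub("^([^,]*),([^,]*),([^,]*),[^,]*", "\\1,\\2,\\3,not-a-date",
                txt[3])
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_lines(txt, bad)
  expect_error(read_waiting_list(bad), "line 3")
})
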
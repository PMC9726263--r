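test_that("occupancy expands starts into inclusive within-day windows", {
  inst <- manual_instance()
  s <- schedule(data.frame(patient = c("A", "B"), room = c("R1", "R1"),
                           surgeon = c("S1", "S1"), block = c(3L, 1L),
                           day = c(1L, 1L)), inst)
  occ <- occupancy(s, inst)
  expect_equal(sort(occ$block[occ$patient == "A"]), c(3L, 4L)) # du = 2
  expect_equal(occ$block[occ$patient == "B"], 1L)              # du = 1
  expect_true(all(occ$room == "R1" & occ$day == 1L))
})

test_that("day-boundary starts are rejected for every (start, duration) pair", {
  # brute force over a 6-block day: start t with duration du is legal iff
  # t + du - 1 <= 6
  rooms <- "R1"; surgeons <- "S1"
  for (du in 1:6) for (t in 1:6) {
    p <- patient("P", duration = du, deadline = 1,
                 room_eligible = c(R1 = TRUE), surgeon_eligible = c(S1 = TRUE),
                 assign_cost = matrix(1, 1, 1, dimnames = list(rooms, surgeons)))
    inst <- surgical_instance(
      list(p), rooms, surgeons, calendar(1, 6),
      room_capacity(matrix(6, 1, 1, dimnames = list(rooms, NULL)),
                    matrix(0, 1, 1), matrix(0, 1, 1),
                    matrix(0, 1, 1), matrix(0, 1, 1)),
      surgeon_limits(6, c(S1 = 6)),
      icu_params(5, 0, 0, 0, 1),
      cost_params(matrix(0, 1, 1), matrix(0, 1, 1)))
    s <- schedule(data.frame(patient = "P", room = "R1", surgeon = "S1",
                             block = t, day = 1L), inst)
    if (t + du - 1L <= 6L) {
      expect_equal(nrow(occupancy(s, inst)), du)
      expect_false("7" %in% validate_schedule(s, inst)$equation)
    } else {
      expect_error(occupancy(s, inst), "overruns")
      expect_true("7" %in% validate_schedule(s, inst)$equation)
    }
  }
})

test_that("validator flags missing coverage and double-booked rooms", {
  inst <- manual_instance()
  v <- validate_schedule(schedule(data.frame(patient = character(),
                                             room = character(),
                                             surgeon = character(),
                                             block = integer(),
                                             day = integer()), inst), inst)
  expect_setequal(v$equation, "6")
  expect_equal(nrow(v), 3L) # one per elective patient

  s <- schedule(data.frame(patient = c("A", "B"), room = c("R1", "R1"),
                           surgeon = c("S1", "S2"), block = c(1L, 2L),
                           day = c(1L, 1L)), inst)
  # A (du 2) occupies blocks 1-2; B collides at block 2
  v <- validate_schedule(s, inst)
  expect_true("9" %in% v$equation)
  expect_true(any(grepl("o=R1,t=2,d=1", v$indices)))
})

test_that("violation report is deterministically sorted by equation then indices", {
  inst <- manual_instance()
  s <- schedule(data.frame(patient = "A", room = "R2", surgeon = "S1",
                           block = 5L, day = 1L), inst)
  s$icu_shortage[1] <- -1
  v <- validate_schedule(s, inst)
  eqnum <- as.numeric(v$equation)
  expect_true(all(diff(eqnum) >= 0))
  expect_identical(v, validate_schedule(s, inst))
})

test_that("cost components match the tight idle/overtime/shortage formulas", {
  inst <- manual_instance()
  # empty schedule: idle = sum(EC * HN) = 4 cells * 4 blocks * 1
  cb <- evaluate_cost(schedule(data.frame(patient = character(),
                                          room = character(),
                                          surgeon = character(),
                                          block = integer(),
                                          day = integer()), inst),
                      inst, check = FALSE)
  expect_equal(cb$idle, 16)
  expect_equal(cb$assignment, 0)

  # overtime: 8 occupied elective blocks against HN = 6 at LC = 2 costs 4
  rooms <- "R1"; surgeons <- "S1"
  pats <- list(
    patient("P1", duration = 4, deadline = 1, room_eligible = c(R1 = TRUE),
            surgeon_eligible = c(S1 = TRUE),
            assign_cost = matrix(0, 1, 1, dimnames = list(rooms, surgeons))),
    patient("P2", duration = 4, deadline = 1, room_eligible = c(R1 = TRUE),
            surgeon_eligible = c(S1 = TRUE),
            assign_cost = matrix(0, 1, 1, dimnames = list(rooms, surgeons))))
  inst2 <- surgical_instance(
    pats, rooms, surgeons, calendar(1, 10),
    room_capacity(matrix(6, 1, 1, dimnames = list(rooms, NULL)),
                  matrix(4, 1, 1), matrix(4, 1, 1),
                  matrix(0, 1, 1), matrix(0, 1, 1)),
    surgeon_limits(10, c(S1 = 10)),
    icu_params(5, 0, 0, 0, 1),
    cost_params(matrix(0, 1, 1), matrix(2, 1, 1)))
  s <- schedule(data.frame(patient = c("P1", "P2"), room = "R1",
                           surgeon = "S1", block = c(1L, 5L), day = 1L),
                inst2)
  cb <- evaluate_cost(s, inst2)
  expect_equal(cb$overtime, 4)
  expect_equal(cb$total, 4)
})

test_that("full breakdown equals a straight-line recomputation from raw starts", {
  inst <- manual_instance()
  s <- schedule(data.frame(patient = c("A", "B", "C"),
                           room = c("R2", "R1", "R1"),
                           surgeon = c("S1", "S2", "S2"),
                           block = c(1L, 1L, 2L), day = c(1L, 1L, 2L)),
                inst)
  expect_equal(nrow(validate_schedule(s, inst)), 0L)
  cb <- evaluate_cost(s, inst)

  # independent recomputation, term by term
  z <- qnorm(0.95)
  assign <- 7 + 8 + 4 # A@R2S1, B@R1S2, C@R1S2
  load <- matrix(0, 2, 2, dimnames = list(c("R1", "R2"), NULL))
  load["R2", 1] <- 2; load["R1", 1] <- 1; load["R1", 2] <- 2
  idle <- sum(1 * pmax(4 - load, 0))
  over <- sum(2 * pmax(load - 4, 0))
  icu_budget <- 4 - 1 - z * sqrt(0.5 + 0.25)
  icu_load <- c(1, 1) # A on day 1; C on day 2 (2-day stay clipped at horizon)
  shortage <- sum(30 * pmax(icu_load - icu_budget, 0))
  expect_equal(cb$assignment, assign)
  expect_equal(cb$idle, idle)
  expect_equal(cb$overtime, over)
  expect_equal(cb$icu_shortage, shortage)
  expect_equal(cb$total, assign + idle + over + shortage)

  # pricing an infeasible schedule is refused with the validator's verdict
  bad <- schedule(data.frame(patient = "A", room = "R2", surgeon = "S1",
                             block = 1L, day = 1L), inst)
  expect_error(evaluate_cost(bad, inst), "infeasible")
})

test_that("perturbing any single start changes the occupancy map", {
  for (seed in 1:5) {
    inst <- tiny_instance(seed)
    en <- solve_enumeration(inst)
    if (en$status != "optimal") next
    base <- occupancy(en$schedule, inst)
    st <- en$schedule$starts
    for (i in which(!is.na(st$room))) {
      st2 <- st
      st2$block[i] <- if (st2$block[i] > 1L) st2$block[i] - 1L else
        st2$block[i] + 1L
      p <- orsched:::patient_by_id(inst, st2$patient[i])
      if (st2$block[i] + p$duration - 1L > inst$calendar$blocks_per_day) next
      pert <- occupancy(schedule(st2[!is.na(st2$room), ], inst), inst)
      expect_false(isTRUE(all.equal(base, pert)))
    }
  }
})

test_that("zero variances make the validator verdict independent of alpha", {
  inst <- tiny_instance(3,
                        emergency_or_var_range = c(0, 0),
                        icu_capacity_var_range = c(0, 0),
                        icu_emergency_var_range = c(0, 0))
  set.seed(99)
  for (k in 1:10) {
    st <- data.frame(
      patient = c("P1", "P2", "P3"),
      room = sample(inst$rooms, 3, replace = TRUE),
      surgeon = sample(inst$surgeons, 3, replace = TRUE),
      block = sample.int(3, 3, replace = TRUE),
      day = sample.int(2, 3, replace = TRUE))
    s <- schedule(st, inst)
    verdicts <- lapply(c(0.05, 0.5, 0.95, 0.999), function(a)
      validate_schedule(s, inst, alpha = a))
    for (v in verdicts[-1]) expect_identical(v, verdicts[[1]])
  }
})
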
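test_that("reservation margin matches the normal-quantile safety rule", {
  expect_equal(reserve_margin(2, 0, 0.7), 2)       # degenerate normal
  expect_equal(reserve_margin(2, 1, 0.5), 2)       # median of symmetric law
  # mean 2, variance 4, alpha 0.95: 2 + 2 * z_0.95 (frozen quantile value)
  expect_equal(reserve_margin(2, 4, 0.95), 5.289707, tolerance = 1e-6)
  expect_equal(reserve_margin(c(1, 2), c(0, 4), 0.95),
               c(1, 5.289707), tolerance = 1e-6)
  expect_error(reserve_margin(1, 1, 1), "alpha")
  expect_error(reserve_margin(1, 1, 0), "alpha")
  expect_error(reserve_margin(1, -1, 0.5), "variance")
})

one_room_instance <- function(n_blocks, duration, HN = n_blocks, HS = 0,
                              HO = 0, assign = matrix(1, 1, 1)) {
  rooms <- "R1"; surgeons <- "S1"
  p <- patient("P", duration = duration, deadline = 1,
               room_eligible = c(R1 = TRUE), surgeon_eligible = c(S1 = TRUE),
               assign_cost = assign)
  surgical_instance(
    list(p), rooms, surgeons, calendar(1, n_blocks),
    room_capacity(matrix(HN, 1, 1), matrix(HS, 1, 1), matrix(HO, 1, 1),
                  matrix(0, 1, 1), matrix(0, 1, 1)),
    surgeon_limits(n_blocks, c(S1 = n_blocks)),
    icu_params(5, 0, 0, 0, 1),
    cost_params(matrix(0, 1, 1), matrix(0, 1, 1)))
}

test_that("variable grid enumerates exactly the feasible start cells", {
  inst <- one_room_instance(n_blocks = 2, duration = 1)
  m <- build_milp(inst)
  expect_equal(sum(m$xi > 0), 2L) # two feasible starts
  # a 3-day horizon with a day-1 deadline creates no post-deadline starts
  rooms <- c("R1", "R2"); surgeons <- "S1"
  p <- patient("P", duration = 1, deadline = 1,
               room_eligible = c(R1 = TRUE, R2 = TRUE),
               surgeon_eligible = c(S1 = TRUE),
               assign_cost = matrix(c(3, 5), 2, 1))
  inst3 <- surgical_instance(
    list(p), rooms, surgeons, calendar(3, 2),
    room_capacity(matrix(2, 2, 3), matrix(0, 2, 3), matrix(0, 2, 3),
                  matrix(0, 2, 3), matrix(0, 2, 3)),
    surgeon_limits(2, c(S1 = 6)),
    icu_params(rep(5, 3), rep(0, 3), rep(0, 3), rep(0, 3), rep(1, 3)),
    cost_params(matrix(0, 2, 3), matrix(0, 2, 3)))
  m3 <- build_milp(inst3)
  expect_true(all(m3$xi[, , , , 2:3] == 0L))
  r <- solve_milp(m3)
  expect_equal(r$status, "optimal")
  expect_equal(r$objective, 3) # picks the cheaper room
  expect_equal(r$schedule$starts$room, "R1")
})

test_that("cleaning windows after an infectious start block other starts", {
  # infectious q (du 2, cl 2) at block 1 of a 6-block day: any second
  # infectious patient may only start at blocks 5 or 6
  rooms <- "R1"; surgeons <- c("S1", "S2")
  mk <- function(id, s1, s2) patient(
    id, duration = 2, deadline = 1, infectious = TRUE, cleaning_blocks = 2,
    room_eligible = c(R1 = TRUE),
    surgeon_eligible = c(S1 = s1, S2 = s2),
    assign_cost = matrix(1, 1, 2))
  inst <- surgical_instance(
    list(mk("Q", TRUE, FALSE), mk("P", FALSE, TRUE)),
    rooms, surgeons, calendar(1, 6),
    room_capacity(matrix(6, 1, 1), matrix(2, 1, 1), matrix(6, 1, 1),
                  matrix(0, 1, 1), matrix(0, 1, 1)),
    surgeon_limits(6, c(S1 = 6, S2 = 6)),
    icu_params(5, 0, 0, 0, 1),
    cost_params(matrix(0, 1, 1), matrix(0, 1, 1)))
  for (t in 1:5) {
    s <- schedule(data.frame(patient = c("Q", "P"), room = "R1",
                             surgeon = c("S1", "S2"), block = c(1L, t),
                             day = 1L), inst)
    v <- validate_schedule(s, inst)
    if (t <= 4) expect_true(any(v$equation %in% c("8", "9")),
                            label = paste("block", t, "inside window"))
    else expect_equal(nrow(v), 0L, label = paste("block", t, "clear"))
  }
  # and the solver respects the same windows
  r <- solve_milp(build_milp(inst))
  expect_equal(r$status, "optimal")
  st <- r$schedule$starts
  expect_gte(abs(diff(st$block)), 4L)
})

test_that("structurally infeasible instances are reported infeasible", {
  inst <- one_room_instance(n_blocks = 4, duration = 3, HN = 1, HS = 0,
                            HO = 0)
  expect_equal(solve_milp(build_milp(inst))$status, "infeasible")
  expect_equal(solve_enumeration(inst)$status, "infeasible")
})

test_that("solver optimum equals exhaustive enumeration on seeded instances", {
  insts <- lapply(1:20, tiny_instance)
  reps <- solve_milp_batch(lapply(insts, build_milp))
  for (i in seq_along(insts)) {
    en <- solve_enumeration(insts[[i]])
    expect_equal(reps[[i]]$status, en$status)
    if (en$status == "optimal") {
      expect_equal(reps[[i]]$objective, en$objective, tolerance = 1e-9)
      expect_equal(nrow(validate_schedule(reps[[i]]$schedule, insts[[i]])), 0L)
      cb <- evaluate_cost(reps[[i]]$schedule, insts[[i]])
      expect_equal(cb$total, reps[[i]]$objective, tolerance = 1e-6)
    }
  }
})

test_that("raising a room budget never increases the optimum when idle is free", {
  for (seed in 1:6) {
    inst <- tiny_instance(seed, idle_cost_range = c(0, 0))
    base <- solve_enumeration(inst)
    inst2 <- inst
    inst2$room_capacity$regular_blocks <-
      pmin(inst2$room_capacity$regular_blocks + 1L,
           inst2$calendar$blocks_per_day)
    more <- solve_enumeration(inst2)
    if (base$status == "optimal") {
      expect_equal(more$status, "optimal")
      expect_lte(more$objective, base$objective + 1e-9)
    }
  }
})

test_that("rescheduling extension prices deviations from the baseline", {
  base_inst <- manual_instance()
  r0 <- solve_milp(build_milp(base_inst))
  expect_equal(r0$status, "optimal")
  opt_A <- r0$schedule$starts[r0$schedule$starts$patient == "A", ]

  # baseline equal to the unconstrained optimum: no penalty
  b_opt <- list(room = opt_A$room, surgeon = opt_A$surgeon,
                block = opt_A$block, day = opt_A$day)
  inst1 <- manual_instance(baseline = b_opt)
  inst1$patients[[1]]$change_cost <- 11
  m1 <- add_rescheduling(build_milp(inst1), inst1)
  r1 <- solve_milp(m1)
  expect_equal(r1$objective, r0$objective, tolerance = 1e-6)
  expect_false(r1$schedule$changed[["A"]])

  # baseline on a day A can no longer use (deadline moved): forced change,
  # objective grows by exactly the change cost
  inst2 <- manual_instance(baseline = list(room = "R1", surgeon = "S1",
                                           block = 1L, day = 2L))
  inst2$patients[[1]]$deadline <- 1L
  inst2$patients[[1]]$change_cost <- 11
  m2 <- add_rescheduling(build_milp(inst2), inst2)
  r2 <- solve_milp(m2)
  expect_equal(r2$status, "optimal")
  ref2 <- solve_milp(build_milp(inst2)) # same instance without the extension
  expect_equal(r2$objective, ref2$objective + 11, tolerance = 1e-6)
  expect_true(r2$schedule$changed[["A"]])

  # exhausted change budget pins the patient to its baseline
  b_sub <- list(room = "R1", surgeon = "S2", block = 3L, day = 2L)
  inst3 <- manual_instance(baseline = b_sub, reschedule_limit = 1L)
  inst3$patients[[1]]$prior_changes <- 1L
  m3 <- add_rescheduling(build_milp(inst3), inst3)
  r3 <- solve_milp(m3)
  expect_equal(r3$status, "optimal")
  got <- r3$schedule$starts[r3$schedule$starts$patient == "A", ]
  expect_equal(unname(unlist(got[c("room", "surgeon", "block", "day")])),
               c("R1", "S2", "3", "2"))
  expect_error(add_rescheduling(build_milp(base_inst), base_inst),
               "baseline")
})
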
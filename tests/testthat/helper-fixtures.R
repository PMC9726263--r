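# Shared fixtures: tiny instance families, a hand-built instance with known
# costs, schedule mutation helpers, and independent oracles.

# Oracle family: <= 3 patients, <= 2 rooms/surgeons, <= 4 blocks, <= 2 days,
# small enough for exhaustive enumeration.
tiny_spec <- function(seed, ...) {
  args <- list(
    n_patients = 3L, n_infectious = 1L, n_rooms = 2L, n_surgeons = 2L,
    n_days = 2L, blocks_per_day = 4L,
    duration_range = c(1L, 2L), deadline_range = c(1L, 2L),
    icu_days_range = c(0L, 2L), cleaning_range = c(1L, 1L),
    regular_blocks_range = c(2L, 4L), elective_overtime_range = c(0L, 1L),
    emergency_overtime_range = c(0L, 1L),
    emergency_or_mean_range = c(0.2, 0.8),
    emergency_or_var_range = c(0.05, 0.2),
    seed = seed)
  do.call(generator_spec, utils::modifyList(args, list(...)))
}
tiny_instance <- function(seed, ...) generate_instance(tiny_spec(seed, ...))

# Hand-built 2-room / 2-surgeon / 2-day instance with round numbers, used
# where exact cost arithmetic is asserted.
manual_instance <- function(reliability = 0.95, reschedule_limit = 1L,
                            baseline = NULL) {
  rooms <- c("R1", "R2"); surgeons <- c("S1", "S2")
  elig <- function(...) setNames(c(...), rooms)
  selig <- function(...) setNames(c(...), surgeons)
  ac <- function(v) matrix(v, 2, 2, dimnames = list(rooms, surgeons))
  pats <- list(
    patient("A", duration = 2, deadline = 2, icu_days = 1,
            room_eligible = elig(TRUE, TRUE), surgeon_eligible = selig(TRUE, TRUE),
            assign_cost = ac(c(3, 7, 5, 9)), baseline_start = baseline),
    patient("B", duration = 1, deadline = 2, icu_days = 0,
            room_eligible = elig(TRUE, FALSE), surgeon_eligible = selig(TRUE, TRUE),
            assign_cost = ac(c(4, 6, 8, 10))),
    patient("C", duration = 2, deadline = 2, icu_days = 2, infectious = TRUE,
            cleaning_blocks = 1,
            room_eligible = elig(TRUE, TRUE), surgeon_eligible = selig(FALSE, TRUE),
            assign_cost = ac(c(2, 5, 4, 6))))
  mat <- function(v) matrix(v, 2, 2, dimnames = list(rooms, NULL))
  surgical_instance(
    patients = pats, rooms = rooms, surgeons = surgeons,
    calendar = calendar(2, 6),
    room_capacity = room_capacity(
      regular_blocks = mat(c(4, 4, 4, 4)),
      elective_overtime_blocks = mat(c(2, 2, 2, 2)),
      emergency_overtime_blocks = mat(c(1, 1, 1, 1)),
      emergency_demand_mean = mat(rep(0.5, 4)),
      emergency_demand_var = mat(rep(0.25, 4))),
    surgeon_limits = surgeon_limits(6, setNames(c(8, 8), surgeons)),
    icu = icu_params(capacity_mean = c(4, 4), capacity_var = c(0.5, 0.5),
                     emergency_mean = c(1, 1), emergency_var = c(0.25, 0.25),
                     shortage_cost = c(30, 30)),
    costs = cost_params(idle_cost = mat(rep(1, 4)),
                        overtime_cost = mat(rep(2, 4)),
                        reschedule_limit = reschedule_limit),
    reliability = reliability)
}

# Apply one targeted corruption to a feasible schedule; returns NULL when
# the mutation is not applicable, else list(sched, expected_eq).
mutate_schedule <- function(sched, inst, type) {
  st <- sched$starts
  assigned <- which(!is.na(st$room))
  if (!length(assigned)) return(NULL)
  el <- Filter(function(p) !p$emergency, inst$patients)
  dur <- setNames(vapply(el, `[[`, integer(1), "duration"),
                  vapply(el, `[[`, character(1), "id"))
  TT <- inst$calendar$blocks_per_day
  rebuild <- function(st2) schedule(st2[!is.na(st2$room), , drop = FALSE], inst)
  switch(type,
    unassign = {
      st$room[assigned[1]] <- NA
      list(sched = rebuild(st), eq = "6")
    },
    overrun = {
      i <- assigned[dur[st$patient[assigned]] >= 2L][1]
      if (is.na(i)) return(NULL)
      st$block[i] <- TT
      list(sched = rebuild(st), eq = "7")
    },
    collide = {
      if (length(assigned) < 2L) return(NULL)
      a <- assigned[1]
      ok <- assigned[-1][st$block[a] + dur[st$patient[assigned[-1]]] - 1L <= TT]
      if (!length(ok)) return(NULL)
      b <- ok[1]
      st[b, c("room", "block", "day")] <- st[a, c("room", "block", "day")]
      list(sched = rebuild(st), eq = "9")
    },
    late_day = {
      dl <- vapply(st$patient[assigned], function(id)
        orsched:::patient_by_id(inst, id)$deadline, integer(1))
      i <- assigned[dl < inst$calendar$days][1]
      if (is.na(i)) return(NULL)
      st$day[i] <- orsched:::patient_by_id(inst, st$patient[i])$deadline + 1L
      list(sched = rebuild(st), eq = "11")
    },
    bad_room = {
      for (i in assigned) {
        p <- orsched:::patient_by_id(inst, st$patient[i])
        bad <- names(p$room_eligible)[!p$room_eligible]
        if (length(bad)) { st$room[i] <- bad[1]
          return(list(sched = rebuild(st), eq = "12")) }
      }
      NULL
    },
    bad_surgeon = {
      for (i in assigned) {
        p <- orsched:::patient_by_id(inst, st$patient[i])
        bad <- names(p$surgeon_eligible)[!p$surgeon_eligible]
        if (length(bad)) { st$surgeon[i] <- bad[1]
          return(list(sched = rebuild(st), eq = "13")) }
      }
      NULL
    },
    idle_tamper = {
      sched$idle[1, 1] <- sched$idle[1, 1] - 1
      if (sched$idle[1, 1] < 0 ||
          sched$idle[1, 1] <
            max(inst$room_capacity$regular_blocks[1, 1] -
                  orsched:::elective_block_load(sched, inst)[1, 1], 0))
        list(sched = sched, eq = "17") else NULL
    },
    overtime_tamper = {
      sched$overtime[1, 1] <- -1
      list(sched = sched, eq = "18")
    },
    icu_flip = {
      sched$icu_occupy[1, 1] <- !sched$icu_occupy[1, 1]
      list(sched = sched, eq = "21")
    },
    neg_shortage = {
      sched$icu_shortage[1] <- -1
      list(sched = sched, eq = "22")
    },
    stop("unknown mutation type"))
}

mutation_types <- c("unassign", "overrun", "collide", "late_day", "bad_room",
                    "bad_surgeon", "idle_tamper", "overtime_tamper",
                    "icu_flip", "neg_shortage")

# Independent event-timeline clinic simulator: advances a wall clock over
# (arrival, service) pairs already in service order; no Lindley recursion.
timeline_oracle <- function(arrival, service, closing_time) {
  k <- length(arrival)
  wait <- idle <- numeric(k)
  if (k == 0L) return(list(wait = wait, idle = idle, overtime = 0))
  finish <- arrival[1] + service[1]
  for (j in seq_len(k)[-1]) {
    start <- max(arrival[j], finish)
    wait[j] <- start - arrival[j]
    idle[j] <- max(arrival[j] - finish, 0)
    finish <- start + service[j]
  }
  list(wait = wait, idle = idle,
       overtime = max(finish - closing_time, 0))
}

# Straight-line deterministic objective of a single-stream template with
# constant service time (punctual arrivals), for optimizer oracles.
template_oracle_cost <- function(times, s, Tclose, c_w, c_i, c_o) {
  r <- timeline_oracle(sort(times), rep(s, length(times)), Tclose)
  c_w * sum(r$wait) + c_i * sum(r$idle) + c_o * r$overtime
}

# All sorted integer vectors of length n over 0..T (test-local copy).
all_sorted_templates <- function(n, T) {
  out <- list()
  rec <- function(prefix, lo) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in lo:T) rec(c(prefix, v), v)
  }
  rec(integer(), 0L)
  out
}
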
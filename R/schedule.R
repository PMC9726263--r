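#' Build a schedule from start assignments
#'
#' Creates a schedule object from a table of start assignments and derives
#' every dependent quantity canonically: room occupancy, ICU admissions and
#' the occupancy windows they open, minimal ICU shortages under the
#' chance-constrained bed budget, tight idle and overtime block counts, and
#' change flags against any baseline starts.
#'
#' Time blocks and days are 1-based; block \code{t} covers wall-clock
#' \code{[t, t+1)}. Surgeries never span days: a start at block \code{t} of a
#' patient with duration \code{du} occupies blocks \code{t ... t+du-1} of the
#' same day and is rejected if that window overruns the day.
#'
#' @param starts Data frame with columns \code{patient}, \code{room},
#'   \code{surgeon}, \code{block}, \code{day}; one row per patient, with NA
#'   room/surgeon/block/day for unassigned patients. Rows for patients absent
#'   from the table are treated as unassigned.
#' @param instance A \code{\link{surgical_instance}}.
#' @return A list of class \code{"or_schedule"} with elements \code{starts},
#'   \code{icu_admit}, \code{icu_occupy} (patients x days logical matrices),
#'   \code{icu_shortage} (per day), \code{idle}, \code{overtime} (rooms x
#'   days), and \code{changed} (named logical over baselined patients).
#' @export
schedule <- function(starts, instance) {
  cal <- instance$calendar
  el <- elective_patients(instance)
  ids <- vapply(el, `[[`, character(1), "id")
  full <- data.frame(patient = ids, room = NA_character_,
                     surgeon = NA_character_, block = NA_integer_,
                     day = NA_integer_, stringsAsFactors = FALSE)
  if (nrow(starts)) {
    if (anyDuplicated(starts$patient))
      stop("duplicate start rows for patient '",
           starts$patient[duplicated(starts$patient)][1], "'")
    m <- match(starts$patient, full$patient)
    if (anyNA(m))
      stop("start given for unknown or emergency patient '",
           starts$patient[which(is.na(m))[1]], "'")
    full[m, c("room", "surgeon", "block", "day")] <-
      starts[, c("room", "surgeon", "block", "day")]
    full$block <- as.integer(full$block)
    full$day <- as.integer(full$day)
  }
  assigned <- !is.na(full$room)
  if (any(assigned)) {
    bad <- assigned & (full$block < 1L | full$day < 1L |
                         full$day > cal$days |
                         full$block > cal$blocks_per_day)
    if (any(bad))
      stop("start outside the calendar for patient '",
           full$patient[bad][1], "'")
  }

  nD <- cal$days
  admit <- occupy <- matrix(FALSE, length(ids), nD,
                            dimnames = list(ids, NULL))
  for (i in seq_along(el)) {
    if (!assigned[i]) next
    d <- full$day[i]
    admit[i, d] <- TRUE
    dI <- el[[i]]$icu_days
    if (dI > 0L) occupy[i, d:min(d + dI - 1L, nD)] <- TRUE
  }

  sched <- structure(list(
    starts = full,
    icu_admit = admit,
    icu_occupy = occupy,
    icu_shortage = NULL, idle = NULL, overtime = NULL,
    changed = NULL
  ), class = "or_schedule")

  rhs22 <- icu_bed_budget(instance)
  load <- colSums(occupy)
  sched$icu_shortage <- pmax(load - rhs22, 0)

  occ <- elective_block_load(sched, instance) # rooms x days
  HN <- instance$room_capacity$regular_blocks
  sched$idle <- pmax(HN - occ, 0)
  sched$overtime <- pmax(occ - HN, 0)

  base_ids <- ids[!vapply(el, function(p) is.null(p$baseline_start),
                          logical(1))]
  changed <- logical(length(base_ids)); names(changed) <- base_ids
  for (id in base_ids) {
    p <- patient_by_id(instance, id); b <- p$baseline_start
    i <- match(id, full$patient)
    changed[id] <- !assigned[i] ||
      !(identical(full$room[i], b$room) &&
          identical(full$surgeon[i], b$surgeon) &&
          full$block[i] == b$block && full$day[i] == b$day)
  }
  sched$changed <- changed
  sched
}

# Deterministic-equivalent ICU bed budget per day:
# E[capacity] - E[emergency demand] - z_alpha * sqrt(Var[cap] + Var[dem]).
icu_bed_budget <- function(instance, alpha = instance$reliability) {
  icu <- instance$icu
  icu$capacity_mean - icu$emergency_mean -
    stats::qnorm(alpha) * sqrt(icu$capacity_var + icu$emergency_var)
}

# Deterministic-equivalent elective block budget per room-day under the
# emergency reservation: HN + HO - margin(emergency OR demand), floored at 0.
elective_reserved_budget <- function(instance, alpha = instance$reliability) {
  rc <- instance$room_capacity
  pmax(rc$regular_blocks + rc$emergency_overtime_blocks -
         reserve_margin(rc$emergency_demand_mean, rc$emergency_demand_var,
                        alpha), 0)
}

# Occupied elective blocks per (room, day).
elective_block_load <- function(sched, instance) {
  cal <- instance$calendar
  occ <- matrix(0L, length(instance$rooms), cal$days,
                dimnames = list(instance$rooms, NULL))
  st <- sched$starts
  for (i in seq_len(nrow(st))) {
    if (is.na(st$room[i])) next
    p <- patient_by_id(instance, st$patient[i])
    occ[st$room[i], st$day[i]] <- occ[st$room[i], st$day[i]] + p$duration
  }
  occ
}

#' Expand schedule starts into per-block occupancy
#'
#' Expands each start into the inclusive window of blocks the operation
#' occupies: a patient with duration \code{du} starting at block \code{t}
#' occupies blocks \code{t ... t+du-1} of the same room, surgeon and day.
#'
#' @param sched An \code{\link{schedule}} object.
#' @param instance The matching \code{\link{surgical_instance}}.
#' @return Data frame with columns \code{patient}, \code{room},
#'   \code{surgeon}, \code{block}, \code{day}: one row per occupied cell.
#' @export
occupancy <- function(sched, instance) {
  cal <- instance$calendar
  st <- sched$starts
  rows <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    if (is.na(st$room[i])) next
    p <- patient_by_id(instance, st$patient[i])
    last <- st$block[i] + p$duration - 1L
    if (last > cal$blocks_per_day)
      stop("patient '", p$id, "': start at block ", st$block[i],
           " overruns the ", cal$blocks_per_day, "-block day")
    rows[[i]] <- data.frame(patient = p$id, room = st$room[i],
                            surgeon = st$surgeon[i],
                            block = st$block[i]:last, day = st$day[i],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(patient = character(), room = character(),
                      surgeon = character(), block = integer(),
                      day = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Evaluate the cost of a schedule
#'
#' Computes the objective value of a schedule: assignment costs of each
#' (patient, room, surgeon) triple, idle cost of unused regular blocks,
#' overtime cost of elective blocks beyond the regular budget, ICU shortage
#' penalties under the chance-constrained bed budget, and (when baselines
#' are present) rescheduling penalties. Idle, overtime and shortage are
#' recomputed tight from the start assignments, so the total matches the
#' optimum of the corresponding optimization model.
#'
#' @param sched An \code{\link{schedule}}.
#' @param instance The matching \code{\link{surgical_instance}}.
#' @param check Logical; validate the schedule first and refuse to price an
#'   infeasible one (default TRUE).
#' @param rescheduling Logical; include the rescheduling penalty term
#'   (default: TRUE when any patient has a baseline start).
#' @return A \code{\link{cost_breakdown}}.
#' @export
evaluate_cost <- function(sched, instance, check = TRUE,
                          rescheduling = length(sched$changed) > 0) {
  if (check) {
    v <- validate_schedule(sched, instance)
    if (nrow(v))
      stop("schedule is infeasible (", nrow(v), " violation(s), first: ",
           v$message[1], ")")
  }
  st <- sched$starts
  assign_cost <- 0
  for (i in seq_len(nrow(st))) {
    if (is.na(st$room[i])) next
    p <- patient_by_id(instance, st$patient[i])
    assign_cost <- assign_cost +
      p$assign_cost[match(st$room[i], instance$rooms),
                    match(st$surgeon[i], instance$surgeons)]
  }
  occ <- elective_block_load(sched, instance)
  HN <- instance$room_capacity$regular_blocks
  idle <- sum(instance$costs$idle_cost * pmax(HN - occ, 0))
  overtime <- sum(instance$costs$overtime_cost * pmax(occ - HN, 0))
  shortage <- sum(instance$icu$shortage_cost *
                    pmax(colSums(sched$icu_occupy) - icu_bed_budget(instance),
                         0))
  resched <- 0
  if (rescheduling && length(sched$changed)) {
    for (id in names(sched$changed)[sched$changed])
      resched <- resched + patient_by_id(instance, id)$change_cost
  }
  cost_breakdown(assignment = assign_cost, idle = idle, overtime = overtime,
                 icu_shortage = shortage, reschedule = resched)
}

#' @export
print.or_schedule <- function(x, ...) {
  n <- nrow(x$starts); a <- sum(!is.na(x$starts$room))
  cat(sprintf("Surgical schedule: %d/%d elective patients assigned\n", a, n))
  if (a) {
    st <- x$starts[!is.na(x$starts$room), ]
    st <- st[order(st$day, st$room, st$block), ]
    print(st, row.names = FALSE)
  }
  if (any(x$icu_shortage > 0))
    cat("ICU shortage days:",
        paste(which(x$icu_shortage > 0), collapse = ", "), "\n")
  invisible(x)
}
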
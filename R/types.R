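#' Patient record
#'
#' Constructs one elective or emergency patient for a surgical scheduling
#' instance. Durations and cleaning times are expressed in whole time blocks,
#' deadlines in day indices, ICU stays in days.
#'
#' @param id Character scalar, unique patient identifier.
#' @param duration Positive integer, number of consecutive time blocks the
#'   operation occupies.
#' @param deadline Positive integer, last day index on which the operation may
#'   start.
#' @param icu_days Non-negative integer, days the patient occupies an ICU bed
#'   after surgery (0 = no ICU stay).
#' @param infectious Logical; infectious patients require cleaning blocks
#'   after surgery and must be the last case started in their room-day.
#' @param emergency Logical; emergency patients receive no schedule decision,
#'   they are served from reserved stochastic capacity.
#' @param cleaning_blocks Non-negative integer, blocks needed to clean the
#'   room after an infectious patient's operation; must be 0 for
#'   non-infectious patients.
#' @param room_eligible Named logical vector over room ids (TRUE = patient may
#'   be operated in that room).
#' @param surgeon_eligible Named logical vector over surgeon ids.
#' @param assign_cost Numeric matrix rooms x surgeons, cost of assigning this
#'   patient to each (room, surgeon) pair.
#' @param baseline_start Optional list(room, surgeon, block, day): a
#'   previously communicated start used by the rescheduling extension.
#' @param prior_changes Non-negative integer, number of times this patient's
#'   plan was already changed.
#' @param change_cost Non-negative number, penalty for changing this patient's
#'   plan away from the baseline.
#' @return A list of class \code{"or_patient"}.
#' @export
patient <- function(id, duration, deadline, icu_days = 0L,
                    infectious = FALSE, emergency = FALSE,
                    cleaning_blocks = 0L,
                    room_eligible, surgeon_eligible, assign_cost,
                    baseline_start = NULL, prior_changes = 0L,
                    change_cost = 0) {
  stopifnot(is.character(id), length(id) == 1L)
  duration <- as.integer(duration)
  deadline <- as.integer(deadline)
  icu_days <- as.integer(icu_days)
  cleaning_blocks <- as.integer(cleaning_blocks)
  if (duration < 1L) stop("patient '", id, "': duration must be >= 1")
  if (deadline < 1L) stop("patient '", id, "': deadline must be >= 1")
  if (icu_days < 0L) stop("patient '", id, "': icu_days must be >= 0")
  if (!infectious && cleaning_blocks != 0L)
    stop("patient '", id, "': cleaning_blocks must be 0 unless infectious")
  if (infectious && cleaning_blocks < 1L)
    stop("patient '", id, "': infectious patient needs cleaning_blocks >= 1")
  if (!emergency && (!any(room_eligible) || !any(surgeon_eligible)))
    stop("patient '", id, "': needs at least one eligible room and surgeon")
  structure(list(
    id = id, duration = duration, deadline = deadline, icu_days = icu_days,
    infectious = isTRUE(infectious), emergency = isTRUE(emergency),
    cleaning_blocks = cleaning_blocks,
    room_eligible = room_eligible, surgeon_eligible = surgeon_eligible,
    assign_cost = assign_cost, baseline_start = baseline_start,
    prior_changes = as.integer(prior_changes),
    change_cost = as.numeric(change_cost)
  ), class = "or_patient")
}

#' Scheduling calendar
#'
#' @param days Positive integer, number of days in the planning horizon.
#' @param blocks_per_day Positive integer, indivisible time blocks per day.
#' @return A list of class \code{"or_calendar"}.
#' @export
calendar <- function(days, blocks_per_day) {
  days <- as.integer(days); blocks_per_day <- as.integer(blocks_per_day)
  stopifnot(days >= 1L, blocks_per_day >= 1L)
  structure(list(days = days, blocks_per_day = blocks_per_day),
            class = "or_calendar")
}

#' Room capacities and emergency demand
#'
#' All matrices are rooms x days. \code{regular_blocks} is the regular
#' elective budget of a room-day, \code{elective_overtime_blocks} the extra
#' overtime budget open to electives, and \code{emergency_overtime_blocks}
#' the extra budget reserved for emergencies. Emergency operating-room demand
#' is normally distributed per room-day with the given mean and variance.
#'
#' @param regular_blocks,elective_overtime_blocks,emergency_overtime_blocks
#'   Non-negative integer matrices rooms x days.
#' @param emergency_demand_mean,emergency_demand_var Non-negative numeric
#'   matrices rooms x days.
#' @return A list of class \code{"or_room_capacity"}.
#' @export
room_capacity <- function(regular_blocks, elective_overtime_blocks,
                          emergency_overtime_blocks,
                          emergency_demand_mean, emergency_demand_var) {
  mats <- list(regular_blocks, elective_overtime_blocks,
               emergency_overtime_blocks, emergency_demand_mean,
               emergency_demand_var)
  dims <- unique(lapply(mats, dim))
  if (length(dims) != 1L)
    stop("all room-capacity matrices must share the same rooms x days shape")
  if (any(vapply(mats, function(m) any(m < 0), logical(1))))
    stop("room capacities, demand means and variances must be >= 0")
  structure(list(
    regular_blocks = regular_blocks,
    elective_overtime_blocks = elective_overtime_blocks,
    emergency_overtime_blocks = emergency_overtime_blocks,
    emergency_demand_mean = emergency_demand_mean,
    emergency_demand_var = emergency_demand_var
  ), class = "or_room_capacity")
}

#' Surgeon workload limits
#'
#' @param daily_elective_blocks Non-negative integer: blocks of elective
#'   surgery any surgeon may perform per day (shared cap).
#' @param horizon_blocks Named non-negative numeric vector over surgeon ids:
#'   total blocks each surgeon may work over the whole horizon.
#' @return A list of class \code{"or_surgeon_limits"}.
#' @export
surgeon_limits <- function(daily_elective_blocks, horizon_blocks) {
  stopifnot(daily_elective_blocks >= 0, all(horizon_blocks >= 0))
  structure(list(daily_elective_blocks = as.integer(daily_elective_blocks),
                 horizon_blocks = horizon_blocks),
            class = "or_surgeon_limits")
}

#' ICU bed parameters
#'
#' ICU supply and emergency ICU demand are normally distributed per day.
#' Beds demanded beyond the (chance-constrained) available capacity are
#' counted as shortage and penalized linearly.
#'
#' @param capacity_mean,capacity_var Numeric vectors (length = days): mean and
#'   variance of available ICU beds.
#' @param emergency_mean,emergency_var Numeric vectors: mean and variance of
#'   ICU beds taken by emergency patients.
#' @param shortage_cost Numeric vector: penalty per missing bed per day.
#' @return A list of class \code{"or_icu_params"}.
#' @export
icu_params <- function(capacity_mean, capacity_var, emergency_mean,
                       emergency_var, shortage_cost) {
  n <- unique(lengths(list(capacity_mean, capacity_var, emergency_mean,
                           emergency_var, shortage_cost)))
  if (length(n) != 1L) stop("all ICU parameter vectors must have length = days")
  stopifnot(all(capacity_var >= 0), all(emergency_var >= 0),
            all(shortage_cost >= 0))
  structure(list(capacity_mean = capacity_mean, capacity_var = capacity_var,
                 emergency_mean = emergency_mean, emergency_var = emergency_var,
                 shortage_cost = shortage_cost),
            class = "or_icu_params")
}

#' Operating-room cost parameters
#'
#' @param idle_cost Numeric matrix rooms x days: cost per unused regular block.
#' @param overtime_cost Numeric matrix rooms x days: cost per elective block
#'   beyond the regular budget.
#' @param reschedule_limit Non-negative integer: maximum number of times a
#'   non-emergency patient's plan may be changed (rescheduling extension).
#' @return A list of class \code{"or_cost_params"}.
#' @export
cost_params <- function(idle_cost, overtime_cost, reschedule_limit = 0L) {
  stopifnot(all(idle_cost >= 0), all(overtime_cost >= 0),
            reschedule_limit >= 0)
  structure(list(idle_cost = idle_cost, overtime_cost = overtime_cost,
                 reschedule_limit = as.integer(reschedule_limit)),
            class = "or_cost_params")
}

#' Surgical scheduling instance
#'
#' Bundles patients, resources, calendar, stochastic parameters and costs
#' into one validated instance. \code{reliability} is the chance-constraint
#' level alpha: stochastic room and ICU capacities are converted to
#' deterministic equivalents by reserving \code{qnorm(alpha)} standard
#' deviations above the mean emergency demand (see
#' \code{\link{reserve_margin}}).
#'
#' @param patients List of \code{\link{patient}} objects.
#' @param rooms,surgeons Character vectors of unique identifiers.
#' @param calendar A \code{\link{calendar}}.
#' @param room_capacity A \code{\link{room_capacity}}.
#' @param surgeon_limits A \code{\link{surgeon_limits}}.
#' @param icu An \code{\link{icu_params}}.
#' @param costs A \code{\link{cost_params}}.
#' @param reliability Number in (0,1), chance-constraint level (default 0.95).
#' @return A list of class \code{"surgical_instance"}.
#' @export
surgical_instance <- function(patients, rooms, surgeons, calendar,
                              room_capacity, surgeon_limits, icu, costs,
                              reliability = 0.95) {
  if (reliability <= 0 || reliability >= 1)
    stop("reliability must lie strictly inside (0, 1)")
  ids <- vapply(patients, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  if (anyDuplicated(rooms) || anyDuplicated(surgeons))
    stop("room and surgeon ids must be unique")
  # normalize index names so downstream code can index by identifier
  for (nm in names(room_capacity)[1:5])
    rownames(room_capacity[[nm]]) <- rooms
  rownames(costs$idle_cost) <- rownames(costs$overtime_cost) <- rooms
  for (i in seq_along(patients))
    dimnames(patients[[i]]$assign_cost) <- list(rooms, surgeons)
  inst <- structure(list(
    patients = patients, rooms = rooms, surgeons = surgeons,
    calendar = calendar, room_capacity = room_capacity,
    surgeon_limits = surgeon_limits, icu = icu, costs = costs,
    reliability = reliability
  ), class = "surgical_instance")
  check_instance(inst)
  inst
}

# Structural invariants beyond the per-component constructors.
check_instance <- function(inst) {
  cal <- inst$calendar
  nO <- length(inst$rooms); nD <- cal$days
  for (m in inst$room_capacity[1:5])
    if (!all(dim(m) == c(nO, nD)))
      stop("room-capacity matrices must be ", nO, " x ", nD)
  if (any(inst$room_capacity$regular_blocks > cal$blocks_per_day))
    stop("regular_blocks may not exceed blocks_per_day")
  if (length(inst$icu$capacity_mean) != nD)
    stop("ICU parameter vectors must have length ", nD)
  if (!all(dim(inst$costs$idle_cost) == c(nO, nD)))
    stop("cost matrices must be ", nO, " x ", nD)
  if (!setequal(names(inst$surgeon_limits$horizon_blocks), inst$surgeons))
    stop("horizon_blocks must be named by the surgeon ids")
  for (p in inst$patients) {
    if (p$deadline > nD)
      stop("patient '", p$id, "': deadline ", p$deadline,
           " outside the ", nD, "-day horizon")
    if (!p$emergency && p$duration > cal$blocks_per_day)
      stop("patient '", p$id, "': duration exceeds blocks_per_day")
    if (!setequal(names(p$room_eligible), inst$rooms) ||
        !setequal(names(p$surgeon_eligible), inst$surgeons))
      stop("patient '", p$id, "': eligibility vectors must cover all rooms/surgeons")
    if (!all(dim(p$assign_cost) == c(nO, length(inst$surgeons))))
      stop("patient '", p$id, "': assign_cost must be rooms x surgeons")
    if (!is.null(p$baseline_start)) {
      b <- p$baseline_start
      if (!(b$room %in% inst$rooms) || !(b$surgeon %in% inst$surgeons) ||
          b$block < 1L || b$block > cal$blocks_per_day ||
          b$day < 1L || b$day > nD)
        stop("patient '", p$id, "': baseline_start outside the instance grid")
    }
  }
  invisible(inst)
}

# Elective (non-emergency) patients: the model's decision units.
elective_patients <- function(inst) {
  Filter(function(p) !p$emergency, inst$patients)
}

patient_by_id <- function(inst, id) {
  for (p in inst$patients) if (p$id == id) return(p)
  stop("unknown patient id '", id, "'")
}

#' @export
print.surgical_instance <- function(x, ...) {
  el <- elective_patients(x)
  cat("Surgical scheduling instance\n")
  cat(sprintf("  %d patients (%d elective, %d infectious), %d rooms, %d surgeons\n",
              length(x$patients), length(el),
              sum(vapply(x$patients, `[[`, logical(1), "infectious")),
              length(x$rooms), length(x$surgeons)))
  cat(sprintf("  horizon: %d days x %d blocks; reliability alpha = %.3g\n",
              x$calendar$days, x$calendar$blocks_per_day, x$reliability))
  invisible(x)
}

#' Cost breakdown of a schedule
#'
#' @param assignment,idle,overtime,icu_shortage,reschedule Component costs.
#' @return A list of class \code{"cost_breakdown"}; \code{total} is the sum
#'   of the components.
#' @export
cost_breakdown <- function(assignment = 0, idle = 0, overtime = 0,
                           icu_shortage = 0, reschedule = 0) {
  structure(list(assignment = assignment, idle = idle, overtime = overtime,
                 icu_shortage = icu_shortage, reschedule = reschedule,
                 total = assignment + idle + overtime + icu_shortage +
                   reschedule),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Schedule cost breakdown\n")
  for (nm in c("assignment", "idle", "overtime", "icu_shortage", "reschedule"))
    cat(sprintf("  %-13s %12.4f\n", nm, x[[nm]]))
  cat(sprintf("  %-13s %12.4f\n", "total", x$total))
  invisible(x)
}
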
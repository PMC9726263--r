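#' Validate a schedule against the full constraint system
#'
#' Checks a schedule against every restriction of the deterministic
#' chance-constraint equivalent model: full elective coverage, within-day
#' occupancy windows, post-infectious cleaning, room and surgeon
#' non-overlap, deadlines, eligibility, the surgeon daily and horizon caps,
#' the elective and emergency-reserved room budgets, idle/overtime
#' consistency, ICU admission linkage, ICU occupancy windows, the
#' chance-constrained ICU bed budget, and the infectious-last sequencing
#' rule. When any patient carries a baseline start, the rescheduling
#' extension rows (change-flag consistency and the change-count cap) are
#' checked as well.
#'
#' Violations are data, not errors: the return value is a data frame with
#' one row per violated constraint, naming the constraint (by model equation
#' number, or "R1"/"R2" for the extension rows), the indices at which it
#' fails, and the slack (amount by which it is violated). Rows are sorted by
#' (equation, indices) so output is deterministic.
#'
#' @param sched An \code{\link{schedule}}.
#' @param instance The matching \code{\link{surgical_instance}}.
#' @param alpha Chance-constraint level; defaults to the instance's
#'   \code{reliability}.
#' @return Data frame with columns \code{equation}, \code{indices},
#'   \code{slack}, \code{message}; zero rows iff the schedule is feasible.
#' @export
validate_schedule <- function(sched, instance,
                              alpha = instance$reliability) {
  cal <- instance$calendar
  el <- elective_patients(instance)
  ids <- vapply(el, `[[`, character(1), "id")
  st <- sched$starts
  viol <- list()
  add <- function(eq, indices, slack, message)
    viol[[length(viol) + 1L]] <<- data.frame(
      equation = eq, indices = indices, slack = slack, message = message,
      stringsAsFactors = FALSE)

  dur <- vapply(el, `[[`, integer(1), "duration")
  names(dur) <- ids
  i_of <- match(st$patient, ids)
  assigned <- which(!is.na(st$room))

  # (6) every elective patient assigned exactly once
  for (i in seq_along(ids)) {
    n <- sum(st$patient == ids[i] & !is.na(st$room))
    if (n != 1L)
      add("6", paste0("p=", ids[i]), 1 - n,
          paste0("patient ", ids[i], " has ", n,
                 " assignments, needs exactly 1"))
  }

  # (7) occupancy windows stay inside the day
  for (i in assigned) {
    over <- st$block[i] + dur[st$patient[i]] - 1L - cal$blocks_per_day
    if (over > 0L)
      add("7", paste0("p=", st$patient[i]), over,
          paste0("patient ", st$patient[i], " overruns the day by ", over,
                 " block(s)"))
  }
  ok <- assigned[st$block[assigned] + dur[st$patient[assigned]] - 1L <=
                   cal$blocks_per_day]

  # expand within-day occupancy for the overlap checks
  occ_list <- lapply(ok, function(i)
    st$block[i]:(st$block[i] + dur[st$patient[i]] - 1L))

  # (8) cleaning window after each infectious start blocks other starts
  for (j in seq_along(ok)) {
    i <- ok[j]; q <- patient_by_id(instance, st$patient[i])
    if (!q$infectious) next
    win_end <- st$block[i] + q$duration + q$cleaning_blocks - 1L
    for (k in seq_along(ok)) {
      m <- ok[k]
      if (m == i || st$room[m] != st$room[i] || st$day[m] != st$day[i]) next
      if (st$block[m] >= st$block[i] && st$block[m] <= win_end)
        add("8", paste0("q=", q$id, ",p=", st$patient[m], ",o=", st$room[i],
                        ",d=", st$day[i]), 1,
            paste0("patient ", st$patient[m],
                   " starts inside the surgery+cleaning window of infectious ",
                   q$id, " in room ", st$room[i], " day ", st$day[i]))
    }
  }

  # (9) one surgery per room-block; (10) one per surgeon-block
  key9 <- key10 <- list()
  for (j in seq_along(ok)) {
    i <- ok[j]
    for (t in occ_list[[j]]) {
      k9 <- paste0(st$room[i], "|", t, "|", st$day[i])
      k10 <- paste0(st$surgeon[i], "|", t, "|", st$day[i])
      key9[[k9]] <- c(key9[[k9]], st$patient[i])
      key10[[k10]] <- c(key10[[k10]], st$patient[i])
    }
  }
  for (k in names(key9)) if (length(key9[[k]]) > 1L) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    add("9", paste0("o=", parts[1], ",t=", parts[2], ",d=", parts[3]),
        length(key9[[k]]) - 1,
        paste0("room ", parts[1], " block ", parts[2], " day ", parts[3],
               " occupied by ", paste(key9[[k]], collapse = "+")))
  }
  for (k in names(key10)) if (length(key10[[k]]) > 1L) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    add("10", paste0("s=", parts[1], ",t=", parts[2], ",d=", parts[3]),
        length(key10[[k]]) - 1,
        paste0("surgeon ", parts[1], " double-booked at block ", parts[2],
               " day ", parts[3]))
  }

  # (11) deadline, (12) room eligibility, (13) surgeon eligibility
  for (i in assigned) {
    p <- patient_by_id(instance, st$patient[i])
    if (st$day[i] > p$deadline)
      add("11", paste0("p=", p$id), st$day[i] - p$deadline,
          paste0("patient ", p$id, " scheduled on day ", st$day[i],
                 " after deadline ", p$deadline))
    if (!isTRUE(p$room_eligible[[st$room[i]]]))
      add("12", paste0("p=", p$id, ",o=", st$room[i]), 1,
          paste0("patient ", p$id, " not eligible for room ", st$room[i]))
    if (!isTRUE(p$surgeon_eligible[[st$surgeon[i]]]))
      add("13", paste0("p=", p$id, ",s=", st$surgeon[i]), 1,
          paste0("patient ", p$id, " not eligible for surgeon ",
                 st$surgeon[i]))
  }

  # daily/horizon load aggregates from assigned durations
  G <- instance$surgeon_limits$daily_elective_blocks
  for (s in instance$surgeons) for (d in seq_len(cal$days)) {
    load <- sum(dur[st$patient[ok]][st$surgeon[ok] == s & st$day[ok] == d])
    if (load > G)
      add("14", paste0("s=", s, ",d=", d), load - G,
          paste0("surgeon ", s, " works ", load, " > ", G,
                 " elective blocks on day ", d))
  }
  budget16 <- elective_reserved_budget(instance, alpha)
  rc <- instance$room_capacity
  for (o in instance$rooms) for (d in seq_len(cal$days)) {
    load <- sum(dur[st$patient[ok]][st$room[ok] == o & st$day[ok] == d])
    cap15 <- rc$regular_blocks[o, d] + rc$elective_overtime_blocks[o, d]
    if (load > cap15)
      add("15", paste0("o=", o, ",d=", d), load - cap15,
          paste0("room ", o, " day ", d, " elective load ", load,
                 " exceeds regular+overtime budget ", cap15))
    if (load > budget16[o, d] + 1e-9)
      add("16", paste0("o=", o, ",d=", d), load - budget16[o, d],
          sprintf("room %s day %d elective load %d exceeds emergency-reserved budget %.4f",
                  o, d, load, budget16[o, d]))
  }

  # (17)/(18) recorded idle/overtime must be at-or-above the tight values
  occ <- elective_block_load(sched, instance)
  HN <- rc$regular_blocks
  for (o in instance$rooms) for (d in seq_len(cal$days)) {
    need_idle <- max(HN[o, d] - occ[o, d], 0)
    if (sched$idle[o, d] < need_idle - 1e-9)
      add("17", paste0("o=", o, ",d=", d), need_idle - sched$idle[o, d],
          sprintf("idle[%s,%d] = %.4f below required %.4f", o, d,
                  sched$idle[o, d], need_idle))
    need_ot <- max(occ[o, d] - HN[o, d], 0)
    if (sched$overtime[o, d] < need_ot - 1e-9)
      add("18", paste0("o=", o, ",d=", d), need_ot - sched$overtime[o, d],
          sprintf("overtime[%s,%d] = %.4f below required %.4f", o, d,
                  sched$overtime[o, d], need_ot))
  }

  # (19) horizon workload cap per surgeon
  MT <- instance$surgeon_limits$horizon_blocks
  for (s in instance$surgeons) {
    load <- sum(dur[st$patient[ok]][st$surgeon[ok] == s])
    if (load > MT[[s]])
      add("19", paste0("s=", s), load - MT[[s]],
          paste0("surgeon ", s, " horizon load ", load, " exceeds ", MT[[s]]))
  }

  # (20) surgery day implies ICU admission that day
  for (i in ok) {
    pid <- st$patient[i]
    if (!isTRUE(sched$icu_admit[pid, st$day[i]]))
      add("20", paste0("p=", pid, ",d=", st$day[i]), 1,
          paste0("patient ", pid, " operated on day ", st$day[i],
                 " without an ICU admission that day"))
  }

  # (21) ICU occupancy must equal the admission-opened windows
  for (i in seq_along(el)) {
    p <- el[[i]]
    expect <- rep(FALSE, cal$days)
    for (d in which(sched$icu_admit[p$id, ])) {
      if (p$icu_days > 0L)
        expect[d:min(d + p$icu_days - 1L, cal$days)] <- TRUE
    }
    bad <- which(xor(expect, sched$icu_occupy[p$id, ]))
    for (d in bad)
      add("21", paste0("p=", p$id, ",d=", d), 1,
          paste0("ICU occupancy of ", p$id, " on day ", d,
                 " inconsistent with the admission window"))
  }

  # (22) ICU load minus shortage within the chance-constrained bed budget
  budget22 <- icu_bed_budget(instance, alpha)
  load_icu <- colSums(sched$icu_occupy)
  for (d in seq_len(cal$days)) {
    z <- sched$icu_shortage[d]
    if (z < -1e-9)
      add("22", paste0("d=", d), -z,
          paste0("negative ICU shortage on day ", d))
    if (load_icu[d] - z > budget22[d] + 1e-9)
      add("22", paste0("d=", d), load_icu[d] - z - budget22[d],
          sprintf("ICU load %d - shortage %.4f exceeds bed budget %.4f on day %d",
                  load_icu[d], z, budget22[d], d))
  }

  # (23) infectious patients are the last cases started in their room-day
  for (i in ok) {
    q <- patient_by_id(instance, st$patient[i])
    if (!q$infectious) next
    for (m in ok) {
      if (m == i || st$room[m] != st$room[i] || st$day[m] != st$day[i]) next
      pm <- patient_by_id(instance, st$patient[m])
      if (!pm$infectious && st$block[m] > st$block[i])
        add("23", paste0("q=", q$id, ",p=", pm$id, ",o=", st$room[i],
                         ",d=", st$day[i]), 1,
            paste0("non-infectious ", pm$id, " starts after infectious ",
                   q$id, " in room ", st$room[i], " day ", st$day[i]))
    }
  }

  # rescheduling extension rows, active only when baselines exist
  if (length(sched$changed)) {
    theta <- instance$costs$reschedule_limit
    for (id in names(sched$changed)) {
      p <- patient_by_id(instance, id); b <- p$baseline_start
      i <- match(id, st$patient)
      differs <- is.na(st$room[i]) ||
        !(identical(st$room[i], b$room) &&
            identical(st$surgeon[i], b$surgeon) &&
            st$block[i] == b$block && st$day[i] == b$day)
      if (differs && !isTRUE(sched$changed[[id]]))
        add("R1", paste0("p=", id), 1,
            paste0("patient ", id,
                   " deviates from baseline but is not flagged changed"))
      if (p$prior_changes + as.integer(isTRUE(sched$changed[[id]])) > theta)
        add("R2", paste0("p=", id),
            p$prior_changes + as.integer(isTRUE(sched$changed[[id]])) - theta,
            paste0("patient ", id, " exceeds the change cap of ", theta))
    }
  }

  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(equation = character(), indices = character(),
               slack = numeric(), message = character(),
               stringsAsFactors = FALSE)
  eqnum <- suppressWarnings(as.numeric(out$equation))
  eqnum[is.na(eqnum)] <- Inf
  out <- out[order(eqnum, out$indices), , drop = FALSE]
  rownames(out) <- NULL
  out
}
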
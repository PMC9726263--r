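#' Exact solve by exhaustive enumeration
#'
#' Solver-free exact optimizer for small instances: enumerates every full
#' assignment of elective patients to feasible (room, surgeon, block, day)
#' cells by depth-first search with incremental feasibility pruning
#' (pairwise overlap, cleaning windows, infectious-last sequencing, surgeon
#' daily/horizon caps, room budgets) and prices each complete assignment
#' directly from the cost definitions. Independent of the MILP code path;
#' intended as the ground-truth oracle for instances with a handful of
#' patients.
#'
#' @param instance A \code{\link{surgical_instance}}.
#' @param alpha Chance-constraint level; defaults to the instance's
#'   \code{reliability}.
#' @return A list of class \code{"solve_report"} with status "optimal" or
#'   "infeasible"; on success \code{schedule} holds an optimal schedule.
#' @export
solve_enumeration <- function(instance, alpha = instance$reliability) {
  cal <- instance$calendar
  el <- elective_patients(instance)
  np <- length(el)
  TT <- cal$blocks_per_day; DD <- cal$days
  rooms <- instance$rooms; surgeons <- instance$surgeons
  rc <- instance$room_capacity
  budget16 <- elective_reserved_budget(instance, alpha)
  cap15 <- rc$regular_blocks + rc$elective_overtime_blocks
  budget22 <- icu_bed_budget(instance, alpha)
  G <- instance$surgeon_limits$daily_elective_blocks
  MT <- instance$surgeon_limits$horizon_blocks[surgeons]
  HN <- rc$regular_blocks
  EC <- instance$costs$idle_cost; LC <- instance$costs$overtime_cost
  U <- instance$icu$shortage_cost

  t0 <- proc.time()[["elapsed"]]
  cells <- vector("list", np)
  for (i in seq_len(np)) {
    p <- el[[i]]
    os <- which(outer(p$room_eligible[rooms], p$surgeon_eligible[surgeons],
                      `&`), arr.ind = TRUE)
    if (!nrow(os) || p$duration > TT || p$deadline < 1L) {
      cells[[i]] <- matrix(integer(), 0, 4)
      next
    }
    grid <- expand.grid(k = seq_len(nrow(os)),
                        t = seq_len(TT - p$duration + 1L),
                        d = seq_len(min(p$deadline, DD)))
    cells[[i]] <- cbind(o = os[grid$k, 1], s = os[grid$k, 2],
                        t = grid$t, d = grid$d)
  }
  if (any(vapply(cells, nrow, integer(1)) == 0L))
    return(structure(list(status = "infeasible", objective = NA_real_,
                          bound = NA_real_, gap = NA_real_, schedule = NULL,
                          wall_seconds = proc.time()[["elapsed"]] - t0),
                     class = "solve_report"))

  dur <- vapply(el, `[[`, integer(1), "duration")
  infc <- vapply(el, `[[`, logical(1), "infectious")
  clb <- vapply(el, `[[`, integer(1), "cleaning_blocks")
  icu_d <- vapply(el, `[[`, integer(1), "icu_days")
  acost <- lapply(el, `[[`, "assign_cost")

  compatible <- function(i, ci, j, cj) {
    # ci/cj: integer vectors (o, s, t, d)
    if (ci[4] == cj[4]) {
      e_i <- ci[3] + dur[i] - 1L; e_j <- cj[3] + dur[j] - 1L
      if (ci[1] == cj[1]) {
        if (ci[3] <= e_j && cj[3] <= e_i) return(FALSE)            # (9)
        if (infc[i] && cj[3] >= ci[3] &&
            cj[3] <= ci[3] + dur[i] + clb[i] - 1L) return(FALSE)   # (8)
        if (infc[j] && ci[3] >= cj[3] &&
            ci[3] <= cj[3] + dur[j] + clb[j] - 1L) return(FALSE)
        if (infc[i] && !infc[j] && cj[3] > ci[3]) return(FALSE)    # (23)
        if (infc[j] && !infc[i] && ci[3] > cj[3]) return(FALSE)
      }
      if (ci[2] == cj[2] && ci[3] <= e_j && cj[3] <= e_i)
        return(FALSE)                                              # (10)
    }
    TRUE
  }

  best <- Inf; best_cells <- NULL
  chosen <- matrix(0L, np, 4)
  sd_load <- matrix(0L, length(surgeons), DD)
  od_load <- matrix(0L, length(rooms), DD)
  s_tot <- integer(length(surgeons))

  leaf_cost <- function() {
    cst <- 0
    for (i in seq_len(np))
      cst <- cst + acost[[i]][chosen[i, 1], chosen[i, 2]]
    cst <- cst + sum(EC * pmax(HN - od_load, 0)) +
      sum(LC * pmax(od_load - HN, 0))
    load <- numeric(DD)
    for (i in seq_len(np)) if (icu_d[i] > 0L) {
      d <- chosen[i, 4]
      win <- d:min(d + icu_d[i] - 1L, DD)
      load[win] <- load[win] + 1
    }
    cst + sum(U * pmax(load - budget22, 0))
  }

  dfs <- function(i) {
    if (i > np) {
      cst <- leaf_cost()
      if (cst < best) { best <<- cst; best_cells <<- chosen }
      return(invisible())
    }
    cc <- cells[[i]]
    for (r in seq_len(nrow(cc))) {
      ci <- cc[r, ]
      o <- ci[1]; s <- ci[2]; d <- ci[4]
      if (sd_load[s, d] + dur[i] > G) next
      if (od_load[o, d] + dur[i] > cap15[o, d]) next
      if (od_load[o, d] + dur[i] > budget16[o, d] + 1e-9) next
      if (s_tot[s] + dur[i] > MT[s]) next
      ok <- TRUE
      for (j in seq_len(i - 1L))
        if (!compatible(i, ci, j, chosen[j, ])) { ok <- FALSE; break }
      if (!ok) next
      chosen[i, ] <<- ci
      sd_load[s, d] <<- sd_load[s, d] + dur[i]
      od_load[o, d] <<- od_load[o, d] + dur[i]
      s_tot[s] <<- s_tot[s] + dur[i]
      dfs(i + 1L)
      sd_load[s, d] <<- sd_load[s, d] - dur[i]
      od_load[o, d] <<- od_load[o, d] - dur[i]
      s_tot[s] <<- s_tot[s] - dur[i]
    }
  }
  dfs(1L)

  wall <- proc.time()[["elapsed"]] - t0
  if (is.infinite(best))
    return(structure(list(status = "infeasible", objective = NA_real_,
                          bound = NA_real_, gap = NA_real_, schedule = NULL,
                          wall_seconds = wall), class = "solve_report"))
  starts <- data.frame(
    patient = vapply(el, `[[`, character(1), "id"),
    room = rooms[best_cells[, 1]],
    surgeon = surgeons[best_cells[, 2]],
    block = as.integer(best_cells[, 3]),
    day = as.integer(best_cells[, 4]),
    stringsAsFactors = FALSE)
  structure(list(status = "optimal", objective = best, bound = best,
                 gap = 0, schedule = schedule(starts, instance),
                 wall_seconds = wall),
            class = "solve_report")
}
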
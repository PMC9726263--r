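#' Local-search configuration
#'
#' @param max_iterations Positive integer, maximum accepted moves.
#' @param neighborhood Character vector of enabled move types among
#'   "move_start" (same room and surgeon, new block/day, including
#'   insertion of unplaced patients), "swap_patients", "reassign_surgeon"
#'   and "reassign_room".
#' @param restarts Non-negative integer, extra randomized construction
#'   starts explored by \code{\link{solve_heuristic}}.
#' @param seed Integer seed controlling construction tie-breaks and restart
#'   orders.
#' @param accept "first_improvement" or "best_improvement".
#' @return A list of class \code{"search_config"}.
#' @export
search_config <- function(max_iterations = 100L,
                          neighborhood = c("move_start", "swap_patients",
                                           "reassign_surgeon",
                                           "reassign_room"),
                          restarts = 0L, seed = 1L,
                          accept = c("best_improvement",
                                     "first_improvement")) {
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  neighborhood <- match.arg(neighborhood, c("move_start", "swap_patients",
                                            "reassign_surgeon",
                                            "reassign_room"),
                            several.ok = TRUE)
  structure(list(max_iterations = max_iterations,
                 neighborhood = neighborhood,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 accept = match.arg(accept)), class = "search_config")
}

# Placement context: everything the constructive and local-search phases
# need to test feasibility and price assignments without a solver.
make_ctx <- function(instance, alpha = instance$reliability) {
  el <- elective_patients(instance)
  rc <- instance$room_capacity
  list(
    instance = instance, el = el,
    ids = vapply(el, `[[`, character(1), "id"),
    dur = vapply(el, `[[`, integer(1), "duration"),
    dead = vapply(el, `[[`, integer(1), "deadline"),
    infc = vapply(el, `[[`, logical(1), "infectious"),
    clb = vapply(el, `[[`, integer(1), "cleaning_blocks"),
    icu_d = vapply(el, `[[`, integer(1), "icu_days"),
    acost = lapply(el, `[[`, "assign_cost"),
    relig = lapply(el, function(p) p$room_eligible[instance$rooms]),
    selig = lapply(el, function(p) p$surgeon_eligible[instance$surgeons]),
    TT = instance$calendar$blocks_per_day, DD = instance$calendar$days,
    nO = length(instance$rooms), nS = length(instance$surgeons),
    HN = rc$regular_blocks,
    cap15 = rc$regular_blocks + rc$elective_overtime_blocks,
    budget16 = elective_reserved_budget(instance, alpha),
    budget22 = icu_bed_budget(instance, alpha),
    G = instance$surgeon_limits$daily_elective_blocks,
    MT = instance$surgeon_limits$horizon_blocks[instance$surgeons],
    EC = instance$costs$idle_cost, LC = instance$costs$overtime_cost,
    U = instance$icu$shortage_cost)
}

ctx_cells <- function(ctx, i) {
  if (ctx$dur[i] > ctx$TT) return(matrix(integer(), 0, 4))
  os <- which(outer(ctx$relig[[i]], ctx$selig[[i]], `&`), arr.ind = TRUE)
  if (!nrow(os)) return(matrix(integer(), 0, 4))
  grid <- expand.grid(k = seq_len(nrow(os)),
                      t = seq_len(ctx$TT - ctx$dur[i] + 1L),
                      d = seq_len(min(ctx$dead[i], ctx$DD)))
  cbind(o = os[grid$k, 1], s = os[grid$k, 2], t = grid$t, d = grid$d)
}

# Pairwise feasibility of two placed cells (overlap, cleaning windows,
# infectious-last), mirroring the validator's semantics.
ctx_pair_ok <- function(ctx, i, ci, j, cj) {
  if (ci[4] != cj[4]) return(TRUE)
  e_i <- ci[3] + ctx$dur[i] - 1L; e_j <- cj[3] + ctx$dur[j] - 1L
  if (ci[1] == cj[1]) {
    if (ci[3] <= e_j && cj[3] <= e_i) return(FALSE)
    if (ctx$infc[i] && cj[3] >= ci[3] &&
        cj[3] <= ci[3] + ctx$dur[i] + ctx$clb[i] - 1L) return(FALSE)
    if (ctx$infc[j] && ci[3] >= cj[3] &&
        ci[3] <= cj[3] + ctx$dur[j] + ctx$clb[j] - 1L) return(FALSE)
    if (ctx$infc[i] && !ctx$infc[j] && cj[3] > ci[3]) return(FALSE)
    if (ctx$infc[j] && !ctx$infc[i] && ci[3] > cj[3]) return(FALSE)
  }
  if (ci[2] == cj[2] && ci[3] <= e_j && cj[3] <= e_i) return(FALSE)
  TRUE
}

# Global feasibility of a (possibly partial) cell assignment matrix.
ctx_feasible <- function(ctx, cells) {
  placed <- which(cells[, 1] > 0L)
  if (!length(placed)) return(TRUE)
  for (i in placed) {
    # per-cell validity: eligibility, deadline, within-day window
    if (!ctx$relig[[i]][cells[i, 1]] || !ctx$selig[[i]][cells[i, 2]] ||
        cells[i, 4] > ctx$dead[i] ||
        cells[i, 3] + ctx$dur[i] - 1L > ctx$TT) return(FALSE)
  }
  sd_load <- matrix(0L, ctx$nS, ctx$DD)
  od_load <- matrix(0L, ctx$nO, ctx$DD)
  s_tot <- numeric(ctx$nS)
  for (i in placed) {
    o <- cells[i, 1]; s <- cells[i, 2]; d <- cells[i, 4]
    sd_load[s, d] <- sd_load[s, d] + ctx$dur[i]
    od_load[o, d] <- od_load[o, d] + ctx$dur[i]
    s_tot[s] <- s_tot[s] + ctx$dur[i]
  }
  if (any(sd_load > ctx$G) || any(od_load > ctx$cap15) ||
      any(od_load > ctx$budget16 + 1e-9) || any(s_tot > ctx$MT))
    return(FALSE)
  for (a in seq_along(placed)) {
    i <- placed[a]
    if (a > 1L) for (b in seq_len(a - 1L)) {
      j <- placed[b]
      if (!ctx_pair_ok(ctx, i, cells[i, ], j, cells[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Objective of a cell matrix; unplaced patients carry a lexicographic
# penalty so completeness always dominates cost.
UNPLACED_PENALTY <- 1e8
ctx_cost <- function(ctx, cells) {
  placed <- which(cells[, 1] > 0L)
  od_load <- matrix(0L, ctx$nO, ctx$DD)
  icu_load <- numeric(ctx$DD)
  cst <- 0
  for (i in placed) {
    cst <- cst + ctx$acost[[i]][cells[i, 1], cells[i, 2]]
    od_load[cells[i, 1], cells[i, 4]] <-
      od_load[cells[i, 1], cells[i, 4]] + ctx$dur[i]
    if (ctx$icu_d[i] > 0L) {
      win <- cells[i, 4]:min(cells[i, 4] + ctx$icu_d[i] - 1L, ctx$DD)
      icu_load[win] <- icu_load[win] + 1
    }
  }
  cst <- cst + sum(ctx$EC * pmax(ctx$HN - od_load, 0)) +
    sum(ctx$LC * pmax(od_load - ctx$HN, 0)) +
    sum(ctx$U * pmax(icu_load - ctx$budget22, 0))
  cst + UNPLACED_PENALTY * (nrow(cells) - length(placed))
}

cells_to_schedule <- function(ctx, cells) {
  placed <- which(cells[, 1] > 0L)
  starts <- data.frame(
    patient = ctx$ids[placed],
    room = ctx$instance$rooms[cells[placed, 1]],
    surgeon = ctx$instance$surgeons[cells[placed, 2]],
    block = as.integer(cells[placed, 3]),
    day = as.integer(cells[placed, 4]),
    stringsAsFactors = FALSE)
  sch <- schedule(starts, ctx$instance)
  attr(sch, "unplaced") <- ctx$ids[cells[, 1] == 0L]
  sch
}

schedule_to_cells <- function(ctx, sched) {
  cells <- matrix(0L, length(ctx$ids), 4)
  st <- sched$starts
  for (r in seq_len(nrow(st))) {
    if (is.na(st$room[r])) next
    i <- match(st$patient[r], ctx$ids)
    cells[i, ] <- c(match(st$room[r], ctx$instance$rooms),
                    match(st$surgeon[r], ctx$instance$surgeons),
                    st$block[r], st$day[r])
  }
  cells
}

#' Greedy constructive schedule
#'
#' Orders elective patients by (deadline, decreasing duration) with
#' seed-controlled tie-breaking and places each in the cheapest feasible
#' (room, surgeon, block, day) cell under all hard constraints, pricing the
#' full incremental cost (assignment plus idle, overtime and ICU-shortage
#' deltas). Patients with no feasible cell are left unassigned and listed
#' in the \code{"unplaced"} attribute of the result; a complete
#' construction passes \code{\link{validate_schedule}}.
#'
#' @param instance A \code{\link{surgical_instance}}.
#' @param seed Integer seed (tie-break randomization).
#' @param random_order Logical; ignore the deadline ordering and place in a
#'   uniformly random order (used by restarts).
#' @return An \code{\link{schedule}}, possibly incomplete.
#' @export
construct_schedule <- function(instance, seed = 1L, random_order = FALSE) {
  ctx <- make_ctx(instance)
  np <- length(ctx$ids)
  set.seed(seed)
  ord <- if (random_order) sample.int(np) else
    order(ctx$dead, -ctx$dur, stats::runif(np))
  cells <- matrix(0L, np, 4)
  for (i in ord) {
    cand <- ctx_cells(ctx, i)
    if (nrow(cand)) {
      # among equal-cost cells keep the first in preference order:
      # infectious patients as late as possible within the day (they must be
      # the last start of their room-day), clean patients as early as possible
      tp <- if (ctx$infc[i]) -cand[, 3] else cand[, 3]
      cand <- cand[order(cand[, 4], tp, cand[, 1], cand[, 2]), ,
                   drop = FALSE]
    }
    best_v <- Inf; best_c <- NULL
    for (r in seq_len(nrow(cand))) {
      trial <- cells; trial[i, ] <- cand[r, ]
      if (!ctx_feasible(ctx, trial)) next
      v <- ctx_cost(ctx, trial)
      if (v < best_v - 1e-12) { best_v <- v; best_c <- cand[r, ] }
    }
    if (!is.null(best_c)) cells[i, ] <- best_c
  }
  cells_to_schedule(ctx, cells)
}

#' Hill-climbing improvement of a schedule
#'
#' Local search over the configured neighborhoods: relocating a start
#' (including inserting an unplaced patient), swapping two patients' cells,
#' and reassigning the surgeon or room of a start. Only improving moves are
#' accepted (first- or best-improvement), so cost is non-increasing
#' iteration by iteration and every intermediate schedule stays feasible;
#' the search stops at a local optimum or after \code{max_iterations}
#' accepted moves. Deterministic given the inputs and configuration seed.
#' Accepted moves are recorded in the \code{"moves"} attribute.
#'
#' @param sched A feasible (possibly incomplete) \code{\link{schedule}}.
#' @param instance The matching \code{\link{surgical_instance}}.
#' @param config A \code{\link{search_config}}.
#' @return The improved \code{\link{schedule}}.
#' @export
improve_schedule <- function(sched, instance, config = search_config()) {
  ctx <- make_ctx(instance)
  cells <- schedule_to_cells(ctx, sched)
  cur_v <- ctx_cost(ctx, cells)
  np <- length(ctx$ids)
  moves <- list()

  candidate_moves <- function(cells) {
    out <- list()
    for (i in seq_len(np)) {
      cur <- cells[i, ]
      cand <- ctx_cells(ctx, i)
      for (r in seq_len(nrow(cand))) {
        cc <- cand[r, ]
        if (all(cc == cur)) next
        type <- if (cur[1] == 0L) "move_start"
        else if (cc[1] != cur[1]) "reassign_room"
        else if (cc[2] != cur[2]) "reassign_surgeon"
        else "move_start"
        if (!type %in% config$neighborhood) next
        out[[length(out) + 1L]] <- list(type = type, i = i, cell = cc)
      }
    }
    if ("swap_patients" %in% config$neighborhood && np >= 2L) {
      for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
        if (cells[i, 1] == 0L || cells[j, 1] == 0L) next
        out[[length(out) + 1L]] <- list(type = "swap_patients", i = i, j = j)
      }
    }
    out
  }
  apply_move <- function(cells, mv) {
    if (mv$type == "swap_patients") {
      tmp <- cells[mv$i, ]; cells[mv$i, ] <- cells[mv$j, ]
      cells[mv$j, ] <- tmp
    } else cells[mv$i, ] <- mv$cell
    cells
  }

  iter <- 0L
  repeat {
    if (iter >= config$max_iterations) break
    best_mv <- NULL; best_v <- cur_v
    for (mv in candidate_moves(cells)) {
      trial <- apply_move(cells, mv)
      if (!ctx_feasible(ctx, trial)) next
      v <- ctx_cost(ctx, trial)
      if (v < best_v - 1e-9) {
        best_v <- v; best_mv <- mv
        if (config$accept == "first_improvement") break
      }
    }
    if (is.null(best_mv)) break
    cells <- apply_move(cells, best_mv)
    cur_v <- best_v
    iter <- iter + 1L
    moves[[iter]] <- data.frame(
      iteration = iter, type = best_mv$type,
      patient = ctx$ids[best_mv$i], cost = cur_v,
      stringsAsFactors = FALSE)
  }
  out <- cells_to_schedule(ctx, cells)
  attr(out, "moves") <- if (length(moves)) do.call(rbind, moves) else
    data.frame(iteration = integer(), type = character(),
               patient = character(), cost = numeric(),
               stringsAsFactors = FALSE)
  out
}

#' Construct-and-improve heuristic solve
#'
#' Runs the greedy construction followed by local search; additional
#' restarts rebuild from randomized construction orders and keep the best
#' outcome (fewest unplaced patients, then lowest cost).
#'
#' @param instance A \code{\link{surgical_instance}}.
#' @param config A \code{\link{search_config}}.
#' @return A list of class \code{"solve_report"} with status "feasible"
#'   (complete schedule) or "infeasible" (patients left unplaced after all
#'   restarts; the best partial schedule is still returned).
#' @export
solve_heuristic <- function(instance, config = search_config()) {
  t0 <- proc.time()[["elapsed"]]
  best <- NULL; best_key <- c(Inf, Inf)
  for (r in 0:config$restarts) {
    s0 <- construct_schedule(instance, seed = config$seed + r,
                             random_order = r > 0L)
    s1 <- improve_schedule(s0, instance, config)
    ctx <- make_ctx(instance)
    v <- ctx_cost(ctx, schedule_to_cells(ctx, s1))
    key <- c(length(attr(s1, "unplaced")), v)
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2] - 1e-12)) {
      best <- s1; best_key <- key
    }
  }
  complete <- best_key[1] == 0
  structure(list(
    status = if (complete) "feasible" else "infeasible",
    objective = if (complete) best_key[2] else NA_real_,
    bound = NA_real_, gap = NA_real_, schedule = best,
    wall_seconds = proc.time()[["elapsed"]] - t0),
    class = "solve_report")
}
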
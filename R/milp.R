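#' Chance-constraint reservation margin
#'
#' Deterministic-equivalent margin for a normally distributed demand: the
#' amount of capacity that must be set aside so the capacity constraint
#' holds with probability \code{alpha}. Equals
#' \code{mean + qnorm(alpha) * sqrt(variance)}; with zero variance the
#' margin collapses to the mean for every \code{alpha}, and
#' \code{alpha = 0.5} gives the pure expected-value model.
#'
#' @param mean,variance Numeric (vectors or matrices), demand mean and
#'   variance; \code{variance >= 0}.
#' @param alpha Number strictly inside (0, 1): required reliability.
#' @return Numeric of the same shape as \code{mean}.
#' @export
reserve_margin <- function(mean, variance, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number strictly inside (0, 1)")
  if (any(variance < 0)) stop("variance must be >= 0")
  mean + stats::qnorm(alpha) * sqrt(variance)
}

# Internal builder state: flat variable table plus sparse constraint rows.
new_model_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$obj <- numeric(); env$lb <- numeric(); env$ub <- numeric()
  env$integer <- logical(); env$vname <- character()
  env$ri <- list(); env$rj <- list(); env$rv <- list()
  env$rlb <- numeric(); env$rub <- numeric()
  env$req <- character(); env$ridx <- character()
  env$add_var <- function(name, obj = 0, lb = 0, ub = 1, integer = TRUE) {
    env$vname <- c(env$vname, name)
    env$obj <- c(env$obj, obj); env$lb <- c(env$lb, lb)
    env$ub <- c(env$ub, ub); env$integer <- c(env$integer, integer)
    length(env$vname)
  }
  env$add_row <- function(eq, idx, j, v, lb, ub) {
    k <- length(env$rlb) + 1L
    env$ri[[k]] <- rep(k, length(j)); env$rj[[k]] <- j; env$rv[[k]] <- v
    env$rlb[k] <- lb; env$rub[k] <- ub
    env$req[k] <- eq; env$ridx[k] <- idx
    invisible(k)
  }
  env
}

#' Build the scheduling MILP
#'
#' Translates a surgical instance into the mixed-integer program of the
#' deterministic chance-constraint equivalent model: binary start variables
#' x[p,o,s,t,d] for every elective patient over its eligible rooms/surgeons,
#' feasible start blocks and pre-deadline days; occupancy variables linked
#' by the window-expansion rows; ICU admission and occupancy variables; and
#' continuous idle, overtime and ICU-shortage variables. Deadline and
#' eligibility restrictions are enforced structurally (ineligible or
#' post-deadline start variables are never created). Stochastic room and
#' ICU capacities enter as individual chance constraints at level
#' \code{alpha} via \code{\link{reserve_margin}}; reserved room budgets are
#' floored at zero.
#'
#' @param instance A \code{\link{surgical_instance}}.
#' @param alpha Chance-constraint level; defaults to the instance's
#'   \code{reliability}.
#' @return A list of class \code{"milp_model"} holding the variable table,
#'   the sparse constraint rows keyed by model equation number, and the
#'   index maps used to extract a \code{\link{schedule}} from a solution.
#' @export
build_milp <- function(instance, alpha = instance$reliability) {
  cal <- instance$calendar
  el <- elective_patients(instance)
  ids <- vapply(el, `[[`, character(1), "id")
  np <- length(el); nO <- length(instance$rooms)
  nS <- length(instance$surgeons); TT <- cal$blocks_per_day; DD <- cal$days
  b <- new_model_builder()

  xi <- array(0L, c(np, nO, nS, TT, DD))
  xb <- array(0L, c(np, nO, nS, TT, DD))
  for (i in seq_len(np)) {
    p <- el[[i]]
    for (o in seq_len(nO)) {
      if (!isTRUE(p$room_eligible[[instance$rooms[o]]])) next
      for (s in seq_len(nS)) {
        if (!isTRUE(p$surgeon_eligible[[instance$surgeons[s]]])) next
        cp <- p$assign_cost[o, s]
        for (d in seq_len(min(p$deadline, DD))) {
          for (t in seq_len(TT - p$duration + 1L))
            xi[i, o, s, t, d] <- b$add_var(
              sprintf("x[%s,%s,%s,%d,%d]", p$id, instance$rooms[o],
                      instance$surgeons[s], t, d), obj = cp)
          for (t in seq_len(min(TT, TT))) {
            win <- max(t - p$duration + 1L, 1L):t
            win <- win[win <= TT - p$duration + 1L]
            if (!length(win)) next
            xb[i, o, s, t, d] <- b$add_var(
              sprintf("xb[%s,%s,%s,%d,%d]", p$id, instance$rooms[o],
                      instance$surgeons[s], t, d))
            # (7) occupancy window linkage
            b$add_row("7", sprintf("p=%s,o=%s,s=%s,t=%d,d=%d", p$id,
                                   instance$rooms[o], instance$surgeons[s],
                                   t, d),
                      c(xb[i, o, s, t, d], xi[i, o, s, win, d]),
                      c(1, rep(-1, length(win))), 0, 0)
          }
        }
      }
    }
  }

  yi <- matrix(0L, np, DD); ybi <- matrix(0L, np, DD)
  for (i in seq_len(np)) for (d in seq_len(DD)) {
    yi[i, d] <- b$add_var(sprintf("y[%s,%d]", ids[i], d))
    ybi[i, d] <- b$add_var(sprintf("yb[%s,%d]", ids[i], d))
  }
  zi <- integer(DD)
  for (d in seq_len(DD))
    zi[d] <- b$add_var(sprintf("Z[%d]", d),
                       obj = instance$icu$shortage_cost[d],
                       ub = Inf, integer = FALSE)
  ai <- bi <- matrix(0L, nO, DD)
  for (o in seq_len(nO)) for (d in seq_len(DD)) {
    ai[o, d] <- b$add_var(sprintf("idle[%s,%d]", instance$rooms[o], d),
                          obj = instance$costs$idle_cost[o, d],
                          ub = Inf, integer = FALSE)
    bi[o, d] <- b$add_var(sprintf("ot[%s,%d]", instance$rooms[o], d),
                          obj = instance$costs$overtime_cost[o, d],
                          ub = Inf, integer = FALSE)
  }

  nz <- function(v) v[v > 0L]

  # (6) full elective coverage
  for (i in seq_len(np))
    b$add_row("6", paste0("p=", ids[i]), nz(xi[i, , , , ]),
              rep(1, length(nz(xi[i, , , , ]))), 1, 1)

  # (8) cleaning after infectious starts, (23) infectious-last
  for (i in seq_len(np)) {
    q <- el[[i]]
    if (!q$infectious) next
    noninf <- which(!vapply(el, `[[`, logical(1), "infectious"))
    for (o in seq_len(nO)) for (d in seq_len(DD)) for (tp in seq_len(TT)) {
      qstart <- nz(xi[i, o, , tp, d])
      if (!length(qstart)) next
      wend <- min(tp + q$duration + q$cleaning_blocks - 1L, TT)
      others <- setdiff(seq_len(np), i)
      ov <- unlist(lapply(others, function(m) nz(xi[m, o, , tp:wend, d])))
      if (length(ov)) {
        # conditional on q starting at tp: no other start inside the
        # surgery+cleaning window (big-M linearization; M bounded by the
        # window length since starts in one room-block are exclusive)
        M <- min(np - 1L, wend - tp + 1L)
        b$add_row("8", sprintf("q=%s,o=%s,t=%d,d=%d", q$id,
                               instance$rooms[o], tp, d),
                  c(ov, qstart),
                  c(rep(1, length(ov)), rep(M, length(qstart))),
                  -Inf, M)
      }
      if (tp < TT) {
        lv <- unlist(lapply(noninf, function(m)
          nz(xi[m, o, , (tp + 1L):TT, d])))
        if (length(lv)) {
          # conditional on q starting at tp: no non-infectious start later
          # that day in this room (big-M linearization)
          M <- min(length(noninf), TT - tp)
          b$add_row("23", sprintf("q=%s,o=%s,t=%d,d=%d", q$id,
                                  instance$rooms[o], tp, d),
                    c(lv, qstart),
                    c(rep(1, length(lv)), rep(M, length(qstart))),
                    -Inf, M)
        }
      }
    }
  }

  # (9) room and (10) surgeon non-overlap per block
  for (t in seq_len(TT)) for (d in seq_len(DD)) {
    for (o in seq_len(nO)) {
      v <- nz(xb[, o, , t, d])
      if (length(v) > 1L)
        b$add_row("9", sprintf("o=%s,t=%d,d=%d", instance$rooms[o], t, d),
                  v, rep(1, length(v)), -Inf, 1)
    }
    for (s in seq_len(nS)) {
      v <- nz(xb[, , s, t, d])
      if (length(v) > 1L)
        b$add_row("10", sprintf("s=%s,t=%d,d=%d", instance$surgeons[s], t, d),
                  v, rep(1, length(v)), -Inf, 1)
    }
  }

  # (14) surgeon daily cap, (19) surgeon horizon cap
  G <- instance$surgeon_limits$daily_elective_blocks
  for (s in seq_len(nS)) {
    for (d in seq_len(DD)) {
      v <- nz(xb[, , s, , d])
      if (length(v))
        b$add_row("14", sprintf("s=%s,d=%d", instance$surgeons[s], d),
                  v, rep(1, length(v)), -Inf, G)
    }
    v <- nz(xb[, , s, , ])
    if (length(v))
      b$add_row("19", paste0("s=", instance$surgeons[s]),
                v, rep(1, length(v)), -Inf,
                instance$surgeon_limits$horizon_blocks[[instance$surgeons[s]]])
  }

  # (15) elective budget, (16) emergency-reserved budget,
  # (17)/(18) idle and overtime definitions
  rc <- instance$room_capacity
  budget16 <- elective_reserved_budget(instance, alpha)
  for (o in seq_len(nO)) for (d in seq_len(DD)) {
    v <- nz(xb[, o, , , d])
    HN <- rc$regular_blocks[o, d]
    if (length(v)) {
      b$add_row("15", sprintf("o=%s,d=%d", instance$rooms[o], d),
                v, rep(1, length(v)), -Inf,
                HN + rc$elective_overtime_blocks[o, d])
      b$add_row("16", sprintf("o=%s,d=%d", instance$rooms[o], d),
                v, rep(1, length(v)), -Inf, budget16[o, d])
    }
    b$add_row("17", sprintf("o=%s,d=%d", instance$rooms[o], d),
              c(ai[o, d], v), c(1, rep(1, length(v))), HN, Inf)
    b$add_row("18", sprintf("o=%s,d=%d", instance$rooms[o], d),
              c(bi[o, d], v), c(1, rep(-1, length(v))), -HN, Inf)
  }

  # (20) ICU admission linkage (big-M = blocks per day),
  # (21) ICU occupancy windows
  for (i in seq_len(np)) {
    dI <- el[[i]]$icu_days
    for (d in seq_len(DD)) {
      v <- nz(xb[i, , , , d])
      if (length(v))
        b$add_row("20", sprintf("p=%s,d=%d", ids[i], d),
                  c(v, yi[i, d]), c(rep(1, length(v)), -TT), -Inf, 0)
      win <- if (dI > 0L) max(d - dI + 1L, 1L):d else integer()
      b$add_row("21", sprintf("p=%s,d=%d", ids[i], d),
                c(ybi[i, d], yi[i, win]), c(1, rep(-1, length(win))), 0, 0)
    }
  }

  # (22) chance-constrained ICU bed budget
  budget22 <- icu_bed_budget(instance, alpha)
  for (d in seq_len(DD))
    b$add_row("22", paste0("d=", d), c(ybi[, d], zi[d]),
              c(rep(1, np), -1), -Inf, budget22[d])

  structure(list(
    instance = instance, alpha = alpha, rescheduling = FALSE,
    obj = b$obj, lb = b$lb, ub = b$ub, integer = b$integer,
    vname = b$vname,
    ri = unlist(b$ri), rj = unlist(b$rj), rv = unlist(b$rv),
    rlb = b$rlb, rub = b$rub, req = b$req, ridx = b$ridx,
    xi = xi, elective_ids = ids
  ), class = "milp_model")
}

#' Add the rescheduling extension to a model
#'
#' Extends the objective with change penalties for patients that carry a
#' baseline start: a binary change indicator per baselined patient is forced
#' to 1 whenever the chosen start deviates from the baseline cell, priced at
#' the patient's change cost, and the cumulative change count (prior changes
#' plus this one) is capped at the instance's \code{reschedule_limit}. A cap
#' already exhausted pins the patient to its baseline; if that cell is
#' infeasible the model as a whole becomes infeasible (reported by the
#' solver, not as an error).
#'
#' @param model A \code{\link{build_milp}} model.
#' @param instance The instance the model was built from.
#' @return The extended \code{"milp_model"}.
#' @export
add_rescheduling <- function(model, instance) {
  el <- elective_patients(instance)
  based <- Filter(function(p) !is.null(p$baseline_start), el)
  if (!length(based))
    stop("rescheduling extension needs at least one patient with a baseline start")
  theta <- instance$costs$reschedule_limit
  nxt <- length(model$obj)
  k <- length(model$rlb)
  for (p in based) {
    nxt <- nxt + 1L
    model$obj <- c(model$obj, p$change_cost)
    model$lb <- c(model$lb, 0); model$ub <- c(model$ub, 1)
    model$integer <- c(model$integer, TRUE)
    model$vname <- c(model$vname, paste0("gamma[", p$id, "]"))
    b <- p$baseline_start
    i <- match(p$id, model$elective_ids)
    o <- match(b$room, instance$rooms)
    s <- match(b$surgeon, instance$surgeons)
    cell <- model$xi[i, o, s, b$block, b$day]
    k <- k + 1L
    if (cell > 0L) {
      # R1: gamma >= 1 - x[baseline]
      model$ri <- c(model$ri, k, k); model$rj <- c(model$rj, nxt, cell)
      model$rv <- c(model$rv, 1, 1)
      model$rlb[k] <- 1; model$rub[k] <- Inf
    } else {
      # baseline cell structurally infeasible: change is forced
      model$ri <- c(model$ri, k); model$rj <- c(model$rj, nxt)
      model$rv <- c(model$rv, 1)
      model$rlb[k] <- 1; model$rub[k] <- Inf
    }
    model$req[k] <- "R1"; model$ridx[k] <- paste0("p=", p$id)
    # R2: prior + gamma <= theta
    k <- k + 1L
    model$ri <- c(model$ri, k); model$rj <- c(model$rj, nxt)
    model$rv <- c(model$rv, 1)
    model$rlb[k] <- -Inf; model$rub[k] <- theta - p$prior_changes
    model$req[k] <- "R2"; model$ridx[k] <- paste0("p=", p$id)
  }
  model$rescheduling <- TRUE
  model
}

#' @export
print.milp_model <- function(x, ...) {
  cat(sprintf("Scheduling MILP: %d variables (%d integer), %d rows; alpha = %.3g%s\n",
              length(x$obj), sum(x$integer), length(x$rlb), x$alpha,
              if (x$rescheduling) " (+rescheduling)" else ""))
  tb <- table(x$req)
  cat("  rows by equation:",
      paste(sprintf("%s:%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

#' Solve a scheduling MILP
#'
#' Solves the model by branch-and-cut (the HiGHS solver, driven through a
#' bundled SciPy bridge; single-threaded and deterministic). On an optimal
#' or feasible outcome the start variables are extracted into a
#' \code{\link{schedule}} whose canonical re-evaluation matches the solver
#' objective.
#'
#' @param model A \code{\link{build_milp}} model.
#' @param time_limit Wall-clock limit in seconds (default 60).
#' @param gap Relative MIP gap tolerance (default 1e-6).
#' @return A list of class \code{"solve_report"}: \code{status} (one of
#'   "optimal", "feasible", "infeasible", "time_limit"), \code{objective},
#'   \code{bound}, \code{gap}, \code{schedule} (NULL unless a solution was
#'   found) and \code{wall_seconds}.
#' @export
solve_milp <- function(model, time_limit = 60, gap = 1e-6) {
  solve_milp_batch(list(model), time_limit = time_limit, gap = gap)[[1]]
}

#' Solve several scheduling MILPs in one solver call
#'
#' Same as \code{\link{solve_milp}} applied to each model, but amortizes the
#' solver-process start-up over the whole batch; used by the test-scale
#' experiments that solve hundreds of small instances.
#'
#' @param models List of \code{\link{build_milp}} models.
#' @inheritParams solve_milp
#' @return List of \code{"solve_report"} objects, one per model.
#' @export
solve_milp_batch <- function(models, time_limit = 60, gap = 1e-6) {
  payload <- lapply(models, function(m) list(
    obj = m$obj, lb = m$lb, ub = m$ub, integer = as.integer(m$integer),
    ri = m$ri, rj = m$rj, rv = m$rv, rlb = m$rlb, rub = m$rub,
    options = list(time_limit = jsonlite::unbox(time_limit),
                   mip_rel_gap = jsonlite::unbox(gap))
  ))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = FALSE,
                       na = "null")
  script <- system.file("python", "milp_solve.py", package = "orsched")
  if (!nzchar(script))
    script <- file.path("inst", "python", "milp_solve.py")
  if (!file.exists(script))
    stop("MILP bridge script not found; reinstall the package")
  status <- system2("python", c(shQuote(script), shQuote(fin), shQuote(fout)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0)
    stop("MILP solver bridge failed (is python with scipy >= 1.9 on PATH?):\n",
         paste(status, collapse = "\n"))
  res <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  Map(function(m, r) extract_report(m, r), models, res)
}

extract_report <- function(model, r) {
  status <- switch(as.character(r$status),
                   "0" = "optimal", "1" = "time_limit", "2" = "infeasible",
                   "3" = "infeasible", "feasible")
  sched <- NULL; objective <- NA_real_
  if (!is.null(r$x) && length(r$x)) {
    x <- unlist(r$x)
    inst <- model$instance
    sel <- which(model$xi > 0L, arr.ind = TRUE)
    on <- sel[x[model$xi[sel]] > 0.5, , drop = FALSE]
    starts <- data.frame(
      patient = model$elective_ids[on[, 1]],
      room = inst$rooms[on[, 2]],
      surgeon = inst$surgeons[on[, 3]],
      block = as.integer(on[, 4]),
      day = as.integer(on[, 5]),
      stringsAsFactors = FALSE)
    sched <- schedule(starts, inst)
    objective <- as.numeric(r$objective)
    if (status == "time_limit") status <- "feasible"
  } else if (status == "time_limit") {
    # hit the limit without an incumbent
    sched <- NULL
  }
  structure(list(status = status, objective = objective,
                 bound = if (is.null(r$bound)) NA_real_ else
                   as.numeric(r$bound),
                 gap = if (is.null(r$gap)) NA_real_ else as.numeric(r$gap),
                 schedule = sched,
                 wall_seconds = as.numeric(r$wall_seconds)),
            class = "solve_report")
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("Solve: %s", x$status))
  if (!is.na(x$objective))
    cat(sprintf(", objective %.6g (bound %.6g, gap %.2g)",
                x$objective, x$bound, x$gap))
  cat(sprintf(", %.3fs\n", x$wall_seconds))
  invisible(x)
}
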
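INSTANCE_SCHEMA <- "orsched-instance/1"

#' Write a surgical instance to JSON
#'
#' Serializes an instance to the versioned \code{orsched-instance/1} JSON
#' schema. Eligibility vectors and per-day vectors are written as arrays in
#' the instance's room/surgeon/day order; matrices as nested row arrays.
#' Writing the same instance twice yields byte-identical files.
#'
#' @param instance A \code{\link{surgical_instance}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_instance <- function(instance, path) {
  p2l <- function(p) list(
    id = p$id, duration = p$duration, deadline = p$deadline,
    icu_days = p$icu_days, infectious = p$infectious,
    emergency = p$emergency, cleaning_blocks = p$cleaning_blocks,
    room_eligible = unname(p$room_eligible[instance$rooms]),
    surgeon_eligible = unname(p$surgeon_eligible[instance$surgeons]),
    assign_cost = unname(p$assign_cost),
    baseline_start = p$baseline_start,
    prior_changes = p$prior_changes, change_cost = p$change_cost)
  obj <- list(
    schema = INSTANCE_SCHEMA,
    rooms = instance$rooms, surgeons = instance$surgeons,
    calendar = list(days = instance$calendar$days,
                    blocks_per_day = instance$calendar$blocks_per_day),
    reliability = instance$reliability,
    patients = lapply(instance$patients, p2l),
    room_capacity = lapply(unclass(instance$room_capacity)[1:5], unname),
    surgeon_limits = list(
      daily_elective_blocks = instance$surgeon_limits$daily_elective_blocks,
      horizon_blocks =
        unname(instance$surgeon_limits$horizon_blocks[instance$surgeons])),
    icu = unclass(instance$icu)[1:5],
    costs = list(idle_cost = unname(instance$costs$idle_cost),
                 overtime_cost = unname(instance$costs$overtime_cost),
                 reschedule_limit = instance$costs$reschedule_limit))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

need <- function(obj, field, where = "") {
  if (is.null(obj[[field]]))
    stop("instance JSON missing required field ", where, "/", field)
  obj[[field]]
}

as_mat <- function(x, nr, nc, rn) {
  m <- matrix(as.numeric(unlist(x)), nr, nc, byrow = TRUE)
  rownames(m) <- rn
  m
}

#' Read a surgical instance from JSON
#'
#' Parses and validates a file written by \code{\link{write_instance}};
#' \code{read_instance(write_instance(x)) } reproduces \code{x}. Files with
#' an unknown schema version or missing required fields are rejected with
#' an error naming the offending JSON pointer.
#'
#' @param path Path to an \code{orsched-instance/1} JSON file.
#' @return A \code{\link{surgical_instance}}.
#' @export
read_instance <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  schema <- need(obj, "schema")
  if (!identical(schema, INSTANCE_SCHEMA))
    stop("unsupported instance schema version '", schema,
         "' (this build reads ", INSTANCE_SCHEMA, ")")
  rooms <- need(obj, "rooms"); surgeons <- need(obj, "surgeons")
  cal <- need(obj, "calendar")
  nO <- length(rooms); nS <- length(surgeons)
  nD <- need(cal, "days", "/calendar")
  pats <- lapply(need(obj, "patients"), function(p) patient(
    id = need(p, "id", "/patients"),
    duration = p$duration, deadline = p$deadline, icu_days = p$icu_days,
    infectious = p$infectious, emergency = p$emergency,
    cleaning_blocks = p$cleaning_blocks,
    room_eligible = stats::setNames(as.logical(unlist(p$room_eligible)),
                                    rooms),
    surgeon_eligible = stats::setNames(
      as.logical(unlist(p$surgeon_eligible)), surgeons),
    assign_cost = as_mat(p$assign_cost, nO, nS, rooms),
    baseline_start = p$baseline_start,
    prior_changes = p$prior_changes, change_cost = p$change_cost))
  rc <- need(obj, "room_capacity")
  icu <- need(obj, "icu")
  costs <- need(obj, "costs")
  sl <- need(obj, "surgeon_limits")
  surgical_instance(
    patients = pats, rooms = rooms, surgeons = surgeons,
    calendar = calendar(nD, need(cal, "blocks_per_day", "/calendar")),
    room_capacity = room_capacity(
      as_mat(need(rc, "regular_blocks", "/room_capacity"), nO, nD, rooms),
      as_mat(rc$elective_overtime_blocks, nO, nD, rooms),
      as_mat(rc$emergency_overtime_blocks, nO, nD, rooms),
      as_mat(rc$emergency_demand_mean, nO, nD, rooms),
      as_mat(rc$emergency_demand_var, nO, nD, rooms)),
    surgeon_limits = surgeon_limits(
      need(sl, "daily_elective_blocks", "/surgeon_limits"),
      stats::setNames(as.numeric(unlist(sl$horizon_blocks)), surgeons)),
    icu = icu_params(as.numeric(unlist(icu$capacity_mean)),
                     as.numeric(unlist(icu$capacity_var)),
                     as.numeric(unlist(icu$emergency_mean)),
                     as.numeric(unlist(icu$emergency_var)),
                     as.numeric(unlist(icu$shortage_cost))),
    costs = cost_params(as_mat(costs$idle_cost, nO, nD, rooms),
                        as_mat(costs$overtime_cost, nO, nD, rooms),
                        need(costs, "reschedule_limit", "/costs")),
    reliability = need(obj, "reliability"))
}

#' Write a schedule to CSV
#'
#' Fixed dialect: comma separated, header row, UTF-8, LF line endings, one
#' row per assigned patient with 1-based block indices; an empty schedule
#' yields a header-only file.
#'
#' @param sched An \code{\link{schedule}}.
#' @param instance The matching instance (for durations / end blocks).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_schedule <- function(sched, instance, path) {
  st <- sched$starts[!is.na(sched$starts$room), , drop = FALSE]
  dur <- vapply(st$patient, function(id)
    patient_by_id(instance, id)$duration, integer(1))
  out <- data.frame(patient = st$patient, room = st$room,
                    surgeon = st$surgeon, day = st$day,
                    start_block = st$block,
                    end_block = st$block + dur - 1L,
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a schedule from CSV
#'
#' @param path Path to a CSV written by \code{\link{write_schedule}}.
#' @param instance The matching \code{\link{surgical_instance}}.
#' @return An \code{\link{schedule}}.
#' @export
read_schedule <- function(path, instance) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(df$patient))
    stop("schedule CSV has duplicate rows for patient '",
         df$patient[duplicated(df$patient)][1], "'")
  schedule(data.frame(patient = as.character(df$patient),
                      room = as.character(df$room),
                      surgeon = as.character(df$surgeon),
                      block = as.integer(df$start_block),
                      day = as.integer(df$day),
                      stringsAsFactors = FALSE), instance)
}

#' Write a cost breakdown to CSV
#'
#' @param cb A \code{\link{cost_breakdown}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_costs <- function(cb, path) {
  out <- data.frame(component = c("assignment", "idle", "overtime",
                                  "icu_shortage", "reschedule", "total"),
                    cost = c(cb$assignment, cb$idle, cb$overtime,
                             cb$icu_shortage, cb$reschedule, cb$total))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Write a validator report as JSON lines
#'
#' One JSON object per violation, in the validator's deterministic order.
#'
#' @param violations Data frame from \code{\link{validate_schedule}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_violations <- function(violations, path) {
  lines <- vapply(seq_len(nrow(violations)), function(i)
    as.character(jsonlite::toJSON(as.list(violations[i, ]),
                                  auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an OLAS clinic configuration as JSON
#'
#' @param config An \code{\link{olas_config}}.
#' @param path File path.
#' @return \code{path} (write) or an \code{\link{olas_config}} (read).
#' @export
write_olas_config <- function(config, path) {
  obj <- unclass(config)
  if (!is.null(obj$service_olas)) obj$service_olas <- unclass(obj$service_olas)
  if (!is.null(obj$service_doc)) obj$service_doc <- unclass(obj$service_doc)
  jsonlite::write_json(obj, path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_olas_config
#' @export
read_olas_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(d) if (is.null(d)) NULL else do.call(service_dist, d)
  olas_config(n_olas = o$n_olas, n_doc = o$n_doc,
              service_olas = mk(o$service_olas),
              service_doc = mk(o$service_doc),
              closing_time = o$closing_time,
              cost_wait_olas = o$cost_wait_olas,
              cost_wait_doc = o$cost_wait_doc,
              cost_idle = o$cost_idle, cost_overtime = o$cost_overtime,
              arrival_jitter_sd = o$arrival_jitter_sd,
              no_show_prob = o$no_show_prob, seed = o$seed)
}

#' Write / read an appointment template as JSON
#'
#' @param template An \code{\link{appointment_template}}.
#' @param path File path.
#' @return \code{path} (write) or an \code{\link{appointment_template}}
#'   (read).
#' @export
write_template <- function(template, path) {
  jsonlite::write_json(list(times_olas = template$times_olas,
                            times_doc = template$times_doc),
                       path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  appointment_template(if (is.null(o$times_olas)) integer() else o$times_olas,
                       if (is.null(o$times_doc)) integer() else o$times_doc)
}
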
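#' Synthetic instance generator specification
#'
#' Describes a family of surgical scheduling instances. The defaults
#' reproduce the shape of the small-scale illustration class: 10 patients of
#' whom the first 3 are infectious, 3 operating rooms, 3 surgeons, a 5-day
#' week of 6 time blocks per day. Numeric parameter values (durations,
#' costs, capacities) are the generator's own documented ranges — the
#' instance class fixes only the shape, not the values.
#'
#' @param n_patients,n_infectious,n_rooms,n_surgeons,n_days,blocks_per_day
#'   Positive integer counts (\code{n_infectious <= n_patients}; the first
#'   \code{n_infectious} patients are the infectious ones).
#' @param duration_range,deadline_range,icu_days_range,cleaning_range
#'   Integer intervals \code{c(lo, hi)} sampled uniformly per patient.
#' @param assign_cost_range,idle_cost_range,overtime_cost_range,
#'   shortage_cost_range,change_cost_range Numeric intervals for the cost
#'   coefficients.
#' @param regular_blocks_range,elective_overtime_range,emergency_overtime_range
#'   Integer intervals for the per-room-day block budgets.
#' @param emergency_or_mean_range,emergency_or_var_range Numeric intervals
#'   for the normal emergency operating-room demand per room-day.
#' @param icu_capacity_mean_range,icu_capacity_var_range,
#'   icu_emergency_mean_range,icu_emergency_var_range Numeric intervals for
#'   the normal ICU supply/demand per day.
#' @param eligibility_density Probability in (0, 1] that a given room or
#'   surgeon is eligible for a patient (resampled per patient until at least
#'   one room and one surgeon are eligible).
#' @param surgeon_daily_blocks Shared daily elective cap per surgeon;
#'   default = \code{blocks_per_day}.
#' @param surgeon_horizon_frac Fraction of the full horizon each surgeon may
#'   work in total (default 0.7).
#' @param reliability Chance-constraint level of generated instances.
#' @param seed Integer seed; generation is a deterministic function of the
#'   spec including the seed.
#' @return A list of class \code{"generator_spec"}.
#' @export
generator_spec <- function(n_patients = 10L, n_infectious = 3L,
                           n_rooms = 3L, n_surgeons = 3L, n_days = 5L,
                           blocks_per_day = 6L,
                           duration_range = c(1L, 3L),
                           deadline_range = c(2L, 5L),
                           icu_days_range = c(0L, 3L),
                           cleaning_range = c(1L, 2L),
                           assign_cost_range = c(10, 50),
                           idle_cost_range = c(1, 5),
                           overtime_cost_range = c(5, 15),
                           shortage_cost_range = c(20, 60),
                           change_cost_range = c(5, 20),
                           regular_blocks_range = c(4L, 6L),
                           elective_overtime_range = c(0L, 2L),
                           emergency_overtime_range = c(1L, 2L),
                           emergency_or_mean_range = c(0.5, 1.5),
                           emergency_or_var_range = c(0.1, 0.5),
                           icu_capacity_mean_range = c(3, 6),
                           icu_capacity_var_range = c(0.2, 1),
                           icu_emergency_mean_range = c(0, 1),
                           icu_emergency_var_range = c(0.1, 0.3),
                           eligibility_density = 0.8,
                           surgeon_daily_blocks = blocks_per_day,
                           surgeon_horizon_frac = 0.7,
                           reliability = 0.95,
                           seed = 1L) {
  spec <- as.list(environment())
  if (spec$n_infectious > spec$n_patients)
    stop("generator spec: n_infectious exceeds n_patients")
  if (spec$duration_range[1] > spec$blocks_per_day)
    stop("generator spec: duration_range lower bound exceeds blocks_per_day")
  if (spec$deadline_range[1] > spec$n_days)
    stop("generator spec: deadline_range lower bound exceeds n_days")
  for (nm in grep("_range$", names(spec), value = TRUE))
    if (spec[[nm]][1] > spec[[nm]][2])
      stop("generator spec: empty interval in ", nm)
  if (eligibility_density <= 0 || eligibility_density > 1)
    stop("generator spec: eligibility_density must be in (0, 1]")
  structure(spec, class = "generator_spec")
}

# Independent substream per field group: adding a field group never
# perturbs the draws of earlier groups.
substream_seed <- function(seed, group) {
  h <- sum(utf8ToInt(group) * seq_along(utf8ToInt(group)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

ri <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(range[1]:range[2], n, replace = TRUE)
}
ru <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate a surgical scheduling instance
#'
#' Deterministic function of the spec (including its seed). Feasibility of
#' the generated instance is not guaranteed: tight capacities can make an
#' instance infeasible, which is a legitimate output.
#'
#' @param spec A \code{\link{generator_spec}}.
#' @return A \code{\link{surgical_instance}}.
#' @export
generate_instance <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_patients; nO <- spec$n_rooms; nS <- spec$n_surgeons
  nD <- spec$n_days
  rooms <- paste0("R", seq_len(nO)); surgeons <- paste0("S", seq_len(nS))
  ids <- paste0("P", seq_len(n))
  infectious <- seq_len(n) <= spec$n_infectious

  set.seed(substream_seed(spec$seed, "durations"))
  duration <- pmin(ri(n, spec$duration_range), spec$blocks_per_day)
  set.seed(substream_seed(spec$seed, "deadlines"))
  deadline <- pmin(ri(n, spec$deadline_range), nD)
  set.seed(substream_seed(spec$seed, "icu_days"))
  icu_days <- ri(n, spec$icu_days_range)
  set.seed(substream_seed(spec$seed, "cleaning"))
  cleaning <- ifelse(infectious, ri(n, spec$cleaning_range), 0L)

  set.seed(substream_seed(spec$seed, "eligibility"))
  relig <- matrix(FALSE, n, nO); selig <- matrix(FALSE, n, nS)
  for (i in seq_len(n)) {
    repeat {
      r <- stats::runif(nO) < spec$eligibility_density
      s <- stats::runif(nS) < spec$eligibility_density
      if (any(r) && any(s)) { relig[i, ] <- r; selig[i, ] <- s; break }
    }
  }

  set.seed(substream_seed(spec$seed, "assign_costs"))
  acost <- lapply(seq_len(n), function(i)
    matrix(ru(nO * nS, spec$assign_cost_range), nO, nS,
           dimnames = list(rooms, surgeons)))

  set.seed(substream_seed(spec$seed, "capacities"))
  dn <- list(rooms, NULL)
  HN <- matrix(ri(nO * nD, spec$regular_blocks_range), nO, nD, dimnames = dn)
  HN <- pmin(HN, spec$blocks_per_day)
  HS <- matrix(ri(nO * nD, spec$elective_overtime_range), nO, nD,
               dimnames = dn)
  HO <- matrix(ri(nO * nD, spec$emergency_overtime_range), nO, nD,
               dimnames = dn)

  set.seed(substream_seed(spec$seed, "stochastic"))
  hm_mean <- matrix(ru(nO * nD, spec$emergency_or_mean_range), nO, nD,
                    dimnames = dn)
  hm_var <- matrix(ru(nO * nD, spec$emergency_or_var_range), nO, nD,
                   dimnames = dn)
  icu_cap_mean <- ru(nD, spec$icu_capacity_mean_range)
  icu_cap_var <- ru(nD, spec$icu_capacity_var_range)
  icu_em_mean <- ru(nD, spec$icu_emergency_mean_range)
  icu_em_var <- ru(nD, spec$icu_emergency_var_range)

  set.seed(substream_seed(spec$seed, "costs"))
  EC <- matrix(ru(nO * nD, spec$idle_cost_range), nO, nD, dimnames = dn)
  LC <- matrix(ru(nO * nD, spec$overtime_cost_range), nO, nD, dimnames = dn)
  U <- ru(nD, spec$shortage_cost_range)
  dcost <- ru(n, spec$change_cost_range)

  patients <- lapply(seq_len(n), function(i) patient(
    id = ids[i], duration = duration[i], deadline = deadline[i],
    icu_days = icu_days[i], infectious = infectious[i],
    cleaning_blocks = cleaning[i],
    room_eligible = stats::setNames(relig[i, ], rooms),
    surgeon_eligible = stats::setNames(selig[i, ], surgeons),
    assign_cost = acost[[i]], change_cost = dcost[i]))

  mt <- ceiling(spec$surgeon_horizon_frac * nD * spec$blocks_per_day)
  surgical_instance(
    patients = patients, rooms = rooms, surgeons = surgeons,
    calendar = calendar(nD, spec$blocks_per_day),
    room_capacity = room_capacity(HN, HS, HO, hm_mean, hm_var),
    surgeon_limits = surgeon_limits(
      spec$surgeon_daily_blocks,
      stats::setNames(rep(mt, nS), surgeons)),
    icu = icu_params(icu_cap_mean, icu_cap_var, icu_em_mean, icu_em_var, U),
    costs = cost_params(EC, LC, reschedule_limit = 1L),
    reliability = spec$reliability)
}

#' OLAS clinic generator specification
#'
#' @param n_olas,n_doc Patient counts of the two appointment streams.
#' @param closing_time Clinic closing time in minutes.
#' @param family Service-time distribution family: "lognormal",
#'   "exponential" or "deterministic".
#' @param mean_range Interval for the mean service time (minutes).
#' @param cv_range Interval for the coefficient of variation (lognormal
#'   only).
#' @param wait_cost_range,idle_cost_range,overtime_cost_range Intervals for
#'   the unit costs per minute.
#' @param arrival_jitter_sd Standard deviation of arrival unpunctuality in
#'   minutes; 0 means punctual arrivals.
#' @param seed Integer seed.
#' @return A list of class \code{"olas_generator_spec"}.
#' @export
olas_generator_spec <- function(n_olas = 4L, n_doc = 4L, closing_time = 240,
                                family = "lognormal",
                                mean_range = c(10, 25),
                                cv_range = c(0.3, 0.8),
                                wait_cost_range = c(0.5, 2),
                                idle_cost_range = c(1, 4),
                                overtime_cost_range = c(2, 6),
                                arrival_jitter_sd = 0,
                                seed = 1L) {
  if (!family %in% c("lognormal", "exponential", "deterministic"))
    stop("unknown service distribution family '", family, "'")
  stopifnot(n_olas >= 0, n_doc >= 0, closing_time > 0)
  structure(as.list(environment()), class = "olas_generator_spec")
}

#' Generate an OLAS clinic configuration
#'
#' Draws service-time distribution parameters and unit costs inside the
#' spec's ranges; deterministic in the spec's seed.
#'
#' @param spec An \code{\link{olas_generator_spec}}.
#' @return An \code{\link{olas_config}}.
#' @export
generate_olas <- function(spec) {
  stopifnot(inherits(spec, "olas_generator_spec"))
  set.seed(substream_seed(spec$seed, "olas_services"))
  mk <- function() {
    m <- ru(1, spec$mean_range)
    switch(spec$family,
           deterministic = service_dist("deterministic", value = m),
           exponential = service_dist("exponential", rate = 1 / m),
           lognormal = {
             cv <- ru(1, spec$cv_range)
             sdl <- sqrt(log(1 + cv^2))
             service_dist("lognormal", meanlog = log(m) - sdl^2 / 2,
                          sdlog = sdl)
           })
  }
  s_olas <- mk(); s_doc <- mk()
  set.seed(substream_seed(spec$seed, "olas_costs"))
  olas_config(
    n_olas = spec$n_olas, n_doc = spec$n_doc,
    service_olas = s_olas, service_doc = s_doc,
    closing_time = spec$closing_time,
    cost_wait_olas = ru(1, spec$wait_cost_range),
    cost_wait_doc = ru(1, spec$wait_cost_range),
    cost_idle = ru(1, spec$idle_cost_range),
    cost_overtime = ru(1, spec$overtime_cost_range),
    arrival_jitter_sd = spec$arrival_jitter_sd,
    seed = spec$seed)
}
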
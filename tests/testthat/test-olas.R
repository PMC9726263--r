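test_that("single-day dynamics reproduce hand-worked timelines", {
  # one patient: no wait, no idle, no overtime
  cfg1 <- olas_config(1, 0, service_dist("deterministic", value = 10), NULL,
                      closing_time = 100)
  tr <- simulate_day(appointment_template(0L), cfg1, seed = 1)
  expect_equal(tr$patients$wait, 0)
  expect_equal(tr$patients$idle, 0)
  expect_equal(tr$patients$flow, 10)
  expect_equal(tr$overtime, 0)

  # arrivals 0,5,10 with S=8 against T=20: growing queue and overtime 4
  cfg3 <- olas_config(3, 0, service_dist("deterministic", value = 8), NULL,
                      closing_time = 20)
  tr3 <- simulate_day(appointment_template(c(0L, 5L, 10L)), cfg3, seed = 1)
  expect_equal(tr3$patients$wait, c(0, 3, 6))
  expect_equal(tr3$patients$idle, c(0, 0, 0))
  expect_equal(tr3$patients$flow, c(8, 11, 14))
  expect_equal(tr3$overtime, 4)

  # widely spaced arrivals: pure idle, no waiting
  cfg2 <- olas_config(2, 0, service_dist("deterministic", value = 1), NULL,
                      closing_time = 200)
  tr2 <- simulate_day(appointment_template(c(0L, 100L)), cfg2, seed = 1)
  expect_equal(tr2$patients$wait, c(0, 0))
  expect_equal(tr2$patients$idle, c(0, 99))
  expect_equal(tr2$overtime, 0)

  expect_error(simulate_day(appointment_template(c(0L, 250L)), cfg2),
               "closing")
})

test_that("recursion agrees cell-for-cell with the event-timeline oracle", {
  cfg <- generate_olas(olas_generator_spec(n_olas = 3L, n_doc = 3L,
                                           closing_time = 120, seed = 3))
  set.seed(77)
  for (k in 1:200) {
    tpl <- appointment_template(sort(sample(0:120, 3, replace = TRUE)),
                                sort(sample(0:120, 3, replace = TRUE)))
    tr <- simulate_day(tpl, cfg, seed = k)
    o <- timeline_oracle(tr$patients$arrival, tr$patients$service,
                         cfg$closing_time)
    expect_equal(tr$patients$wait, o$wait, tolerance = 1e-12)
    expect_equal(tr$patients$idle, o$idle, tolerance = 1e-12)
    expect_equal(tr$overtime, o$overtime, tolerance = 1e-12)
  }
})

test_that("server-timeline conservation holds exactly every replication", {
  cfg <- generate_olas(olas_generator_spec(n_olas = 4L, n_doc = 3L,
                                           closing_time = 200, seed = 9))
  tpl <- appointment_template(c(0L, 30L, 60L, 90L), c(15L, 75L, 150L))
  for (k in 1:100) {
    r <- orsched:::olas_sim_core(tpl, cfg, seed = k)
    K <- r$K
    lhs <- r$arrival[K] + r$wait[K] + r$service[K] - r$arrival[1]
    expect_equal(lhs, sum(r$service) + sum(r$idle), tolerance = 1e-9)
    expect_true(all(r$wait >= 0) && all(r$idle >= 0) && r$overtime >= 0)
  }
})

test_that("inflating every service time never shortens waits or overtime", {
  cfg <- generate_olas(olas_generator_spec(n_olas = 3L, n_doc = 2L,
                                           closing_time = 100, seed = 5))
  tpl <- appointment_template(c(0L, 20L, 40L), c(10L, 60L))
  for (k in 1:25) {
    base <- orsched:::olas_sim_core(tpl, cfg, seed = k)
    cfg2 <- cfg
    scale_dist <- function(d, lam) switch(d$family,
      deterministic = service_dist("deterministic", value = d$value * lam),
      exponential = service_dist("exponential", rate = d$rate / lam),
      lognormal = service_dist("lognormal", meanlog = d$meanlog + log(lam),
                               sdlog = d$sdlog))
    cfg2$service_olas <- scale_dist(cfg$service_olas, 1.5)
    cfg2$service_doc <- scale_dist(cfg$service_doc, 1.5)
    heavy <- orsched:::olas_sim_core(tpl, cfg2, seed = k)
    expect_true(all(heavy$wait >= base$wait - 1e-12))
    expect_gte(heavy$overtime, base$overtime - 1e-12)
  }
})

test_that("estimator moments behave as Monte-Carlo theory requires", {
  # deterministic services: zero standard errors, weighted-mean objective
  cfgd <- olas_config(2, 1, service_dist("deterministic", value = 12),
                      service_dist("deterministic", value = 6),
                      closing_time = 60, cost_wait_olas = 2,
                      cost_wait_doc = 3, cost_idle = 1.5, cost_overtime = 4)
  tpl <- appointment_template(c(0L, 10L), 30L)
  est <- estimate_template(tpl, cfgd, n_replications = 40)
  expect_equal(est$se$objective, 0)
  expect_equal(est$mean$objective,
               2 * est$mean$wait_olas + 3 * est$mean$wait_doc +
                 1.5 * est$mean$idle + 4 * est$mean$overtime)

  # all-zero costs price every outcome at zero
  cfg0 <- olas_config(2, 1, service_dist("exponential", rate = 0.1),
                      service_dist("exponential", rate = 0.1),
                      closing_time = 60, cost_wait_olas = 0,
                      cost_wait_doc = 0, cost_idle = 0, cost_overtime = 0)
  est0 <- estimate_template(tpl, cfg0, n_replications = 200)
  expect_equal(est0$mean$objective, 0)
  expect_identical(length(est0$rep_seeds), 200L)
})

test_that("two-patient exponential wait matches the quadrature value", {
  mu <- 10; gap <- 8
  cfg <- olas_config(2, 0, service_dist("exponential", rate = 1 / mu), NULL,
                     closing_time = 500)
  tpl <- appointment_template(c(0L, gap))
  est <- estimate_template(tpl, cfg, n_replications = 1e5, seed = 2024)
  # E[W2] = E[max(S1 - gap, 0)] by numeric integration
  truth <- integrate(function(s) (s - gap) * dexp(s, 1 / mu), gap, Inf)$value
  # W2 is the only wait (first patient never waits)
  expect_lt(abs(est$mean$wait_olas - truth), 3 * est$se$wait_olas)
})

test_that("standard errors shrink as one over root n", {
  cfg <- olas_config(2, 0, service_dist("exponential", rate = 0.1), NULL,
                     closing_time = 500)
  tpl <- appointment_template(c(0L, 8L))
  ns <- c(1e2, 1e3, 1e4)
  ses <- vapply(ns, function(n)
    estimate_template(tpl, cfg, n, seed = 7)$se$objective, numeric(1))
  scaled <- ses * sqrt(ns)
  for (r in scaled / scaled[3])
    expect_lt(abs(r - 1), 0.2)
})

test_that("template optimizer reaches known optima", {
  # zero-wait template is attainable and found: t_i = (i-1) * s
  cfg <- olas_config(3, 0, service_dist("deterministic", value = 3), NULL,
                     closing_time = 12, cost_idle = 0, cost_overtime = 0)
  opt <- optimize_template(cfg, budget = 1000, seed = 1, n_replications = 1)
  expect_equal(opt$result$mean$objective, 0)
  expect_equal(opt$template$times_olas, c(0L, 3L, 6L))

  # budget 1 returns the evenly spaced seed template untouched
  cfg2 <- olas_config(3, 0, service_dist("deterministic", value = 5), NULL,
                      closing_time = 12)
  o1 <- optimize_template(cfg2, budget = 1, seed = 1, n_replications = 1)
  expect_equal(o1$template$times_olas, c(0L, 6L, 12L))
  expect_error(optimize_template(cfg2, budget = 0), "budget")
})

test_that("optimizer equals exhaustive template enumeration on a small grid", {
  s <- 4; Tc <- 12
  cfg <- olas_config(3, 0, service_dist("deterministic", value = s), NULL,
                     closing_time = Tc, cost_wait_olas = 1, cost_idle = 2,
                     cost_overtime = 3)
  opt <- optimize_template(cfg, budget = 1000, seed = 1, n_replications = 1)
  oracle <- min(vapply(all_sorted_templates(3, Tc), function(tv)
    template_oracle_cost(tv, s, Tc, 1, 2, 3), numeric(1)))
  expect_equal(opt$result$mean$objective, oracle, tolerance = 1e-9)
})
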
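# Radau collocation machinery, the switching-time transformation and the
# multiphase NLP structure.

test_that("Radau IIA nodes and matrices have the expected structure", {
  expect_equal(radau_points(1), 1)
  expect_equal(radau_points(3),
               c((4 - sqrt(6)) / 10, (4 + sqrt(6)) / 10, 1))
  expect_error(radau_points(4), "unsupported")
  cm <- colloc_matrices(3)
  expect_equal(dim(cm$C), c(4, 3))
  # basis polynomials partition unity: derivative rows sum to zero,
  # endpoint weights sum to one, quadrature weights sum to the interval
  expect_equal(colSums(cm$C), rep(0, 3), tolerance = 1e-12)
  expect_equal(sum(cm$D), 1, tolerance = 1e-12)
  expect_equal(sum(cm$B), 1, tolerance = 1e-12)
})

test_that("degree-3 Radau collocation integrates monomials exactly up to
           degree 4 and not degree 5", {
  cm <- colloc_matrices(3)
  endpoint <- function(k) {
    A <- t(cm$C[2:4, ])
    Z <- solve(A, cm$nodes[2:4]^k) # stages for x' = t^k, x(0) = 0
    sum(cm$D[2:4] * Z)
  }
  for (k in 0:4)
    expect_equal(endpoint(k), 1 / (k + 1), tolerance = 1e-13)
  expect_gt(abs(endpoint(5) - 1 / 6), 1e-4)
})

test_that("time transformation reproduces integration over the original
           interval", {
  # constant rhs on [1, 3]
  g <- transform_time(function(t, x) 2.5, 1, 3)
  expect_equal(rk4(g, 0, 0, 1), 0 + 2 * 2.5, tolerance = 1e-12)
  # linear rhs x' = x on [0, 2]: x(tau) = exp(2 tau)
  g2 <- transform_time(function(t, x) x, 0, 2)
  expect_equal(rk4(g2, 1, 0, 1), exp(2), tolerance = 1e-9)
  expect_equal(rk4(g2, 1, 0, 0.5, n = 1000), exp(1), tolerance = 1e-9)
  # random polynomial rhs in t against direct high-accuracy integration
  set.seed(5)
  for (k in 1:5) {
    cf <- runif(4, -2, 2)
    f <- function(t, x) cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3
    t1 <- runif(1, 0, 1); t2 <- t1 + runif(1, 0.5, 2)
    direct <- sum(cf / (1:4) * (t2^(1:4) - t1^(1:4))) # exact antiderivative
    via <- rk4(transform_time(f, t1, t2), 0, 0, 1, n = 4000)
    expect_equal(via, direct, tolerance = 1e-10)
  }
  expect_error(transform_time(function(t, x) x, 1, 1), "t2 > t1")
})

test_that("multiphase NLP structure: phase and switching-time counts", {
  par <- fx_patient()$params
  sched <- list(t0 = 0, tau = c(0.08, 0.1, 0.17, 0.28, 0.31, 0.42),
                tf = 0.89, t_u = c(0.13, 0.35, 0.6))
  nlp7 <- build_nlp(par, "CONSTANT", sched)
  expect_equal(nlp7$n_phases, 7L)
  expect_equal(nlp7$n_switch_vars, 6L)
  expect_equal(nlp7$n_variables$controls, 1L) # single constant speed
  nlp10 <- build_nlp(par, "PWC", sched)
  expect_equal(nlp10$n_phases, 10L)          # phases 3, 6, 7 split
  expect_equal(nlp10$n_switch_vars, 9L)      # six tau plus three t_u
  expect_equal(nlp10$n_variables$controls, 3L)
  expect_equal(nlp10$n_constraints$switching_residuals, 6L)
  expect_equal(nlp10$n_constraints$dwell, 3L)
  # nominal 1 ms grid over a 0.89 s cycle: 890 intervals in total (the
  # schedule above sits on the millisecond grid, so rounding is exact)
  expect_equal(sum(nlp7$phase_table$n_intervals), 890L)
  expect_equal(sum(nlp10$phase_table$n_intervals), 890L)
  expect_equal(sum(nlp10$phase_table$duration), 0.89)
  nlp_cont <- build_nlp(par, "CONTINUOUS", sched)
  expect_equal(nlp_cont$n_variables$controls,
               sum(nlp_cont$phase_table$n_intervals))
})

test_that("NLP construction rejects inconsistent initialisations", {
  par <- fx_patient()$params
  base <- list(t0 = 0, tau = c(0.08, 0.1, 0.17, 0.28, 0.31, 0.42),
               tf = 0.89)
  expect_error(build_nlp(par, "CONSTANT",
                         modifyList(base, list(tau = rev(base$tau)))),
               "strictly ordered")
  expect_error(build_nlp(par, "PWC", base), "speed-switch times")
  bad_tu <- modifyList(base, list(t_u = c(0.05, 0.35, 0.6)))
  expect_error(build_nlp(par, "PWC", bad_tu), "interleaving")
  big_dwell <- ocp_config(dwell = c(0.5, 0.5, 0.5))
  ok_tu <- modifyList(base, list(t_u = c(0.13, 0.35, 0.6)))
  expect_error(build_nlp(par, "PWC", ok_tu, ocp_cfg = big_dwell),
               "dwell")
})

test_that("switching residuals vanish at event-located boundaries and the
           dwell-time inequalities evaluate correctly", {
  traj <- fx_free_cycle()$traj
  sw <- switching_residuals(traj, fx_patient()$params, eps_sw = 1e-3)
  expect_true(all(sw$satisfied))
  expect_lt(max(abs(sw$residual)), 1e-6)
  dw <- dwell_time_constraints(0.2, 0.45, 0.8, 0, 0.88, c(0.25, 0.2, 0.3))
  # t1 - t0 + tf - t3 = 0.28 >= 0.25; t2 - t1 = 0.25 >= 0.2; but
  # t3 - t2 = 0.35 >= 0.3
  expect_true(all(dw$satisfied))
  dw2 <- dwell_time_constraints(0.2, 0.45, 0.8, 0, 0.88, c(0.25, 0.25, 0.4))
  expect_equal(dw2$residual[2], 0)
  expect_true(dw2$satisfied[2])  # boundary-satisfied at equality
  expect_false(dw2$satisfied[3]) # 0.35 < 0.4 violated
})

test_that("sequential Radau collocation matches the adaptive simulator on
           a fixed schedule", {
  pat <- fx_patient()
  par <- pat$params
  sch <- round(schedule_from_simulation(par), 3)
  ss <- steady_state_x0(par, pump_constant(0), tf = 0.89, schedule = sch,
                        lvad_present = FALSE)
  col <- solve_collocation_ivp(par, pump_constant(0), ss$x0, sch,
                               dt = 1e-3, lvad_present = FALSE)
  sim <- simulate_cycle(par, pump_constant(0), ss$x0, schedule = sch,
                        lvad_present = FALSE)
  idx <- match(round(col$time, 9), round(sim$time, 9))
  expect_true(all(!is.na(idx))) # millisecond grids coincide
  dmax <- max(abs(col$states - sim$states[idx, ]) /
                (1 + abs(sim$states[idx, ])))
  expect_lt(dmax, 1e-5)
})
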
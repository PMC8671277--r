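# Optimal control: configuration, warm start, scenario solves and the
# pulsatility classifier.

test_that("configuration validation rejects inconsistent settings", {
  expect_error(ocp_config(rho1 = 1.5))
  expect_error(ocp_config(eps_flow = -1))
  expect_error(ocp_config(u_lb = 9000, u_ub = 8000))
  expect_error(ocp_config(dwell = c(0.1, 0.1)))
  cfg <- ocp_config()
  expect_true(all(cfg$tf_bounds == c(0.84, 0.94)))
})

test_that("the warm start is a feasible periodic cycle with an ordered
           schedule that satisfies the collocation equations", {
  pat <- fx_patient()
  warm <- initialize_ocp(pat$params, ocp_config())
  expect_true(all(diff(c(0, warm$schedule, warm$tf)) > 0))
  expect_true(is.finite(warm$objective$J))
  expect_equal(warm$objective$J,
               warm$objective$J_unloading - warm$objective$J_aov)
  # the simulated warm start satisfies the collocation system: stepping
  # the Radau scheme along the realised schedule reproduces the
  # trajectory's terminal state
  sch <- round(warm$schedule, 3)
  col <- solve_collocation_ivp(pat$params, pump_constant(warm$u_init),
                               warm$x0, sch, tf = warm$tf, dt = 1e-3)
  sim <- simulate_cycle(pat$params, pump_constant(warm$u_init), warm$x0,
                        tf = warm$tf, schedule = sch)
  expect_equal(as.numeric(col$states[nrow(col$states), ]),
               unname(sim$xf), tolerance = 1e-6)
})

test_that("the pulsatility classifier discriminates co- and
           counterpulsative speed patterns", {
  t <- seq(0, 0.89, by = 0.01)
  n <- length(t)
  phase <- ifelse(t < 0.1, 1L, ifelse(t < 0.35, 3L, 7L))
  st <- matrix(0, n, 9)
  vc <- phase %in% 2:4
  u_co <- ifelse(vc, 10000, 5000)
  tr_co <- fake_trajectory(t, st, u = u_co, phase = phase)
  expect_equal(classify_pulsatility(tr_co)$class, "copulsative")
  tr_ct <- fake_trajectory(t, st, u = 15000 - u_co, phase = phase)
  expect_equal(classify_pulsatility(tr_ct)$class, "counterpulsative")
  tr_flat <- fake_trajectory(t, st, u = rep(8000, n), phase = phase)
  expect_equal(classify_pulsatility(tr_flat)$class, "indeterminate")
})

test_that("a pwc optimum embeds exactly into the continuous control set", {
  pat <- fx_patient()
  cfg <- ocp_config()
  pr <- pump_pwc(c(9500, 5000, 9800), c(0.15, 0.4, 0.7),
                 cfg$u_lb, cfg$u_ub)
  ss1 <- steady_state_x0(pat$params, pr, tf = 0.89)
  J_pwc <- evaluate_objective(simulate_cycle(pat$params, pr, ss1$x0,
                                             tf = 0.89))$J
  edges <- sort(unique(c(seq(0, 0.89, length.out = 25)[-25], pr$times)))
  gr <- pump_grid(edges, pump_speed(pr, edges + 1e-9), cfg$u_lb, cfg$u_ub)
  ss2 <- steady_state_x0(pat$params, gr, tf = 0.89)
  J_grid <- evaluate_objective(simulate_cycle(pat$params, gr, ss2$x0,
                                              tf = 0.89))$J
  expect_equal(J_grid, J_pwc, tolerance = 1e-6)
})

test_that("the constant-speed solve improves on its warm start and
           returns a feasible cycle", {
  pat <- fx_patient()
  cfg <- ocp_config()
  warm <- initialize_ocp(pat$params, cfg)
  res <- solve_ocp("CONSTANT", pat$params, cfg, warm,
                   control_opts = list(iter.max = 60))
  expect_s3_class(res, "ocp_result")
  expect_true(res$feasible)
  expect_true(res$profile$u >= cfg$u_lb && res$profile$u <= cfg$u_ub)
  expect_true(res$tf >= cfg$tf_bounds[1] && res$tf <= cfg$tf_bounds[2])
  expect_equal(res$J, res$J_unloading - res$J_aov, tolerance = 1e-12)
  # the periodicity, backflow and bound constraints hold at the optimum
  expect_true(res$constraints$periodicity$satisfied)
  expect_true(res$constraints$min_Q_LVAD$satisfied)
  expect_equal(res$constraints$bound_violations$value, 0)
})
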
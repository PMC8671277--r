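# Event-detecting cycle simulation, steady-state search, and the
# objective/constraint/metric functionals.

test_that("pump profiles validate and evaluate correctly", {
  expect_error(pump_pwc(c(1, 2, 3), c(0.3, 0.2, 0.5)), "t1 < t2 < t3")
  expect_error(pump_pwc(c(1, 2, 3), c(0.2, 0.3, 0.5), u_lb = 2), "bounds")
  pr <- pump_pwc(c(9000, 4000, 9500), c(0.15, 0.35, 0.6))
  # level 1 wraps around the cycle end
  expect_equal(pump_speed(pr, c(0, 0.2, 0.4, 0.7, 0.88)),
               c(9000, 4000, 9500, 9000, 9000))
  gr <- pump_grid(c(0, 0.3, 0.6), c(5000, 7000, 6000))
  expect_equal(pump_speed(gr, c(0.1, 0.45, 0.9)), c(5000, 7000, 6000))
})

test_that("the pump-free reference cycle realises the canonical sequence
           with physiological left-atrial pressure", {
  fc <- fx_free_cycle()
  traj <- fc$traj
  # six events, strictly increasing, inside the cycle
  expect_length(traj$tau, 6)
  expect_true(all(diff(c(traj$t0, traj$tau, traj$tf)) > 0))
  expect_equal(traj$t_VC, traj$tau[1])
  expect_equal(traj$t_R, traj$tau[4])
  # left atrial pressure stays in the 10-20 mmHg band
  expect_gte(min(traj$states[, "P_LA"]), 10)
  expect_lte(max(traj$states[, "P_LA"]), 20)
  # AVP sweeps (at least) the switching band
  expect_lte(min(traj$states[, "s"]), -0.5)
  expect_gte(max(traj$states[, "s"]), 0.5)
})

test_that("total compartment volume change over a cycle equals the AVP
           piston displacement term", {
  fc <- fx_free_cycle()
  traj <- fc$traj
  p <- unclass(fx_patient()$params)
  Cs <- p[c("C_LA", "C_LV", "C_A", "C_S", "C_V")]
  coef <- p[["A_LA"]] + (1 + p[["k_RAD"]]) * p[["A_LV"]]
  dV <- sum(Cs * (traj$xf[1:5] - traj$states[1, 1:5]))
  ds <- unname(traj$xf[9] - traj$states[1, 9])
  expect_equal(dV, coef * ds, tolerance = 1e-6)
})

test_that("steady state search reaches periodicity and a periodic
           trajectory has vanishing periodicity residuals", {
  fc <- fx_free_cycle()
  expect_lt(fc$ss$resid, 1e-6)
  rep_ <- evaluate_constraints(fc$traj, ocp_config())
  expect_true(rep_$periodicity$satisfied)
  expect_lt(max(rep_$periodicity$value), 1e-3)
  # without a pump the backflow bound holds for any positive tolerance
  expect_true(rep_$min_Q_LVAD$satisfied)
  expect_equal(rep_$min_Q_LVAD$value, 0)
})

test_that("simulation fails loudly on degenerate input and infeasible
           sequences", {
  pat <- fx_patient()
  expect_error(
    simulate_cycle(pat$params, pump_constant(0), rep(1, 9), tf = 0.89),
    "outside")
  x0 <- fx_free_cycle()$ss$x0
  # far above the partial-support range the canonical order breaks once
  # the cycle settles; the error names the missing event
  expect_error(
    steady_state_x0(pat$params, pump_constant(12000), x0, tf = 0.89),
    "missing event")
  expect_error(
    simulate_cycle(pat$params, pump_constant(0), x0, tf = 0.89,
                   schedule = c(0.3, 0.2, 0.4, 0.5, 0.6, 0.7)),
    "strictly increasing")
})

test_that("objective quadrature follows the two-term structure", {
  t <- seq(0, 1, by = 0.01)
  n <- length(t)
  st <- matrix(0, n, 9)
  tr0 <- fake_trajectory(t, st)
  expect_equal(evaluate_objective(tr0)$J, 0) # all flows zero
  # rho1 = 0 leaves only the aortic-flow reward
  st2 <- st; st2[, 2] <- 50
  tr2 <- fake_trajectory(t, st2, q_aov = rep(10, n))
  o <- evaluate_objective(tr2, rho1 = 0, rho3 = 0.004)
  expect_equal(o$J, -0.004 * 10 * 1)
  expect_equal(o$J_unloading, 0)
  # rho1 = 1 leaves only the unloading term: P_LV * Q_AoV = 500
  o1 <- evaluate_objective(tr2, rho1 = 1, rho2 = 1e-3)
  expect_equal(o1$J, 1e-3 * 500)
  expect_equal(o1$J, o1$J_unloading - o1$J_aov)
})

test_that("derived metrics: AVPD amplitude, durations and cardiac output", {
  t <- seq(0, 0.89, length.out = 101) # grid hits the apex at t = 0.445
  n <- length(t)
  st <- matrix(0, n, 9)
  st[, 9] <- 0.5 - abs(1 - 2 * t / 0.89) # sweeps exactly -S_D to +S_D
  tr <- fake_trajectory(t, st, q_aov = rep(20, n))
  m <- derived_metrics(tr)
  expect_equal(m$avpd_amplitude_mm, 10)    # 10 mm from S_D = 0.5
  expect_equal(m$atrial_contraction_s, tr$tau[1])
  expect_equal(sum(m$phase_durations_s), tr$tf - tr$t0)
  # constant outflow q: CO = 60 q mL/min
  expect_equal(m$cardiac_output_mL_min, 60 * 20, tolerance = 1e-12)
  tr_flat <- fake_trajectory(t, matrix(0, n, 9))
  expect_equal(derived_metrics(tr_flat)$avpd_amplitude_mm, 0)
})

test_that("a trajectory with the target outflow meets the cardiac-output
           constraint exactly", {
  cfg <- ocp_config(V_CO = 1200, eps_CO = 100)
  t <- seq(0, 0.89, by = 0.01)
  n <- length(t)
  tr <- fake_trajectory(t, matrix(0, n, 9), q_aov = rep(20, n))
  rep_ <- evaluate_constraints(tr, cfg)
  expect_equal(rep_$cardiac_output$value, 1200, tolerance = 1e-12)
  expect_true(rep_$cardiac_output$satisfied)
})

test_that("trajectory CSV export round-trips the node data", {
  traj <- fx_free_cycle()$traj
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  df <- read.csv(f, check.names = FALSE)
  expect_true(all(c("t", state_names(), "u", "Q_MV", "Q_AoV", "phase")
                  %in% names(df)))
  expect_equal(nrow(df), length(traj$time))
  expect_equal(df$P_LV, unname(traj$states[, "P_LV"]))
})

test_that("refining the output grid leaves the terminal state unchanged", {
  pat <- fx_patient()
  x0 <- fx_free_cycle()$ss$x0
  t1 <- simulate_cycle(pat$params, pump_constant(0), x0, tf = 0.89,
                       out_dt = 1e-3, lvad_present = FALSE)
  t2 <- simulate_cycle(pat$params, pump_constant(0), x0, tf = 0.89,
                       out_dt = 2.5e-4, lvad_present = FALSE)
  expect_equal(t1$xf, t2$xf, tolerance = 1e-7)
  expect_equal(t1$tau, t2$tau, tolerance = 5e-6)
})
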
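# Shared lazily-computed fixtures; everything is generated in code from
# fixed seeds. The cache persists across test files within one test run.
.fx <- new.env(parent = emptyenv())

fx_patient <- function() {
  if (is.null(.fx$patient)) .fx$patient <- make_reference_patient()
  .fx$patient
}

# noise-free synthetic measurement series at the true parameters
fx_gen0 <- function() {
  if (is.null(.fx$gen0))
    .fx$gen0 <- generate_measurements(fx_patient(), n_m = 27, noise_sd = 0)
  .fx$gen0
}

# pump-free periodic cycle of the reference patient
fx_free_cycle <- function() {
  if (is.null(.fx$free)) {
    pat <- fx_patient()
    ss <- steady_state_x0(pat$params, pump_constant(0), tf = pat$h_cycle,
                          lvad_present = FALSE)
    .fx$free <- list(
      ss = ss,
      traj = simulate_cycle(pat$params, pump_constant(0), ss$x0,
                            tf = pat$h_cycle, lvad_present = FALSE))
  }
  .fx$free
}

# full three-scenario comparison (slowest fixture, used by several tests)
fx_comparison <- function() {
  if (is.null(.fx$cmp)) .fx$cmp <- compare_scenarios(fx_patient()$params)
  .fx$cmp
}

# minimal hand-built trajectory object for quadrature-formula unit tests
fake_trajectory <- function(time, states, u = rep(0, length(time)),
                            q_mv = rep(0, length(time)),
                            q_aov = rep(0, length(time)),
                            phase = rep(7L, length(time)),
                            tau = seq(time[1], time[length(time)],
                                      length.out = 8)[2:7],
                            lvad_present = TRUE) {
  colnames(states) <- state_names()
  structure(list(time = time, states = states, u = u, q_mv = q_mv,
                 q_aov = q_aov, phase = phase, tau = tau,
                 t_VC = tau[1], t_R = tau[4],
                 t0 = time[1], tf = time[length(time)],
                 xf = states[nrow(states), ],
                 control = pump_constant(0), lvad_present = lvad_present,
                 modes = phase_modes()),
            class = "lvad_trajectory")
}

# simple fixed-step RK4, used as an integration oracle independent of the
# package's compiled integrator
rk4 <- function(f, x0, t0, t1, n = 2000) {
  h <- (t1 - t0) / n
  x <- x0
  t <- t0
  for (k in seq_len(n)) {
    k1 <- f(t, x)
    k2 <- f(t + h / 2, x + h / 2 * k1)
    k3 <- f(t + h / 2, x + h / 2 * k2)
    k4 <- f(t + h, x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  x
}
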
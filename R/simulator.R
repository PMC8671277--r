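# Event-detecting forward simulation of one cardiac cycle and evaluation
# of the objective and constraint functionals on trajectories.

#' Pump speed profiles
#'
#' Control parameterisations for the three scenarios: a single constant
#' speed, a three-level piecewise-constant (pwc) step profile with switch
#' times `t1 < t2 < t3` (level 1 wraps around the cycle end), or a
#' zero-order-hold grid standing in for the continuous scenario.
#'
#' @param u constant speed (rpm).
#' @param levels numeric length 3, pwc speeds `u1, u2, u3` (rpm).
#' @param times numeric length 3, pwc switch times `t1 < t2 < t3` (s).
#' @param grid_times,grid_values zero-order-hold nodes for the
#'   continuous-scenario discretisation.
#' @param u_lb,u_ub admissible speed range (rpm); all values checked.
#' @return object of class `"pump_profile"`.
#' @examples
#' pump_constant(8000)
#' pump_pwc(c(9000, 4000, 9500), c(0.15, 0.35, 0.6))
#' @export
pump_constant <- function(u, u_lb = 0, u_ub = Inf) {
  stopifnot(is.finite(u), u >= u_lb, u <= u_ub)
  structure(list(scenario = "CONSTANT", type = 0L, u = u,
                 u_lb = u_lb, u_ub = u_ub),
            class = "pump_profile")
}

#' @rdname pump_constant
#' @export
pump_pwc <- function(levels, times, u_lb = 0, u_ub = Inf) {
  stopifnot(length(levels) == 3L, length(times) == 3L,
            all(is.finite(levels)), all(is.finite(times)))
  if (!all(diff(times) > 0)) stop("pwc switch times must satisfy t1 < t2 < t3")
  if (any(levels < u_lb | levels > u_ub)) stop("pwc level outside speed bounds")
  structure(list(scenario = "PWC", type = 1L, levels = as.numeric(levels),
                 times = as.numeric(times), u_lb = u_lb, u_ub = u_ub),
            class = "pump_profile")
}

#' @rdname pump_constant
#' @export
pump_grid <- function(grid_times, grid_values, u_lb = 0, u_ub = Inf) {
  stopifnot(length(grid_times) == length(grid_values), length(grid_times) >= 1L,
            all(diff(grid_times) > 0))
  if (any(grid_values < u_lb | grid_values > u_ub))
    stop("grid value outside speed bounds")
  structure(list(scenario = "CONTINUOUS", type = 2L,
                 grid_times = as.numeric(grid_times),
                 grid_values = as.numeric(grid_values),
                 u_lb = u_lb, u_ub = u_ub),
            class = "pump_profile")
}

#' @rdname pump_constant
#' @param profile a `pump_profile`.
#' @param t times at which to evaluate the speed.
#' @return `pump_speed()`: speed in rpm at each `t`.
#' @export
pump_speed <- function(profile, t) {
  stopifnot(inherits(profile, "pump_profile"))
  switch(profile$scenario,
    CONSTANT = rep(profile$u, length(t)),
    PWC = {
      u <- ifelse(t < profile$times[1], profile$levels[1],
             ifelse(t < profile$times[2], profile$levels[2],
               ifelse(t < profile$times[3], profile$levels[3],
                      profile$levels[1])))
      u
    },
    CONTINUOUS = {
      idx <- findInterval(t, profile$grid_times, rightmost.closed = FALSE)
      profile$grid_values[pmax(idx, 1L)]
    })
}

.ctrl_list <- function(profile, lvad_present = TRUE) {
  stopifnot(inherits(profile, "pump_profile"))
  base <- switch(profile$scenario,
    CONSTANT = list(type = 0L, u = profile$u),
    PWC = list(type = 1L, levels = profile$levels, times = profile$times),
    CONTINUOUS = list(type = 2L, grid_times = profile$grid_times,
                      grid_values = profile$grid_values))
  base$lvad_present <- lvad_present
  base
}

.PHASE_EVENT_NAMES <- c(
  "atrial contraction end (s = -S_D)",
  "mitral valve closure (P_LA = P_LV)",
  "aortic valve opening (P_LV = P_A)",
  "ventricular contraction end (s = +S_D)",
  "aortic valve closure (P_LV = P_A)",
  "mitral valve opening (P_LA = P_LV)")

#' Default initial state near the pump-free periodic cycle
#'
#' @param par an [lvad_params()] vector (used for scale only).
#' @return an [lvad_state()] guess suitable as a steady-state search
#'   start for physiological parameter sets.
#' @export
default_x0 <- function(par = lvad_params()) {
  lvad_state(P_LA = 13, P_LV = 11, P_A = 80, P_S = 78, P_V = 15,
             Q_A = 15, Q_LVAD = 0, v = -0.5, s = -0.1)
}

#' Simulate one cardiac cycle through the seven-phase sequence
#'
#' Integrates the switched system with an adaptive Dormand--Prince 5(4)
#' method. In the default event-driven mode the contraction force
#' switches at the first roots of `s = -S_D` and `s = +S_D` and the
#' valves at the pressure-equality roots, in the canonical phase order;
#' events are located on the dense output to near machine precision in
#' time. Supplying a `schedule` of six switching times instead fixes the
#' phase boundaries and forces each phase's valve/contraction modes
#' unconditionally (the phase-fixed dynamics used by the
#' personalisation).
#'
#' @param par an [lvad_params()] vector.
#' @param control a `pump_profile`.
#' @param x0 initial state; `s(t0)` must lie in `[-S_D, S_D]`.
#' @param t0,tf cycle start and end (s).
#' @param schedule `NULL` (event-driven) or numeric length 6 of switching
#'   times `t0 < tau_1 < ... < tau_6 < tf`.
#' @param out_dt output grid spacing (s); event times are always included.
#' @param lvad_present logical; `FALSE` clamps `Q_LVAD` to zero.
#' @return object of class `"lvad_trajectory"`: list with `time`,
#'   `states` (matrix, canonical columns), `u`, `q_mv`, `q_aov`, `phase`,
#'   `tau` (realised switching times), `t_VC`, `t_R`, `t0`, `tf`, `xf`.
#' @export
simulate_cycle <- function(par, control, x0, t0 = 0, tf = 0.89,
                           schedule = NULL, out_dt = 1e-3,
                           lvad_present = TRUE) {
  x0 <- as.numeric(x0)
  if (length(x0) != 9L || any(!is.finite(x0))) stop("x0 must be 9 finite values")
  sd_ <- par[["S_D"]]
  if (x0[9] < -sd_ - 1e-9 || x0[9] > sd_ + 1e-9)
    stop("initial AVP position s(t0) outside [-S_D, S_D]")
  if (!is.null(schedule)) {
    schedule <- as.numeric(schedule)
    if (length(schedule) != 6L || any(diff(c(t0, schedule, tf)) <= 0))
      stop("schedule must hold 6 strictly increasing times inside (t0, tf)")
  }
  res <- .sim_cycle_cpp(x0, .par_vec(par), t0, tf,
                        .ctrl_list(control, lvad_present),
                        if (is.null(schedule)) numeric(0) else schedule,
                        out_dt, 5e-3)
  if (res$status == 9L)
    stop("integration failed (step-size collapse / blow-up)")
  if (res$status %in% 1:6)
    stop("phase sequence infeasible: event not reached before tf in phase ",
         res$status, " [", .PHASE_EVENT_NAMES[res$status], "]")
  keep <- !duplicated(res$time)
  states <- res$states[keep, , drop = FALSE]
  colnames(states) <- state_names()
  structure(list(
    time = res$time[keep], states = states, u = res$u[keep],
    q_mv = res$q_mv[keep], q_aov = res$q_aov[keep], phase = res$phase[keep],
    tau = as.numeric(res$tau), t_VC = res$tau[1], t_R = res$tau[4],
    t0 = t0, tf = tf, xf = res$xf,
    control = control, lvad_present = lvad_present,
    modes = phase_modes()
  ), class = "lvad_trajectory")
}

#' @export
print.lvad_trajectory <- function(x, ...) {
  cat(sprintf("cardiac-cycle trajectory: [%g, %g] s, %d nodes\n",
              x$t0, x$tf, length(x$time)))
  cat("switching times tau:", paste(signif(x$tau, 5), collapse = " "), "\n")
  invisible(x)
}

.steady_search <- function(x0, pv, t0, tf, ctrl, schedule, tol,
                           max_cycles) {
  res <- .steady_newton_cpp(x0, pv, t0, tf, ctrl, schedule, tol, 30L, 5e-3)
  if (res$status == 0L && is.finite(res$resid) && res$resid < tol) return(res)
  .steady_cycle_cpp(x0, pv, t0, tf, ctrl, schedule, tol, max_cycles, 5e-3)
}

#' Periodic steady state of the cycle map
#'
#' Iterates full cycles from `x0` until the start and end states agree to
#' `tol` in the scaled max-norm (the periodicity constraint of the
#' steady-state assumption). Total blood volume
#' `sum(C_i P_i) - (A_LA + (1 + k_RAD) A_LV) s` is an invariant of the
#' dynamics, so the fixed point reached depends on the volume implied by
#' the initial guess.
#'
#' @inheritParams simulate_cycle
#' @param tol convergence tolerance on `max |x(tf)-x(t0)| / (1+|x|)`.
#' @param max_cycles iteration cap of the fallback fixed-point iteration
#'   (a Newton search on the cycle map, restricted to the volume level
#'   set, is tried first).
#' @return list with the periodic start state `x0`, iteration count
#'   `cycles` and final `resid`.
#' @export
steady_state_x0 <- function(par, control, x0 = default_x0(par), t0 = 0,
                            tf = 0.89, schedule = NULL, tol = 1e-6,
                            max_cycles = 800, lvad_present = TRUE) {
  res <- .steady_search(as.numeric(x0), .par_vec(par), t0, tf,
                        .ctrl_list(control, lvad_present),
                        if (is.null(schedule)) numeric(0) else
                          as.numeric(schedule),
                        tol, max_cycles)
  if (res$status == 9L) stop("integration failed during steady-state search")
  if (res$status %in% 1:6)
    stop("steady-state search hit an infeasible cycle: missing event in ",
         "phase ", res$status, " [", .PHASE_EVENT_NAMES[res$status], "]")
  if (res$resid >= tol)
    warning("steady-state search did not reach tol (resid = ",
            signif(res$resid, 3), ")")
  x <- as.numeric(res$x0)
  names(x) <- state_names()
  list(x0 = x, cycles = res$cycles, resid = res$resid)
}

.trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

#' Intra-cycle control objective
#'
#' `J = int [rho1 rho2 P_LV (Q_AoV + Q_LVAD - Q_MV)
#'          - (1 - rho1) rho3 Q_AoV] dt`:
#' the first term is the ventricular hydraulic load (unloading when
#' minimised), the second rewards flow through the aortic valve.
#' Quadrature is trapezoidal on the trajectory's output grid (event
#' nodes included).
#'
#' @param traj an `lvad_trajectory`.
#' @param rho1 trade-off weight in `[0, 1]`.
#' @param rho2 unit scaling of the unloading term (J per mmHg*mL).
#' @param rho3 unit scaling of the valve-flow term (J per mL).
#' @return list with `J`, `J_unloading`, `J_aov` where
#'   `J = J_unloading - J_aov`.
#' @export
evaluate_objective <- function(traj, rho1 = 0.5, rho2 = 1.33322e-4,
                               rho3 = 0.004) {
  stopifnot(inherits(traj, "lvad_trajectory"), rho1 >= 0, rho1 <= 1)
  q_lvad <- if (traj$lvad_present) traj$states[, "Q_LVAD"] else 0
  unl <- .trapz(traj$time,
                traj$states[, "P_LV"] * (traj$q_aov + q_lvad - traj$q_mv))
  aov <- .trapz(traj$time, traj$q_aov)
  J_unloading <- rho1 * rho2 * unl
  J_aov <- (1 - rho1) * rho3 * aov
  list(J = J_unloading - J_aov, J_unloading = J_unloading, J_aov = J_aov)
}

#' Constraint functionals on a cycle trajectory
#'
#' Evaluates, by trapezoidal quadrature on the output grid: the net LV
#' flow balance; the nine periodicity residuals `|x(tf) - x(t0)|`; the
#' accumulated aortic-valve flow (partial support); the most negative
#' pump flow (backflow limit); the realised cardiac output
#' `60/(tf - t0) * int (Q_AoV + Q_LVAD) dt` in mL/min; and state/control
#' bound violations. Each is flagged satisfied iff within its tolerance.
#'
#' @param traj an `lvad_trajectory`.
#' @param cfg an [ocp_config()] (tolerances and bounds).
#' @return object of class `"constraint_report"`: per-constraint `value`,
#'   `tol`/`bound`, `satisfied`, plus `all_satisfied`.
#' @export
evaluate_constraints <- function(traj, cfg = ocp_config()) {
  stopifnot(inherits(traj, "lvad_trajectory"))
  t <- traj$time
  q_lvad <- if (traj$lvad_present) traj$states[, "Q_LVAD"] else
    rep(0, length(t))

  flow_balance <- .trapz(t, traj$q_mv - traj$q_aov - q_lvad)
  periodicity <- abs(traj$xf - traj$states[1, ])
  partial <- .trapz(t, traj$q_aov)
  min_q_lvad <- min(q_lvad)
  co <- 60 / (traj$tf - traj$t0) * .trapz(t, traj$q_aov + q_lvad)
  n_bound <- sum(t(traj$states) < cfg$x_lb - 1e-9) +
    sum(t(traj$states) > cfg$x_ub + 1e-9) +
    sum(traj$u < cfg$u_lb - 1e-9 | traj$u > cfg$u_ub + 1e-9)

  rep_ <- list(
    flow_balance = list(value = flow_balance, tol = cfg$eps_flow,
                        satisfied = abs(flow_balance) <= cfg$eps_flow),
    periodicity = list(value = periodicity, tol = cfg$eps_per,
                       satisfied = all(periodicity <= cfg$eps_per)),
    partial_support = list(value = partial, tol = cfg$eps_partial,
                           satisfied = partial >= cfg$eps_partial),
    min_Q_LVAD = list(value = min_q_lvad, tol = cfg$eps_back,
                      satisfied = min_q_lvad >= -cfg$eps_back),
    cardiac_output = list(value = co, target = cfg$V_CO, tol = cfg$eps_CO,
                          satisfied = abs(co - cfg$V_CO) <= cfg$eps_CO),
    bound_violations = list(value = n_bound, satisfied = n_bound == 0L)
  )
  rep_$all_satisfied <- all(vapply(rep_[1:6], `[[`, logical(1), "satisfied"))
  class(rep_) <- "constraint_report"
  rep_
}

#' @export
print.constraint_report <- function(x, ...) {
  cat("constraint report:\n")
  for (nm in setdiff(names(x), "all_satisfied")) {
    v <- x[[nm]]$value
    cat(sprintf("  %-17s %-9s value %s\n", nm,
                if (x[[nm]]$satisfied) "OK" else "VIOLATED",
                paste(signif(v, 4), collapse = " ")))
  }
  invisible(x)
}

#' Summary metrics of a simulated cycle
#'
#' Atrioventricular-plane displacement amplitude in mm
#' (`10 * (max s - min s)`, cm to mm), atrial-contraction duration
#' `tau_1 - t0`, phase durations, cardiac output (L/min) and stroke
#' volumes through valve and pump.
#'
#' @param traj an `lvad_trajectory`.
#' @return list of named scalars (plus the phase-duration vector).
#' @export
derived_metrics <- function(traj) {
  stopifnot(inherits(traj, "lvad_trajectory"))
  s <- traj$states[, "s"]
  q_lvad <- if (traj$lvad_present) traj$states[, "Q_LVAD"] else 0 * traj$time
  bounds <- c(traj$t0, traj$tau, traj$tf)
  co_ml_min <- 60 / (traj$tf - traj$t0) *
    .trapz(traj$time, traj$q_aov + q_lvad)
  list(
    avpd_amplitude_mm = 10 * (max(s) - min(s)),
    atrial_contraction_s = traj$tau[1] - traj$t0,
    phase_durations_s = diff(bounds),
    cardiac_output_L_min = co_ml_min / 1000,
    cardiac_output_mL_min = co_ml_min,
    stroke_aov_mL = .trapz(traj$time, traj$q_aov),
    stroke_lvad_mL = .trapz(traj$time, q_lvad)
  )
}

#' Export a trajectory to CSV
#'
#' One row per output node: `t`, the nine states, `u`, `Q_MV`, `Q_AoV`,
#' `phase`.
#'
#' @param traj an `lvad_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(t = traj$time, traj$states, u = traj$u,
                   Q_MV = traj$q_mv, Q_AoV = traj$q_aov, phase = traj$phase,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.lvad_trajectory <- function(x, ...) {
  data.frame(t = x$time, x$states, u = x$u, Q_MV = x$q_mv, Q_AoV = x$q_aov,
             phase = x$phase, check.names = FALSE)
}
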
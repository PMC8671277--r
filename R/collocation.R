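# Radau direct collocation: interpolation matrices, the switching-time
# scaling of each phase onto [0,1], the multiphase NLP structure, and a
# sequential collocation solve used as an independent integration route.

#' Radau IIA collocation points
#'
#' Collocation nodes on `(0, 1]` (the right endpoint is always a node,
#' giving stiff accuracy). Degrees 1--3 are supported; degree 3 is the
#' default used by the transcription.
#'
#' @param degree polynomial degree (number of collocation points).
#' @return numeric vector of nodes in increasing order, last element 1.
#' @export
radau_points <- function(degree = 3) {
  switch(as.character(degree),
    "1" = 1,
    "2" = c(1 / 3, 1),
    "3" = c((4 - sqrt(6)) / 10, (4 + sqrt(6)) / 10, 1),
    stop("unsupported collocation degree (1, 2 or 3)"))
}

# Lagrange basis on nodes {0, c_1..c_d}: coefficient vectors in
# ascending powers
.lagrange_basis <- function(nodes) {
  d1 <- length(nodes)
  lapply(seq_len(d1), function(j) {
    coef <- 1
    for (k in seq_len(d1)[-j]) {
      # multiply by (x - nodes[k]) / (nodes[j] - nodes[k])
      coef <- c(0, coef) - nodes[k] * c(coef, 0)
      coef <- coef / (nodes[j] - nodes[k])
    }
    coef
  })
}

.poly_eval <- function(coef, x) sum(coef * x^(seq_along(coef) - 1))
.poly_deriv <- function(coef) {
  if (length(coef) == 1) return(0)
  coef[-1] * seq_len(length(coef) - 1)
}
.poly_int01 <- function(coef) sum(coef / seq_along(coef))

#' Collocation matrices for one interval
#'
#' Lagrange-polynomial differentiation matrix `C` (`C[j, r]` is the
#' derivative of basis `j - 1` at node `r`), end-point weights `D`
#' (basis value at 1, used for the continuity map) and quadrature
#' weights `B` (integral of each basis over the interval) on the node
#' set `{0, radau_points(degree)}`.
#'
#' @inheritParams radau_points
#' @return list with matrix `C` (`(degree+1) x degree`), vectors `D` and
#'   `B` (length `degree + 1`).
#' @export
colloc_matrices <- function(degree = 3) {
  nodes <- c(0, radau_points(degree))
  basis <- .lagrange_basis(nodes)
  d <- degree
  C <- matrix(0, d + 1, d)
  for (j in seq_len(d + 1)) {
    dc <- .poly_deriv(basis[[j]])
    for (r in seq_len(d)) C[j, r] <- .poly_eval(dc, nodes[r + 1])
  }
  D <- vapply(basis, .poly_eval, numeric(1), x = 1)
  B <- vapply(basis, .poly_int01, numeric(1))
  list(C = C, D = D, B = B, nodes = nodes)
}

#' Switching-time transformation of a right-hand side
#'
#' Rescales dynamics on a phase `[t1, t2]` onto the unit interval: the
#' returned function satisfies `x'(tau) = (t2 - t1) f(t1 + (t2 - t1) tau,
#' x, ...)`, so integrating it over `[0, 1]` reproduces integration of
#' `f` over `[t1, t2]`. This is the device that turns phase durations
#' into continuous decision variables.
#'
#' @param rhs function `f(t, x, ...)` returning the state derivative.
#' @param t1,t2 phase boundaries, `t2 > t1`.
#' @return function `g(tau, x, ...)` on `[0, 1]`.
#' @export
transform_time <- function(rhs, t1, t2) {
  if (!is.function(rhs)) stop("rhs must be a function")
  if (!(t2 > t1)) stop("phase requires t2 > t1")
  h <- t2 - t1
  function(tau, x, ...) h * rhs(t1 + h * tau, x, ...)
}

#' Transcription configuration
#'
#' @param dt nominal discretisation spacing (s); the per-phase interval
#'   count is fixed from the initialisation durations at this spacing and
#'   kept while durations vary.
#' @param degree Radau collocation degree.
#' @param eps_sw switching-residual tolerance for the phase-boundary
#'   conditions.
#' @param tf_bounds admissible cycle length interval (s).
#' @return list of class `"transcription_config"`.
#' @export
transcription_config <- function(dt = 1e-3, degree = 3, eps_sw = 1e-3,
                                 tf_bounds = c(0.84, 0.94)) {
  stopifnot(dt > 0, degree >= 1, eps_sw > 0,
            length(tf_bounds) == 2, all(tf_bounds > 0),
            tf_bounds[1] < tf_bounds[2])
  structure(list(dt = dt, degree = as.integer(degree), eps_sw = eps_sw,
                 tf_bounds = tf_bounds),
            class = "transcription_config")
}

#' Build the multiphase NLP structure
#'
#' Lays out the direct-collocation transcription of the switched optimal
#' control problem after the switching-time scaling: the canonical seven
#' phases, or ten for the pwc scenario (phases 3, 6 and 7 are split at
#' the speed-switch times, which must fall between mitral closure and
#' aortic opening, between aortic closure and mitral opening, and between
#' mitral opening and the cycle end). Node counts per phase are fixed
#' integers derived from the initialisation durations at the nominal
#' spacing; durations remain continuous variables.
#'
#' @param par an [lvad_params()] vector.
#' @param scenario `"CONSTANT"`, `"CONTINUOUS"` or `"PWC"`.
#' @param schedule_init list with `t0`, `tau` (length 6), `tf`, and for
#'   pwc `t_u` (length 3, speed-switch times).
#' @param cfg a [transcription_config()].
#' @param ocp_cfg an [ocp_config()] (dwell times, bounds).
#' @return object of class `"multiphase_nlp"`: phase table, variable and
#'   constraint counts, and the switching-residual descriptors.
#' @export
build_nlp <- function(par, scenario = c("CONSTANT", "CONTINUOUS", "PWC"),
                      schedule_init, cfg = transcription_config(),
                      ocp_cfg = ocp_config()) {
  scenario <- match.arg(scenario)
  t0 <- schedule_init$t0
  tf <- schedule_init$tf
  tau <- schedule_init$tau
  if (length(tau) != 6L || any(diff(c(t0, tau, tf)) <= 0))
    stop("initialisation schedule must be strictly ordered")
  if (scenario == "PWC") {
    t_u <- schedule_init$t_u
    if (is.null(t_u) || length(t_u) != 3L)
      stop("pwc scenario needs the three speed-switch times t_u")
    ok <- t_u[1] > tau[2] && t_u[1] < tau[3] &&
      t_u[2] > tau[5] && t_u[2] < tau[6] &&
      t_u[3] > tau[6] && t_u[3] < tf
    if (!ok)
      stop("speed-switch times violate the phase-interleaving assumption")
    if (sum(ocp_cfg$dwell) > diff(cfg$tf_bounds) + (cfg$tf_bounds[1] - t0))
      stop("dwell times exceed the admissible cycle length")
    # split phases 3, 6, 7 at the speed switches -> 10 phases
    bounds <- sort(c(t0, tau, t_u, tf))
    base_phase <- c(1, 2, 3, 3, 4, 5, 6, 6, 7, 7)
  } else {
    bounds <- c(t0, tau, tf)
    base_phase <- 1:7
  }
  durations <- diff(bounds)
  n_int <- pmax(1L, as.integer(round(durations / cfg$dt)))
  modes <- phase_modes()[base_phase, ]
  d <- cfg$degree
  n_phases <- length(durations)

  n_state_nodes <- sum(n_int + 1L) * 9L
  n_state_colloc <- sum(n_int) * d * 9L
  n_controls <- switch(scenario,
    CONSTANT = 1L,
    CONTINUOUS = sum(n_int),
    PWC = 3L)
  n_switch_vars <- if (scenario == "PWC") 9L else 6L
  n_durations <- n_phases

  counts <- list(
    collocation_eqs = sum(n_int) * d * 9L,
    continuity_eqs = sum(n_int) * 9L,
    phase_linking = (n_phases - 1L) * 9L,
    switching_residuals = 6L,
    duration_sum = 1L,
    dwell = if (scenario == "PWC") 3L else 0L,
    pwc_ordering = if (scenario == "PWC") 6L else 0L,
    flow_balance = 1L, periodicity = 9L, partial_support = 1L,
    cardiac_output = 1L
  )
  structure(list(
    scenario = scenario, n_phases = n_phases,
    phase_table = data.frame(
      phase = seq_len(n_phases), base_phase = base_phase,
      t_start = head(bounds, -1), t_end = tail(bounds, -1),
      duration = durations, n_intervals = n_int,
      contraction = modes$contraction, mitral = modes$mitral,
      aortic = modes$aortic, row.names = NULL),
    degree = d,
    n_switch_vars = n_switch_vars,
    n_variables = list(states = n_state_nodes + n_state_colloc,
                       controls = n_controls,
                       durations = n_durations,
                       switch_times = n_switch_vars),
    n_constraints = counts,
    eps_sw = cfg$eps_sw,
    tf_bounds = cfg$tf_bounds
  ), class = "multiphase_nlp")
}

#' @export
print.multiphase_nlp <- function(x, ...) {
  cat(sprintf("multiphase collocation NLP (%s): %d phases, degree %d\n",
              x$scenario, x$n_phases, x$degree))
  cat(sprintf("  switching-time variables: %d\n", x$n_switch_vars))
  cat(sprintf("  variables: %d states, %d controls, %d durations\n",
              x$n_variables$states, x$n_variables$controls,
              x$n_variables$durations))
  cat(sprintf("  intervals per phase: %s\n",
              paste(x$phase_table$n_intervals, collapse = " ")))
  invisible(x)
}

#' NLP structure dump for regression tests
#'
#' @param nlp a `"multiphase_nlp"`.
#' @param path JSON output path.
#' @export
write_nlp_json <- function(nlp, path) {
  jsonlite::write_json(list(
    scenario = nlp$scenario, n_phases = nlp$n_phases,
    n_switch_vars = nlp$n_switch_vars,
    n_variables = nlp$n_variables, n_constraints = nlp$n_constraints,
    intervals = nlp$phase_table$n_intervals), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Phase-boundary switching residuals
#'
#' The six conditions that must hold (to tolerance `eps_sw`) at the
#' transformed phase boundaries: `s + S_D` at the end of atrial
#' contraction, `P_LA - P_LV` at mitral closure, `P_LV - P_A` at aortic
#' opening, `s - S_D` at the end of ventricular contraction,
#' `P_LV - P_A` at aortic closure and `P_LA - P_LV` at mitral opening.
#'
#' @param traj an `lvad_trajectory` whose grid contains the switching
#'   times (event nodes are always recorded).
#' @param par an [lvad_params()] vector.
#' @param eps_sw residual tolerance.
#' @return data frame with `boundary`, `residual`, `satisfied`.
#' @export
switching_residuals <- function(traj, par, eps_sw = 1e-3) {
  stopifnot(inherits(traj, "lvad_trajectory"), eps_sw > 0)
  at <- function(tt, col) approx(traj$time, traj$states[, col], xout = tt,
                                 rule = 2)$y
  tau <- traj$tau
  res <- c(
    at(tau[1], "s") + par[["S_D"]],
    at(tau[2], "P_LA") - at(tau[2], "P_LV"),
    at(tau[3], "P_LV") - at(tau[3], "P_A"),
    at(tau[4], "s") - par[["S_D"]],
    at(tau[5], "P_LV") - at(tau[5], "P_A"),
    at(tau[6], "P_LA") - at(tau[6], "P_LV"))
  data.frame(
    boundary = 1:6,
    residual = res,
    satisfied = abs(res) <= eps_sw)
}

#' Minimum dwell-time residuals for the pwc speed profile
#'
#' Three inequalities `t1 - t0 + tf - t3 >= D1` (level 1 wraps around the
#' cycle end), `t2 - t1 >= D2`, `t3 - t2 >= D3`; a residual is satisfied
#' iff non-negative.
#'
#' @param t1,t2,t3 speed-switch times (s).
#' @param t0,tf cycle boundaries (s).
#' @param D numeric length 3 of minimum dwell times (s), positive.
#' @return data frame with `level`, `residual`, `satisfied`.
#' @export
dwell_time_constraints <- function(t1, t2, t3, t0, tf, D) {
  stopifnot(length(D) == 3L, all(D > 0))
  res <- c(t1 - t0 + tf - t3 - D[1], t2 - t1 - D[2], t3 - t2 - D[3])
  data.frame(level = 1:3, residual = res, satisfied = res >= -1e-12)
}

#' Sequential Radau collocation integration of a fixed schedule
#'
#' Solves the collocation equations interval by interval (equivalent to
#' implicit Radau IIA time stepping) through the seven phases of a given
#' schedule with phase-fixed modes. This route shares no code with the
#' adaptive Runge--Kutta simulator and serves as the cross-module
#' consistency oracle.
#'
#' @param par an [lvad_params()] vector.
#' @param control a `pump_profile`.
#' @param x0 initial state (length 9).
#' @param schedule numeric length 6 of switching times.
#' @param t0,tf cycle boundaries (s).
#' @param dt nominal interval length (s).
#' @param degree Radau degree.
#' @param lvad_present logical, pump present.
#' @return list with `time` (interval boundary nodes) and `states`
#'   (matrix, canonical columns).
#' @export
solve_collocation_ivp <- function(par, control, x0, schedule, t0 = 0,
                                  tf = 0.89, dt = 1e-3, degree = 3,
                                  lvad_present = TRUE) {
  stopifnot(length(schedule) == 6L, all(diff(c(t0, schedule, tf)) > 0))
  cm <- colloc_matrices(degree)
  d <- degree
  pv <- .par_vec(par)
  bounds <- c(t0, schedule, tf)
  modes <- phase_modes()

  f <- function(x, tt, ph) {
    cmode <- match(modes$contraction[ph], c("ZERO", "AC", "VC")) - 1L
    .rhs_cpp(x, pump_speed(control, tt), pv, cmode,
             modes$mitral[ph] == "OPEN", modes$aortic[ph] == "OPEN",
             FALSE, lvad_present)
  }
  fd_jac <- function(x, tt, ph) {
    J <- matrix(0, 9, 9)
    f0 <- f(x, tt, ph)
    for (j in 1:9) {
      hj <- 1e-6 * max(1, abs(x[j]))
      xp <- x; xp[j] <- xp[j] + hj
      J[, j] <- (f(xp, tt, ph) - f0) / hj
    }
    J
  }

  times <- t0
  xs <- matrix(as.numeric(x0), nrow = 1)
  x <- as.numeric(x0)
  for (ph in 1:7) {
    a <- bounds[ph]; b <- bounds[ph + 1]
    n <- max(1L, as.integer(round((b - a) / dt)))
    h <- (b - a) / n
    for (k in seq_len(n)) {
      tk <- a + (k - 1) * h
      Jf <- fd_jac(x, tk, ph)
      # chord-Newton on the d stacked stage states
      A <- kronecker(t(cm$C[2:(d + 1), , drop = FALSE]), diag(9)) -
        h * kronecker(diag(d), Jf)
      Alu <- A
      Z <- matrix(rep(x, d), 9, d)
      for (iter in 1:30) {
        R <- matrix(0, 9, d)
        for (r in seq_len(d)) {
          xp <- cm$C[1, r] * x
          for (j in seq_len(d)) xp <- xp + cm$C[j + 1, r] * Z[, j]
          R[, r] <- xp - h * f(Z[, r], tk + cm$nodes[r + 1] * h, ph)
        }
        if (max(abs(R)) < 1e-11) break
        dz <- solve(Alu, as.numeric(-R))
        Z <- Z + matrix(dz, 9, d)
      }
      x <- cm$D[1] * x
      for (j in seq_len(d)) x <- x + cm$D[j + 1] * Z[, j]
      times <- c(times, tk + h)
      xs <- rbind(xs, x)
    }
  }
  colnames(xs) <- state_names()
  list(time = times, states = xs)
}
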
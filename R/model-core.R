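# Domain types and the switched right-hand side; the compiled twin in
# src/cycle.cpp is cross-checked against eval_rhs() by the test suite.

.STATE_NAMES <- c("P_LA", "P_LV", "P_A", "P_S", "P_V", "Q_A", "Q_LVAD",
                  "v", "s")

#' State vector of the switched cardiovascular model
#'
#' Nine differential states, ordered as
#' `x = [P_LA, P_LV, P_A, P_S, P_V, Q_A, Q_LVAD, v, s]`:
#' pressures (mmHg) of left atrium, left ventricle, aorta, systemic artery
#' and venous system; aortic and pump flow (mL/s); velocity (cm/s) and
#' position (cm) of the atrioventricular plane.
#'
#' @param ... either nine named scalars or a single numeric vector of
#'   length 9 in canonical order.
#' @return named numeric vector of class `"lvad_state"`.
#' @export
lvad_state <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.numeric(args[[1]]) && length(args[[1]]) == 9L) {
    x <- as.numeric(args[[1]])
  } else {
    if (!setequal(names(args), .STATE_NAMES))
      stop("state requires exactly the fields: ",
           paste(.STATE_NAMES, collapse = ", "))
    x <- vapply(.STATE_NAMES, function(nm) as.numeric(args[[nm]]), numeric(1))
  }
  if (any(!is.finite(x))) stop("non-finite state value")
  names(x) <- .STATE_NAMES
  class(x) <- "lvad_state"
  x
}

#' @rdname lvad_state
#' @return `state_names()`: the canonical ordering of the nine states.
#' @export
state_names <- function() .STATE_NAMES

#' Mitral and aortic valve flows
#'
#' Diode law of each valve: in the `"free"` regime the flow is
#' `(P_up - P_down)/R` when the upstream pressure exceeds the downstream
#' pressure and zero otherwise. A fixed regime (`"open"` or `"closed"`)
#' applies that branch unconditionally, which is how the phase-fixed
#' dynamics of the multiphase transcription evaluate the flows.
#'
#' @param P_LA,P_LV,P_A pressures (mmHg).
#' @param R_M,R_AoV valve resistances (mmHg*s/mL), strictly positive.
#' @param regime `"free"`, `"open"` or `"closed"`.
#' @return flow in mL/s.
#' @examples
#' mitral_flow(11, 10, 0.1)         # 10
#' mitral_flow(10, 11, 0.1)         # 0 (free regime)
#' aortic_flow(100, 90, 0.5)        # 20
#' @export
mitral_flow <- function(P_LA, P_LV, R_M, regime = c("free", "open", "closed")) {
  regime <- match.arg(regime)
  if (!is.finite(R_M) || R_M <= 0) stop("R_M must be strictly positive")
  open <- switch(regime, free = P_LA > P_LV, open = TRUE, closed = FALSE)
  if (open) (P_LA - P_LV) / R_M else 0
}

#' @rdname mitral_flow
#' @export
aortic_flow <- function(P_LV, P_A, R_AoV, regime = c("free", "open", "closed")) {
  regime <- match.arg(regime)
  if (!is.finite(R_AoV) || R_AoV <= 0) stop("R_AoV must be strictly positive")
  open <- switch(regime, free = P_LV > P_A, open = TRUE, closed = FALSE)
  if (open) (P_LV - P_A) / R_AoV else 0
}

#' Signed atrioventricular contraction force
#'
#' Piecewise-constant force acting on the AVP piston. The sign convention
#' makes the switching events reachable: atrial contraction (`"AC"`)
#' applies `-|F_AC|`, pulling the plane towards the basal threshold
#' `-S_D`; ventricular contraction (`"VC"`) applies `+|F_VC|`, driving it
#' to `+S_D`; `"ZERO"` is the relaxed state.
#'
#' @param mode `"AC"`, `"VC"` or `"ZERO"`.
#' @param par an [lvad_params()] vector.
#' @return signed force (mmHg*cm^2).
#' @export
contraction_force <- function(mode, par) {
  validate_params(par)
  switch(mode,
         AC = -abs(par[["F_AC"]]),
         VC = abs(par[["F_VC"]]),
         ZERO = 0,
         stop("unknown contraction mode '", mode, "'"))
}

#' Phase modes of the canonical cardiac cycle
#'
#' The assumed sequence of seven active subsystems: contraction mode,
#' mitral and aortic valve state for each phase. Phase 1 is atrial
#' contraction with open mitral valve; phases 2--4 carry the ventricular
#' contraction through mitral closure, isovolumic pressure build-up and
#' ejection; phases 5--7 relax, close the aortic valve and refill.
#'
#' @return `phase_modes()`: data frame with columns `phase`,
#'   `contraction`, `mitral`, `aortic` (7 rows).
#' @export
phase_modes <- function() {
  data.frame(
    phase = 1:7,
    contraction = c("AC", "VC", "VC", "VC", "ZERO", "ZERO", "ZERO"),
    mitral = c("OPEN", "OPEN", "CLOSED", "CLOSED", "CLOSED", "CLOSED", "OPEN"),
    aortic = c("CLOSED", "CLOSED", "CLOSED", "OPEN", "OPEN", "CLOSED",
               "CLOSED"),
    stringsAsFactors = FALSE
  )
}

#' @rdname phase_modes
#' @param phase integer in 1..7.
#' @return `phase_mode()`: one-row list with fields `contraction`,
#'   `mitral`, `aortic`.
#' @export
phase_mode <- function(phase) {
  stopifnot(length(phase) == 1L, phase %in% 1:7)
  as.list(phase_modes()[phase, c("contraction", "mitral", "aortic")])
}

#' Enumerate all subsystems of the switched dynamics
#'
#' Cartesian product of the three contraction settings with the two
#' states of each valve: 12 subsystems in total, of which the canonical
#' schedule visits 7.
#'
#' @return data frame with columns `contraction`, `mitral`, `aortic`
#'   (12 rows, each combination exactly once).
#' @export
enumerate_subsystems <- function() {
  grid <- expand.grid(
    contraction = c("AC", "VC", "ZERO"),
    mitral = c("OPEN", "CLOSED"),
    aortic = c("OPEN", "CLOSED"),
    stringsAsFactors = FALSE
  )
  grid[order(grid$contraction, grid$mitral, grid$aortic), , drop = FALSE]
}

#' Path conditions attached to a phase mode
#'
#' Residual functions that must be non-negative while the mode is active:
#' `AC` requires `s > -S_D`, `VC` requires `s < S_D`, an open valve
#' requires a positive forward pressure difference and a closed valve a
#' non-positive one. Usable directly as path constraints in a
#' transcription.
#'
#' @param mode list with fields `contraction`, `mitral`, `aortic`
#'   (see [phase_mode()]).
#' @return named list of functions `f(x, par)` returning a residual that
#'   is `>= 0` iff the condition holds (strict conditions are satisfied
#'   at equality only on the switching surface itself).
#' @export
phase_conditions <- function(mode) {
  conds <- list()
  if (mode$contraction == "AC")
    conds$ac_position <- function(x, par) x[["s"]] + par[["S_D"]]
  if (mode$contraction == "VC")
    conds$vc_position <- function(x, par) par[["S_D"]] - x[["s"]]
  conds$mitral <- if (mode$mitral == "OPEN") {
    function(x, par) x[["P_LA"]] - x[["P_LV"]]
  } else {
    function(x, par) x[["P_LV"]] - x[["P_LA"]]
  }
  conds$aortic <- if (mode$aortic == "OPEN") {
    function(x, par) x[["P_LV"]] - x[["P_A"]]
  } else {
    function(x, par) x[["P_A"]] - x[["P_LV"]]
  }
  conds
}

#' Right-hand side of the switched ODE system (reference implementation)
#'
#' Pure-R evaluation of the nine state derivatives; the compiled
#' integrator carries an equivalent implementation that the test suite
#' cross-checks against this one. Valve flows follow `mode` (or the free
#' pressure-driven regime), the contraction force follows
#' [contraction_force()], and `s' = v` always.
#'
#' @param x state vector (length 9, canonical order).
#' @param u pump speed (rpm).
#' @param par an [lvad_params()] vector.
#' @param mode phase mode list (see [phase_mode()]); ignored for the
#'   valves when `free_valves = TRUE`.
#' @param free_valves logical; if `TRUE` valve flows are pressure-driven.
#' @param lvad_present logical; if `FALSE` the pump branch is absent and
#'   `Q_LVAD` is clamped at zero (personalisation setting).
#' @return named numeric vector of derivatives.
#' @export
eval_rhs <- function(x, u, par, mode = phase_mode(1), free_valves = TRUE,
                     lvad_present = TRUE) {
  validate_params(par)
  x <- as.numeric(x)
  if (length(x) != 9L || any(!is.finite(x))) stop("state must be 9 finite values")
  if (!is.finite(u)) stop("pump speed must be finite")
  names(x) <- .STATE_NAMES
  p <- unclass(par)

  vregime <- function(open) if (open) "open" else "closed"
  q_mv <- if (free_valves) mitral_flow(x[["P_LA"]], x[["P_LV"]], p[["R_M"]])
          else mitral_flow(x[["P_LA"]], x[["P_LV"]], p[["R_M"]],
                           vregime(mode$mitral == "OPEN"))
  q_aov <- if (free_valves) aortic_flow(x[["P_LV"]], x[["P_A"]], p[["R_AoV"]])
           else aortic_flow(x[["P_LV"]], x[["P_A"]], p[["R_AoV"]],
                            vregime(mode$aortic == "OPEN"))
  f_c <- contraction_force(mode$contraction, par)
  q_lvad <- if (lvad_present) x[["Q_LVAD"]] else 0

  dx <- c(
    P_LA = (x[["P_V"]] - x[["P_LA"]]) / (p[["C_LA"]] * p[["R_V"]]) -
      (q_mv - p[["A_LA"]] * x[["v"]]) / p[["C_LA"]],
    P_LV = (1 + p[["k_RAD"]]) * p[["A_LV"]] * x[["v"]] / p[["C_LV"]] +
      (q_mv - q_aov - q_lvad) / p[["C_LV"]],
    P_A = (q_aov + q_lvad - x[["Q_A"]]) / p[["C_A"]],
    P_S = (x[["P_V"]] - x[["P_S"]]) / (p[["C_S"]] * p[["R_S"]]) +
      x[["Q_A"]] / p[["C_S"]],
    P_V = (x[["P_S"]] - x[["P_V"]]) / (p[["C_V"]] * p[["R_S"]]) +
      (x[["P_LA"]] - x[["P_V"]]) / (p[["C_V"]] * p[["R_V"]]),
    Q_A = (x[["P_A"]] - x[["P_S"]] - p[["R_C"]] * x[["Q_A"]]) / p[["L_S"]],
    Q_LVAD = if (lvad_present) {
      (x[["P_LV"]] - x[["P_A"]] - p[["R_LVAD"]] * x[["Q_LVAD"]] -
         p[["beta"]] * u^2) / p[["L_LVAD"]]
    } else 0,
    v = (-p[["R_AVP"]] * x[["v"]] - p[["A_LV"]] * x[["P_LV"]] +
           p[["A_LA"]] * x[["P_LA"]] + f_c) / p[["L_AVP"]],
    s = x[["v"]]
  )
  dx
}

# compiled twin, used by tests to assert equivalence with eval_rhs()
.eval_rhs_compiled <- function(x, u, par, mode = phase_mode(1),
                               free_valves = TRUE, lvad_present = TRUE) {
  cmode <- match(mode$contraction, c("ZERO", "AC", "VC")) - 1L
  .rhs_cpp(as.numeric(x), u, .par_vec(par), cmode,
           mode$mitral == "OPEN", mode$aortic == "OPEN",
           free_valves, lvad_present)
}
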
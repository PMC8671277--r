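#' @useDynLib lvadopt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats nlminb rnorm runif approx sd setNames
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

# canonical parameter order shared with the compiled core
.PAR_NAMES <- c(
  "C_LA", "C_LV", "C_A", "C_S", "C_V",
  "R_V", "R_S", "R_C", "R_M", "R_AoV", "R_LVAD", "R_AVP",
  "L_S", "L_LVAD", "L_AVP",
  "A_LA", "A_LV", "k_RAD", "beta", "F_AC", "F_VC", "S_D"
)

.PAR_UNITS <- c(
  C_LA = "mL/mmHg", C_LV = "mL/mmHg", C_A = "mL/mmHg", C_S = "mL/mmHg",
  C_V = "mL/mmHg",
  R_V = "mmHg*s/mL", R_S = "mmHg*s/mL", R_C = "mmHg*s/mL", R_M = "mmHg*s/mL",
  R_AoV = "mmHg*s/mL", R_LVAD = "mmHg*s/mL", R_AVP = "mmHg*s/cm",
  L_S = "mmHg*s^2/mL", L_LVAD = "mmHg*s^2/mL", L_AVP = "mmHg*s^2/cm",
  A_LA = "cm^2", A_LV = "cm^2", k_RAD = "1", beta = "mmHg/rpm^2",
  F_AC = "mmHg*cm^2", F_VC = "mmHg*cm^2", S_D = "cm"
)

# estimated subvector p = [R_AVP, C_LV, L_AVP, F_VC, F_AC, A_LV, A_LA,
# k_RAD, S_D]
.EST_NAMES <- c("R_AVP", "C_LV", "L_AVP", "F_VC", "F_AC", "A_LV", "A_LA",
                "k_RAD", "S_D")

#' Model parameters of the AVPD heart / LVAD system
#'
#' Builds the full parameter set of the lumped cardiovascular model:
#' compliances `C_*` (mL/mmHg) of left atrium, left ventricle, aorta,
#' systemic artery and venous system; resistances `R_*` of the venous
#' return, systemic periphery, aortic characteristic impedance, the two
#' valves, the pump cannula circuit and the atrioventricular-plane (AVP)
#' velocity drag; inertances `L_*`; AVP piston cross sections `A_LA`,
#' `A_LV` (cm^2); the radial-pumping amplification `k_RAD`; the pump
#' speed-to-pressure coefficient `beta` (mmHg/rpm^2, negative so that
#' `-beta * u^2` adds forward pump head); contraction force magnitudes
#' `F_AC`, `F_VC`; and the switching distance `S_D` (cm) bounding the AVP
#' excursion.
#'
#' Defaults combine the personalised estimate
#' `p* = [324.2, 0.6, 20.4, 4709, 900, 42, 25, 1.35, 0.5]` for the nine
#' estimated parameters with documented placeholder values for the
#' remaining circulation and pump constants, calibrated once so that the
#' pump-free steady cycle reproduces a dilated-failure haemodynamic
#' picture (cardiac output about 3.3 L/min, left-atrial pressure inside
#' 10--20 mmHg, systolic LV pressure about 103 mmHg).
#'
#' @param ... named replacements for individual parameters.
#' @return A named numeric vector of class `"lvad_params"`.
#' @examples
#' p <- lvad_params()
#' p2 <- lvad_params(R_S = 1.4)
#' @export
lvad_params <- function(...) {
  par <- c(
    C_LA = 10, C_LV = 0.6, C_A = 0.45, C_S = 1.5, C_V = 80,
    R_V = 0.05, R_S = 1.2, R_C = 0.04, R_M = 0.02, R_AoV = 0.015,
    R_LVAD = 0.35, R_AVP = 324.2,
    L_S = 5e-4, L_LVAD = 0.05, L_AVP = 20.4,
    A_LA = 25, A_LV = 42, k_RAD = 1.35, beta = -1.02e-6,
    F_AC = 900, F_VC = 4709, S_D = 0.5
  )
  repl <- list(...)
  if (length(repl)) {
    bad <- setdiff(names(repl), .PAR_NAMES)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    par[names(repl)] <- vapply(repl, as.numeric, numeric(1))
  }
  par <- par[.PAR_NAMES]
  class(par) <- "lvad_params"
  validate_params(par)
  par
}

#' Validate a parameter vector
#'
#' Checks positivity of compliances, resistances, inertances, areas,
#' contraction force magnitudes and the switching distance; `beta` may
#' take either sign but must be finite and non-zero.
#'
#' @param par object created by [lvad_params()].
#' @return `par`, invisibly, or an error naming the offending field.
#' @export
validate_params <- function(par) {
  if (!inherits(par, "lvad_params") || length(par) != length(.PAR_NAMES) ||
      !identical(names(unclass(par)), .PAR_NAMES))
    stop("not an 'lvad_params' vector")
  if (any(!is.finite(par))) stop("non-finite parameter value")
  pos <- setdiff(.PAR_NAMES, "beta")
  bad <- pos[unclass(par)[pos] <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  if (par[["beta"]] == 0) stop("beta must be non-zero")
  invisible(par)
}

#' @export
print.lvad_params <- function(x, ...) {
  cat("AVPD/LVAD model parameters:\n")
  print(data.frame(value = as.numeric(x), unit = .PAR_UNITS[names(unclass(x))]))
  invisible(x)
}

#' Extract or insert the estimated parameter subvector
#'
#' The nine personalisation parameters, in the order
#' `[R_AVP, C_LV, L_AVP, F_VC, F_AC, A_LV, A_LA, k_RAD, S_D]`.
#'
#' @param par an [lvad_params()] vector.
#' @return `estimated_params()`: named numeric vector of length 9.
#' @export
estimated_params <- function(par) {
  validate_params(par)
  unclass(par)[.EST_NAMES]
}

#' @rdname estimated_params
#' @param p numeric vector of length 9 (same order as [estimated_params()]).
#' @return `set_estimated_params()`: the updated `lvad_params` vector.
#' @export
set_estimated_params <- function(par, p) {
  validate_params(par)
  stopifnot(length(p) == 9L)
  par[.EST_NAMES] <- as.numeric(p)
  validate_params(par)
  par
}

#' Default box bounds for the estimated parameters
#'
#' Wide physiological ranges used by the personalisation solver for
#' projection; the estimate `p*` sits comfortably in the interior.
#'
#' @return list with numeric vectors `lb` and `ub` (length 9, named).
#' @export
default_param_bounds <- function() {
  lb <- c(R_AVP = 50, C_LV = 0.1, L_AVP = 2, F_VC = 500, F_AC = 100,
          A_LV = 10, A_LA = 5, k_RAD = 0.1, S_D = 0.2)
  ub <- c(R_AVP = 1000, C_LV = 3, L_AVP = 100, F_VC = 20000, F_AC = 5000,
          A_LV = 100, A_LA = 60, k_RAD = 4, S_D = 1.5)
  list(lb = lb, ub = ub)
}

#' Read / write parameter sets as annotated JSON
#'
#' The file stores one object per parameter with `value` and `unit`
#' fields; units are checked against the package's canonical unit table
#' on load.
#'
#' @param path file path.
#' @return `read_params_json()` returns an [lvad_params()] vector.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!setequal(names(obj), .PAR_NAMES))
    stop("parameter file must define exactly the fields: ",
         paste(.PAR_NAMES, collapse = ", "))
  vals <- vapply(.PAR_NAMES, function(nm) {
    rec <- obj[[nm]]
    if (!is.list(rec) || is.null(rec$value))
      stop("field '", nm, "' must be an object with a 'value' entry")
    if (!is.null(rec$unit) && !identical(rec$unit, unname(.PAR_UNITS[nm])))
      stop("field '", nm, "' has unit '", rec$unit, "', expected '",
           .PAR_UNITS[nm], "'")
    as.numeric(rec$value)
  }, numeric(1))
  do.call(lvad_params, as.list(vals))
}

#' @rdname read_params_json
#' @param par an [lvad_params()] vector.
#' @export
write_params_json <- function(par, path) {
  validate_params(par)
  obj <- lapply(.PAR_NAMES, function(nm)
    list(value = as.numeric(par[[nm]]), unit = unname(.PAR_UNITS[nm])))
  names(obj) <- .PAR_NAMES
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# strip class for the compiled core
.par_vec <- function(par) {
  validate_params(par)
  as.numeric(par)
}
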
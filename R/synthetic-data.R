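# Synthetic stand-ins for the undeposited clinical inputs: a reference
# patient (parameter set + haemodynamic targets) and noisy LV-pressure
# measurement series with the structure the personalisation assumes.

#' Construct a reference patient
#'
#' The `"paper_subject"` preset combines the personalised estimate of the
#' nine high-sensitivity parameters with the package's placeholder
#' circulation constants and a 0.89 s cycle (67 bpm). Its pump-free
#' periodic simulation reproduces a dilated left-heart-failure picture:
#' left-atrial pressure inside 10--20 mmHg, cardiac output near
#' 3.5 L/min, AVPD amplitude near 10 mm. Haemodynamic targets carry the
#' tolerances within which the synthetic subject is expected to match
#' them; the end-systolic LV pressure target carries a wide (20%)
#' tolerance because the velocity drag of the personalised `R_AVP` caps
#' the simulated peak near 103 mmHg.
#'
#' @param profile preset name; only `"paper_subject"` is defined.
#' @return object of class `"reference_patient"`: `params`
#'   ([lvad_params()]), `h_cycle` (s), `p` (the nine estimated values),
#'   `targets` (list of `value`/`rel_tol` records), `x0_guess`.
#' @export
make_reference_patient <- function(profile = "paper_subject") {
  if (!identical(profile, "paper_subject"))
    stop("unknown patient preset '", profile, "'")
  p_true <- c(R_AVP = 324.2, C_LV = 0.6, L_AVP = 20.4, F_VC = 4709,
              F_AC = 900, A_LV = 42, A_LA = 25, k_RAD = 1.35, S_D = 0.5)
  params <- set_estimated_params(lvad_params(), p_true)
  structure(list(
    profile = profile,
    params = params,
    p = p_true,
    h_cycle = 0.89,
    targets = list(
      lv_pressure_es = list(value = 120, unit = "mmHg", rel_tol = 0.20),
      lv_pressure_ed = list(value = 5, unit = "mmHg", abs_tol = 4),
      la_pressure_range = list(value = c(10, 20), unit = "mmHg"),
      cardiac_output = list(value = 3.5, unit = "L/min", rel_tol = 0.15),
      lv_volume_ed = list(value = 281, unit = "mL"),
      lv_volume_es = list(value = 228, unit = "mL"),
      avpd_amplitude = list(value = 10, unit = "mm", rel_tol = 0.1)
    ),
    x0_guess = default_x0(params)
  ), class = "reference_patient")
}

#' @export
print.reference_patient <- function(x, ...) {
  cat("reference patient '", x$profile, "': cycle ", x$h_cycle, " s\n",
      sep = "")
  print(x$p)
  invisible(x)
}

#' Generate a noisy LV-pressure measurement series
#'
#' Simulates one pump-free periodic cycle of the patient, samples
#' `P_LV` at `n_m` times and adds independent Gaussian noise. Default
#' sampling is even spacing over the open cycle (never duplicating the
#' periodic endpoint); the `"systole_dense"` layout concentrates half the
#' samples in the contraction phases. Reported `sigma` is
#' `max(noise_sd, 1)` per sample, mirroring unit measurement weights.
#'
#' @param patient a [make_reference_patient()] object.
#' @param n_m number of samples (>= 2).
#' @param noise_sd measurement noise standard deviation (mmHg, >= 0).
#' @param seed integer seed for reproducibility (optional).
#' @param layout `"even"` or `"systole_dense"`.
#' @return list with the [measurement_set()] `data`, the noise-free
#'   `truth`, the realised `schedule` (six switching times) and the
#'   periodic start state `x0`.
#' @export
generate_measurements <- function(patient, n_m = 27, noise_sd = 1,
                                  seed = NULL,
                                  layout = c("even", "systole_dense")) {
  stopifnot(inherits(patient, "reference_patient"), n_m >= 2, noise_sd >= 0)
  layout <- match.arg(layout)
  if (!is.null(seed)) set.seed(seed)
  par <- patient$params
  tf <- patient$h_cycle
  ctrl <- pump_constant(0)
  ss <- steady_state_x0(par, ctrl, patient$x0_guess, 0, tf,
                        lvad_present = FALSE)
  traj <- simulate_cycle(par, ctrl, ss$x0, 0, tf, lvad_present = FALSE)

  if (layout == "even") {
    times <- seq(0, tf, length.out = n_m + 1)[seq_len(n_m)]
  } else {
    n_sys <- ceiling(n_m / 2)
    sys <- seq(traj$t0, traj$tau[5], length.out = n_sys + 1)[-1]
    dia <- seq(traj$tau[5], tf, length.out = n_m - n_sys + 2)
    times <- sort(unique(c(sys, head(dia[-1], -1))))[seq_len(n_m)]
  }
  truth <- approx(traj$time, traj$states[, "P_LV"], xout = times, rule = 2)$y
  noise <- if (noise_sd > 0) rnorm(n_m, 0, noise_sd) else 0
  data <- measurement_set(times, truth + noise, sigma = max(noise_sd, 1))
  list(data = data, truth = truth, schedule = traj$tau, x0 = ss$x0,
       trajectory = traj)
}

#' @rdname make_reference_patient
#' @param patient a `"reference_patient"`.
#' @param path JSON output path for the preset.
#' @export
write_patient_json <- function(patient, path) {
  jsonlite::write_json(list(
    profile = patient$profile, h_cycle = patient$h_cycle,
    p = as.list(patient$p),
    targets = patient$targets), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
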
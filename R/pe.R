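# Model personalisation: weighted nonlinear least squares on measured LV
# pressure via damped Gauss-Newton, and Fisher-information uncertainty.

#' Measurement set for personalisation
#'
#' Left-ventricular pressure samples over one cycle: strictly increasing
#' times, values in mmHg and per-sample standard deviations (default 1).
#'
#' @param time sample times (s), strictly increasing.
#' @param value measured LV pressure (mmHg).
#' @param sigma measurement standard deviations (mmHg), recycled.
#' @return data frame of class `"measurement_set"` with attributes `n_m`.
#' @export
measurement_set <- function(time, value, sigma = 1) {
  n <- length(time)
  if (n < 2L) stop("at least two measurements required")
  if (length(value) != n) stop("time and value lengths differ")
  if (any(!is.finite(time)) || any(!is.finite(value)))
    stop("non-finite measurement")
  if (any(diff(time) <= 0)) stop("measurement times must be strictly increasing")
  sigma <- rep_len(sigma, n)
  if (any(sigma <= 0)) stop("sigma must be positive")
  structure(data.frame(time = time, value = value, sigma = sigma),
            class = c("measurement_set", "data.frame"), n_m = n)
}

#' @rdname measurement_set
#' @param path CSV path with columns `t`, `value`, `sigma`.
#' @export
read_measurements_csv <- function(path) {
  df <- read.csv(path)
  need <- c("t", "value", "sigma")
  if (!all(need %in% names(df)))
    stop("measurement CSV needs columns: ", paste(need, collapse = ", "))
  measurement_set(df$t, df$value, df$sigma)
}

#' @rdname measurement_set
#' @param data a `measurement_set`.
#' @export
write_measurements_csv <- function(data, path) {
  write.csv(data.frame(t = data$time, value = data$value, sigma = data$sigma),
            path, row.names = FALSE)
  invisible(path)
}

#' Extract a fixed phase schedule from a simulation
#'
#' The personalisation fixes the phase durations; following the
#' initialisation strategy, they are taken from the realised switching
#' events of an event-driven simulation with the supplied (default)
#' parameter values.
#'
#' @param par an [lvad_params()] vector.
#' @param t0,tf cycle boundaries (s).
#' @param x0 optional start state; defaults to the periodic state.
#' @return numeric length 6 of switching times.
#' @export
schedule_from_simulation <- function(par, t0 = 0, tf = 0.89, x0 = NULL) {
  ctrl <- pump_constant(0)
  if (is.null(x0))
    x0 <- steady_state_x0(par, ctrl, t0 = t0, tf = tf,
                          lvad_present = FALSE)$x0
  traj <- simulate_cycle(par, ctrl, x0, t0, tf, lvad_present = FALSE)
  traj$tau
}

# total stressed volume invariant of the dynamics:
# sum(C_i P_i) - (A_LA + (1 + k_RAD) A_LV) s  is exactly conserved, so the
# periodic fixed point depends on the volume implied by the search seed
.total_volume <- function(x, par) {
  Cs <- as.numeric(par)[1:5]
  coef <- par[["A_LA"]] + (1 + par[["k_RAD"]]) * par[["A_LV"]]
  sum(Cs * x[1:5]) - coef * x[9]
}

# steady periodic start for fixed-schedule, pump-free dynamics; cached
# warm start across parameter iterates, projected back onto the volume
# level set of the reference state so the forward model is a pure
# function of the parameters
.pe_steady <- function(par, schedule, t0, tf, cache = NULL) {
  ref <- as.numeric(default_x0(par))
  guess <- if (!is.null(cache) && !is.null(cache$x0)) cache$x0 else ref
  Cs <- as.numeric(par)[1:5]
  dv <- (.total_volume(ref, par) - .total_volume(guess, par)) / sum(Cs)
  guess[1:5] <- guess[1:5] + dv
  res <- .steady_search(guess, .par_vec(par), t0, tf,
                        list(type = 0L, u = 0, lvad_present = FALSE),
                        as.numeric(schedule), 1e-9, 1000)
  if (res$status != 0L) stop("fixed-schedule steady state failed")
  if (!is.null(cache)) cache$x0 <- res$x0
  res$x0
}

# forward model: predicted LV pressure at the sample times plus the six
# phase-boundary switching residuals of the transcription, which carry
# the S_D information that the phase-fixed dynamics alone do not
.pe_forward <- function(p, data, schedule, base_par, t0, tf, cache = NULL) {
  if (any(data$time < t0 | data$time > tf))
    stop("measurement time outside the cycle [t0, tf]")
  par <- set_estimated_params(base_par, p)
  x0 <- .pe_steady(par, schedule, t0, tf, cache)
  traj <- simulate_cycle(par, pump_constant(0), x0, t0, tf,
                         schedule = schedule, lvad_present = FALSE)
  pred <- approx(traj$time, traj$states[, "P_LV"], xout = data$time,
                 rule = 2)$y
  sw <- switching_residuals(traj, par, eps_sw = 1)$residual
  list(pred = pred, sw = sw)
}

#' Model LV pressure at the measurement times
#'
#' Simulates the pump-free, phase-fixed periodic cycle at parameters `p`
#' (the nine-element estimated subvector inserted into `base_par`) and
#' interpolates `P_LV` at the requested times.
#'
#' @param p estimated subvector (length 9, order of [estimated_params()]).
#' @param data a [measurement_set()].
#' @param schedule fixed switching times (length 6).
#' @param base_par full parameter vector supplying the non-estimated
#'   constants.
#' @param t0,tf cycle boundaries (s).
#' @param cache optional environment carrying the steady-state warm start.
#' @return numeric vector of model `P_LV` at `data$time`.
#' @export
pe_predict <- function(p, data, schedule, base_par = lvad_params(), t0 = 0,
                       tf = 0.89, cache = NULL) {
  .pe_forward(p, data, schedule, base_par, t0, tf, cache)$pred
}

#' Weighted residual vector of the personalisation problem
#'
#' Residual `i` is `(measured_i - model_i) / sigma_i`; the pump is absent
#' (`Q_LVAD` is zero) and the phase durations are fixed.
#'
#' @inheritParams pe_predict
#' @return numeric vector of length `n_m`.
#' @export
residual_vector <- function(p, data, schedule, base_par = lvad_params(),
                            t0 = 0, tf = 0.89, cache = NULL) {
  (data$value - pe_predict(p, data, schedule, base_par, t0, tf, cache)) /
    data$sigma
}

# data residuals augmented with the switching residuals, weighted by
# sigma_sw (the Eq.-(25)-style boundary conditions act as penalised
# equality constraints in the Gauss-Newton problem)
.pe_resid_aug <- function(p, data, schedule, base_par, t0, tf, sigma_sw,
                          cache = NULL) {
  fw <- .pe_forward(p, data, schedule, base_par, t0, tf, cache)
  c((data$value - fw$pred) / data$sigma, fw$sw / sigma_sw)
}

#' Residual Jacobian by central finite differences
#'
#' @inheritParams pe_predict
#' @param rel_step relative perturbation size per parameter.
#' @return `n_m x 9` matrix `d r / d p`.
#' @export
pe_jacobian <- function(p, data, schedule, base_par = lvad_params(), t0 = 0,
                        tf = 0.89, rel_step = 1e-4, cache = NULL,
                        sigma_sw = NULL) {
  fn <- if (is.null(sigma_sw)) {
    function(q) residual_vector(q, data, schedule, base_par, t0, tf, cache)
  } else {
    function(q) .pe_resid_aug(q, data, schedule, base_par, t0, tf, sigma_sw,
                              cache)
  }
  r0 <- fn(p)
  J <- matrix(0, length(r0), length(p))
  for (j in seq_along(p)) {
    hj <- rel_step * max(abs(p[j]), 1e-6)
    pp <- p; pp[j] <- pp[j] + hj
    pm <- p; pm[j] <- pm[j] - hj
    J[, j] <- (fn(pp) - fn(pm)) / (2 * hj)
  }
  J
}

.pe_objective <- function(r, p, prior) {
  phi <- if (is.null(prior)) 0 else
    0.5 * sum(prior$weight * (p - prior$mean)^2)
  0.5 * sum(r^2) + phi
}

#' Personalise the model by damped Gauss-Newton
#'
#' Minimises `0.5 * sum(((measured - model)/sigma)^2) + phi(p)` over the
#' nine estimated parameters with the phase durations fixed and the pump
#' absent. Steps are Gauss-Newton directions from a QR solve of the
#' finite-difference Jacobian, damped by Armijo backtracking, with simple
#' projection onto the box bounds. The objective is non-increasing across
#' accepted iterations; non-convergence is reported with the iterate
#' history rather than hidden.
#'
#' @param data a [measurement_set()].
#' @param p0 start vector (length 9), inside the bounds.
#' @param bounds list with `lb`, `ub` (see [default_param_bounds()]).
#' @param schedule fixed switching times (length 6).
#' @param base_par full parameter vector for the non-estimated constants.
#' @param t0,tf cycle boundaries (s).
#' @param prior optional quadratic prior `phi(p) = 0.5 * sum(w (p - m)^2)`
#'   as `list(mean =, weight =)`; default none (`phi = 0`).
#' @param sigma_sw weight (as a standard deviation) of the six
#'   phase-boundary switching residuals appended to the least-squares
#'   system; they carry the `S_D` information and act as penalised
#'   versions of the transcription's boundary constraints.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the scaled step norm.
#' @return object of class `"pe_result"`: `p_star`; `objective` (the
#'   data-misfit half-sum-of-squares plus prior, as in the estimation
#'   problem statement); `merit` (objective plus switching penalty, the
#'   quantity the solver decreases monotonically); `rmsd` (mmHg,
#'   `sqrt(2 * objective / n_m)` for unit weights); `sd_percent`
#'   (Fisher-information relative SDs); `switching_residuals`;
#'   `converged`; `iterations`; `history` (per-iteration merit);
#'   `schedule`.
#' @export
solve_pe <- function(data, p0, bounds = default_param_bounds(),
                     schedule, base_par = lvad_params(), t0 = 0, tf = 0.89,
                     prior = NULL, sigma_sw = 0.05, max_iter = 40,
                     tol = 1e-8) {
  stopifnot(length(p0) == 9L)
  lb <- bounds$lb; ub <- bounds$ub
  if (any(p0 < lb) || any(p0 > ub)) stop("p0 outside bounds")
  cache <- new.env(parent = emptyenv())
  p <- as.numeric(p0)
  rfun <- function(q) .pe_resid_aug(q, data, schedule, base_par, t0, tf,
                                    sigma_sw, cache)
  n_m <- attr(data, "n_m")
  r <- rfun(p)
  obj <- .pe_objective(r, p, prior)
  history <- obj
  converged <- FALSE

  lambda <- 1e-3
  for (iter in seq_len(max_iter)) {
    J <- pe_jacobian(p, data, schedule, base_par, t0, tf, cache = cache,
                     sigma_sw = sigma_sw)
    if (!is.null(prior)) {
      W <- sqrt(prior$weight)
      J <- rbind(J, diag(W, length(p)))
      r_use <- c(r, W * (p - prior$mean))
    } else r_use <- r
    JtJ <- crossprod(J)
    g <- crossprod(J, r_use)
    D <- pmax(sqrt(diag(JtJ)), 1e-10) # column scaling of the damping
    accepted <- FALSE
    for (ls in 1:30) {
      # Levenberg-Marquardt damped Gauss-Newton step with projection
      dir <- tryCatch(solve(JtJ + lambda * diag(D^2), -g),
                      error = function(e) NULL)
      if (!is.null(dir)) {
        p_try <- pmin(pmax(p + as.numeric(dir), lb), ub)
        r_try <- tryCatch(rfun(p_try), error = function(e) NULL)
        if (!is.null(r_try)) {
          obj_try <- .pe_objective(r_try, p_try, prior)
          if (obj_try < obj) {
            rel_step <- max(abs(p_try - p) / pmax(abs(p), 1e-6))
            p <- p_try; r <- r_try; obj <- obj_try
            history <- c(history, obj)
            lambda <- max(lambda / 3, 1e-10)
            accepted <- TRUE
            if (rel_step < tol) converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 4
      if (lambda > 1e10) break
    }
    if (!accepted) converged <- TRUE # stationary within damping range
    if (!accepted || converged) break
  }

  obj_data <- 0.5 * sum(r[seq_len(n_m)]^2) +
    if (is.null(prior)) 0 else 0.5 * sum(prior$weight * (p - prior$mean)^2)
  J <- pe_jacobian(p, data, schedule, base_par, t0, tf, cache = cache,
                   sigma_sw = sigma_sw)
  fish <- fisher_sd_from_jacobian(J, setNames(p, .EST_NAMES))
  structure(list(
    p_star = setNames(p, .EST_NAMES),
    objective = obj_data, merit = obj,
    rmsd = sqrt(2 * obj_data / n_m),
    switching_residuals = r[n_m + seq_len(6)] * sigma_sw,
    sd_percent = fish$sd_percent, identifiable = fish$identifiable,
    converged = converged, iterations = length(history) - 1L,
    history = history, schedule = schedule, prior = prior,
    sigma_sw = sigma_sw
  ), class = "pe_result")
}

#' @export
print.pe_result <- function(x, ...) {
  cat("personalisation result (damped Gauss-Newton):\n")
  print(data.frame(estimate = x$p_star, sd_percent = x$sd_percent))
  cat(sprintf("objective %.6g  rmsd %.4g mmHg  iterations %d  converged %s\n",
              x$objective, x$rmsd, x$iterations, x$converged))
  invisible(x)
}

#' Fisher-information relative standard deviations
#'
#' Gauss-Newton approximation of the parameter covariance at the optimum:
#' `cov = (J' J)^-1` with `J` the sigma-weighted residual Jacobian, and
#' `%SD_i = 100 * sqrt(cov_ii) / |p_i|`. A rank-deficient Jacobian yields
#' per-parameter non-identifiability flags instead of an error.
#'
#' @param J residual Jacobian (`n_m x n_p`).
#' @param p parameter vector at which `J` was evaluated.
#' @return list with `sd_percent`, `identifiable` (logical), `cov`.
#' @export
fisher_sd_from_jacobian <- function(J, p) {
  qrJ <- qr(J)
  np <- length(p)
  if (qrJ$rank < np) {
    idf <- rep(FALSE, np)
    # columns pivoted beyond the rank are the non-identified directions
    idf[qrJ$pivot[seq_len(qrJ$rank)]] <- TRUE
    return(list(sd_percent = setNames(rep(NA_real_, np), names(p)),
                identifiable = setNames(idf, names(p)), cov = NULL))
  }
  # work in relative parameters (columns scaled by |p|): identical
  # mathematics, far better conditioning for the strongly correlated
  # force/area/drag directions
  sc <- abs(p)
  sc[sc == 0] <- 1
  Jr <- J %*% diag(sc, np)
  cov_rel <- tryCatch(solve(crossprod(Jr)), error = function(e) NULL)
  if (is.null(cov_rel))
    return(list(sd_percent = setNames(rep(NA_real_, np), names(p)),
                identifiable = setNames(rep(FALSE, np), names(p)),
                cov = NULL))
  sdp <- 100 * sqrt(pmax(diag(cov_rel), 0))
  sdp[abs(p) == 0] <- NA_real_
  cov <- diag(sc, np) %*% cov_rel %*% diag(sc, np)
  list(sd_percent = setNames(sdp, names(p)),
       identifiable = setNames(rep(TRUE, np), names(p)), cov = cov)
}

#' @rdname fisher_sd_from_jacobian
#' @inheritParams pe_predict
#' @param p_star estimate at which to evaluate the Jacobian.
#' @param sigma_sw switching-residual weight (see [solve_pe()]); set
#'   `NULL` to use the data residuals alone.
#' @export
fisher_sd <- function(p_star, data, schedule, base_par = lvad_params(),
                      t0 = 0, tf = 0.89, sigma_sw = 0.05) {
  J <- pe_jacobian(p_star, data, schedule, base_par, t0, tf,
                   sigma_sw = sigma_sw)
  fisher_sd_from_jacobian(J, p_star)
}

#' @rdname solve_pe
#' @param result a `"pe_result"`.
#' @param path JSON output path.
#' @export
write_pe_json <- function(result, path) {
  jsonlite::write_json(list(
    p_star = as.list(result$p_star), objective = result$objective,
    rmsd = result$rmsd, sd_percent = as.list(result$sd_percent),
    converged = result$converged, iterations = result$iterations,
    history = result$history, schedule = result$schedule),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
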
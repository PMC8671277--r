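# Personalisation: residual structure, Gauss-Newton behaviour and
# Fisher-information uncertainty.

test_that("measurement sets validate and round-trip through CSV", {
  expect_error(measurement_set(1, 2), "at least two")
  expect_error(measurement_set(c(0.2, 0.1), c(1, 2)), "strictly increasing")
  expect_error(measurement_set(c(0.1, 0.2), c(1, 2), sigma = 0), "positive")
  ms <- measurement_set(c(0.1, 0.2, 0.4), c(10, 50, 20), sigma = 2)
  f <- tempfile(fileext = ".csv")
  write_measurements_csv(ms, f)
  ms2 <- read_measurements_csv(f)
  expect_equal(ms2$time, ms$time)
  expect_equal(ms2$value, ms$value)
  expect_equal(ms2$sigma, ms$sigma)
})

test_that("residuals vanish on noise-free data at the true parameters and
           scale inversely with sigma", {
  pat <- fx_patient()
  gen <- fx_gen0()
  r <- residual_vector(pat$p, gen$data, gen$schedule, tf = pat$h_cycle)
  expect_lt(max(abs(r)), 5e-3) # steady-state / interpolation tolerance
  # doubling sigma halves the residuals
  d2 <- measurement_set(gen$data$time, gen$data$value, sigma = 2)
  r2 <- residual_vector(pat$p * 1.02, d2, gen$schedule, tf = pat$h_cycle)
  d1 <- measurement_set(gen$data$time, gen$data$value, sigma = 1)
  r1 <- residual_vector(pat$p * 1.02, d1, gen$schedule, tf = pat$h_cycle)
  expect_equal(r2, r1 / 2, tolerance = 1e-10)
  expect_error(
    residual_vector(pat$p, measurement_set(c(0.1, 1.5), c(10, 10)),
                    gen$schedule, tf = pat$h_cycle),
    "outside the cycle")
})

test_that("the data objective is permutation-invariant half the squared
           residual norm", {
  pat <- fx_patient()
  gen <- fx_gen0()
  p <- pat$p * 1.03
  r <- residual_vector(p, gen$data, gen$schedule, tf = pat$h_cycle)
  obj <- 0.5 * sum(r^2)
  set.seed(3)
  idx <- sample(nrow(gen$data))
  ord <- order(gen$data$time[idx])
  shuf <- measurement_set(gen$data$time[idx][ord], gen$data$value[idx][ord],
                          gen$data$sigma[idx][ord])
  r_shuf <- residual_vector(p, shuf, gen$schedule, tf = pat$h_cycle)
  expect_equal(0.5 * sum(r_shuf^2), obj, tolerance = 1e-12)
})

test_that("the finite-difference Jacobian is step-size robust", {
  pat <- fx_patient()
  gen <- fx_gen0()
  J1 <- pe_jacobian(pat$p, gen$data, gen$schedule, rel_step = 1e-4)
  J2 <- pe_jacobian(pat$p, gen$data, gen$schedule, rel_step = 4e-4)
  expect_lt(max(abs(J1 - J2)) / max(abs(J1)), 1e-4)
})

test_that("Gauss-Newton recovers the generating parameters from a
           perturbed start on noise-free data", {
  pat <- fx_patient()
  gen <- fx_gen0()
  p0 <- pat$p * 1.02
  fit <- solve_pe(gen$data, p0, schedule = gen$schedule,
                  tf = pat$h_cycle, max_iter = 80)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$p_star - pat$p) / pat$p), 0.01)
  # merit is non-increasing across accepted iterations
  expect_true(all(diff(fit$history) <= 1e-12))
  expect_lte(fit$merit, fit$history[1])
  # rmsd algebra: sqrt(2 obj / n_m) with unit weights
  expect_equal(fit$rmsd, sqrt(2 * fit$objective / 27), tolerance = 1e-12)
  expect_error(solve_pe(gen$data, pat$p * 100, schedule = gen$schedule),
               "outside bounds")
})

test_that("Fisher relative SDs: closed form for the scalar linear model
           and weighting homogeneity", {
  # r_i = a t_i - y_i: J column is t_i, %SD = 100 / (|a| sqrt(sum t^2))
  t <- c(0.5, 1, 1.5, 2)
  a <- 3
  J <- matrix(t, ncol = 1)
  f <- fisher_sd_from_jacobian(J, c(a = a))
  expect_equal(unname(f$sd_percent), 100 / (abs(a) * sqrt(sum(t^2))),
               tolerance = 1e-12)
  expect_true(all(f$identifiable))
  # scaling all sigma by c scales the Jacobian by 1/c and all %SD by c
  f3 <- fisher_sd_from_jacobian(J / 3, c(a = a))
  expect_equal(unname(f3$sd_percent), 3 * unname(f$sd_percent),
               tolerance = 1e-12)
  # a zero column is flagged non-identifiable instead of erroring
  J2 <- cbind(t, 0)
  f2 <- fisher_sd_from_jacobian(J2, c(a = a, b = 1))
  expect_false(all(f2$identifiable))
  expect_true(all(is.na(f2$sd_percent)))
})

test_that("noisy replicates: well-conditioned estimates fall within three
           estimated SDs of truth (scaled-down replicate check)", {
  # scaled down from the 50-replicate design for runtime: 8 seeded
  # replicates, solver warm-started at truth with a small iteration cap
  pat <- fx_patient()
  well <- c("C_LV", "k_RAD") # lowest %SD components of this design
  hits <- 0
  n_rep <- 8
  for (k in seq_len(n_rep)) {
    gen <- generate_measurements(pat, n_m = 27, noise_sd = 1,
                                 seed = 100 + k)
    fit <- solve_pe(gen$data, pat$p, schedule = gen$schedule,
                    tf = pat$h_cycle, max_iter = 12)
    sd_abs <- fit$sd_percent / 100 * abs(fit$p_star)
    dev <- abs(fit$p_star - pat$p)
    if (all(dev[well] <= 3 * sd_abs[well])) hits <- hits + 1
  }
  expect_gte(hits, n_rep - 1)
})
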
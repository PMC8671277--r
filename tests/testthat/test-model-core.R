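# Domain types, valve laws, contraction force, mode enumeration and the
# switched right-hand side.

test_that("valve flows follow the diode law and reject bad resistances", {
  expect_equal(mitral_flow(10, 10, 0.1), 0)
  expect_equal(mitral_flow(11, 10, 0.1), 10)
  expect_equal(mitral_flow(10, 11, 0.1), 0)
  expect_equal(aortic_flow(100, 100, 0.5), 0)
  expect_equal(aortic_flow(100, 90, 0.5), 20)
  expect_equal(aortic_flow(80, 100, 0.5), 0)
  # fixed-mode regimes apply their branch unconditionally
  expect_equal(mitral_flow(10, 11, 0.1, regime = "open"), -10)
  expect_equal(aortic_flow(100, 90, 0.5, regime = "closed"), 0)
  expect_error(mitral_flow(11, 10, 0), "strictly positive")
  expect_error(aortic_flow(100, 90, -1), "strictly positive")
})

test_that("valve flows are never negative in the free regime", {
  set.seed(42)
  for (k in 1:200) {
    p1 <- runif(1, -20, 150)
    p2 <- runif(1, -20, 150)
    expect_gte(mitral_flow(p1, p2, runif(1, 0.005, 0.1)), 0)
    expect_gte(aortic_flow(p1, p2, runif(1, 0.005, 0.1)), 0)
  }
})

test_that("contraction force has the documented magnitudes and signs", {
  par <- fx_patient()$params
  expect_equal(contraction_force("ZERO", par), 0)
  # magnitudes from the personalised estimate p*
  expect_equal(abs(contraction_force("VC", par)), 4709)
  expect_equal(abs(contraction_force("AC", par)), 900)
  # sign convention: atrial contraction drives s towards -S_D,
  # ventricular contraction towards +S_D
  expect_lt(contraction_force("AC", par), 0)
  expect_gt(contraction_force("VC", par), 0)
  expect_error(contraction_force("XX", par), "unknown contraction mode")
})

test_that("subsystem enumeration spans the full mode product", {
  subs <- enumerate_subsystems()
  expect_equal(nrow(subs), 12L)
  expect_equal(nrow(unique(subs)), 12L)
  # the canonical schedule uses 7 of the 12
  canon <- unique(phase_modes()[, c("contraction", "mitral", "aortic")])
  expect_equal(nrow(canon), 7L)
  key <- function(df) paste(df$contraction, df$mitral, df$aortic)
  expect_true(all(key(canon) %in% key(subs)))
})

test_that("phase conditions encode the mode path constraints", {
  par <- fx_patient()$params # S_D = 0.5
  x <- lvad_state(P_LA = 10, P_LV = 10, P_A = 100, P_S = 80, P_V = 12,
                  Q_A = 0, Q_LVAD = 0, v = 0, s = -0.49)
  ac <- phase_conditions(phase_mode(1))
  expect_gt(ac$ac_position(x, par), 0)       # s = -S_D + 0.01 admissible
  expect_equal(ac$mitral(x, par), 0)         # boundary P_LA = P_LV
  mv_closed <- phase_conditions(phase_mode(3))
  expect_gte(mv_closed$mitral(x, par), 0)    # closed valve at equality
  aov_open <- phase_conditions(phase_mode(4))
  x2 <- lvad_state(P_LA = 10, P_LV = 80, P_A = 100, P_S = 80, P_V = 12,
                   Q_A = 0, Q_LVAD = 0, v = 0, s = 0)
  expect_lt(aov_open$aortic(x2, par), 0)     # 80 > 100 is false: violated
})

test_that("right-hand side matches the stated structure", {
  par <- fx_patient()$params
  x <- c(12, 8, 70, 72, 14, 0, 0, 3.2, 0.1)
  dx <- eval_rhs(x, 0, par, phase_mode(1))
  expect_equal(unname(dx[["s"]]), 3.2)       # s' = v always
  # P_S = P_V and P_LA = P_V: venous derivative vanishes
  x2 <- c(14, 8, 70, 14, 14, 0, 0, 0, 0.1)
  expect_equal(unname(eval_rhs(x2, 0, par, phase_mode(1))[["P_V"]]), 0)
  # no aortic, pump or arterial flow: aortic pressure derivative vanishes
  x3 <- c(12, 8, 70, 72, 14, 0, 0, 0, 0.1)
  expect_equal(unname(eval_rhs(x3, 0, par, phase_mode(1))[["P_A"]]), 0)
  expect_error(eval_rhs(c(x[-1], NaN), 0, par, phase_mode(1)), "finite")
})

test_that("compiled and reference right-hand sides agree on random states", {
  par <- fx_patient()$params
  set.seed(7)
  for (k in 1:50) {
    x <- c(runif(5, 0, 150), runif(2, -200, 500), runif(1, -15, 15),
           runif(1, -0.5, 0.5))
    u <- runif(1, 0, 12000)
    ph <- sample(1:7, 1)
    for (fv in c(TRUE, FALSE)) for (lv in c(TRUE, FALSE)) {
      d1 <- eval_rhs(x, u, par, phase_mode(ph), free_valves = fv,
                     lvad_present = lv)
      d2 <- lvadopt:::.eval_rhs_compiled(x, u, par, phase_mode(ph),
                                         free_valves = fv,
                                         lvad_present = lv)
      expect_equal(unname(d1), as.numeric(d2), tolerance = 1e-12)
    }
  }
})

test_that("volume bookkeeping: compartment volume derivatives sum to the
           AVP piston term", {
  par <- fx_patient()$params
  p <- unclass(par)
  coef <- p[["A_LA"]] + (1 + p[["k_RAD"]]) * p[["A_LV"]]
  Cs <- p[c("C_LA", "C_LV", "C_A", "C_S", "C_V")]
  set.seed(11)
  for (k in 1:100) {
    x <- c(runif(5, 0, 150), runif(2, -200, 500), runif(1, -15, 15),
           runif(1, -0.5, 0.5))
    ph <- sample(1:7, 1)
    fv <- sample(c(TRUE, FALSE), 1)
    dx <- eval_rhs(x, runif(1, 0, 10000), par, phase_mode(ph),
                   free_valves = fv)
    lhs <- sum(Cs * dx[1:5])
    expect_equal(lhs, coef * x[8], tolerance = 1e-9 * (1 + abs(coef * x[8])))
  }
})

test_that("mode-fixed dynamics agree with the free regime where the mode
           conditions hold", {
  par <- fx_patient()$params
  set.seed(23)
  n_checked <- 0
  for (k in 1:400) {
    x <- c(runif(5, 0, 150), runif(2, -200, 500), runif(1, -15, 15),
           runif(1, -0.49, 0.49))
    names(x) <- state_names()
    ph <- sample(1:7, 1)
    mode <- phase_mode(ph)
    conds <- phase_conditions(mode)
    if (!all(vapply(conds, function(f) f(x, par) > 0, logical(1)))) next
    n_checked <- n_checked + 1
    d_free <- eval_rhs(x, 5000, par, mode, free_valves = TRUE)
    d_fixed <- eval_rhs(x, 5000, par, mode, free_valves = FALSE)
    expect_equal(d_free, d_fixed, tolerance = 1e-12)
  }
  expect_gt(n_checked, 30) # the sample actually exercised the property
})

test_that("state and parameter validation reject malformed input", {
  expect_error(lvad_state(P_LA = 1), "fields")
  expect_error(lvad_params(C_LV = -1), "strictly positive")
  expect_error(lvad_params(nonsense = 1), "unknown parameter")
  p <- lvad_params()
  expect_equal(names(estimated_params(p)),
               c("R_AVP", "C_LV", "L_AVP", "F_VC", "F_AC", "A_LV", "A_LA",
                 "k_RAD", "S_D"))
  p2 <- set_estimated_params(p, estimated_params(p) * 1.1)
  expect_equal(p2[["F_VC"]], 4709 * 1.1)
})
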
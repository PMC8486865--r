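test_that("protein binding relaxes to a 25% free fraction and conserves drug", {
  p <- default_params()
  # no association: nothing binds
  p0 <- p; p0$pk$k_a <- 0
  expect_equal(binding_step(1, 0, dt = 1e5, p0)$B, 0)
  # equilibrium free fraction k_d / (k_a + k_d) = 25%
  eq <- binding_step(1, 0, dt = 1e7, p)
  expect_equal(eq$F, 0.25)
  expect_equal(eq$B, 0.75)
  # bound roughly three times free at equilibrium
  expect_equal(eq$B / eq$F, 3)
  # conservation and exactness against a stiff ODE solve
  st <- binding_step(0.6, 0.1, dt = 500, p)
  expect_equal(st$F + st$B, 0.7)
  ode <- deSolve::ode(c(F = 0.6, B = 0.1), c(0, 500),
                      function(t, y, par) {
                        list(c(-p$pk$k_a * y[1] + p$pk$k_d * y[2],
                               p$pk$k_a * y[1] - p$pk$k_d * y[2]))
                      }, NULL, rtol = 1e-12, atol = 1e-14)
  expect_equal(st$F, unname(ode[2, "F"]), tolerance = 1e-8)
})

test_that("liposome release is leaky below, bursting above the melting range", {
  p <- default_params()
  expect_equal(thermodox_release_rate(37), p$pk$k_leak)
  # >= 95% payload released within 60 s at 41 degC
  k41 <- thermodox_release_rate(41)
  expect_gte(1 - exp(-k41 * 60), 0.95)
  # monotone trigger
  Ts <- seq(36, 43, by = 0.25)
  expect_true(all(diff(thermodox_release_rate(Ts)) >= 0))
  # ~30% leak over 2.5 h at body temperature
  expect_equal(1 - exp(-p$pk$k_leak * 2.5 * 3600), 0.30, tolerance = 0.02)
})

test_that("plasma PK conserves mass without elimination and scales with dose", {
  p <- default_params()
  s <- simulate_plasma_pk(50, "thermodox", p, duration = 3600,
                          clearance = FALSE)
  tot <- (s$T_sys + s$F_sys + s$B_sys) +
    p$pk$V_ratio * (s$T_ves + s$F_ves + s$B_ves)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-8)
  # doubling the bolus doubles every trajectory
  s1 <- simulate_plasma_pk(50, "free_dox", p, duration = 3600)
  s2 <- simulate_plasma_pk(100, "free_dox", p, duration = 3600)
  expect_equal(as.matrix(s2[, -1]), 2 * as.matrix(s1[, -1]),
               tolerance = 1e-7)
})

test_that("systemic free doxorubicin has a sub-30-minute half-life", {
  s <- simulate_plasma_pk(50, "free_dox", duration = 2 * 3600, dt_out = 10)
  hl <- free_drug_half_life(s)
  expect_lt(hl, 30 * 60)
  expect_gt(hl, 5 * 60)   # not instantaneous either
})

test_that("intravascular release empties tumor-vessel liposomes during heating", {
  p <- default_params()
  Tv <- function(t) ifelse(t < 3600, 41.5, 37)
  heated <- simulate_plasma_pk(50, "thermodox", p, T_vessel = Tv,
                               duration = 2 * 3600)
  unheated <- simulate_plasma_pk(50, "thermodox", p, duration = 2 * 3600)
  i <- which(heated$time == 3600)
  drop <- 1 - heated$T_ves[i] / unheated$T_ves[i]
  expect_gte(drop, 0.90)
  # the burst appears as free drug in the vessel
  expect_gt(max(heated$F_ves), max(unheated$F_ves))
})

test_that("the tumor-vessel compartment barely feeds back on systemic plasma", {
  ratio <- vessel_feedback_check()
  expect_lt(ratio, 0.01)
  # no vessel volume, no feedback
  p0 <- default_params(); p0$pk$V_ratio <- 0
  expect_equal(vessel_feedback_check(params = p0), 0)
  # feedback grows with the volume ratio
  p2 <- default_params(); p2$pk$V_ratio <- 5e-3
  expect_gt(vessel_feedback_check(params = p2), ratio)
})

test_that("trajectories stay nonnegative across random nonnegative rate sets", {
  set.seed(42)
  for (i in 1:5) {
    p <- default_params()
    p$pk$k_a <- runif(1, 0, 3e-3)
    p$pk$k_d <- runif(1, 0, 1e-3)
    p$pk$k_el_F <- runif(1, 0, 1e-3)
    p$pk$k_el_T <- runif(1, 0, 2e-4)
    p$pk$k_endo <- runif(1, 0, 5e-4)
    p$pk$Q_perf <- runif(1, 0, 5e-3)
    s <- simulate_plasma_pk(50, sample(c("free_dox", "thermodox"), 1), p,
                            T_vessel = function(t) 37 + 5 * (t < 1800),
                            duration = 3 * 3600)
    expect_gte(min(as.matrix(s[, -1])), -1e-12)
  }
})
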
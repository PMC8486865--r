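# Independent oracle for the transvascular flux: integrate the 1-D membrane
# convection-diffusion problem numerically (shooting on the constant flux N)
# and scale by the vascular surface density.
membrane_flux_oracle <- function(C_v, C_i, phi_v, P, sigma_f, sv) {
  L <- 1e-6                       # wall thickness (arbitrary; P = D/L)
  D <- P * L
  v <- phi_v * (1 - sigma_f) / sv # fluid velocity through the wall
  shoot <- function(N) {
    sol <- deSolve::ode(c(C = C_v), seq(0, L, length.out = 5),
                        function(x, y, par) list((v * y[1] - N) / D),
                        NULL, rtol = 1e-12, atol = 1e-14)
    unname(sol[nrow(sol), "C"]) - C_i
  }
  scale <- max(abs(c(C_v, C_i, 1e-6)))
  N <- uniroot(shoot, interval = c(-1e3 * scale, 1e3 * scale),
               tol = 1e-15 * scale)$root
  sv * N
}

test_that("the Patlak flux matches the membrane-transport oracle", {
  set.seed(11)
  for (i in 1:8) {
    C_v <- runif(1, 0, 1)
    C_i <- runif(1, 0, 1)
    P <- 10^runif(1, -8, -6)
    sv <- 2e4
    sigma_f <- runif(1, 0, 0.9)
    # keep the wall Peclet number in a numerically honest range
    phi_v <- runif(1, 0, 10) * P * sv / (1 - sigma_f)
    J <- transvascular_flux(C_v, C_i, phi_v, P, sigma_f, sv)
    J_or <- membrane_flux_oracle(C_v, C_i, phi_v, P, sigma_f, sv)
    expect_equal(J, J_or, tolerance = 1e-6)
  }
})

test_that("the Patlak flux has the correct degenerate limits", {
  # no filtration: pure diffusion
  expect_equal(transvascular_flux(2, 0.5, 0, 1e-7, 0.1, 2e4),
               1e-7 * 2e4 * 1.5)
  # equal concentrations and no filtration: no flux
  expect_equal(transvascular_flux(1, 1, 0, 1e-7, 0.1, 2e4), 0)
  # continuity across Pe -> 0 (series expansion branch)
  sv <- 2e4; P <- 1e-7
  J_small <- transvascular_flux(1, 0, 1e-15, P, 0.1, sv)
  expect_equal(J_small, P * sv, tolerance = 1e-6)
})

test_that("hyperthermia scales the vessel wall but caps the sieving factor", {
  # permeability doubled at 43 degC
  J37 <- transvascular_flux(1, 0, 0, 1e-7, 0.1, 2e4, T_local = 37)
  J43 <- transvascular_flux(1, 0, 0, 1e-7, 0.1, 2e4, T_local = 43)
  expect_equal(J43 / J37, 2)
  # convective sieving (1 - sigma) never exceeds 1
  Jconv <- transvascular_flux(1, 0, 1e-4, 0, 0.1, 2e4, T_local = 43)
  expect_equal(Jconv, 1e-4 * 1)
})

test_that("cellular exchange conserves drug and honors its balance point", {
  p <- default_params()
  xi <- p$transport$xi; eps <- p$transport$eps
  # balance: C_F = C_int * eps / xi leaves both pools unchanged
  st <- cellular_exchange(0.5 * eps / xi, 0.5, dt = 1000)
  expect_equal(st$C_F, 0.5 * eps / xi, tolerance = 1e-12)
  expect_equal(st$C_int, 0.5, tolerance = 1e-12)
  # conservation
  st2 <- cellular_exchange(0.8, 0.1, dt = 123)
  expect_equal(st2$C_F + st2$C_int, 0.9)
  # initial uptake slope is 2.4-fold faster at 42.6 degC
  dt <- 1e-3
  up37 <- cellular_exchange(1, 0, dt, T_local = 37)$C_int
  up426 <- cellular_exchange(1, 0, dt, T_local = 42.6)$C_int
  expect_equal(up426 / up37, 2.4, tolerance = 1e-4)
})

test_that("the transport march conserves a uniform field with all sources off", {
  p <- default_params()
  p$pk$k_leak <- 0; p$pk$k_burst <- 0
  p$transport$lambda_lymph <- 0
  g <- build_domain(p)
  # damage 0 disables every Starling source and flattens the pressure field
  flow <- solve_interstitial_flow(g$domain, g$zones, p,
                                  damage = rep(0, g$domain$n))
  ser <- data.frame(time = c(0, 7200), T_sys = 0, F_sys = 0, B_sys = 0,
                    T_ves = 0, F_ves = 0, B_ves = 0)
  run <- solve_cdr(g$domain, g$zones, flow, ser, p, duration = 3600,
                   output_dt = 600)
  # start from a uniform interstitial field
  n <- g$domain$n
  run2 <- doxtherm:::cdr_march(g$domain, g$zones, flow, p, 3600,
                               pkspec = list(mode = "prescribed", series = ser),
                               state0 = list(CF = rep(0.3, n), CB = rep(0.1, n),
                                             CT = rep(0.2, n),
                                             Cint = rep(0, n), N = rep(1, n)),
                               output_dt = 600)
  tot0 <- 0.3 + 0.1 + 0.2
  totT <- run2$final$CF + run2$final$CB + run2$final$CT + run2$final$Cint
  expect_lt(max(abs(totT - tot0)) / tot0, 1e-10)
})

test_that("a prescribed vessel history drives tumor-interstitial accumulation", {
  p <- default_params()
  g <- build_domain(p)
  flow <- solve_interstitial_flow(g$domain, g$zones, p)
  tt <- seq(0, 7200, by = 600)
  ser <- data.frame(time = tt, T_sys = 0, F_sys = 0.002, B_sys = 0,
                    T_ves = 0, F_ves = 0.002, B_ves = 0)
  run <- solve_cdr(g$domain, g$zones, flow, ser, p, duration = 7200,
                   output_dt = 600)
  # free drug accumulates fastest where the vasculature is densest
  cf <- run$final$CF
  z <- g$zones$zone
  expect_gt(mean(cf[z == "proliferative"]), mean(cf[z == "quiescent"]))
  expect_gt(mean(cf[z == "quiescent"]), mean(cf[z == "hypoxic"]))
  expect_true(all(cf >= 0))
})
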
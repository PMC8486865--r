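#' Volumetric heat source of magnetic nanoparticles under AMF
#'
#' Linear-response (Rosensweig) dissipation of single-domain maghemite
#' particles in an alternating magnetic field:
#' \deqn{P = \pi \mu_0 \chi''(f) f H^2,\qquad
#'       \chi'' = \chi_0 \frac{\omega\tau}{1 + (\omega\tau)^2},}
#' with the Langevin initial susceptibility
#' \eqn{\chi_0 = \mu_0 \phi M_s^2 V_c / (3 k_B T)} and the effective
#' relaxation time combining Neel and Brownian mechanisms in parallel,
#' \eqn{\tau = \tau_N\tau_B/(\tau_N+\tau_B)}. The particle clusters are
#' pre-accumulated uniformly over the tumor, so the returned field is the
#' single-particle dissipation scaled by the local volume fraction (zero in
#' normal tissue).
#'
#' @param domain From [build_domain()].
#' @param params Parameter list; `params$mnp` and `params$amf` are used.
#' @param volume_fraction Optional override of the tumor MNP volume fraction.
#' @return List with `Q` (W/m^3 per node), `P_unit` (W/m^3 at volume fraction
#'   1), and the relaxation diagnostics `tau_N`, `tau_B`, `tau`.
#' @export
mnp_volumetric_power <- function(domain, params = default_params(),
                                 volume_fraction = NULL) {
  mp <- params$mnp
  amf <- params$amf
  if (mp$core_diameter <= 0) stop("MNP core diameter must be positive", call. = FALSE)
  phi <- volume_fraction %||% mp$volume_fraction
  kB <- 1.380649e-23
  mu0 <- 4e-7 * pi
  T_K <- 273.15 + 37
  V_c <- pi / 6 * mp$core_diameter^3
  d_h <- mp$core_diameter + 2 * mp$shell_thickness
  V_h <- pi / 6 * d_h^3
  tau_N <- mp$tau0 * exp(mp$anisotropy_constant * V_c / (kB * T_K))
  tau_B <- 3 * mp$viscosity * V_h / (kB * T_K)
  tau <- tau_N * tau_B / (tau_N + tau_B)
  omega <- 2 * pi * amf$f
  chi0_unit <- mu0 * mp$saturation_magnetization^2 * V_c / (3 * kB * T_K)
  chi2_unit <- chi0_unit * omega * tau / (1 + (omega * tau)^2)
  P_unit <- pi * mu0 * chi2_unit * amf$f * amf$H^2
  Q <- ifelse(domain$in_tumor, phi * P_unit, 0)
  list(Q = Q, P_unit = P_unit, tau_N = tau_N, tau_B = tau_B, tau = tau,
       volume_fraction = phi)
}

#' Transient Pennes bioheat solver on the radial domain
#'
#' Integrates
#' \deqn{\rho c \,\partial T/\partial t = \nabla\cdot(k\nabla T)
#'   + \omega_b \rho_b c_b (T_a - T) + Q_{met} + Q}
#' with a fully implicit (unconditionally stable) Euler step, a fixed
#' temperature `T_a` at the outer boundary, and regularity at r = 0.
#' Perfusion is the zone perfusion optionally scaled node-wise by an
#' ablation damage factor, the single perfusion truth source shared with the
#' drug-transport model.
#'
#' @param domain,zones From [build_domain()].
#' @param params Parameter list (`params$bioheat`).
#' @param source Volumetric heat source per node (W/m^3), e.g.
#'   `mnp_volumetric_power(...)$Q`; a scalar is recycled. May also be a list
#'   of such fields, which are summed.
#' @param duration Total integration time (s).
#' @param dt Time step (s).
#' @param T0 Initial temperature field (degC), default uniform `T_a`.
#' @param output_dt Interval between stored snapshots (s).
#' @param damage Optional perfusion damage factor per node in `[0, 1]`.
#' @return Object of class `temperature_field`: `times`, matrix `T`
#'   (nodes x snapshots), `T_max` (overall maximum), `T_peak_t` (running
#'   spatial maximum per snapshot), and `energy_residual` (relative
#'   discrete energy-balance error).
#' @export
solve_bioheat <- function(domain, zones, params = default_params(),
                          source = 0, duration = 3600, dt = 1,
                          T0 = NULL, output_dt = 60, damage = NULL) {
  bh <- params$bioheat
  n <- domain$n
  if (is.list(source)) source <- Reduce(`+`, source)
  if (length(source) == 1L) source <- rep(source, n)
  stopifnot(length(source) == n)
  if (is.null(damage)) damage <- rep(1, n)
  perf <- zones$perfusion * damage
  rc <- bh$rho * bh$c
  sink <- perf * bh$rho_b * bh$c_b          # W/(m^3 K)

  L <- sph_diffusion_matrix(domain$r, bh$k, bc_outer = "dirichlet")
  M <- L / rc - diag(sink / rc, n)
  A <- diag(n) - dt * M
  A[n, ] <- 0
  A[n, n] <- 1
  Ainv <- solve(A)
  q <- (source + sink * bh$T_a + bh$Q_met) / rc

  T <- if (is.null(T0)) rep(bh$T_a, n) else T0
  nsteps <- ceiling(duration / dt)
  keep <- unique(c(0, seq(0, nsteps, by = max(1L, round(output_dt / dt))), nsteps))
  keep <- sort(keep)
  out_T <- matrix(NA_real_, n, length(keep))
  out_t <- keep * dt
  ik <- 1L
  if (keep[1L] == 0) {
    out_T[, 1L] <- T
    ik <- 2L
  }
  T_max <- max(T)
  e_num <- 0; e_den <- 0
  vol <- domain$vol
  interior <- seq_len(n - 1L)
  for (m in seq_len(nsteps)) {
    rhs <- T + dt * q
    rhs[n] <- bh$T_a
    T_new <- as.numeric(Ainv %*% rhs)
    if (any(!is.finite(T_new))) {
      stop("bioheat solver produced non-finite temperatures", call. = FALSE)
    }
    # discrete energy audit over interior nodes (boundary row is Dirichlet)
    lhs_e <- sum(rc * (T_new[interior] - T[interior]) * vol[interior])
    rhs_e <- dt * sum(((L %*% T_new)[interior] +
                         (sink * (bh$T_a - T_new) + source + bh$Q_met)[interior]) *
                        vol[interior])
    e_num <- e_num + (lhs_e - rhs_e)
    e_den <- e_den + abs(rhs_e)
    T <- T_new
    T_max <- max(T_max, max(T))
    if (ik <= length(keep) && m == keep[ik]) {
      out_T[, ik] <- T
      ik <- ik + 1L
    }
  }
  structure(list(times = out_t, T = out_T, T_max = T_max,
                 T_peak_t = apply(out_T, 2, max),
                 energy_residual = if (e_den > 0) e_num / e_den else 0,
                 r = domain$r),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat("temperature_field:", ncol(x$T), "snapshots over",
      format(max(x$times)), "s; peak", format(x$T_max, digits = 4), "degC\n")
  invisible(x)
}

#' Calibrate the MNP volume fraction to a target peak temperature
#'
#' The Pennes problem is linear in the heat source, so the temperature rise
#' above baseline scales exactly with the MNP volume fraction. A single
#' reference solve therefore determines the volume fraction whose 1-h AMF
#' exposure peaks at the target temperature (default 42.6 degC).
#'
#' @param params Parameter list.
#' @param target Target spatial-temporal peak temperature (degC).
#' @param phi_ref Reference volume fraction for the probe solve.
#' @param dt Bioheat time step (s).
#' @return The calibrated volume fraction (scalar).
#' @export
calibrate_mnp_volume_fraction <- function(params = default_params(),
                                          target = 42.6, phi_ref = 1e-4,
                                          dt = 2) {
  g <- build_domain(params)
  src <- mnp_volumetric_power(g$domain, params, volume_fraction = phi_ref)
  tf <- solve_bioheat(g$domain, g$zones, params, source = src$Q,
                      duration = params$amf$duration, dt = dt)
  rise <- tf$T_max - params$bioheat$T_a
  if (rise <= 0) stop("reference solve produced no heating", call. = FALSE)
  phi_ref * (target - params$bioheat$T_a) / rise
}
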
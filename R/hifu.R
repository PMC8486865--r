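# Focused-ultrasound field, heating, CEM43 dose and ablation zoning.

#' Acoustic field of a focused bowl transducer
#'
#' Evaluates the linear lossy acoustic field of a single-element spherically
#' curved radiator by direct Rayleigh integration over the bowl surface with
#' a complex wavenumber (absorption linear in frequency). The field is
#' computed on an axisymmetric (z, r) grid centred on the geometric focus.
#' The source velocity amplitude is set from the acoustic power and the bowl
#' area. On axis the integral reproduces the O'Neil closed form.
#'
#' The bowl-surface quadrature must resolve the phase: the arc spacing is
#' required to be at most one sixth of a wavelength, otherwise the function
#' refuses with the minimum usable quadrature size.
#'
#' @param params Parameter list; `params$hifu` is used.
#' @return Object of class `acoustic_field`: axial coordinates `z` (m, from
#'   the transducer), lateral `r`, matrices `p_amp` (Pa), `intensity`
#'   (W/m^2) and `Q` (W/m^3, equal to `2 alpha I`), plus `focus`,
#'   `wavelength` and the grid spacings.
#' @export
compute_acoustic_field <- function(params = default_params()) {
  hf <- params$hifu
  if (hf$acoustic_power < 0) stop("acoustic power must be >= 0", call. = FALSE)
  if (hf$focal_length <= hf$aperture_radius / 2) {
    stop("focal length must exceed half the aperture radius", call. = FALSE)
  }
  a <- hf$aperture_radius
  F0 <- hf$focal_length
  f <- hf$frequency
  lambda <- hf$c / f
  k0 <- 2 * pi / lambda
  alpha <- hf$attenuation_np_m_mhz * f / 1e6     # Np/m
  kc <- complex(real = k0, imaginary = alpha)

  theta_max <- asin(a / F0)
  arc <- F0 * theta_max
  n_theta_min <- ceiling(6 * arc / lambda)
  if (hf$n_theta < n_theta_min) {
    stop("bowl quadrature too coarse for the wavelength: need n_theta >= ",
         n_theta_min, call. = FALSE)
  }
  h <- F0 * (1 - cos(theta_max))                  # bowl depth
  S <- 2 * pi * F0 * h                            # curved bowl area
  u0 <- sqrt(2 * hf$acoustic_power / (hf$rho * hf$c * S))

  # midpoint quadrature over the bowl surface (azimuthal half-range, x2)
  th <- (seq_len(hf$n_theta) - 0.5) * theta_max / hf$n_theta
  ph <- (seq_len(hf$n_phi) - 0.5) * pi / hf$n_phi
  dth <- theta_max / hf$n_theta
  dph <- pi / hf$n_phi
  rho_s <- F0 * sin(th)
  z_s <- F0 * (1 - cos(th))
  w <- 2 * F0^2 * sin(th) * dth * dph             # dS weights per (theta, phi)
  sp <- list(
    rho = rep(rho_s, times = hf$n_phi),
    z = rep(z_s, times = hf$n_phi),
    cphi = rep(cos(ph), each = hf$n_theta),
    w = rep(w, times = hf$n_phi))

  z <- seq(F0 - hf$box_z / 2, F0 + hf$box_z / 2, by = hf$dz)
  r <- seq(0, hf$box_r, by = hf$dr)
  nz <- length(z)
  nr <- length(r)
  pamp <- matrix(0, nz, nr)
  pref <- -1i * hf$rho * hf$c * kc * u0 / (2 * pi)
  if (hf$acoustic_power > 0) {
    rho2 <- sp$rho^2
    for (iz in seq_len(nz)) {
      dz2 <- (z[iz] - sp$z)^2
      # distances field-point x surface-point for the whole lateral row
      R2 <- outer(r^2, dz2 + rho2, "+") -
        2 * outer(r, sp$rho * sp$cphi, "*")
      R <- sqrt(R2)
      pamp[iz, ] <- Mod(pref * as.vector((exp(1i * kc * R) / R) %*% sp$w))
    }
  }
  intensity <- pamp^2 / (2 * hf$rho * hf$c)
  structure(list(z = z, r = r, p_amp = pamp, intensity = intensity,
                 Q = 2 * alpha * intensity, focus = F0, wavelength = lambda,
                 dz = hf$dz, dr = hf$dr, alpha = alpha, u0 = u0,
                 aperture_radius = a),
            class = "acoustic_field")
}

#' @export
print.acoustic_field <- function(x, ...) {
  cat("acoustic_field:", length(x$z), "x", length(x$r), "grid; peak |p|",
      format(max(x$p_amp) / 1e6, digits = 3), "MPa; peak Q",
      format(max(x$Q), digits = 3), "W/m^3\n")
  invisible(x)
}

# Perfusion (1/s) at a distance `d` from the tumor center, using the same
# zone rules as build_domain (the focus sits at the tumor center).
perfusion_at_distance <- function(d, params) {
  zp <- params$zones
  R <- params$geometry$tumor_radius
  out <- rep(zp$perfusion[["normal"]], length(d))
  out[d <= R] <- zp$perfusion[["proliferative"]]
  out[d <= zp$quiescent_fraction * R] <- zp$perfusion[["quiescent"]]
  out[d <= zp$hypoxic_fraction * R] <- zp$perfusion[["hypoxic"]]
  out
}

#' Axisymmetric bioheat solve for a sonication
#'
#' Explicit finite-difference integration of the Pennes equation on the
#' acoustic (z, r) grid during sonication and a cool-down period. The time
#' step must satisfy the diffusive stability limit; the temperature history
#' is stored every `store_dt` seconds (dense enough for thermal dosimetry)
#' and the per-node running peak temperature is tracked at every step.
#'
#' @param ac An `acoustic_field` from [compute_acoustic_field()].
#' @param params Parameter list.
#' @param duration Sonication duration (s); default from `params$hifu`.
#' @param cool_down Additional unheated time to integrate (s).
#' @param dt Time step (s); default from `params$hifu`.
#' @param store_dt Snapshot interval (s), at most 0.5 s.
#' @return Object of class `axisym_temperature`: `times`, `T` (node-major
#'   matrix, `nz*nr` rows), `peak_T` per node, grid vectors `z`, `r`, and
#'   `focus`.
#' @export
solve_bioheat_axisym <- function(ac, params = default_params(),
                                 duration = NULL, cool_down = NULL,
                                 dt = NULL, store_dt = 0.5) {
  hf <- params$hifu
  bh <- params$bioheat
  duration <- duration %||% hf$duration
  cool_down <- cool_down %||% hf$cool_down
  dt <- dt %||% hf$dt
  store_dt <- min(store_dt, 0.5)
  z <- ac$z; r <- ac$r
  nz <- length(z); nr <- length(r)
  dz <- ac$dz; drr <- ac$dr
  alpha_th <- bh$k / (bh$rho * bh$c)
  dt_max <- 1 / (2 * alpha_th * (1 / dz^2 + 1 / drr^2))
  if (dt > dt_max) {
    stop("time step ", dt, " s violates the diffusive stability limit (",
         signif(dt_max, 3), " s); reduce params$hifu$dt", call. = FALSE)
  }
  dist <- sqrt(outer((z - ac$focus)^2, r^2, "+"))
  sink <- perfusion_at_distance(dist, params) * bh$rho_b * bh$c_b
  dim(sink) <- c(nz, nr)
  rc <- bh$rho * bh$c

  Tfld <- matrix(bh$T_a, nz, nr)
  peak <- Tfld
  n_heat <- round(duration / dt)
  n_tot <- n_heat + round(cool_down / dt)
  every <- max(1L, round(store_dt / dt))
  kept <- seq(0L, n_tot, by = every)
  out <- matrix(NA_real_, nz * nr, length(kept))
  out[, 1L] <- as.vector(Tfld)
  times <- kept * dt
  ik <- 2L
  rp <- r + drr / 2
  rm <- pmax(r - drr / 2, 0)
  for (m in seq_len(n_tot)) {
    lap_z <- matrix(0, nz, nr)
    lap_z[2:(nz - 1), ] <- (Tfld[3:nz, ] - 2 * Tfld[2:(nz - 1), ] +
                              Tfld[1:(nz - 2), ]) / dz^2
    lap_r <- matrix(0, nz, nr)
    lap_r[, 2:(nr - 1)] <- (sweep(Tfld[, 3:nr] - Tfld[, 2:(nr - 1)], 2,
                                  rp[2:(nr - 1)], "*") -
                            sweep(Tfld[, 2:(nr - 1)] - Tfld[, 1:(nr - 2)], 2,
                                  rm[2:(nr - 1)], "*")) /
      matrix(r[2:(nr - 1)] * drr^2, nz, nr - 2, byrow = TRUE)
    lap_r[, 1] <- 4 * (Tfld[, 2] - Tfld[, 1]) / drr^2
    Q <- if (m <= n_heat) ac$Q else 0
    Tfld <- Tfld + dt * (alpha_th * (lap_z + lap_r) +
                           (sink * (bh$T_a - Tfld) + Q) / rc)
    # Dirichlet far-field edges
    Tfld[1, ] <- bh$T_a; Tfld[nz, ] <- bh$T_a; Tfld[, nr] <- bh$T_a
    if (any(!is.finite(Tfld))) {
      stop("axisymmetric bioheat solve became unstable", call. = FALSE)
    }
    peak <- pmax(peak, Tfld)
    if (ik <= length(kept) && m == kept[ik]) {
      out[, ik] <- as.vector(Tfld)
      ik <- ik + 1L
    }
  }
  structure(list(times = times, T = out, peak_T = as.vector(peak),
                 z = z, r = r, focus = ac$focus, dz = dz, dr = drr),
            class = "axisym_temperature")
}

#' Cumulative equivalent minutes at 43 degC (CEM43)
#'
#' Sapareto-Dewey thermal dose,
#' \eqn{CEM43 = \sum R^{43 - T}\,\Delta t} (minutes), with R = 0.5 for
#' T >= 43 degC and R = 0.25 below.
#'
#' @param times Sample times (s).
#' @param T Temperature history: matrix nodes x length(times) (a vector is
#'   treated as a single node).
#' @return CEM43 per node, in equivalent minutes at 43 degC.
#' @export
#' @examples
#' compute_thermal_dose(c(0, 600), matrix(43, 1, 2))  # 10 min
compute_thermal_dose <- function(times, T) {
  if (is.null(dim(T))) T <- matrix(T, nrow = 1L)
  stopifnot(ncol(T) == length(times))
  dt_min <- diff(times) / 60
  Rf <- ifelse(T >= 43, 0.5, 0.25)
  contrib <- Rf^(43 - T)
  # left-endpoint sum over intervals
  as.numeric(contrib[, -ncol(contrib), drop = FALSE] %*% dt_min)
}

#' Classify ablation zones from thermal dose and peak temperature
#'
#' Nodes with CEM43 of at least 240 min form the coagulative-necrosis core
#' (alpha); nodes with at least 30 min of dose, or a peak temperature of
#' 45 degC or more, are sublethal (beta); nodes whose peak temperature
#' reached the 43-45 degC band without a damaging dose are the
#' vessel-vulnerable but cell-viable periphery (gamma); everything else is
#' unaffected.
#'
#' @param dose CEM43 per node (min), from [compute_thermal_dose()].
#' @param peak_T Peak temperature per node (degC) from the same run.
#' @return Factor per node with levels `alpha`, `beta`, `gamma`, `none`
#'   (class `ablation_zones`).
#' @export
classify_ablation_zones <- function(dose, peak_T) {
  stopifnot(length(dose) == length(peak_T))
  zone <- rep("none", length(dose))
  zone[peak_T >= 43 & peak_T < 45] <- "gamma"
  zone[dose >= 30 | peak_T >= 45] <- "beta"
  zone[dose >= 240] <- "alpha"
  structure(factor(zone, levels = c("alpha", "beta", "gamma", "none")),
            class = c("ablation_zones", "factor"))
}

#' Perfusion damage factors from ablation zones
#'
#' Fraction of baseline perfusion retained per node: 0 in the necrotic core
#' (alpha), 0.2 in the sublethal ring (beta, below the 25% ceiling), 0.5 in
#' the vulnerable-vessel periphery (gamma) and 1 elsewhere.
#'
#' @param zones An `ablation_zones` factor.
#' @return Numeric damage factor per node in `[0, 1]`.
#' @export
build_perfusion_damage <- function(zones) {
  c(alpha = 0, beta = 0.2, gamma = 0.5, none = 1)[as.character(zones)]
}

#' Volume-equivalent spherical radii of the ablation zones
#'
#' Integrates the axisymmetric cell volumes of the (cumulative) alpha,
#' alpha+beta and alpha+beta+gamma regions and converts each to the radius
#' of the sphere of equal volume, centred on the focus. These radii map the
#' 2D lesion onto the 1D radial treatment grid.
#'
#' @param zones `ablation_zones` on the axisymmetric grid.
#' @param tf The `axisym_temperature` (for the grid).
#' @return Named vector `c(alpha=, beta=, gamma=)` of radii (m).
#' @export
ablation_zone_radii <- function(zones, tf) {
  nz <- length(tf$z); nr <- length(tf$r)
  rw <- ifelse(tf$r == 0, pi * (tf$dr / 2)^2, 2 * pi * tf$r * tf$dr) * tf$dz
  cellv <- matrix(rw, nz, nr, byrow = TRUE)
  zv <- as.character(zones)
  v_a <- sum(cellv[zv == "alpha"])
  v_b <- v_a + sum(cellv[zv == "beta"])
  v_g <- v_b + sum(cellv[zv == "gamma"])
  r_eq <- function(v) (3 * v / (4 * pi))^(1 / 3)
  c(alpha = r_eq(v_a), beta = r_eq(v_b), gamma = r_eq(v_g))
}

# Damage factors on the 1D radial grid from zone-equivalent radii.
radial_damage_from_radii <- function(radii, domain) {
  d <- rep(1, domain$n)
  d[domain$r <= radii[["gamma"]]] <- 0.5
  d[domain$r <= radii[["beta"]]] <- 0.2
  d[domain$r <= radii[["alpha"]]] <- 0
  d
}
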
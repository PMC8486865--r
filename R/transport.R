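# Interstitial convection-diffusion-reaction transport of liposomal, free
# and bound drug, coupled to the plasma pharmacokinetics.

#' Transvascular solute flux (Patlak form)
#'
#' Combined diffusive-convective flux across the vessel wall per unit
#' tissue volume,
#' \deqn{J = P\,(S/V)\,f_p(T)\,(C_v - C_i)\,\frac{Pe}{e^{Pe}-1}
#'       + \phi_v (1-\sigma_f)_{\rm eff} C_v,}
#' with the Peclet number \eqn{Pe = \phi_v (1-\sigma_f)_{\rm eff} /
#' (P\,(S/V)\,f_p(T))}. The permeability fold-change \eqn{f_p(T)} scales
#' both the diffusive permeability and the convective sieving factor
#' \eqn{(1-\sigma_f)} (capped at 1), consistent with a thermally enlarged
#' pore size. The Pe -> 0 limit reduces to pure diffusion and is evaluated
#' by series expansion.
#'
#' @param C_vessel,C_interstitial Concentrations (kg/m^3), vectorized.
#' @param phi_v Transvascular fluid source (1/s).
#' @param P Vascular permeability (m/s).
#' @param sigma_f Filtration reflection coefficient.
#' @param sv Vascular surface density S/V (1/m).
#' @param T_local Temperature (degC), default baseline.
#' @param params Parameter list.
#' @return Flux in kg/(m^3 s) (positive into the interstitium).
#' @export
transvascular_flux <- function(C_vessel, C_interstitial, phi_v, P, sigma_f,
                               sv, T_local = 37, params = default_params()) {
  pm <- permeability_multiplier(T_local, params)
  sieve <- pmin((1 - sigma_f) * pm, 1)
  PS <- P * sv * pm
  conv <- phi_v * sieve
  pe <- ifelse(PS > 0, conv / PS, 0)
  diff_term <- ifelse(PS > 0, PS * (C_vessel - C_interstitial) * peclet_factor(pe), 0)
  diff_term + conv * C_vessel
}

#' Cellular uptake/efflux exchange step
#'
#' Advances the free extracellular / intracellular pair under
#' \eqn{dC_{int}/dt = f_m(T)(\xi C_F - \varepsilon C_{int})} (and the
#' opposite sign for \eqn{C_F}) by the exact exponential solution of the
#' exchange; the transmembrane fold-change \eqn{f_m(T)} scales uptake and
#' efflux alike. The pair sum is conserved by this step.
#'
#' @param C_F Free extracellular concentration (kg/m^3), vectorized.
#' @param C_int Intracellular concentration (kg/m^3).
#' @param dt Time step (s).
#' @param T_local Temperature (degC).
#' @param params Parameter list (`params$transport$xi`, `$eps`).
#' @return List with updated `C_F` and `C_int`.
#' @export
cellular_exchange <- function(C_F, C_int, dt, T_local = 37,
                              params = default_params()) {
  tr <- params$transport
  tm <- transmembrane_multiplier(T_local, params)
  rate <- tm * (tr$xi + tr$eps)
  tot <- C_F + C_int
  eqF <- tr$eps / (tr$xi + tr$eps) * tot
  Fn <- eqF + (C_F - eqF) * exp(-rate * dt)
  list(C_F = Fn, C_int = tot - Fn)
}

# --- temperature schedule helpers -------------------------------------------

# A temperature schedule is NULL (uniform baseline) or list(times, T) with T a
# nodes x length(times) matrix; outside the covered range the baseline holds.
temp_at <- function(sched, t, n, baseline = 37) {
  if (is.null(sched)) return(rep(baseline, n))
  tt <- sched$times
  if (t <= tt[1L]) return(sched$T[, 1L])
  nt <- length(tt)
  if (t >= tt[nt]) return(sched$T[, nt])
  j <- findInterval(t, tt)
  w <- (t - tt[j]) / (tt[j + 1L] - tt[j])
  sched$T[, j] * (1 - w) + sched$T[, j + 1L] * w
}

# --- the coupled march -------------------------------------------------------

# Advances plasma PK (live or prescribed), interstitial transport of T/F/B,
# intracellular drug and cell survival from t = 0 to `duration`.
#
# pkspec: list(mode = "live", y0 = numeric(6)) or
#         list(mode = "prescribed", series = data.frame from simulate_plasma_pk)
cdr_march <- function(domain, zones, flow, params, duration,
                      Tsched = NULL, pkspec, state0 = NULL,
                      heating_interval = NULL, output_dt = 60,
                      snapshot_dt = 900, merged_vessel = FALSE) {
  tr <- params$transport
  pk <- params$pk
  pd <- params$pd
  n <- domain$n
  r <- domain$r
  vol <- domain$vol
  tum <- domain$in_tumor
  nrm <- !tum
  baseT <- params$bioheat$T_a

  V_Tp <- pk$V_ratio * pk$V_Sp
  P_F <- ifelse(tum, tr$P_F[["tumor"]], tr$P_F[["normal"]])
  P_T <- ifelse(tum, tr$P_T[["tumor"]], tr$P_T[["normal"]])
  sg_F <- ifelse(tum, tr$sigma_f_F[["tumor"]], tr$sigma_f_F[["normal"]])
  sg_T <- ifelse(tum, tr$sigma_f_T[["tumor"]], tr$sigma_f_T[["normal"]])
  sv <- zones$sv * flow$damage
  phi_v <- flow$phi_v
  phi_L <- flow$phi_L

  # time grid: fine steps while any heating is active, coarse otherwise
  dt_h <- params$protocol$dt_heating
  dt_b <- params$protocol$dt_base
  if (!is.null(heating_interval)) {
    h0 <- heating_interval[1L]
    h1 <- min(heating_interval[2L] + 600, duration)  # include cool-down
    tgrid <- unique(c(seq(0, max(h0, 0), by = dt_b),
                      seq(max(h0, 0), h1, by = dt_h),
                      seq(h1, duration, by = dt_b), duration))
  } else {
    tgrid <- unique(c(seq(0, duration, by = dt_b), duration))
  }
  tgrid <- sort(tgrid)

  # implicit diffusion factorizations per species and step size
  Ld <- list(F = sph_diffusion_matrix(r, tr$D_F, "neumann"),
             B = sph_diffusion_matrix(r, tr$D_B, "neumann"),
             T = sph_diffusion_matrix(r, tr$D_T, "neumann"))
  dts <- sort(unique(round(diff(tgrid), 10)))
  Ainv <- lapply(dts, function(dt) {
    lapply(Ld, function(L) solve(diag(n) - dt * L))
  })

  # state
  if (is.null(state0)) {
    state0 <- list(CF = numeric(n), CB = numeric(n), CT = numeric(n),
                   Cint = numeric(n), N = rep(1, n))
  }
  CF <- state0$CF; CB <- state0$CB; CT <- state0$CT
  Cint <- state0$Cint; N <- state0$N
  live <- identical(pkspec$mode, "live")
  if (live) {
    y <- pkspec$y0
  } else {
    ser <- pkspec$series
    pk_interp <- function(t) {
      j <- findInterval(t, ser$time, all.inside = TRUE)
      w <- (t - ser$time[j]) / (ser$time[j + 1L] - ser$time[j])
      w <- min(max(w, 0), 1)
      as.numeric((1 - w) * ser[j, -1L] + w * ser[j + 1L, -1L])
    }
    y <- pk_interp(0)
  }
  injected <- if (live) pk$V_Sp * sum(y[1:3]) + V_Tp * sum(y[4:6]) else NA_real_

  cleared <- 0; endo <- 0; lymph_removed <- 0; boundary_out <- 0

  out_times <- seq(0, duration, by = output_dt)
  rec <- matrix(NA_real_, length(out_times), 13)
  colnames(rec) <- c("time", "T_sys", "F_sys", "B_sys", "T_ves", "F_ves",
                     "B_ves", "CF_ecm", "CB_ecm", "CT_ecm", "C_int", "N",
                     "mass_error")
  snap_times <- seq(0, duration, by = snapshot_dt)
  snaps <- list(CF = matrix(NA_real_, n, length(snap_times)),
                Cint = matrix(NA_real_, n, length(snap_times)),
                CT = matrix(NA_real_, n, length(snap_times)),
                N = matrix(NA_real_, n, length(snap_times)))
  tum_avg <- function(x) volume_average(x, vol, tum)

  record <- function(i, t) {
    mass_err <- if (live && injected > 0) {
      total <- pk$V_Sp * sum(y[1:3]) + V_Tp * sum(y[4:6]) +
        sum((CF + CB + CT + Cint) * vol) + cleared + endo +
        lymph_removed + boundary_out
      (total - injected) / injected
    } else NA_real_
    rec[i, ] <<- c(t, y, tum_avg(CF), tum_avg(CB), tum_avg(CT),
                   tum_avg(Cint), tum_avg(N), mass_err)
  }
  record(1L, 0)
  isnap <- 1L
  snaps$CF[, 1L] <- CF; snaps$Cint[, 1L] <- Cint
  snaps$CT[, 1L] <- CT; snaps$N[, 1L] <- N
  iout <- 2L; isnap <- 2L

  for (m in seq_len(length(tgrid) - 1L)) {
    t0 <- tgrid[m]; t1 <- tgrid[m + 1L]
    dt <- t1 - t0
    Tloc <- temp_at(Tsched, (t0 + t1) / 2, n, baseT)
    T_ves <- volume_average(Tloc, vol, tum)
    pmv <- permeability_multiplier(Tloc, params)
    krel_loc <- thermodox_release_rate(Tloc, params)

    # per-node transvascular coefficients: J = a * C_vessel - b * C_i
    sieve_F <- pmin((1 - sg_F) * pmv, 1)
    sieve_T <- pmin((1 - sg_T) * pmv, 1)
    PS_F <- P_F * sv * pmv
    PS_T <- P_T * sv * pmv
    conv_F <- phi_v * sieve_F
    conv_T <- phi_v * sieve_T
    b_F <- ifelse(PS_F > 0, PS_F * peclet_factor(ifelse(PS_F > 0, conv_F / PS_F, 0)), 0)
    b_T <- ifelse(PS_T > 0, PS_T * peclet_factor(ifelse(PS_T > 0, conv_T / PS_T, 0)), 0)
    a_F <- b_F + conv_F
    a_T <- b_T + conv_T

    # aggregated exchange coefficients for the plasma ODE (per plasma volume).
    # With a merged vessel compartment (free-drug protocols: systemic and
    # tumor-microvessel plasma treated as one pool) the tumor wall drains
    # systemic plasma directly.
    if (merged_vessel) {
      LF_t <- 0; ST_F <- 0; LT_t <- 0; ST_T <- 0
      LF_n <- sum(a_F * vol) / pk$V_Sp
      SN_F <- sum(b_F * CF * vol) / pk$V_Sp
      LT_n <- sum(a_T * vol) / pk$V_Sp
      SN_T <- sum(b_T * CT * vol) / pk$V_Sp
    } else {
      LF_t <- sum(a_F[tum] * vol[tum]) / V_Tp
      ST_F <- sum(b_F[tum] * CF[tum] * vol[tum]) / V_Tp
      LT_t <- sum(a_T[tum] * vol[tum]) / V_Tp
      ST_T <- sum(b_T[tum] * CT[tum] * vol[tum]) / V_Tp
      LF_n <- sum(a_F[nrm] * vol[nrm]) / pk$V_Sp
      SN_F <- sum(b_F[nrm] * CF[nrm] * vol[nrm]) / pk$V_Sp
      LT_n <- sum(a_T[nrm] * vol[nrm]) / pk$V_Sp
      SN_T <- sum(b_T[nrm] * CT[nrm] * vol[nrm]) / pk$V_Sp
    }

    if (live) {
      # augmented RK4: y (6) plus integrals of Fv, Tv, Fs, Ts, and of the
      # clearance/endothelial sink concentrations for the mass audit
      nsub <- max(1L, ceiling(dt / 1))
      h <- dt / nsub
      aug <- c(y, numeric(10))
      deriv <- function(a) {
        yy <- a[1:6]
        loss <- list(F_tum = LF_t * yy[5L] - ST_F,
                     T_tum = LT_t * yy[4L] - ST_T,
                     F_nrm = LF_n * yy[2L] - SN_F,
                     T_nrm = LT_n * yy[1L] - SN_T)
        d <- pk_derivs(yy, T_ves, params, loss = loss)
        c(d,
          yy[5L], yy[4L], yy[2L], yy[1L],                 # Fv, Tv, Fs, Ts
          pk$k_el_F * (yy[2L] + yy[3L]) + pk$k_el_T * yy[1L],  # systemic clearance
          pk$k_endo * (yy[4L] + yy[5L] + yy[6L]),              # endothelial
          yy[2L], yy[3L], yy[4L], yy[6L])                      # spare integrals
      }
      for (s in seq_len(nsub)) {
        k1 <- deriv(aug)
        k2 <- deriv(aug + h / 2 * k1)
        k3 <- deriv(aug + h / 2 * k2)
        k4 <- deriv(aug + h * k3)
        aug <- aug + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      y <- pmax(aug[1:6], 0)
      int_Fv <- aug[7L]; int_Tv <- aug[8L]
      int_Fs <- aug[9L]; int_Ts <- aug[10L]
      cleared <- cleared + pk$V_Sp * aug[11L]
      endo <- endo + V_Tp * aug[12L]
    } else {
      y_mid <- pk_interp((t0 + t1) / 2)
      y <- pk_interp(t1)
      int_Fv <- y_mid[5L] * dt; int_Tv <- y_mid[4L] * dt
      int_Fs <- y_mid[2L] * dt; int_Ts <- y_mid[1L] * dt
    }

    # transvascular gain per node over the step (kg/m^3 tissue)
    dCF <- numeric(n); dCT <- numeric(n)
    int_Fv_t <- if (merged_vessel) int_Fs else int_Fv
    int_Tv_t <- if (merged_vessel) int_Ts else int_Tv
    dCF[tum] <- a_F[tum] * int_Fv_t - b_F[tum] * CF[tum] * dt
    dCT[tum] <- a_T[tum] * int_Tv_t - b_T[tum] * CT[tum] * dt
    dCF[nrm] <- a_F[nrm] * int_Fs - b_F[nrm] * CF[nrm] * dt
    dCT[nrm] <- a_T[nrm] * int_Ts - b_T[nrm] * CT[nrm] * dt
    CF <- pmax(CF + dCF, 0)
    CT <- pmax(CT + dCT, 0)

    # interstitial protein binding (exact exchange)
    bnd <- binding_step(CF, CB, dt, params)
    CF <- bnd$F; CB <- bnd$B

    # interstitial liposome release
    rel <- CT * (1 - exp(-krel_loc * dt))
    CT <- CT - rel
    CF <- CF + rel

    # cellular uptake / efflux
    cx <- cellular_exchange(CF, Cint, dt, Tloc, params)
    CF <- cx$C_F; Cint <- cx$C_int

    # lymphatic removal (normal tissue only): convective fluid sink plus
    # baseline lymphatic solute clearance
    lymf <- 1 - exp(-(phi_L + tr$lambda_lymph * nrm) * dt)
    lymph_removed <- lymph_removed + sum((CF + CB + CT) * lymf * vol)
    CF <- CF * (1 - lymf); CB <- CB * (1 - lymf); CT <- CT * (1 - lymf)

    # advection (explicit upwind) + diffusion (implicit)
    Minv <- Ainv[[which.min(abs(dts - dt))]]
    advF <- advect_upwind(CF, flow$ifv, r)
    advB <- advect_upwind(CB, flow$ifv, r)
    advT <- advect_upwind(CT, flow$ifv, r)
    boundary_out <- boundary_out +
      dt * (advF$outflow_rate + advB$outflow_rate + advT$outflow_rate)
    CF <- as.numeric(Minv$F %*% (CF + dt * advF$tend))
    CB <- as.numeric(Minv$B %*% (CB + dt * advB$tend))
    CT <- as.numeric(Minv$T %*% (CT + dt * advT$tend))

    # pharmacodynamics
    om <- kill_rate(Cint, params)
    N <- N * exp((pd$k_p - pd$k_deg - om) * dt)

    while (iout <= length(out_times) && out_times[iout] <= t1 + 1e-9) {
      record(iout, out_times[iout])
      iout <- iout + 1L
    }
    while (isnap <= length(snap_times) && snap_times[isnap] <= t1 + 1e-9) {
      snaps$CF[, isnap] <- CF; snaps$Cint[, isnap] <- Cint
      snaps$CT[, isnap] <- CT; snaps$N[, isnap] <- N
      isnap <- isnap + 1L
    }
  }

  list(series = as.data.frame(rec), snapshots = snaps,
       snapshot_times = snap_times,
       final = list(CF = CF, CB = CB, CT = CT, Cint = Cint, N = N),
       audit = list(cleared = cleared, endothelial = endo,
                    lymphatic = lymph_removed, boundary_out = boundary_out,
                    injected = injected,
                    max_mass_error = if (all(is.na(rec[, "mass_error"])))
                      NA_real_ else max(abs(rec[, "mass_error"]), na.rm = TRUE)))
}

#' Solve interstitial drug transport with a prescribed vessel history
#'
#' Integrates the convection-diffusion-reaction system for liposomal, free
#' and bound drug in the interstitium (plus intracellular drug and cell
#' survival) when the plasma concentrations are already known, e.g. from
#' [simulate_plasma_pk()]. Transvascular exchange follows the Patlak flux
#' of [transvascular_flux()]; binding, temperature-triggered release,
#' cellular exchange, lymphatic drainage and upwind advection with implicit
#' diffusion are applied by operator splitting.
#'
#' @param domain,zones From [build_domain()].
#' @param flow A `fluid_field` from [solve_interstitial_flow()].
#' @param vessel_series Data frame from [simulate_plasma_pk()] (columns
#'   `time`, `T_sys` ... `B_ves`).
#' @param params Parameter list.
#' @param duration Simulated time (s).
#' @param Tsched Optional temperature schedule `list(times, T)` with `T` a
#'   nodes-by-times matrix; `NULL` means uniform 37 degC.
#' @param heating_interval Optional `c(start, end)` (s) during which the
#'   fine time step is used.
#' @param output_dt,snapshot_dt Output cadences (s).
#' @return List with `series` (tumor-average time series), `snapshots`
#'   (nodal fields), `final` state and `audit`.
#' @export
solve_cdr <- function(domain, zones, flow, vessel_series,
                      params = default_params(), duration = 6 * 3600,
                      Tsched = NULL, heating_interval = NULL,
                      output_dt = 60, snapshot_dt = 900) {
  cdr_march(domain, zones, flow, params, duration, Tsched = Tsched,
            pkspec = list(mode = "prescribed", series = vessel_series),
            heating_interval = heating_interval,
            output_dt = output_dt, snapshot_dt = snapshot_dt)
}
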
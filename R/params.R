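#' Default physical and protocol parameters
#'
#' Returns the full nested parameter list used by every solver in the package.
#' Values are SI throughout. Vascular and fluid magnitudes follow the standard
#' Baxter–Jain poroelastic tumor description; pharmacokinetic, transport and
#' pharmacodynamic rate constants are calibrated against the printed anchors of
#' the underlying treatment model (25% free fraction, sub-30-min free-drug
#' half-life, 20-min intracellular lag, 42.6 degC mild-hyperthermia peak,
#' 11%/40% kill fractions). The methods vignette documents each calibration.
#'
#' @return A named list with components `geometry`, `zones`, `fluid`,
#'   `thermal_response`, `bioheat`, `mnp`, `amf`, `hifu`, `pk`, `transport`,
#'   `pd`, `drug` and `protocol`.
#' @export
#' @examples
#' p <- default_params()
#' p$pk$k_d / (p$pk$k_a + p$pk$k_d)  # equilibrium free fraction, 0.25
default_params <- function() {
  list(
    geometry = list(
      tumor_radius = 5e-3,            # m
      normal_shell_thickness = 5e-3,  # m
      grid_spacing = 1e-4,            # m
      symmetry = "radial_1d"
    ),
    zones = list(
      # radial fractions of the tumor radius bounding hypoxic and quiescent zones
      hypoxic_fraction = 1 / 3,
      quiescent_fraction = 2 / 3,
      sv_nominal = 2e4,               # tumor vascular surface density S/V, 1/m
      sv_scale = c(hypoxic = 0.1, quiescent = 0.5, proliferative = 1.0),
      sv_normal = 7e3,                # 1/m
      perfusion = c(hypoxic = 2e-4, quiescent = 1e-3,
                    proliferative = 2e-3, normal = 5e-4),  # 1/s
      lymph_k_normal = 1e-6           # 1/(Pa s), zero in all tumor zones
    ),
    fluid = list(
      K = c(tumor = 1.9e-13, normal = 6.4e-15),  # m^2/(Pa s)
      Lp = c(tumor = 2.1e-11, normal = 2.7e-12), # m/(Pa s)
      p_v = 2080,                     # Pa (~15.6 mmHg microvascular pressure)
      sigma = c(tumor = 0.82, normal = 0.91),
      pi_v = 2640,                    # Pa plasma oncotic pressure
      pi_i = c(tumor = 2306, normal = 1333)      # Pa interstitial oncotic
    ),
    thermal_response = list(
      form = "linear_ramp",
      T_baseline = 37,
      T_top = 43,
      # transmembrane ramp fixed by the 42.6 degC -> 2.4-fold anchor
      trans_anchor_T = 42.6,
      trans_anchor_fold = 2.4,
      perm_fold_max = 2.0
    ),
    bioheat = list(
      rho = 1050, c = 3639, k = 0.52,  # tissue
      rho_b = 1060, c_b = 3840,        # blood
      T_a = 37, Q_met = 0
    ),
    mnp = list(
      core_diameter = 18e-9,          # m, maghemite
      saturation_magnetization = 3e5, # A/m
      anisotropy_constant = 4.7e3,    # J/m^3
      tau0 = 1e-9,                    # s, Neel attempt time
      viscosity = 1e-3,               # Pa s, solvent (Brownian relaxation)
      shell_thickness = 1e-9,         # m, hydrodynamic coating
      # tumor volume fraction of pre-accumulated clusters; calibrated so the
      # 1-h AMF exposure peaks at 42.6 degC (see calibrate_mnp_volume_fraction)
      volume_fraction = 1.29006695146e-3
    ),
    amf = list(H = 13e3, f = 300e3, duration = 3600),  # A/m, Hz, s
    hifu = list(
      acoustic_power = 30,            # W
      frequency = 1.44e6,             # Hz
      aperture_radius = 32e-3,        # m
      focal_length = 64e-3,           # m
      duration = 60,                  # s
      rho = 1050, c = 1540,           # acoustic medium
      attenuation_np_m_mhz = 5,       # Np/(m MHz), linear in f
      # axisymmetric computation box centred on the focus
      box_z = 30e-3, box_r = 10e-3, dz = 5e-4, dr = 2.5e-4,
      dt = 0.05, cool_down = 60,
      n_theta = 192, n_phi = 128      # Rayleigh-integral quadrature
    ),
    pk = list(
      k_a = 1.5e-3,                   # 1/s association with plasma protein
      k_d = 5e-4,                     # 1/s dissociation (free fraction 25%)
      k_el_F = 5e-4,                  # 1/s systemic clearance of free drug
      k_el_T = 3e-5,                  # 1/s systemic clearance of liposomes
      k_endo = 1e-4,                  # 1/s endothelial uptake in tumor vessels
      Q_perf = 2.8e-3,                # 1/s plasma exchange (vessel-volume basis)
      V_Sp = 5e-5,                    # m^3 systemic plasma volume
      V_ratio = 1e-3,                 # V_Tp / V_Sp
      k_leak = 3.9e-5,                # 1/s liposome leak below the melting range
      k_burst = 0.06,                 # 1/s burst release above 41 degC
      T_melt_lo = 39, T_melt_hi = 41  # degC lipid melting range
    ),
    transport = list(
      D_F = 1.6e-10,                  # m^2/s free doxorubicin
      D_B = 1.6e-10 / 3,              # bound drug diffuses slower
      D_T = 2e-13,                    # liposome: poor diffusion
      P_F = c(tumor = 2e-8, normal = 6e-9),  # m/s vascular permeability
      P_T = c(tumor = 2e-9, normal = 0),     # normal wall excludes 100-nm carrier
      sigma_f_F = c(tumor = 0.1, normal = 0.9),
      sigma_f_T = c(tumor = 0.9, normal = 1.0),
      xi = 1.3e-3,                    # 1/s cellular uptake
      eps = 1.3e-3,                   # 1/s cellular efflux (MDR)
      lambda_lymph = 5e-4             # 1/s lymphatic solute clearance (normal)
    ),
    pd = list(
      k_p = 3e-6,                     # 1/s proliferation
      k_deg = 2.6e-6,                 # 1/s physiological degradation
      f_max = 1.8e-5,                 # 1/s maximal drug kill rate (calibrated)
      EC50 = 2e-4                     # kg/m^3 half-saturation (calibrated)
    ),
    drug = list(
      dose_to_conc = 3.82e-4,         # (kg/m^3) per (mg/m^2); 50 -> 0.0191
      doses = c(50, 100, 150)         # mg/m^2
    ),
    protocol = list(
      total_sim_time = 24 * 3600,
      hyperthermia_window = c(0, 3600),
      ablation_window = c(0, 60),
      dt_heating = 1, dt_base = 10, output_dt = 60
    )
  )
}

#' Load a simulation configuration file
#'
#' Reads a YAML (or JSON) configuration and merges it over
#' [default_params()]. Keys absent from the defaults are rejected, so typos
#' cannot silently fall back to default values.
#'
#' @param path Path to a YAML/JSON file whose top-level sections are a subset
#'   of the sections of [default_params()].
#' @return A full parameter list as from [default_params()] with the file's
#'   overrides applied.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(default_params(), cfg, path = "")
}

# Recursive merge that refuses unknown keys.
merge_config <- function(base, override, path = "") {
  if (!is.list(override)) {
    return(coerce_like(base, override, path))
  }
  nm <- names(override)
  if (is.null(nm) || any(nm == "")) {
    stop("config entries under '", path, "' must be named", call. = FALSE)
  }
  unknown <- setdiff(nm, names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(sub("^/", "", paste0(path, "/", unknown)), collapse = ", "),
         call. = FALSE)
  }
  for (k in nm) {
    base[[k]] <- if (is.list(base[[k]])) {
      merge_config(base[[k]], override[[k]], paste0(path, "/", k))
    } else {
      coerce_like(base[[k]], override[[k]], paste0(path, "/", k))
    }
  }
  base
}

coerce_like <- function(base, value, path) {
  if (is.numeric(base)) {
    value <- unlist(value)
    if (!is.numeric(value)) {
      stop("config key '", sub("^/", "", path), "' must be numeric", call. = FALSE)
    }
    if (!is.null(names(base))) {
      if (is.null(names(value))) {
        if (length(value) != length(base)) {
          stop("config key '", sub("^/", "", path), "' needs ",
               length(base), " value(s)", call. = FALSE)
        }
        names(value) <- names(base)
      } else {
        bad <- setdiff(names(value), names(base))
        if (length(bad)) {
          stop("unknown config key(s): ",
               paste0(sub("^/", "", path), "/", bad, collapse = ", "),
               call. = FALSE)
        }
        base[names(value)] <- value
        return(base)
      }
    }
    return(value)
  }
  if (is.character(base)) return(as.character(value))
  value
}
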
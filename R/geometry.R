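#' Build the simulation domain and vascular zone map
#'
#' Discretizes a spherically symmetric tumor of radius `tumor_radius`
#' surrounded by a shell of normal tissue on a uniform radial grid, and
#' assigns every node to one of four vascular zones: hypoxic core, quiescent
#' mid-region, proliferative rim (ordered by increasing microvessel density),
#' and normal tissue. Per-zone vascular surface density, blood perfusion and
#' lymphatic drainage are attached to the zone map; functional lymphatics
#' exist only in normal tissue.
#'
#' @param params Parameter list as from [default_params()] (or
#'   [load_config()]); `params$geometry` and `params$zones` are used.
#' @return A list with components `domain` (class `tissue_domain`: radial
#'   nodes `r`, spacing `dr`, node count `n`, shell volumes `vol`, tumor mask
#'   `in_tumor`) and `zones` (class `zone_map`: factor `zone`, fields `sv`,
#'   `perfusion`, `lymph_k` per node).
#' @export
#' @examples
#' g <- build_domain(default_params())
#' table(g$zones$zone)
build_domain <- function(params = default_params()) {
  geo <- params$geometry
  zp <- params$zones
  if (geo$tumor_radius <= 0 || geo$grid_spacing <= 0 ||
      geo$normal_shell_thickness <= 0) {
    stop("geometry parameters must be positive", call. = FALSE)
  }
  R <- geo$tumor_radius
  R_out <- R + geo$normal_shell_thickness
  dr <- geo$grid_spacing
  n <- round(R_out / dr) + 1L
  if ((R / dr) < 50) {
    stop("grid too coarse: the tumor radius must span at least 50 nodes ",
         "(reduce geometry$grid_spacing)", call. = FALSE)
  }
  r <- seq(0, R_out, length.out = n)
  in_tumor <- r <= R + 1e-12

  frac <- r / R
  zone <- character(n)
  zone[in_tumor & frac < zp$hypoxic_fraction] <- "hypoxic"
  zone[in_tumor & frac >= zp$hypoxic_fraction &
         frac < zp$quiescent_fraction] <- "quiescent"
  zone[in_tumor & frac >= zp$quiescent_fraction] <- "proliferative"
  zone[!in_tumor] <- "normal"
  zone <- factor(zone, levels = c("hypoxic", "quiescent", "proliferative", "normal"))

  sv <- numeric(n)
  sv[zone == "hypoxic"] <- zp$sv_nominal * zp$sv_scale[["hypoxic"]]
  sv[zone == "quiescent"] <- zp$sv_nominal * zp$sv_scale[["quiescent"]]
  sv[zone == "proliferative"] <- zp$sv_nominal * zp$sv_scale[["proliferative"]]
  sv[zone == "normal"] <- zp$sv_normal

  perf <- unname(zp$perfusion[as.character(zone)])
  lymph <- ifelse(zone == "normal", zp$lymph_k_normal, 0)

  domain <- structure(
    list(r = r, dr = dr, n = n, tumor_radius = R, outer_radius = R_out,
         symmetry = geo$symmetry, vol = shell_volumes(r), in_tumor = in_tumor),
    class = "tissue_domain")
  zones <- structure(
    list(zone = zone, sv = sv, perfusion = perf, lymph_k = lymph),
    class = "zone_map")
  list(domain = domain, zones = zones)
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat("tissue_domain: 1D spherical, tumor radius",
      format(x$tumor_radius * 1e3), "mm in",
      format((x$outer_radius - x$tumor_radius) * 1e3),
      "mm normal shell;", x$n, "nodes, dr =", format(x$dr * 1e3), "mm\n")
  invisible(x)
}

#' @export
print.zone_map <- function(x, ...) {
  print(table(x$zone))
  invisible(x)
}

#' Convert a surface dose to an injected plasma concentration
#'
#' The injected bolus is assumed to mix instantaneously in systemic plasma,
#' giving an initial concentration linear in the administered surface dose.
#' The conversion is anchored so that 50 mg/m^2 maps to 0.0191 kg/m^3 (and
#' therefore 150 mg/m^2 to 0.0573 kg/m^3).
#'
#' @param dose Administered dose in mg/m^2 (vectorized, must be >= 0).
#' @param params Parameter list; `params$drug$dose_to_conc` holds the factor.
#' @return Initial plasma concentration(s) in kg/m^3.
#' @export
#' @examples
#' dose_to_plasma_concentration(50)   # 0.0191
dose_to_plasma_concentration <- function(dose, params = default_params()) {
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  dose * params$drug$dose_to_conc
}
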
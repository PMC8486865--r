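# Temperature-scaling of vascular permeability and transmembrane exchange.
#
# Mild hyperthermia (< 43 degC) widens vessel-wall pores and fluidizes cell
# membranes. Both effects are modeled as monotone fold-change functions of
# local temperature, equal to 1 at the 37 degC baseline and saturating at the
# top of the mild-hyperthermia range. The transmembrane ramp is pinned by the
# observed 2.4-fold exchange-rate increase at 42.6 degC, which fixes its
# 43 degC plateau at 2.5.

thermal_ramp <- function(T, T0, T1, fold_max) {
  f <- 1 + (fold_max - 1) * (T - T0) / (T1 - T0)
  pmin(pmax(f, 1), fold_max)
}

check_T_physical <- function(T) {
  if (any(!is.finite(T)) || any(T < 30) || any(T > 120)) {
    stop("temperature outside the physical range of the model", call. = FALSE)
  }
}

#' Transmembrane exchange fold-change with temperature
#'
#' Fold-change of the cellular uptake/efflux rate relative to 37 degC. A
#' piecewise-linear ramp from (37 degC, 1) to (43 degC, f_max) is used, with
#' f_max fixed so the multiplier is exactly 2.4 at 42.6 degC; above 43 degC
#' the value is held at f_max (mild hyperthermia ends there).
#'
#' @param T Temperature in degC (vectorized).
#' @param params Parameter list (`params$thermal_response`).
#' @return Dimensionless fold-change, >= 1 for T >= 37 degC.
#' @export
#' @examples
#' transmembrane_multiplier(c(37, 42.6))  # 1.0, 2.4
transmembrane_multiplier <- function(T, params = default_params()) {
  check_T_physical(T)
  tr <- params$thermal_response
  fold_max <- 1 + (tr$trans_anchor_fold - 1) *
    (tr$T_top - tr$T_baseline) / (tr$trans_anchor_T - tr$T_baseline)
  thermal_ramp(T, tr$T_baseline, tr$T_top, fold_max)
}

#' Vascular permeability fold-change with temperature
#'
#' Fold-change of the vessel-wall diffusive permeability (and of the
#' convective sieving factor 1 - sigma_f, consistent with a pore-size
#' increase) relative to 37 degC. Linear ramp to `perm_fold_max` (default 2)
#' at 43 degC, held constant above.
#'
#' @inheritParams transmembrane_multiplier
#' @return Dimensionless fold-change, >= 1 for T >= 37 degC.
#' @export
permeability_multiplier <- function(T, params = default_params()) {
  check_T_physical(T)
  tr <- params$thermal_response
  thermal_ramp(T, tr$T_baseline, tr$T_top, tr$perm_fold_max)
}
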
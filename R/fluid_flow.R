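#' Solve steady interstitial fluid pressure and velocity
#'
#' Solves the steady Darcy problem for interstitial fluid pressure (IFP)
#' on the radial domain,
#' \deqn{\nabla\cdot(-K\nabla p) = \phi_v - \phi_L,}
#' with the Starling transvascular source
#' \eqn{\phi_v = L_p (S/V) (p_v - p - \sigma(\pi_v - \pi_i))} and a lymphatic
#' sink \eqn{\phi_L = k_L\, p} active only in normal tissue. The outer
#' boundary (far normal tissue) is held at p = 0 and a zero-flux regularity
#' condition applies at r = 0. The interstitial fluid velocity (IFV) is the
#' Darcy velocity \eqn{v = -K \nabla p}.
#'
#' @param domain,zones From [build_domain()].
#' @param params Parameter list; `params$fluid` and the zone map fields are
#'   used.
#' @param damage Optional perfusion-damage factor per node in `[0, 1]`
#'   (fraction of baseline `Lp * S/V` retained), e.g. from
#'   [build_perfusion_damage()] mapped onto the radial grid.
#' @return An object of class `fluid_field`: list with `ifp` (Pa), `ifv`
#'   (m/s, radial, on nodes), `phi_v` and `phi_L` (1/s), `p_e` (effective
#'   filtration pressure per node), and the mass-balance `residual`
#'   (net volumetric imbalance relative to total transvascular production).
#' @export
#' @examples
#' g <- build_domain(default_params())
#' ff <- solve_interstitial_flow(g$domain, g$zones, default_params())
#' max(ff$ifp)  # plateau IFP close to the effective filtration pressure
solve_interstitial_flow <- function(domain, zones, params = default_params(),
                                    damage = NULL) {
  fl <- params$fluid
  n <- domain$n
  tum <- domain$in_tumor
  if (is.null(damage)) damage <- rep(1, n)
  stopifnot(length(damage) == n, all(damage >= 0), all(damage <= 1))

  K <- ifelse(tum, fl$K[["tumor"]], fl$K[["normal"]])
  Lp <- ifelse(tum, fl$Lp[["tumor"]], fl$Lp[["normal"]])
  sigma <- ifelse(tum, fl$sigma[["tumor"]], fl$sigma[["normal"]])
  pi_i <- ifelse(tum, fl$pi_i[["tumor"]], fl$pi_i[["normal"]])
  p_e <- fl$p_v - sigma * (fl$pi_v - pi_i)

  s_v <- Lp * zones$sv * damage     # 1/(Pa s)
  lym <- zones$lymph_k * damage

  L <- sph_diffusion_matrix(domain$r, face_harmonic(K), bc_outer = "dirichlet")
  A <- L - diag(s_v + lym, n)
  A[n, ] <- 0
  A[n, n] <- 1
  b <- -s_v * p_e
  b[n] <- 0                          # outer Dirichlet p = 0
  p <- as.numeric(solve(A, b))

  phi_v <- s_v * (p_e - p)
  phi_L <- lym * p

  # Darcy velocity, central differences (one-sided at the ends)
  dp <- numeric(n)
  dp[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * domain$dr)
  dp[1] <- 0                         # regularity at r = 0
  dp[n] <- (p[n] - p[n - 1]) / domain$dr
  ifv <- -K * dp

  # discrete outer-face volumetric outflow consistent with the FV operator
  Kf <- face_harmonic(K)
  a_face <- face_areas(domain$r)
  outflow <- a_face[n - 1L] * Kf[n - 1L] * (p[n - 1L] - p[n]) / domain$dr
  src <- sum(((phi_v - phi_L) * domain$vol)[-n])
  residual <- (src - outflow) / max(sum(abs(phi_v) * domain$vol), 1e-300)

  structure(list(ifp = p, ifv = ifv, phi_v = phi_v, phi_L = phi_L,
                 p_e = p_e, s_v = s_v, damage = damage, residual = residual),
            class = "fluid_field")
}

#' Re-solve interstitial flow under a perfusion-damage map
#'
#' Scales the vascular filtration capacity `Lp * S/V` (and the lymphatic
#' drainage) node-wise by the damage factor and re-solves the steady flow
#' problem. A damage factor of 1 everywhere reproduces the input field.
#'
#' @param domain,zones,params As for [solve_interstitial_flow()].
#' @param damage Numeric vector of per-node retained-perfusion fractions in
#'   `[0, 1]`.
#' @return A new `fluid_field`.
#' @export
apply_perfusion_damage_to_flow <- function(domain, zones, params, damage) {
  solve_interstitial_flow(domain, zones, params, damage = damage)
}

#' @export
print.fluid_field <- function(x, ...) {
  cat("fluid_field: IFP max", format(max(x$ifp), digits = 4), "Pa;",
      "IFV max", format(max(abs(x$ifv)), digits = 3), "m/s;",
      "mass-balance residual", format(x$residual, digits = 2), "\n")
  invisible(x)
}
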
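# Independent analytic oracles shared by the unit and acceptance suites.

# Closed-form IFP profile for a uniform spherical tumor with Starling
# sources, p(r) = p_e (1 - (R/r) sinh(a r/R)/sinh(a)),
# a^2 = Lp (S/V) R^2 / K, with p = 0 at the outer radius R.
spherical_ifp_oracle <- function(r, R, K, Lp, sv, p_e) {
  a <- sqrt(Lp * sv * R^2 / K)
  out <- p_e * (1 - (R / r) * sinh(a * r / R) / sinh(a))
  out[r == 0] <- p_e * (1 - a / sinh(a))
  out
}

# Parameter set that collapses the domain to a single uniform tissue so the
# spherical closed form applies exactly.
uniform_params <- function() {
  p <- default_params()
  p$zones$sv_scale <- c(hypoxic = 1, quiescent = 1, proliferative = 1)
  p$zones$sv_normal <- p$zones$sv_nominal
  p$zones$lymph_k_normal <- 0
  for (f in c("K", "Lp", "sigma", "pi_i")) {
    p$fluid[[f]][["normal"]] <- p$fluid[[f]][["tumor"]]
  }
  p
}

# O'Neil closed-form on-axis amplitude of a spherically curved radiator:
# |p(z)| = 2 rho c u0 (F/|F - z|) |sin(k (R_edge(z) - z)/2)|, with R_edge the
# distance from the axial point to the bowl rim.
oneil_on_axis <- function(z, a, F0, rho, c, f, u0) {
  k <- 2 * pi * f / c
  h <- F0 * (1 - sqrt(1 - (a / F0)^2))
  Redge <- sqrt(a^2 + (z - h)^2)
  out <- 2 * rho * c * u0 * abs(F0 / (F0 - z)) * abs(sin(k * (Redge - z) / 2))
  out[abs(z - F0) < 1e-12] <- rho * c * u0 * k * h
  out
}

# Reduced evaluation grid for sonication tests (field accuracy is set by the
# bowl quadrature, which stays at its default resolution).
hifu_fast_params <- function() {
  p <- default_params()
  p$hifu$box_r <- 6e-3
  p$hifu$dr <- 5e-4
  p$hifu$dz <- 1e-3
  p
}

# Cached default-power sonication (acoustic field + axisymmetric heating) on
# the reduced grid.
get_hifu_stage <- function() {
  cached("hifu30_fast", {
    p <- hifu_fast_params()
    ac <- compute_acoustic_field(p)
    tf <- solve_bioheat_axisym(ac, p)
    list(params = p, acoustic = ac, temperature = tf)
  })
}
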
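# Internal numerical helpers shared by the radial solvers.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Finite-volume shell volumes for a radial grid r (first node at r = 0).
# Faces sit halfway between nodes; the first cell is a sphere of radius dr/2,
# the last cell ends at r[n] (the boundary node owns a half shell).
shell_volumes <- function(r) {
  n <- length(r)
  dr <- r[2L] - r[1L]
  f_in <- pmax(r - dr / 2, 0)
  f_out <- r + dr / 2
  f_out[n] <- r[n]
  (4 / 3) * pi * (f_out^3 - f_in^3)
}

# Face areas 4*pi*r_face^2 for faces between node i and i+1.
face_areas <- function(r) {
  rf <- (r[-length(r)] + r[-1L]) / 2
  4 * pi * rf^2
}

# Conservative finite-volume operator for (1/r^2) d/dr (r^2 D dC/dr) on a
# uniform radial grid. `d_face` is the diffusivity on the n-1 interior faces
# (harmonic mean of node values if it varies). Returns a dense n x n matrix L
# so that dC/dt = L %*% C.
#
# bc_outer: "neumann" imposes zero flux through the outer face; "dirichlet"
# replaces the last row by zeros (the boundary node is held by the caller).
sph_diffusion_matrix <- function(r, d_face, bc_outer = c("neumann", "dirichlet")) {
  bc_outer <- match.arg(bc_outer)
  n <- length(r)
  dr <- r[2L] - r[1L]
  if (length(d_face) == 1L) d_face <- rep(d_face, n - 1L)
  stopifnot(length(d_face) == n - 1L)
  vol <- shell_volumes(r)
  area <- face_areas(r)
  g <- area * d_face / dr            # face conductances
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      L[i, i - 1L] <- L[i, i - 1L] + g[i - 1L] / vol[i]
      L[i, i] <- L[i, i] - g[i - 1L] / vol[i]
    }
    if (i < n) {
      L[i, i + 1L] <- L[i, i + 1L] + g[i] / vol[i]
      L[i, i] <- L[i, i] - g[i] / vol[i]
    }
  }
  if (bc_outer == "dirichlet") L[n, ] <- 0
  L
}

# Harmonic mean of a node-valued coefficient onto interior faces.
face_harmonic <- function(x) {
  a <- x[-length(x)]
  b <- x[-1L]
  2 * a * b / (a + b)
}

# Peclet weighting Pe / (exp(Pe) - 1) with a series fallback near Pe = 0.
peclet_factor <- function(pe) {
  out <- numeric(length(pe))
  small <- abs(pe) < 1e-8
  out[small] <- 1 - pe[small] / 2
  out[!small] <- pe[!small] / expm1(pe[!small])
  out
}

# Volume-weighted average of a nodal field over a logical mask.
volume_average <- function(x, vol, mask = NULL) {
  if (!is.null(mask)) {
    x <- x[mask]
    vol <- vol[mask]
  }
  sum(x * vol) / sum(vol)
}

# Upwind conservative advection tendency for a radial velocity field defined
# on nodes. Returns list(tend, outflow_rate) where outflow_rate is the mass
# per second leaving through the outer face (for the mass audit).
advect_upwind <- function(C, v, r) {
  n <- length(r)
  vol <- shell_volumes(r)
  area <- face_areas(r)
  vf <- (v[-n] + v[-1L]) / 2
  Cup <- ifelse(vf >= 0, C[-n], C[-1L])
  flux <- area * vf * Cup            # kg/s through interior faces
  # outer boundary face: outflow with upwind (interior) concentration
  a_out <- 4 * pi * r[n]^2
  f_out <- a_out * max(v[n], 0) * C[n]
  tend <- numeric(n)
  tend[1L] <- -flux[1L] / vol[1L]
  if (n > 2L) tend[2:(n - 1L)] <- (flux[1:(n - 2L)] - flux[2:(n - 1L)]) / vol[2:(n - 1L)]
  tend[n] <- (flux[n - 1L] - f_out) / vol[n]
  list(tend = tend, outflow_rate = f_out)
}
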
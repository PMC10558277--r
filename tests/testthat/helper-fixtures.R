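# Shared fixtures: small meshes and parameter sets used across the suite.

mesh_1d <- function(L = 0.05, n = 50, vessel = TRUE) {
  m <- make_box_mesh(L, n)
  if (vessel) m <- tag_vessel(m, vessel_spec(matrix(0, 1, 1), L / n))
  m
}

# Parameter set with both phases mobility-matched and no capillarity:
# fractional flow reduces to f(s) = s, so saturation transport is linear
# advection -- convenient for scheme-vs-scheme comparisons.
params_advection <- function(phi = 0.05) {
  thermo_parameters(phi = phi, gamma = 0,
                    mu_blood = 1e-3, mu_bolus = 1e-3,
                    kappa_blood = 5e-12, kappa_bolus = 5e-12,
                    pd = 1e-30)
}

# A schedule that never injects (pure relaxation / sealed studies).
no_injection <- function(params) injection_schedule(params, duration = 0)

# Discretely divergence-free swirl fluxes on a 2D mesh from a stream
# function on the nodes (zero on the boundary, so the domain is sealed).
swirl_fluxes <- function(mesh, amplitude = 1e-9) {
  stopifnot(mesh$dim == 2)
  L <- mesh$extents
  psi <- function(x, y) {
    amplitude * sin(pi * x / L[1]) * sin(pi * y / L[2])
  }
  f <- mesh$faces
  Qt <- numeric(nrow(f))
  h <- mesh$h
  for (k in seq_len(nrow(f))) {
    if (!is.na(f$tag[k])) next
    cx <- f$c1[k]; cy <- f$c2[k]
    if (f$axis[k] == 1) {
      # vertical face: flux = psi(top) - psi(bottom)
      Qt[k] <- psi(cx, cy + h[2] / 2) - psi(cx, cy - h[2] / 2)
    } else {
      # horizontal face: flux = -(psi(right) - psi(left))
      Qt[k] <- -(psi(cx + h[1] / 2, cy) - psi(cx - h[1] / 2, cy))
    }
  }
  Qt
}

# Gaussian bolus blob centred in the domain, for transport studies.
blob_saturation <- function(mesh, peak = 0.5, width = 0.2) {
  ctr <- mesh$extents / 2
  r2 <- rowSums(sweep(mesh$centers, 2, ctr)^2)
  peak * exp(-r2 / (2 * (width * max(mesh$extents))^2))
}
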
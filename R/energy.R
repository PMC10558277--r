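#' Volume-fraction-averaged mixture thermal properties
#'
#' Under the thermal-equilibrium assumption a single mixture temperature is
#' transported, with conductivity and thermal inertia averaged over the
#' co-located constituents:
#' `k = (1-phi) k_tissue + phi s_blood k_blood + phi s_bolus k_bolus`,
#' and analogously `rho c` with the per-constituent products.
#'
#' @param s_bolus bolus saturation per cell.
#' @param params a [thermo_parameters()] set.
#' @return list with `k_mix` (W/m/K) and `rhoc_mix` (J/m^3/K) per cell, each
#'   a convex combination of the constituent values.
#' @export
mixture_properties <- function(s_bolus, params) {
  phi <- params$phi
  s_blood <- 1 - s_bolus
  k_mix <- (1 - phi) * params$k_tissue +
    phi * s_blood * params$k_blood +
    phi * s_bolus * params$k_bolus
  rhoc_mix <- (1 - phi) * params$rho_tissue * params$c_tissue +
    phi * s_blood * params$rho_blood * params$c_blood +
    phi * s_bolus * params$rho_bolus * params$c_bolus
  list(k_mix = k_mix, rhoc_mix = rhoc_mix)
}

#' Implicitly advance the mixture temperature
#'
#' One backward-Euler step of the convection-diffusion-reaction equation for
#' the mixture temperature: porous convection with the saturation- and
#' heat-capacity-weighted phase fluxes (first-order upwind on temperature),
#' diffusion by two-point flux with harmonic-mean conductivity, and the
#' hydrolysis heat source from [heat_source()]. While the injection is
#' active, VESSEL faces impose the upstream temperature `u0` as the inflow
#' value for convection and a half-cell conductive exchange (the
#' strong-inflow limit of the Robin inflow condition); after the delivery
#' window they are insulated. FAR faces are zero-gradient.
#'
#' @param mesh a `thermo_mesh`.
#' @param u temperature per cell (deg C).
#' @param s_bolus end-of-step bolus saturation per cell (operator splitting:
#'   the flow is advanced first).
#' @param Q_blood,Q_bolus per-face phase volumetric fluxes (m^3/s), signed
#'   positive out of the owner cell (zero when the injection is inactive).
#' @param params a [thermo_parameters()] set.
#' @param schedule an [injection_schedule()].
#' @param t current time (s).
#' @param dt time step (s).
#' @param far_bc far-boundary flow treatment (affects which faces carry
#'   convective in/outflow).
#' @return list with the new temperature `u`, per-step energy-budget entries
#'   (J): `heat_released` (reaction), `energy_delta` (stored, end-of-step
#'   rho c), `boundary_in` (net vessel convective + conductive input), and
#'   the mixture fields `k_mix`, `rhoc_mix`.
#' @export
advance_temperature <- function(mesh, u, s_bolus, Q_blood, Q_bolus,
                                params, schedule, t, dt,
                                far_bc = "dirichlet") {
  if (dt <= 0) abort("dt must be positive", class = "thermo_input_error")
  f <- mesh$faces
  cls <- classify_faces(mesh, schedule, t, params, far_bc)
  n <- mesh$ncell
  V <- mesh$volume
  phi <- params$phi
  mix <- mixture_properties(s_bolus, params)

  i <- f$owner; j <- f$neighbor
  int <- which(is.na(f$tag))
  ves <- which(f$tag %in% "VESSEL" & cls$type == "dirichlet")

  # heat-capacity flux through each face, W/K, positive out of the owner
  C <- phi * (params$rho_blood * params$c_blood * Q_blood +
              params$rho_bolus * params$c_bolus * Q_bolus)

  # harmonic-mean face conductivity
  kf <- numeric(nrow(f))
  kf[int] <- 2 * mix$k_mix[i[int]] * mix$k_mix[j[int]] /
    (mix$k_mix[i[int]] + mix$k_mix[j[int]])
  kf[ves] <- mix$k_mix[i[ves]]
  Tr <- f$area / f$dist

  diag0 <- mix$rhoc_mix * V / dt
  rhs <- diag0 * u + V * heat_source(s_bolus, params)

  ti <- seq_len(n); tj <- seq_len(n); tx <- diag0

  # interior diffusion
  cf <- Tr[int] * kf[int]
  ti <- c(ti, i[int], j[int], i[int], j[int])
  tj <- c(tj, i[int], j[int], j[int], i[int])
  tx <- c(tx, cf, cf, -cf, -cf)

  # interior convection, non-conservative upwind: only inflow faces couple
  Ci <- C[int]
  own_in <- Ci < 0   # inflow into owner from neighbor
  if (any(own_in)) {
    ti <- c(ti, i[int][own_in], i[int][own_in])
    tj <- c(tj, i[int][own_in], j[int][own_in])
    tx <- c(tx, -Ci[own_in], Ci[own_in])
  }
  nb_in <- Ci > 0    # inflow into neighbor from owner
  if (any(nb_in)) {
    ti <- c(ti, j[int][nb_in], j[int][nb_in])
    tj <- c(tj, j[int][nb_in], i[int][nb_in])
    tx <- c(tx, Ci[nb_in], -Ci[nb_in])
  }

  # vessel inflow during injection: convective inflow at u0 + conduction to u0
  if (length(ves) > 0L) {
    Cv <- C[ves]; ov <- i[ves]
    vin <- Cv < 0
    if (any(vin)) {
      ti <- c(ti, ov[vin]); tj <- c(tj, ov[vin]); tx <- c(tx, -Cv[vin])
      rhs <- rhs + tabulate_add(ov[vin], -Cv[vin] * schedule$u0, n)
    }
    cc <- Tr[ves] * kf[ves]
    ti <- c(ti, ov); tj <- c(tj, ov); tx <- c(tx, cc)
    rhs <- rhs + tabulate_add(ov, cc * schedule$u0, n)
  }
  # far boundary: zero-gradient, so neither conduction nor a convective
  # upwind difference contributes to the non-conservative form.

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  u_new <- as.numeric(Matrix::solve(A, rhs))
  res <- as.numeric(A %*% u_new - rhs)
  if (!all(is.finite(u_new)) ||
      sqrt(sum(res^2)) / max(1, max(abs(rhs))) > 1e-8) {
    abort("temperature step failed to reach the linear tolerance",
          class = "thermo_timestep_failure")
  }

  heat_released <- sum(V * heat_source(s_bolus, params)) * dt
  energy_delta <- sum(mix$rhoc_mix * V * (u_new - u))
  boundary_in <- 0
  if (length(ves) > 0L) {
    Cv <- C[ves]; ov <- i[ves]
    boundary_in <- sum(pmax(-Cv, 0) * (schedule$u0 - u_new[ov])) * dt +
      sum(Tr[ves] * kf[ves] * (schedule$u0 - u_new[ov])) * dt
  }

  list(u = u_new, heat_released = heat_released,
       energy_delta = energy_delta, boundary_in = boundary_in,
       k_mix = mix$k_mix, rhoc_mix = mix$rhoc_mix)
}
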
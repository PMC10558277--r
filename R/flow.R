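#' Brooks-Corey capillary pressure
#'
#' Capillary pressure between the nonwetting bolus and wetting blood phases,
#' `pc = pd / s_blood`, with a saturation floor `s_min` so the law stays
#' bounded as blood is fully displaced: `pc` is capped near `pd / s_min`.
#' The floor is applied through a C1-smooth max (smoothing width `s_min/10`)
#' so that implicit Newton solvers see a differentiable law; away from the
#' floor the smoothing is negligible (`pc(1) = pd` to ~1e-9 relative).
#' `pc` is monotonically non-increasing in blood saturation.
#'
#' @param s_blood blood saturation (dimensionless).
#' @param pd displacement pressure (Pa).
#' @param s_min regularization floor (default 1e-3).
#' @return capillary pressure (Pa).
#' @examples
#' capillary_pressure(1, 7498.05)    # pd itself
#' capillary_pressure(0.5, 7498.05)  # doubled
#' @export
capillary_pressure <- function(s_blood, pd, s_min = 1e-3) {
  pd / smooth_floor(s_blood, s_min)
}

# C1 smooth max(x, m) with width m/10: exact to ~1e-9 away from the corner.
smooth_floor <- function(x, m) {
  d <- m / 10
  0.5 * (x + m + sqrt((x - m)^2 + d^2))
}

# d/dx of smooth_floor
smooth_floor_deriv <- function(x, m) {
  d <- m / 10
  0.5 * (1 + (x - m) / sqrt((x - m)^2 + d^2))
}

#' Phase mobility
#'
#' Saturation-weighted permeability-to-viscosity ratio,
#' `lambda = s * kappa / mu`, multiplying the pressure gradient in each
#' phase's Darcy flux.
#'
#' @param s phase saturation in \[0, 1\].
#' @param kappa permeability (m^2).
#' @param mu dynamic viscosity (Pa s), > 0.
#' @return mobility, m^2/(Pa s).
#' @export
mobility <- function(s, kappa, mu) {
  if (any(mu <= 0)) {
    abort("viscosity must be strictly positive",
          class = "thermo_invalid_parameter")
  }
  s * kappa / mu
}

# Classify each face for time t: "interior", "dirichlet" (with value), or
# "noflow". Vessel faces are pressure-driven only while the injection is
# active; afterwards they seal (convective transport stops with the delivery).
classify_faces <- function(mesh, schedule, t, params, far_bc) {
  f <- mesh$faces
  type <- ifelse(is.na(f$tag), "interior", "noflow")
  pval <- rep(NA_real_, nrow(f))
  active <- injection_active(schedule, t)
  ves <- which(f$tag %in% "VESSEL")
  far <- which(f$tag %in% "FAR")
  if (active) {
    type[ves] <- "dirichlet"
    pval[ves] <- schedule$p_injection
  }
  if (identical(far_bc, "dirichlet")) {
    type[far] <- "dirichlet"
    pval[far] <- params$p0
  }
  list(type = type, pval = pval, active = active)
}

# Per-face upwinded phase saturations for the pressure assembly. Lagged:
# the previous pressure decides the upwind side; arithmetic mean when no
# previous field (or zero driving difference -- the symmetric tie-break).
face_saturations <- function(mesh, s_bolus, params, cls, p_prev = NULL) {
  f <- mesh$faces
  s_blood <- 1 - s_bolus
  pc <- capillary_pressure(s_blood, params$pd, params$s_min)
  i <- f$owner
  j <- f$neighbor
  int <- is.na(f$tag)

  so_f <- sb_f <- numeric(nrow(f))
  # interior: mean, then upwind by lagged pressure where available
  so_f[int] <- 0.5 * (s_bolus[i[int]] + s_bolus[j[int]])
  sb_f[int] <- 0.5 * (s_blood[i[int]] + s_blood[j[int]])
  if (!is.null(p_prev)) {
    po <- p_prev + pc
    ii <- i[int]; jj <- j[int]
    db <- p_prev[ii] - p_prev[jj]
    do <- po[ii] - po[jj]
    so_f[int] <- ifelse(do > 0, s_bolus[ii], ifelse(do < 0, s_bolus[jj], so_f[int]))
    sb_f[int] <- ifelse(db > 0, s_blood[ii], ifelse(db < 0, s_blood[jj], sb_f[int]))
  }
  # boundary: vessel carries the inflow composition, far is zero-gradient
  ves <- which(f$tag %in% "VESSEL" & cls$type == "dirichlet")
  so_f[ves] <- schedule_s0_or(params)
  sb_f[ves] <- 1 - so_f[ves]
  far <- which(f$tag %in% "FAR" & cls$type == "dirichlet")
  so_f[far] <- s_bolus[i[far]]
  sb_f[far] <- s_blood[i[far]]
  list(so = so_f, sb = sb_f, pc = pc)
}

schedule_s0_or <- function(params) params$s0

# Assemble the total-pressure system A p = b: two-point flux with
# harmonic-mean kappa/mu (uniform here) times upwinded saturation factors;
# capillary-gradient flux and reaction volume source on the right-hand side.
assemble_pressure_system <- function(mesh, s_bolus, params, schedule, t,
                                     far_bc = "dirichlet", p_prev = NULL) {
  f <- mesh$faces
  cls <- classify_faces(mesh, schedule, t, params, far_bc)
  fs <- face_saturations(mesh, s_bolus, params, cls, p_prev)

  mob_b <- params$kappa_blood / params$mu_blood
  mob_o <- params$kappa_bolus / params$mu_bolus
  lam_b <- fs$sb * mob_b
  lam_o <- fs$so * mob_o
  lam_t <- lam_b + lam_o
  Tr <- f$area / f$dist

  n <- mesh$ncell
  b <- mesh$volume * params$gamma * params$rho_dcacl * params$epsilon *
    params$phi * s_bolus * (1 / params$rho_blood - 1 / params$rho_bolus)

  int <- which(is.na(f$tag))
  dir <- which(cls$type == "dirichlet")
  if (length(dir) == 0L) {
    abort("pressure system is singular: no pressure boundary condition active",
          class = "thermo_solver_error")
  }

  i <- f$owner[int]; j <- f$neighbor[int]
  cf <- Tr[int] * lam_t[int]
  ti <- c(i, j, i, j, f$owner[dir])
  tj <- c(i, j, j, i, f$owner[dir])
  tx <- c(cf, cf, -cf, -cf, Tr[dir] * lam_t[dir])

  # capillary-gradient flux (explicit in saturation): moves to the RHS
  fpc <- Tr[int] * lam_o[int] * (fs$pc[i] - fs$pc[j])
  b <- b - tabulate_add(i, fpc, n) + tabulate_add(j, fpc, n)
  b <- b + tabulate_add(f$owner[dir],
                        Tr[dir] * lam_t[dir] * cls$pval[dir], n)

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  list(A = A, b = b, cls = cls, fs = fs,
       lam_t = lam_t, lam_o = lam_o, Tr = Tr)
}

# Total volumetric Darcy flux through every face (m^3/s, positive out of the
# owner), evaluated with the same face mobilities the pressure assembly used,
# so the discrete fluxes conserve volume cell by cell up to the reaction
# source. Zero on no-flow faces.
total_face_flux <- function(mesh, sys, p) {
  f <- mesh$faces
  Q <- numeric(nrow(f))
  int <- which(is.na(f$tag))
  i <- f$owner; j <- f$neighbor
  Q[int] <- sys$Tr[int] * sys$lam_t[int] * (p[i[int]] - p[j[int]]) +
    sys$Tr[int] * sys$lam_o[int] * (sys$fs$pc[i[int]] - sys$fs$pc[j[int]])
  dir <- which(sys$cls$type == "dirichlet")
  Q[dir] <- sys$Tr[dir] * sys$lam_t[dir] * (p[i[dir]] - sys$cls$pval[dir])
  Q
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  if (length(idx) == 0L) return(out)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Solve the total-pressure equation
#'
#' Solves the discrete elliptic equation for blood pressure on the mesh:
#' the divergence of the total Darcy flux balances the reaction volume
#' source, with the capillary-pressure gradient driving the bolus phase.
#' Dirichlet `p = p_injection(t)` applies on VESSEL faces while the injection
#' is active and `p = p0` on FAR faces (unless the far boundary is sealed);
#' vessel faces seal after the delivery window.
#'
#' @param mesh a `thermo_mesh`.
#' @param s_bolus bolus saturation per cell.
#' @param params a [thermo_parameters()] set.
#' @param schedule an [injection_schedule()].
#' @param t current time (s).
#' @param far_bc `"dirichlet"` (atmospheric far field) or `"noflow"` (sealed).
#' @param p_prev previous pressure field for lagged upwinding (optional).
#' @return blood pressure per cell (Pa).
#' @export
solve_pressure <- function(mesh, s_bolus, params, schedule, t,
                           far_bc = "dirichlet", p_prev = NULL) {
  sys <- assemble_pressure_system(mesh, s_bolus, params, schedule, t,
                                  far_bc, p_prev)
  p <- as.numeric(Matrix::solve(sys$A, sys$b))
  res <- as.numeric(sys$A %*% p - sys$b)
  scale <- max(1, max(abs(sys$b)))
  if (sqrt(sum(res^2)) / scale > 1e-10) {
    abort("pressure linear solve did not reach residual tolerance",
          class = "thermo_solver_error")
  }
  p
}

#' Darcy face velocities from a pressure field
#'
#' Two-point flux approximation of the phase Darcy velocities on every face.
#' The saturation-free gradient velocities `g = -(kappa/mu) grad(p_phase)`
#' are returned alongside the mobility-weighted velocities `v = s_up * g`
#' (upwinded saturation factor; arithmetic mean on zero-velocity ties). The
#' bolus phase uses `p_bolus = p_blood + pc`, with a zero-gradient capillary
#' extrapolation on boundary faces. Velocities are signed positive outward
#' from the face's owner cell.
#'
#' @inheritParams solve_pressure
#' @param p blood pressure per cell (Pa).
#' @return list of per-face vectors `g_blood`, `g_bolus`, `v_blood`,
#'   `v_bolus` (m/s) and the upwinded face saturations `s_bolus_face`.
#' @export
darcy_velocity <- function(mesh, p, s_bolus, params, schedule, t,
                           far_bc = "dirichlet") {
  f <- mesh$faces
  cls <- classify_faces(mesh, schedule, t, params, far_bc)
  s_blood <- 1 - s_bolus
  pc <- capillary_pressure(s_blood, params$pd, params$s_min)
  po <- p + pc
  mob_b <- params$kappa_blood / params$mu_blood
  mob_o <- params$kappa_bolus / params$mu_bolus

  nF <- nrow(f)
  g_b <- g_o <- numeric(nF)
  i <- f$owner; j <- f$neighbor
  int <- which(is.na(f$tag))
  g_b[int] <- mob_b * (p[i[int]] - p[j[int]]) / f$dist[int]
  g_o[int] <- mob_o * (po[i[int]] - po[j[int]]) / f$dist[int]
  dir <- which(cls$type == "dirichlet")
  g_b[dir] <- mob_b * (p[i[dir]] - cls$pval[dir]) / f$dist[dir]
  g_o[dir] <- mob_o * (p[i[dir]] - cls$pval[dir]) / f$dist[dir]

  up <- function(g, cell_val, other_val) {
    ifelse(g > 0, cell_val, ifelse(g < 0, other_val,
                                   0.5 * (cell_val + other_val)))
  }
  s_o_face <- s_b_face <- numeric(nF)
  s_o_face[int] <- up(g_o[int], s_bolus[i[int]], s_bolus[j[int]])
  s_b_face[int] <- up(g_b[int], s_blood[i[int]], s_blood[j[int]])
  ves <- which(f$tag %in% "VESSEL" & cls$type == "dirichlet")
  far <- which(f$tag %in% "FAR" & cls$type == "dirichlet")
  s_o_face[ves] <- up(g_o[ves], s_bolus[i[ves]], params$s0)
  s_b_face[ves] <- up(g_b[ves], s_blood[i[ves]], 1 - params$s0)
  s_o_face[far] <- s_bolus[i[far]]
  s_b_face[far] <- s_blood[i[far]]

  list(g_blood = g_b, g_bolus = g_o,
       v_blood = g_b * s_b_face, v_bolus = g_o * s_o_face,
       s_bolus_face = s_o_face, s_blood_face = s_b_face)
}

#' Implicitly advance the bolus saturation
#'
#' Backward-Euler update of the bolus mass balance in fractional-flow form:
#' the conservative total Darcy face flux from the pressure solve is split
#' between the phases by the saturation-dependent fractional-flow function
#' `f(s) = lambda_bolus / (lambda_bolus + lambda_blood)` (first-order upwind,
#' implicit), with implicit capillary cross-diffusion and the implicit
#' hydrolysis sink. Equivalent to the phase-velocity form of the continuous
#' model, and monotone: the scheme keeps the saturation in \[0, 1\] without
#' clipping at any time step. The nonlinear system is solved by damped Newton
#' iteration. Vessel inflow carries the inflow saturation `s0`; the far
#' boundary is zero-gradient.
#'
#' @inheritParams solve_pressure
#' @param Qt per-face total volumetric Darcy fluxes (m^3/s, positive out of
#'   the owner cell), from the pressure solve (or prescribed).
#' @param dt time step (s), > 0.
#' @param tol scaled Newton residual tolerance.
#' @param max_iter maximum Newton iterations.
#' @return list with the new saturation `s`, the scaled residual norm
#'   `residual`, the Newton iteration count `iterations`, the per-face bolus
#'   volumetric fluxes `Q_bolus` (m^3/s, consistent with the converged
#'   saturations), and step mass-budget entries (kg): `mass_in`, `mass_out`
#'   (boundary), `mass_reacted`.
#' @export
advance_saturation <- function(mesh, s_bolus, Qt, params, schedule, t, dt,
                               far_bc = "dirichlet", tol = 1e-10,
                               max_iter = 25) {
  if (dt <= 0) abort("dt must be positive", class = "thermo_input_error")
  f <- mesh$faces
  cls <- classify_faces(mesh, schedule, t, params, far_bc)
  n <- mesh$ncell
  V <- mesh$volume
  phi <- params$phi
  g_eff <- params$gamma * params$epsilon * params$rho_dcacl / params$rho_bolus

  mob_o <- params$kappa_bolus / params$mu_bolus
  mob_b <- params$kappa_blood / params$mu_blood
  frac <- function(s) s * mob_o / (s * mob_o + (1 - s) * mob_b)
  dfrac <- function(s) mob_o * mob_b / (s * mob_o + (1 - s) * mob_b)^2
  pc_fun <- function(s) capillary_pressure(1 - s, params$pd, params$s_min)
  # d pc / d s_bolus, consistent with the smooth floor
  dpc_fun <- function(s) {
    se <- smooth_floor(1 - s, params$s_min)
    params$pd / se^2 * smooth_floor_deriv(1 - s, params$s_min)
  }

  i <- f$owner; j <- f$neighbor
  int <- which(is.na(f$tag))
  ves <- which(f$tag %in% "VESSEL" & cls$type == "dirichlet")
  far <- which(f$tag %in% "FAR" & cls$type == "dirichlet")
  ii <- i[int]; jj <- j[int]; Qi <- Qt[int]
  upc <- ifelse(Qi >= 0, ii, jj)          # upwind cell per interior face
  Tr <- f$area / f$dist

  s_in_ves <- params$s0
  f_in_ves <- frac(s_in_ves)

  # constitutive laws extended linearly (C1) outside [0, 1] so Newton sees a
  # globally smooth system; the converged solution lies inside the bounds
  clamp01 <- function(s) pmin(1, pmax(0, s))
  ext <- function(fun, dfun) {
    list(f = function(s) {
      sc <- clamp01(s)
      fun(sc) + dfun(sc) * (s - sc)
    },
    d = function(s) dfun(clamp01(s)))
  }
  frac_e <- ext(frac, dfrac)
  pc_e <- ext(pc_fun, dpc_fun)
  dcell0 <- function(s) frac(s) * (1 - s) * mob_b
  ddcell0 <- function(s) dfrac(s) * (1 - s) * mob_b - frac(s) * mob_b
  dcell_e <- ext(dcell0, ddcell0)

  residual_and_flux <- function(s) {
    fr <- frac_e$f(s)
    pc <- pc_e$f(s)
    # capillary cross-diffusion coefficient per interior face: donor-cell
    # (upstream in the capillary driving force) value of the degenerate
    # coefficient f * lambda_blood -- the monotone choice
    Dcell <- dcell_e$f(s)
    donor <- ifelse(pc[ii] >= pc[jj], ii, jj)
    Df <- Dcell[donor]
    Qo <- numeric(nrow(f))
    Qo[int] <- fr[upc] * Qi + Tr[int] * Df * (pc[ii] - pc[jj])
    Qo[ves] <- ifelse(Qt[ves] < 0, f_in_ves * Qt[ves], fr[i[ves]] * Qt[ves])
    Qo[far] <- fr[i[far]] * Qt[far]       # zero-gradient composition
    R <- phi * V / dt * (s - s_bolus) + phi * V * g_eff * s
    R <- R + tabulate_add(ii, Qo[int], n) - tabulate_add(jj, Qo[int], n)
    bnd <- c(ves, far)
    if (length(bnd)) R <- R + tabulate_add(i[bnd], Qo[bnd], n)
    list(R = R, Qo = Qo, fr = fr, Df = Df, donor = donor, pc = pc)
  }

  jacobian <- function(s, rf) {
    ti <- seq_len(n); tj <- seq_len(n)
    tx <- rep(phi * V / dt + phi * V * g_eff, n)
    # advective part: d/ds_up of f(s_up) * Qt
    dF <- frac_e$d(s)[upc] * Qi
    ti <- c(ti, ii, jj); tj <- c(tj, upc, upc); tx <- c(tx, dF, -dF)
    # capillary part, exact: Q = Tr * D(s_donor) * (pc_i - pc_j)
    dpci <- pc_e$d(s)[ii]; dpcj <- pc_e$d(s)[jj]
    dpc_diff <- rf$pc[ii] - rf$pc[jj]
    dD <- dcell_e$d(s)
    dDi <- ifelse(rf$donor == ii, dD[ii], 0)
    dDj <- ifelse(rf$donor == jj, dD[jj], 0)
    dQi_dsi <- Tr[int] * (dDi * dpc_diff + rf$Df * dpci)
    dQi_dsj <- Tr[int] * (dDj * dpc_diff - rf$Df * dpcj)
    ti <- c(ti, ii, jj, ii, jj)
    tj <- c(tj, ii, ii, jj, jj)
    tx <- c(tx, dQi_dsi, -dQi_dsi, dQi_dsj, -dQi_dsj)
    # boundary outflow composition
    dfr <- frac_e$d(s)
    for (bidx in list(ves, far)) {
      if (!length(bidx)) next
      ob <- i[bidx]
      is_far <- bidx %in% far
      dQ <- ifelse(Qt[bidx] > 0 | is_far, dfr[ob] * Qt[bidx], 0)
      ti <- c(ti, ob); tj <- c(tj, ob); tx <- c(tx, dQ)
    }
    Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  }

  s <- s_bolus
  denom <- max(phi * V / dt * sqrt(n), max(abs(Qt)), 1e-30)
  rf <- residual_and_flux(s)
  conv <- function(rf) sqrt(sum(rf$R^2)) / denom <= tol
  iter <- 0L
  while (!conv(rf) && iter < max_iter) {
    J <- jacobian(s, rf)
    delta <- tryCatch(as.numeric(Matrix::solve(J, -rf$R)),
                      error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) {
      abort("Newton linear solve failed in the saturation step",
            class = "thermo_timestep_failure")
    }
    # damped update with backtracking on the residual norm
    step <- 1
    repeat {
      s_try <- s + step * delta
      rf_try <- residual_and_flux(s_try)
      if (sqrt(sum(rf_try$R^2)) <= (1 - 1e-4 * step) * sqrt(sum(rf$R^2)) ||
          step < 1 / 256) break
      step <- step / 2
    }
    if (sqrt(sum(rf_try$R^2)) >= sqrt(sum(rf$R^2))) {
      abort("Newton iteration stagnated in the saturation step",
            class = "thermo_timestep_failure")
    }
    s <- s_try
    rf <- rf_try
    iter <- iter + 1L
  }
  if (!conv(rf)) {
    abort("saturation Newton iteration did not converge",
          class = "thermo_timestep_failure")
  }
  # bounds are maintained by the monotone scheme up to round-off
  if (min(s) < -1e-8 || max(s) > 1 + 1e-8) {
    abort("saturation left [0, 1] beyond round-off",
          class = "thermo_timestep_failure")
  }
  s <- pmin(1, pmax(0, s))
  rf <- residual_and_flux(s)
  rnorm <- sqrt(sum(rf$R^2)) / denom

  # step mass budget (kg) from the converged discrete fluxes
  bnd <- c(ves, far)
  Qb <- rf$Qo[bnd]
  mass_in <- sum(pmax(-Qb, 0)) * params$rho_bolus * dt
  mass_out <- sum(pmax(Qb, 0)) * params$rho_bolus * dt
  mass_reacted <- params$rho_bolus * phi * g_eff * V * sum(s) * dt

  list(s = s, residual = rnorm, iterations = iter, Q_bolus = rf$Qo,
       mass_in = mass_in, mass_out = mass_out, mass_reacted = mass_reacted)
}

#' Total bolus mass on the mesh
#'
#' `sum(phi * rho_bolus * s * V)` over cells: the conserved quantity of the
#' saturation equation in sealed, reaction-free runs.
#'
#' @inheritParams solve_pressure
#' @return mass in kg.
#' @export
bolus_mass <- function(mesh, s_bolus, params) {
  params$phi * params$rho_bolus * mesh$volume * sum(s_bolus)
}
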
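test_that("capillary pressure follows the regularized Brooks-Corey law", {
  pd <- 0.074 * atm_to_pa(1)
  expect_equal(capillary_pressure(1, pd), pd, tolerance = 1e-8)
  expect_equal(capillary_pressure(0.5, pd), 2 * pd, tolerance = 1e-6)
  # floor: capped near pd / s_min for vanishing blood saturation
  expect_equal(capillary_pressure(1e-6, pd, s_min = 1e-3), pd / 1e-3,
               tolerance = 0.01)
  # monotone non-increasing in blood saturation
  s <- seq(0, 1, by = 0.01)
  expect_true(all(diff(capillary_pressure(s, pd)) <= 0))
})

test_that("mobility is linear in saturation", {
  expect_equal(mobility(0, 5e-12, 8.9e-4), 0)
  expect_equal(mobility(1, 5e-12, 8.9e-4), 5e-12 / 8.9e-4)
  expect_equal(mobility(0.5, 5e-12, 8.9e-4),
               0.5 * mobility(1, 5e-12, 8.9e-4))
  expect_error(mobility(0.5, 5e-12, 0), class = "thermo_invalid_parameter")
})

test_that("1D pressure is linear between boundary values with uniform mobility", {
  p <- thermo_parameters(gamma = 0)   # no reaction volume source
  mesh <- mesh_1d(0.05, 50)
  sched <- injection_schedule(p)
  s <- rep(1, mesh$ncell)             # single mobile phase
  pr <- solve_pressure(mesh, s, p, sched, t = 1)
  # linear profile between p_injection (left) and p0 (right)
  x <- mesh$centers[, 1]
  expected <- p$p_injection + (p$p0 - p$p_injection) * x / 0.05
  expect_equal(pr, expected, tolerance = 1e-10)
  # constant Darcy flux along the domain (signed along +x via the face
  # orientation: velocities are stored positive outward from the owner)
  vel <- darcy_velocity(mesh, pr, s, p, sched, t = 1)
  vx <- vel$v_bolus * mesh$faces$nsign
  expect_lt(diff(range(vx)), 1e-9 * max(abs(vx)))
})

test_that("sparse pressure solve matches a dense direct solve", {
  p <- thermo_parameters()
  mesh <- tag_vessel(make_box_mesh(c(0.02, 0.02), c(8, 8)),
                     vessel_spec(matrix(c(0.01, 0), 1, 2), 3e-3))
  sched <- injection_schedule(p)
  s <- blob_saturation(mesh, peak = 0.6)
  sys <- thermoembo:::assemble_pressure_system(mesh, s, p, sched, t = 1)
  dense <- solve(as.matrix(sys$A), sys$b)
  sparse <- solve_pressure(mesh, s, p, sched, t = 1)
  expect_equal(sparse, as.numeric(dense), tolerance = 1e-10)
})

test_that("Darcy velocity reproduces hand arithmetic and flips with the gradient", {
  p <- thermo_parameters(gamma = 0)
  mesh <- mesh_1d(0.05, 50)
  sched <- injection_schedule(p)
  s <- rep(1, mesh$ncell)
  pr <- solve_pressure(mesh, s, p, sched, t = 1)
  vel <- darcy_velocity(mesh, pr, s, p, sched, t = 1)
  int <- is.na(mesh$faces$tag)
  hand <- (5e-12 / 0.70e-3) * (0.16 * atm_to_pa(1) / 0.05)
  expect_equal(mean(vel$v_bolus[int]), hand, tolerance = 1e-6)
  expect_equal(hand, 2.316e-3, tolerance = 1e-3)

  # uniform pressure: all velocities vanish
  v0 <- darcy_velocity(mesh, rep(p$p0, mesh$ncell), s, p,
                       no_injection(p), t = 1)
  expect_equal(max(abs(v0$v_bolus[int])), 0)
  # antisymmetry: reflecting the interior pressure flips interior velocities
  pref <- 2 * mean(pr) - pr
  vflip <- darcy_velocity(mesh, pref, s, p, sched, t = 1)
  expect_equal(vflip$g_bolus[int], -vel$g_bolus[int], tolerance = 1e-9)
})

test_that("uniform saturation decays at the effective reaction rate", {
  p <- thermo_parameters()
  mesh <- make_box_mesh(c(0.01, 0.01), c(4, 4))
  sched <- no_injection(p)
  Qt <- numeric(nrow(mesh$faces))
  s <- rep(0.8, mesh$ncell)
  dt <- 1
  for (k in 1:400) {
    s <- advance_saturation(mesh, s, Qt, p, sched, k * dt, dt,
                            far_bc = "noflow")$s
  }
  g_eff <- p$gamma * p$epsilon * p$rho_dcacl / p$rho_bolus
  exact <- 0.8 * exp(-g_eff * 400)
  expect_lt(max(abs(s - exact)) / exact, 0.005)

  # inert bolus: exactly unchanged
  p0 <- thermo_parameters(gamma = 0)
  s1 <- advance_saturation(mesh, rep(0.8, mesh$ncell), Qt, p0, sched, 0, 1,
                           far_bc = "noflow")$s
  expect_equal(s1, rep(0.8, mesh$ncell))
})

test_that("implicit saturation advection agrees with an explicit reference", {
  p <- params_advection()
  mesh <- mesh_1d(1, 100)
  sched <- injection_schedule(p, duration = 1e6)
  f <- mesh$faces
  q <- 5e-4                       # m^3/s; front speed q/phi = 1 cm/s
  Qt <- ifelse(is.na(f$tag), q,
               ifelse(f$tag == "VESSEL", -q, q))
  t_end <- 20
  s_imp <- rep(0, mesh$ncell)
  dt_i <- 0.025
  for (k in seq_len(t_end / dt_i)) {
    s_imp <- advance_saturation(mesh, s_imp, Qt, p, sched,
                                (k - 1) * dt_i, dt_i)$s
  }
  # explicit first-order upwind reference at tiny dt (brute-force oracle)
  h <- mesh$h
  dt_e <- 0.005
  s_exp <- rep(0, mesh$ncell)
  co <- dt_e * q / (p$phi * mesh$volume)
  for (k in seq_len(t_end / dt_e)) {
    upstream <- c(1, s_exp[-mesh$ncell])   # inflow carries s0 = 1
    s_exp <- s_exp - co * (s_exp - upstream)
  }
  expect_lt(mean(abs(s_imp - s_exp)), 1e-3)
})

test_that("sealed reaction-free transport conserves bolus mass exactly", {
  p <- thermo_parameters(gamma = 0)
  mesh <- make_box_mesh(c(0.02, 0.02), c(16, 16))
  sched <- no_injection(p)
  Qt <- swirl_fluxes(mesh)
  s <- blob_saturation(mesh)
  m0 <- bolus_mass(mesh, s, p)
  for (k in 1:40) {
    s <- advance_saturation(mesh, s, Qt, p, sched, k, 1,
                            far_bc = "noflow", tol = 1e-12)$s
  }
  expect_lt(abs(bolus_mass(mesh, s, p) - m0) / m0, 1e-10)
})

test_that("saturation stays in [0, 1] across time steps and flow regimes", {
  p <- thermo_parameters()
  mesh <- make_box_mesh(c(0.02, 0.02), c(12, 12))
  sched <- no_injection(p)
  Qt <- swirl_fluxes(mesh, amplitude = 1e-8)
  for (dt in c(0.1, 1, 10)) {
    s <- blob_saturation(mesh, peak = 0.95, width = 0.1)
    for (k in 1:20) {
      s <- advance_saturation(mesh, s, Qt, p, sched, k * dt, dt,
                              far_bc = "noflow")$s
      expect_true(all(s >= 0 & s <= 1))
    }
  }
})

test_that("reacting transport closes the discrete mass balance each step", {
  p <- thermo_parameters()
  mesh <- mesh_1d(0.05, 30)
  sched <- injection_schedule(p)
  cfg <- sim_config(mesh, p, sched, dt = 1, t_end = 40)
  sim <- run_simulation(cfg)
  led <- sim$ledger
  n <- nrow(led)
  resid <- led$bolus_mass[n] -
    (led$mass_in[n] - led$mass_out[n] - led$mass_reacted[n])
  expect_lt(abs(resid) / max(led$bolus_mass), 1e-9)
})
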
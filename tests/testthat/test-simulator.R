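test_that("injection schedules validate their window and pressures", {
  p <- thermo_parameters()
  sch <- injection_schedule(p)
  expect_equal(sch$duration, 25)
  expect_true(injection_active(sch, 0))
  expect_true(injection_active(sch, 24.9))
  expect_false(injection_active(sch, 25))
  expect_false(injection_active(no_injection(p), 0))
  expect_error(injection_schedule(p, p_injection = p$p0 / 2),
               class = "thermo_input_error")
  expect_error(injection_schedule(p, duration = -1),
               class = "thermo_input_error")
})

test_that("initialization gives ambient temperature, no bolus, resting pressure", {
  p <- thermo_parameters()
  mesh <- mesh_1d(0.02, 10)
  # injection not yet started: pressure relaxes to p0 everywhere
  cfg <- sim_config(mesh, p, injection_schedule(p, t_start = 100),
                    dt = 1, t_end = 200)
  st <- initialize_state(cfg)
  expect_equal(range(st$u), c(21, 21))
  expect_equal(bolus_mass(mesh, st$s_bolus, p), 0)
  expect_equal(st$p_blood, rep(p$p0, mesh$ncell), tolerance = 1e-12)

  expect_error(sim_config(mesh, p, dt = -1), class = "thermo_config_error")
  expect_error(sim_config(mesh, p, s_init = 2), class = "thermo_config_error")
})

test_that("an inert, uninjected state is a fixed point of the stepper", {
  p <- thermo_parameters(gamma = 0)
  mesh <- mesh_1d(0.02, 10)
  cfg <- sim_config(mesh, p, no_injection(p), dt = 1, t_end = 10)
  st <- initialize_state(cfg)
  st2 <- sim_step(st, cfg)
  expect_equal(st2$u, st$u, tolerance = 1e-13)
  expect_equal(st2$s_bolus, st$s_bolus)
})

test_that("two half steps and one full step agree to first order", {
  p <- thermo_parameters()
  mesh <- mesh_1d(0.05, 25)
  cfg <- sim_config(mesh, p, injection_schedule(p), dt = 1, t_end = 30)
  st <- initialize_state(cfg)
  for (k in 1:5) st <- sim_step(st, cfg, 1)

  one <- sim_step(st, cfg, 1)
  halves <- sim_step(sim_step(st, cfg, 0.5), cfg, 0.5)
  quarters <- st
  for (k in 1:4) quarters <- sim_step(quarters, cfg, 0.25)

  d1 <- max(abs(one$u - quarters$u))
  d2 <- max(abs(halves$u - quarters$u))
  expect_lt(d2, d1)          # refinement reduces the splitting error
  expect_lt(d1, 2)           # and the error is O(dt)-small on this scale
})

test_that("velocities are identically zero once the injection ends", {
  p <- thermo_parameters()
  mesh <- mesh_1d(0.03, 15)
  cfg <- sim_config(mesh, p, injection_schedule(p, duration = 5),
                    dt = 1, t_end = 12)
  sim <- run_simulation(cfg)
  expect_equal(max(abs(sim$state$Q_total)), 0)
  expect_equal(max(abs(sim$state$Q_bolus)), 0)
})

test_that("runs are deterministic and checkpoint on schedule", {
  p <- thermo_parameters()
  mesh <- mesh_1d(0.03, 15)
  cfg <- sim_config(mesh, p, injection_schedule(p, duration = 5),
                    dt = 1, t_end = 50, checkpoint_interval = 10)
  sim1 <- run_simulation(cfg)
  sim2 <- run_simulation(cfg)
  expect_identical(sim1$ledger, sim2$ledger)
  expect_identical(sim1$state$u, sim2$state$u)
  times <- vapply(sim1$checkpoints, `[[`, numeric(1), "time")
  expect_equal(times, c(0, 10, 20, 30, 40, 50))

  cfg0 <- sim_config(mesh, p, injection_schedule(p, duration = 5),
                     dt = 1, t_end = 0)
  sim0 <- run_simulation(cfg0)
  expect_length(sim0$checkpoints, 1L)
  expect_equal(sim0$checkpoints[[1]]$time, 0)
})

test_that("the ledger closes the bolus mass budget during delivery", {
  p <- thermo_parameters()
  mesh <- mesh_1d(0.05, 30)
  cfg <- sim_config(mesh, p, injection_schedule(p), dt = 1, t_end = 60)
  sim <- run_simulation(cfg)
  led <- sim$ledger
  n <- nrow(led)
  resid <- led$bolus_mass[n] -
    (led$mass_in[n] - led$mass_out[n] - led$mass_reacted[n])
  expect_lt(abs(resid) / max(led$bolus_mass), 1e-9)
  # injected volume is reported and positive once delivery has happened
  expect_gt(led$injected_volume[n], 0)
})

test_that("a sealed reacting run converts chemical energy into stored heat", {
  p <- thermo_parameters()
  mesh <- make_box_mesh(c(0.01, 0.01), c(4, 4))
  cfg <- sim_config(mesh, p, no_injection(p), dt = 1, t_end = 1200,
                    far_bc = "noflow", s_init = 0.5)
  sim <- run_simulation(cfg)
  led <- sim$ledger
  n <- nrow(led)
  # chemical energy released, from the model's closed-form reacted mass
  reacted_mass <- p$phi * p$rho_bolus * mesh$volume *
    sum(0.5 - sim$state$s_bolus)
  e_chem <- p$h_total / p$w_dcacl * reacted_mass
  expect_lt(abs(led$energy_stored[n] - e_chem) / e_chem, 0.01)
  expect_lt(abs(led$heat_released[n] - led$energy_stored[n]) /
              led$heat_released[n], 1e-9)
})

test_that("probe temperatures keep rising after the delivery window", {
  p <- thermo_parameters()
  mesh <- mesh_1d(0.05, 50)
  cfg <- sim_config(mesh, p, injection_schedule(p), dt = 1, t_end = 150,
                    checkpoint_interval = 5)
  sim <- run_simulation(cfg)
  ts <- probe_timeseries(sim, matrix(c(0.025, 0.04), ncol = 1))
  post <- ts[ts$time > 25, ]
  for (pr in unique(post$probe)) {
    u <- post$u[post$probe == pr]
    expect_true(all(diff(u) > 0))
  }
  # and bolus is still present (the reaction keeps heating)
  expect_gt(min(sim$state$s_bolus), 0)
})

test_that("simulation summaries and plots are well-formed", {
  p <- thermo_parameters()
  mesh <- mesh_1d(0.02, 10)
  cfg <- sim_config(mesh, p, injection_schedule(p, duration = 5),
                    dt = 1, t_end = 10)
  sim <- run_simulation(cfg)
  gl <- generics::glance(sim)
  expect_equal(gl$t_end, 10)
  expect_equal(gl$n_steps, 10L)
  expect_s3_class(generics::tidy(sim), "tbl_df")
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
})

test_that("VTK checkpoints are written as readable text", {
  p <- thermo_parameters()
  mesh <- mesh_1d(0.02, 10)
  cfg <- sim_config(mesh, p, injection_schedule(p, duration = 5),
                    dt = 1, t_end = 10, checkpoint_interval = 5)
  sim <- run_simulation(cfg)
  dir <- file.path(tempdir(), "thermoembo-vtk")
  write_checkpoints(sim, dir)
  files <- list.files(dir, pattern = "\\.vtk$")
  expect_length(files, length(sim$checkpoints))
  head <- readLines(file.path(dir, files[1]), n = 4)
  expect_equal(head[1], "# vtk DataFile Version 3.0")
  expect_true(file.exists(file.path(dir, "ledger.csv")))
  unlink(dir, recursive = TRUE)
})
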
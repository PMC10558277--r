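test_that("line profiles reproduce uniform and linear fields", {
  mesh <- make_box_mesh(c(0.05, 0.02), c(50, 10))
  uni <- rep(21, mesh$ncell)
  pr <- line_profile(uni, mesh, c(0.001, 0.01), c(0.049, 0.01), n = 25)
  expect_equal(pr$value, rep(21, 25))
  expect_equal(nrow(pr), 25L)
  expect_true(all(diff(pr$position_mm) > 0))

  lin <- 3 + 100 * mesh$centers[, 1]
  pr2 <- line_profile(lin, mesh, c(0.0005, 0.01), c(0.0495, 0.01), n = 30)
  expect_equal(pr2$value, 3 + 100 * seq(0.0005, 0.0495, length.out = 30),
               tolerance = 1e-10)

  expect_error(line_profile(uni, mesh, c(-0.01, 0.01), c(0.04, 0.01)),
               class = "thermo_input_error")
  expect_error(line_profile(uni, mesh, c(0.01, 0.01), c(0.04, 0.01), n = 1),
               class = "thermo_input_error")
})

test_that("nearest-cell and multilinear sampling differ by a one-cell bound", {
  mesh <- make_box_mesh(0.05, 50)
  smooth <- sin(2 * pi * mesh$centers[, 1] / 0.05)
  a <- line_profile(smooth, mesh, 0.002, 0.048, n = 101)
  b <- line_profile(smooth, mesh, 0.002, 0.048, n = 101, method = "nearest")
  # brute-force bound: max finite difference between adjacent cells
  bound <- max(abs(diff(smooth)))
  expect_lte(max(abs(a$value - b$value)), bound + 1e-12)
})

test_that("profile comparison reports difference and correlation statistics", {
  mesh <- make_box_mesh(0.05, 50)
  fld <- 21 + 30 * exp(-((mesh$centers[, 1] - 0.02) / 0.01)^2)
  a <- line_profile(fld, mesh, 0.001, 0.049, n = 20)
  cmp <- compare_profiles(a, a)
  expect_equal(cmp$mean_abs_diff, 0)
  expect_equal(cmp$max_abs_diff, 0)
  expect_equal(cmp$pearson_r, 1, tolerance = 1e-12)

  b <- a
  b$value <- a$value + 2
  cmp2 <- compare_profiles(b, a)
  expect_equal(cmp2$mean_abs_diff, 2)
  expect_equal(cmp2$max_abs_diff, 2)
  expect_equal(cmp2$pearson_r, 1, tolerance = 1e-12)

  # hand-computed Pearson on two fixed 5-point vectors
  x <- c(1, 3, 2, 5, 4); y <- c(2, 1, 4, 3, 5)
  pa <- tibble::tibble(position_mm = 1:5, value = x)
  pb <- tibble::tibble(position_mm = 1:5, value = y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cmp3 <- compare_profiles(pa, pb)
  expect_equal(cmp3$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(generics::glance(cmp3)$n, 5L)

  pz <- tibble::tibble(position_mm = 1:5, value = rep(1, 5))
  expect_error(compare_profiles(pa, pz), class = "thermo_zero_variance")
  expect_error(compare_profiles(pa, pb[1:3, ]), class = "thermo_input_error")
})

test_that("synthetic thermometry adds calibrated, reproducible noise", {
  p <- thermo_parameters()
  mesh <- mesh_1d(0.02, 10)
  cfg <- sim_config(mesh, p, injection_schedule(p, duration = 5),
                    dt = 1, t_end = 44.6, checkpoint_interval = 22.3)
  sim <- run_simulation(cfg)

  f1 <- synthesize_thermometry(sim, snr = 10, seed = 3)
  f2 <- synthesize_thermometry(sim, snr = 10, seed = 3)
  expect_identical(f1, f2)

  # snr -> infinity recovers the clean fields
  f3 <- synthesize_thermometry(sim, snr = 1e12, seed = 3)
  expect_equal(f3[[2]]$u, sim$checkpoints[[2]]$u, tolerance = 1e-8)

  # moment check on a large draw: sample sd within 1% of sigma_ref/snr
  big <- sim
  big$checkpoints <- list(list(time = 0, u = rep(0, 1e5)))
  fr <- synthesize_thermometry(big, snr = 10, frame_dt = 22.3, seed = 11)
  expect_lt(abs(sd(fr[[1]]$u) - 1) / 1, 0.01)
})

test_that("probe series are constant for constant fields and repeatable", {
  p <- thermo_parameters()
  mesh <- mesh_1d(0.02, 10)
  cfg <- sim_config(mesh, p, no_injection(p), dt = 1, t_end = 50,
                    checkpoint_interval = 10, far_bc = "noflow")
  sim <- run_simulation(cfg)  # gamma > 0 but s = 0: nothing happens
  ts <- probe_timeseries(sim, matrix(c(0.005, 0.005), ncol = 1))
  expect_equal(unique(ts$u), 21)
  expect_equal(ts$u[ts$probe == 1], ts$u[ts$probe == 2])
  expect_error(probe_timeseries(sim, matrix(0.5, 1, 1)),
               class = "thermo_input_error")
})

test_that("probe-fit pipeline recovers the configured hydrolysis rate", {
  # parameter set in which the bolus saturation (and hence the temperature
  # approach to steady state) decays exactly at gamma:
  # epsilon * rho_DCACl = rho_bolus
  p <- thermo_parameters(epsilon = 1, rho_dcacl = 1280, rho_bolus = 1280)
  mesh <- make_box_mesh(c(0.01, 0.01), c(2, 2))
  cfg <- sim_config(mesh, p, no_injection(p), dt = 1, t_end = 1200,
                    checkpoint_interval = 22.3, far_bc = "noflow",
                    s_init = 0.5)
  sim <- run_simulation(cfg)
  ts <- probe_timeseries(sim, matrix(c(0.005, 0.005), 1, 2))
  fit <- fit_hydrolysis_rate(ts$time, ts$u, baseline = 21)
  expect_lt(abs(fit$gamma_hat - p$gamma) / p$gamma, 0.10)
})
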
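#' Injection schedule
#'
#' Time-dependent boundary forcing at the vessel interface: a constant
#' injection pressure applied over a delivery window, with the bolus entering
#' as the only constituent at the upstream (hydrolysis) temperature. Outside
#' the window vessel faces seal and convective transport stops.
#'
#' @param params a [thermo_parameters()] set supplying the defaults.
#' @param t_start injection start time (s).
#' @param duration delivery window (s); 25 s by default.
#' @param p_injection injection pressure (Pa).
#' @param s0 inflow bolus saturation (1: pure bolus).
#' @param u0 inflow temperature (deg C); defaults to the calorimetric
#'   upstream temperature of `params`.
#' @return an `injection_schedule` list.
#' @export
injection_schedule <- function(params = thermo_parameters(),
                               t_start = 0, duration = 25,
                               p_injection = params$p_injection,
                               s0 = params$s0,
                               u0 = params$u0) {
  if (duration < 0) {
    abort("injection duration must be non-negative", class = "thermo_input_error")
  }
  if (duration > 0 && p_injection <= params$p0) {
    abort("p_injection must exceed p0 during injection",
          class = "thermo_input_error")
  }
  structure(list(t_start = t_start, duration = duration,
                 p_injection = p_injection, s0 = s0, u0 = u0),
            class = "injection_schedule")
}

#' Is the injection active at time t?
#'
#' @param schedule an [injection_schedule()].
#' @param t time (s); a step starting at `t` uses the state at `t`.
#' @return logical.
#' @export
injection_active <- function(schedule, t) {
  schedule$duration > 0 &&
    t >= schedule$t_start - 1e-12 &&
    t < schedule$t_start + schedule$duration - 1e-12
}

#' Simulation configuration
#'
#' Bundles the mesh, physical parameters, injection schedule, and time
#' stepping controls for [run_simulation()].
#'
#' @param mesh a [make_box_mesh()] mesh, usually with [tag_vessel()] applied.
#' @param params a [thermo_parameters()] set.
#' @param schedule an [injection_schedule()].
#' @param dt time step (s).
#' @param t_end final time (s); the default covers the 20-min monitoring
#'   window.
#' @param checkpoint_interval checkpoint spacing (s); the default matches one
#'   thermometry frame (22.3 s).
#' @param far_bc `"dirichlet"` (atmospheric far boundary) or `"noflow"`
#'   (sealed domain, for conservation studies).
#' @param s_init initial bolus saturation: a scalar or one value per cell
#'   (0 before delivery; nonzero for sealed reaction/conservation studies).
#' @param dt_min smallest dt the step-halving retry may reach.
#' @return a `sim_config` list.
#' @export
sim_config <- function(mesh, params = thermo_parameters(),
                       schedule = injection_schedule(params),
                       dt = 1, t_end = 1200, checkpoint_interval = 22.3,
                       far_bc = c("dirichlet", "noflow"),
                       s_init = 0, dt_min = 1e-3) {
  far_bc <- match.arg(far_bc)
  if (dt <= 0) abort("config field 'dt' must be positive",
                     class = "thermo_config_error")
  if (t_end < 0) abort("config field 't_end' must be non-negative",
                       class = "thermo_config_error")
  if (checkpoint_interval < dt) {
    abort("config field 'checkpoint_interval' must be at least dt",
          class = "thermo_config_error")
  }
  if (!inherits(mesh, "thermo_mesh")) {
    abort("config field 'mesh' must be a thermo_mesh",
          class = "thermo_config_error")
  }
  if (!length(s_init) %in% c(1L, mesh$ncell) ||
      any(s_init < 0 | s_init > 1)) {
    abort("config field 's_init' must be in [0, 1], length 1 or ncell",
          class = "thermo_config_error")
  }
  structure(list(mesh = mesh, params = params, schedule = schedule,
                 dt = dt, t_end = t_end,
                 checkpoint_interval = checkpoint_interval,
                 far_bc = far_bc, s_init = rep(s_init, length.out = mesh$ncell),
                 dt_min = dt_min),
            class = "sim_config")
}

#' Initialize the simulation state
#'
#' Ambient temperature everywhere, no bolus, and the pressure field solved
#' once for the initial boundary configuration (uniform `p0` when the
#' injection has not yet started).
#'
#' @param config a [sim_config()].
#' @return a `sim_state` list: `time`, per-cell `u`, `s_bolus`, `p_blood`,
#'   per-face velocities, and zeroed cumulative ledgers.
#' @export
initialize_state <- function(config) {
  mesh <- config$mesh
  params <- config$params
  s0f <- config$s_init %||% rep(0, mesh$ncell)
  u <- rep(params$u_init, mesh$ncell)
  if (injection_active(config$schedule, 0) || config$far_bc == "dirichlet") {
    p <- solve_pressure(mesh, s0f, params, config$schedule, 0, config$far_bc)
  } else {
    p <- rep(params$p0, mesh$ncell)
  }
  structure(list(time = 0, u = u, s_bolus = s0f, p_blood = p,
                 Q_total = numeric(nrow(mesh$faces)),
                 Q_bolus = numeric(nrow(mesh$faces)),
                 cum = list(mass_in = 0, mass_out = 0, mass_reacted = 0,
                            injected_volume = 0,
                            heat_released = 0, energy_stored = 0,
                            boundary_heat_in = 0)),
            class = "sim_state")
}

#' Advance the simulation by one operator-split implicit step
#'
#' The coupling order is flow first, then heat: solve the pressure equation,
#' evaluate Darcy face velocities, advance the bolus saturation implicitly,
#' and advance the temperature with the end-of-step saturations and
#' velocities. When the injection is inactive all velocities are identically
#' zero (the delivery drives the only convection in this model) and the flow
#' solve is skipped. On a step failure the step is retried with dt halved,
#' down to `config$dt_min`.
#'
#' @param state a `sim_state`.
#' @param config a [sim_config()].
#' @param dt step size (s); defaults to `config$dt`.
#' @return the advanced `sim_state`.
#' @export
sim_step <- function(state, config, dt = config$dt) {
  attempt <- function(dtt) {
    mesh <- config$mesh
    params <- config$params
    sched <- config$schedule
    t <- state$time
    active <- injection_active(sched, t)

    if (active) {
      sys <- assemble_pressure_system(mesh, state$s_bolus, params, sched, t,
                                      config$far_bc, p_prev = state$p_blood)
      p <- as.numeric(Matrix::solve(sys$A, sys$b))
      Qt <- total_face_flux(mesh, sys, p)
    } else {
      p <- state$p_blood
      Qt <- numeric(nrow(mesh$faces))
    }

    sat <- advance_saturation(mesh, state$s_bolus, Qt, params,
                              sched, t, dtt, config$far_bc)
    Qb <- Qt - sat$Q_bolus
    th <- advance_temperature(mesh, state$u, sat$s, Qb, sat$Q_bolus,
                              params, sched, t, dtt, config$far_bc)

    cum <- state$cum
    cum$mass_in <- cum$mass_in + sat$mass_in
    cum$mass_out <- cum$mass_out + sat$mass_out
    cum$mass_reacted <- cum$mass_reacted + sat$mass_reacted
    cum$injected_volume <- cum$injected_volume +
      sat$mass_in / params$rho_bolus
    cum$heat_released <- cum$heat_released + th$heat_released
    cum$energy_stored <- cum$energy_stored + th$energy_delta
    cum$boundary_heat_in <- cum$boundary_heat_in + th$boundary_in

    structure(list(time = t + dtt, u = th$u, s_bolus = sat$s, p_blood = p,
                   Q_total = Qt, Q_bolus = sat$Q_bolus,
                   cum = cum),
              class = "sim_state")
  }

  dtt <- dt
  repeat {
    out <- tryCatch(attempt(dtt), thermo_timestep_failure = function(e) e)
    if (!inherits(out, "error")) {
      if (dtt < dt) {  # finish the remainder of the requested step
        return(sim_step(out, config, dt - dtt))
      }
      return(out)
    }
    dtt <- dtt / 2
    if (dtt < config$dt_min) {
      abort(paste0("time step underflow at t = ", signif(state$time, 6),
                   " s (dt fell below ", config$dt_min, " s): ",
                   conditionMessage(out)),
            class = "thermo_simulation_failure")
    }
  }
}

#' Run the coupled simulation
#'
#' Steps the state from 0 to `t_end`, recording a checkpoint (temperature,
#' saturation, pressure) at the configured interval and a per-step ledger of
#' mass and energy balances. Deterministic for a given configuration.
#'
#' @param config a [sim_config()].
#' @return a `thermoembo_sim` object: `config`, `checkpoints` (list of
#'   `list(time, u, s_bolus, p_blood)`), `ledger` (a tibble with one row per
#'   step: time, temperature extrema, bolus mass and its budget terms, and
#'   the cumulative energy terms), and the final `state`.
#' @examples
#' mesh <- tag_vessel(make_box_mesh(0.02, 16),
#'                    vessel_spec(matrix(0, 1, 1), 1e-3))
#' cfg <- sim_config(mesh, dt = 1, t_end = 50)
#' sim <- run_simulation(cfg)
#' sim$ledger
#' @export
run_simulation <- function(config) {
  state <- initialize_state(config)
  mesh <- config$mesh
  params <- config$params

  checkpoints <- list(snapshot(state))
  next_cp <- config$checkpoint_interval
  rows <- list()

  while (state$time < config$t_end - 1e-9) {
    dt <- min(config$dt, config$t_end - state$time)
    state <- sim_step(state, config, dt)
    rows[[length(rows) + 1L]] <- ledger_row(state, mesh, params)
    if (state$time >= next_cp - 1e-9) {
      checkpoints[[length(checkpoints) + 1L]] <- snapshot(state)
      next_cp <- next_cp + config$checkpoint_interval
    }
  }
  if (length(checkpoints) == 0L ||
      checkpoints[[length(checkpoints)]]$time < state$time - 1e-9) {
    checkpoints[[length(checkpoints) + 1L]] <- snapshot(state)
  }

  ledger <- if (length(rows)) do.call(rbind, rows) else ledger_row(state, mesh, params)[0, ]
  structure(list(config = config, checkpoints = checkpoints,
                 ledger = as_tibble(ledger), state = state),
            class = "thermoembo_sim")
}

snapshot <- function(state) {
  list(time = state$time, u = state$u, s_bolus = state$s_bolus,
       p_blood = state$p_blood)
}

ledger_row <- function(state, mesh, params) {
  data.frame(
    time = state$time,
    u_min = min(state$u), u_mean = mean(state$u), u_max = max(state$u),
    bolus_mass = bolus_mass(mesh, state$s_bolus, params),
    mass_in = state$cum$mass_in,
    mass_out = state$cum$mass_out,
    mass_reacted = state$cum$mass_reacted,
    injected_volume = state$cum$injected_volume,
    heat_released = state$cum$heat_released,
    energy_stored = state$cum$energy_stored,
    boundary_heat_in = state$cum$boundary_heat_in
  )
}

#' @export
print.thermoembo_sim <- function(x, ...) {
  cat(sprintf("<thermoembo_sim> %d checkpoints to t = %.1f s on a %s-cell mesh\n",
              length(x$checkpoints), x$state$time,
              paste(x$config$mesh$cells, collapse = "x")))
  n <- nrow(x$ledger)
  if (n > 0) {
    cat(sprintf("  final u: min %.2f / mean %.2f / max %.2f C; bolus mass %.3g kg\n",
                x$ledger$u_min[n], x$ledger$u_mean[n], x$ledger$u_max[n],
                x$ledger$bolus_mass[n]))
  }
  invisible(x)
}
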
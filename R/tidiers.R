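#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
NULL

#' Tidy a hydrolysis kinetics fit
#'
#' @param x a [fit_hydrolysis_rate()] result.
#' @param ... unused.
#' @return a tibble with one row per fitted parameter (`uss`, `gamma`).
#' @method tidy hydrolysis_fit
#' @export
tidy.hydrolysis_fit <- function(x, ...) {
  tibble(term = c("uss", "gamma"),
         estimate = c(x$uss, x$gamma_hat))
}

#' One-row summary of a hydrolysis kinetics fit
#'
#' @inheritParams tidy.hydrolysis_fit
#' @return a one-row tibble: `uss`, `gamma`, `residual_rms`, `n`,
#'   `converged`, `degenerate`.
#' @method glance hydrolysis_fit
#' @export
glance.hydrolysis_fit <- function(x, ...) {
  tibble(uss = x$uss, gamma = x$gamma_hat, residual_rms = x$residual_norm,
         n = nrow(x$data), converged = x$converged, degenerate = x$degenerate)
}

#' @method autoplot hydrolysis_fit
#' @export
autoplot.hydrolysis_fit <- function(object, ...) {
  dat <- object$data
  tt <- seq(min(dat$time), max(dat$time), length.out = 200)
  fitdat <- data.frame(time = tt,
                       rise = object$uss * (1 - exp(-object$gamma_hat * tt)))
  ggplot(dat, aes(x = .data$time, y = .data$rise)) +
    geom_point() +
    geom_line(data = fitdat, colour = "firebrick") +
    labs(x = "time [s]", y = "temperature rise [°C]",
         title = sprintf("first-order kinetics fit: u_ss = %.1f °C, γ = %.3g 1/s",
                         object$uss, object$gamma_hat))
}

#' Tidy a profile comparison
#'
#' @param x a [compare_profiles()] result.
#' @param ... unused.
#' @return a tibble with one row per statistic.
#' @method tidy profile_comparison
#' @export
tidy.profile_comparison <- function(x, ...) {
  tibble(statistic = c("mean_abs_diff", "max_abs_diff", "pearson_r", "p_value"),
         value = c(x$mean_abs_diff, x$max_abs_diff, x$pearson_r, x$p_value))
}

#' One-row summary of a profile comparison
#'
#' @inheritParams tidy.profile_comparison
#' @return a one-row tibble.
#' @method glance profile_comparison
#' @export
glance.profile_comparison <- function(x, ...) {
  tibble(mean_abs_diff = x$mean_abs_diff, max_abs_diff = x$max_abs_diff,
         pearson_r = x$pearson_r, p_value = x$p_value, n = x$n)
}

#' Tidy a simulation: its per-step ledger
#'
#' @param x a [run_simulation()] result.
#' @param ... unused.
#' @return the ledger tibble (one row per time step).
#' @method tidy thermoembo_sim
#' @export
tidy.thermoembo_sim <- function(x, ...) x$ledger

#' One-row summary of a simulation run
#'
#' @inheritParams tidy.thermoembo_sim
#' @return a one-row tibble: final time, temperature extrema, bolus mass,
#'   injected volume, cumulative heat released and stored.
#' @method glance thermoembo_sim
#' @export
glance.thermoembo_sim <- function(x, ...) {
  n <- nrow(x$ledger)
  tibble(t_end = x$state$time,
         u_min = x$ledger$u_min[n], u_mean = x$ledger$u_mean[n],
         u_max = x$ledger$u_max[n],
         bolus_mass = x$ledger$bolus_mass[n],
         injected_volume = x$ledger$injected_volume[n],
         heat_released = x$ledger$heat_released[n],
         energy_stored = x$ledger$energy_stored[n],
         n_steps = n)
}

#' @method autoplot thermoembo_sim
#' @export
autoplot.thermoembo_sim <- function(object, ...) {
  led <- object$ledger
  ggplot(led, aes(x = .data$time)) +
    geom_line(aes(y = .data$u_max, colour = "max")) +
    geom_line(aes(y = .data$u_mean, colour = "mean")) +
    geom_line(aes(y = .data$u_min, colour = "min")) +
    labs(x = "time [s]", y = "temperature [°C]", colour = NULL,
         title = "domain temperature envelope")
}

#' @method autoplot thermo_profile
#' @export
autoplot.thermo_profile <- function(object, ...) {
  ggplot(as.data.frame(object), aes(x = .data$position_mm, y = .data$value)) +
    geom_line() +
    labs(x = "distance along profile [mm]", y = "value",
         title = "line profile")
}

#' @importFrom rlang .data
NULL
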
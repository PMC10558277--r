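#' Combined heat of reaction
#'
#' The heat released by DCACl hydrolysis and by the secondary reactions of
#' dichloroacetic acid with latent tissue buffers are treated as additive.
#'
#' @param h_dca heat of hydrolysis (J/mol).
#' @param h_salt heat of the secondary/neutralization reactions (J/mol).
#' @return combined heat of reaction (J/mol).
#' @examples
#' combined_heat(93e3, 45e3) # 138 kJ/mol
#' @export
combined_heat <- function(h_dca, h_salt) {
  stopifnot(is.finite(h_dca), is.finite(h_salt))
  h_dca + h_salt
}

#' Inter-phase mass exchange from hydrolysis
#'
#' Hydrolysis consumes the bolus and returns byproducts to the blood, so the
#' bolus sees a mass sink `q_bolus = -gamma * rho_DCACl * epsilon * phi * s`
#' and the blood the equal-and-opposite source.
#'
#' @param s_bolus bolus saturation field (dimensionless, in \[0, 1\]).
#' @param params a [thermo_parameters()] set.
#' @return bolus mass sink field, kg/m^3/s (non-positive).
#' @examples
#' p <- thermo_parameters()
#' bolus_mass_sink(1, p)   # about -0.034 kg/m^3/s
#' @export
bolus_mass_sink <- function(s_bolus, params) {
  stopifnot(all(s_bolus >= -1e-8 & s_bolus <= 1 + 1e-8))
  s_bolus <- pmin(1, pmax(0, s_bolus))
  -params$gamma * params$rho_dcacl * params$epsilon * params$phi * s_bolus
}

#' Volumetric heat source from hydrolysis
#'
#' Chemical bond energy converted to heat per unit volume and time:
#' `h * gamma * rho_DCACl * epsilon * phi * s / W_DCACl`.
#'
#' @inheritParams bolus_mass_sink
#' @return heat source field, W/m^3 (non-negative).
#' @examples
#' p <- thermo_parameters()
#' heat_source(1, p)   # about 3.2e4 W/m^3
#' @export
heat_source <- function(s_bolus, params) {
  if (params$w_dcacl == 0) {
    abort("w_dcacl must be non-zero", class = "thermo_invalid_parameter")
  }
  stopifnot(all(s_bolus >= -1e-8 & s_bolus <= 1 + 1e-8))
  s_bolus <- pmin(1, pmax(0, s_bolus))
  params$h_total * params$gamma * params$rho_dcacl * params$epsilon *
    params$phi * s_bolus / params$w_dcacl
}

#' Calorimetric upstream temperature
#'
#' The maximum temperature achievable by complete hydrolysis of the injected
#' DCACl in a reference tissue mass:
#' `u0 = u_init + h * n_DCACl / (m_tissue * c_tissue)`. Used as the inflow
#' temperature at the vessel interface.
#'
#' @param params a [thermo_parameters()] set (uses `u_init`, `h_total`,
#'   `n_dcacl`, `m_tissue`, `c_tissue`).
#' @return upstream temperature in deg C.
#' @examples
#' upstream_temperature(thermo_parameters())  # ~97.7 C
#' @export
upstream_temperature <- function(params) {
  if (params$m_tissue <= 0 || params$c_tissue <= 0) {
    abort("m_tissue and c_tissue must be strictly positive",
          class = "thermo_invalid_parameter")
  }
  params$u_init + params$h_total * params$n_dcacl /
    (params$m_tissue * params$c_tissue)
}

#' DCACl volume fraction of the bolus from solution concentration
#'
#' Converts the concentration of the delivered DCACl-in-oil solution into the
#' volume fraction `epsilon` the mixture model uses:
#' `epsilon = c\[mol/m^3\] * W / rho`.
#'
#' @param concentration DCACl concentration of the solution, mol/L.
#' @param w_dcacl molecular weight, kg/mol.
#' @param rho_dcacl density of pure DCACl, kg/m^3.
#' @return dimensionless volume fraction in \[0, 1\].
#' @examples
#' dcacl_volume_fraction(2, 0.147, 1532)  # ~0.192
#' @export
dcacl_volume_fraction <- function(concentration, w_dcacl, rho_dcacl) {
  stopifnot(concentration >= 0, w_dcacl > 0, rho_dcacl > 0)
  eps <- concentration * 1000 * w_dcacl / rho_dcacl
  if (eps > 1 + 1e-12) {
    abort("inconsistent solution: implied DCACl volume fraction exceeds 1",
          class = "thermo_inconsistent_solution")
  }
  min(eps, 1)
}

#' Fit the hydrolysis rate constant from a time-temperature curve
#'
#' Fits the first-order kinetic model `u(t) = u_ss * (1 - exp(-gamma * t))`
#' to the temperature rise above baseline by bounded nonlinear least squares.
#' This is how the hydrolysis time constant is estimated from thermometry
#' when calorimetric measurements are unavailable.
#'
#' Starting values are derived from the data: `u_ss` from the maximum
#' observed rise and `gamma` from the half-rise time.
#'
#' @param times sample times (s), strictly increasing, at least 3.
#' @param temps temperatures (deg C) at `times`; absolute if `baseline` is
#'   given (it is subtracted), otherwise already rise-above-baseline.
#' @param baseline baseline temperature (deg C) to subtract; default 0
#'   (temps are already rises).
#' @return a `hydrolysis_fit` object with fields `uss` (fitted steady-state
#'   rise, deg C), `gamma_hat` (1/s), `residual_norm` (RMS residual, deg C),
#'   `converged`, `degenerate`, and a `data` tibble; supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @examples
#' t <- seq(0, 1200, by = 22.3)
#' u <- 77 * (1 - exp(-2.33e-3 * t))
#' fit <- fit_hydrolysis_rate(t, u)
#' fit$gamma_hat
#' @export
fit_hydrolysis_rate <- function(times, temps, baseline = 0) {
  if (length(times) < 3 || length(temps) != length(times)) {
    abort("need at least 3 (time, temperature) samples of equal length",
          class = "thermo_input_error")
  }
  if (any(diff(times) <= 0)) {
    abort("times must be strictly increasing", class = "thermo_input_error")
  }
  rise <- temps - baseline

  out <- list(
    data = tibble(time = as.numeric(times), rise = as.numeric(rise)),
    baseline = baseline
  )

  # Degenerate flat signal: u_ss -> 0, rate unidentifiable.
  if (max(rise) <= 0 || sd(rise) == 0) {
    out$uss <- 0
    out$gamma_hat <- 0
    out$residual_norm <- sqrt(mean(rise^2))
    out$converged <- FALSE
    out$degenerate <- TRUE
    return(structure(out, class = "hydrolysis_fit"))
  }

  uss0 <- max(rise)
  t_half <- suppressWarnings(
    approx(rise, times, xout = uss0 / 2, ties = "ordered")$y
  )
  g0 <- if (is.finite(t_half) && t_half > 0) log(2) / t_half else 1 / max(times)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      rise ~ uss * (1 - exp(-g * time)),
      data = out$data,
      start = list(uss = uss0, g = g0),
      lower = c(uss = 0, g = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    abort(paste0("kinetics fit failed to converge: ", conditionMessage(fit),
                 " (last start: uss = ", signif(uss0, 4),
                 ", gamma = ", signif(g0, 4), ")"),
          class = "thermo_fit_failure")
  }

  cf <- coef(fit)
  out$uss <- unname(cf["uss"])
  out$gamma_hat <- unname(cf["g"])
  out$residual_norm <- sqrt(mean(stats::resid(fit)^2))
  out$converged <- fit$convInfo$isConv %||% TRUE
  out$degenerate <- FALSE
  structure(out, class = "hydrolysis_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hydrolysis_fit <- function(x, ...) {
  cat("<hydrolysis_fit>\n")
  cat(sprintf("  u_ss = %.3f C, gamma = %.4g 1/s, RMS residual = %.3g C\n",
              x$uss, x$gamma_hat, x$residual_norm))
  if (x$degenerate) cat("  (degenerate: flat signal, rate unidentifiable)\n")
  invisible(x)
}
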
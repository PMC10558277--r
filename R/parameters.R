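#' Physical and delivery parameters for a thermoembolization model
#'
#' Collects every constant the coupled flow/energy model needs: reaction
#' thermochemistry and kinetics of DCACl hydrolysis, per-constituent
#' (tissue, blood, bolus) thermal and flow properties, capillary and boundary
#' pressures, and the calorimetric quantities that fix the upstream
#' temperature. Defaults are the reference parameter set for ex vivo kidney
#' delivery of 2 mol/L DCACl in oil; tissue conductivity and density are
#' literature-typical soft-tissue values since only the tissue specific heat
#' is constrained by the reference set.
#'
#' Temperatures are handled in degrees Celsius throughout: the model is linear
#' in temperature, so the offset from kelvin cancels everywhere.
#'
#' @param phi porosity of the tissue (void volume fraction), dimensionless.
#' @param epsilon DCACl volume fraction within the bolus. Default is derived
#'   from `dcacl_molarity` via [dcacl_volume_fraction()] (about 0.192 for a
#'   2 mol/L solution).
#' @param gamma first-order hydrolysis rate constant (1/s): the rate at which
#'   DCACl escapes the oily solvent and reacts.
#' @param h_dca heat of the DCACl hydrolysis reaction (J/mol).
#' @param h_salt heat of the secondary/neutralization reactions (J/mol).
#' @param h_total combined heat of reaction (J/mol); defaults to
#'   `h_dca + h_salt` and must equal it when all three are supplied.
#' @param rho_dcacl DCACl density (kg/m^3).
#' @param w_dcacl DCACl molecular weight (kg/mol).
#' @param dcacl_molarity concentration of the delivered DCACl-in-oil solution
#'   (mol/L); only used to derive `epsilon` when that is not given.
#' @param rho_tissue,c_tissue,k_tissue tissue density (kg/m^3), specific heat
#'   (J/kg/K) and thermal conductivity (W/m/K).
#' @param rho_blood,c_blood,k_blood blood density, specific heat, conductivity.
#' @param mu_blood,kappa_blood blood viscosity (Pa s) and permeability (m^2).
#' @param rho_bolus,c_bolus,k_bolus bolus (DCACl + oil) density, specific heat,
#'   conductivity.
#' @param mu_bolus,kappa_bolus bolus viscosity (Pa s) and permeability (m^2).
#' @param pd displacement pressure of the Brooks-Corey capillary model (Pa).
#' @param p_injection injection pressure applied at the vessel interface (Pa).
#' @param p0 far-field (atmospheric) pressure (Pa).
#' @param u_init initial/ambient temperature (deg C).
#' @param s0 inflow bolus saturation at the vessel interface (the bolus enters
#'   as the only constituent, so 1 by default).
#' @param n_dcacl moles of injected DCACl (mol), for the calorimetric upstream
#'   temperature.
#' @param m_tissue reference tissue mass for the calorimetric estimate (kg).
#' @param s_min regularization floor for saturations inside the capillary
#'   pressure law (prevents division blow-up as blood saturation vanishes).
#' @return A `thermo_params` list with all fields above plus the derived
#'   `u0` (upstream temperature, deg C, from [upstream_temperature()]).
#' @examples
#' p <- thermo_parameters()
#' p$u0       # ~97.7 deg C
#' p$epsilon  # ~0.192
#' @export
thermo_parameters <- function(phi = 0.05,
                              epsilon = NULL,
                              gamma = 2.33e-3,
                              h_dca = 93e3,
                              h_salt = 45e3,
                              h_total = NULL,
                              rho_dcacl = 1532,
                              w_dcacl = 0.147,
                              dcacl_molarity = 2,
                              rho_tissue = 1050, c_tissue = 3600, k_tissue = 0.5,
                              rho_blood = 1045, c_blood = 3600, k_blood = 0.53,
                              mu_blood = 8.90e-4, kappa_blood = 5e-12,
                              rho_bolus = 1280, c_bolus = 1970, k_bolus = 0.15,
                              mu_bolus = 0.70e-3, kappa_bolus = 5e-12,
                              pd = 0.074 * .ATM,
                              p_injection = 1.16 * .ATM,
                              p0 = .ATM,
                              u_init = 21,
                              s0 = 1,
                              n_dcacl = 2e-3,
                              m_tissue = 1e-3,
                              s_min = 1e-3) {
  if (is.null(h_total)) h_total <- h_dca + h_salt
  if (abs(h_total - (h_dca + h_salt)) > 1e-9 * max(1, abs(h_total))) {
    abort("h_total must equal h_dca + h_salt (the reaction heats are additive)",
          class = "thermo_invalid_parameter")
  }
  if (is.null(epsilon)) {
    epsilon <- dcacl_volume_fraction(dcacl_molarity, w_dcacl, rho_dcacl)
  }

  p <- list(
    phi = phi, epsilon = epsilon, gamma = gamma,
    h_dca = h_dca, h_salt = h_salt, h_total = h_total,
    rho_dcacl = rho_dcacl, w_dcacl = w_dcacl,
    rho_tissue = rho_tissue, c_tissue = c_tissue, k_tissue = k_tissue,
    rho_blood = rho_blood, c_blood = c_blood, k_blood = k_blood,
    mu_blood = mu_blood, kappa_blood = kappa_blood,
    rho_bolus = rho_bolus, c_bolus = c_bolus, k_bolus = k_bolus,
    mu_bolus = mu_bolus, kappa_bolus = kappa_bolus,
    pd = pd, p_injection = p_injection, p0 = p0,
    u_init = u_init, s0 = s0,
    n_dcacl = n_dcacl, m_tissue = m_tissue, s_min = s_min
  )
  validate_thermo_params(p)
  p$u0 <- upstream_temperature(p)
  structure(p, class = "thermo_params")
}

validate_thermo_params <- function(p) {
  pos <- c("rho_dcacl", "w_dcacl",
           "rho_tissue", "c_tissue", "k_tissue",
           "rho_blood", "c_blood", "k_blood", "mu_blood", "kappa_blood",
           "rho_bolus", "c_bolus", "k_bolus", "mu_bolus", "kappa_bolus",
           "m_tissue", "s_min")
  for (f in pos) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      abort(paste0("parameter '", f, "' must be strictly positive"),
            class = "thermo_invalid_parameter")
    }
  }
  if (!(p$phi > 0 && p$phi < 1)) {
    abort("porosity phi must lie strictly in (0, 1)",
          class = "thermo_invalid_parameter")
  }
  if (p$epsilon < 0 || p$epsilon > 1) {
    abort("epsilon (DCACl volume fraction) must lie in [0, 1]",
          class = "thermo_invalid_parameter")
  }
  if (p$gamma < 0) {
    abort("gamma (hydrolysis rate) must be non-negative",
          class = "thermo_invalid_parameter")
  }
  if (p$s0 < 0 || p$s0 > 1) {
    abort("s0 (inflow saturation) must lie in [0, 1]",
          class = "thermo_invalid_parameter")
  }
  invisible(p)
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params>\n")
  cat(sprintf("  reaction : gamma = %.3g 1/s, h = %.0f kJ/mol (%.0f + %.0f), epsilon = %.3f\n",
              x$gamma, x$h_total / 1e3, x$h_dca / 1e3, x$h_salt / 1e3, x$epsilon))
  cat(sprintf("  tissue   : phi = %.3f, c = %.0f J/kg/K, k = %.2f W/m/K\n",
              x$phi, x$c_tissue, x$k_tissue))
  cat(sprintf("  pressures: p_inj = %.3f atm, p0 = %.3f atm, pd = %.3f atm\n",
              pa_to_atm(x$p_injection), pa_to_atm(x$p0), pa_to_atm(x$pd)))
  cat(sprintf("  thermal  : u_init = %.1f C, u0 = %.2f C\n", x$u_init, x$u0))
  invisible(x)
}
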
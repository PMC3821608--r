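#' Oxygen diffusion coefficient in water at 37 C (cm^2/s)
#'
#' Reference free-solution value used to bound the strut diffusivity sweep
#' and as the default rescaling target for oxygen estimates.
#' @export
D_W_OXYGEN <- 2.68e-5

#' Kinetic and transport constants of the scaffold growth model
#'
#' Bundles the Michaelis-Menten oxygen consumption, Monod proliferation and
#' transport parameters with their published defaults.  Values are stored in
#' the units stated below; solvers convert to SI internally.
#'
#' The `k_d` first-order decay rate is a model extension: capped Monod
#' growth alone cannot produce the transient bottom-surface density peak and
#' subsequent decline seen in the simulations this package reproduces, so a
#' constant per-capita loss (net doubling rate `r_g` - `k_d`) is the minimal
#' closure.  It defaults to a tenth of the maximum doubling rate and may be
#' set to 0, in which case density is non-decreasing and peak-time metrics
#' are undefined.
#'
#' @param v_max maximum cellular oxygen consumption rate, mol/cell/s.
#' @param k_m half-maximum-rate oxygen concentration, mol/m^3.
#' @param k Monod saturation constant, mol/m^3 (3 nmol/mL = 3e-3 mol/m^3).
#' @param c_0 maximum dissolved oxygen concentration, mol/m^3.
#' @param rho_0 seeding cell density, cells/m^3.
#' @param rho_max maximum (confluent) cell density, cells/m^3.
#' @param t_d minimum cell division time, hours; the maximum doubling rate
#'   is `r_g_max = 1 / t_d` per hour.
#' @param d_t oxygen diffusivity of the cell-culture domain, cm^2/s.
#' @param d_s oxygen diffusivity of the strut material, cm^2/s, in
#'   `[0, D_W_OXYGEN]`; the default is the 0.93 * D_w permeable-strut
#'   estimate for the nanofibrous material.
#' @param k_d first-order cell decay rate, per hour (see Details).
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(v_max = 3.3e-16, k_m = 3.79e-3, k = 3e-3,
                           c_0 = 0.1, rho_0 = 2.1e11, rho_max = 1.5e14,
                           t_d = 36.5, d_t = 2.0e-5,
                           d_s = 0.93 * D_W_OXYGEN,
                           k_d = 0.1 / t_d) {
  vals <- c(v_max = v_max, k_m = k_m, k = k, c_0 = c_0, rho_0 = rho_0,
            rho_max = rho_max, t_d = t_d, d_t = d_t, d_s = d_s, k_d = k_d)
  if (any(!is.finite(vals)) || any(vals < 0))
    ps_stop("permstrut_domain_error",
            "all kinetic parameters must be finite and non-negative")
  if (rho_0 > rho_max)
    ps_stop("permstrut_domain_error", "rho_0 must not exceed rho_max")
  if (d_s > D_W_OXYGEN * (1 + 1e-12))
    ps_stop("permstrut_domain_error",
            "strut diffusivity cannot exceed the free-water value")
  if (t_d <= 0)
    ps_stop("permstrut_domain_error", "t_d must be positive")
  structure(list(v_max = v_max, k_m = k_m, k = k, c_0 = c_0,
                 rho_0 = rho_0, rho_max = rho_max, t_d = t_d,
                 r_g_max = 1 / t_d, d_t = d_t, d_s = d_s,
                 d_w = D_W_OXYGEN, k_d = k_d),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  consumption: V_max = %.3g mol/cell/s, K_m = %.3g mol/m^3\n",
              x$v_max, x$k_m))
  cat(sprintf("  growth: t_d = %g h (r_g_max = %.4g /h), K = %.3g mol/m^3, k_d = %.4g /h\n",
              x$t_d, x$r_g_max, x$k, x$k_d))
  cat(sprintf("  transport: D_t = %.3g, D_s = %.3g cm^2/s; C_0 = %g mol/m^3\n",
              x$d_t, x$d_s, x$c_0))
  cat(sprintf("  densities: rho_0 = %.3g, rho_max = %.3g cells/m^3\n",
              x$rho_0, x$rho_max))
  invisible(x)
}
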
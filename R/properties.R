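#' Adjusted constants of the empirical property correlations
#'
#' The published sigma1-sigma6 (mN/m) and A1-A9 constants of the surface
#' tension and refractive-index correlations. A1-A4 are unit-carrying
#' conversion constants equal to 1 in the g/mL, cm3/mol, bar, mN/m, K unit
#' system used throughout this package.
#'
#' @return Named list with vectors `sigma` (length 6) and `a` (length 9).
#' @export
property_constants <- function() {
  list(
    sigma = c(393.4, -5.3e-5, -3.72e-2, -50.3, 1.132, 108.9),
    a = c(1, 1, 1, 1, 5.17e-2, -11.625, 2.27e-3, 1.3668, 25.89)
  )
}

#' Liquid density correlation for eutectic solvents
#'
#' \deqn{\rho_L = -1.13\times10^{-6} T_c^2 + 2.566\times10^{-3} T_c
#'   + 0.2376\,\omega^{0.2211} - 4.67\times10^{-4} V_c - 4.64\times10^{-4} T}
#' with \eqn{T_c} in K, \eqn{V_c} in cm3/mol and T in K; the result is in
#' g/mL. Exactly linear in `T` and `v_c`.
#'
#' @param t_c Critical temperature (K).
#' @param v_c Critical molar volume (cm3/mol).
#' @param omega Acentric factor (> 0; the fractional power is undefined for
#'   the intended branch otherwise).
#' @param t Temperature (K).
#' @return Density in g/mL.
#' @export
#' @examples
#' density_correlation(600, 500, 1, 298)
density_correlation <- function(t_c, v_c, omega, t) {
  if (any(t <= 0)) abort("t must be > 0", class = "eutectr_validation_error")
  if (any(omega <= 0)) {
    abort("omega must be > 0 (fractional power undefined)",
          class = "eutectr_validation_error")
  }
  -1.13e-6 * t_c^2 + 2.566e-3 * t_c + 0.2376 * omega^0.2211 -
    4.67e-4 * v_c - 4.64e-4 * t
}

#' Surface tension correlation for eutectic solvents
#'
#' The published equation is typeset with flattened term grouping; this
#' implementation adopts the reading under which every logarithm argument and
#' ratio is dimensionless given the published units of the conversion
#' constants A1-A4 (`grouping = "dimensional"`, the default):
#' \deqn{\sigma_L = \sigma_1\ln\rho + \sigma_2\,\omega\,P_c/P_{ref}
#'  + \sigma_3 T_c \ln\!\big(A_1\rho^2 (V_c + \sigma_4 A_2 \omega^2)\big)
#'  + \sigma_5 A_3 \frac{M_w\sqrt{T}}{P_c}\ln\!\Big(\frac{V_c\,\rho\,A_4}{\sqrt{T}}\Big)
#'  + \sigma_6}
#' An alternative reading (`"inverse_sqrt_t"`) divides the fourth term's
#' prefactor by T instead of multiplying by \eqn{\sqrt{T}}. Neither reading
#' reproduces the study's printed surface tensions from group-contribution
#' critical properties (see the methods vignette); both are surfaced so the
#' ambiguity is explicit rather than silently resolved.
#'
#' @param t_c,p_c,v_c,omega Mixture critical properties (K, bar, cm3/mol, -).
#' @param mw Mixture molar mass (g/mol).
#' @param rho Liquid density (g/mL), typically from [density_correlation()]
#'   at the same temperature; a measured density may be supplied instead.
#' @param t Temperature (K).
#' @param grouping `"dimensional"` (default) or `"inverse_sqrt_t"`.
#' @param constants Correlation constants, by default [property_constants()].
#' @param p_ref Reference pressure (bar), default 1.
#' @return Surface tension in mN/m.
#' @export
surface_tension_correlation <- function(t_c, p_c, v_c, omega, mw, rho, t,
                                        grouping = c("dimensional", "inverse_sqrt_t"),
                                        constants = property_constants(),
                                        p_ref = eutectr_constants()$p_ref) {
  grouping <- match.arg(grouping)
  s <- constants$sigma
  a <- constants$a
  if (any(rho <= 0)) {
    abort("surface tension: log argument rho must be > 0 (term 1)",
          class = "eutectr_validation_error")
  }
  arg3 <- a[1] * rho^2 * (v_c + s[4] * a[2] * omega^2)
  if (any(arg3 <= 0)) {
    abort("surface tension: log argument of the sigma3 term is non-positive",
          class = "eutectr_validation_error")
  }
  arg4 <- v_c * rho * a[4] / sqrt(t)
  if (any(arg4 <= 0)) {
    abort("surface tension: log argument of the sigma5 term is non-positive",
          class = "eutectr_validation_error")
  }
  pre4 <- if (grouping == "dimensional") {
    a[3] * mw * sqrt(t) / p_c
  } else {
    a[3] * mw / (sqrt(t) * p_c)
  }
  s[1] * log(rho) + s[2] * omega * p_c / p_ref +
    s[3] * t_c * log(arg3) + s[5] * pre4 * log(arg4) + s[6]
}

#' Refractive index correlation for eutectic solvents
#'
#' \deqn{n = A_5\omega^3 + A_6\,\omega^2/M_w + A_7 P_c + A_8 + A_9\,\omega/T}
#' The grouping (division by \eqn{M_w} and by T) is fixed by the published
#' units of \eqn{A_6} (mol/g) and \eqn{A_9} (K) and reproduces the study's
#' printed refractive indices to about 0.2% from group-contribution critical
#' properties.
#'
#' @param p_c Critical pressure (bar).
#' @param omega Acentric factor.
#' @param mw Molar mass (g/mol).
#' @param t Temperature (K).
#' @param constants Correlation constants, by default [property_constants()].
#' @return Refractive index (dimensionless), typically 1.3-1.6.
#' @export
#' @examples
#' refractive_index_correlation(25, 0, 150, 298) # reduces to A7*Pc + A8
refractive_index_correlation <- function(p_c, omega, mw, t,
                                         constants = property_constants()) {
  if (any(t <= 0)) abort("t must be > 0", class = "eutectr_validation_error")
  a <- constants$a
  a[5] * omega^3 + a[6] * omega^2 / mw + a[7] * p_c + a[8] + a[9] * omega / t
}

#' Mixture molar mass
#'
#' \deqn{M_w = (x_i M_{w,i} + x_j M_{w,j}) / (x_i + x_j)}
#'
#' @param mw_i,mw_j Pure-component molar masses (g/mol).
#' @param x_i,x_j Mole fractions (need not sum to 1; at least one positive).
#' @return Mixture molar mass in g/mol.
#' @export
#' @examples
#' mixture_mw(156.27, 154.25, 0.7, 0.3) # 155.66
mixture_mw <- function(mw_i, mw_j, x_i, x_j) {
  if (any(x_i + x_j <= 0)) {
    abort("x_i + x_j must be > 0", class = "eutectr_validation_error")
  }
  (x_i * mw_i + x_j * mw_j) / (x_i + x_j)
}

#' Percentage relative error
#'
#' \deqn{e_r = 100\,(\mathrm{theoretical}-\mathrm{experimental})/\mathrm{experimental}}
#'
#' @param theoretical,experimental Numeric vectors; `experimental` must be
#'   non-zero.
#' @return Signed percentage error.
#' @export
#' @examples
#' relative_error(1.1116, 0.9152) # 21.5
relative_error <- function(theoretical, experimental) {
  if (any(experimental == 0)) {
    abort("experimental value must be non-zero", class = "eutectr_validation_error")
  }
  100 * (theoretical - experimental) / experimental
}

#' Theoretical property report for binary systems
#'
#' Assembles, per system, the mixture critical properties (Modified
#' Lydersen-Joback-Reid plus the chosen combining rule), the theoretical
#' density, surface tension (both term groupings) and refractive index at
#' temperature `t`, and — when experimental values are supplied — the
#' percentage relative error of each property.
#'
#' @param systems A systems tibble (`label`, `comp_i`, `comp_j`, `x_i`), e.g.
#'   [terpene_systems()].
#' @param compounds A compound tibble, e.g. [terpene_compounds()].
#' @param t Temperature (K), default 298.
#' @param experimental Optional long tibble `label`, `property`, `experimental`
#'   (properties named `density_g_mL`, `surface_tension_mN_m`,
#'   `refractive_index`), e.g. [terpene_measured_properties()].
#' @param mixing_rule Passed to [mix_critical_properties()].
#' @param omega_method Passed to [estimate_critical_properties()].
#' @return A long tibble: `label`, `t_K`, `property`, `theoretical`,
#'   `experimental`, `e_r_pct` (the last two absent if no experimental data),
#'   plus `sigma_alternative` rows carried in the `property` key
#'   (`surface_tension_alt_mN_m`) so both readings are visible.
#' @export
#' @examples
#' property_report(terpene_systems(), terpene_compounds())
property_report <- function(systems, compounds, t = 298,
                            experimental = NULL,
                            mixing_rule = c("lee_kesler", "linear"),
                            omega_method = c("rudkin", "edmister")) {
  mixing_rule <- match.arg(mixing_rule)
  omega_method <- match.arg(omega_method)
  cp <- estimate_critical_properties(compounds, omega_method = omega_method)
  rows <- lapply(seq_len(nrow(systems)), function(i) {
    sys <- systems[i, ]
    pair <- cp[match(c(sys$comp_i, sys$comp_j), cp$name), ]
    if (anyNA(pair$name)) {
      abort(paste0("system '", sys$label, "': compound missing from registry"),
            class = "eutectr_validation_error")
    }
    mix <- mix_critical_properties(pair, c(sys$x_i, 1 - sys$x_i), rule = mixing_rule)
    mw <- mixture_mw(pair$mw[1], pair$mw[2], sys$x_i, 1 - sys$x_i)
    rho <- density_correlation(mix$t_c_K, mix$v_c_cm3_mol, mix$omega, t)
    sig <- surface_tension_correlation(mix$t_c_K, mix$p_c_bar, mix$v_c_cm3_mol,
                                       mix$omega, mw, rho, t)
    sig_alt <- surface_tension_correlation(mix$t_c_K, mix$p_c_bar, mix$v_c_cm3_mol,
                                           mix$omega, mw, rho, t,
                                           grouping = "inverse_sqrt_t")
    n <- refractive_index_correlation(mix$p_c_bar, mix$omega, mw, t)
    tibble(
      label = sys$label, t_K = t,
      property = c("mw_g_mol", "density_g_mL", "surface_tension_mN_m",
                   "surface_tension_alt_mN_m", "refractive_index"),
      theoretical = c(mw, rho, sig, sig_alt, n)
    )
  })
  report <- bind_rows(rows)
  if (!is.null(experimental)) {
    report <- left_join(report, experimental[, c("label", "property", "experimental")],
                        by = c("label", "property")) |>
      mutate(e_r_pct = ifelse(is.na(.data$experimental), NA_real_,
                              relative_error(.data$theoretical,
                                             ifelse(is.na(.data$experimental), 1,
                                                    .data$experimental))))
  }
  report
}
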
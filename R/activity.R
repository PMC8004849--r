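#' Activity-coefficient model objects
#'
#' An activity model maps (composition, temperature, compound pair) to
#' liquid-phase activity coefficients. Three models are provided:
#' `activity_ideal()` (\eqn{\gamma \equiv 1}), `activity_unifac()`
#' (group-contribution, see [unifac_gamma()]) and `activity_margules()`
#' (two-parameter Margules; an analytic non-ideal model used chiefly as a
#' test oracle). All satisfy \eqn{\gamma_i \to 1} as \eqn{x_i \to 1} and are
#' continuous in `x` and `t`.
#'
#' @param subgroups,interactions UNIFAC parameter tables; defaults are the
#'   shipped Hansen-1991 VLE revision.
#' @param a12,a21 Margules parameters in J/mol.
#' @return An object of class `activity_model`.
#' @name activity_model
NULL

new_activity_model <- function(id, fun, ...) {
  structure(list(id = id, fun = fun, ...), class = "activity_model")
}

#' @rdname activity_model
#' @export
activity_ideal <- function() {
  new_activity_model("ideal", function(x, t, compounds) rep(1, length(x)))
}

#' @rdname activity_model
#' @export
activity_unifac <- function(subgroups = unifac_subgroups(),
                            interactions = unifac_interactions()) {
  cache <- new.env(parent = emptyenv())
  fun <- function(x, t, compounds) {
    key <- paste(compounds$name, collapse = "|")
    setup <- cache[[key]]
    if (is.null(setup)) {
      setup <- unifac_setup(compounds, subgroups, interactions)
      cache[[key]] <- setup
    }
    exp(unifac_ln_gamma_c(x, setup) + unifac_ln_gamma_r(x, t, setup))
  }
  new_activity_model("unifac", fun, table_version = unifac_table_version())
}

#' @rdname activity_model
#' @export
activity_margules <- function(a12, a21) {
  fun <- function(x, t, compounds) {
    margules_gamma(x[1], t, a12, a21)
  }
  new_activity_model(sprintf("margules(%g,%g)", a12, a21), fun,
                     a12 = a12, a21 = a21)
}

#' Evaluate an activity model
#'
#' @param model An `activity_model`.
#' @param x Composition vector summing to 1 (component i first).
#' @param t Temperature (K).
#' @param compounds Two-row compound tibble (needed by UNIFAC; ignored by
#'   the ideal and Margules models).
#' @return Vector of activity coefficients.
#' @export
#' @examples
#' activity_coefficients(activity_ideal(), c(0.5, 0.5), 298)
activity_coefficients <- function(model, x, t, compounds = NULL) {
  stopifnot(inherits(model, "activity_model"))
  if (abs(sum(x) - 1) > 1e-9) {
    abort("composition must sum to 1", class = "eutectr_validation_error")
  }
  g <- model$fun(x, t, compounds)
  stopifnot(all(is.finite(g)), all(g > 0))
  g
}

#' @export
print.activity_model <- function(x, ...) {
  cat("<activity_model:", x$id, ">\n")
  invisible(x)
}

#' Two-parameter Margules activity coefficients
#'
#' \deqn{RT\ln\gamma_1 = (A_{12} + 2(A_{21}-A_{12})x_1)\,x_2^2}
#' \deqn{RT\ln\gamma_2 = (A_{21} + 2(A_{12}-A_{21})x_2)\,x_1^2}
#' Closed-form, so it serves as the analytic non-ideal oracle for the
#' solid-liquid-equilibrium solvers; \eqn{A_{12}=A_{21}=0} recovers the
#' ideal model.
#'
#' @param x1 Mole fraction of component 1 (scalar or vector).
#' @param t Temperature (K).
#' @param a12,a21 Margules parameters (J/mol); negative values give
#'   negative deviation (\eqn{\gamma < 1}).
#' @return If `x1` is scalar, `c(gamma1, gamma2)`; otherwise a two-column
#'   matrix.
#' @export
#' @examples
#' margules_gamma(0.5, 300, -1000, -1000)
margules_gamma <- function(x1, t, a12, a21) {
  r_gas <- eutectr_constants()$r_gas
  x2 <- 1 - x1
  g1 <- exp((a12 + 2 * (a21 - a12) * x1) * x2^2 / (r_gas * t))
  g2 <- exp((a21 + 2 * (a12 - a21) * x2) * x1^2 / (r_gas * t))
  if (length(x1) == 1) c(g1, g2) else cbind(g1, g2)
}

#' Activity coefficients over a composition grid
#'
#' @param model An `activity_model`.
#' @param compounds Two-row compound tibble.
#' @param x_grid Mole fractions of component i.
#' @param t Temperature (K), scalar or one per grid point.
#' @return Tibble `x_i`, `t_K`, `gamma_i`, `gamma_j`, `model`.
#' @export
activity_grid <- function(model, compounds, x_grid, t) {
  t <- rep_len(t, length(x_grid))
  g <- t(vapply(seq_along(x_grid), function(k) {
    activity_coefficients(model, c(x_grid[k], 1 - x_grid[k]), t[k], compounds)
  }, numeric(2)))
  tibble(x_i = x_grid, t_K = t, gamma_i = g[, 1], gamma_j = g[, 2],
         model = model$id)
}
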
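#' Fit an NMR chemical-shift temperature coefficient
#'
#' The temperature coefficient of an exchangeable (hydroxyl) proton is the
#' slope of the ordinary-least-squares line of chemical shift versus
#' temperature. In nonpolar media a coefficient more negative than
#' -0.005 ppm/K indicates intermolecular hydrogen bonding, one less negative
#' than -0.003 ppm/K indicates intramolecular hydrogen bonding; slopes in
#' between (boundaries included) are reported as indeterminate.
#'
#' @param data A data frame with one shift series: temperature and chemical
#'   shift columns.
#' @param t,delta Column names (tidy-eval) holding temperature (K) and
#'   chemical shift (ppm); defaults `t_K`, `delta_ppm`.
#' @param label Optional series label stored on the result.
#' @return An object of class `tcoeff_fit` with elements `t_coeff`
#'   (ppm/K), `intercept` (ppm), `r_squared`, `classification`, `n`, `data`.
#' @export
#' @examples
#' series <- synthetic_nmr_series(-0.015, 10, seq(298, 323, 5), 0.003, seed = 1)
#' fit <- fit_tcoeff(series)
#' tidy(fit)
fit_tcoeff <- function(data, t = "t_K", delta = "delta_ppm", label = NULL) {
  t_col <- rlang::as_name(rlang::enquo(t)) %||% "t_K"
  d_col <- rlang::as_name(rlang::enquo(delta)) %||% "delta_ppm"
  tv <- data[[t_col]]
  dv <- data[[d_col]]
  if (is.null(tv) || is.null(dv)) {
    abort(paste0("columns '", t_col, "' and '", d_col, "' required"),
          class = "eutectr_format_error")
  }
  if (length(tv) < 3) {
    abort("a temperature-coefficient fit needs at least 3 points",
          class = "eutectr_validation_error")
  }
  if (stats::var(tv) == 0) {
    abort("zero temperature variance: slope is undefined",
          class = "eutectr_validation_error")
  }
  fit <- lm(dv ~ tv)
  # summary() warns on exactly collinear (noiseless) input; the slope and
  # intercept are still exact there
  smry <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  r2 <- if (stats::var(dv) == 0) 1 else smry$r.squared
  structure(list(
    t_coeff = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    std_error = smry$coefficients[2, "Std. Error"],
    classification = classify_hbond(slope),
    n = length(tv),
    label = label,
    data = tibble(t_K = tv, delta_ppm = dv)
  ), class = "tcoeff_fit")
}

#' @export
print.tcoeff_fit <- function(x, ...) {
  cat(sprintf("T_coeff = %.4g ppm/K (r^2 = %.4f, n = %d): %s\n",
              x$t_coeff, x$r_squared, x$n, x$classification))
  invisible(x)
}

#' @rdname fit_tcoeff
#' @param x A `tcoeff_fit`.
#' @param ... Unused.
#' @method tidy tcoeff_fit
#' @export
tidy.tcoeff_fit <- function(x, ...) {
  tibble(label = x$label %||% NA_character_, t_coeff_ppm_K = x$t_coeff,
         intercept_ppm = x$intercept, r_squared = x$r_squared,
         classification = x$classification)
}

#' @rdname fit_tcoeff
#' @method glance tcoeff_fit
#' @export
glance.tcoeff_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, std_error = x$std_error, n = x$n)
}

#' @rdname fit_tcoeff
#' @param object A `tcoeff_fit`.
#' @method autoplot tcoeff_fit
#' @export
autoplot.tcoeff_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$t_K, y = .data$delta_ppm)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.5) +
    labs(x = "T (K)", y = expression(delta ~ "(ppm)"),
         subtitle = sprintf("T_coeff = %.4g ppm/K (%s)",
                            object$t_coeff, object$classification)) +
    theme_minimal()
}

#' Classify hydrogen-bond type from a temperature coefficient
#'
#' @param t_coeff Temperature coefficient(s) in ppm/K; must be finite.
#' @param thresholds Length-2 numeric `c(inter, intra)`: slopes below the
#'   first are intermolecular, above the second intramolecular; the closed
#'   interval in between (boundaries included) is indeterminate. Defaults
#'   `c(-0.005, -0.003)`.
#' @return Character vector in
#'   `{"intermolecular", "intramolecular", "indeterminate"}`.
#' @export
#' @examples
#' classify_hbond(c(-0.0212, -0.002, -0.004))
classify_hbond <- function(t_coeff, thresholds = c(-0.005, -0.003)) {
  stopifnot(all(is.finite(t_coeff)), thresholds[1] <= thresholds[2])
  dplyr::case_when(
    t_coeff < thresholds[1] ~ "intermolecular",
    t_coeff > thresholds[2] ~ "intramolecular",
    TRUE ~ "indeterminate"
  )
}

#' Read NMR shift series from a CSV file
#'
#' Expects a header and columns `t_K` and `delta_ppm`; an optional `label`
#' column separates multiple series in one file.
#'
#' @param path CSV file path.
#' @return A tibble; fit each series with [fit_tcoeff()].
#' @export
read_nmr_series <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "eutectr_format_error")
  }
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
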
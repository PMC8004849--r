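#' Solid-liquid equilibrium of a binary eutectic system
#'
#' The liquidus of component i obeys the simplified solid-liquid-equilibrium
#' relation (heat-capacity change on melting neglected)
#' \deqn{\ln(x_i^L \gamma_i^L) = \frac{\Delta H_{fus,i}}{R}
#'   \left(\frac{1}{T_{fus,i}} - \frac{1}{T}\right)}
#' which is the algebraic equivalent of the printed form
#' \eqn{\ln(x\gamma) = \frac{\Delta H_{fus}}{RT}(T/T_{fus} - 1)}.
#' The eutectic point is where the two liquidus branches intersect, i.e.
#' where the branch mole fractions sum to one.
#'
#' @name sle
NULL

# right-hand side of the liquidus relation; dh_fus stored in kJ/mol.
liquidus_rhs <- function(t_fus, dh_fus_kJ_mol, t) {
  dh_fus_kJ_mol * 1000 / eutectr_constants()$r_gas * (1 / t_fus - 1 / t)
}

# Solve x on the liquidus of one branch at fixed T.
# component: 1 (comp_i of the pair) or 2 (comp_j).
solve_branch_x <- function(pair, component, t, model,
                           damping = 0.5, max_iter = 200, tol = 1e-10) {
  t_fus <- pair$t_fus_K[component]
  rhs <- liquidus_rhs(t_fus, pair$dh_fus_kJ_mol[component], t)
  x <- min(exp(rhs), 1)  # ideal solution as starting point (exact if gamma = 1)
  if (identical(model$id, "ideal")) {
    return(list(x = x, residual = 0, converged = TRUE))
  }
  gamma_at <- function(xc) {
    comp <- if (component == 1) c(xc, 1 - xc) else c(1 - xc, xc)
    activity_coefficients(model, comp, t, pair)[component]
  }
  resid <- Inf
  for (iter in seq_len(max_iter)) {
    g <- gamma_at(x)
    target <- exp(rhs) / g
    x_new <- (1 - damping) * x + damping * min(max(target, 1e-15), 1)
    resid <- log(x_new * gamma_at(x_new)) - rhs
    x <- x_new
    if (abs(resid) < tol) {
      return(list(x = x, residual = resid, converged = TRUE))
    }
  }
  # fall back on a bracketed solve before giving up
  f <- function(xc) log(xc) + log(gamma_at(xc)) - rhs
  lo <- 1e-12
  hi <- 1 - 1e-12
  if (f(lo) * f(hi) <= 0) {
    root <- uniroot(f, c(lo, hi), tol = 1e-14)
    return(list(x = root$root, residual = f(root$root), converged = TRUE))
  }
  abort(paste0("liquidus composition solve did not converge at T = ", signif(t, 6),
               " K (residuals at brackets: ", signif(f(lo), 3), ", ",
               signif(f(hi), 3), ")"),
        class = "eutectr_solver_error")
}

#' Liquidus composition at a temperature
#'
#' Solves the liquidus relation of one component of a binary pair for the
#' liquid mole fraction `x` at temperature `t`. The ideal model has the
#' closed form \eqn{x = \exp[(\Delta H_{fus}/R)(1/T_{fus} - 1/T)]};
#' non-ideal models are solved by damped successive substitution
#' (damping 0.5, at most 200 iterations, residual below 1e-10) with a
#' bracketed fallback.
#'
#' @param pair Two-row compound tibble (see [system_pair()]).
#' @param t Temperature (K); must satisfy `0 < t <= t_fus` of the component.
#' @param component Which branch: `"i"` (first row, default) or `"j"`.
#' @param model An `activity_model`, default ideal.
#' @return The liquid mole fraction of the branch's component.
#' @export
#' @examples
#' pair <- system_pair(terpene_compounds(), "menthol", "borneol")
#' liquidus_x_at_t(pair, 289.8)            # menthol branch, about 0.695
#' liquidus_x_at_t(pair, 289.8, "j")       # borneol branch, about 0.303
liquidus_x_at_t <- function(pair, t, component = c("i", "j"),
                            model = activity_ideal()) {
  component <- match.arg(component)
  k <- if (component == "i") 1L else 2L
  if (t <= 0 || t > pair$t_fus_K[k] + 1e-9) {
    abort(paste0("t must be in (0, T_fus] = (0, ", pair$t_fus_K[k], "]"),
          class = "eutectr_validation_error")
  }
  solve_branch_x(pair, k, t, model)$x
}

#' Liquidus temperature at a composition
#'
#' Inverse of [liquidus_x_at_t()]: the temperature at which a liquid of
#' composition `x` (mole fraction of the branch's component) is in
#' equilibrium with that pure solid. Solved by bracketed root finding on
#' T in `[floor_t, T_fus]`.
#'
#' @inheritParams liquidus_x_at_t
#' @param x Mole fraction of the branch's component in the liquid.
#' @param floor_t Lower temperature bound (K), default 150.
#' @return Temperature in K.
#' @export
liquidus_t_at_x <- function(pair, x, component = c("i", "j"),
                            model = activity_ideal(), floor_t = 150) {
  component <- match.arg(component)
  k <- if (component == "i") 1L else 2L
  t_fus <- pair$t_fus_K[k]
  if (x >= 1 - 1e-12) return(t_fus)
  g <- function(t) {
    comp <- if (k == 1) c(x, 1 - x) else c(1 - x, x)
    gam <- activity_coefficients(model, comp, t, pair)[k]
    log(x * gam) - liquidus_rhs(t_fus, pair$dh_fus_kJ_mol[k], t)
  }
  if (g(floor_t) < 0) {
    abort(paste0("no liquidus temperature above the floor (", floor_t,
                 " K) for x = ", x), class = "eutectr_solver_error")
  }
  uniroot(g, c(floor_t, t_fus), tol = 1e-8)$root
}

#' Locate the eutectic point of a binary system
#'
#' Finds `(x_e, t_e)` such that the two liquidus branch mole fractions sum
#' to one, by bracketed root finding (Brent) on T over
#' `[floor_t, min(T_fus) - eps]` with an inner composition solve per branch.
#' Both liquidus residuals at the solution are checked against `tol`.
#'
#' @param pair Two-row compound tibble; `x_e` refers to the first row's
#'   component.
#' @param model An `activity_model`, default ideal.
#' @param floor_t Lower temperature bound (K), default 150 (sub-200 K
#'   eutectics are physically in scope for strongly non-ideal pairs).
#' @param tol Acceptance tolerance on the liquidus residuals, default 1e-8.
#' @return An object of class `eutectic_point` with elements `x_e`, `t_e`,
#'   `model`, `converged`, `residuals`, `pair_names`, `label`.
#' @export
#' @examples
#' pair <- system_pair(terpene_compounds(), "menthol", "borneol")
#' find_eutectic(pair)                      # 289.9 K, x about 0.697
#' find_eutectic(pair, activity_unifac())   # 290.0 K
find_eutectic <- function(pair, model = activity_ideal(), floor_t = 150,
                          tol = 1e-8) {
  t_max <- min(pair$t_fus_K) - 1e-6
  f <- function(t) {
    solve_branch_x(pair, 1L, t, model)$x + solve_branch_x(pair, 2L, t, model)$x - 1
  }
  f_lo <- f(floor_t)
  f_hi <- f(t_max)
  if (f_lo * f_hi > 0) {
    abort(paste0("liquidus branches do not cross in [", floor_t, ", ",
                 signif(t_max, 6), "] K (branch sums - 1: ", signif(f_lo, 3),
                 ", ", signif(f_hi, 3), "); consider lowering floor_t"),
          class = "eutectr_solver_error")
  }
  t_e <- uniroot(f, c(floor_t, t_max), tol = 1e-8, f.lower = f_lo,
                 f.upper = f_hi)$root
  x_i <- solve_branch_x(pair, 1L, t_e, model)$x
  x_j <- solve_branch_x(pair, 2L, t_e, model)$x
  gam <- activity_coefficients(model, c(x_i, 1 - x_i), t_e, pair)
  res <- c(
    log(x_i * gam[1]) - liquidus_rhs(pair$t_fus_K[1], pair$dh_fus_kJ_mol[1], t_e),
    abs(x_i + x_j - 1)
  )
  gam_j <- activity_coefficients(model, c(1 - x_j, x_j), t_e, pair)[2]
  res[3] <- log(x_j * gam_j) - liquidus_rhs(pair$t_fus_K[2], pair$dh_fus_kJ_mol[2], t_e)
  res <- res[c(1, 3, 2)]
  names(res) <- c("branch_i", "branch_j", "fraction_sum")
  structure(list(
    x_e = x_i, t_e = t_e, model = model$id,
    converged = all(abs(res) < tol),
    residuals = res,
    pair_names = pair$name,
    label = paste(pair$name, collapse = ":")
  ), class = "eutectic_point")
}

#' @export
print.eutectic_point <- function(x, ...) {
  cat(sprintf("Eutectic point (%s, %s model): T_e = %.2f K, x_e(%s) = %.4f%s\n",
              x$label, x$model, x$t_e, x$pair_names[1], x$x_e,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @rdname find_eutectic
#' @param x An `eutectic_point`.
#' @param ... Unused.
#' @method tidy eutectic_point
#' @export
tidy.eutectic_point <- function(x, ...) {
  tibble(label = x$label, model = x$model, x_e = x$x_e, t_e_K = x$t_e,
         converged = x$converged)
}

#' @rdname find_eutectic
#' @method glance eutectic_point
#' @export
glance.eutectic_point <- function(x, ...) {
  tibble(model = x$model, converged = x$converged,
         max_abs_residual = max(abs(x$residuals)))
}

#' Tabulate a phase diagram for one binary system
#'
#' Computes both liquidus branches on a composition grid for each requested
#' activity model and attaches the eutectic point per model.
#'
#' @param pair Two-row compound tibble.
#' @param models Named list of `activity_model`s, default
#'   `list(ideal = activity_ideal())`.
#' @param x_grid Grid of mole fractions of component i, strictly inside
#'   (0, 1).
#' @param floor_t Lower temperature bound (K).
#' @return An object of class `phase_diagram`: list with tibbles `branches`
#'   (`model`, `branch`, `component`, `x_i`, `t_K`) and `eutectics`
#'   (one row per model), plus `label`.
#' @export
#' @examples
#' pair <- system_pair(terpene_compounds(), "menthol", "borneol")
#' pd <- phase_diagram(pair, x_grid = seq(0.1, 0.9, 0.1))
#' pd$eutectics
phase_diagram <- function(pair, models = list(ideal = activity_ideal()),
                          x_grid = seq(0.02, 0.98, by = 0.02), floor_t = 150) {
  stopifnot(all(x_grid > 0), all(x_grid < 1))
  branches <- list()
  eutectics <- list()
  for (mname in names(models)) {
    model <- models[[mname]]
    for (br in c("i", "j")) {
      k <- if (br == "i") 1L else 2L
      xb <- if (br == "i") x_grid else 1 - x_grid  # branch-component fraction
      t_K <- vapply(xb, function(xx) {
        tryCatch(liquidus_t_at_x(pair, xx, br, model, floor_t),
                 eutectr_solver_error = function(e) NA_real_)
      }, numeric(1))
      branches[[length(branches) + 1L]] <- tibble(
        model = mname, branch = br, component = pair$name[k],
        x_i = if (br == "i") xb else 1 - xb, t_K = t_K
      )
    }
    eu <- find_eutectic(pair, model, floor_t = floor_t)
    eutectics[[length(eutectics) + 1L]] <- mutate(tidy(eu), model = mname)
  }
  structure(list(
    label = paste(pair$name, collapse = ":"),
    branches = bind_rows(branches),
    eutectics = bind_rows(eutectics)
  ), class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("<phase_diagram:", x$label, ">\n")
  print(x$eutectics)
  invisible(x)
}

#' @rdname phase_diagram
#' @param x A `phase_diagram`.
#' @param ... Unused.
#' @method tidy phase_diagram
#' @export
tidy.phase_diagram <- function(x, ...) {
  mutate(x$branches, label = x$label)
}

#' Plot a phase diagram
#'
#' Stable-liquidus view: each branch drawn for the compositions where it is
#' the upper (stable) branch, with the eutectic points marked.
#'
#' @param object A `phase_diagram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_diagram
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot(object$branches, aes(x = .data$x_i, y = .data$t_K,
                              colour = .data$component,
                              linetype = .data$model)) +
    geom_line(na.rm = TRUE) +
    geom_point(data = object$eutectics,
               aes(x = .data$x_e, y = .data$t_e_K, shape = .data$model),
               inherit.aes = FALSE, size = 2.5) +
    labs(x = paste0("x(", object$label, " first component)"), y = "T (K)",
         title = paste("SLE phase diagram:", object$label)) +
    theme_minimal()
}

#' Classify deviation from ideality of an eutectic point
#'
#' A system qualifies as a deep-eutectic-solvent candidate when its real
#' (measured or model-predicted) eutectic temperature lies below the ideal
#' one: negative deviation iff
#' `t_e_real < t_e_ideal - tolerance`; positive iff above by more than
#' `tolerance`; otherwise approximately ideal.
#'
#' @param t_e_real,t_e_ideal Eutectic temperatures (K); both finite.
#' @param tolerance Dead band in K, default 0.5.
#' @return One of `"negative deviation (DES candidate)"`, `"~ideal"`,
#'   `"positive deviation"` (vectorized).
#' @export
#' @examples
#' classify_deep(300.8, 309.6) # negative deviation
#' classify_deep(290.0, 289.8) # ~ideal at the default tolerance
classify_deep <- function(t_e_real, t_e_ideal, tolerance = 0.5) {
  stopifnot(all(is.finite(t_e_real)), all(is.finite(t_e_ideal)), tolerance >= 0)
  dplyr::case_when(
    t_e_real < t_e_ideal - tolerance ~ "negative deviation (DES candidate)",
    t_e_real > t_e_ideal + tolerance ~ "positive deviation",
    TRUE ~ "~ideal"
  )
}
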
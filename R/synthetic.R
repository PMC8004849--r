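#' Generate a synthetic binary system
#'
#' Draws two fabricated compounds with melting temperatures and fusion
#' enthalpies uniform over the requested ranges. The default ranges span the
#' domain of the terpene study (melting points of a few hundred kelvin,
#' fusion enthalpies of order 5-20 kJ/mol), so generated systems exercise
#' the same numerical regime as the real fixtures. Deterministic for a fixed
#' seed; degenerate ranges (min = max) yield exactly the requested values.
#'
#' @param seed Integer seed.
#' @param t_fus_range Range of melting temperatures (K), default
#'   `c(280, 490)`.
#' @param dh_fus_range Range of fusion enthalpies (kJ/mol), default
#'   `c(5, 20)`.
#' @return A two-row compound tibble (names `synth_a`, `synth_b`) usable
#'   everywhere a [system_pair()] is.
#' @export
#' @examples
#' synthetic_system(42)
synthetic_system <- function(seed, t_fus_range = c(280, 490),
                             dh_fus_range = c(5, 20)) {
  if (any(t_fus_range <= 0) || any(dh_fus_range <= 0) ||
      diff(t_fus_range) < 0 || diff(dh_fus_range) < 0) {
    abort("ranges must be positive and non-decreasing",
          class = "eutectr_validation_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  t_fus <- runif(2, t_fus_range[1], t_fus_range[2])
  dh <- runif(2, dh_fus_range[1], dh_fus_range[2])
  new_compound_tbl(
    name = c("synth_a", "synth_b"), formula = NA_character_,
    mw = c(150, 150), t_fus_K = t_fus, dh_fus_kJ_mol = dh,
    unifac_groups = list(setNames(numeric(0), character(0)),
                         setNames(numeric(0), character(0))),
    ljr_groups = list(setNames(numeric(0), character(0)),
                      setNames(numeric(0), character(0)))
  )
}

#' Brute-force eutectic location by grid scan
#'
#' Independent oracle for [find_eutectic()]: a pure grid search with no
#' shared machinery. For each temperature on a grid over
#' `[floor_t, min(T_fus)]`, each branch's composition is taken as the grid
#' point minimizing the absolute liquidus residual over an `x` grid, and the
#' reported eutectic is the temperature minimizing the deviation of the
#' branch-fraction sum from one. A coarse 1 K pass bounds the answer; a fine
#' pass at `t_step` within +/- 2 K refines it. Accuracy is bounded by the
#' grid steps.
#'
#' @param pair Two-row compound tibble.
#' @param model An `activity_model` whose coefficients can be evaluated on
#'   composition vectors (ideal and Margules are; this oracle is not meant
#'   for UNIFAC).
#' @param x_step Composition grid step, default 1e-4.
#' @param t_step Temperature grid step (K), default 0.01.
#' @param floor_t Lower temperature bound (K), default 150.
#' @return List with `x_e`, `t_e`, `objective` (|sum - 1| at the optimum).
#' @export
#' @examples
#' pair <- system_pair(terpene_compounds(), "menthol", "borneol")
#' brute_force_eutectic(pair, x_step = 1e-3, t_step = 0.1)
brute_force_eutectic <- function(pair, model = activity_ideal(),
                                 x_step = 1e-4, t_step = 0.01, floor_t = 150) {
  stopifnot(x_step > 0, t_step > 0)
  x_grid <- seq(x_step, 1, by = x_step)
  t_max <- min(pair$t_fus_K) - 1e-9
  gamma_vec <- function(component, t) {
    # gamma of `component` across its own fraction grid
    if (identical(model$id, "ideal")) return(rep(1, length(x_grid)))
    if (!is.null(model$a12)) {
      x1 <- if (component == 1) x_grid else 1 - x_grid
      g <- margules_gamma(x1, t, model$a12, model$a21)
      return(g[, component])
    }
    vapply(x_grid, function(xx) {
      comp <- if (component == 1) c(xx, 1 - xx) else c(1 - xx, xx)
      activity_coefficients(model, comp, t, pair)[component]
    }, numeric(1))
  }
  lx <- log(x_grid)
  scan <- function(t_grid) {
    obj <- vapply(t_grid, function(t) {
      xs <- vapply(1:2, function(k) {
        rhs <- liquidus_rhs(pair$t_fus_K[k], pair$dh_fus_kJ_mol[k], t)
        resid <- abs(lx + log(gamma_vec(k, t)) - rhs)
        x_grid[which.min(resid)]
      }, numeric(1))
      abs(sum(xs) - 1)
    }, numeric(1))
    t_grid[which.min(obj)]
  }
  coarse <- scan(seq(floor_t, t_max, by = 1))
  fine_grid <- seq(max(floor_t, coarse - 2), min(t_max, coarse + 2), by = t_step)
  t_e <- scan(fine_grid)
  rhs_i <- liquidus_rhs(pair$t_fus_K[1], pair$dh_fus_kJ_mol[1], t_e)
  x_e <- x_grid[which.min(abs(lx + log(gamma_vec(1, t_e)) - rhs_i))]
  rhs_j <- liquidus_rhs(pair$t_fus_K[2], pair$dh_fus_kJ_mol[2], t_e)
  x_j <- x_grid[which.min(abs(lx + log(gamma_vec(2, t_e)) - rhs_j))]
  if (x_e + x_j > 1.5 || x_e + x_j < 0.5) {
    abort("no feasible eutectic found on the grid", class = "eutectr_solver_error")
  }
  list(x_e = x_e, t_e = t_e, objective = abs(x_e + x_j - 1))
}

#' Generate a synthetic NMR shift series
#'
#' Straight line delta = intercept + slope * T with optional Gaussian noise;
#' deterministic per seed.
#'
#' @param slope Slope in ppm/K.
#' @param intercept Intercept in ppm.
#' @param temps Temperatures (K), at least 3, strictly increasing.
#' @param noise_sd Gaussian noise standard deviation (ppm); 0 gives the
#'   exact line.
#' @param seed Integer seed.
#' @param label Optional label column value.
#' @return Tibble with columns `t_K`, `delta_ppm` (and `label` if given).
#' @export
#' @examples
#' synthetic_nmr_series(-0.015, 10, seq(298, 323, 5), 0.005, seed = 7)
synthetic_nmr_series <- function(slope, intercept, temps, noise_sd = 0,
                                 seed = 1, label = NULL) {
  if (length(temps) < 3 || any(diff(temps) <= 0)) {
    abort("temps must contain at least 3 strictly increasing values",
          class = "eutectr_validation_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  delta <- intercept + slope * temps + rnorm(length(temps), 0, noise_sd)
  out <- tibble(t_K = temps, delta_ppm = delta)
  if (!is.null(label)) out <- mutate(out, label = label, .before = 1)
  out
}
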
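#' Modified Lydersen-Joback-Reid group-contribution table
#'
#' Group contributions to the normal boiling point (Joback-Reid) and to the
#' critical temperature, pressure and volume (Modified Lydersen), shipped as
#' a versioned CSV under `inst/extdata/`.
#'
#' @return A tibble with columns `group`, `dtb_K`, `dtc`, `dpc_bar`,
#'   `dvc_cm3_mol`, `n_C`, `n_H`, `n_O`.
#' @export
ljr_groups <- function() {
  read_table_file("ljr_groups.csv")
}

ljr_method_constants <- function() {
  list(tb_base = 198.2, tc_a = 0.5703, tc_b = 1.0121, pc_c = 0.2573, vc_base = 6.75)
}

ljr_group_sums <- function(compounds, table) {
  lapply(seq_len(nrow(compounds)), function(i) {
    gmap <- compounds$ljr_groups[[i]]
    unknown <- setdiff(names(gmap), table$group)
    if (length(unknown)) {
      abort(paste0("compound '", compounds$name[i], "': group(s) not in LJR table: ",
                   paste(unknown, collapse = ", ")),
            class = "eutectr_validation_error")
    }
    idx <- match(names(gmap), table$group)
    list(
      tb = sum(gmap * table$dtb_K[idx]),
      tc = sum(gmap * table$dtc[idx]),
      pc = sum(gmap * table$dpc_bar[idx]),
      vc = sum(gmap * table$dvc_cm3_mol[idx])
    )
  })
}

#' Estimate normal boiling points by group contribution
#'
#' Joback-Reid form: `Tb = 198.2 + sum(n_k * dTb_k)`. A compound with an
#' empty group map returns the base constant.
#'
#' @param compounds A compound tibble (list-column `ljr_groups`).
#' @param table Contribution table, by default [ljr_groups()].
#' @return The compound tibble with `t_b_K` filled in (existing non-`NA`
#'   values are kept).
#' @export
#' @examples
#' estimate_boiling_point(terpene_compounds())$t_b_K
estimate_boiling_point <- function(compounds, table = ljr_groups()) {
  sums <- ljr_group_sums(compounds, table)
  est <- ljr_method_constants()$tb_base + map_dbl(sums, "tb")
  mutate(compounds, t_b_K = ifelse(is.na(.data$t_b_K), est, .data$t_b_K))
}

#' Estimate critical properties by the Modified Lydersen-Joback-Reid method
#'
#' Computes, per compound,
#' \deqn{T_b = 198.2 + \sum n_k \Delta T_{bM,k}}
#' \deqn{T_c = T_b / (0.5703 + 1.0121 \sum n_k \Delta T_{M,k} - (\sum n_k \Delta T_{M,k})^2)}
#' \deqn{P_c = M / (0.2573 + \sum n_k \Delta P_{M,k})^2 \quad \mathrm{[bar]}}
#' \deqn{V_c = 6.75 + \sum n_k \Delta V_{M,k} \quad \mathrm{[cm^3/mol]}}
#' and the acentric factor from a vapor-pressure-based correlation
#' (see [acentric_factor()]).
#'
#' @param compounds A compound tibble.
#' @param table Contribution table, by default [ljr_groups()].
#' @param omega_method Correlation for the acentric factor, `"rudkin"`
#'   (default, the modified Rudkin form commonly paired with this method in
#'   the deep-eutectic-solvent density literature) or `"edmister"`.
#' @return A tibble with columns `name`, `mw`, `t_b_K`, `t_c_K`, `p_c_bar`,
#'   `v_c_cm3_mol`, `omega`.
#' @export
#' @examples
#' estimate_critical_properties(terpene_compounds())
estimate_critical_properties <- function(compounds, table = ljr_groups(),
                                         omega_method = c("rudkin", "edmister")) {
  omega_method <- match.arg(omega_method)
  k <- ljr_method_constants()
  compounds <- estimate_boiling_point(compounds, table)
  sums <- ljr_group_sums(compounds, table)
  st <- map_dbl(sums, "tc")
  sp <- map_dbl(sums, "pc")
  sv <- map_dbl(sums, "vc")
  denom_t <- k$tc_a + k$tc_b * st - st^2
  if (any(denom_t <= 0)) {
    bad <- compounds$name[denom_t <= 0]
    abort(paste0("non-physical Tc denominator (<= 0) for: ",
                 paste(bad, collapse = ", "), "; sum(dtc) = ",
                 paste(signif(st[denom_t <= 0], 4), collapse = ", ")),
          class = "eutectr_validation_error")
  }
  t_c <- compounds$t_b_K / denom_t
  p_c <- compounds$mw / (k$pc_c + sp)^2
  v_c <- k$vc_base + sv
  tibble(
    name = compounds$name, mw = compounds$mw, t_b_K = compounds$t_b_K,
    t_c_K = t_c, p_c_bar = p_c, v_c_cm3_mol = v_c,
    omega = acentric_factor(compounds$t_b_K, t_c, p_c, method = omega_method)
  )
}

#' Acentric factor from Tb, Tc and Pc
#'
#' The source correlations need an acentric factor but do not state how it
#' was obtained; two standard vapor-pressure-based correlations are provided
#' as pluggable strategies. `"rudkin"` (default) is the modified Rudkin /
#' Lydersen-type form used together with the Modified Lydersen-Joback-Reid
#' method in the deep-eutectic-solvent density literature:
#' \deqn{\omega = \frac{(T_b-43)(T_c-43)}{(T_c-T_b)(0.7T_c-43)}\log_{10}\frac{P_c}{P_b}
#'  - \frac{T_c-43}{T_c-T_b}\log_{10}\frac{P_c}{P_b} + \log_{10}\frac{P_c}{P_b} - 1}
#' with \eqn{P_b = 1.01325} bar. `"edmister"` is
#' \eqn{\omega = \frac{3}{7}\frac{T_b/T_c}{1-T_b/T_c}\log_{10}(P_c/1.01325)-1}.
#'
#' @param t_b,t_c Normal boiling and critical temperatures (K); `t_b < t_c`
#'   required.
#' @param p_c Critical pressure (bar).
#' @param method `"rudkin"` or `"edmister"`.
#' @return Numeric vector of acentric factors.
#' @export
#' @examples
#' acentric_factor(420, 600, 25)
acentric_factor <- function(t_b, t_c, p_c, method = c("rudkin", "edmister")) {
  method <- match.arg(method)
  if (any(t_b >= t_c)) {
    abort("acentric factor requires t_b < t_c", class = "eutectr_validation_error")
  }
  if (any(p_c <= 0)) {
    abort("acentric factor requires p_c > 0", class = "eutectr_validation_error")
  }
  lg <- log10(p_c / 1.01325)
  if (method == "rudkin") {
    (t_b - 43) * (t_c - 43) / ((t_c - t_b) * (0.7 * t_c - 43)) * lg -
      (t_c - 43) / (t_c - t_b) * lg + lg - 1
  } else {
    theta <- t_b / t_c
    3 / 7 * theta / (1 - theta) * lg - 1
  }
}

#' Combine pure-component critical properties into mixture values
#'
#' Default rule `"lee_kesler"`:
#' \deqn{V_{c,m} = \tfrac{1}{8}\sum_i\sum_j x_i x_j (V_{c,i}^{1/3}+V_{c,j}^{1/3})^3}
#' \deqn{T_{c,m} = \frac{1}{8 V_{c,m}}\sum_i\sum_j x_i x_j (V_{c,i}^{1/3}+V_{c,j}^{1/3})^3 \sqrt{T_{c,i}T_{c,j}}}
#' \deqn{\omega_m = \sum_i x_i\omega_i,\qquad
#'       P_{c,m} = (0.2905-0.085\,\omega_m)\,R\,T_{c,m}/V_{c,m}}
#' with R = 83.14 cm3 bar/(mol K). `"linear"` is plain mole-fraction
#' weighting of every property. Both reduce to the pure-component values at
#' the endpoints and are symmetric under component exchange.
#'
#' @param props Critical-property tibble from [estimate_critical_properties()]
#'   (one row per component).
#' @param x Mole fractions, same length as `nrow(props)`, summing to 1
#'   within 1e-9.
#' @param rule `"lee_kesler"` (default) or `"linear"`.
#' @return One-row tibble with mixture `mw`, `t_c_K`, `p_c_bar`,
#'   `v_c_cm3_mol`, `omega`.
#' @export
#' @examples
#' cp <- estimate_critical_properties(terpene_compounds())
#' mix_critical_properties(cp[cp$name %in% c("menthol", "borneol"), ], c(0.7, 0.3))
mix_critical_properties <- function(props, x, rule = c("lee_kesler", "linear")) {
  rule <- match.arg(rule)
  if (length(x) != nrow(props)) {
    abort("x must have one fraction per component", class = "eutectr_validation_error")
  }
  if (abs(sum(x) - 1) > 1e-9) {
    abort(paste0("mole fractions must sum to 1 (got ", format(sum(x), digits = 12), ")"),
          class = "eutectr_validation_error")
  }
  mw <- sum(x * props$mw)
  omega <- sum(x * props$omega)
  if (rule == "linear") {
    return(tibble(mw = mw, t_c_K = sum(x * props$t_c_K),
                  p_c_bar = sum(x * props$p_c_bar),
                  v_c_cm3_mol = sum(x * props$v_c_cm3_mol), omega = omega))
  }
  v3 <- props$v_c_cm3_mol^(1 / 3)
  vij <- outer(v3, v3, `+`)^3
  xx <- outer(x, x)
  v_c <- sum(xx * vij) / 8
  t_c <- sum(xx * vij * sqrt(outer(props$t_c_K, props$t_c_K))) / (8 * v_c)
  p_c <- (0.2905 - 0.085 * omega) * 83.14 * t_c / v_c
  tibble(mw = mw, t_c_K = t_c, p_c_bar = p_c, v_c_cm3_mol = v_c, omega = omega)
}
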
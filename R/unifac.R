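#' UNIFAC subgroup parameter table (Hansen 1991 VLE revision)
#'
#' Volume (R) and surface-area (Q) parameters for the subgroups used by the
#' shipped fixtures, with their main-group assignments, as a versioned CSV
#' data file.
#'
#' @return Tibble with columns `subgroup`, `main_group`, `main_name`, `R`,
#'   `Q`, `n_C`, `n_H`, `n_O`.
#' @export
unifac_subgroups <- function() {
  read_table_file("unifac_subgroups.csv")
}

#' UNIFAC main-group interaction parameters (Hansen 1991 VLE revision)
#'
#' @return Tibble with columns `main_m`, `main_n`, `a_mn_K`; `a_mm = 0` is
#'   implied and need not be listed.
#' @export
unifac_interactions <- function() {
  read_table_file("unifac_interactions.csv")
}

unifac_table_version <- function() "hansen-1991-vle"

# Resolve per-compound subgroup count matrix and R/Q sums.
unifac_setup <- function(compounds, subgroups, interactions) {
  maps <- compounds$unifac_groups
  empty <- vapply(maps, function(m) length(m) == 0, logical(1))
  if (any(empty)) {
    abort(paste0("compound(s) without UNIFAC groups: ",
                 paste(compounds$name[empty], collapse = ", ")),
          class = "eutectr_validation_error")
  }
  used <- sort(unique(unlist(lapply(maps, names))))
  unknown <- setdiff(used, subgroups$subgroup)
  if (length(unknown)) {
    abort(paste0("subgroup(s) not in parameter table: ",
                 paste(unknown, collapse = ", ")),
          class = "eutectr_validation_error")
  }
  sg <- subgroups[match(used, subgroups$subgroup), ]
  nu <- t(vapply(maps, function(m) {
    v <- numeric(length(used))
    v[match(names(m), used)] <- m
    v
  }, numeric(length(used))))  # n_compounds x n_subgroups
  mains <- sort(unique(sg$main_group))
  amat <- matrix(0, length(mains), length(mains),
                 dimnames = list(mains, mains))
  for (r in seq_len(nrow(interactions))) {
    i <- as.character(interactions$main_m[r])
    j <- as.character(interactions$main_n[r])
    if (i %in% rownames(amat) && j %in% colnames(amat)) {
      amat[i, j] <- interactions$a_mn_K[r]
    }
  }
  # every off-diagonal pair actually used must be present (zero allowed only
  # for same main group)
  listed <- paste(interactions$main_m, interactions$main_n)
  for (i in mains) {
    for (j in mains) {
      if (i != j && !(paste(i, j) %in% listed)) {
        abort(paste0("missing interaction parameter for main groups ", i, "-", j),
              class = "eutectr_validation_error")
      }
    }
  }
  list(
    sub = used, nu = nu, Rk = sg$R, Qk = sg$Q,
    main_of = match(sg$main_group, mains), amat = amat,
    r_i = as.numeric(nu %*% sg$R), q_i = as.numeric(nu %*% sg$Q)
  )
}

# ln Gamma_k for group fractions X (vector over setup$sub) at temperature t.
unifac_ln_Gamma <- function(X, t, setup) {
  theta <- setup$Qk * X / sum(setup$Qk * X)
  a_sub <- setup$amat[setup$main_of, setup$main_of, drop = FALSE]
  psi <- exp(-a_sub / t)                    # psi[m, k] = exp(-a_{m k}/T)
  s1 <- as.numeric(theta %*% psi)           # sum_m theta_m psi_mk
  s2 <- as.numeric(psi %*% (theta / s1))    # sum_m theta_m psi_km / s1_m
  setup$Qk * (1 - log(s1) - s2)
}

#' UNIFAC combinatorial contribution
#'
#' Original-form combinatorial term (Flory-Huggins size part with the
#' Staverman-Guggenheim shape correction, coordination number z = 10):
#' \deqn{\ln\gamma_i^C = \ln\frac{\Phi_i}{x_i} + \frac{z}{2} q_i \ln\frac{\theta_i}{\Phi_i}
#'   + l_i - \frac{\Phi_i}{x_i}\sum_j x_j l_j}
#' with \eqn{r_i = \sum_k \nu_k^{(i)} R_k}, \eqn{q_i = \sum_k \nu_k^{(i)} Q_k},
#' \eqn{l_i = 5(r_i - q_i) - (r_i - 1)}.
#'
#' @param x Composition vector (sums to 1).
#' @param compounds Compound tibble (one row per mixture component, same
#'   order as `x`) with non-empty `unifac_groups`.
#' @param subgroups,interactions Parameter tables.
#' @return Vector of \eqn{\ln\gamma_i^C}.
#' @export
unifac_combinatorial <- function(x, compounds, subgroups = unifac_subgroups(),
                                 interactions = unifac_interactions()) {
  setup <- unifac_setup(compounds, subgroups, interactions)
  unifac_ln_gamma_c(x, setup)
}

unifac_ln_gamma_c <- function(x, setup) {
  xs <- pmax(x, 1e-12)  # guard for limiting compositions
  r <- setup$r_i
  q <- setup$q_i
  phi <- r * xs / sum(r * xs)
  theta <- q * xs / sum(q * xs)
  l <- 5 * (r - q) - (r - 1)
  log(phi / xs) + 5 * q * log(theta / phi) + l - phi / xs * sum(xs * l)
}

#' UNIFAC residual contribution
#'
#' Solution-of-groups residual term:
#' \deqn{\ln\gamma_i^R = \sum_k \nu_k^{(i)} (\ln\Gamma_k - \ln\Gamma_k^{(i)})}
#' with the group activity coefficients \eqn{\Gamma_k} evaluated in the
#' mixture and in pure liquid i, and \eqn{\psi_{mn} = \exp(-a_{mn}/T)}.
#'
#' @inheritParams unifac_combinatorial
#' @param t Temperature (K).
#' @return Vector of \eqn{\ln\gamma_i^R}.
#' @export
unifac_residual <- function(x, t, compounds, subgroups = unifac_subgroups(),
                            interactions = unifac_interactions()) {
  setup <- unifac_setup(compounds, subgroups, interactions)
  unifac_ln_gamma_r(x, t, setup)
}

unifac_ln_gamma_r <- function(x, t, setup) {
  xs <- pmax(x, 1e-12)
  Xmix <- as.numeric(xs %*% setup$nu)
  Xmix <- Xmix / sum(Xmix)
  lng_mix <- unifac_ln_Gamma(Xmix, t, setup)
  vapply(seq_along(xs), function(i) {
    nui <- setup$nu[i, ]
    Xi <- nui / sum(nui)
    lng_i <- unifac_ln_Gamma(Xi, t, setup)
    sum(nui * (lng_mix - lng_i))
  }, numeric(1))
}

#' UNIFAC activity coefficients
#'
#' \eqn{\gamma_i = \exp(\ln\gamma_i^C + \ln\gamma_i^R)}. Compositions are
#' clamped at 1e-12 inside the logarithmic terms so the pure-component and
#' infinite-dilution limits evaluate cleanly; reported values always use the
#' exact input `x`.
#'
#' @inheritParams unifac_residual
#' @return Vector of activity coefficients \eqn{\gamma_i > 0}.
#' @export
#' @examples
#' pair <- system_pair(terpene_compounds(), "menthol", "borneol")
#' unifac_gamma(c(0.5, 0.5), 298, pair)
unifac_gamma <- function(x, t, compounds, subgroups = unifac_subgroups(),
                         interactions = unifac_interactions()) {
  setup <- unifac_setup(compounds, subgroups, interactions)
  exp(unifac_ln_gamma_c(x, setup) + unifac_ln_gamma_r(x, t, setup))
}
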
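# Independent reference UNIFAC implementation used as a test oracle.
#
# Written as plain scalar loops directly from the standard statement of the
# model (combinatorial: Flory-Huggins + Staverman-Guggenheim with z = 10;
# residual: solution of groups with psi_mn = exp(-a_mn/T)), sharing no code
# with the package implementation. Only valid at interior compositions
# (0 < x < 1); the package's clamped limits are tested separately.

oracle_sub_row <- function(sub, g) sub[sub$subgroup == g, , drop = FALSE]

oracle_a <- function(inter, m, n) {
  if (m == n) return(0)
  hit <- inter$a_mn_K[inter$main_m == m & inter$main_n == n]
  if (length(hit) != 1) stop("oracle: missing interaction ", m, "-", n)
  hit
}

# ln Gamma_k for a named vector of subgroup amounts (counts or fractions)
oracle_ln_Gamma <- function(amounts, t, sub, inter) {
  gs <- names(amounts)
  X <- amounts / sum(amounts)
  Q <- numeric(length(gs))
  main <- integer(length(gs))
  for (k in seq_along(gs)) {
    row <- oracle_sub_row(sub, gs[k])
    Q[k] <- row$Q
    main[k] <- row$main_group
  }
  TH <- Q * X / sum(Q * X)
  out <- numeric(length(gs))
  for (k in seq_along(gs)) {
    s1 <- 0
    for (m in seq_along(gs)) {
      s1 <- s1 + TH[m] * exp(-oracle_a(inter, main[m], main[k]) / t)
    }
    s2 <- 0
    for (m in seq_along(gs)) {
      den <- 0
      for (n in seq_along(gs)) {
        den <- den + TH[n] * exp(-oracle_a(inter, main[n], main[m]) / t)
      }
      s2 <- s2 + TH[m] * exp(-oracle_a(inter, main[k], main[m]) / t) / den
    }
    out[k] <- Q[k] * (1 - log(s1) - s2)
  }
  names(out) <- gs
  out
}

# group_maps: list of named count vectors, one per molecule
oracle_unifac_lngamma <- function(x, t, group_maps,
                                  sub = unifac_subgroups(),
                                  inter = unifac_interactions()) {
  nmol <- length(group_maps)
  r <- q <- numeric(nmol)
  for (i in seq_len(nmol)) {
    for (g in names(group_maps[[i]])) {
      row <- oracle_sub_row(sub, g)
      r[i] <- r[i] + group_maps[[i]][[g]] * row$R
      q[i] <- q[i] + group_maps[[i]][[g]] * row$Q
    }
  }
  phi <- r * x / sum(r * x)
  th <- q * x / sum(q * x)
  l <- 5 * (r - q) - (r - 1)
  comb <- log(phi / x) + 5 * q * log(th / phi) + l - phi / x * sum(x * l)

  all_groups <- unique(unlist(lapply(group_maps, names)))
  mix_amounts <- stats::setNames(numeric(length(all_groups)), all_groups)
  for (i in seq_len(nmol)) {
    for (g in names(group_maps[[i]])) {
      mix_amounts[g] <- mix_amounts[g] + x[i] * group_maps[[i]][[g]]
    }
  }
  ln_mix <- oracle_ln_Gamma(mix_amounts, t, sub, inter)
  resid <- numeric(nmol)
  for (i in seq_len(nmol)) {
    counts <- group_maps[[i]]
    ln_pure <- oracle_ln_Gamma(unlist(counts), t, sub, inter)
    for (g in names(counts)) {
      resid[i] <- resid[i] + counts[[g]] * (ln_mix[g] - ln_pure[g])
    }
  }
  list(comb = comb, resid = resid, total = comb + resid)
}
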
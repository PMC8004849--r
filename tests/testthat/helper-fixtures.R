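# Shared fixtures for the test suite. Everything is built in code; the only
# files read are the package's own parameter tables.

terpenes <- terpene_compounds()

fixture_pair <- function(a, b) system_pair(terpenes, a, b)

pair_men_bor <- fixture_pair("menthol", "borneol")
pair_men_cam <- fixture_pair("menthol", "camphor")
pair_thy_bor <- fixture_pair("thymol", "borneol")
pair_thy_cam <- fixture_pair("thymol", "camphor")

fixture_pairs <- list(
  "Men:Bor" = pair_men_bor, "Men:Cam" = pair_men_cam,
  "Thy:Bor" = pair_thy_bor, "Thy:Cam" = pair_thy_cam
)

# A symmetric synthetic pair: equal melting data forces x_e = 0.5 and the
# closed-form eutectic temperature 1/T = 1/300 + R ln2 / 10000.
symmetric_pair <- function() {
  tibble::tibble(
    name = c("sym_a", "sym_b"), formula = NA_character_, mw = c(100, 100),
    t_fus_K = c(300, 300), dh_fus_kJ_mol = c(10, 10), t_b_K = NA_real_,
    unifac_groups = list(stats::setNames(numeric(0), character(0)),
                         stats::setNames(numeric(0), character(0))),
    ljr_groups = list(stats::setNames(numeric(0), character(0)),
                      stats::setNames(numeric(0), character(0)))
  )
}

# Deterministic Margules parameters for a seeded synthetic system.
seeded_margules <- function(seed) {
  set.seed(seed + 10000L)
  list(a12 = stats::runif(1, -2000, 1000), a21 = stats::runif(1, -2000, 1000))
}
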
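test_that("the ideal model returns unit coefficients everywhere", {
  m <- activity_ideal()
  expect_equal(activity_coefficients(m, c(0.5, 0.5), 298), c(1, 1))
  expect_equal(activity_coefficients(m, c(1, 0), 400), c(1, 1))
  expect_error(activity_coefficients(m, c(0.5, 0.6), 298),
               class = "eutectr_validation_error")
})

test_that("UNIFAC satisfies the pure-component limits", {
  m <- activity_unifac()
  for (pair in fixture_pairs) {
    g_i <- activity_coefficients(m, c(1, 0), 300, pair)
    g_j <- activity_coefficients(m, c(0, 1), 300, pair)
    expect_equal(g_i[1], 1, tolerance = 1e-9)
    expect_equal(g_j[2], 1, tolerance = 1e-9)
  }
})

test_that("combinatorial term vanishes for size-identical molecules", {
  # two molecules with identical subgroup maps have equal r and q
  twin <- pair_men_bor
  twin$unifac_groups[[2]] <- twin$unifac_groups[[1]]
  lnc <- unifac_combinatorial(c(0.3, 0.7), twin)
  expect_equal(lnc, c(0, 0), tolerance = 1e-12)
})

test_that("residual term vanishes when all interaction parameters are zero", {
  inter <- unifac_interactions()
  inter$a_mn_K <- 0
  for (x1 in c(0.2, 0.5, 0.8)) {
    lnr <- unifac_residual(c(x1, 1 - x1), 298, pair_men_bor,
                           interactions = inter)
    expect_equal(lnr, c(0, 0), tolerance = 1e-12)
  }
})

test_that("uncovered subgroups and missing interactions are reported by name", {
  odd <- pair_men_bor
  odd$unifac_groups[[1]] <- c(CF3 = 1)
  expect_error(unifac_gamma(c(0.5, 0.5), 298, odd), regexp = "CF3")
  inter <- unifac_interactions()
  inter <- inter[!(inter$main_m == 1 & inter$main_n == 5), ]
  expect_error(unifac_gamma(c(0.5, 0.5), 298, pair_men_bor,
                            interactions = inter),
               regexp = "1-5")
})

test_that("UNIFAC matches the independent loop-based oracle to 1e-6 in ln gamma", {
  cases <- list(
    list(pair = pair_men_bor, t = 298),
    list(pair = pair_men_cam, t = 290),
    list(pair = pair_thy_bor, t = 300),
    list(pair = pair_thy_cam, t = 310)
  )
  for (case in cases) {
    maps <- case$pair$unifac_groups
    for (x1 in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
      x <- c(x1, 1 - x1)
      pkg <- log(unifac_gamma(x, case$t, case$pair))
      ora <- oracle_unifac_lngamma(x, case$t, maps)
      expect_equal(pkg, ora$total, tolerance = 1e-6)
      expect_equal(unifac_combinatorial(x, case$pair), ora$comb,
                   tolerance = 1e-6)
      expect_equal(unifac_residual(x, case$t, case$pair), ora$resid,
                   tolerance = 1e-6)
    }
  }
})

test_that("UNIFAC reproduces frozen reference values", {
  # frozen from a separately written reference implementation
  frozen <- list(
    list(pair = pair_men_bor, x1 = 0.5, t = 298,
         ln = c(0.001068342986, 0.001143067355)),
    list(pair = pair_men_cam, x1 = 0.3, t = 290,
         ln = c(0.296338129901, 0.069854867186)),
    list(pair = pair_thy_bor, x1 = 0.5, t = 300,
         ln = c(-0.636238499826, -0.583878607005)),
    list(pair = pair_thy_cam, x1 = 0.6, t = 310,
         ln = c(-0.231915547905, -0.590860815844)),
    list(pair = pair_men_bor, x1 = 0.25, t = 310,
         ln = c(0.002467770165, 0.000293445241))
  )
  for (f in frozen) {
    got <- log(unifac_gamma(c(f$x1, 1 - f$x1), f$t, f$pair))
    expect_equal(got, f$ln, tolerance = 1e-9)
  }
})

test_that("thymol systems show negative deviation over mid compositions", {
  m <- activity_unifac()
  for (pair in list(pair_thy_bor, pair_thy_cam)) {
    g <- activity_grid(m, pair, seq(0.3, 0.7, 0.1), 300)
    expect_true(all(g$gamma_i < 1))
    expect_true(all(g$gamma_j < 1))
  }
})

test_that("gamma is continuous and bounded near the composition limits", {
  m <- activity_unifac()
  for (pair in fixture_pairs) {
    for (t in c(250, 300, 350)) {
      g <- activity_grid(m, pair, c(1e-6, 1e-3, 0.5, 1 - 1e-3, 1 - 1e-6), t)
      expect_true(all(is.finite(c(g$gamma_i, g$gamma_j))))
      expect_true(all(c(g$gamma_i, g$gamma_j) > 0))
    }
    # continuity: neighbouring compositions give nearby gammas
    gg <- activity_grid(m, pair, c(0.5, 0.5 + 1e-6), 300)
    expect_lt(abs(diff(log(gg$gamma_i))), 1e-4)
  }
})

test_that("UNIFAC is Gibbs-Duhem consistent by finite differences", {
  m <- activity_unifac()
  h <- 1e-4
  for (pair in fixture_pairs) {
    worst <- 0
    for (x1 in seq(0.05, 0.95, by = 0.01)) {
      up <- log(activity_coefficients(m, c(x1 + h, 1 - x1 - h), 300, pair))
      dn <- log(activity_coefficients(m, c(x1 - h, 1 - x1 + h), 300, pair))
      d <- (up - dn) / (2 * h)
      worst <- max(worst, abs(x1 * d[1] + (1 - x1) * d[2]))
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("Margules coefficients follow the closed form", {
  # pure limit: gamma1 = 1 exactly; gamma2 is at infinite dilution,
  # exp(A21/RT) by the closed form
  expect_equal(margules_gamma(1, 300, -1000, -1000),
               c(1, exp(-1000 / (8.314 * 300))), tolerance = 1e-12)
  expect_equal(margules_gamma(0.5, 300, 0, 0), c(1, 1))
  g <- margules_gamma(0.5, 300, -1000, -1000)
  expect_equal(g, rep(exp(-250 / (8.314 * 300)), 2), tolerance = 1e-12)
  # asymmetric parameters: direct transcription at x1 = 0.3, T = 320
  a12 <- -800; a21 <- 400; x1 <- 0.3; tt <- 320
  expect_equal(
    margules_gamma(x1, tt, a12, a21),
    c(exp((a12 + 2 * (a21 - a12) * x1) * (1 - x1)^2 / (8.314 * tt)),
      exp((a21 + 2 * (a12 - a21) * (1 - x1)) * x1^2 / (8.314 * tt))),
    tolerance = 1e-12)
  # Gibbs-Duhem for the analytic model as well
  h <- 1e-6
  for (x1 in c(0.2, 0.5, 0.8)) {
    d <- (log(margules_gamma(x1 + h, 300, -800, 400)) -
            log(margules_gamma(x1 - h, 300, -800, 400))) / (2 * h)
    expect_lt(abs(x1 * d[1] + (1 - x1) * d[2]), 1e-6)
  }
})
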
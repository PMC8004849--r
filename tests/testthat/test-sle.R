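test_that("liquidus composition obeys the closed ideal form", {
  # melting-point limit
  expect_equal(liquidus_x_at_t(pair_men_bor, 309.72), 1, tolerance = 1e-12)
  # menthol at 289.8 K: exp(1638.20 * (1/309.72 - 1/289.8)) = 0.695
  expect_equal(round(liquidus_x_at_t(pair_men_bor, 289.8), 3), 0.695)
  # borneol branch at the same temperature
  expect_equal(round(liquidus_x_at_t(pair_men_bor, 289.8, "j"), 3), 0.303)
  # direct closed-form agreement at an arbitrary temperature
  t <- 280
  expect_equal(liquidus_x_at_t(pair_men_bor, t),
               exp(13620 / 8.314 * (1 / 309.72 - 1 / t)), tolerance = 1e-12)
  expect_error(liquidus_x_at_t(pair_men_bor, 320), class = "eutectr_validation_error")
})

test_that("liquidus x is strictly increasing in T on each ideal branch", {
  ts <- seq(250, 309, by = 1)
  xs <- vapply(ts, function(t) liquidus_x_at_t(pair_men_bor, t), numeric(1))
  expect_true(all(diff(xs) > 0))
  xs_j <- vapply(ts, function(t) liquidus_x_at_t(pair_men_bor, t, "j"), numeric(1))
  expect_true(all(diff(xs_j) > 0))
})

test_that("liquidus_t_at_x inverts liquidus_x_at_t", {
  for (t in c(260, 280, 300)) {
    x <- liquidus_x_at_t(pair_men_bor, t)
    expect_equal(liquidus_t_at_x(pair_men_bor, x), t, tolerance = 1e-6)
  }
  # and for a non-ideal model
  m <- activity_margules(-1500, 500)
  x <- solve_branch_x_for_test <- liquidus_x_at_t(pair_men_bor, 280, "i", m)
  expect_equal(liquidus_t_at_x(pair_men_bor, x, "i", m), 280, tolerance = 1e-6)
  expect_equal(liquidus_t_at_x(pair_men_bor, 1), 309.72)
})

test_that("a symmetric pair has x_e = 0.5 and the closed-form temperature", {
  eu <- find_eutectic(symmetric_pair())
  expect_equal(eu$x_e, 0.5, tolerance = 1e-9)
  expect_equal(eu$t_e, 1 / (1 / 300 + 8.314 * log(2) / 10000), tolerance = 1e-6)
  expect_equal(eu$t_e, 255.7796, tolerance = 1e-4)
  expect_true(eu$converged)
})

test_that("ideal eutectics satisfy both liquidus equations to tolerance", {
  for (pair in fixture_pairs) {
    eu <- find_eutectic(pair)
    expect_true(eu$converged)
    expect_lt(max(abs(eu$residuals)), 1e-8)
    expect_lt(eu$t_e, min(pair$t_fus_K))
    expect_true(eu$x_e > 0 && eu$x_e < 1)
    # branch fractions sum to one
    xi <- liquidus_x_at_t(pair, eu$t_e, "i")
    xj <- liquidus_x_at_t(pair, eu$t_e, "j")
    expect_equal(xi + xj, 1, tolerance = 1e-8)
  }
})

test_that("solver matches the brute-force grid oracle on the fixture systems", {
  for (pair in fixture_pairs) {
    eu <- find_eutectic(pair)
    bf <- brute_force_eutectic(pair, x_step = 1e-4, t_step = 0.01)
    expect_equal(bf$t_e, eu$t_e, tolerance = 0.02)
    expect_equal(bf$x_e, eu$x_e, tolerance = 2e-4)
  }
})

test_that("UNIFAC and ideal diagrams nearly coincide for menthol:borneol", {
  ideal <- find_eutectic(pair_men_bor)
  uni <- find_eutectic(pair_men_bor, activity_unifac())
  expect_lt(abs(uni$t_e - ideal$t_e), 0.5)
  # shared-composition liquidus temperatures differ by well under a kelvin
  m <- activity_unifac()
  for (x in c(0.2, 0.5, 0.8)) {
    t_id <- liquidus_t_at_x(pair_men_bor, x)
    t_un <- liquidus_t_at_x(pair_men_bor, x, "i", m)
    expect_lt(abs(t_id - t_un), 0.5)
  }
})

test_that("an error suggests lowering the floor when branches cannot cross", {
  pair <- symmetric_pair()
  expect_error(find_eutectic(pair, floor_t = 299),
               class = "eutectr_solver_error")
  expect_error(find_eutectic(pair, floor_t = 299), regexp = "floor_t")
})

test_that("phase diagrams tabulate both branches with the eutectic attached", {
  pd <- phase_diagram(pair_men_bor,
                      models = list(ideal = activity_ideal()),
                      x_grid = seq(0.1, 0.9, 0.1))
  expect_s3_class(pd, "phase_diagram")
  expect_equal(sort(unique(pd$branches$branch)), c("i", "j"))
  # branch tops approach the pure melting points
  top_i <- liquidus_t_at_x(pair_men_bor, 0.999999)
  expect_equal(top_i, 309.72, tolerance = 1e-3)
  expect_equal(liquidus_t_at_x(pair_men_bor, 0.999999, "j"), 481.33,
               tolerance = 1e-3)
  expect_equal(nrow(pd$eutectics), 1)
  expect_equal(pd$eutectics$t_e_K, 289.91, tolerance = 0.01)
  # degenerate one-point grid still works
  pd1 <- phase_diagram(pair_men_bor, x_grid = 0.5)
  expect_equal(nrow(pd1$branches), 2)
  expect_equal(nrow(pd1$eutectics), 1)
  # tidy/autoplot interfaces
  expect_s3_class(tidy(pd), "tbl_df")
  expect_s3_class(ggplot2::autoplot(pd), "ggplot")
  expect_s3_class(tidy(find_eutectic(pair_men_bor)), "tbl_df")
  expect_s3_class(glance(find_eutectic(pair_men_bor)), "tbl_df")
})

test_that("deep-eutectic classification applies the documented dead band", {
  expect_equal(classify_deep(300.8, 309.6), "negative deviation (DES candidate)")
  expect_equal(classify_deep(300, 300), "~ideal")
  expect_equal(classify_deep(290.0, 289.8), "~ideal")
  expect_equal(classify_deep(310, 300), "positive deviation")
  # boundary behaviour at the default 0.5 K tolerance
  expect_equal(classify_deep(299.5, 300), "~ideal")
  expect_equal(classify_deep(299.49, 300), "negative deviation (DES candidate)")
})

test_that("the flagged published inconsistencies are real", {
  # the printed Thy:Bor ideal point lies on the thymol liquidus but does not
  # solve both branches: the self-consistent eutectic is near 305 K, x 0.65
  eu <- find_eutectic(pair_thy_bor)
  expect_lt(abs(liquidus_x_at_t(pair_thy_bor, 309.6) - 0.722), 0.002)
  expect_equal(eu$t_e, 305.06, tolerance = 0.01)
  expect_equal(eu$x_e, 0.648, tolerance = 0.001)
  # Thy:Cam: the printed temperature is reproduced, the printed composition
  # (0.457) is not self-consistent (solver gives about 0.574)
  eu2 <- find_eutectic(pair_thy_cam)
  expect_equal(eu2$t_e, 300.1, tolerance = 0.2)
  expect_equal(eu2$x_e, 0.574, tolerance = 0.001)
})
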
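empty_compound <- function() {
  tibble::tibble(
    name = "void", formula = NA_character_, mw = 100, t_fus_K = 300,
    dh_fus_kJ_mol = 10, t_b_K = NA_real_,
    unifac_groups = list(stats::setNames(numeric(0), character(0))),
    ljr_groups = list(stats::setNames(numeric(0), character(0)))
  )
}

one_group_compound <- function(group, n = 1, mw = 100) {
  cmp <- empty_compound()
  cmp$mw <- mw
  cmp$ljr_groups <- list(stats::setNames(n, group))
  cmp
}

test_that("boiling point estimate is the base constant plus a linear group sum", {
  # empty group map -> Joback-Reid base constant
  expect_equal(estimate_boiling_point(empty_compound())$t_b_K, 198.2)

  # menthol, hand-summed from the shipped table:
  # 198.2 + 3*23.58 (CH3) + 21.74 (CH) + 3*27.15 (ring CH2)
  #       + 3*21.78 (ring CH) + 92.88 (OH) = 530.35
  men <- terpenes[terpenes$name == "menthol", ]
  expect_equal(estimate_boiling_point(men)$t_b_K, 530.35, tolerance = 1e-10)

  # doubling every count doubles the summed contribution exactly
  men2 <- men
  men2$ljr_groups[[1]] <- men$ljr_groups[[1]] * 2
  expect_equal(estimate_boiling_point(men2)$t_b_K - 198.2,
               2 * (530.35 - 198.2), tolerance = 1e-10)

  # a supplied boiling point is kept
  men$t_b_K <- 489.5
  expect_equal(estimate_boiling_point(men)$t_b_K, 489.5)

  expect_error(estimate_boiling_point(one_group_compound("XYZ")),
               class = "eutectr_validation_error")
})

test_that("critical-property expressions match direct arithmetic on a toy molecule", {
  # one OH group: sums are dtb 92.88, dtc 0.0741, dpc 0.1500, dvc 30.40
  cmp <- one_group_compound("OH", 1, mw = 50)
  cp <- estimate_critical_properties(cmp)
  tb <- 198.2 + 92.88
  expect_equal(cp$t_b_K, tb)
  expect_equal(cp$t_c_K, tb / (0.5703 + 1.0121 * 0.0741 - 0.0741^2),
               tolerance = 1e-12)
  expect_equal(cp$p_c_bar, 50 / (0.2573 + 0.15)^2, tolerance = 1e-12)
  expect_equal(cp$v_c_cm3_mol, 6.75 + 30.40, tolerance = 1e-12)
})

test_that("Vc strictly increases when a positive-contribution group is added", {
  base <- terpenes[terpenes$name == "borneol", ]
  more <- base
  more$ljr_groups[[1]]["CH2"] <- 1
  expect_gt(estimate_critical_properties(more)$v_c_cm3_mol,
            estimate_critical_properties(base)$v_c_cm3_mol)
})

test_that("estimates are invariant to group-map ordering", {
  men <- terpenes[terpenes$name == "menthol", ]
  shuffled <- men
  g <- men$ljr_groups[[1]]
  shuffled$ljr_groups[[1]] <- g[rev(seq_along(g))]
  expect_equal(estimate_critical_properties(shuffled),
               estimate_critical_properties(men))
})

test_that("MLJR critical temperature agrees with a classic Joback evaluation", {
  # cyclohexanol (C6H12O): 5 ring CH2, 1 ring CH, 1 OH; M = 100.16.
  # Classic Joback with its published ring/OH contributions gives
  # Tb = 448.61 K and Tc = 448.61/(0.584 + 0.965*0.1363 - 0.1363^2) = 643.67 K
  # (independent hand evaluation; experimental Tc is 650 K).
  cyhexol <- empty_compound()
  cyhexol$mw <- 100.16
  cyhexol$ljr_groups <- list(c(ring_CH2 = 5, ring_CH = 1, OH = 1))
  cp <- estimate_critical_properties(cyhexol)
  expect_equal(cp$t_b_K, 448.61, tolerance = 1e-6)
  expect_lt(abs(cp$t_c_K - 643.67) / 643.67, 0.01)
})

test_that("acentric factor follows the documented correlations", {
  # at p_c = 1 bar both correlations collapse to the same closed form;
  # direct evaluation at t_b = 350, t_c = 500 gives -1.00571661
  expect_equal(acentric_factor(350, 500, 1, "rudkin"), -1.00571661,
               tolerance = 1e-7)
  expect_equal(acentric_factor(350, 500, 1, "edmister"), -1.00571661,
               tolerance = 1e-7)
  # direct transcription of the Rudkin form at a physical point
  tb <- 420; tc <- 600; pc <- 25
  lg <- log10(pc / 1.01325)
  expect_equal(acentric_factor(tb, tc, pc),
               (tb - 43) * (tc - 43) / ((tc - tb) * (0.7 * tc - 43)) * lg -
                 (tc - 43) / (tc - tb) * lg + lg - 1,
               tolerance = 1e-12)
  # not a function of v_c at all (signature takes t_b, t_c, p_c only)
  expect_named(formals(acentric_factor), c("t_b", "t_c", "p_c", "method"))
  expect_error(acentric_factor(500, 400, 10), class = "eutectr_validation_error")
})

test_that("mixture combining rules reduce to pure components and means", {
  cp <- estimate_critical_properties(terpenes)
  men <- cp[cp$name == "menthol", ]
  # single component at x = 1: Tc, Vc, omega reduce exactly; the Lee-Kesler
  # mixture Pc is a corresponding-states estimate that intentionally does
  # not return the input Pc (the linear rule does)
  mixed <- mix_critical_properties(men, 1)
  expect_equal(mixed$t_c_K, men$t_c_K)
  expect_equal(mixed$v_c_cm3_mol, men$v_c_cm3_mol)
  expect_equal(mixed$omega, men$omega)
  expect_equal(mix_critical_properties(men, 1, rule = "linear")$p_c_bar,
               men$p_c_bar)
  # two identical components at any split
  two <- dplyr::bind_rows(men, men)
  for (x in c(0.2, 0.5, 0.9)) {
    m <- mix_critical_properties(two, c(x, 1 - x))
    expect_equal(m, mixed, tolerance = 1e-12)
  }
  # linear rule gives arithmetic means at 50/50
  pairp <- cp[cp$name %in% c("menthol", "borneol"), ]
  lin <- mix_critical_properties(pairp, c(0.5, 0.5), rule = "linear")
  expect_equal(lin$t_c_K, mean(pairp$t_c_K))
  expect_equal(lin$omega, mean(pairp$omega))
  # symmetry under component exchange
  a <- mix_critical_properties(pairp, c(0.3, 0.7))
  b <- mix_critical_properties(pairp[2:1, ], c(0.7, 0.3))
  expect_equal(a, b, tolerance = 1e-12)
  # continuity: small composition change, small property change
  d <- mix_critical_properties(pairp, c(0.5 + 1e-6, 0.5 - 1e-6))
  m0 <- mix_critical_properties(pairp, c(0.5, 0.5))
  expect_lt(abs(d$t_c_K - m0$t_c_K), 1e-3)
  expect_error(mix_critical_properties(pairp, c(0.5, 0.6)),
               class = "eutectr_validation_error")
})
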
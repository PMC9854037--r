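test_that("built-in materials carry the tabulated densities and closed compositions", {
  expected <- list(
    cobalt = 8.85, stainless_steel_1 = 7.98, stainless_steel_2 = 7.93,
    air = 0.001205, water = 1.0
  )
  for (nm in names(expected)) {
    m <- builtin_material(nm)
    expect_equal(m$density, expected[[nm]])
    expect_lt(abs(sum(m$composition) - 1), 1e-3)
    expect_true(all(m$composition > 0))
  }
})

test_that("material_spec rejects malformed inputs", {
  expect_error(material_spec("x", -1, c(H = 1)), "positive")
  expect_error(material_spec("x", 1, c(H = 0.5, O = 0.4)), "sum to 1")
  expect_error(material_spec("x", 1, c(Xx = 1)), "no embedded coefficients")
  expect_error(material_spec("x", 1, c(0.5, 0.5)), "named")
})

test_that("mixture coefficients reproduce the published water and air anchors", {
  # published mass energy-absorption values at 1.25 MeV: water 0.02965,
  # air 0.02666 cm^2/g; their ratio drives the dose-rate constant
  expect_equal(mass_coefficient("water", 1.25, "mu_en_rho"), 0.02965,
               tolerance = 0.005)
  expect_equal(mass_coefficient("air", 1.25, "mu_en_rho"), 0.02666,
               tolerance = 0.005)
  expect_equal(mass_coefficient("water", 1.25, "mu_rho"), 0.06323,
               tolerance = 0.005)
  ratio <- mass_coefficient("water", 1.25, "mu_en_rho") /
    mass_coefficient("air", 1.25, "mu_en_rho")
  expect_equal(ratio, 1.112, tolerance = 0.005)
})

test_that("log-log interpolation is exact at table nodes and monotone between", {
  tab <- material_coefficients("water")
  at_nodes <- mass_coefficient("water", tab$energy_mev, "mu_rho")
  expect_equal(at_nodes, tab$mu_rho, tolerance = 1e-12)
  # between two nodes the interpolant stays within the bracketing values
  mid <- mass_coefficient("water", sqrt(0.3 * 0.4), "mu_rho")
  lo <- tab$mu_rho[tab$energy_mev == 0.4]
  hi <- tab$mu_rho[tab$energy_mev == 0.3]
  expect_true(mid > lo && mid < hi)
})

test_that("interaction fractions sum to one and behave physically", {
  for (mat in c("water", "air", "stainless_steel_1", "cobalt")) {
    f <- interaction_fractions(mat, c(0.02, 0.1, 0.5, 1.17, 1.33))
    expect_equal(f$f_compton + f$f_photoelectric + f$f_pair,
                 rep(1, 5), tolerance = 1e-12)
    expect_true(all(f$f_pair[f$energy_mev < 1.022] == 0))
  }
  # Compton dominates in water at the source energies
  fw <- interaction_fractions("water", 1.25)
  expect_gt(fw$f_compton, 0.99)
  # photoelectric dominates in steel at 20 keV
  fs <- interaction_fractions("stainless_steel_1", 0.02)
  expect_gt(fs$f_photoelectric, 0.9)
})

test_that("the closed-form Klein-Nishina total matches quadrature of the differential", {
  re2 <- 2.8179403262e-13^2
  for (E in c(0.05, 0.3, 1.17, 1.33)) {
    a <- E / 0.51099895
    # dsigma/deps = (pi re^2 / a) (eps + 1/eps)(1 - eps sin^2 / (1+eps^2))
    quad <- integrate(function(e) kn_density(e, E),
                      1 / (1 + 2 * a), 1, rel.tol = 1e-12)$value *
      pi * re2 / a
    expect_equal(kn_cross_section(E), quad, tolerance = 1e-9)
  }
})
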
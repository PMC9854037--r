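test_that("scoring grid cells take the zone-appropriate dimensions", {
  g <- build_scoring_grid(r = c(0.5, 1.0, 2.0, 3.0, 5.0))
  expect_equal(g$thickness, c(0.025, 0.025, 0.05, 0.1, 0.1))
  expect_equal(g$height, c(0.005, 0.005, 0.05, 0.1, 0.1))
  expect_error(build_scoring_grid(r = 12), "r <= 10")
  expect_error(build_scoring_grid(r = 0), "r <= 10")
  yz <- build_scoring_grid(yz = cbind(y = c(1, 3), z = c(0, 4)))
  expect_equal(yz$r, c(1, 5))
  expect_equal(yz$theta, c(90, atan2(3, 4) * 180 / pi))
})

test_that("ring cell volumes match the analytic annulus formula", {
  g <- build_scoring_grid(r = c(0.5, 2, 5), theta = c(30, 90))
  v <- tg43co:::grid_cell_volume(g)
  m <- tg43co:::grid_cell_matrix(g)
  ref <- pi * (m[, "rout"]^2 - m[, "rin"]^2) * g$height
  expect_equal(v, ref, tolerance = 1e-10)
  expect_true(all(v > 0))
})

test_that("decay sampling emits the two-line spectrum uniformly from the core", {
  src <- builtin_source("1_2")
  set.seed(1)
  d <- sample_decay(src, 5000)
  expect_equal(nrow(d), 10000)
  expect_true(all(d$weight == 1))
  # exactly one photon of each line per decay
  per_decay <- tapply(d$energy, d$decay, function(e) sort(e))
  expect_true(all(vapply(per_decay, identical, logical(1), c(1.17, 1.33))))
  # positions inside the core
  expect_true(all(d$x^2 + d$y^2 <= src$core_radius^2 + 1e-12))
  expect_true(all(abs(d$z) <= src$core_length / 2 + 1e-12))
  # mean emission position consistent with the core center within 3 sigma
  se_xy <- src$core_radius / sqrt(2) / sqrt(5000)
  se_z <- src$core_length / sqrt(12) / sqrt(5000)
  expect_lt(abs(mean(d$x[!duplicated(d$decay)])), 3 * se_xy)
  expect_lt(abs(mean(d$z[!duplicated(d$decay)])), 3 * se_z)
  # unit directions
  expect_equal(d$dx^2 + d$dy^2 + d$dz^2, rep(1, 10000), tolerance = 1e-12)
  # determinism
  set.seed(1)
  expect_identical(d, sample_decay(src, 5000))
})

test_that("Compton samples satisfy the scattering relation and match quadrature moments", {
  set.seed(5)
  E <- 1.25
  s <- sample_compton(E, 1e6)
  a <- E / 0.51099895
  # exact kinematics for every sample
  expect_equal(s$energy, E / (1 + a * (1 - cos(s$angle))), tolerance = 1e-9)
  # energy bounds: backscatter floor at E/(1+2a)
  expect_true(all(s$energy >= E / (1 + 2 * a) - 1e-12))
  expect_true(all(s$energy <= E + 1e-12))
  # mean retained fraction vs numerical quadrature of the Klein-Nishina
  # differential cross section, within 0.2%
  expect_equal(mean(s$energy) / E, kn_mean_fraction(E), tolerance = 0.002)
  # backscatter energy at 1.33 MeV
  expect_equal(1.33 / (1 + 2 * 1.33 / 0.51099895), 0.2144, tolerance = 1e-3)
  expect_error(sample_compton(-1, 10), "positive")
})

test_that("water simulation is reproducible bit-for-bit from the seed", {
  src <- builtin_source("1_2")
  grid <- build_scoring_grid(r = c(1, 2))
  a <- run_water_simulation(src, grid, 2000, seed = 99)
  b <- run_water_simulation(src, grid, 2000, seed = 99)
  expect_identical(a$kerma_per_decay, b$kerma_per_decay)
  expect_identical(a$rel_unc, b$rel_unc)
  c <- run_water_simulation(src, grid, 2000, seed = 100)
  expect_false(identical(a$kerma_per_decay, c$kerma_per_decay))
  expect_equal(attr(a, "estimator"), "collision kerma, track-length")
  expect_true(all(a$kerma_per_decay >= 0))
  expect_identical(a$kerma_approx, c(FALSE, FALSE))
})

test_that("energy is conserved over a full analog run", {
  src <- builtin_source("1_2")
  grid <- build_scoring_grid(r = 1)
  w <- run_water_simulation(src, grid, 5000, seed = 3)
  led <- attr(w, "energy_ledger")
  expect_equal(led[["emitted"]], 5000 * (1.17 + 1.33), tolerance = 1e-12)
  imbalance <- abs(led[["emitted"]] - led[["absorbed"]] - led[["escaped"]]) /
    led[["emitted"]]
  expect_lt(imbalance, 1e-9)
})

test_that("primary-only bare transport matches the closed-form attenuation law", {
  src <- builtin_source("1_2")
  grid <- build_scoring_grid(r = c(2, 5, 8))
  w <- run_water_simulation(src, grid, 3e5, seed = 21, mode = "primary_only",
                            bare = TRUE)
  oracle <- primary_kerma_oracle(grid$r)
  for (i in seq_len(nrow(grid))) {
    rel <- w$kerma_per_decay[i] / oracle[i] - 1
    expect_lt(abs(rel), 3 * w$rel_unc[i] + 0.003)
  }
})

test_that("statistical uncertainty scales as one over root n", {
  src <- builtin_source("1_2")
  grid <- build_scoring_grid(r = 1)
  ns <- c(1e5, 4e5, 1.6e6)
  u <- vapply(seq_along(ns), function(i)
    run_water_simulation(src, grid, ns[i], seed = 30 + i)$rel_unc,
    numeric(1))
  expect_equal(u[1] / u[2], 2, tolerance = 0.2)
  expect_equal(u[2] / u[3], 2, tolerance = 0.2)
})

test_that("azimuthal symmetry: independent seeds agree within uncertainties", {
  src <- builtin_source("3")
  grid <- build_scoring_grid(r = 2, theta = c(30, 90, 150))
  a <- run_water_simulation(src, grid, 4e5, seed = 51)
  b <- run_water_simulation(src, grid, 4e5, seed = 52)
  for (i in seq_len(nrow(grid))) {
    z <- abs(a$kerma_per_decay[i] - b$kerma_per_decay[i]) /
      sqrt((a$kerma_per_decay[i] * a$rel_unc[i])^2 +
           (b$kerma_per_decay[i] * b$rel_unc[i])^2)
    expect_lt(z, 4)
  }
})

test_that("air simulation validates geometry and scales with inverse square", {
  src <- builtin_source("1_2")
  expect_error(run_air_simulation(src, 10, scoring_distance = 0.05),
               "capsule radius")
  expect_error(run_air_simulation(src, 10, scoring_distance = 200),
               "air cube")
  # bare-source S_k against the closed-form primary air-kerma oracle
  ak <- run_air_simulation(src, 3e5, seed = 61, bare = TRUE)
  lines <- c(1.17, 1.33)
  mu_air <- mass_coefficient("air", lines) * 0.001205
  muen <- mass_coefficient("air", lines, "mu_en_rho")
  oracle <- sum(lines * muen * exp(-mu_air * 100)) / (4 * pi * 1e4) *
    1.602176634e-10 * 3600 * 1e4 * 100
  expect_equal(ak$sk_per_bq, oracle, tolerance = 3 * ak$rel_unc + 0.01)
  # inverse-square invariance between 50 and 100 cm after d^2 scaling
  a50 <- run_air_simulation(src, 6e5, seed = 62, scoring_distance = 50,
                            bare = TRUE)
  a100 <- run_air_simulation(src, 6e5, seed = 63, scoring_distance = 100,
                             bare = TRUE)
  tol <- 0.01 + 3 * sqrt(a50$rel_unc^2 + a100$rel_unc^2)
  expect_equal(a50$sk_per_bq / a100$sk_per_bq, 1, tolerance = tol)
})

test_that("capsule attenuation lowers the primary air-kerma strength", {
  src <- builtin_source("1_2")
  enc <- run_air_simulation(src, 6e6, seed = 71, mode = "primary_only")
  bare <- run_air_simulation(src, 6e6, seed = 72, mode = "primary_only",
                             bare = TRUE)
  expect_lt(enc$sk_per_bq, bare$sk_per_bq)
})
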
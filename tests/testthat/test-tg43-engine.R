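test_that("geometry factor reproduces the closed forms and limits", {
  expect_equal(geometry_factor(2, 45, 0), 0.25, tolerance = 1e-15)
  expect_equal(geometry_factor(1, 90, 0.1), 2 * atan(0.05) / 0.1,
               tolerance = 1e-12)
  expect_equal(geometry_factor(1, 0, 0.1), 1 / (1 - 0.0025),
               tolerance = 1e-12)
  expect_error(geometry_factor(0.03, 0, 0.1), "active line")
  expect_error(geometry_factor(-1, 90, 0.1), "positive")
  expect_error(geometry_factor(1, 200, 0.1), "degrees")
})

test_that("geometry factor matches the numerical line integral", {
  for (L in c(0.1, 0.2)) {
    for (r in c(0.25, 1, 2, 5, 10)) {
      for (th in c(0.01, 0.5, 5, 30, 60, 90, 120, 175, 179.99)) {
        expect_equal(geometry_factor(r, th, L),
                     geometry_factor_quadrature(r, th, L),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("geometry factor is mirror symmetric and tends to inverse square", {
  th <- c(1, 10, 45, 80)
  expect_equal(geometry_factor(2, th, 0.2),
               geometry_factor(2, 180 - th, 0.2), tolerance = 1e-14)
  for (r in c(0.25, 1, 5)) {
    rel <- abs(geometry_factor(r, 90, 0.1) * r^2 - 1)
    expect_lt(rel, 0.1^2 / (2 * r^2))
  }
})

test_that("parameter interpolation is exact at nodes and normalized", {
  p <- fixture_params("ch12")
  g <- p$g
  ip <- interp_parameters(p, g$r, 90)
  expect_equal(ip$g, g$g, tolerance = 1e-12)
  expect_equal(interp_parameters(p, 1, 90)$g, 1, tolerance = 1e-15)
  expect_true(all(abs(interp_parameters(p, c(0.5, 3, 7), 90)$F - 1) < 1e-12))
  # arbitrary tabulated node of the F table
  expect_equal(interp_parameters(p, 2, 30)$F, p$F_table["2", "30"],
               tolerance = 1e-12)
  expect_error(interp_parameters(p, 12, 90), "outside")
  expect_equal(interp_parameters(p, 12, 90, extrapolate = TRUE)$g,
               g$g[g$r == 10], tolerance = 1e-12)
})

test_that("2D dose rate reproduces the hand-evaluated chains", {
  p <- fixture_params("ch12")
  # reference point: all ratios unity
  expect_equal(dose_rate_2d(p, 1, 90, sk = 1), p$lambda, tolerance = 1e-12)
  # transverse point at 2 cm: Lambda g(2) G(2,90)/G(1,90)
  d2 <- dose_rate_2d(p, 2, 90, sk = 1)
  expect_equal(d2, 1.115 * 0.981 * geometry_factor(2, 90, 0.1) /
                 geometry_factor(1, 90, 0.1), tolerance = 1e-12)
  expect_equal(round(d2, 4), 0.2736)
  expect_equal(dose_rate_2d(p, 2, 90, sk = 0), 0)
  expect_equal(dose_rate_2d(p, 3, 45, sk = 2),
               2 * dose_rate_2d(p, 3, 45, sk = 1), tolerance = 1e-14)
})

test_that("1D dose rate uses the tabulated 1D anisotropy", {
  p <- fixture_params("ch12")
  d1 <- dose_rate_1d(p, 2, sk = 1)
  expect_equal(d1, dose_rate_2d(p, 2, 90, sk = 1) * 0.993,
               tolerance = 1e-12)
  expect_equal(round(d1, 4), 0.2717)
  # forcing phi_an = 1 recovers S_k Lambda at the reference radius
  p1 <- p
  p1$phi_an <- data.frame(r = c(1, 10), phi_an = c(1, 1))
  expect_equal(dose_rate_1d(p1, 1, sk = 3), 3 * p$lambda, tolerance = 1e-12)
  expect_error(dose_rate_1d(p, 0.5), "phi_an")
})

test_that("dose rate is continuous across the transverse plane and nodes", {
  p <- fixture_params("ch12")
  eps <- 1e-9
  expect_equal(dose_rate_2d(p, 2, 90 - eps), dose_rate_2d(p, 2, 90 + eps),
               tolerance = 1e-6)
  expect_equal(dose_rate_2d(p, 3 - 1e-12, 45), dose_rate_2d(p, 3 + 1e-12, 45),
               tolerance = 1e-9)
})

test_that("along-away table maps the reference cell and marks out-of-range cells", {
  p <- fixture_params("ch12")
  aa <- along_away_table(p, y = c(0, 1, 10), z = c(-10, 0, 10))
  expect_s3_class(aa, "along_away")
  expect_equal(aa["0", "1"], p$lambda, tolerance = 1e-12)
  # y = z = 0 is inside the source region -> below the minimum radius
  expect_true(is.na(aa["0", "0"]))
  # corner at r = sqrt(200) > 10 cm is outside the table
  expect_true(is.na(aa["10", "10"]))
  finite <- aa[!is.na(aa)]
  expect_true(all(finite > 0))
})

test_that("along-away table is z-symmetric once F is symmetrized", {
  p <- fixture_params("ch12")
  # symmetric synthetic F on a theta grid closed under theta -> 180 - theta
  tv <- c(10, 30, 60, 90, 120, 150, 170)
  rv <- c(0.25, 1, 4, 10)
  Fs <- outer(rv, tv, function(r, t) 1 - 0.1 * cos(t * pi / 180)^2)
  dimnames(Fs) <- list(rv, tv)
  ps <- tg43_parameters(p$channel, p$L, p$lambda, p$g, F_table = Fs,
                        phi_an = p$phi_an)
  aa <- along_away_table(ps, y = c(0.5, 2, 6), z = c(-4, -1, 1, 4))
  expect_equal(aa["-4", ], aa["4", ], tolerance = 1e-12)
  expect_equal(aa["-1", ], aa["1", ], tolerance = 1e-12)
})

test_that("the full QA grid computes without error and is positive where defined", {
  p <- fixture_params("ch3")
  aa <- along_away_table(p)
  expect_equal(dim(aa), c(25, 14))
  finite <- aa[!is.na(aa)]
  expect_true(all(is.finite(finite)) && all(finite > 0))
})
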
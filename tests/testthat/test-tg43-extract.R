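# round-trip scaffolding: forward model -> noise-free grid -> extraction
roundtrip_setup <- function(channel = "ch12") {
  p <- fixture_params(channel)
  rs <- p$g$r
  ths <- c(5, 10, 20, 30, 45, 60, 75, 90, 105, 120, 135, 150, 165, 175)
  grid <- build_scoring_grid(r = rs, theta = ths)
  sk <- 2.985e-07
  water <- synthesize_dose_grid(p, grid, sk_per_bq = sk)
  list(p = p, grid = grid, water = water, sk = sk)
}

test_that("engine then extraction is the identity on noise-free grids", {
  for (ch in c("ch12", "ch3")) {
    rt <- roundtrip_setup(ch)
    lam <- dose_rate_constant(rt$water, rt$sk)
    expect_equal(lam$lambda, rt$p$lambda, tolerance = 1e-9)
    g <- radial_dose_function(rt$water, rt$p$L)
    expect_equal(g$g, rt$p$g$g, tolerance = 1e-9)
    Fm <- anisotropy_2d(rt$water, rt$p$L)
    ref <- interp_parameters(rt$p, rep(rt$p$g$r, each = 14),
                             rep(as.numeric(colnames(Fm)), 14))$F
    expect_equal(as.vector(t(Fm)), ref, tolerance = 1e-9)
  }
})

test_that("the two phi_an routes through the dose grid agree", {
  rt <- roundtrip_setup("ch12")
  Fm <- anisotropy_2d(rt$water, rt$p$L)
  for (r in c(1, 2, 5)) {
    via_F <- anisotropy_1d(Fm, r, rt$p$L)
    via_grid <- anisotropy_1d(rt$water, r, rt$p$L)
    expect_equal(via_F, via_grid, tolerance = 1e-6)
  }
})

test_that("phi_an of a point-isotropic field is exactly one", {
  ths <- c(0, 5, 15, 30, 45, 60, 75, 90, 105, 120, 135, 150, 165, 175)
  Fm <- matrix(1, 3, length(ths), dimnames = list(c(1, 2, 5), ths))
  expect_equal(anisotropy_1d(Fm, 2, L = 0), 1, tolerance = 1e-12)
})

test_that("phi_an integration converges under theta refinement", {
  # smooth synthetic anisotropy evaluated on coarse and halved grids
  f <- function(th) 1 - 0.05 * cos(th * pi / 180)^2
  th1 <- seq(0, 180, by = 10)
  th2 <- seq(0, 180, by = 5)
  F1 <- matrix(f(th1), 1, dimnames = list(2, th1))
  F2 <- matrix(f(th2), 1, dimnames = list(2, th2))
  v1 <- anisotropy_1d(F1, 2, L = 0.1)
  v2 <- anisotropy_1d(F2, 2, L = 0.1)
  expect_lt(abs(v1 - v2), 1e-4)
})

test_that("phi_an from the printed channel-1/2 anisotropy column matches the table", {
  p <- fixture_params("ch12")
  got <- anisotropy_1d(p$F_table, 2, L = 0.1)
  expect_equal(got, 0.993, tolerance = 0.005)
  expect_error(anisotropy_1d(p$F_table, 0.25, L = 0.1), "coverage")
})

test_that("dose-rate constant is a per-decay ratio with scale invariance", {
  grid <- build_scoring_grid(r = 1)
  w <- as.data.frame(grid)
  w$kerma_per_decay <- 1.115 / (3600 * 100)
  w$rel_unc <- 0
  expect_equal(dose_rate_constant(w, 1)$lambda, 1.115, tolerance = 1e-12)
  w2 <- w
  w2$kerma_per_decay <- 2 * w$kerma_per_decay
  expect_equal(dose_rate_constant(w2, 2)$lambda, 1.115, tolerance = 1e-12)
  w$r <- 2
  expect_error(dose_rate_constant(w, 1), "no cell")
})

test_that("radial dose function of an inverse-square field is unity", {
  rs <- c(0.5, 1, 2, 5, 10)
  grid <- build_scoring_grid(r = rs)
  w <- as.data.frame(grid)
  w$kerma_per_decay <- 1e-13 / rs^2
  w$rel_unc <- 0
  g <- radial_dose_function(w, L = 0)
  expect_equal(g$g, rep(1, 5), tolerance = 1e-12)
})

test_that("anisotropy of an isotropic point field is unity everywhere", {
  grid <- build_scoring_grid(r = c(1, 2), theta = c(30, 90, 150))
  w <- as.data.frame(grid)
  w$kerma_per_decay <- 1e-13 / w$r^2
  w$rel_unc <- 0
  Fm <- anisotropy_2d(w, L = 0)
  expect_equal(as.vector(Fm), rep(1, 6), tolerance = 1e-12)
})

test_that("radial table comparison reproduces the printed cross-code statistics", {
  cmp <- compare_radial_tables(
    data.frame(r = c(1, 2), g = c(1, 0.98)),
    data.frame(r = c(1, 2), g = c(1, 0.98)))
  expect_equal(cmp$per_r$diff_pct, c(0, 0))
  expect_equal(cmp$max_abs_pct, 0)
  # antisymmetry up to the denominator convention
  ga <- data.frame(r = c(1, 2, 3), g = c(1, 0.98, 0.95))
  gb <- data.frame(r = c(1, 2, 3), g = c(1, 0.99, 0.94))
  ab <- compare_radial_tables(ga, gb, "relative_to_a")
  ba <- compare_radial_tables(gb, ga, "relative_to_b")
  expect_equal(ab$per_r$diff_pct, ba$per_r$diff_pct, tolerance = 1e-12)
  expect_error(compare_radial_tables(ga, gb[1:2, ]), "radius grid")
})

test_that("uncertainty budgets combine in quadrature", {
  expect_equal(round(uncertainty_budget(c(1.21, 1.34, 1.24))$total_pct, 2),
               2.19)
  expect_equal(round(uncertainty_budget(c(1.19, 1.42, 1.35))$total_pct, 2),
               2.29)
  expect_equal(uncertainty_budget(3.7)$total_pct, 3.7)
  expect_equal(uncertainty_budget(numeric(0))$total_pct, 0)
  expect_error(uncertainty_budget(c(1, -2)), ">= 0")
  # permutation invariance and first-degree homogeneity
  x <- c(0.4, 1.1, 2.2, 0.9)
  expect_equal(uncertainty_budget(x)$total_pct,
               uncertainty_budget(rev(x))$total_pct)
  expect_equal(uncertainty_budget(3 * x)$total_pct,
               3 * uncertainty_budget(x)$total_pct, tolerance = 1e-12)
})

test_that("extract_tg43 bundles a complete parameter set from a synthetic grid", {
  rt <- roundtrip_setup("ch3")
  ps <- extract_tg43(rt$water, rt$sk, L = rt$p$L)
  expect_s3_class(ps, "tg43_parameters")
  expect_equal(ps$lambda, rt$p$lambda, tolerance = 1e-9)
  expect_equal(ps$g$g, rt$p$g$g, tolerance = 1e-9)
  expect_false(is.null(ps$F_table))
  expect_true(all(is.finite(ps$phi_an$phi_an)))
  expect_true(all(ps$phi_an$phi_an > 0.9 & ps$phi_an$phi_an < 1.05))
})
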
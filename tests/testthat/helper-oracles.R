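# Independent oracles used across the test files. These deliberately avoid
# the package's own computational paths.

# brute-force ray marching through the nested-cylinder source geometry:
# classify points every `step` cm along the ray and sum per-material lengths
# until the ray leaves the capsule cylinder.
march_path_lengths <- function(spec, origin, direction, step = 1e-5) {
  cap_r <- spec$capsule_outer_diameter / 2
  off <- spec$core_axial_offset
  cap_z <- c(-off - spec$capsule_length / 2, -off + spec$capsule_length / 2)
  # analytic exit t from the capsule cylinder (radial and axial)
  a <- sum(direction[1:2]^2)
  texit <- Inf
  if (a > 1e-14) {
    b <- sum(origin[1:2] * direction[1:2])
    cc <- sum(origin[1:2]^2) - cap_r^2
    disc <- b^2 - a * cc
    if (disc > 0) texit <- min(texit, (-b + sqrt(disc)) / a)
  }
  if (abs(direction[3]) > 1e-14) {
    tz <- if (direction[3] > 0) (cap_z[2] - origin[3]) / direction[3]
          else (cap_z[1] - origin[3]) / direction[3]
    texit <- min(texit, max(0, tz))
  }
  ts <- seq(step / 2, texit, by = step)
  px <- origin[1] + ts * direction[1]
  py <- origin[2] + ts * direction[2]
  pz <- origin[3] + ts * direction[3]
  rho2 <- px^2 + py^2
  in_core <- rho2 <= spec$core_radius^2 &
    pz >= -spec$core_length / 2 & pz <= spec$core_length / 2
  in_cap <- rho2 <= cap_r^2 & pz >= cap_z[1] & pz <= cap_z[2] & !in_core
  c(core = sum(in_core) * step, capsule = sum(in_cap) * step)
}

# Klein-Nishina differential cross section in the scattered energy
# fraction eps (unnormalized), for quadrature oracles
kn_density <- function(eps, energy) {
  a <- energy / 0.51099895
  t <- (1 - eps) / (a * eps)
  sin2 <- t * (2 - t)
  (1 / eps + eps) * (1 - eps * sin2 / (1 + eps^2))
}

# mean fraction of energy retained by the scattered photon
kn_mean_fraction <- function(energy) {
  a <- energy / 0.51099895
  lo <- 1 / (1 + 2 * a)
  num <- integrate(function(e) e * kn_density(e, energy), lo, 1,
                   rel.tol = 1e-10)$value
  den <- integrate(function(e) kn_density(e, energy), lo, 1,
                   rel.tol = 1e-10)$value
  num / den
}

# line-source geometry factor by numerical integration of dl / d^2 along
# the active segment
geometry_factor_quadrature <- function(r, theta_deg, L) {
  th <- theta_deg * pi / 180
  y <- r * sin(th)
  z <- r * cos(th)
  integrate(function(l) 1 / (y^2 + (z - l)^2), -L / 2, L / 2,
            rel.tol = 1e-13, abs.tol = 0)$value / L
}

# closed-form primary collision kerma (Gy per decay) of a bare point
# source with the two-line spectrum at distance r in water
primary_kerma_oracle <- function(r, medium = "water",
                                 density = builtin_material(medium)$density) {
  lines <- c(1.17, 1.33)
  mu <- mass_coefficient(medium, lines, "mu_rho") * density
  muen <- mass_coefficient(medium, lines, "mu_en_rho")
  vapply(r, function(ri)
    sum(lines * muen * exp(-mu * ri)) / (4 * pi * ri^2) * 1.602176634e-10,
    numeric(1))
}

# reference TG-43 parameter set built from the packaged tables
fixture_params <- function(channel = c("ch12", "ch3")) {
  channel <- match.arg(channel)
  fx <- load_fixtures()
  g <- fx$radial_dose
  gcol <- if (channel == "ch12") g$ch12_geant4 else g$ch3_geant4
  lam <- if (channel == "ch12") 1.115 else 1.116
  L <- if (channel == "ch12") 0.1 else 0.2
  ani <- fx$anisotropy[[channel]]
  tg43_parameters(channel = if (channel == "ch12") "1_2" else "3",
                  L = L, lambda = lam,
                  g = data.frame(r = g$r_cm, g = gcol),
                  F_table = ani$F, phi_an = ani$phi_an,
                  code = "fixture")
}
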
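#' Define a material by density and elemental mass fractions
#'
#' A material is a named density plus a set of (element, mass fraction)
#' pairs. Photon interaction coefficients of the material are obtained by
#' mass-fraction additivity over the embedded element coefficient table
#' (the standard mixture rule), so any alloy or compound made of the
#' supported elements (H, C, N, O, Si, Ar, Ti, Cr, Mn, Fe, Co, Ni) can be
#' described.
#'
#' @param name character label.
#' @param density mass density in g/cm^3, positive.
#' @param composition named numeric vector of elemental mass fractions;
#'   names are element symbols, values must sum to 1 within 1e-3.
#' @return An object of class `material_spec`: a list with elements
#'   `name`, `density` and `composition`.
#' @examples
#' material_spec("water", 1.0, c(H = 0.111901, O = 0.888099))
#' @export
material_spec <- function(name, density, composition) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("density must be a single positive number")
  if (is.null(names(composition)) || any(names(composition) == ""))
    stop("composition must be a named numeric vector of mass fractions")
  known <- element_coefficients()$element
  bad <- setdiff(names(composition), unique(known))
  if (length(bad))
    stop("no embedded coefficients for element(s): ", paste(bad, collapse = ", "))
  if (any(composition < 0)) stop("mass fractions must be non-negative")
  if (abs(sum(composition) - 1) > 1e-3)
    stop("mass fractions must sum to 1 within 1e-3 (got ",
         format(sum(composition)), ")")
  structure(list(name = name, density = density, composition = composition),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat("<material_spec>", x$name, sprintf("(%.6g g/cm3)\n", x$density))
  comp <- paste(sprintf("%s %.6g", names(x$composition), x$composition),
                collapse = ", ")
  cat(" ", comp, "\n")
  invisible(x)
}

#' Built-in materials of the source model
#'
#' The five materials of the simulated system: the metallic cobalt active
#' core, the two stainless-steel alloys used for the capsule and the drive
#' cable, dry air (0% humidity) and liquid water. Densities and mass
#' fractions follow the manufacturer material specification of the source.
#'
#' @param name one of `"cobalt"`, `"stainless_steel_1"`,
#'   `"stainless_steel_2"`, `"air"`, `"water"`.
#' @return A [material_spec()] object.
#' @examples
#' builtin_material("cobalt")$density  # 8.85
#' @export
builtin_material <- function(name = c("cobalt", "stainless_steel_1",
                                      "stainless_steel_2", "air", "water")) {
  name <- match.arg(name)
  switch(name,
    cobalt = material_spec("cobalt", 8.85, c(Co = 1)),
    stainless_steel_1 = material_spec("stainless_steel_1", 7.98,
      c(C = 0.001, Si = 0.007, Mn = 0.01, Cr = 0.18, Ni = 0.1, Ti = 0.004,
        Fe = 0.698)),
    stainless_steel_2 = material_spec("stainless_steel_2", 7.93,
      c(C = 0.001, Si = 0.007, Mn = 0.01, Cr = 0.18, Ni = 0.09, Fe = 0.712)),
    air = material_spec("air", 0.001205,
      c(C = 0.000124, N = 0.755268, O = 0.231781, Ar = 0.012827)),
    water = material_spec("water", 1.0, c(H = 0.111901, O = 0.888099))
  )
}

#' Embedded element photon coefficient table
#'
#' Mass attenuation (`mu_rho`) and mass energy-absorption (`mu_en_rho`)
#' coefficients, both in cm^2/g, on a common 10 keV to 1.5 MeV energy grid
#' for the elements needed by the built-in materials. Compiled once from
#' the standard published photon-coefficient compilations and shipped as
#' package data; values between grid points are obtained by log-log
#' interpolation.
#'
#' @return data.frame with columns `element`, `Z`, `A`, `energy_mev`,
#'   `mu_rho`, `mu_en_rho`.
#' @export
element_coefficients <- function() {
  if (is.null(.tg43co_cache$elements)) {
    path <- system.file("extdata", "photon_mass_coefficients.csv",
                        package = "tg43co", mustWork = TRUE)
    .tg43co_cache$elements <- utils::read.csv(path)
  }
  .tg43co_cache$elements
}

#' Photon coefficient table for a material
#'
#' Builds the material's mass attenuation and mass energy-absorption
#' coefficients by mass-fraction additivity over the element table, and
#' the per-interaction fractions (Compton / photoelectric / pair). The
#' Compton part is the exact Klein-Nishina cross section per electron
#' times the material's electrons per gram; the non-Compton remainder of
#' the total is attributed to photoelectric absorption below the 1.022 MeV
#' pair threshold and to pair production above it.
#'
#' @param material a [material_spec()] or the name of a built-in material.
#' @return data.frame with columns `energy_mev`, `mu_rho`, `mu_en_rho`,
#'   `f_compton`, `f_photoelectric`, `f_pair` (fractions sum to 1), with
#'   attributes `density` and `z_over_a` (electrons per atomic mass unit).
#' @export
material_coefficients <- function(material) {
  material <- as_material(material)
  key <- paste0(material$name, "#", material$density, "#",
                paste(names(material$composition), material$composition,
                      collapse = ";"))
  hit <- .tg43co_cache$materials[[key]]
  if (!is.null(hit)) return(hit)
  el <- element_coefficients()
  E <- sort(unique(el$energy_mev))
  mu <- numeric(length(E)); men <- numeric(length(E)); zoa <- 0
  for (sym in names(material$composition)) {
    w <- material$composition[[sym]]
    rows <- el[el$element == sym, ]
    rows <- rows[order(rows$energy_mev), ]
    stopifnot(identical(rows$energy_mev, E))
    mu <- mu + w * rows$mu_rho
    men <- men + w * rows$mu_en_rho
    zoa <- zoa + w * rows$Z[1] / rows$A[1]
  }
  # Compton fraction from the analytic Klein-Nishina cross section
  mu_c <- pmin(kn_cross_section(E) * 6.02214076e23 * zoa, mu)
  rest <- mu - mu_c
  out <- data.frame(energy_mev = E, mu_rho = mu, mu_en_rho = men,
                    f_compton = mu_c / mu,
                    f_photoelectric = ifelse(E < 1.022, rest / mu, 0),
                    f_pair = ifelse(E < 1.022, 0, rest / mu))
  attr(out, "density") <- material$density
  attr(out, "z_over_a") <- zoa
  if (is.null(.tg43co_cache$materials))
    .tg43co_cache$materials <- list()
  .tg43co_cache$materials[[key]] <- out
  out
}

as_material <- function(x) {
  if (inherits(x, "material_spec")) return(x)
  if (is.character(x) && length(x) == 1L) return(builtin_material(x))
  stop("expected a material_spec or a built-in material name")
}

#' Interpolate material coefficients at arbitrary photon energies
#'
#' Log-log interpolation of the embedded coefficient tables; exact at
#' table nodes. Energies are clamped to the 10 keV - 1.5 MeV tabulated
#' range.
#'
#' @param material a [material_spec()] or built-in material name.
#' @param energy photon energies in MeV (vectorized).
#' @param what `"mu_rho"` (mass attenuation) or `"mu_en_rho"` (mass
#'   energy-absorption), both cm^2/g.
#' @return numeric vector of coefficients.
#' @export
mass_coefficient <- function(material, energy,
                             what = c("mu_rho", "mu_en_rho")) {
  what <- match.arg(what)
  if (any(energy <= 0)) stop("energy must be positive (MeV)")
  tab <- material_coefficients(material)
  loglog_interp(tab$energy_mev, tab[[what]], energy)
}

#' Per-interaction fractions at given photon energies
#'
#' @inheritParams mass_coefficient
#' @return data.frame with columns `energy_mev`, `f_compton`,
#'   `f_photoelectric`, `f_pair` (rows sum to 1).
#' @export
interaction_fractions <- function(material, energy) {
  tab <- material_coefficients(material)
  f <- vapply(c("f_compton", "f_photoelectric", "f_pair"), function(col) {
    # fractions interpolated linearly in log E; pair kept zero below threshold
    stats::approx(log(tab$energy_mev), tab[[col]], log(pmin(pmax(energy,
      min(tab$energy_mev)), max(tab$energy_mev))), rule = 2)$y
  }, numeric(length(energy)))
  f <- matrix(f, nrow = length(energy))
  f[energy < 1.022, 3] <- 0
  f <- f / rowSums(f)
  data.frame(energy_mev = energy, f_compton = f[, 1],
             f_photoelectric = f[, 2], f_pair = f[, 3])
}

#' Total Klein-Nishina cross section per electron
#'
#' Closed-form integral of the Klein-Nishina differential cross section
#' over all scattering angles, for a free stationary electron.
#'
#' @param energy photon energies in MeV (vectorized, positive).
#' @return cross sections in cm^2 per electron.
#' @examples
#' kn_cross_section(1.25)  # ~1.888e-25 cm^2
#' @export
kn_cross_section <- function(energy) {
  if (any(energy <= 0)) stop("energy must be positive")
  a <- energy / 0.51099895
  re2 <- 2.8179403262e-13^2
  2 * pi * re2 * ((1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) -
                                     log(1 + 2 * a) / a) +
                  log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2)
}

# log-log interpolation with clamping outside the grid
loglog_interp <- function(x, y, xout) {
  xo <- pmin(pmax(xout, min(x)), max(x))
  exp(stats::approx(log(x), log(y), log(xo), rule = 2)$y)
}
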
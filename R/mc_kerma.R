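#' Build a cylindrical-ring scoring grid
#'
#' Ring-shaped scoring cells centered on the requested sampling positions,
#' with zone-dependent dimensions: radial thickness 0.025 cm and height
#' 0.005 cm for cells whose center lies at 0 < r <= 1 cm from the source
#' center, 0.05/0.05 cm for 1 < r < 3 cm, and 0.1/0.1 cm for
#' 3 <= r <= 10 cm. Positions may be given either as polar samples
#' (`r`, `theta`) or directly as away/along pairs via `yz`.
#'
#' @param r radial sample distances from the source center, cm (0, 10].
#' @param theta polar angles in degrees (recycled against `r` by
#'   crossing: one cell per (r, theta) combination).
#' @param yz optional two-column matrix or data.frame of (y, z) cell
#'   centers in cm (y = away from the axis, z = along); overrides
#'   `r`/`theta`.
#' @return data.frame of class `scoring_grid` with one row per cell:
#'   `r`, `theta`, `y`, `z`, `thickness`, `height`.
#' @examples
#' build_scoring_grid(r = c(0.5, 2, 5))[, c("r", "thickness", "height")]
#' @export
build_scoring_grid <- function(r = NULL, theta = 90, yz = NULL) {
  if (!is.null(yz)) {
    yz <- as.matrix(yz)
    stopifnot(ncol(yz) == 2)
    y <- yz[, 1]; z <- yz[, 2]
    rr <- sqrt(y^2 + z^2)
    th <- atan2(y, z) * 180 / pi
  } else {
    if (is.null(r)) stop("either r or yz must be given")
    g <- expand.grid(r = r, theta = theta)
    rr <- g$r; th <- g$theta
    y <- rr * sin(th * pi / 180)
    z <- rr * cos(th * pi / 180)
  }
  if (any(rr <= 0) || any(rr > 10))
    stop("sampling positions must satisfy 0 < r <= 10 cm")
  thickness <- ifelse(rr <= 1, 0.025, ifelse(rr < 3, 0.05, 0.1))
  height <- ifelse(rr <= 1, 0.005, ifelse(rr < 3, 0.05, 0.1))
  out <- data.frame(r = rr, theta = th, y = y, z = z,
                    thickness = thickness, height = height)
  class(out) <- c("scoring_grid", "data.frame")
  out
}

# cell bounds matrix (rin, rout, zlo, zhi) for the C++ kernel; rings whose
# center sits closer to the axis than half the thickness are clipped at 0.
grid_cell_matrix <- function(grid) {
  rin <- pmax(0, grid$y - grid$thickness / 2)
  cbind(rin = rin, rout = grid$y + grid$thickness / 2,
        zlo = grid$z - grid$height / 2, zhi = grid$z + grid$height / 2)
}

# ring volumes (cm^3)
grid_cell_volume <- function(grid) {
  m <- grid_cell_matrix(grid)
  pi * (m[, "rout"]^2 - m[, "rin"]^2) * (m[, "zhi"] - m[, "zlo"])
}

#' Sample radioactive decays of the two-line cobalt-60 spectrum
#'
#' Each decay emits the two gamma lines (1.17 and 1.33 MeV) from a single
#' position sampled uniformly in the active core volume, each with an
#' independent isotropic direction and statistical weight 1. This mirrors
#' the emission stage of the transport kernel and is exposed for testing
#' and diagnostics.
#'
#' @param spec a [source_spec()].
#' @param n number of decays.
#' @return data.frame with `2 * n` rows: `x`, `y`, `z` (cm), `dx`, `dy`,
#'   `dz` (unit direction), `energy` (MeV), `weight` (all 1), `decay` id.
#' @export
sample_decay <- function(spec, n = 1) {
  stopifnot(inherits(spec, "source_spec"), n >= 1)
  rr <- spec$core_radius * sqrt(stats::runif(n))
  ph <- stats::runif(n, 0, 2 * pi)
  x <- rr * cos(ph); y <- rr * sin(ph)
  z <- stats::runif(n, -spec$core_length / 2, spec$core_length / 2)
  idx <- rep(seq_len(n), each = 2)
  ct <- stats::runif(2 * n, -1, 1)
  st <- sqrt(1 - ct^2)
  dph <- stats::runif(2 * n, 0, 2 * pi)
  data.frame(decay = idx,
             x = x[idx], y = y[idx], z = z[idx],
             dx = st * cos(dph), dy = st * sin(dph), dz = ct,
             energy = rep(c(1.17, 1.33), n),
             weight = 1)
}

#' Sample Klein-Nishina Compton scattering
#'
#' Draws scattered-photon energies and scattering angles from the
#' Klein-Nishina differential cross section for a free stationary
#' electron. Every sample satisfies the Compton relation
#' E' = E / (1 + (E / 0.511)(1 - cos theta)).
#'
#' @param energy incident photon energy in MeV (single positive value).
#' @param n number of samples.
#' @return data.frame with columns `energy` (MeV, scattered) and `angle`
#'   (radians).
#' @export
sample_compton <- function(energy, n = 1) {
  if (!is.numeric(energy) || length(energy) != 1L || energy <= 0)
    stop("energy must be a single positive number (MeV)")
  m <- cpp_kn_sample(energy, as.integer(n))
  data.frame(energy = m[, 1], angle = acos(pmin(1, pmax(-1, m[, 2]))))
}

# assemble the physics arrays for the C++ kernel. Material order:
# 1 core, 2 capsule, 3 cable, 4 surrounding medium.
sim_physics <- function(spec, medium, bare) {
  mats <- if (bare) {
    rep(list(as_material(medium)), 4)
  } else {
    list(spec$core_material, spec$capsule_material, spec$cable_material,
         as_material(medium))
  }
  tabs <- lapply(mats, material_coefficients)
  E <- tabs[[1]]$energy_mev
  logmu <- vapply(tabs, function(t)
    log(t$mu_rho * attr(t, "density")), numeric(length(E)))
  ne <- vapply(tabs, function(t)
    attr(t, "z_over_a") * 6.02214076e23 * attr(t, "density"), numeric(1))
  list(loge = log(E), logmu = logmu,
       logmuen = log(tabs[[4]]$mu_en_rho), ne = ne)
}

#' Run the water-phantom kerma simulation
#'
#' Analog photon Monte Carlo of the encapsulated source at the center of a
#' 30-cm-radius liquid water sphere. Collision kerma is scored with a
#' track-length estimator (track length in cell x energy x mass
#' energy-absorption coefficient / cell volume) on the supplied ring
#' grid, normalized per decay; type-A uncertainties come from the
#' variance over history batches. Collision kerma approximates absorbed
#' dose under charged-particle equilibrium, which for this spectrum is
#' established about 1 cm from the source; cells closer than 0.7 cm are
#' flagged `kerma_approx`.
#'
#' @param spec a [source_spec()].
#' @param grid a [build_scoring_grid()] result, all cells within r <= 10.
#' @param n_histories number of decays (each emitting both gamma lines).
#' @param seed integer seed; recorded in the result.
#' @param mode `"full"` (analog transport with scatter) or
#'   `"primary_only"` (photons killed at their first interaction, for
#'   benchmarking against the closed-form attenuation law).
#' @param bare if `TRUE`, ignore the source structure: emission from a
#'   point at the origin with no encapsulation (benchmark geometry).
#' @param n_batches number of history batches for the type-A variance.
#' @return data.frame of class `dose_grid`: the grid columns plus
#'   `kerma_per_decay` (Gy), `rel_unc`, `kerma_approx`; attributes
#'   `channel`, `n_histories`, `seed`, `mode`, `estimator`, `energy_ledger`.
#' @export
run_water_simulation <- function(spec, grid, n_histories, seed = 1L,
                                 mode = c("full", "primary_only"),
                                 bare = FALSE, n_batches = 100L) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "source_spec"), n_histories >= 1)
  if (!nrow(grid)) stop("empty scoring grid")
  if (any(grid$r > 10)) stop("scoring cells must lie within r <= 10 cm")
  run_sim(spec, grid, n_histories, seed, mode, bare,
          medium = "water", world = c(0, 30), n_batches = n_batches)
}

#' Run the air-phantom simulation and estimate air-kerma strength
#'
#' Analog transport of the source photons in a 3 x 3 x 3 m cube of dry
#' air, scoring collision kerma in a ring cell 0.1 cm high and 0.1 cm
#' thick on the transverse axis at `scoring_distance`. The air-kerma
#' strength per unit activity is the scored kerma rate times the squared
#' scoring distance (1 Bq = 3600 decays/h).
#'
#' @inheritParams run_water_simulation
#' @param scoring_distance transverse-axis distance of the scoring ring,
#'   cm; must exceed the capsule radius and fit inside the air cube.
#' @return An object of class `air_kerma`: list with `sk_per_bq`
#'   (cGy cm^2 h^-1 Bq^-1), `kerma_per_decay` (Gy), `rel_unc`,
#'   `scoring_distance`, `n_histories`, `seed`.
#' @export
run_air_simulation <- function(spec, n_histories, seed = 1L,
                               scoring_distance = 100,
                               mode = c("full", "primary_only"),
                               bare = FALSE, n_batches = 100L) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "source_spec"), n_histories >= 1)
  if (!bare && scoring_distance <= spec$capsule_outer_diameter / 2)
    stop("scoring distance must exceed the capsule radius")
  if (scoring_distance >= 150) stop("scoring ring must fit in the air cube")
  grid <- data.frame(r = scoring_distance, theta = 90,
                     y = scoring_distance, z = 0,
                     thickness = 0.1, height = 0.1)
  res <- run_sim(spec, grid, n_histories, seed, mode, bare,
                 medium = "air", world = c(1, 150), n_batches = n_batches)
  k <- res$kerma_per_decay[1]
  structure(list(
    sk_per_bq = k * .DECAYS_PER_HOUR_PER_BQ * scoring_distance^2 * .CGY_PER_GY,
    kerma_per_decay = k,
    rel_unc = res$rel_unc[1],
    scoring_distance = scoring_distance,
    n_histories = n_histories, seed = seed, mode = attr(res, "mode"),
    energy_ledger = attr(res, "energy_ledger")
  ), class = "air_kerma")
}

#' @export
print.air_kerma <- function(x, ...) {
  cat("<air_kerma>\n")
  cat(sprintf("  S_k per Bq: %.4e cGy cm2 h-1 Bq-1 (+- %.2f%%)\n",
              x$sk_per_bq, 100 * x$rel_unc))
  cat(sprintf("  scoring distance %g cm, %g histories, seed %d, mode %s\n",
              x$scoring_distance, x$n_histories, x$seed, x$mode))
  invisible(x)
}

run_sim <- function(spec, grid, n_histories, seed, mode, bare, medium,
                    world, n_batches) {
  phys <- sim_physics(spec, medium, bare)
  cells <- grid_cell_matrix(grid)
  vols <- grid_cell_volume(grid)
  set.seed(as.integer(seed))
  raw <- cpp_run_sim(source_geom_vector(spec, has_source = !bare), world,
                     cells, phys$loge, phys$logmu, phys$logmuen, phys$ne,
                     c(1.17, 1.33), as.double(n_histories),
                     as.integer(n_batches), mode == "primary_only",
                     0.010)
  out <- as.data.frame(grid)
  out$kerma_per_decay <- raw$track_mev_cm3_per_g / vols / n_histories *
    .MEV_PER_G_TO_GY
  out$rel_unc <- raw$rel_unc
  out$kerma_approx <- out$r < 0.7
  structure(out,
            channel = spec$channel_id,
            n_histories = n_histories, seed = as.integer(seed), mode = mode,
            bare = bare,
            estimator = "collision kerma, track-length",
            energy_ledger = c(emitted = raw$emitted, absorbed = raw$absorbed,
                              escaped = raw$escaped),
            class = c("dose_grid", "data.frame"))
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> channel %s, %g histories, seed %d, mode %s\n",
              attr(x, "channel"), attr(x, "n_histories"), attr(x, "seed"),
              attr(x, "mode")))
  cat(" ", attr(x, "estimator"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("  ...", nrow(x), "cells\n")
  invisible(x)
}

#' Write a dose grid (or air-kerma result) to CSV with a JSON sidecar
#'
#' One row per cell in long layout plus a `<path>.json` metadata sidecar
#' recording channel, seed, history count and estimator.
#'
#' @param x a `dose_grid` from [run_water_simulation()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(x, path) {
  stopifnot(inherits(x, "dose_grid"))
  utils::write.csv(format_full(as.data.frame(x)), path, row.names = FALSE,
                   quote = FALSE)
  meta <- list(channel = attr(x, "channel"),
               n_histories = attr(x, "n_histories"),
               seed = attr(x, "seed"), mode = attr(x, "mode"),
               estimator = attr(x, "estimator"))
  writeLines(to_json(meta), paste0(path, ".json"))
  invisible(path)
}

#' Read a dose grid written by [write_dose_grid()]
#'
#' @param path CSV path (the `.json` sidecar is read if present).
#' @return a `dose_grid` data.frame.
#' @export
read_dose_grid <- function(path) {
  out <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) from_json_flat(meta_path) else list()
  structure(out,
            channel = meta$channel, n_histories = as.numeric(meta$n_histories),
            seed = as.integer(meta$seed), mode = meta$mode,
            estimator = meta$estimator,
            class = c("dose_grid", "data.frame"))
}

# 17-significant-digit formatting so doubles round-trip exactly
format_full <- function(df) {
  df[] <- lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col)
  df
}

# minimal flat JSON writer/reader for run metadata (scalar fields only)
to_json <- function(x) {
  items <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    val <- if (is.character(v)) paste0("\"", v, "\"") else
      sprintf("%.17g", as.numeric(v))
    paste0("\"", nm, "\": ", val)
  }, character(1))
  paste0("{", paste(items, collapse = ", "), "}")
}

from_json_flat <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- sub("^\\s*\\{", "", sub("\\}\\s*$", "", txt))
  parts <- strsplit(txt, ",(?=\\s*\")", perl = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    key <- gsub("[\" ]", "", kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    out[[key]] <- if (grepl("^\"", val)) gsub("\"", "", val) else as.numeric(val)
  }
  out
}
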
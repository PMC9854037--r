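#' Specify an encapsulated cylindrical HDR source
#'
#' Geometry and materials of one source wire: a cylindrical active core
#' centered (by default) inside a stainless-steel capsule, with a drive
#' cable attached to the proximal capsule end. The coordinate system has
#' z along the source long axis with the origin at the active-core center;
#' the polar angle theta is measured from +z (the distal tip), so
#' theta = 90 degrees is the transverse plane. The cable extends in -z.
#'
#' @param channel_id `"1_2"` or `"3"` (label only; geometry is set by the
#'   remaining arguments).
#' @param core_radius,core_length active core radius and length L, cm.
#' @param capsule_outer_diameter,capsule_length capsule dimensions, cm.
#' @param core_material,capsule_material,cable_material [material_spec()]
#'   objects.
#' @param core_axial_offset position of the core center relative to the
#'   capsule center, cm (0 = centered).
#' @param cable_length,cable_radius drive-cable stub dimensions, cm. The
#'   cable matters only for the dose shadow near theta = 180 degrees.
#' @return An object of class `source_spec`.
#' @seealso [builtin_source()] for the two packaged source designs.
#' @export
source_spec <- function(channel_id, core_radius, core_length,
                        capsule_outer_diameter, capsule_length,
                        core_material, capsule_material,
                        cable_material = builtin_material("stainless_steel_2"),
                        core_axial_offset = 0,
                        cable_length = 2, cable_radius = 0.05) {
  channel_id <- as.character(channel_id)
  if (!channel_id %in% c("1_2", "3"))
    stop("unknown channel id: ", channel_id, " (expected \"1_2\" or \"3\")")
  stopifnot(core_radius > 0, core_length > 0, capsule_length > 0,
            capsule_outer_diameter > 0, cable_length >= 0, cable_radius >= 0)
  cap_r <- capsule_outer_diameter / 2
  if (core_radius > cap_r)
    stop("core does not fit inside the capsule (radius)")
  if (core_length / 2 + abs(core_axial_offset) > capsule_length / 2)
    stop("core does not fit inside the capsule (length)")
  structure(list(
    channel_id = channel_id,
    core_radius = core_radius, core_length = core_length,
    capsule_outer_diameter = capsule_outer_diameter,
    capsule_length = capsule_length,
    core_material = as_material(core_material),
    capsule_material = as_material(capsule_material),
    cable_material = as_material(cable_material),
    core_axial_offset = core_axial_offset,
    cable_length = cable_length, cable_radius = cable_radius
  ), class = "source_spec")
}

#' @export
print.source_spec <- function(x, ...) {
  cat("<source_spec> channel", x$channel_id, "\n")
  cat(sprintf("  core:    r = %.3f cm, L = %.3f cm, %s\n",
              x$core_radius, x$core_length, x$core_material$name))
  cat(sprintf("  capsule: d = %.3f cm, length = %.3f cm, %s\n",
              x$capsule_outer_diameter, x$capsule_length,
              x$capsule_material$name))
  cat(sprintf("  cable:   r = %.3f cm, length = %.2f cm, %s (proximal, -z)\n",
              x$cable_radius, x$cable_length, x$cable_material$name))
  invisible(x)
}

#' Built-in source designs of the afterloading system
#'
#' The two source designs of the three-channel afterloader: channels 1
#' and 2 share a design with a 0.5 mm radius, 1 mm long active core;
#' channel 3 uses a 2 mm long core of the same radius. Both cores are
#' encapsulated in a 2.1 mm diameter, 5.8 mm long stainless-steel capsule,
#' with the core centered in the capsule by default.
#'
#' @param channel_id `"1_2"` or `"3"`.
#' @param ... overrides passed on to [source_spec()] (for example
#'   `core_axial_offset` or a different `core_material` density).
#' @return A [source_spec()] object.
#' @examples
#' builtin_source("1_2")$core_length  # 0.1 cm
#' builtin_source("3")$core_length    # 0.2 cm
#' @export
builtin_source <- function(channel_id = c("1_2", "3"), ...) {
  channel_id <- as.character(channel_id[1])
  if (!channel_id %in% c("1_2", "3"))
    stop("unknown channel id: ", channel_id)
  args <- list(
    channel_id = channel_id,
    core_radius = 0.05,
    core_length = if (channel_id == "1_2") 0.1 else 0.2,
    capsule_outer_diameter = 0.21,
    capsule_length = 0.58,
    core_material = builtin_material("cobalt"),
    capsule_material = builtin_material("stainless_steel_1")
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(source_spec, args)
}

# flatten geometry for the C++ tracer:
# c(has_source, core_r, core_zlo, core_zhi, cap_r, cap_zlo, cap_zhi,
#   cab_r, cab_zlo, cab_zhi)
source_geom_vector <- function(spec, has_source = TRUE) {
  if (!has_source)
    return(c(0, rep(0, 9)))
  off <- spec$core_axial_offset
  cap_zlo <- -off - spec$capsule_length / 2
  cap_zhi <- -off + spec$capsule_length / 2
  c(1,
    spec$core_radius, -spec$core_length / 2, spec$core_length / 2,
    spec$capsule_outer_diameter / 2, cap_zlo, cap_zhi,
    spec$cable_radius, cap_zlo - spec$cable_length, cap_zlo)
}

#' Ray path lengths through the source capsule
#'
#' Traces a ray from a point inside (or on) the source assembly and
#' returns the ordered material segments (active core, capsule steel)
#' traversed before the ray exits the capsule cylinder. The segment
#' lengths sum to the chord length from the origin to the capsule exit.
#' The drive cable, which lies beyond the capsule, is not included.
#'
#' @param spec a [source_spec()].
#' @param origin numeric length-3 point (cm), inside or on the capsule.
#' @param direction numeric length-3 unit vector.
#' @return data.frame with columns `material` and `length` (cm).
#' @examples
#' src <- builtin_source("1_2")
#' path_lengths(src, c(0, 0, 0), c(1, 0, 0))  # core 0.05, capsule 0.055
#' @export
path_lengths <- function(spec, origin, direction) {
  stopifnot(inherits(spec, "source_spec"),
            length(origin) == 3, length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6)
    stop("direction must be a unit vector (|d| = ", format(nrm), ")")
  g <- source_geom_vector(spec)
  rho2 <- origin[1]^2 + origin[2]^2
  eps <- 1e-12
  inside_cap <- rho2 <= g[5]^2 + 1e-9 &&
    origin[3] >= g[6] - 1e-9 && origin[3] <= g[7] + 1e-9
  if (!inside_cap) stop("origin is outside the capsule")
  seg <- cpp_path_lengths(g, as.numeric(origin), as.numeric(direction))
  mat_names <- c(spec$core_material$name, spec$capsule_material$name)
  out <- data.frame(material = mat_names[seg[, 1]], length = seg[, 2])
  out[out$length > eps, , drop = FALSE]
}
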
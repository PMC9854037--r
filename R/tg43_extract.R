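#' Dose-rate constant from water and air simulations
#'
#' Lambda = D(r0, theta0) / S_k with r0 = 1 cm, theta0 = 90 degrees. Both
#' numerator and denominator are per decay, so the activity normalization
#' cancels; the reported value is in cGy h^-1 U^-1. The type-A
#' uncertainty is propagated in quadrature from the two inputs.
#'
#' @param water a `dose_grid` from [run_water_simulation()] containing a
#'   cell at (r = 1 cm, theta = 90 deg).
#' @param air an `air_kerma` result from [run_air_simulation()], or a
#'   number interpreted as S_k per decay rate (cGy cm^2 h^-1 Bq^-1).
#' @return list with `lambda` (cGy h^-1 U^-1) and `rel_unc`.
#' @export
dose_rate_constant <- function(water, air) {
  ref <- ref_cell(water)
  sk <- if (inherits(air, "air_kerma")) air$sk_per_bq else as.numeric(air)
  sk_unc <- if (inherits(air, "air_kerma")) air$rel_unc else 0
  if (!is.finite(sk) || sk <= 0) stop("invalid air-kerma strength")
  d_rate <- ref$kerma_per_decay * .DECAYS_PER_HOUR_PER_BQ * .CGY_PER_GY
  list(lambda = d_rate / sk,
       rel_unc = sqrt(nz(ref$rel_unc)^2 + nz(sk_unc)^2))
}

nz <- function(x) if (is.null(x) || !is.finite(x)) 0 else x

ref_cell <- function(water, r = 1, theta = 90) {
  i <- which(abs(water$r - r) < 1e-9 & abs(water$theta - theta) < 1e-9)
  if (!length(i))
    stop("dose grid has no cell at (r = ", r, " cm, theta = ", theta, " deg)")
  water[i[1], ]
}

#' Radial dose function from a dose grid
#'
#' g(r) = [D(r, theta0) G(r0, theta0)] / [D(r0, theta0) G(r, theta0)]
#' over the transverse-axis cells of the grid; g(1 cm) = 1 by
#' construction.
#'
#' @param water a `dose_grid` with transverse (theta = 90 deg) cells
#'   including r = 1 cm.
#' @param L active source length, cm.
#' @return data.frame with columns `r`, `g` (and `rel_unc` when the grid
#'   carries uncertainties).
#' @export
radial_dose_function <- function(water, L) {
  tr <- water[abs(water$theta - 90) < 1e-9, ]
  if (!nrow(tr)) stop("dose grid has no transverse-axis cells")
  ref <- ref_cell(water)
  tr <- tr[order(tr$r), ]
  G <- geometry_factor(tr$r, 90, L)
  G0 <- geometry_factor(1, 90, L)
  g <- tr$kerma_per_decay * G0 / (ref$kerma_per_decay * G)
  out <- data.frame(r = tr$r, g = g)
  if (!is.null(tr$rel_unc))
    out$rel_unc <- sqrt(nz_vec(tr$rel_unc)^2 + nz(ref$rel_unc)^2) *
      ifelse(abs(tr$r - 1) < 1e-9, 0, 1)
  out
}

nz_vec <- function(x) ifelse(is.finite(x), x, 0)

#' 2D anisotropy function from a dose grid
#'
#' F(r, theta) = [D(r, theta) G(r, theta0)] / [D(r, theta0) G(r, theta)];
#' F(r, 90 deg) = 1 by construction.
#'
#' @param water a `dose_grid` with cells at each requested (r, theta) and
#'   the matching transverse cell (r, 90 deg).
#' @param L active source length, cm.
#' @param theta_axis_eval polar angle (degrees) used to evaluate the
#'   geometry factor for cells tabulated at theta = 0, whose ring cell
#'   degenerates on the axis.
#' @return numeric matrix F with r rownames and theta colnames.
#' @export
anisotropy_2d <- function(water, L, theta_axis_eval = 0.5) {
  rs <- sort(unique(water$r))
  ths <- sort(unique(water$theta))
  if (!any(abs(ths - 90) < 1e-9))
    stop("dose grid has no transverse (theta = 90) cells")
  Fm <- matrix(NA_real_, length(rs), length(ths),
               dimnames = list(r = as.character(rs), theta = as.character(ths)))
  for (i in seq_along(rs)) {
    tr <- water[abs(water$r - rs[i]) < 1e-9 & abs(water$theta - 90) < 1e-9, ]
    if (!nrow(tr))
      stop("missing transverse cell at r = ", rs[i], " cm")
    Gt <- geometry_factor(rs[i], 90, L)
    for (j in seq_along(ths)) {
      cell <- water[abs(water$r - rs[i]) < 1e-9 &
                    abs(water$theta - ths[j]) < 1e-9, ]
      if (!nrow(cell)) next
      th_eval <- if (ths[j] < 1e-9) theta_axis_eval else
        if (ths[j] > 180 - 1e-9) 180 - theta_axis_eval else ths[j]
      G <- geometry_factor(rs[i], th_eval, L)
      Fm[i, j] <- cell$kerma_per_decay[1] * Gt /
        (tr$kerma_per_decay[1] * G)
    }
  }
  Fm
}

#' 1D anisotropy function
#'
#' phi_an(r) = integral of D(r, theta) sin(theta) d theta over [0, pi],
#' divided by 2 D(r, theta0), with D(r, theta) proportional to
#' G(r, theta) F(r, theta). The anisotropy function is taken piecewise
#' linear between the available theta samples and clamped to its edge
#' value beyond the first/last tabulated theta (the sin(theta) weight
#' makes these tails sub-0.3% contributions); each interval is integrated
#' by fixed-order Gauss-Legendre quadrature with the geometry factor and
#' sin(theta) evaluated exactly, so a constant F with L = 0 integrates to
#' exactly 1 (a plain trapezoid on the coarse tabulated grid would bias
#' the integral low by ~0.6% through the curvature of sin(theta)).
#'
#' @param x either an F matrix (r rownames, theta colnames) as returned
#'   by [anisotropy_2d()], or a `dose_grid` containing cells at
#'   (r, theta).
#' @param r radius at which to evaluate, cm (must be tabulated).
#' @param L active source length, cm.
#' @param theta_axis_eval as in [anisotropy_2d()].
#' @return phi_an(r), dimensionless.
#' @export
anisotropy_1d <- function(x, r, L, theta_axis_eval = 0.5) {
  if (inherits(x, "dose_grid")) x <- anisotropy_2d(x, L, theta_axis_eval)
  Fm <- as.matrix(x)
  rv <- as.numeric(rownames(Fm))
  tv <- as.numeric(colnames(Fm))
  i <- which(abs(rv - r) < 1e-9)
  if (!length(i)) stop("r = ", r, " cm is not tabulated in the F table")
  Frow <- Fm[i[1], ]
  ok <- !is.na(Frow)
  th <- tv[ok]; Fv <- Frow[ok]
  if (min(th) > 5 + 1e-9 || max(th) < 175 - 1e-9)
    stop("insufficient theta coverage (need theta_min <= 5, theta_max >= 175)")
  # clamp the anisotropy to its edge values out to the axis
  if (min(th) > 0) { th <- c(0, th); Fv <- c(Fv[1], Fv) }
  if (max(th) < 180) { th <- c(th, 180); Fv <- c(Fv, Fv[length(Fv)]) }
  # 5-point Gauss-Legendre nodes/weights on [-1, 1]
  gl_x <- c(-0.906179845938664, -0.538469310105683, 0,
            0.538469310105683, 0.906179845938664)
  gl_w <- c(0.236926885056189, 0.478628670499366, 0.568888888888889,
            0.478628670499366, 0.236926885056189)
  rad <- th * pi / 180
  num <- 0
  for (i in seq_len(length(th) - 1)) {
    h <- rad[i + 1] - rad[i]
    if (h <= 0) next
    tq <- (rad[i] + rad[i + 1]) / 2 + gl_x * h / 2
    frac <- (tq - rad[i]) / h
    Fq <- Fv[i] + frac * (Fv[i + 1] - Fv[i])
    tq_deg <- pmin(pmax(tq * 180 / pi, theta_axis_eval),
                   180 - theta_axis_eval)
    Gq <- geometry_factor(rep(r, 5), tq_deg, L)
    num <- num + h / 2 * sum(gl_w * Gq * Fq * sin(tq))
  }
  den <- 2 * geometry_factor(r, 90, L) * Fv[which.min(abs(th - 90))]
  unname(num / den)
}

#' Compare two radial dose function tables
#'
#' Elementwise relative differences in percent between two g(r) tables
#' on a shared radius grid, with a selectable denominator convention:
#' `"relative_to_a"` gives (g_B - g_A) / g_A, `"relative_to_b"` gives
#' (g_A - g_B) / g_B.
#'
#' @param g_a,g_b data.frames with columns `r`, `g` on identical radius
#'   grids.
#' @param convention denominator convention (see above).
#' @return list with `per_r` (data.frame: `r`, `diff_pct`) and
#'   `max_abs_pct`.
#' @export
compare_radial_tables <- function(g_a, g_b,
                                  convention = c("relative_to_a",
                                                 "relative_to_b")) {
  convention <- match.arg(convention)
  g_a <- as.data.frame(g_a); g_b <- as.data.frame(g_b)
  if (nrow(g_a) != nrow(g_b) || any(abs(g_a$r - g_b$r) > 1e-9))
    stop("the two tables must share the same radius grid")
  d <- if (convention == "relative_to_a") (g_b$g - g_a$g) / g_a$g
       else (g_a$g - g_b$g) / g_b$g
  per_r <- data.frame(r = g_a$r, diff_pct = 100 * d)
  list(per_r = per_r, max_abs_pct = max(abs(per_r$diff_pct)))
}

#' Combine an uncertainty budget in quadrature
#'
#' Total relative uncertainty as the root sum of squares of the
#' components (type A statistical and type B systematic alike), the
#' standard quadrature combination.
#'
#' @param components data.frame with columns `label`, `pct` (relative
#'   uncertainty in percent) and optionally `type` ("A" or "B"); or a
#'   bare numeric vector of percentages.
#' @return object of class `uncertainty_budget`: list with `components`
#'   and `total_pct`.
#' @examples
#' uncertainty_budget(c(1.21, 1.34, 1.24))$total_pct  # 2.19
#' @export
uncertainty_budget <- function(components) {
  if (is.numeric(components))
    components <- data.frame(label = sprintf("component_%d",
                                             seq_along(components)),
                             pct = as.numeric(components),
                             type = rep("B", length(components)))
  components <- as.data.frame(components)
  stopifnot("pct" %in% names(components))
  if (any(components$pct < 0)) stop("uncertainty components must be >= 0")
  if (!"type" %in% names(components)) components$type <- "B"
  total <- sqrt(sum(components$pct^2))
  structure(list(components = components, total_pct = total),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("<uncertainty_budget>\n")
  if (nrow(x$components))
    for (i in seq_len(nrow(x$components)))
      cat(sprintf("  %-28s %5.2f%%  (type %s)\n", x$components$label[i],
                  x$components$pct[i], x$components$type[i]))
  cat(sprintf("  total (quadrature)           %5.2f%%\n", x$total_pct))
  invisible(x)
}

#' Extract a full TG-43 parameter set from simulations
#'
#' Convenience wrapper running the extraction operations on a water dose
#' grid and an air-kerma result: dose-rate constant, radial dose
#' function, 2D anisotropy (when the grid has off-transverse cells) and
#' 1D anisotropy at every radius with sufficient angular coverage.
#'
#' @param water a `dose_grid`.
#' @param air an `air_kerma` result or S_k per Bq.
#' @param L active source length, cm.
#' @param channel,code labels stored in the result.
#' @return a [tg43_parameters()] object.
#' @export
extract_tg43 <- function(water, air, L,
                         channel = attr(water, "channel"),
                         code = "tg43co") {
  lam <- dose_rate_constant(water, air)
  g <- radial_dose_function(water, L)
  ths <- unique(water$theta)
  Fm <- NULL
  phi <- NULL
  if (length(ths) > 1) {
    Fm <- anisotropy_2d(water, L)
    rs <- as.numeric(rownames(Fm))
    tv <- as.numeric(colnames(Fm))
    phis <- vapply(seq_along(rs), function(i) {
      okth <- tv[!is.na(Fm[i, ])]
      if (length(okth) < 3 || min(okth) > 5 || max(okth) < 175)
        return(NA_real_)
      anisotropy_1d(Fm, rs[i], L)
    }, numeric(1))
    phi <- data.frame(r = rs, phi_an = phis)
  }
  tg43_parameters(channel = channel, L = L, lambda = lam$lambda,
                  lambda_unc = lam$rel_unc,
                  sk_per_bq = if (inherits(air, "air_kerma"))
                    air$sk_per_bq else as.numeric(air),
                  g = g[, c("r", "g")], F_table = Fm, phi_an = phi,
                  code = code)
}
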
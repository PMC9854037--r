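#' Line-source geometry factor
#'
#' TG-43 geometry factor G(r, theta) = beta / (L r sin theta), where beta
#' is the angle subtended by the active length L at the field point. beta
#' is computed as `atan2(y L, r^2 - L^2/4)` (the closed angle-addition
#' form), which is numerically stable at small theta and large r. On the
#' long axis (theta = 0 or 180 degrees) the degenerate limit
#' `1 / (r^2 - L^2/4)` is used, and L = 0 gives the point-source `1/r^2`.
#'
#' @param r distance from the source center, cm (> 0), vectorized.
#' @param theta polar angle in degrees (0 to 180), vectorized.
#' @param L active length, cm (>= 0).
#' @return geometry factor in cm^-2.
#' @examples
#' geometry_factor(2, 45, 0)      # 0.25: point source
#' geometry_factor(1, 90, 0.1)    # 2 atan(0.05) / 0.1
#' @export
geometry_factor <- function(r, theta, L) {
  stopifnot(length(L) == 1L, L >= 0)
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  if (any(r <= 0)) stop("r must be positive")
  if (any(theta < 0 | theta > 180)) stop("theta must be in [0, 180] degrees")
  if (L == 0) return(1 / r^2)
  th <- theta * pi / 180
  y <- r * sin(th)
  z <- r * cos(th)
  on_source <- y < 1e-12 & abs(z) <= L / 2
  if (any(on_source)) stop("field point lies on the active line segment")
  denom <- r^2 - L^2 / 4
  G <- ifelse(y < 1e-12,
              1 / denom,
              atan2(y * L, denom) / (L * y))
  G
}

#' Bundle extracted dosimetric parameters
#'
#' Container for one channel's TG-43 parameter set: active length L,
#' dose-rate constant, air-kerma strength, radial dose function table,
#' 2D anisotropy table and 1D anisotropy table.
#'
#' @param channel channel label ("1_2" or "3").
#' @param L active length, cm.
#' @param lambda dose-rate constant, cGy h^-1 U^-1.
#' @param sk_per_bq air-kerma strength per Bq, cGy cm^2 h^-1 Bq^-1
#'   (optional).
#' @param g data.frame with columns `r`, `g`; must contain r = 1 with
#'   g = 1.
#' @param F_table numeric matrix of F(r, theta), rows indexed by r
#'   (attribute/dimnames `r`), columns by theta in degrees; the theta = 90
#'   column must be 1.
#' @param phi_an data.frame with columns `r`, `phi_an` (optional).
#' @param code label of the producing code/simulator.
#' @param lambda_unc relative uncertainty of `lambda` (optional).
#' @return object of class `tg43_parameters`.
#' @export
tg43_parameters <- function(channel, L, lambda, g, F_table = NULL,
                            phi_an = NULL, sk_per_bq = NA_real_,
                            code = "tg43co", lambda_unc = NA_real_) {
  stopifnot(is.numeric(L), L >= 0, is.numeric(lambda), lambda > 0)
  g <- as.data.frame(g)
  stopifnot(all(c("r", "g") %in% names(g)))
  i1 <- which(abs(g$r - 1) < 1e-9)
  if (!length(i1) || abs(g$g[i1] - 1) > 1e-9)
    stop("g table must contain g(r = 1 cm) = 1")
  if (any(g$g <= 0)) stop("g values must be positive")
  if (!is.null(F_table)) {
    F_table <- as.matrix(F_table)
    rv <- as.numeric(rownames(F_table))
    tv <- as.numeric(colnames(F_table))
    if (any(is.na(rv)) || any(is.na(tv)))
      stop("F_table needs numeric r rownames and theta colnames")
    j90 <- which(abs(tv - 90) < 1e-9)
    if (!length(j90) || any(abs(F_table[, j90] - 1) > 1e-9, na.rm = TRUE))
      stop("F_table must have F(r, 90 deg) = 1")
    if (any(F_table <= 0, na.rm = TRUE)) stop("F values must be positive")
  }
  if (!is.null(phi_an)) {
    phi_an <- as.data.frame(phi_an)
    stopifnot(all(c("r", "phi_an") %in% names(phi_an)))
  }
  structure(list(channel = channel, code = code, L = L, lambda = lambda,
                 lambda_unc = lambda_unc, sk_per_bq = sk_per_bq, g = g,
                 F_table = F_table, phi_an = phi_an),
            class = "tg43_parameters")
}

#' @export
print.tg43_parameters <- function(x, ...) {
  cat(sprintf("<tg43_parameters> channel %s (%s)\n", x$channel, x$code))
  cat(sprintf("  L = %.3f cm, Lambda = %.4f cGy h-1 U-1", x$L, x$lambda))
  if (is.finite(x$sk_per_bq))
    cat(sprintf(", S_k = %.4e cGy cm2 h-1 Bq-1", x$sk_per_bq))
  cat("\n")
  cat(sprintf("  g(r): %d radii [%g, %g] cm", nrow(x$g), min(x$g$r),
              max(x$g$r)))
  if (!is.null(x$F_table))
    cat(sprintf("; F(r,theta): %d x %d table", nrow(x$F_table),
                ncol(x$F_table)))
  cat("\n")
  invisible(x)
}

#' Interpolate g(r) and F(r, theta) from a parameter set
#'
#' g by linear interpolation in r; F bilinear in (r, theta), clamping
#' theta outside the tabulated range (and treating missing table entries
#' by nearest available theta at that radius). Exact at table nodes.
#'
#' @param params a [tg43_parameters()] object.
#' @param r,theta evaluation points (vectorized, recycled to common
#'   length).
#' @param extrapolate if `FALSE` (default), r outside the tabulated range
#'   is an error; if `TRUE`, r is clamped.
#' @return data.frame with columns `r`, `theta`, `g`, `F`.
#' @export
interp_parameters <- function(params, r, theta = 90, extrapolate = FALSE) {
  stopifnot(inherits(params, "tg43_parameters"))
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  rng <- range(params$g$r)
  if (!extrapolate && (any(r < rng[1] - 1e-9) || any(r > rng[2] + 1e-9)))
    stop("r outside the tabulated range [", rng[1], ", ", rng[2],
         "] cm (set extrapolate = TRUE to clamp)")
  rc <- pmin(pmax(r, rng[1]), rng[2])
  gv <- stats::approx(params$g$r, params$g$g, rc, rule = 2)$y
  Fv <- rep(1, n)
  if (!is.null(params$F_table))
    Fv <- interp_F(params$F_table, rc, theta)
  data.frame(r = r, theta = theta, g = gv, F = Fv)
}

# bilinear interpolation on the F matrix with theta clamped to the
# tabulated range; NA entries are filled by the nearest tabulated theta
# at the same radius before interpolating.
interp_F <- function(F_table, r, theta) {
  rv <- as.numeric(rownames(F_table))
  tv <- as.numeric(colnames(F_table))
  Ff <- fill_F_na(F_table)
  rq <- pmin(pmax(r, min(rv)), max(rv))
  tq <- pmin(pmax(theta, min(tv)), max(tv))
  ir <- findInterval(rq, rv, rightmost.closed = TRUE)
  it <- findInterval(tq, tv, rightmost.closed = TRUE)
  ir <- pmin(pmax(ir, 1L), length(rv) - 1L)
  it <- pmin(pmax(it, 1L), length(tv) - 1L)
  fr <- (rq - rv[ir]) / (rv[ir + 1] - rv[ir])
  ft <- (tq - tv[it]) / (tv[it + 1] - tv[it])
  fr <- pmin(pmax(fr, 0), 1); ft <- pmin(pmax(ft, 0), 1)
  (1 - fr) * (1 - ft) * Ff[cbind(ir, it)] +
    fr * (1 - ft) * Ff[cbind(ir + 1L, it)] +
    (1 - fr) * ft * Ff[cbind(ir, it + 1L)] +
    fr * ft * Ff[cbind(ir + 1L, it + 1L)]
}

fill_F_na <- function(F_table) {
  tv <- as.numeric(colnames(F_table))
  t(apply(F_table, 1, function(row) {
    if (!anyNA(row)) return(row)
    ok <- which(!is.na(row))
    row[-ok] <- row[ok][vapply(tv[-ok], function(t)
      which.min(abs(tv[ok] - t)), integer(1))]
    row
  }))
}

#' TG-43 2D dose rate
#'
#' Dose rate at (r, theta):
#' `D(r, theta) = S_k Lambda [G(r, theta) / G(r0, theta0)] g(r) F(r, theta)`
#' with the reference point r0 = 1 cm, theta0 = 90 degrees.
#'
#' @inheritParams interp_parameters
#' @param sk air-kerma strength in U (1 U = 1 cGy cm^2 h^-1).
#' @return dose rate(s) in cGy/h.
#' @export
dose_rate_2d <- function(params, r, theta, sk = 1, extrapolate = FALSE) {
  ip <- interp_parameters(params, r, theta, extrapolate = extrapolate)
  G <- geometry_factor(ip$r, ip$theta, params$L)
  G0 <- geometry_factor(1, 90, params$L)
  sk * params$lambda * G / G0 * ip$g * ip$F
}

#' TG-43 1D dose rate
#'
#' `D(r) = S_k Lambda [G(r, theta0) / G(r0, theta0)] g(r) phi_an(r)`,
#' with phi_an interpolated linearly in r.
#'
#' @inheritParams dose_rate_2d
#' @return dose rate(s) in cGy/h.
#' @export
dose_rate_1d <- function(params, r, sk = 1, extrapolate = FALSE) {
  stopifnot(inherits(params, "tg43_parameters"))
  if (is.null(params$phi_an)) stop("parameter set has no phi_an table")
  ip <- interp_parameters(params, r, 90, extrapolate = extrapolate)
  pa <- params$phi_an[!is.na(params$phi_an$phi_an), ]
  rngp <- range(pa$r)
  if (!extrapolate && (any(r < rngp[1] - 1e-9) || any(r > rngp[2] + 1e-9)))
    stop("r outside the tabulated phi_an range")
  phi <- stats::approx(pa$r, pa$phi_an, pmin(pmax(r, rngp[1]), rngp[2]),
                       rule = 2)$y
  G <- geometry_factor(ip$r, 90, params$L)
  G0 <- geometry_factor(1, 90, params$L)
  sk * params$lambda * G / G0 * ip$g * phi
}

#' Along-away QA dose-rate table
#'
#' Dose rate per unit air-kerma strength on a cylindrical (y, z) grid:
#' y is the distance away from the source axis, z the signed distance
#' along it (positive toward the distal tip). Each cell is evaluated with
#' [dose_rate_2d()] at S_k = 1 U after conversion r = sqrt(y^2 + z^2),
#' theta = atan2(y, z). Cells outside the tabulated radial range are
#' returned as `NA`.
#'
#' @param params a [tg43_parameters()] object.
#' @param y away distances, cm (>= 0).
#' @param z along distances, cm (signed).
#' @return object of class `along_away`: numeric matrix (rows z, columns
#'   y) of dose rates in cGy h^-1 U^-1, with dimnames giving the grids.
#' @export
along_away_table <- function(params, y = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2,
                                           3, 4, 5, 6, 7, 8, 10),
                             z = c(-10, -8, -7, -6, -5, -4, -3, -2, -1.5,
                                   -1, -0.75, -0.5, 0, 0.5, 0.75, 1, 1.5,
                                   2, 3, 4, 5, 6, 7, 8, 10)) {
  stopifnot(inherits(params, "tg43_parameters"), all(y >= 0))
  gr <- expand.grid(z = z, y = y)
  r <- sqrt(gr$y^2 + gr$z^2)
  th <- atan2(gr$y, gr$z) * 180 / pi
  rng <- range(params$g$r)
  ok <- r >= rng[1] - 1e-9 & r <= rng[2] + 1e-9
  vals <- rep(NA_real_, nrow(gr))
  if (any(ok))
    vals[ok] <- dose_rate_2d(params, r[ok], th[ok], sk = 1)
  m <- matrix(vals, nrow = length(z), ncol = length(y),
              dimnames = list(z = as.character(z), y = as.character(y)))
  structure(m, class = c("along_away", "matrix"))
}

#' @export
print.along_away <- function(x, digits = 3, ...) {
  cat("<along_away> dose rate, cGy h-1 U-1 (rows z, cols y)\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Synthesize a noise-free dose grid from a parameter set
#'
#' Evaluates the forward TG-43 model on a scoring grid and packages the
#' result as a `dose_grid`, as if it had been produced by a noiseless
#' simulation. Used for round-trip validation of the extraction
#' operations (engine then extraction must be the identity).
#'
#' @param params a [tg43_parameters()] object.
#' @param grid a [build_scoring_grid()] result.
#' @param sk_per_bq air-kerma strength per decay rate used to convert the
#'   dose rate back to kerma per decay.
#' @return a `dose_grid` data.frame.
#' @export
synthesize_dose_grid <- function(params, grid, sk_per_bq = 3e-07) {
  d <- dose_rate_2d(params, grid$r, grid$theta, sk = 1, extrapolate = FALSE)
  out <- as.data.frame(grid)
  # invert the reporting conversion: cGy/h per U -> Gy per decay
  out$kerma_per_decay <- d * sk_per_bq /
    (.DECAYS_PER_HOUR_PER_BQ * .CGY_PER_GY)
  out$rel_unc <- 0
  out$kerma_approx <- out$r < 0.7
  structure(out, channel = params$channel, n_histories = Inf,
            seed = NA_integer_, mode = "synthetic",
            estimator = "forward TG-43 model",
            class = c("dose_grid", "data.frame"))
}
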
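#' Evaluate the radial dose function model
#'
#' The five-term polynomial-times-exponential parameterization commonly
#' used for HDR sources:
#' `g(r) = (a0 r^-2 + a1 r^-1 + a2 + a3 r + a4 r^2) exp(-a5 r)`,
#' with a0 in cm^2, a1 in cm, a2 dimensionless, a3 in cm^-1, a4 in
#' cm^-2 and a5 in cm^-1.
#'
#' @param coefficients numeric vector (a0, a1, a2, a3, a4, a5).
#' @param r radii in cm, positive (vectorized).
#' @return model values g(r).
#' @examples
#' eval_gr_model(c(0, 0, 1, 0, 0, 0), 5)  # 1
#' @export
eval_gr_model <- function(coefficients, r) {
  stopifnot(length(coefficients) == 6)
  if (any(r <= 0)) stop("r must be positive")
  a <- as.numeric(coefficients)
  (a[1] / r^2 + a[2] / r + a[3] + a[4] * r + a[5] * r^2) * exp(-a[6] * r)
}

#' Fit the radial dose function model
#'
#' Unweighted least-squares fit of
#' `g(r) = (a0 r^-2 + a1 r^-1 + a2 + a3 r + a4 r^2) exp(-a5 r)` to a g(r)
#' table. The single nonlinear parameter a5 is profiled: for each a5 on a
#' grid over \[0, 1\] cm^-1 the remaining coefficients solve a linear
#' least-squares problem, and the best grid point is refined by a
#' bounded 1-D optimization. The procedure is deterministic given the
#' data.
#'
#' @param g_table data.frame with columns `r` (cm) and `g` (positive).
#' @param r_range fit range `c(r_min, r_max)` in cm; points outside are
#'   ignored.
#' @param a5_grid profiling grid for a5, cm^-1.
#' @return object of class `gr_fit`: list with `coefficients` (named
#'   a0..a5), `r_squared`, `deviations` (data.frame `r`, `g`, `fit`,
#'   `dev_pct`), `max_dev_pct` and `r_range`.
#' @examples
#' fit <- fit_radial(data.frame(r = c(0.5, 1, 2, 3, 5, 7, 10),
#'                              g = c(1.04, 1, 0.98, 0.97, 0.94, 0.9, 0.85)))
#' fit$r_squared
#' @export
fit_radial <- function(g_table, r_range = c(0.25, 10),
                       a5_grid = seq(0, 1, by = 0.005)) {
  g_table <- as.data.frame(g_table)
  stopifnot(all(c("r", "g") %in% names(g_table)))
  keep <- g_table$r >= r_range[1] - 1e-9 & g_table$r <= r_range[2] + 1e-9
  r <- g_table$r[keep]
  g <- g_table$g[keep]
  if (length(r) < 7)
    stop("need at least 7 points in the fit range (6 free parameters)")
  if (any(g <= 0)) stop("g values must be positive")

  basis <- cbind(r^-2, r^-1, 1, r, r^2)
  sse_at <- function(a5) {
    X <- basis * exp(-a5 * r)
    fit <- stats::lm.fit(X, g)
    sum(fit$residuals^2)
  }
  sse_grid <- vapply(a5_grid, sse_at, numeric(1))
  i <- which.min(sse_grid)
  lo <- a5_grid[max(1L, i - 1L)]
  hi <- a5_grid[min(length(a5_grid), i + 1L)]
  a5 <- if (hi > lo)
    stats::optimize(sse_at, c(lo, hi), tol = 1e-12)$minimum
  else a5_grid[i]
  if (sse_at(a5_grid[i]) < sse_at(a5)) a5 <- a5_grid[i]

  X <- basis * exp(-a5 * r)
  lin <- stats::lm.fit(X, g)
  coefs <- stats::setNames(c(lin$coefficients, a5),
                           c("a0", "a1", "a2", "a3", "a4", "a5"))
  pred <- eval_gr_model(coefs, r)
  ss_res <- sum((g - pred)^2)
  ss_tot <- sum((g - mean(g))^2)
  dev_pct <- 100 * abs(pred - g) / g
  structure(list(
    coefficients = coefs,
    r_squared = 1 - ss_res / ss_tot,
    deviations = data.frame(r = r, g = g, fit = pred, dev_pct = dev_pct),
    max_dev_pct = max(dev_pct),
    r_range = r_range
  ), class = "gr_fit")
}

#' @export
print.gr_fit <- function(x, ...) {
  cat("<gr_fit> g(r) = (a0/r^2 + a1/r + a2 + a3 r + a4 r^2) exp(-a5 r)\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("  R^2 = %.6f, max |deviation| = %.3f%% over r in [%g, %g] cm\n",
              x$r_squared, x$max_dev_pct, x$r_range[1], x$r_range[2]))
  invisible(x)
}
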
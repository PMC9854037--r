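#' Load the packaged reference tables
#'
#' The published dosimetric tables for the two source designs of the
#' GZP3 afterloading system, shipped as CSV package data exactly as
#' printed (three-decimal values, missing entries as NA):
#' dose-rate constants for this source family and similar commercial
#' cobalt-60 sources, radial dose functions g(r) from two independent
#' Monte Carlo codes, 1D/2D anisotropy tables per channel, and the
#' along-away QA dose-rate tables. Cells that deviate by more than 25%
#' from all of their immediate row and column neighbors are flagged as
#' anomalies (apparent typographical errors in the print); anomalous
#' values are stored verbatim, never corrected.
#'
#' @return object of class `fixture_set`: list with elements
#'   `dose_rate_constants` (data.frame), `radial_dose` (data.frame),
#'   `anisotropy` (per channel: list with `F` matrix, `phi_an`
#'   data.frame, `anomaly` logical matrix), `along_away` (per channel:
#'   list with `values` matrix and `anomaly` matrix).
#' @examples
#' fx <- load_fixtures()
#' fx$radial_dose$ch12_geant4[fx$radial_dose$r_cm == 1]  # 1
#' @export
load_fixtures <- function() {
  drc <- read_fixture("table2_dose_rate_constant.csv")
  g <- read_fixture("table3_radial_dose.csv")

  ani <- list(
    ch12 = parse_anisotropy(read_fixture("table4_anisotropy_ch12.csv")),
    ch3 = parse_anisotropy(read_fixture("table5_anisotropy_ch3.csv"))
  )
  aa <- list(
    ch12 = parse_along_away(read_fixture("table6_along_away_ch12.csv")),
    ch3 = parse_along_away(read_fixture("table7_along_away_ch3.csv"))
  )
  structure(list(dose_rate_constants = drc, radial_dose = g,
                 anisotropy = ani, along_away = aa),
            class = "fixture_set")
}

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "tg43co", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  expected <- .fixture_md5[[name]]
  if (!is.null(expected) && !identical(md5, expected))
    stop("package data file ", name, " is corrupted (checksum mismatch)")
  utils::read.csv(path, check.names = FALSE)
}

# md5 checksums of the shipped fixture CSVs, frozen at packaging time
.fixture_md5 <- list(
  "table2_dose_rate_constant.csv" = "5f4097672559f46f1a537190d4d45a53",
  "table3_radial_dose.csv" = "542828ec0c3178a8563201ffe6e41e34",
  "table4_anisotropy_ch12.csv" = "dd574a8e842cda0af7a19dd9cc82bb63",
  "table5_anisotropy_ch3.csv" = "08d797d0f9550de9332f3baafdc4275b",
  "table6_along_away_ch12.csv" = "0666afc4dc0b53125053ea6a5a74d231",
  "table7_along_away_ch3.csv" = "75b3cb5c7f43d9fe6f233f64657b228d"
)

parse_anisotropy <- function(df) {
  phi_row <- df$theta_deg == "phi_an"
  Fm <- as.matrix(df[!phi_row, -1])
  theta <- as.numeric(df$theta_deg[!phi_row])
  r <- as.numeric(sub("^r", "", colnames(Fm)))
  Fm <- t(Fm)  # rows r, cols theta
  dimnames(Fm) <- list(r = r, theta = theta)
  phi <- data.frame(r = r, phi_an = as.numeric(df[phi_row, -1]))
  list(F = Fm, phi_an = phi, anomaly = neighbor_anomalies(Fm))
}

parse_along_away <- function(df) {
  m <- as.matrix(df[, -1])
  z <- as.numeric(df$z_cm)
  y <- as.numeric(sub("^y", "", colnames(m)))
  dimnames(m) <- list(z = z, y = y)
  list(values = m, anomaly = neighbor_anomalies(m))
}

# flag cells deviating > 25% from every available immediate neighbor in
# both the row and the column direction
neighbor_anomalies <- function(m, threshold = 0.25) {
  out <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      v <- m[i, j]
      if (is.na(v)) next
      nb <- c(if (i > 1) m[i - 1, j], if (i < nrow(m)) m[i + 1, j],
              if (j > 1) m[i, j - 1], if (j < ncol(m)) m[i, j + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb) && all(abs(v - nb) / pmax(abs(nb), 1e-12) > threshold))
        out[i, j] <- TRUE
    }
  }
  out
}

#' @export
print.fixture_set <- function(x, ...) {
  cat("<fixture_set>\n")
  cat(sprintf("  dose-rate constants: %d sources\n",
              nrow(x$dose_rate_constants)))
  cat(sprintf("  radial dose: %d radii x 4 code/channel columns\n",
              nrow(x$radial_dose)))
  for (ch in names(x$anisotropy))
    cat(sprintf("  anisotropy %s: %d x %d F table, %d anomalies\n", ch,
                nrow(x$anisotropy[[ch]]$F), ncol(x$anisotropy[[ch]]$F),
                sum(x$anisotropy[[ch]]$anomaly)))
  for (ch in names(x$along_away))
    cat(sprintf("  along-away %s: %d x %d, %d anomalies\n", ch,
                nrow(x$along_away[[ch]]$values),
                ncol(x$along_away[[ch]]$values),
                sum(x$along_away[[ch]]$anomaly)))
  invisible(x)
}

#' Write a table to CSV in long or matrix layout
#'
#' Matrix layout mirrors the printed row/column ordering (first column
#' the row coordinate, header the column coordinate); long layout emits
#' one row per cell with 17-significant-digit values so doubles
#' round-trip exactly. Missing entries are written as NA, never as
#' zeros.
#'
#' @param x a matrix with numeric dimnames (matrix layout) or a
#'   data.frame (long layout).
#' @param path output file path.
#' @param layout `"matrix"` or `"long"`.
#' @param row_label,col_label coordinate names used in the header.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, layout = c("matrix", "long"),
                        row_label = "row", col_label = "col") {
  layout <- match.arg(layout)
  if (layout == "matrix") {
    m <- as.matrix(x)
    df <- data.frame(rownames(m), m, check.names = FALSE)
    names(df) <- c(row_label, colnames(m))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    df <- x
    if (is.matrix(x)) {
      df <- expand.grid(row = as.numeric(rownames(x)),
                        col = as.numeric(colnames(x)))
      names(df) <- c(row_label, col_label)
      df$value <- as.vector(x)
    }
    utils::write.csv(format_full(as.data.frame(df)), path,
                     row.names = FALSE, quote = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read a matrix-layout table written by [write_table()]
#'
#' @param path CSV path.
#' @return numeric matrix with the first CSV column as rownames.
#' @export
read_matrix_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Fixture-derived comparison statistics
#'
#' Recomputes the cross-code and cross-source comparison statistics from
#' the packaged tables: the per-radius relative g(r) differences between
#' the two Monte Carlo codes for each channel, the relative difference
#' between the two codes' dose-rate constants, and the maximum spread of
#' the dose-rate constant against the similar commercial sources using
#' the (Lambda_this - Lambda_other) / Lambda_this convention.
#'
#' @param fixtures a [load_fixtures()] result (loaded fresh if omitted).
#' @return list with `g_max_diff_pct` (per channel), `lambda_diff_pct`
#'   (per channel), `lambda_max_spread_pct`.
#' @export
fixture_statistics <- function(fixtures = load_fixtures()) {
  g <- fixtures$radial_dose
  cmp12 <- compare_radial_tables(
    data.frame(r = g$r_cm, g = g$ch12_geant4),
    data.frame(r = g$r_cm, g = g$ch12_egsnrc), "relative_to_a")
  cmp3 <- compare_radial_tables(
    data.frame(r = g$r_cm, g = g$ch3_geant4),
    data.frame(r = g$r_cm, g = g$ch3_egsnrc), "relative_to_a")
  drc <- fixtures$dose_rate_constants
  tw <- drc[drc$group == "this_work", ]
  lam_diff <- vapply(split(tw, tw$source), function(s) {
    100 * abs(s$lambda_cgy_per_hu[s$code == "Geant4"] -
              s$lambda_cgy_per_hu[s$code == "EGSnrc"]) /
      s$lambda_cgy_per_hu[s$code == "EGSnrc"]
  }, numeric(1))
  lit <- drc$lambda_cgy_per_hu[drc$group == "literature"]
  spread <- outer(tw$lambda_cgy_per_hu, lit,
                  function(a, b) 100 * (a - b) / a)
  list(g_max_diff_pct = c(ch12 = cmp12$max_abs_pct, ch3 = cmp3$max_abs_pct),
       lambda_diff_pct = lam_diff,
       lambda_max_spread_pct = max(abs(spread)))
}
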
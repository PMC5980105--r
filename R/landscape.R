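# Synthetic landscape covariates: spatially autocorrelated ordinal RSF and
# mortality-risk score surfaces, plus continuous terrain-ruggedness (TRI) and
# canopy-closure (CC) fields used as detector-site covariates.

smooth_field <- function(z, range_cells) {
  # separable Gaussian-kernel smoothing; range_cells is the kernel sd in cells
  if (range_cells <= 0) return(z)
  half <- max(1L, ceiling(3 * range_cells))
  k <- stats::dnorm(seq(-half, half), sd = range_cells)
  k <- k / sum(k)
  pad_apply <- function(mat) {
    nr <- nrow(mat)
    idx <- c(rep(1L, half), seq_len(nr), rep(nr, half))   # replicate-pad edges
    padded <- mat[idx, , drop = FALSE]
    out <- apply(padded, 2L, function(col) stats::filter(col, k, sides = 2L))
    out[(half + 1L):(half + nr), , drop = FALSE]
  }
  z <- pad_apply(z)
  t(pad_apply(t(z)))
}

quantile_bin <- function(z, levels) {
  br <- stats::quantile(z, probs = seq(0, 1, length.out = levels + 1L),
                        names = FALSE)
  br[1L] <- -Inf; br[levels + 1L] <- Inf
  br <- cummax(br + seq_along(br) * 0)           # guard non-monotone ties
  if (any(duplicated(br))) br <- br + seq_along(br) * 1e-12
  matrix(findInterval(z, br, rightmost.closed = TRUE, left.open = TRUE) ,
         nrow = nrow(z))
}

#' Generate a synthetic landscape of RSF and mortality-risk scores
#'
#' Produces paired ordinal score rasters emulating the resource-selection
#' (RSF) and mortality-risk covariate maps used as density-surface inputs,
#' together with continuous TRI- and CC-like surfaces for detector-site
#' covariates. Each surface is a Gaussian random field obtained by smoothing
#' white noise with a Gaussian kernel of the stated range; RSF and Risk can
#' be generated with a chosen correlation, and are then quantile-binned into
#' ordinal scores `1..levels`.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in projected km.
#' @param resolution Cell size in km (> 0).
#' @param autocorr_range Gaussian smoothing scale in km; 0 gives i.i.d. cells.
#' @param rsf_levels,risk_levels Number of ordinal score bins (>= 2).
#' @param rsf_risk_cor Correlation between the latent RSF and Risk fields,
#'   in (-1, 1). Default 0.
#' @param seed Integer seed; identical seeds give identical landscapes.
#' @return An object of class `bear_landscape`: list with `extent`,
#'   `resolution`, cell-center coordinate vectors `xc`, `yc`, and matrices
#'   `rsf`, `risk` (ordinal), `tri`, `cc` (continuous, mean 0 sd ~1),
#'   indexed `[x, y]`.
#' @examples
#' ls <- generate_landscape(c(0, 20, 0, 20), resolution = 1,
#'                          autocorr_range = 4, seed = 1)
#' table(ls$rsf)
#' @export
generate_landscape <- function(extent, resolution = 1,
                               autocorr_range = 10,
                               rsf_levels = 10L, risk_levels = 10L,
                               rsf_risk_cor = 0, seed = 1L) {
  stopifnot(length(extent) == 4L)
  if (!(extent[2L] > extent[1L]) || !(extent[4L] > extent[3L]))
    stop("degenerate extent: require xmax > xmin and ymax > ymin")
  if (resolution <= 0) stop("resolution must be > 0")
  if (rsf_levels < 2L || risk_levels < 2L) stop("score levels must be >= 2")
  if (abs(rsf_risk_cor) >= 1) stop("rsf_risk_cor must be in (-1, 1)")

  nx <- max(2L, ceiling((extent[2L] - extent[1L]) / resolution))
  ny <- max(2L, ceiling((extent[4L] - extent[3L]) / resolution))
  xc <- extent[1L] + (seq_len(nx) - 0.5) * resolution
  yc <- extent[3L] + (seq_len(ny) - 0.5) * resolution

  set.seed(as.integer(seed))
  rcells <- autocorr_range / resolution
  z1 <- matrix(stats::rnorm(nx * ny), nx, ny)
  z2 <- matrix(stats::rnorm(nx * ny), nx, ny)
  ztri <- matrix(stats::rnorm(nx * ny), nx, ny)
  zcc <- matrix(stats::rnorm(nx * ny), nx, ny)
  f1 <- smooth_field(z1, rcells)
  f2 <- rsf_risk_cor * f1 + sqrt(1 - rsf_risk_cor^2) * smooth_field(z2, rcells)
  std <- function(m) (m - mean(m)) / stats::sd(m)
  structure(list(
    extent = as.numeric(extent), resolution = resolution,
    autocorr_range = autocorr_range, seed = as.integer(seed),
    xc = xc, yc = yc,
    rsf = quantile_bin(f1, rsf_levels),
    risk = quantile_bin(f2, risk_levels),
    tri = std(smooth_field(ztri, rcells)),
    cc = std(smooth_field(zcc, rcells))
  ), class = "bear_landscape")
}

#' Look up landscape values at point locations
#'
#' Nearest-cell lookup of one of the landscape surfaces; coordinates outside
#' the raster extent return `NA`.
#'
#' @param landscape A [generate_landscape()] object.
#' @param x,y Point coordinates (km).
#' @param layer One of `"rsf"`, `"risk"`, `"tri"`, `"cc"`.
#' @return Numeric vector of cell values.
#' @export
landscape_value <- function(landscape, x, y, layer = "rsf") {
  stopifnot(inherits(landscape, "bear_landscape"))
  layer <- match.arg(layer, c("rsf", "risk", "tri", "cc"))
  ext <- landscape$extent; res <- landscape$resolution
  m <- landscape[[layer]]
  ix <- floor((x - ext[1L]) / res) + 1L
  iy <- floor((y - ext[3L]) / res) + 1L
  ok <- ix >= 1L & ix <= nrow(m) & iy >= 1L & iy <= ncol(m)
  out <- rep(NA_real_, length(x))
  out[ok] <- m[cbind(ix[ok], iy[ok])]
  out
}

#' @export
print.bear_landscape <- function(x, ...) {
  cat("Synthetic landscape:", nrow(x$rsf), "x", ncol(x$rsf), "cells at",
      x$resolution, "km; autocorrelation range", x$autocorr_range, "km\n")
  cat("RSF levels:", max(x$rsf), " Risk levels:", max(x$risk), "\n")
  invisible(x)
}
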
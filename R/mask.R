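# Habitat mask: the regular point lattice over which all SECR integrals are
# approximated. Default spacing 3.5 km, i.e. half the snag-cell edge.

#' Build a habitat mask around a sampling grid
#'
#' Lays a regular lattice of points over the grid polygon plus a buffer,
#' attaches RSF/Risk covariates summarized from a landscape raster, and
#' flags points inside the sampling grid and inside the "province" polygon
#' (the region with covariate coverage; points outside it get
#' nearest-neighbour covariate fills, see
#' [summarize_covariates_to_mask()]).
#'
#' @param grid_polygon Two-column vertex matrix of the sampling-grid
#'   perimeter, or a [study_design()].
#' @param buffer Buffer width in km around the grid polygon's bounding box.
#' @param spacing Mask point spacing in km (default 3.5); cell area is
#'   `spacing^2`.
#' @param landscape Optional [generate_landscape()] object supplying RSF and
#'   Risk values.
#' @param province_polygon Optional polygon of covariate coverage; mask
#'   points outside it have covariates filled from the nearest covered point.
#' @param radius_km Summary radius for covariates around each point.
#' @return A `data.frame` of class `bear_mask` with columns `x`, `y`,
#'   `inside_grid`, `inside_province`, and (with a landscape) `RSF`, `Risk`,
#'   `filled`; attributes `spacing` and `cell_area` (km^2).
#' @export
make_mask <- function(grid_polygon, buffer, spacing = 3.5,
                      landscape = NULL, province_polygon = NULL,
                      radius_km = 1.75) {
  if (inherits(grid_polygon, "snag_design")) grid_polygon <- grid_polygon$grid_polygon
  gp <- ring_matrix(grid_polygon)
  if (spacing <= 0) stop("spacing must be > 0")
  if (buffer < 0) stop("buffer must be >= 0")
  xr <- range(gp[, 1L]); yr <- range(gp[, 2L])
  xs <- seq(xr[1L] - buffer + spacing / 2, xr[2L] + buffer, by = spacing)
  ys <- seq(yr[1L] - buffer + spacing / 2, yr[2L] + buffer, by = spacing)
  pts <- expand.grid(x = xs, y = ys)
  mask <- data.frame(x = pts$x, y = pts$y)
  mask$inside_grid <- point_in_polygon(mask$x, mask$y, gp)
  mask$inside_province <- if (is.null(province_polygon)) TRUE else
    point_in_polygon(mask$x, mask$y, ring_matrix(province_polygon))
  attr(mask, "spacing") <- spacing
  attr(mask, "cell_area") <- spacing^2
  attr(mask, "grid_polygon") <- gp
  class(mask) <- c("bear_mask", "data.frame")
  if (!is.null(landscape)) {
    mask$RSF <- summarize_covariates_to_mask(landscape, mask, "rsf", radius_km)
    mask$Risk <- summarize_covariates_to_mask(landscape, mask, "risk", radius_km)
    mask$filled <- attr(mask$RSF, "filled") | attr(mask$Risk, "filled")
    attributes(mask$RSF) <- NULL; attributes(mask$Risk) <- NULL
  }
  mask
}

#' Summarize a raster covariate onto mask points
#'
#' Mean raster value within `radius_km` of each mask point (the covariates
#' are summarized within 1.75 km buffers so they describe variation at the
#' 3.5 km point spacing). Points with no raster coverage — or outside the
#' province polygon — take the value of the nearest covered mask point.
#'
#' @param landscape A [generate_landscape()] object (or a list with the same
#'   layer structure).
#' @param mask A [make_mask()] mask or data frame with `x`, `y` and
#'   optionally `inside_province`.
#' @param layer Layer name in the landscape object.
#' @param radius_km Averaging radius (km).
#' @return Numeric vector (one value per mask point) with attribute
#'   `filled`: logical, TRUE where the value was borrowed from the nearest
#'   covered point.
#' @export
summarize_covariates_to_mask <- function(landscape, mask, layer = "rsf",
                                         radius_km = 1.75) {
  res <- landscape$resolution
  ext <- landscape$extent
  m <- landscape[[layer]]
  if (is.null(m)) stop("landscape has no layer '", layer, "'")
  if (all(is.na(m))) stop("raster layer is entirely missing")
  covered <- if (!is.null(mask$inside_province)) mask$inside_province else
    rep(TRUE, nrow(mask))
  r <- max(0L, floor(radius_km / res))
  val <- rep(NA_real_, nrow(mask))
  for (i in which(covered)) {
    ix <- floor((mask$x[i] - ext[1L]) / res) + 1L
    iy <- floor((mask$y[i] - ext[3L]) / res) + 1L
    xs <- max(1L, ix - r):min(nrow(m), ix + r)
    ys <- max(1L, iy - r):min(ncol(m), iy + r)
    if (ix + r < 1L || ix - r > nrow(m) || iy + r < 1L || iy - r > ncol(m))
      next
    v <- m[xs, ys]
    val[i] <- mean(v, na.rm = TRUE)
  }
  filled <- is.na(val)
  if (all(filled)) stop("no mask point has raster coverage")
  if (any(filled)) {
    ok <- which(!filled)
    for (i in which(filled)) {
      d2 <- (mask$x[ok] - mask$x[i])^2 + (mask$y[ok] - mask$y[i])^2
      val[i] <- val[ok[which.min(d2)]]
    }
  }
  attr(val, "filled") <- filled
  val
}

mask_cell_area <- function(mask) {
  a <- attr(mask, "cell_area")
  if (is.null(a)) stop("mask has no cell_area attribute")
  a
}

#' @export
print.bear_mask <- function(x, ...) {
  cat("Habitat mask:", nrow(x), "points at", attr(x, "spacing"),
      "km spacing (cell area", mask_cell_area(x), "km^2);",
      sum(x$inside_grid), "inside the sampling grid\n")
  invisible(x)
}
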
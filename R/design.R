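# Sampling-grid design and hair-snag placement. The field design places one
# snag station per 7 x 7 km cell and moves it between the 4 sampling sessions.

#' Define a systematic hair-snag sampling design
#'
#' @param n_cells_x,n_cells_y Number of grid cells in each direction.
#' @param cell_size Cell edge in km (default 7, the standard snag-grid cell).
#' @param n_occasions Number of sampling sessions (default 4).
#' @param move_sites Logical; re-draw each site within its cell every
#'   occasion (the standard protocol) or keep sites fixed.
#' @param origin `c(x, y)` of the grid's lower-left corner in km.
#' @return An object of class `snag_design` with the grid polygon in
#'   `$grid_polygon` and grid dimensions.
#' @export
study_design <- function(n_cells_x, n_cells_y, cell_size = 7,
                         n_occasions = 4L, move_sites = TRUE,
                         origin = c(0, 0)) {
  stopifnot(n_cells_x >= 1L, n_cells_y >= 1L, cell_size > 0, n_occasions >= 1L)
  gp <- rect_polygon(origin[1L], origin[1L] + n_cells_x * cell_size,
                     origin[2L], origin[2L] + n_cells_y * cell_size)
  structure(list(n_cells_x = as.integer(n_cells_x),
                 n_cells_y = as.integer(n_cells_y),
                 cell_size = cell_size,
                 n_occasions = as.integer(n_occasions),
                 move_sites = isTRUE(move_sites),
                 origin = as.numeric(origin),
                 grid_polygon = gp),
            class = "snag_design")
}

#' @export
print.snag_design <- function(x, ...) {
  cat("Hair-snag design:", x$n_cells_x, "x", x$n_cells_y, "cells of",
      x$cell_size, "km;", x$n_occasions, "occasions;",
      if (x$move_sites) "sites moved between occasions" else "fixed sites",
      "\n")
  invisible(x)
}

#' Place hair-snag detectors for every occasion
#'
#' One detector per cell per occasion, drawn uniformly within the cell
#' (re-drawn each occasion when `move_sites`), mirroring the protocol of
#' relocating each site between sessions. Site covariates (terrain
#' ruggedness and canopy closure at site and landscape scales) are sampled
#' from the landscape at the detector location when a landscape is supplied.
#'
#' @param design A [study_design()].
#' @param landscape Optional [generate_landscape()] object for covariates.
#' @param seed Integer seed.
#' @return A `data.frame` (class `snag_layout`) with columns `occasion`,
#'   `detector_id`, `x`, `y` and, with a landscape, `TRI_site`,
#'   `TRI_landscape`, `CC_site`, `CC_landscape`.
#' @export
place_detectors <- function(design, landscape = NULL, seed = 1L) {
  stopifnot(inherits(design, "snag_design"))
  set.seed(as.integer(seed))
  cs <- design$cell_size
  cells <- expand.grid(cx = seq_len(design$n_cells_x),
                       cy = seq_len(design$n_cells_y))
  ncell <- nrow(cells)
  draw <- function() {
    data.frame(
      detector_id = paste0("C", cells$cx, "_", cells$cy),
      x = design$origin[1L] + (cells$cx - 1L) * cs + stats::runif(ncell) * cs,
      y = design$origin[2L] + (cells$cy - 1L) * cs + stats::runif(ncell) * cs,
      stringsAsFactors = FALSE)
  }
  fixed <- if (!design$move_sites) draw() else NULL
  out <- do.call(rbind, lapply(seq_len(design$n_occasions), function(s) {
    d <- if (design$move_sites) draw() else fixed
    cbind(occasion = s, d)
  }))
  if (!is.null(landscape)) {
    # site scale ~ immediate cell; landscape scale ~ 10 km neighbourhood mean
    out$TRI_site <- landscape_value(landscape, out$x, out$y, "tri")
    out$CC_site <- landscape_value(landscape, out$x, out$y, "cc")
    out$TRI_landscape <- neighbourhood_mean(landscape, out$x, out$y, "tri", 10)
    out$CC_landscape <- neighbourhood_mean(landscape, out$x, out$y, "cc", 10)
  }
  attr(out, "n_occasions") <- design$n_occasions
  class(out) <- c("snag_layout", "data.frame")
  out
}

neighbourhood_mean <- function(landscape, x, y, layer, radius_km) {
  m <- landscape[[layer]]
  ext <- landscape$extent; res <- landscape$resolution
  r <- max(1L, round(radius_km / res))
  vapply(seq_along(x), function(i) {
    ix <- floor((x[i] - ext[1L]) / res) + 1L
    iy <- floor((y[i] - ext[3L]) / res) + 1L
    xs <- max(1L, ix - r):min(nrow(m), ix + r)
    ys <- max(1L, iy - r):min(ncol(m), iy + r)
    mean(m[xs, ys])
  }, numeric(1L))
}

layout_occasions <- function(layout) {
  n <- attr(layout, "n_occasions")
  if (is.null(n)) n <- max(layout$occasion)
  as.integer(n)
}
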
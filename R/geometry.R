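# Planar geometry on projected-km coordinates. All polygons are closed rings
# given as a two-column matrix (x, y); the closing vertex may be present or not.

ring_matrix <- function(poly) {
  m <- as.matrix(poly)
  if (ncol(m) < 2L) stop("polygon must have two coordinate columns")
  m <- m[, 1:2, drop = FALSE]
  storage.mode(m) <- "double"
  n <- nrow(m)
  if (n >= 2L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3L) stop("polygon needs at least 3 distinct vertices")
  m
}

#' Axis-aligned rectangle polygon
#'
#' Convenience constructor used for sampling-grid perimeters.
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in km.
#' @return A 4 x 2 matrix of vertices (counter-clockwise, open ring).
#' @export
rect_polygon <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Signed polygon area (shoelace formula)
#' @param poly Two-column vertex matrix.
#' @return Area in km^2 (absolute value).
#' @export
polygon_area <- function(poly) {
  m <- ring_matrix(poly)
  x <- m[, 1L]; y <- m[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

#' Test points for polygon membership
#'
#' Even-odd ray casting; points exactly on an edge count as inside.
#'
#' @param x,y Numeric vectors of point coordinates (km).
#' @param poly Two-column vertex matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  m <- ring_matrix(poly)
  n <- nrow(m)
  px <- m[, 1L]; py <- m[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  inside <- logical(length(x))
  on_edge <- logical(length(x))
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (qy[i] > y))
    if (any(crosses)) {
      xint <- px[i] + (y[crosses] - py[i]) * (qx[i] - px[i]) / (qy[i] - py[i])
      flip <- x[crosses] < xint
      inside[crosses] <- xor(inside[crosses], flip)
    }
    # collinear-and-within-segment check for boundary points
    d <- (qx[i] - px[i]) * (y - py[i]) - (qy[i] - py[i]) * (x - px[i])
    seg <- abs(d) < 1e-9 &
      x >= pmin(px[i], qx[i]) - 1e-9 & x <= pmax(px[i], qx[i]) + 1e-9 &
      y >= pmin(py[i], qy[i]) - 1e-9 & y <= pmax(py[i], qy[i]) + 1e-9
    on_edge <- on_edge | seg
  }
  inside | on_edge
}

#' Distance from points to a polygon boundary
#'
#' Euclidean distance to the nearest edge, in km. With `signed = TRUE`
#' points outside the polygon get negative distances, which is the
#' convention used for telemetry distance-from-grid-edge covariates
#' (positive = interior).
#'
#' @param x,y Point coordinates (km).
#' @param poly Two-column vertex matrix.
#' @param signed Logical; negate distances for exterior points.
#' @return Numeric vector of distances (km).
#' @export
edge_distance <- function(x, y, poly, signed = TRUE) {
  m <- ring_matrix(poly)
  n <- nrow(m)
  px <- m[, 1L]; py <- m[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  d2 <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    vx <- qx[i] - px[i]; vy <- qy[i] - py[i]
    len2 <- vx * vx + vy * vy
    t <- if (len2 > 0) ((x - px[i]) * vx + (y - py[i]) * vy) / len2 else 0
    t <- pmin(1, pmax(0, t))
    dx <- x - (px[i] + t * vx); dy <- y - (py[i] + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  d <- sqrt(d2)
  if (signed) d <- ifelse(point_in_polygon(x, y, m), d, -d)
  d
}
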
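# Readers/writers for the interchange formats: delimited text for layouts,
# captures, masks and telemetry (coordinates in km, documented in a header
# comment), GeoJSON for polygons, ESRI ASCII grid for rasterized surfaces.

write_commented_csv <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_commented_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  attr(df, "header_comments") <- sub("^# ?", "", hdr)
  df
}

#' Write / read a detector layout
#'
#' Delimited text, one row per detector per occasion (`occasion`,
#' `detector_id`, `x`, `y`, site covariates), coordinates in projected km.
#'
#' @param layout A [place_detectors()] layout.
#' @param path File path.
#' @return `read_detectors` returns the layout `data.frame` with the
#'   `n_occasions` attribute restored.
#' @export
write_detectors <- function(layout, path) {
  write_commented_csv(as.data.frame(layout), path,
                      c("hair-snag detector layout; coordinates in km",
                        paste0("n_occasions=", layout_occasions(layout))))
  invisible(path)
}

#' @rdname write_detectors
#' @export
read_detectors <- function(path) {
  df <- read_commented_csv(path)
  req <- c("occasion", "detector_id", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("layout file lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  if (anyNA(df$x) || anyNA(df$y)) {
    bad <- which(is.na(df$x) | is.na(df$y))[1L]
    stop("layout row ", bad, ": coordinate parse failure")
  }
  if (anyDuplicated(paste(df$occasion, df$detector_id)))
    stop("duplicate detector id within an occasion")
  hdr <- attr(df, "header_comments")
  ns <- sub("n_occasions=", "", grep("n_occasions=", hdr, value = TRUE))
  attr(df, "n_occasions") <- if (length(ns)) as.integer(ns[1L]) else
    max(df$occasion)
  class(df) <- c("snag_layout", "data.frame")
  df
}

#' Write / read capture data
#'
#' Delimited text with columns `session`, `animal_id`, `occasion`,
#' `detector_id`, `sex`. On read, cross-references against a layout are
#' validated with the offending row number when one is supplied.
#'
#' @param capture Capture records.
#' @param path File path.
#' @param session Session label written with each record.
#' @param layout Optional layout for id validation on read.
#' @export
write_captures <- function(capture, path, session = "S1") {
  df <- data.frame(session = session,
                   animal_id = capture$animal_id,
                   occasion = capture$occasion,
                   detector_id = capture$detector_id,
                   sex = if ("sex" %in% names(capture)) capture$sex else NA,
                   stringsAsFactors = FALSE)
  write_commented_csv(df, path,
                      c("capture records (binary detections per occasion)",
                        paste0("n_occasions=", attr(capture, "n_occasions")
                               %||% max(capture$occasion))))
  invisible(path)
}

#' @rdname write_captures
#' @export
read_captures <- function(path, layout = NULL) {
  df <- read_commented_csv(path)
  req <- c("animal_id", "occasion", "detector_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("capture file lacks column(s): ",
                         paste(miss, collapse = ", "))
  hdr <- attr(df, "header_comments")
  ns <- sub("n_occasions=", "", grep("n_occasions=", hdr, value = TRUE))
  S <- if (length(ns)) as.integer(ns[1L]) else max(df$occasion)
  if (!is.null(layout)) {
    key <- paste(df$occasion, df$detector_id)
    lkey <- paste(layout$occasion, layout$detector_id)
    bad <- which(!key %in% lkey)
    if (length(bad))
      stop("capture row ", bad[1L], ": detector '", df$detector_id[bad[1L]],
           "' unknown for occasion ", df$occasion[bad[1L]])
    if (any(df$occasion > layout_occasions(layout)))
      stop("capture row ", which(df$occasion > layout_occasions(layout))[1L],
           ": occasion beyond the layout's sessions")
  }
  attr(df, "n_occasions") <- S
  attr(df, "header_comments") <- NULL
  class(df) <- c("snag_captures", "data.frame")
  df
}

#' Write / read a habitat mask
#'
#' CSV with `x`, `y`, covariates and region flags; spacing recorded in a
#' header comment. A missing RSF/Risk value on an in-grid point is a
#' validation error on read.
#'
#' @param mask A [make_mask()] mask.
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  write_commented_csv(as.data.frame(mask), path,
                      c("habitat mask; coordinates in km",
                        paste0("spacing=", attr(mask, "spacing"))))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  df <- read_commented_csv(path)
  if (!all(c("x", "y") %in% names(df))) stop("mask file needs x and y")
  hdr <- attr(df, "header_comments")
  sp <- sub("spacing=", "", grep("spacing=", hdr, value = TRUE))
  spacing <- if (length(sp)) as.numeric(sp[1L]) else
    stats::median(diff(sort(unique(df$x))))
  if (!is.finite(spacing) || spacing <= 0) stop("cannot determine mask spacing")
  if ("RSF" %in% names(df) && "inside_grid" %in% names(df)) {
    bad <- which(df$inside_grid & (is.na(df$RSF) | is.na(df$Risk)))
    if (length(bad))
      stop("mask row ", bad[1L], ": missing covariate inside the grid")
  }
  attr(df, "spacing") <- spacing
  attr(df, "cell_area") <- spacing^2
  attr(df, "header_comments") <- NULL
  class(df) <- c("bear_mask", "data.frame")
  df
}

#' Write / read telemetry locations
#' @param telemetry `data.frame` with `animal_id`, `sex`, `x`, `y`.
#' @param path File path.
#' @export
write_telemetry <- function(telemetry, path) {
  write_commented_csv(telemetry, path, "telemetry locations; km")
  invisible(path)
}

#' @rdname write_telemetry
#' @export
read_telemetry <- function(path) {
  df <- read_commented_csv(path)
  if (!all(c("animal_id", "x", "y") %in% names(df)))
    stop("telemetry file needs animal_id, x, y")
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  if (anyNA(df$x) || anyNA(df$y))
    stop("telemetry row ", which(is.na(df$x) | is.na(df$y))[1L],
         ": coordinate parse failure")
  attr(df, "header_comments") <- NULL
  df
}

#' Write / read a polygon as GeoJSON
#'
#' Single-ring polygons in the projected-km plane (no CRS handling).
#'
#' @param poly Two-column vertex matrix.
#' @param path File path.
#' @export
write_polygon <- function(poly, path) {
  m <- ring_matrix(poly)
  ring <- rbind(m, m[1L, ])
  gj <- list(type = "Feature",
             properties = list(units = "km"),
             geometry = list(type = "Polygon",
                             coordinates = list(lapply(seq_len(nrow(ring)),
                               function(i) as.numeric(ring[i, ])))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygon
#' @export
read_polygon <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- if (!is.null(gj$geometry)) gj$geometry else gj
  if (is.null(geom$type) || geom$type != "Polygon")
    stop("expected a GeoJSON Polygon")
  ring <- geom$coordinates[[1L]]
  m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p[1:2]))))
  colnames(m) <- c("x", "y")
  ring_matrix(m)
}

#' Write / read a simulation truth record
#'
#' CSV of true activity centers (all animals, detected or not) for
#' parameter-recovery checks.
#'
#' @param truth The `truth` element of a [simulate_study()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  write_commented_csv(truth$centers, path,
                      c("true activity centers (synthetic)",
                        paste0("seed=", truth$seed)))
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read_commented_csv(path)
}

#' Write a density surface as an ESRI ASCII grid
#'
#' Rasterizes a regular-lattice surface column (`D` by default) to the
#' plain-text ASCII-grid format.
#'
#' @param surface A [predict_density()] surface (regular lattice).
#' @param path File path.
#' @param column Column to rasterize.
#' @export
write_ascii_grid <- function(surface, path, column = "D") {
  xs <- sort(unique(surface$x)); ys <- sort(unique(surface$y))
  sp <- stats::median(diff(xs))
  m <- matrix(NA_real_, length(ys), length(xs))
  m[cbind(match(surface$y, ys), match(surface$x, xs))] <- surface[[column]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", length(xs)),
               paste("nrows", length(ys)),
               paste("xllcorner", min(xs) - sp / 2),
               paste("yllcorner", min(ys) - sp / 2),
               paste("cellsize", sp),
               "NODATA_value -9999"), con)
  for (i in rev(seq_along(ys))) {
    row <- m[i, ]
    row[is.na(row)] <- -9999
    writeLines(paste(format(row, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}
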
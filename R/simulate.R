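# Synthetic-study generator: known-truth populations, Bernoulli half-normal
# hair-snag detections, and bivariate-normal telemetry scatter.

#' Simulate activity centers from a log-linear density surface
#'
#' Centers are drawn from an inhomogeneous Poisson process with intensity
#' `D(x) = exp(beta0 + beta' z(x))` bears per 1000 km^2, realized as
#' independent Poisson counts per mask cell with uniform jitter within the
#' cell. Covariates named in `betas` are z-scored over the mask before the
#' linear predictor is formed, so `beta0` is the log density at average
#' habitat.
#'
#' @param mask A [make_mask()] mask (or data frame with `x`, `y` and any
#'   covariate columns named in `betas`).
#' @param betas Named numeric vector: `intercept` (log bears per 1000 km^2)
#'   plus optional covariate coefficients per covariate SD, e.g.
#'   `c(intercept = log(10), RSF = 0.5)`.
#' @param seed Integer seed.
#' @param sex Optional sex label attached to every center.
#' @return `data.frame` with `animal`, `x`, `y` (+ `sex`), one row per
#'   simulated center.
#' @export
simulate_population <- function(mask, betas = c(intercept = log(10)),
                                seed = 1L, sex = NULL) {
  stopifnot(is.numeric(betas), !is.null(names(betas)),
            "intercept" %in% names(betas))
  a <- mask_cell_area(mask)
  lp <- rep(betas[["intercept"]], nrow(mask))
  for (nm in setdiff(names(betas), "intercept")) {
    if (!nm %in% names(mask)) stop("mask lacks covariate '", nm, "'")
    z <- mask[[nm]]
    lp <- lp + betas[[nm]] * (z - mean(z)) / stats::sd(z)
  }
  if (any(abs(lp) > 50)) stop("density linear predictor overflows (|lp| > 50)")
  set.seed(as.integer(seed))
  mu <- exp(lp) * a / 1000          # expected centers per mask cell
  counts <- stats::rpois(length(mu), mu)
  n <- sum(counts)
  sp <- sqrt(a)
  idx <- rep.int(seq_along(counts), counts)
  out <- data.frame(
    animal = if (n) paste0(if (is.null(sex)) "A" else substr(sex, 1, 1),
                           seq_len(n)) else character(0),
    x = mask$x[idx] + (stats::runif(n) - 0.5) * sp,
    y = mask$y[idx] + (stats::runif(n) - 0.5) * sp,
    stringsAsFactors = FALSE)
  if (!is.null(sex)) out$sex <- if (n) sex else character(0)
  out
}

#' Simulate hair-snag detections of activity centers
#'
#' Independent Bernoulli draw per animal x detector x occasion with
#' half-normal probability `g0 * exp(-d^2 / (2 sigma^2))` of leaving an
#' identifiable hair sample. Animals never detected are absent from the
#' returned capture data (as in real DNA sampling) but remain in the truth
#' record kept by [simulate_study()].
#'
#' @param centers `data.frame` with `animal`, `x`, `y` and optionally `sex`.
#' @param layout A [place_detectors()] layout.
#' @param g0 Detection probability at the home-range center, in (0, 1).
#' @param sigma Movement scale (km), > 0.
#' @param seed Integer seed.
#' @return `data.frame` (class `snag_captures`) with columns `animal_id`,
#'   `sex`, `occasion`, `detector_id`; attribute `n_occasions`.
#' @export
simulate_detections <- function(centers, layout, g0, sigma, seed = 1L) {
  if (g0 < 0 || g0 > 1) stop("g0 must be in [0, 1]")
  if (sigma <= 0) stop("sigma must be > 0")
  set.seed(as.integer(seed))
  S <- layout_occasions(layout)
  recs <- vector("list", S)
  n <- nrow(centers)
  for (s in seq_len(S)) {
    det <- layout[layout$occasion == s, , drop = FALSE]
    if (n == 0L || nrow(det) == 0L) next
    d2 <- outer(centers$x, det$x, "-")^2 + outer(centers$y, det$y, "-")^2
    p <- g0 * exp(-d2 / (2 * sigma^2))
    hit <- matrix(stats::runif(length(p)) < p, nrow = n)
    ij <- which(hit, arr.ind = TRUE)
    if (nrow(ij)) {
      recs[[s]] <- data.frame(
        animal_id = centers$animal[ij[, 1L]],
        sex = if ("sex" %in% names(centers)) centers$sex[ij[, 1L]] else NA_character_,
        occasion = s,
        detector_id = det$detector_id[ij[, 2L]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(animal_id = character(0), sex = character(0),
                      occasion = integer(0), detector_id = character(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$animal_id, out$occasion, out$detector_id), ]
  rownames(out) <- NULL
  attr(out, "n_occasions") <- S
  class(out) <- c("snag_captures", "data.frame")
  out
}

#' Simulate telemetry locations around activity centers
#'
#' Circular bivariate normal scatter (independent N(0, sigma) per axis)
#' around each animal's center, emulating radio-collar fixes during the
#' sampling season.
#'
#' @param centers `data.frame` with `animal`, `x`, `y`, optionally `sex`.
#' @param sigma Per-axis standard deviation (km), >= 0.
#' @param n_locations Locations per animal (>= 1).
#' @param seed Integer seed.
#' @return `data.frame` with `animal_id`, `sex`, `x`, `y`.
#' @export
simulate_telemetry <- function(centers, sigma, n_locations = 30L, seed = 1L) {
  if (n_locations < 1L) stop("n_locations must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  set.seed(as.integer(seed))
  n <- nrow(centers)
  k <- n * n_locations
  data.frame(
    animal_id = rep(centers$animal, each = n_locations),
    sex = if ("sex" %in% names(centers))
      rep(centers$sex, each = n_locations) else NA_character_,
    x = rep(centers$x, each = n_locations) + stats::rnorm(k, 0, sigma),
    y = rep(centers$y, each = n_locations) + stats::rnorm(k, 0, sigma),
    stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic hair-snag study
#'
#' End-to-end generator: landscape, systematic snag design, moved detectors,
#' habitat mask, sex-specific populations from log-linear density surfaces,
#' Bernoulli half-normal detections, and telemetry for a subsample of
#' animals. Defaults emulate a single bear-management-area survey: 7-km
#' cells sampled over 4 sessions with sites moved between sessions,
#' female bears with higher `g0` and smaller movement scale than males,
#' density increasing with RSF and decreasing with mortality risk.
#'
#' @param n_cells_x,n_cells_y Grid dimensions in cells.
#' @param cell_size Cell edge (km).
#' @param n_occasions Number of sessions.
#' @param buffer Mask buffer (km).
#' @param spacing Mask spacing (km).
#' @param detection Named list per sex: `list(F = c(g0 = , sigma = ), ...)`.
#' @param density Named list per sex of density beta vectors (see
#'   [simulate_population()]).
#' @param n_collared Collared animals per sex for telemetry.
#' @param telemetry_locations Fixes per collared animal.
#' @param landscape_autocorr Autocorrelation range of the covariate fields (km).
#' @param rsf_risk_cor Correlation of the latent RSF and Risk fields.
#' @param seed Integer master seed (all component seeds derive from it).
#' @return List of class `bear_study`: `landscape`, `design`, `layout`,
#'   `mask`, `captures`, `telemetry`, and `truth` (centers of *all* animals
#'   plus generating parameters).
#' @export
simulate_study <- function(n_cells_x = 10L, n_cells_y = 10L, cell_size = 7,
                           n_occasions = 4L, buffer = NULL, spacing = 3.5,
                           detection = list(F = c(g0 = 0.2, sigma = 5),
                                            M = c(g0 = 0.1, sigma = 10)),
                           density = list(
                             F = c(intercept = log(12), RSF = 0.4, Risk = -0.3),
                             M = c(intercept = log(8), RSF = 0.4, Risk = -0.3)),
                           n_collared = 15L, telemetry_locations = 30L,
                           landscape_autocorr = 10, rsf_risk_cor = 0.2,
                           seed = 1L) {
  seed <- as.integer(seed)
  sigmas <- vapply(detection, function(p) p[["sigma"]], numeric(1))
  if (is.null(buffer)) buffer <- min(100, 3 * max(sigmas))
  design <- study_design(n_cells_x, n_cells_y, cell_size, n_occasions)
  ext <- c(design$origin[1L] - buffer,
           design$origin[1L] + n_cells_x * cell_size + buffer,
           design$origin[2L] - buffer,
           design$origin[2L] + n_cells_y * cell_size + buffer)
  landscape <- generate_landscape(ext, resolution = 1,
                                  autocorr_range = landscape_autocorr,
                                  rsf_risk_cor = rsf_risk_cor,
                                  seed = seed)
  layout <- place_detectors(design, landscape, seed = seed + 1L)
  mask <- make_mask(design$grid_polygon, buffer = buffer, spacing = spacing,
                    landscape = landscape)
  sexes <- names(detection)
  captures <- list(); telemetry <- list(); centers <- list()
  for (i in seq_along(sexes)) {
    sx <- sexes[i]
    cen <- simulate_population(mask, density[[sx]], seed = seed + 10L + i,
                               sex = sx)
    centers[[sx]] <- cen
    captures[[sx]] <- simulate_detections(
      cen, layout, g0 = detection[[sx]][["g0"]],
      sigma = detection[[sx]][["sigma"]], seed = seed + 20L + i)
    if (n_collared > 0L && nrow(cen) > 0L) {
      set.seed(seed + 30L + i)
      coll <- cen[sample.int(nrow(cen), min(n_collared, nrow(cen))), ]
      telemetry[[sx]] <- simulate_telemetry(
        coll, sigma = detection[[sx]][["sigma"]],
        n_locations = telemetry_locations, seed = seed + 40L + i)
    }
  }
  cap <- do.call(rbind, captures)
  rownames(cap) <- NULL
  attr(cap, "n_occasions") <- design$n_occasions
  class(cap) <- c("snag_captures", "data.frame")
  tel <- if (length(telemetry)) do.call(rbind, telemetry) else NULL
  if (!is.null(tel)) rownames(tel) <- NULL
  structure(list(
    landscape = landscape, design = design, layout = layout, mask = mask,
    captures = cap, telemetry = tel,
    truth = list(centers = do.call(rbind, centers),
                 detection = detection, density = density, seed = seed)),
    class = "bear_study")
}

#' @export
print.bear_study <- function(x, ...) {
  cat("Synthetic hair-snag study:", x$design$n_cells_x, "x",
      x$design$n_cells_y, "cells,", x$design$n_occasions, "occasions\n")
  cat("  true animals:", nrow(x$truth$centers),
      " detected:", length(unique(x$captures$animal_id)),
      " detections:", nrow(x$captures), "\n")
  invisible(x)
}
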
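# Telemetry residency and the closed-model/telemetry density estimator.
# Residency (share of a collared animal's locations inside the sampling
# grid) is modelled as a logistic function of the animal's mean
# distance-from-grid-edge; detected animals' closed-model abundance
# contributions are then weighted by predicted residency to correct for
# partial use of the grid.

#' Fit a telemetry residency model
#'
#' Per collared animal, residency is the fraction of its locations inside
#' the grid polygon; its covariate is the mean distance from the grid edge
#' of its *inside-grid* locations only (matching how DNA-detected animals'
#' mean detection locations are computed). A binomial GLM with logit link
#' regresses residency on distance. Animals with zero inside-grid
#' locations carry no defined mean location and are excluded with a
#' warning.
#'
#' @param telemetry `data.frame` with `animal_id`, `x`, `y` (km).
#' @param grid_polygon Grid perimeter (vertex matrix).
#' @return Object of class `residency_fit`: `glm` (the fitted binomial
#'   GLM), `animals` (per-animal table: locations, fraction inside, mean
#'   distance), `dist_range`, `boundary` flag (all-inside data).
#' @export
fit_residency <- function(telemetry, grid_polygon) {
  gp <- ring_matrix(grid_polygon)
  ids <- unique(as.character(telemetry$animal_id))
  if (length(ids) < 2L) stop("need >= 2 collared animals")
  inside <- point_in_polygon(telemetry$x, telemetry$y, gp)
  tab <- do.call(rbind, lapply(ids, function(id) {
    sel <- as.character(telemetry$animal_id) == id
    n_in <- sum(inside[sel])
    if (n_in == 0L) return(NULL)
    mx <- mean(telemetry$x[sel & inside]); my <- mean(telemetry$y[sel & inside])
    data.frame(animal = id, n = sum(sel), n_in = n_in,
               residency = n_in / sum(sel),
               dist_edge = edge_distance(mx, my, gp),
               stringsAsFactors = FALSE)
  }))
  dropped <- length(ids) - nrow(tab)
  if (dropped > 0L)
    warning(dropped, " animal(s) with zero inside-grid locations excluded")
  if (nrow(tab) < 2L) stop("fewer than 2 usable collared animals")
  boundary <- all(tab$residency == 1)
  if (boundary)
    warning("all locations inside the grid: residency intercept at the ",
            "parameter-space boundary")
  g <- suppressWarnings(stats::glm(
    cbind(n_in, n - n_in) ~ dist_edge, family = stats::binomial(),
    data = tab))
  structure(list(glm = g, animals = tab,
                 dist_range = range(tab$dist_edge), boundary = boundary),
            class = "residency_fit")
}

#' Predicted residency at given distances from the grid edge
#'
#' @param object A [fit_residency()] model.
#' @param dist_edge Distances (km; positive = inside the grid).
#' @param warn Warn when predicting outside the fitted distance range.
#' @return Predicted residency values in (0, 1).
#' @export
predict_residency <- function(object, dist_edge, warn = TRUE) {
  stopifnot(inherits(object, "residency_fit"))
  out_of_range <- dist_edge < object$dist_range[1L] |
    dist_edge > object$dist_range[2L]
  if (warn && any(out_of_range))
    warning(sum(out_of_range), " distance(s) outside the fitted range; ",
            "residency clamped to the (0, 1) model prediction")
  pmin(1, pmax(0, stats::predict(object$glm,
                                 newdata = data.frame(dist_edge = dist_edge),
                                 type = "response")))
}

#' @export
print.residency_fit <- function(x, ...) {
  cat("Telemetry residency model:", nrow(x$animals), "collared animals\n")
  print(stats::coef(x$glm))
  invisible(x)
}

#' Closed-model / telemetry density estimate
#'
#' The comparison density estimator: each detected animal contributes
#' `r_i / pstar_i` to abundance, where `pstar_i` is its closed-model
#' probability of at least one detection and `r_i` its predicted residency
#' at its mean DNA-detection location's distance from the grid edge;
#' density is the residency-weighted Horvitz-Thompson sum divided by grid
#' area. With residency identically 1 this reduces to `N / A`. A
#' `mean_residency` variant multiplies the closed-model `N` by the mean
#' predicted residency instead of weighting per animal.
#'
#' @param closed A [fit_closed()] fit on the same animals.
#' @param residency A [fit_residency()] model.
#' @param capture Capture data used to locate each detected animal (mean of
#'   its detection-site coordinates).
#' @param layout Detector layout supplying site coordinates.
#' @param grid_polygon Grid perimeter; its area is the density denominator.
#' @param method `"per_animal"` (default) or `"mean_residency"`.
#' @return `data.frame` with `D_per_1000km2`, `se`, `lcl`, `ucl`,
#'   `N_effective`, `mean_residency`, `area_km2`.
#' @export
density_closed_telemetry <- function(closed, residency, capture, layout,
                                     grid_polygon,
                                     method = c("per_animal",
                                                "mean_residency")) {
  method <- match.arg(method)
  stopifnot(inherits(closed, "closed_fit"), inherits(residency, "residency_fit"))
  gp <- ring_matrix(grid_polygon)
  A <- polygon_area(gp)
  if (A <= 0) stop("grid area must be > 0")
  key <- paste(capture$occasion, capture$detector_id)
  lkey <- paste(layout$occasion, layout$detector_id)
  k <- match(key, lkey)
  if (anyNA(k)) stop("capture records reference detectors missing from layout")
  ids <- sort(unique(as.character(capture$animal_id)))
  if (length(ids) != closed$n)
    stop("capture data and closed fit disagree on the number of animals")
  mx <- tapply(layout$x[k], as.character(capture$animal_id), mean)[ids]
  my <- tapply(layout$y[k], as.character(capture$animal_id), mean)[ids]
  dist_i <- edge_distance(mx, my, gp)
  r_i <- predict_residency(residency, dist_i)
  pstar <- closed$pstar
  est_fun <- function(th_c, beta_r) {
    ps <- closed_pstar_at(closed, th_c)
    eta <- beta_r[1L] + beta_r[2L] * dist_i
    ri <- stats::plogis(eta)
    if (method == "per_animal") sum(ri / ps) else sum(1 / ps) * mean(ri)
  }
  beta_r <- stats::coef(residency$glm)
  Neff <- est_fun(closed$theta, beta_r)
  # delta method over closed-model and residency parameters (independent
  # data sources => block-diagonal covariance), plus the HT component
  th_all <- c(closed$theta, beta_r)
  nc <- length(closed$theta)
  grad <- vapply(seq_along(th_all), function(i) {
    h <- 1e-5 * max(abs(th_all[i]), 1)
    e <- rep(0, length(th_all)); e[i] <- h
    (est_fun((th_all + e)[1:nc], (th_all + e)[-(1:nc)]) -
       est_fun((th_all - e)[1:nc], (th_all - e)[-(1:nc)])) / (2 * h)
  }, numeric(1))
  Vr <- stats::vcov(residency$glm)
  V <- matrix(0, length(th_all), length(th_all))
  V[1:nc, 1:nc] <- closed$vcov
  V[-(1:nc), -(1:nc)] <- Vr
  varN <- drop(t(grad) %*% V %*% grad) +
    sum((r_i^2) * (1 - pstar) / pstar^2)
  D <- 1000 * Neff / A
  seD <- 1000 * sqrt(max(varN, 0)) / A
  ci <- lognormal_ci(D, seD)
  data.frame(D_per_1000km2 = D, se = seD, lcl = ci[1L], ucl = ci[2L],
             N_effective = Neff, mean_residency = mean(r_i), area_km2 = A)
}

closed_pstar_at <- function(closed, th) {
  S <- closed$S; n <- closed$n
  switch(closed$model,
    M0 = , Mb = rep(1 - (1 - stats::plogis(th[1L]))^S, n),
    Mt = rep(1 - prod(1 - stats::plogis(th)), n),
    Mh2 = {
      p <- stats::plogis(th[1:2]); pi1 <- stats::plogis(th[3L])
      rep(sum(c(pi1, 1 - pi1) * (1 - (1 - p)^S)), n)
    })
}
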
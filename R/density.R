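# Density-surface models: the five-model log-linear candidate set over the
# mask covariates, density prediction with delta-method SEs, and region
# abundance.

DENSITY_MODEL_SET <- list(
  constant   = ~1,
  RSF        = ~RSF,
  Risk       = ~Risk,
  `RSF+Risk` = ~RSF + Risk,
  `RSF*Risk` = ~RSF * Risk)

#' Fit the density-surface candidate model set
#'
#' Fits the five log-linear density models (constant, RSF, Risk, RSF+Risk,
#' RSF x Risk) with a shared detection-model structure — the phase-2
#' analysis, run after the best detection model has been selected on a
#' constant-density fit. Detection parameters are re-estimated jointly in
#' every fit, so supported detection covariates remain in the model.
#'
#' @inheritParams fit_secr
#' @param models Named list of density formulas (default the 5-model set).
#' @param hessian `"best"` (default: covariance computed for the top-ranked
#'   model only), `"all"`, or `"none"` (likelihood ranking only).
#' @param trace Print optimizer progress.
#' @return List of class `density_model_set`: `fits` (named list of
#'   [fit_secr()] objects), `table` (the [model_table()]), `best` (name of
#'   the top-ranked model).
#' @export
fit_density_models <- function(capture, layout, mask,
                               model = list(g0 = ~1, sigma = ~1),
                               models = DENSITY_MODEL_SET,
                               hessian = c("best", "all", "none"),
                               trace = FALSE) {
  hessian <- match.arg(hessian)
  fits <- vector("list", length(models))
  names(fits) <- names(models)
  start <- NULL
  for (nm in names(models)) {
    fits[[nm]] <- fit_secr(capture, layout, mask, model = model,
                           density = models[[nm]], start = start,
                           hessian = hessian == "all", trace = trace)
    if (is.null(start)) {
      # warm-start later models at the constant fit's detection parameters
      th <- fits[[nm]]$theta
      start <- th[setdiff(names(th), "D")]
    }
    b <- fits[[nm]]$theta
    dens_terms <- grep("^D\\.", names(b))
    if (length(dens_terms) && any(abs(b[dens_terms]) > 10))
      warning("possible separation/boundary in density coefficients of ",
              nm, " model")
  }
  tab <- model_table(fits, reference = "constant")
  best <- tab$model[1L]
  if (hessian == "best") fits[[best]] <- secr_add_vcov(fits[[best]])
  structure(list(fits = fits, table = tab, best = best),
            class = "density_model_set")
}

#' @export
print.density_model_set <- function(x, ...) {
  cat("Density-surface model set (best:", x$best, ")\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Predict the density surface from a fitted model
#'
#' Per-mask-point density `D(x) = exp(beta' z(x))` in bears per 1000 km^2,
#' with delta-method standard errors on the response scale. Points whose
#' covariates fall outside the range seen on the sampled grid are flagged
#' `extrapolated` (with a warning) — predictions there rely on the fitted
#' relationship holding beyond the data.
#'
#' @param fit A [fit_secr()] fit.
#' @param mask Mask to predict onto (default: the fitting mask).
#' @return `data.frame` of class `density_surface`: `x`, `y`, `D`, `SE`,
#'   `linear_predictor`, `inside_grid`, `extrapolated`; attribute
#'   `cell_area`.
#' @export
predict_density <- function(fit, mask = NULL) {
  stopifnot(inherits(fit, "secr_fit"))
  if (!fit$converged) warning("predicting from a fit flagged as not converged")
  dd <- fit$prep$dens
  if (is.null(mask)) {
    mask <- fit$prep$mask
    Xd <- dd$Xd
  } else {
    dat <- data.frame(row.names = seq_len(nrow(mask)))
    for (v in names(dd$centers))
      dat[[v]] <- (mask[[v]] - dd$centers[v]) / dd$scales[v]
    Xd <- stats::model.matrix(dd$formula, data = dat)
    colnames(Xd) <- ifelse(colnames(Xd) == "(Intercept)", "D",
                           paste0("D.", colnames(Xd)))
  }
  beta <- fit$theta[colnames(Xd)]
  V <- fit$vcov[colnames(Xd), colnames(Xd), drop = FALSE]
  lp <- drop(Xd %*% beta)
  D <- exp(lp)
  var_lp <- rowSums((Xd %*% V) * Xd)
  SE <- D * sqrt(pmax(var_lp, 0))
  extrap <- rep(FALSE, nrow(mask))
  ref <- if (!is.null(fit$prep$mask$inside_grid)) fit$prep$mask$inside_grid
    else rep(TRUE, nrow(fit$prep$mask))
  for (v in names(dd$centers)) {
    if (!v %in% names(mask)) next
    rng <- range(fit$prep$mask[[v]][ref])
    extrap <- extrap | mask[[v]] < rng[1L] | mask[[v]] > rng[2L]
  }
  if (any(extrap))
    warning(sum(extrap), " mask points outside the fitted covariate range ",
            "(flagged extrapolated)")
  out <- data.frame(x = mask$x, y = mask$y, D = D, SE = SE,
                    linear_predictor = lp,
                    inside_grid = mask$inside_grid %||% TRUE,
                    extrapolated = extrap)
  attr(out, "cell_area") <- mask_cell_area(mask)
  attr(out, "fit") <- fit
  class(out) <- c("density_surface", "data.frame")
  out
}

#' Abundance and density of a mask region
#'
#' Horvitz-Thompson-style plug-in abundance over a flagged mask region:
#' `N = (a / 1000) * sum D(x)` over region points, with delta-method
#' variance from the fitted coefficient covariance and a log-normal 95\%
#' confidence interval. Extrapolated points are excluded by default.
#'
#' @param surface A [predict_density()] surface (with its fit attached).
#' @param region Logical vector over mask points, or the name of a logical
#'   mask column (default `"inside_grid"`, the sampled-grid convention).
#' @param include_extrapolated Include flagged extrapolated points.
#' @return `data.frame` with `N`, `se`, `lcl`, `ucl`, `area_km2`, and the
#'   mean density `D_per_1000km2` (+ CI) on the region.
#' @export
region_abundance <- function(surface, region = "inside_grid",
                             include_extrapolated = FALSE) {
  stopifnot(inherits(surface, "density_surface"))
  fit <- attr(surface, "fit")
  if (is.character(region)) region <- surface[[region]]
  region <- as.logical(region)
  if (!any(region, na.rm = TRUE)) stop("empty region")
  keep <- region & (include_extrapolated | !surface$extrapolated)
  if (!any(keep)) stop("region contains only extrapolated points")
  a <- attr(surface, "cell_area")
  N <- a / 1000 * sum(surface$D[keep])
  dd <- fit$prep$dens
  # rebuild the design rows for the kept points from the linear predictor
  Xd <- dd$Xd
  if (nrow(Xd) != nrow(surface))
    stop("surface and fitted mask differ; refit or predict on the fit mask")
  beta <- fit$theta[colnames(Xd)]
  V <- fit$vcov[colnames(Xd), colnames(Xd), drop = FALSE]
  grad <- a / 1000 * colSums(surface$D[keep] * Xd[keep, , drop = FALSE])
  vN <- drop(t(grad) %*% V %*% grad)
  se <- sqrt(max(vN, 0))
  ci <- lognormal_ci(N, se)
  area <- a * sum(keep)
  data.frame(N = N, se = se, lcl = ci[1L], ucl = ci[2L], area_km2 = area,
             D_per_1000km2 = 1000 * N / area,
             D_lcl = 1000 * ci[1L] / area, D_ucl = 1000 * ci[2L] / area)
}

# Log-normal CI for a positive estimate (the standard capture-recapture
# interval form).
lognormal_ci <- function(est, se, level = 0.95) {
  if (est <= 0 || se == 0) return(c(est, est))
  z <- stats::qnorm(1 - (1 - level) / 2)
  cv2 <- (se / est)^2
  C <- exp(z * sqrt(log(1 + cv2)))
  c(est / C, est * C)
}
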
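# Source-sink classification of the mask: median splits of RSF and
# mortality-risk scores define "safe harbor" (high RSF, low Risk) and
# "attractive sink" (high RSF, high Risk) quadrants.

RISK_CATEGORIES <- c("safe_harbor", "attractive_sink",
                     "low_rsf_low_risk", "low_rsf_high_risk")

#' Classify mask points into RSF/Risk quadrants
#'
#' High/low splits of RSF and Risk at their medians over in-grid mask
#' points: high RSF + low Risk = "safe_harbor" (source-like), high RSF +
#' high Risk = "attractive_sink". "High" means strictly above the median,
#' so median ties go to the low class. Because the split is rank-based the
#' labels are invariant to monotone rescaling of the scores.
#'
#' @param mask A mask with `RSF` and `Risk` columns (only `inside_grid`
#'   points are classified by default).
#' @param in_grid_only Restrict both the medians and the labels to in-grid
#'   points (out-of-grid points get `NA`).
#' @return Factor over mask points with levels
#'   `safe_harbor, attractive_sink, low_rsf_low_risk, low_rsf_high_risk`;
#'   attributes `rsf_median`, `risk_median`.
#' @export
categorize_mask <- function(mask, in_grid_only = TRUE) {
  if (!all(c("RSF", "Risk") %in% names(mask)))
    stop("mask needs RSF and Risk covariates")
  ref <- if (in_grid_only && !is.null(mask$inside_grid)) mask$inside_grid
    else rep(TRUE, nrow(mask))
  if (anyNA(mask$RSF[ref]) || anyNA(mask$Risk[ref]))
    stop("missing RSF/Risk among classified points")
  rsf_med <- stats::median(mask$RSF[ref])
  risk_med <- stats::median(mask$Risk[ref])
  if (all(mask$RSF[ref] == mask$RSF[ref][1L]))
    stop("RSF is constant: no median split possible")
  if (all(mask$Risk[ref] == mask$Risk[ref][1L]))
    stop("Risk is constant: no median split possible")
  high_rsf <- mask$RSF > rsf_med
  high_risk <- mask$Risk > risk_med
  lab <- ifelse(high_rsf & !high_risk, "safe_harbor",
         ifelse(high_rsf & high_risk, "attractive_sink",
         ifelse(!high_rsf & !high_risk, "low_rsf_low_risk",
                "low_rsf_high_risk")))
  lab[!ref] <- NA
  structure(factor(lab, levels = RISK_CATEGORIES),
            rsf_median = rsf_med, risk_median = risk_med)
}

#' Mean density, area and relative abundance per RSF/Risk category
#'
#' For each quadrant: mean predicted density, total area, and relative
#' abundance (mean density x area). Also reports the overall mean density
#' (the reference line against which category deviations indicate
#' selection or aversion) and the abundance expected if animals were
#' spread evenly, i.e. proportional to category area.
#'
#' @param surface A [predict_density()] surface.
#' @param labels A [categorize_mask()] factor on the same mask.
#' @return `data.frame` with one row per category: `category`,
#'   `mean_density` (per 1000 km^2), `area_km2`, `relative_abundance`
#'   (bears), `expected_equal_density` (bears under uniform density),
#'   `n_points`; attribute `overall_mean_density`.
#' @export
category_summary <- function(surface, labels) {
  stopifnot(inherits(surface, "density_surface"))
  if (length(labels) != nrow(surface))
    stop("labels and surface are not on the same mask")
  a <- attr(surface, "cell_area")
  keep <- !is.na(labels)
  D <- surface$D[keep]; lab <- droplevels(labels[keep])
  overall <- mean(D)
  total_area <- a * sum(keep)
  rows <- lapply(RISK_CATEGORIES, function(cat) {
    sel <- lab == cat
    np <- sum(sel)
    if (np == 0L)
      return(data.frame(category = cat, mean_density = NA_real_,
                        area_km2 = 0, relative_abundance = 0,
                        expected_equal_density = 0, n_points = 0L,
                        empty = TRUE))
    area <- a * np
    md <- mean(D[sel])
    data.frame(category = cat, mean_density = md, area_km2 = area,
               relative_abundance = md * area / 1000,
               expected_equal_density = overall * area / 1000,
               n_points = np, empty = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_mean_density") <- overall
  attr(out, "total_area_km2") <- total_area
  class(out) <- c("category_summary", "data.frame")
  out
}

#' Tally activity centers per RSF/Risk category
#'
#' The activity-center counterpart to [category_summary()]: counts
#' posterior-mode home-range centers per quadrant, for comparing the
#' density-surface and center-based views of selection.
#'
#' @param centers A [center_posterior()] result.
#' @param labels A [categorize_mask()] factor on the fitting mask.
#' @return `data.frame` with `category`, `count`.
#' @export
category_center_counts <- function(centers, labels) {
  s <- if (inherits(centers, "center_estimates")) centers$summary else centers
  tab <- table(factor(labels[s$mode_index], levels = RISK_CATEGORIES))
  data.frame(category = names(tab), count = as.integer(tab))
}
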
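# Home-range-center (activity-center) posteriors from a fitted SECR model.

#' Posterior distributions of activity centers
#'
#' For each detected animal, the posterior weight of each mask point x is
#' proportional to `D(x) * Pr(history | x)` under the fitted model,
#' normalized over the mask (computed in log space to guard underflow).
#' The point summaries are the posterior mode (the mask point of maximum
#' weight, ties broken by lowest mask index) and the posterior mean
#' (weighted centroid).
#'
#' @param fit A [fit_secr()] fit.
#' @param animals Optional character vector restricting to some animals.
#' @return List of class `center_estimates`: `summary` (`data.frame` with
#'   `animal`, `sex`, `mode_x`, `mode_y`, `mean_x`, `mean_y`,
#'   `mode_index`) and `weights` (animals x mask-points matrix).
#' @export
center_posterior <- function(fit, animals = NULL) {
  stopifnot(inherits(fit, "secr_fit"))
  prep <- fit$prep
  pars <- split_theta(fit$theta, prep)
  st1 <- secr_stage1(prep, pars)
  r <- drop(prep$dens$Xd %*% pars$betaD)
  pi1 <- if (st1$C == 2L) stats::plogis(pars$pmix_l) else 1
  w <- if (st1$C == 2L) c(pi1, 1 - pi1) else 1
  n <- prep$n
  logpost <- NULL
  for (cc in seq_len(st1$C)) {
    cl <- st1$classes[[cc]]
    A <- cl$DT
    A <- if (is.null(cl$struct))
      sweep(A, 2L, cl$totQ + r, "+") else A + cl$struct + rep(r, each = n)
    A <- A + log(w[cc])
    logpost <- if (is.null(logpost)) A else {
      m <- pmax(logpost, A)
      m + log(exp(logpost - m) + exp(A - m))
    }
  }
  rm <- logpost[cbind(seq_len(n), max.col(logpost, ties.method = "first"))]
  if (any(!is.finite(rm))) stop("all-zero posterior weights for animal ",
                                prep$animals[which(!is.finite(rm))[1L]])
  W <- exp(logpost - rm)
  W <- W / rowSums(W)
  mode_index <- apply(W, 1L, which.max)      # which.max = lowest index on ties
  mean_x <- drop(W %*% prep$mask$x)
  mean_y <- drop(W %*% prep$mask$y)
  sex <- if ("sex" %in% names(prep$capture))
    vapply(split(as.character(prep$capture$sex), prep$aidx),
           function(s) s[1L], character(1))[as.character(seq_len(n))]
  else rep(NA_character_, n)
  keep <- if (is.null(animals)) seq_len(n) else {
    idx <- match(animals, prep$animals)
    if (anyNA(idx)) stop("unknown animal(s): ",
                         paste(animals[is.na(idx)], collapse = ", "))
    idx
  }
  summary <- data.frame(
    animal = prep$animals[keep], sex = sex[keep],
    mode_x = prep$mask$x[mode_index[keep]],
    mode_y = prep$mask$y[mode_index[keep]],
    mean_x = mean_x[keep], mean_y = mean_y[keep],
    mode_index = mode_index[keep], stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(summary = summary, weights = W[keep, , drop = FALSE],
                 mask = prep$mask),
            class = "center_estimates")
}

#' @export
print.center_estimates <- function(x, ...) {
  cat("Activity-center posteriors for", nrow(x$summary), "animals\n")
  print(utils::head(x$summary), digits = 4)
  invisible(x)
}

#' Share of home-range centers in a region
#'
#' Counts animals whose posterior-mode center falls in a flagged region
#' (e.g. across a provincial boundary) and reports the percentage rounded
#' to one decimal, the tabulation used for "centers in British Columbia"
#' style summaries.
#'
#' @param centers A [center_posterior()] result, or its `summary` data
#'   frame.
#' @param region Logical vector over mask points, a logical vector aligned
#'   with the centers, or a polygon (vertex matrix) tested against the mode
#'   coordinates.
#' @return `data.frame` with `count`, `total`, `percent`.
#' @export
proportion_in_region <- function(centers, region) {
  s <- if (inherits(centers, "center_estimates")) centers$summary else centers
  if (nrow(s) == 0L) stop("no centers")
  inside <- if (is.matrix(region) || is.data.frame(region)) {
    point_in_polygon(s$mode_x, s$mode_y, region)
  } else if (is.logical(region) && length(region) == nrow(s)) {
    region
  } else if (is.logical(region) && !is.null(s$mode_index)) {
    region[s$mode_index]
  } else stop("region must be a polygon or a logical flag vector")
  region_percent(sum(inside), nrow(s))
}

#' Percentage from printed counts
#'
#' `100 * count / total` rounded to one decimal — the tabulation rule used
#' for region summaries, usable directly on published counts.
#'
#' @param count,total Non-negative integers, `total > 0`.
#' @return `data.frame` with `count`, `total`, `percent`.
#' @export
region_percent <- function(count, total) {
  stopifnot(total > 0, count >= 0, count <= total)
  data.frame(count = count, total = total,
             percent = round(100 * count / total, 1))
}
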
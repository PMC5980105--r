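# Maximum-likelihood fitting of the SECR model, with AICc model selection
# and buffer-width (effective sampling area) diagnostics.

#' Fit a spatially explicit capture-recapture model
#'
#' Maximizes the SECR likelihood by quasi-Newton (BFGS) iteration with the
#' density intercept concentrated out of the likelihood. Variances come
#' from the inverse of a central-difference Hessian at the optimum.
#'
#' @inheritParams secr_loglik
#' @param model List of one-sided formulas for `g0` and `sigma`. Terms:
#'   `trend` (linear in occasion), `b` (animal-level learned response),
#'   `bk` (site-specific learned response), `h2` (2-class Pledger mixture),
#'   or any numeric layout covariate (z-scored internally).
#' @param density One-sided formula over mask covariates (log link).
#' @param start Optional named start vector on link scales.
#' @param hessian Compute the Hessian-based covariance matrix (default
#'   TRUE). Skipping it speeds up fits used only for likelihood ranking;
#'   such fits have `NA` variances.
#' @param trace Print optimizer progress.
#' @return An object of class `secr_fit` with elements `theta`, `loglik`,
#'   `vcov`, `n` (detected individuals), `k` (parameters), `aicc`,
#'   `converged`, `sigma_identifiable`, `Lambda` (expected detections) and
#'   the model specification. Use [predict.secr_fit()] for back-transformed
#'   parameter estimates and [predict_density()] for the density surface.
#' @export
fit_secr <- function(capture, layout, mask,
                     model = list(g0 = ~1, sigma = ~1), density = ~1,
                     start = NULL, hessian = TRUE, trace = FALSE) {
  prep <- secr_prep(capture, layout, mask, model, density)
  if (prep$n < 1L) stop("no detected animals: nothing to fit")
  # sigma identifiability requires recaptures at >= 2 distinct detectors
  nsites <- tapply(prep$capture$detector_id, prep$aidx,
                   function(d) length(unique(d)))
  sigma_identifiable <- any(nsites >= 2L)
  theta0 <- secr_start(prep, start)
  iD <- which(prep$par_names == "D")
  free <- setdiff(seq_along(theta0), iD)

  nll <- function(th_red) {
    th <- theta0
    th[free] <- th_red
    th[iD] <- 0
    out <- tryCatch(
      -secr_eval(prep, split_theta(th, prep), concentrate = TRUE)$loglik,
      error = function(e) NA_real_)
    if (!is.finite(out)) 1e10 else out
  }
  opt <- stats::optim(theta0[free], nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-9,
                                     trace = as.integer(trace)))
  theta <- theta0
  theta[free] <- opt$par
  s2 <- secr_eval(prep, split_theta(replace(theta, iD, 0), prep),
                  concentrate = TRUE)
  theta[iD] <- s2$b0
  names(theta) <- prep$par_names
  loglik <- s2$loglik

  full_nll <- function(th) {
    out <- tryCatch(
      -secr_eval(prep, split_theta(th, prep), concentrate = FALSE)$loglik,
      error = function(e) NA_real_)
    if (!is.finite(out)) 1e10 else out
  }
  if (hessian) {
    H <- num_hessian(full_nll, theta)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    hess_ok <- !is.null(vc) && all(is.finite(vc)) && all(diag(vc) >= 0)
    if (!hess_ok) vc <- pseudo_inverse(H)
  } else {
    vc <- matrix(NA_real_, length(theta), length(theta),
                 dimnames = list(prep$par_names, prep$par_names))
    hess_ok <- TRUE
  }
  g0hat <- stats::plogis(theta[[1L]])
  if (g0hat > 0.999)
    warning("g0 estimate at boundary (", signif(g0hat, 4), ")")
  if (!sigma_identifiable)
    warning("no spatial recaptures: sigma is not identifiable; ",
            "estimates suppressed from reports")
  k <- length(theta)
  fit <- structure(list(
    theta = theta, loglik = loglik, vcov = vc,
    n = prep$n, k = k,
    aicc = if (prep$n > k + 1L) aicc(loglik, k, prep$n) else NA_real_,
    Lambda = prep$n,                 # = exp(b0) * G at the concentrated MLE
    converged = opt$convergence == 0L && hess_ok,
    sigma_identifiable = sigma_identifiable,
    model = model, density = density,
    counts = c(n = prep$n, detections = nrow(prep$capture)),
    prep = prep), class = "secr_fit")
  fit
}

# Fill in the Hessian-based covariance of a fit made with hessian = FALSE.
secr_add_vcov <- function(fit) {
  prep <- fit$prep
  full_nll <- function(th) {
    out <- tryCatch(
      -secr_eval(prep, split_theta(th, prep), concentrate = FALSE)$loglik,
      error = function(e) NA_real_)
    if (!is.finite(out)) 1e10 else out
  }
  H <- num_hessian(full_nll, fit$theta)
  vc <- tryCatch(solve(H), error = function(e) NULL)
  ok <- !is.null(vc) && all(is.finite(vc)) && all(diag(vc) >= 0)
  fit$vcov <- if (ok) vc else pseudo_inverse(H)
  fit$converged <- fit$converged && ok
  fit
}

secr_start <- function(prep, start = NULL) {
  theta <- stats::setNames(rep(0, length(prep$par_names)), prep$par_names)
  # movement-scale start from spread of each animal's detection locations
  xy <- prep$layout[prep$k_all, c("x", "y")]
  dev2 <- unlist(lapply(split(xy, prep$aidx), function(p) {
    if (nrow(p) < 2L) return(NULL)
    (p$x - mean(p$x))^2 + (p$y - mean(p$y))^2
  }))
  sigma0 <- if (length(dev2) && sum(dev2) > 0) sqrt(mean(dev2)) * sqrt(2)
    else attr(prep$mask, "spacing") %||% 3.5
  p0 <- min(0.5, max(0.02, nrow(prep$capture) / (prep$n * prep$S * 2)))
  theta[["g0"]] <- stats::qlogis(p0)
  theta[["sigma"]] <- log(sigma0)
  if (prep$g0i$has_h2) theta[["g0.h2"]] <- 0.5
  if (prep$sgi$has_h2) theta[["sigma.h2"]] <- 0.5
  theta[["D"]] <- log(max(prep$n, 1))   # placeholder; concentrated anyway
  if (!is.null(start)) {
    bad <- setdiff(names(start), names(theta))
    if (length(bad)) stop("unknown start parameter(s): ",
                          paste(bad, collapse = ", "))
    theta[names(start)] <- start
  }
  theta
}

num_hessian <- function(fn, theta, rel_step = 1e-4) {
  p <- length(theta)
  h <- rel_step * pmax(abs(theta), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(theta)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- rep(0, p); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (fn(theta + ei) - 2 * f0 + fn(theta - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(theta + ei + ej) - fn(theta + ei - ej) -
             fn(theta - ei + ej) + fn(theta - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  dimnames(H) <- list(names(theta), names(theta))
  H
}

pseudo_inverse <- function(H, tol = 1e-8) {
  e <- eigen(H, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1)
  inv <- rep(0, length(e$values))
  inv[pos] <- 1 / e$values[pos]
  out <- e$vectors %*% diag(inv, length(inv)) %*% t(e$vectors)
  dimnames(out) <- dimnames(H)
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k + 1) / (n - k - 1)` with `n` the number of
#' detected individuals (the standard SECR sample-size convention).
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Effective sample size (detected individuals).
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1 (n = ", n,
                       ", k = ", k, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc model-selection table
#'
#' Ranks fits on the same data by AICc, with Akaike weights
#' `w_i = exp(-0.5 dAICc_i) / sum_j exp(-0.5 dAICc_j)` and a tied-support
#' flag for models within 2 AICc units of the reference (constant) model,
#' mirroring the convention of flagging covariate models whose AICc differs
#' from the constant model's by less than 2.
#'
#' @param fits Named list of `secr_fit` objects on identical data.
#' @param reference Name of the reference model for the tied flag (default
#'   `"constant"` when present).
#' @return `data.frame` with columns `model`, `k`, `loglik`, `aicc`,
#'   `dAICc`, `weight`, `tied_with_reference`, ordered by AICc.
#' @export
model_table <- function(fits, reference = "constant") {
  stopifnot(length(fits) >= 1L)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  sig <- vapply(fits, function(f)
    paste(f$n, nrow(f$prep$capture), sum(f$prep$capture$occasion),
          length(unique(f$prep$capture$detector_id))), character(1))
  if (length(unique(sig)) != 1L)
    stop("fits are not all on the same capture data")
  aic <- vapply(fits, function(f) f$aicc, numeric(1))
  d <- aic - min(aic)
  w <- exp(-d / 2); w <- w / sum(w)
  out <- data.frame(model = names(fits),
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    aicc = aic, dAICc = d, weight = w,
                    stringsAsFactors = FALSE)
  out$tied_with_reference <- if (reference %in% out$model) {
    ref_aicc <- out$aicc[out$model == reference]
    abs(out$aicc - ref_aicc) < 2 & out$model != reference
  } else NA
  out <- out[order(out$aicc), ]
  rownames(out) <- NULL
  out
}

#' Density estimate versus mask buffer width
#'
#' The effective-sampling-area diagnostic: for each buffer width a mask of
#' that extent is built around the detectors and the constant-density MLE
#' conditional on fixed detection parameters, `D = n / esa`, is reported,
#' where `esa = a * sum_m pdot(x_m)` (km^2). The density estimate
#' stabilizes once the buffer is wide enough that animals centered beyond
#' it are effectively undetectable.
#'
#' @param capture Capture data.
#' @param layout Detector layout.
#' @param g0,sigma Fixed (provisional or fitted) detection parameters.
#' @param buffer_widths Numeric vector of buffer widths (km).
#' @param spacing Mask spacing (km); every buffer must be >= spacing.
#' @return `data.frame` of class `esa_curve`: `buffer`, `esa_km2`,
#'   `density` (bears per 1000 km^2), `rel_change` versus previous row.
#' @seealso [suggest_buffer()]
#' @export
esa_curve <- function(capture, layout, g0, sigma, buffer_widths,
                      spacing = 3.5) {
  if (any(buffer_widths < spacing))
    stop("buffer widths must be at least the mask spacing (", spacing, " km)")
  buffer_widths <- sort(buffer_widths)
  n <- length(unique(capture$animal_id))
  xr <- range(layout$x); yr <- range(layout$y)
  inv2s2 <- 1 / (2 * sigma^2)
  res <- lapply(buffer_widths, function(b) {
    xs <- seq(xr[1L] - b + spacing / 2, xr[2L] + b, by = spacing)
    ys <- seq(yr[1L] - b + spacing / 2, yr[2L] + b, by = spacing)
    pts <- expand.grid(x = xs, y = ys)
    d2 <- dist2_cpp(layout$x, layout$y, pts$x, pts$y)
    kern <- secr_kernel_cpp(d2, rep(g0, nrow(layout)),
                            rep(inv2s2, nrow(layout)),
                            as.integer(layout$occasion),
                            layout_occasions(layout), integer(0))
    esa <- spacing^2 * sum(1 - exp(colSums(kern$logQ)))
    c(esa_km2 = esa, density = 1000 * n / esa)
  })
  out <- data.frame(buffer = buffer_widths, do.call(rbind, res))
  out$rel_change <- c(NA, abs(diff(out$density)) / out$density[-nrow(out)])
  class(out) <- c("esa_curve", "data.frame")
  out
}

#' Choose a mask buffer from an esa curve
#'
#' Smallest buffer at which the density estimate changes by less than `tol`
#' (default 1 percent) relative to the previous, narrower buffer.
#'
#' @param curve An [esa_curve()] result.
#' @param tol Relative-change threshold.
#' @return Buffer width (km).
#' @export
suggest_buffer <- function(curve, tol = 0.01) {
  ok <- which(curve$rel_change < tol)
  if (!length(ok)) {
    warning("density estimate not yet stable at the widest buffer; ",
            "returning the widest")
    return(curve$buffer[nrow(curve)])
  }
  curve$buffer[ok[1L]]
}

#' @export
print.secr_fit <- function(x, ...) {
  cat("SECR fit:", x$n, "individuals,", x$counts[["detections"]],
      "detections;", x$k, "parameters\n")
  cat("  logLik", format(x$loglik, digits = 8), " AICc",
      format(x$aicc, digits = 8),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  print(predict(x), digits = 4)
  invisible(x)
}

#' @export
coef.secr_fit <- function(object, ...) object$theta

#' @export
vcov.secr_fit <- function(object, ...) object$vcov

#' @export
logLik.secr_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Back-transformed SECR parameter estimates
#'
#' Real-scale estimates of `g0`, `sigma`, the mixing proportion (if any)
#' and density at average habitat, with delta-method SEs and asymmetric
#' 95\% confidence intervals computed on the link scale (logit for
#' probabilities, log for positive parameters).
#'
#' @param object A [fit_secr()] fit.
#' @param ... Unused.
#' @return `data.frame` with `parameter`, `estimate`, `se`, `lcl`, `ucl`.
#' @export
predict.secr_fit <- function(object, ...) {
  th <- object$theta
  se <- sqrt(pmax(diag(object$vcov), 0))
  z <- stats::qnorm(0.975)
  rows <- list()
  add <- function(name, est, s, l, u)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, estimate = est, se = s, lcl = l, ucl = u,
      stringsAsFactors = FALSE)
  lgt <- function(name, label) {
    p <- stats::plogis(th[[name]]); sl <- se[[name]]
    add(label, p, p * (1 - p) * sl,
        stats::plogis(th[[name]] - z * sl), stats::plogis(th[[name]] + z * sl))
  }
  pos <- function(name, label, scale = 1) {
    v <- exp(th[[name]]) * scale; sl <- se[[name]]
    add(label, v, v * sl, v * exp(-z * sl), v * exp(z * sl))
  }
  lgt("g0", "g0")
  if (object$sigma_identifiable) pos("sigma", "sigma_km")
  if ("pmix" %in% names(th)) lgt("pmix", "pmix")
  pos("D", "D_per_1000km2")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
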
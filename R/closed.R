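# Huggins-style closed-population models on session-pooled histories.
# Abundance by Horvitz-Thompson summation over each animal's probability of
# being detected at least once.

#' Collapse spatial captures to per-session detection histories
#'
#' Pools detections over hair-snag sites within each session: the closed
#' models use only whether each animal was detected anywhere on each
#' occasion.
#'
#' @param capture Capture data (`animal_id`, `occasion`, `detector_id`,
#'   optional `sex`).
#' @param n_occasions Number of occasions (default from the data attribute).
#' @return Object of class `closed_histories`: binary matrix (animals x
#'   occasions) with animal ids as rownames and a `sex` attribute.
#' @export
collapse_to_sessions <- function(capture, n_occasions = NULL) {
  S <- n_occasions %||% attr(capture, "n_occasions") %||% max(capture$occasion)
  animals <- sort(unique(as.character(capture$animal_id)))
  H <- matrix(0L, length(animals), S,
              dimnames = list(animals, paste0("occ", seq_len(S))))
  H[cbind(match(as.character(capture$animal_id), animals),
          capture$occasion)] <- 1L
  sex <- if ("sex" %in% names(capture))
    vapply(split(as.character(capture$sex), as.character(capture$animal_id)),
           function(s) s[1L], character(1))[animals]
  else NULL
  structure(H, sex = sex, class = c("closed_histories", "matrix"))
}

#' Session-pooled sampling efficiency
#'
#' Share of detected animals seen in more than one session (the "p > 1"
#' efficiency statistic of survey summary tables).
#'
#' @param histories A [collapse_to_sessions()] matrix.
#' @return Proportion in \[0, 1\].
#' @export
session_efficiency <- function(histories) {
  mean(rowSums(histories) > 1L)
}

#' Fit a Huggins closed-population model
#'
#' Conditional-likelihood estimation of detection probability under `M0`
#' (constant), `Mt` (occasion-specific), `Mb` (behavioural response:
#' first-capture vs recapture probability) or `Mh2` (2-class finite
#' mixture). Abundance is the Horvitz-Thompson sum `N = sum_i 1/pstar_i`
#' over each animal's probability of at least one detection, with variance
#' combining the HT binomial component and delta-method parameter
#' uncertainty, and a log-normal interval on `N - n`.
#'
#' @param histories A [collapse_to_sessions()] matrix (or any binary
#'   animals x occasions matrix with at least one detection per row).
#' @param model One of `"M0"`, `"Mt"`, `"Mb"`, `"Mh2"`.
#' @return Object of class `closed_fit`: `theta` (link scale), `p`
#'   (real-scale detection estimates), `pstar` (per animal), `N`, `se`,
#'   `lcl`, `ucl`, `loglik`, `aicc`, `vcov`, `converged`.
#' @export
fit_closed <- function(histories, model = c("M0", "Mt", "Mb", "Mh2")) {
  model <- match.arg(model)
  H <- unclass(histories)
  if (any(rowSums(H) < 1L)) stop("every included animal needs >= 1 detection")
  n <- nrow(H); S <- ncol(H)
  if (S < 2L) stop("need >= 2 occasions")
  if (model == "Mh2" && all(rowSums(H) == S))
    warning("all animals detected every occasion: mixture at boundary")
  first <- apply(H, 1L, function(h) which(h == 1L)[1L])

  loglik_fun <- switch(model,
    M0 = function(th) {
      p <- stats::plogis(th[1L])
      pstar <- 1 - (1 - p)^S
      sum(H) * log(p) + (n * S - sum(H)) * log(1 - p) - n * log(pstar)
    },
    Mt = function(th) {
      p <- stats::plogis(th)
      pstar <- 1 - prod(1 - p)
      sum(t(H) * log(p) + t(1 - H) * log(1 - p)) - n * log(pstar)
    },
    Mb = function(th) {
      p <- stats::plogis(th[1L]); cc <- stats::plogis(th[2L])
      ll <- 0
      for (i in seq_len(n)) {
        f <- first[i]
        ll <- ll + (f - 1L) * log(1 - p) + log(p)
        if (f < S) {
          h <- H[i, (f + 1L):S]
          ll <- ll + sum(h * log(cc) + (1 - h) * log(1 - cc))
        }
      }
      ll - n * log(1 - (1 - p)^S)
    },
    Mh2 = function(th) {
      p <- stats::plogis(th[1:2]); pi1 <- stats::plogis(th[3L])
      w <- c(pi1, 1 - pi1)
      k <- rowSums(H)
      pr <- w[1L] * p[1L]^k * (1 - p[1L])^(S - k) +
        w[2L] * p[2L]^k * (1 - p[2L])^(S - k)
      pstar <- sum(w * (1 - (1 - p)^S))
      sum(log(pr)) - n * log(pstar)
    })
  npar <- switch(model, M0 = 1L, Mt = S, Mb = 2L, Mh2 = 3L)
  th0 <- rep(stats::qlogis(max(0.05, min(0.95, mean(H)))), npar)
  if (model == "Mh2") th0 <- th0 + c(-0.5, 0.5, 0)
  nll <- function(th) {
    v <- tryCatch(-loglik_fun(th), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(th0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  th <- opt$par
  ll <- -opt$value
  pstar_fun <- function(th) {
    switch(model,
      M0 = rep(1 - (1 - stats::plogis(th[1L]))^S, n),
      Mt = rep(1 - prod(1 - stats::plogis(th)), n),
      Mb = rep(1 - (1 - stats::plogis(th[1L]))^S, n),
      Mh2 = {
        p <- stats::plogis(th[1:2]); pi1 <- stats::plogis(th[3L])
        rep(sum(c(pi1, 1 - pi1) * (1 - (1 - p)^S)), n)
      })
  }
  pstar <- pstar_fun(th)
  N <- sum(1 / pstar)
  H2 <- num_hessian(nll, th)
  V <- tryCatch(solve(H2), error = function(e) pseudo_inverse(H2))
  grad <- vapply(seq_along(th), function(i) {
    h <- 1e-5 * max(abs(th[i]), 1)
    e <- rep(0, length(th)); e[i] <- h
    (sum(1 / pstar_fun(th + e)) - sum(1 / pstar_fun(th - e))) / (2 * h)
  }, numeric(1))
  varN <- sum((1 - pstar) / pstar^2) + drop(t(grad) %*% V %*% grad)
  se <- sqrt(max(varN, 0))
  f0 <- max(N - n, 0)
  ci <- if (f0 > 0 && se > 0) {
    C <- exp(stats::qnorm(0.975) * sqrt(log(1 + (se / f0)^2)))
    c(n + f0 / C, n + f0 * C)
  } else c(N, N)
  p_real <- switch(model,
    M0 = c(p = stats::plogis(th[1L])),
    Mt = stats::setNames(stats::plogis(th), paste0("p", seq_len(S))),
    Mb = c(p = stats::plogis(th[1L]), c = stats::plogis(th[2L])),
    Mh2 = c(p1 = stats::plogis(th[1L]), p2 = stats::plogis(th[2L]),
            pmix = stats::plogis(th[3L])))
  structure(list(model = model, theta = th, p = p_real, pstar = pstar,
                 n = n, S = S, N = N, se = se, lcl = ci[1L], ucl = ci[2L],
                 loglik = ll, k = npar,
                 aicc = if (n > npar + 1L) aicc(ll, npar, n) else NA_real_,
                 vcov = V, converged = opt$convergence == 0L),
            class = "closed_fit")
}

#' @export
print.closed_fit <- function(x, ...) {
  cat("Huggins closed model", x$model, ": n =", x$n, ", N =",
      format(x$N, digits = 5), " (", format(x$lcl, digits = 5), "-",
      format(x$ucl, digits = 5), ")\n")
  print(round(x$p, 4))
  invisible(x)
}
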
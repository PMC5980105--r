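# Half-normal detection function and per-animal capture-history probability.

#' Half-normal detection probability
#'
#' Probability that an animal centered `distance` km from a hair-snag site
#' is detected there on one occasion: `g0 * exp(-d^2 / (2 sigma^2))`.
#'
#' @param distance Distance from the home-range center (km), >= 0.
#' @param g0 Detection probability at distance zero, in \[0, 1\].
#' @param sigma Spatial scale of movement (km), > 0.
#' @return Detection probability, monotone non-increasing in distance.
#' @examples
#' detection_prob(0, 0.2, 5)                    # g0
#' detection_prob(5 * sqrt(2 * log(2)), 0.2, 5) # half height
#' @export
detection_prob <- function(distance, g0, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(g0 < 0 | g0 > 1)) stop("g0 must be in [0, 1]")
  if (any(distance < 0)) stop("distance must be >= 0")
  g0 * exp(-distance^2 / (2 * sigma^2))
}

#' Overall detection probability of an animal at a given center
#'
#' Probability of at least one detection anywhere over the whole survey for
#' an animal centered at `(x, y)`:
#' `1 - prod over occasions and detectors of (1 - p)`.
#'
#' @param x,y Center coordinates (km); vectorized.
#' @param layout A [place_detectors()] layout (all occasions).
#' @param g0,sigma Half-normal detection parameters.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
pdot <- function(x, y, layout, g0, sigma) {
  d2 <- outer(layout$x, x, "-")^2 + outer(layout$y, y, "-")^2
  lq <- colSums(log1p(-pmin(g0 * exp(-d2 / (2 * sigma^2)), 1 - 1e-12)))
  1 - exp(lq)
}

#' Probability of one animal's capture history given its center
#'
#' Straight product-form likelihood of a binary detection history across
#' all detector-occasions, with optional behavioural responses and a
#' 2-class finite mixture. `b` adds a logit-scale offset to `g0` for all
#' occasions after the animal's first detection; `bk` adds an offset at a
#' given site from the occasion after the animal's first detection at that
#' site. With two classes, returns the mixture
#' `sum_u pi_u * P(history | class u)`.
#'
#' @param history `data.frame` with columns `occasion`, `detector_id`
#'   listing the animal's detections (zero rows = all-zero history).
#' @param center `c(x, y)` of the activity center (km).
#' @param layout A [place_detectors()] layout.
#' @param g0,sigma Scalars, or length-2 vectors for a 2-class mixture.
#' @param b,bk Logit-scale behavioural-response offsets on `g0` (default 0).
#' @param pmix Class-1 weight in (0, 1) when `g0`/`sigma` have length 2.
#' @return The history probability.
#' @export
capture_history_prob <- function(history, center, layout, g0, sigma,
                                 b = 0, bk = 0, pmix = NULL) {
  ncls <- max(length(g0), length(sigma))
  g0 <- rep_len(g0, ncls); sigma <- rep_len(sigma, ncls)
  if (ncls == 2L && (is.null(pmix) || pmix <= 0 || pmix >= 1))
    stop("2-class mixture requires pmix in (0, 1)")
  w <- if (ncls == 2L) c(pmix, 1 - pmix) else 1
  if (nrow(history) > 0) {
    key <- paste(history$occasion, history$detector_id)
    lkey <- paste(layout$occasion, layout$detector_id)
    if (!all(key %in% lkey))
      stop("history references unknown detector-occasion: ",
           paste(setdiff(key, lkey), collapse = ", "))
  }
  f_animal <- if (nrow(history)) min(history$occasion) else Inf
  f_site <- if (nrow(history))
    tapply(history$occasion, history$detector_id, min) else NULL
  total <- 0
  for (u in seq_len(ncls)) {
    lp <- 0
    for (r in seq_len(nrow(layout))) {
      s <- layout$occasion[r]; id <- layout$detector_id[r]
      eta_off <- 0
      if (s > f_animal) eta_off <- eta_off + b
      if (!is.null(f_site) && id %in% names(f_site) && s > f_site[[id]])
        eta_off <- eta_off + bk
      gg <- stats::plogis(stats::qlogis(min(max(g0[u], 1e-12), 1 - 1e-12)) +
                            eta_off)
      d <- sqrt((layout$x[r] - center[1L])^2 + (layout$y[r] - center[2L])^2)
      p <- detection_prob(d, gg, sigma[u])
      detected <- nrow(history) > 0 &&
        any(history$occasion == s & history$detector_id == id)
      lp <- lp + if (detected) log(max(p, 1e-300)) else log1p(-min(p, 1 - 1e-12))
    }
    total <- total + w[u] * exp(lp)
  }
  total
}
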
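# Independent brute-force implementations used as oracles. These share no
# code with the package internals: plain loops, direct formulas.

# Full SECR log-likelihood by direct summation over mask points.
# g0v / sigv: detection parameters per layout row (trap-occasion), so
# trend / site-covariate models can be expressed by the caller.
# D: density per mask point, bears per 1000 km^2.
brute_secr_loglik <- function(capture, layout, mask, g0v, sigv, D) {
  M <- nrow(mask)
  a <- attr(mask, "cell_area") / 1000
  animals <- sort(unique(as.character(capture$animal_id)))
  n <- length(animals)
  lkey <- paste(layout$occasion, layout$detector_id)
  sum_pdot <- 0
  Ls <- rep(0, n)
  for (m in seq_len(M)) {
    pr_no <- 1
    prh <- rep(1, n)
    for (r in seq_len(nrow(layout))) {
      d <- sqrt((layout$x[r] - mask$x[m])^2 + (layout$y[r] - mask$y[m])^2)
      p <- g0v[r] * exp(-d^2 / (2 * sigv[r]^2))
      pr_no <- pr_no * (1 - p)
      for (i in seq_len(n)) {
        det <- any(capture$animal_id == animals[i] &
                     paste(capture$occasion, capture$detector_id) == lkey[r])
        prh[i] <- prh[i] * if (det) p else (1 - p)
      }
    }
    sum_pdot <- sum_pdot + D[m] * (1 - pr_no)
    Ls <- Ls + D[m] * prh
  }
  sum(log(a * Ls)) - a * sum_pdot - lgamma(n + 1)
}

# Random tiny SECR instance for oracle comparisons.
random_tiny_fixture <- function(seed) {
  set.seed(seed)
  S <- sample(1:3, 1)
  ndet <- sample(2:4, 1)
  layout <- data.frame(
    occasion = rep(seq_len(S), each = ndet),
    detector_id = rep(paste0("d", seq_len(ndet)), S),
    x = round(stats::runif(S * ndet, 0, 8), 2),
    y = round(stats::runif(S * ndet, 0, 8), 2))
  attr(layout, "n_occasions") <- S
  mg <- expand.grid(x = seq(-2, 10, by = 4), y = seq(-2, 10, by = 4))
  mask <- data.frame(x = mg$x, y = mg$y)
  attr(mask, "cell_area") <- 16
  attr(mask, "spacing") <- 4
  n_an <- sample(1:3, 1)
  rows <- sort(sample(nrow(layout), min(nrow(layout), n_an + 2)))
  capture <- data.frame(
    animal_id = paste0("A", sample(seq_len(n_an), length(rows), replace = TRUE)),
    occasion = layout$occasion[rows],
    detector_id = layout$detector_id[rows])
  capture <- capture[!duplicated(capture), ]
  list(layout = layout, mask = mask, capture = capture,
       g0 = stats::runif(1, 0.1, 0.6), sigma = stats::runif(1, 1.5, 4),
       D = stats::runif(1, 10, 60))
}

# Conditional log-likelihood of the M0 closed model, for grid-search oracle.
brute_m0_loglik <- function(H, p) {
  S <- ncol(H)
  k <- rowSums(H)
  sum(k * log(p) + (S - k) * log(1 - p)) - nrow(H) * log(1 - (1 - p)^S)
}
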
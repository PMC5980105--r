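test_that("the likelihood equals brute-force mask summation on tiny instances", {
  for (seed in 1:12) {
    fx <- random_tiny_fixture(seed)
    theta <- c(qlogis(fx$g0), log(fx$sigma), log(fx$D))
    ll <- secr_loglik(fx$capture, fx$layout, fx$mask, theta)
    bl <- brute_secr_loglik(fx$capture, fx$layout, fx$mask,
                            g0v = rep(fx$g0, nrow(fx$layout)),
                            sigv = rep(fx$sigma, nrow(fx$layout)),
                            D = rep(fx$D, nrow(fx$mask)))
    expect_equal(ll, bl, tolerance = 1e-10)
  }
})

test_that("trend, covariate and density-surface terms match brute force", {
  fx <- random_tiny_fixture(101)
  S <- attr(fx$layout, "n_occasions")
  set.seed(101)
  fx$layout$TRI_site <- rnorm(nrow(fx$layout))
  fx$mask$RSF <- runif(nrow(fx$mask), 1, 9)
  # g0 ~ trend + TRI_site, density ~ RSF, reproducing the internal
  # standardization explicitly on the oracle side
  b <- c(g0 = -1, trend = 0.3, tri = 0.4, sigma = log(2.5),
         D = log(30), D.RSF = 0.5)
  ztri <- (fx$layout$TRI_site - mean(fx$layout$TRI_site)) /
    sd(fx$layout$TRI_site)
  g0v <- plogis(b["g0"] + b["trend"] * (fx$layout$occasion - (S + 1) / 2) +
                  b["tri"] * ztri)
  zrsf <- (fx$mask$RSF - mean(fx$mask$RSF)) / sd(fx$mask$RSF)
  Dv <- exp(b["D"] + b["D.RSF"] * zrsf)
  ll <- secr_loglik(fx$capture, fx$layout, fx$mask,
                    theta = c(b["g0"], b["trend"], b["tri"], b["sigma"],
                              b["D"], b["D.RSF"]),
                    model = list(g0 = ~trend + TRI_site, sigma = ~1),
                    density = ~RSF)
  bl <- brute_secr_loglik(fx$capture, fx$layout, fx$mask, g0v,
                          rep(2.5, nrow(fx$layout)), Dv)
  expect_equal(ll, bl, tolerance = 1e-10)
})

test_that("the likelihood is invariant to rigid motions of all coordinates", {
  fx <- tiny_fixture()
  theta <- c(qlogis(0.3), log(2.5), log(40))
  ll <- secr_loglik(fx$capture, fx$layout, fx$mask, theta)
  # translation
  lay2 <- fx$layout; msk2 <- fx$mask
  lay2$x <- lay2$x + 57; lay2$y <- lay2$y - 13
  msk2$x <- msk2$x + 57; msk2$y <- msk2$y - 13
  attr(msk2, "cell_area") <- 9
  expect_equal(secr_loglik(fx$capture, lay2, msk2, theta), ll,
               tolerance = 1e-8)
  # rotation by 30 degrees
  th <- pi / 6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(d) {
    xy <- as.matrix(d[, c("x", "y")]) %*% R
    d$x <- xy[, 1]; d$y <- xy[, 2]; d
  }
  lay3 <- rot(fx$layout); msk3 <- rot(fx$mask)
  attr(msk3, "cell_area") <- 9
  expect_equal(secr_loglik(fx$capture, lay3, msk3, theta), ll,
               tolerance = 1e-8)
})

test_that("mask refinement barely changes the likelihood when sigma >> spacing", {
  set.seed(3)
  lay <- data.frame(occasion = rep(1:2, each = 4),
                    detector_id = rep(paste0("d", 1:4), 2),
                    x = rep(c(4, 8, 4, 8), 2), y = rep(c(4, 4, 8, 8), 2))
  attr(lay, "n_occasions") <- 2L
  cap <- data.frame(animal_id = c("A1", "A1", "A2"), occasion = c(1L, 2L, 2L),
                    detector_id = c("d1", "d4", "d2"))
  mk <- function(sp) {
    g <- expand.grid(x = seq(-6 + sp / 2, 18, by = sp),
                     y = seq(-6 + sp / 2, 18, by = sp))
    m <- data.frame(x = g$x, y = g$y)
    attr(m, "cell_area") <- sp^2
    m
  }
  theta <- c(qlogis(0.3), log(8), log(40))   # sigma 8 km >> spacing
  ll1 <- secr_loglik(cap, lay, mk(2), theta)
  ll2 <- secr_loglik(cap, lay, mk(1), theta)
  expect_lt(abs(ll1 - ll2), 0.1)
})

test_that("no data and negligible detection give log-likelihood zero", {
  fx <- tiny_fixture()
  empty <- fx$capture[0, ]
  ll <- secr_loglik(empty, fx$layout, fx$mask,
                    theta = c(-40, log(2.5), log(40)))
  expect_equal(ll, 0, tolerance = 1e-8)
})

test_that("adding parameters never decreases the maximized log-likelihood", {
  st <- small_study(seed = 21, n_cells = 4, buffer = 10)
  lay <- st$layout; msk <- st$mask; cap <- st$capture
  f0 <- fit_secr(cap, lay, msk, hessian = FALSE)
  f1 <- fit_secr(cap, lay, msk, model = list(g0 = ~trend, sigma = ~1),
                 hessian = FALSE)
  f2 <- fit_secr(cap, lay, msk, model = list(g0 = ~trend + TRI_site,
                                             sigma = ~1), hessian = FALSE)
  expect_gte(f1$loglik, f0$loglik - 1e-6)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("degenerate mixtures reproduce the one-class likelihood", {
  fx <- tiny_fixture()
  theta1 <- c(qlogis(0.3), log(2.5), log(40))
  ll1 <- secr_loglik(fx$capture, fx$layout, fx$mask, theta1)
  h2 <- list(g0 = ~h2, sigma = ~1)
  # equal class parameters
  expect_equal(secr_loglik(fx$capture, fx$layout, fx$mask,
                           c(qlogis(0.3), 0, log(2.5), 0.7, log(40)),
                           model = h2), ll1, tolerance = 1e-10)
  # pmix -> 1 (class 2 weight vanishes)
  expect_equal(secr_loglik(fx$capture, fx$layout, fx$mask,
                           c(qlogis(0.3), 2, log(2.5), 30, log(40)),
                           model = h2), ll1, tolerance = 1e-8)
})

test_that("behavioural-response terms change the likelihood as specified", {
  fx <- tiny_fixture()
  base <- secr_loglik(fx$capture, fx$layout, fx$mask,
                      c(qlogis(0.3), log(2.5), log(40)))
  bmod <- list(g0 = ~b, sigma = ~1)
  expect_equal(secr_loglik(fx$capture, fx$layout, fx$mask,
                           c(qlogis(0.3), 0, log(2.5), log(40)), model = bmod),
               base, tolerance = 1e-10)
  lb <- secr_loglik(fx$capture, fx$layout, fx$mask,
                    c(qlogis(0.3), 1.2, log(2.5), log(40)), model = bmod)
  expect_false(isTRUE(all.equal(lb, base)))
  # oracle for b: animal A1 detected first on occasion 1, so occasion-2
  # detector rows get the boosted g0 in its history; Lambda stays naive
  g0n <- 0.3; g0e <- plogis(qlogis(0.3) + 1.2)
  a <- 9 / 1000; D <- 40
  lkey <- paste(fx$layout$occasion, fx$layout$detector_id)
  Ls <- c(0, 0); sum_pdot <- 0
  for (m in seq_len(nrow(fx$mask))) {
    prh <- c(1, 1); pr_no <- 1
    for (r in seq_len(nrow(fx$layout))) {
      d <- sqrt((fx$layout$x[r] - fx$mask$x[m])^2 +
                  (fx$layout$y[r] - fx$mask$y[m])^2)
      ker <- exp(-d^2 / (2 * 2.5^2))
      pr_no <- pr_no * (1 - g0n * ker)
      # A1: first detection occasion 1 -> occasion 2 experienced
      p1 <- (if (fx$layout$occasion[r] > 1) g0e else g0n) * ker
      det1 <- any(fx$capture$animal_id == "A1" &
                    paste(fx$capture$occasion, fx$capture$detector_id) ==
                    lkey[r])
      prh[1] <- prh[1] * if (det1) p1 else (1 - p1)
      # A2: first detection occasion 1 -> occasion 2 experienced
      p2 <- (if (fx$layout$occasion[r] > 1) g0e else g0n) * ker
      det2 <- any(fx$capture$animal_id == "A2" &
                    paste(fx$capture$occasion, fx$capture$detector_id) ==
                    lkey[r])
      prh[2] <- prh[2] * if (det2) p2 else (1 - p2)
    }
    Ls <- Ls + D * prh
    sum_pdot <- sum_pdot + D * (1 - pr_no)
  }
  oracle <- sum(log(a * Ls)) - a * sum_pdot - lgamma(3)
  expect_equal(lb, oracle, tolerance = 1e-10)
})

test_that("likelihood errors carry useful context", {
  fx <- tiny_fixture()
  bad <- fx$capture
  bad$detector_id[1] <- "zz"
  expect_error(secr_loglik(bad, fx$layout, fx$mask,
                           c(0, 0, 0)), "row 1")
  expect_error(secr_loglik(fx$capture, fx$layout, fx$mask, c(0, 0)),
               "length")
})
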
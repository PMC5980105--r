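uniform_mask <- function(n_side = 10, spacing = 10) {
  g <- expand.grid(x = (seq_len(n_side) - 0.5) * spacing,
                   y = (seq_len(n_side) - 0.5) * spacing)
  m <- data.frame(x = g$x, y = g$y)
  attr(m, "cell_area") <- spacing^2
  attr(m, "spacing") <- spacing
  m
}

test_that("population size follows the Poisson intensity", {
  msk <- uniform_mask(10, 10)            # 10,000 km^2
  pop <- simulate_population(msk, c(intercept = log(10)), seed = 1)
  expect_lt(abs(nrow(pop) - 100), 3 * sqrt(100))
  expect_identical(pop,
                   simulate_population(msk, c(intercept = log(10)), seed = 1))
})

test_that("a positive RSF coefficient shifts centers to high-RSF habitat", {
  msk <- uniform_mask(20, 5)
  set.seed(42)
  msk$RSF <- runif(nrow(msk), 1, 10)
  pop <- simulate_population(msk, c(intercept = log(120), RSF = 0.8), seed = 2)
  expect_gt(nrow(pop), 500)
  rsf_at <- function(p) {
    i <- vapply(seq_len(nrow(p)), function(j)
      which.min((msk$x - p$x[j])^2 + (msk$y - p$y[j])^2), integer(1))
    msk$RSF[i]
  }
  expect_gt(mean(rsf_at(pop)), mean(msk$RSF))
})

test_that("intercept-only intensity gives spatially uniform centers", {
  msk <- uniform_mask(8, 10)
  pvals <- vapply(1:100, function(s) {
    pop <- simulate_population(msk, c(intercept = log(40)), seed = s)
    qx <- cut(pop$x, breaks = seq(0, 80, by = 20))
    qy <- cut(pop$y, breaks = seq(0, 80, by = 20))
    suppressWarnings(stats::chisq.test(table(qx, qy))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("linear-predictor overflow is rejected", {
  msk <- uniform_mask(4, 10)
  msk$RSF <- c(rep(0, 15), 1e4)
  expect_error(simulate_population(msk, c(intercept = 0, RSF = 60), seed = 1),
               "overflow")
})

test_that("detection at distance zero with g0 = 1 is certain, g0 = 0 empty", {
  lay <- data.frame(occasion = 1L, detector_id = "d1", x = 0, y = 0)
  attr(lay, "n_occasions") <- 1L
  cen <- data.frame(animal = "A1", x = 0, y = 0)
  cap <- simulate_detections(cen, lay, g0 = 1, sigma = 3, seed = 1)
  expect_equal(nrow(cap), 1L)
  expect_equal(nrow(simulate_detections(cen, lay, g0 = 0, sigma = 3,
                                        seed = 1)), 0L)
})

test_that("detection counts match the closed-form Bernoulli probability", {
  lay <- data.frame(occasion = 1L, detector_id = "d1", x = 0, y = 0)
  attr(lay, "n_occasions") <- 1L
  cen <- data.frame(animal = paste0("A", 1:100), x = 5, y = 0)
  p <- 0.2 * exp(-0.5)                       # 0.12131
  counts <- vapply(1:30, function(s)
    nrow(simulate_detections(cen, lay, g0 = 0.2, sigma = 5, seed = s)),
    numeric(1))
  sd_bin <- sqrt(100 * p * (1 - p))
  expect_lt(abs(mean(counts) - 100 * p), 3 * sd_bin / sqrt(30))
})

test_that("capture records conserve per-animal detections", {
  st <- small_study(seed = 9)
  cap <- st$capture
  expect_gt(nrow(cap), 0)
  expect_false(anyDuplicated(paste(cap$animal_id, cap$occasion,
                                   cap$detector_id)) > 0)
  counts <- table(cap$animal_id)
  expect_true(all(counts >= 1))
  expect_equal(sum(counts), nrow(cap))
})

test_that("detection distances follow the implied half-normal sampling law", {
  # uniform centers around one detector: detected distances ~ Rayleigh(sigma)
  set.seed(77)
  sigma <- 4
  n <- 180000
  cen <- data.frame(animal = paste0("A", seq_len(n)),
                    x = runif(n, -20, 20), y = runif(n, -20, 20))
  lay <- data.frame(occasion = 1L, detector_id = "d1", x = 0, y = 0)
  attr(lay, "n_occasions") <- 1L
  cap <- simulate_detections(cen, lay, g0 = 0.5, sigma = sigma, seed = 8)
  d <- sqrt(cen$x[match(cap$animal_id, cen$animal)]^2 +
              cen$y[match(cap$animal_id, cen$animal)]^2)
  expect_gt(length(d), 5000)
  ks <- stats::ks.test(d, function(q) 1 - exp(-q^2 / (2 * sigma^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("telemetry scatter is circular bivariate normal", {
  cen <- data.frame(animal = "A1", x = 12, y = -3)
  tel0 <- simulate_telemetry(cen, sigma = 0, n_locations = 20, seed = 1)
  expect_true(all(tel0$x == 12 & tel0$y == -3))
  tel <- simulate_telemetry(cen, sigma = 5, n_locations = 10000, seed = 2)
  expect_lt(abs(mean(tel$x) - 12), 0.05 * 5)
  expect_lt(abs(mean(tel$y) + 3), 0.05 * 5)
  r <- sqrt((tel$x - 12)^2 + (tel$y + 3)^2)
  expect_lt(abs(mean(r < 5) - (1 - exp(-0.5))), 0.02)
})

test_that("the full study generator is seed-deterministic", {
  s1 <- simulate_study(n_cells_x = 4, n_cells_y = 4, buffer = 10, seed = 5,
                       n_collared = 4)
  s2 <- simulate_study(n_cells_x = 4, n_cells_y = 4, buffer = 10, seed = 5,
                       n_collared = 4)
  expect_identical(s1$captures, s2$captures)
  expect_identical(s1$truth$centers, s2$truth$centers)
  expect_identical(s1$telemetry, s2$telemetry)
})
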
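grid40 <- rect_polygon(0, 40, 0, 40)

test_that("residency model handles the all-inside boundary case", {
  set.seed(1)
  cen <- data.frame(animal = paste0("T", 1:6),
                    x = runif(6, 15, 25), y = runif(6, 15, 25))
  tel <- simulate_telemetry(cen, sigma = 2, n_locations = 40, seed = 2)
  expect_warning(rf <- fit_residency(tel, grid40), "boundary")
  expect_true(rf$boundary)
  r <- suppressWarnings(predict_residency(rf, c(5, 15)))
  expect_true(all(r > 0.95))
})

test_that("animals with no inside-grid locations are excluded with warning", {
  set.seed(2)
  cen <- data.frame(animal = paste0("T", 1:5),
                    x = c(runif(4, 10, 30), 200), y = c(runif(4, 10, 30), 200))
  tel <- simulate_telemetry(cen, sigma = 2, n_locations = 30, seed = 3)
  w <- capture_warnings(rf <- fit_residency(tel, grid40))
  expect_match(w, "excluded", all = FALSE)
  expect_equal(nrow(rf$animals), 4)
})

test_that("residency increases with distance from edge and the slope sign
           is recovered reliably", {
  signs <- vapply(1:100, function(s) {
    set.seed(s)
    d <- runif(12, 1, 18)
    cen <- data.frame(animal = paste0("T", 1:12), x = d, y = 20)
    tel <- simulate_telemetry(cen, sigma = 6, n_locations = 25,
                              seed = s + 1000)
    rf <- suppressWarnings(fit_residency(tel, grid40))
    unname(coef(rf$glm)[2]) > 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("the combined estimator reduces to N/A when residency is 1", {
  st <- small_study(seed = 61, n_cells = 5, sigma = 3,
                    betas = c(intercept = log(30)))
  H <- collapse_to_sessions(st$capture)
  cf <- fit_closed(H, "M0")
  grid <- st$design$grid_polygon
  # deep-interior collared animals: residency ~ 1 everywhere
  cen <- data.frame(animal = paste0("T", 1:8),
                    x = runif(8, 14, 21), y = runif(8, 14, 21))
  tel <- simulate_telemetry(cen, sigma = 1, n_locations = 50, seed = 62)
  rf <- suppressWarnings(fit_residency(tel, grid))
  est <- suppressWarnings(
    density_closed_telemetry(cf, rf, st$capture, st$layout, grid))
  A <- polygon_area(grid)
  expect_equal(est$D_per_1000km2, 1000 * cf$N / A, tolerance = 0.02)
  # per-animal and mean-residency variants agree when residency is constant
  est2 <- suppressWarnings(
    density_closed_telemetry(cf, rf, st$capture, st$layout, grid,
                             method = "mean_residency"))
  expect_equal(est$D_per_1000km2, est2$D_per_1000km2, tolerance = 0.02)
})

test_that("halved residency halves the density estimate", {
  st <- small_study(seed = 63, n_cells = 5)
  H <- collapse_to_sessions(st$capture)
  cf <- fit_closed(H, "M0")
  grid <- st$design$grid_polygon
  # construct balanced telemetry: every animal half inside, half outside,
  # across a spread of distances => flat fitted residency of one half
  tab_in <- expand.grid(animal = paste0("T", 1:6), k = 1:10)
  d <- rep(seq(2, 12, by = 2), times = 10)
  tel <- rbind(
    data.frame(animal_id = tab_in$animal, x = d, y = 20),
    data.frame(animal_id = tab_in$animal, x = -5, y = 20))
  rf <- fit_residency(tel, grid)
  expect_equal(unname(coef(rf$glm)[2]), 0, tolerance = 1e-6)
  est <- suppressWarnings(
    density_closed_telemetry(cf, rf, st$capture, st$layout, grid))
  A <- polygon_area(grid)
  expect_equal(est$D_per_1000km2, 0.5 * 1000 * cf$N / A, tolerance = 0.01)
})
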
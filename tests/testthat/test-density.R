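test_that("raster covariates summarize onto the mask correctly", {
  ls <- generate_landscape(c(0, 20, 0, 20), resolution = 1,
                           autocorr_range = 0, seed = 1)
  msk <- data.frame(x = c(2.5, 10.5), y = c(2.5, 10.5))
  # constant raster -> constant mask covariate
  ls$rsf[] <- 7
  v <- summarize_covariates_to_mask(ls, msk, "rsf", radius_km = 1.75)
  expect_equal(as.numeric(v), c(7, 7))
  # radius below resolution -> containing-cell value
  v1 <- summarize_covariates_to_mask(ls, msk, "risk", radius_km = 0.4)
  expect_equal(as.numeric(v1),
               landscape_value(ls, msk$x, msk$y, "risk"))
})

test_that("points outside coverage are filled from the nearest covered point", {
  ls <- generate_landscape(c(0, 20, 0, 20), resolution = 1,
                           autocorr_range = 0, seed = 2)
  msk <- data.frame(x = c(2.5, 6.5, 40.5), y = c(2.5, 2.5, 2.5),
                    inside_province = c(TRUE, TRUE, FALSE))
  v <- summarize_covariates_to_mask(ls, msk, "rsf", radius_km = 0.4)
  expect_equal(v[3], v[2])       # nearest covered mask point
  expect_equal(attr(v, "filled"), c(FALSE, FALSE, TRUE))
  ls$rsf[] <- NA_integer_
  expect_error(summarize_covariates_to_mask(ls, msk, "rsf"), "missing")
})

test_that("prediction from a constant model is flat at exp(b0)", {
  st <- small_study(seed = 41, n_cells = 5)
  fit <- fit_secr(st$capture, st$layout, st$mask)
  surf <- predict_density(fit)
  expect_equal(unique(round(surf$D, 10)),
               round(exp(fit$theta[["D"]]), 10))
  expect_true(all(surf$SE >= 0))
})

test_that("log-link prediction doubles density per log-2 coefficient unit", {
  st <- small_study(seed = 42, n_cells = 5)
  fit <- fit_secr(st$capture, st$layout, st$mask, density = ~RSF)
  # forcing beta_RSF = log 2: density ratio between points 1 SD apart = 2
  fit$theta[["D.RSF"]] <- log(2)
  surf <- suppressWarnings(predict_density(fit))
  z <- (st$mask$RSF - fit$prep$dens$centers["RSF"]) /
    fit$prep$dens$scales["RSF"]
  expect_equal(surf$D / exp(fit$theta[["D"]]), 2^z, tolerance = 1e-10)
})

test_that("region abundance integrates the surface with correct additivity", {
  # uniform density 10 per 1000 km^2 over a 10,000 km^2 region
  g <- expand.grid(x = (1:10 - 0.5) * 10, y = (1:10 - 0.5) * 10)
  msk <- data.frame(x = g$x, y = g$y, inside_grid = TRUE)
  attr(msk, "cell_area") <- 100; attr(msk, "spacing") <- 10
  fit <- structure(list(
    theta = c(D = log(10)), vcov = matrix(0.04, 1, 1, dimnames = list("D", "D")),
    converged = TRUE,
    prep = list(mask = msk,
                dens = list(Xd = matrix(1, 100, 1,
                                        dimnames = list(NULL, "D")),
                            centers = numeric(0), scales = numeric(0),
                            formula = ~1))), class = "secr_fit")
  surf <- predict_density(fit, msk)
  ab <- region_abundance(surf)
  expect_equal(ab$N, 100)
  expect_equal(ab$D_per_1000km2, 10)
  # disjoint halves add to the whole
  left <- surf$x < 50
  ab_l <- region_abundance(surf, region = left)
  ab_r <- region_abundance(surf, region = !left)
  expect_equal(ab_l$N + ab_r$N, ab$N, tolerance = 1e-12)
  expect_error(region_abundance(surf, region = rep(FALSE, 100)), "empty")
})

test_that("nested density models never lose likelihood and rank sensibly", {
  st <- small_study(seed = 43, n_cells = 5,
                    betas = c(intercept = log(30), RSF = 0.5))
  dm <- fit_density_models(st$capture, st$layout, st$mask, hessian = "none")
  ll <- setNames(vapply(dm$fits, function(f) f$loglik, numeric(1)),
                 names(dm$fits))
  expect_gte(ll[["RSF"]], ll[["constant"]] - 1e-6)
  expect_gte(ll[["RSF+Risk"]], ll[["RSF"]] - 1e-6)
  expect_gte(ll[["RSF+Risk"]], ll[["Risk"]] - 1e-6)
  expect_gte(ll[["RSF*Risk"]], ll[["RSF+Risk"]] - 1e-6)
  expect_s3_class(dm$table, "data.frame")
  expect_equal(sum(dm$table$weight), 1, tolerance = 1e-12)
})

test_that("integrated abundance is stable under mask refinement", {
  st <- small_study(seed = 44, n_cells = 4, buffer = 12, spacing = 4)
  fit1 <- fit_secr(st$capture, st$layout, st$mask)
  ab1 <- region_abundance(predict_density(fit1))
  msk2 <- make_mask(st$design, buffer = 12, spacing = 2,
                    landscape = st$landscape)
  fit2 <- fit_secr(st$capture, st$layout, msk2)
  ab2 <- region_abundance(predict_density(fit2))
  expect_lt(abs(ab1$N - ab2$N) / ab2$N, 0.01)
})

test_that("SE of abundance shrinks as data grow", {
  st_small <- small_study(seed = 45, n_cells = 4,
                          betas = c(intercept = log(12)))
  st_big <- small_study(seed = 45, n_cells = 8,
                        betas = c(intercept = log(60)))
  cv <- function(st) {
    fit <- fit_secr(st$capture, st$layout, st$mask)
    ab <- region_abundance(predict_density(fit))
    ab$se / ab$N
  }
  expect_gt(cv(st_small), cv(st_big))
})
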
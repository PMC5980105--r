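test_that("a single fit recovers generating parameters within its CIs", {
  st <- small_study(seed = 31, n_cells = 6, g0 = 0.25, sigma = 4,
                    betas = c(intercept = log(25)))
  fit <- fit_secr(st$capture, st$layout, st$mask)
  expect_true(fit$converged)
  p <- predict(fit)
  expect_true(p$lcl[p$parameter == "g0"] <= 0.25 &&
                0.25 <= p$ucl[p$parameter == "g0"])
  expect_true(p$lcl[p$parameter == "sigma_km"] <= 4 &&
                4 <= p$ucl[p$parameter == "sigma_km"])
  expect_true(p$lcl[p$parameter == "D_per_1000km2"] <= 25 &&
                25 <= p$ucl[p$parameter == "D_per_1000km2"])
  expect_equal(fit$Lambda, fit$n)
})

test_that("the optimizer reaches the same optimum from perturbed starts", {
  st <- small_study(seed = 32, n_cells = 5)
  base <- fit_secr(st$capture, st$layout, st$mask, hessian = FALSE)
  set.seed(1)
  lls <- vapply(1:5, function(i) {
    start <- base$theta[c("g0", "sigma")] + rnorm(2, 0, 0.4)
    fit_secr(st$capture, st$layout, st$mask, start = start,
             hessian = FALSE)$loglik
  }, numeric(1))
  expect_lt(max(lls) - min(lls), 1e-4)
  expect_lt(abs(base$loglik - max(lls)), 1e-4)
})

test_that("fits without spatial recaptures flag sigma as unidentifiable", {
  lay <- data.frame(occasion = rep(1:2, each = 2),
                    detector_id = rep(c("a", "b"), 2),
                    x = rep(c(0, 20), 2), y = 0)
  attr(lay, "n_occasions") <- 2L
  msk <- data.frame(x = seq(-6, 26, by = 4), y = 0)
  attr(msk, "cell_area") <- 16; attr(msk, "spacing") <- 4
  cap <- data.frame(animal_id = c("A1", "A2"), occasion = c(1L, 1L),
                    detector_id = c("a", "b"))
  expect_warning(fit <- fit_secr(cap, lay, msk, hessian = FALSE),
                 "not identifiable")
  expect_false(fit$sigma_identifiable)
  expect_false("sigma_km" %in% predict(fit)$parameter)
})

test_that("AICc follows its closed form and guards its domain", {
  expect_equal(aicc(-100, 3, 30), 200 + 6 + 24 / 26)
  expect_equal(aicc(-100, 0, 30), 200)
  expect_lt(abs(aicc(-100, 3, 1e6) - (200 + 6)), 0.01)
  expect_error(aicc(-100, 5, 6), "n must exceed")
})

fake_fit <- function(name, loglik, k, n = 30) {
  structure(list(theta = numeric(0), loglik = loglik, k = k, n = n,
                 aicc = aicc(loglik, k, n),
                 prep = list(capture = data.frame(
                   animal_id = "A1", occasion = 1L, detector_id = "a"))),
            class = "secr_fit")
}

test_that("model table computes delta-AICc, weights and tie flags", {
  # two models separated by exactly 2 AICc units
  f1 <- fake_fit("constant", -100, 2)
  f2 <- fake_fit("alt", -99, 3)
  d2 <- f2$aicc - f1$aicc
  expect_equal(d2, 2 * 3 + 2 * 3 * 4 / 26 - (2 * 2 + 2 * 2 * 3 / 27) - 2,
               tolerance = 1e-12)
  tab <- model_table(list(constant = f1, alt = f2))
  expect_equal(tab$dAICc[1], 0)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  # the canonical delta = {0, 2} weight split
  f3 <- fake_fit("m2", f1$loglik - 1, 2)      # exactly +2 AICc
  tab2 <- model_table(list(constant = f1, m2 = f3))
  expect_equal(tab2$weight, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-6)
  expect_equal(round(tab2$weight, 3), c(0.731, 0.269))
  # "tied" means strictly less than 2 units from the reference model
  expect_false(tab2$tied_with_reference[2])
  f5 <- fake_fit("m3", f1$loglik - 0.75, 2)   # +1.5 AICc
  expect_true(model_table(
    list(constant = f1, m3 = f5))$tied_with_reference[2])
  # single model
  expect_equal(model_table(list(only = f1))$weight, 1)
  # mixed data refused
  f4 <- fake_fit("other", -90, 2)
  f4$prep$capture <- rbind(f4$prep$capture, f4$prep$capture)
  expect_error(model_table(list(a = f1, b = f4)), "same capture data")
})

test_that("the esa curve stabilizes with buffer width", {
  st <- small_study(seed = 33, n_cells = 5, sigma = 4)
  curve <- esa_curve(st$capture, st$layout, g0 = 0.25, sigma = 4,
                     buffer_widths = seq(4, 28, by = 4), spacing = 4)
  # wide-buffer asymptote: change < 0.5% beyond 4 sigma
  wide <- curve[curve$buffer > 16, ]
  expect_true(all(wide$rel_change < 0.005))
  # step changes eventually decreasing
  rc <- curve$rel_change[-1]
  expect_true(all(diff(rc[(length(rc) - 3):length(rc)]) <= 1e-9))
  # minimal buffer (grid only) overestimates density: closure bias
  expect_gt(curve$density[1], curve$density[nrow(curve)])
  expect_error(esa_curve(st$capture, st$layout, 0.25, 4, buffer_widths = 2,
                         spacing = 4), "spacing")
  expect_equal(suggest_buffer(curve), curve$buffer[which(curve$rel_change
                                                         < 0.01)[1]])
})
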
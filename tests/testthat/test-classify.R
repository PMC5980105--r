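mask4 <- function(rsf, risk) {
  m <- data.frame(x = seq_along(rsf), y = 0, RSF = rsf, Risk = risk,
                  inside_grid = TRUE)
  attr(m, "cell_area") <- 1; attr(m, "spacing") <- 1
  m
}

test_that("median splits assign the four quadrants with ties going low", {
  m <- mask4(c(1, 2, 3, 4), c(4, 3, 2, 1))
  lab <- categorize_mask(m)
  expect_equal(as.character(lab),
               c("low_rsf_high_risk", "low_rsf_high_risk",
                 "safe_harbor", "safe_harbor"))
  expect_equal(attr(lab, "rsf_median"), 2.5)
  # a value equal to the median is "low"
  m2 <- mask4(c(1, 2, 2, 4, 5), c(1, 2, 3, 4, 5))
  lab2 <- categorize_mask(m2)
  expect_equal(as.character(lab2)[3], "low_rsf_low_risk")
})

test_that("labels are invariant to monotone rescaling of the scores", {
  set.seed(4)
  m <- mask4(runif(40, 1, 10), runif(40, 1, 10))
  lab <- categorize_mask(m)
  m2 <- m
  m2$RSF <- exp(m$RSF / 3)
  m2$Risk <- m$Risk^3
  expect_equal(as.character(categorize_mask(m2)), as.character(lab))
})

test_that("degenerate covariates are rejected", {
  expect_error(categorize_mask(mask4(rep(3, 5), 1:5)), "constant")
  expect_error(categorize_mask(mask4(1:5, rep(2, 5))), "no median|constant")
})

test_that("all four categories occur on generated landscapes", {
  ls <- generate_landscape(c(0, 60, 0, 60), resolution = 1,
                           autocorr_range = 8, seed = 9)
  msk <- make_mask(rect_polygon(5, 55, 5, 55), buffer = 0, spacing = 3.5,
                   landscape = ls)
  lab <- categorize_mask(msk)
  expect_true(all(table(lab) > 0))
  # categories partition the in-grid mask
  expect_equal(sum(table(lab)), sum(msk$inside_grid))
})

test_that("category summaries conserve abundance and detect selection", {
  set.seed(6)
  m <- mask4(runif(60, 1, 10), runif(60, 1, 10))
  lab <- categorize_mask(m)
  # uniform density: every category at the overall mean; abundance ~ area
  unif <- data.frame(x = m$x, y = m$y, D = 8, SE = 0, linear_predictor = log(8),
                     inside_grid = TRUE, extrapolated = FALSE)
  attr(unif, "cell_area") <- 1
  class(unif) <- c("density_surface", "data.frame")
  cs <- category_summary(unif, lab)
  expect_equal(cs$mean_density, rep(8, 4))
  expect_equal(cs$relative_abundance, 8 * cs$area_km2 / 1000)
  expect_equal(cs$relative_abundance, cs$expected_equal_density)
  # total abundance conserved across the partition
  expect_equal(sum(cs$relative_abundance), 8 * 60 / 1000, tolerance = 1e-9)
  # density decreasing in Risk: safe harbor outranks attractive sink
  risky <- unif
  risky$D <- 20 * exp(-0.25 * m$Risk + 0.1 * m$RSF)
  cs2 <- category_summary(risky, lab)
  get <- function(cat) cs2$mean_density[cs2$category == cat]
  expect_gt(get("safe_harbor"), get("attractive_sink"))
})

test_that("center counts per category line up with the labels", {
  m <- mask4(c(1, 2, 3, 4), c(4, 3, 2, 1))
  lab <- categorize_mask(m)
  centers <- data.frame(animal = c("a", "b", "c"), mode_index = c(3, 4, 1))
  cc <- category_center_counts(centers, lab)
  expect_equal(cc$count[cc$category == "safe_harbor"], 2L)
  expect_equal(cc$count[cc$category == "low_rsf_high_risk"], 1L)
})
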
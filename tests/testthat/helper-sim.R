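# Small simulation scaffolds shared across test files.

# A compact single-sex study with enough detections to fit reliably.
small_study <- function(seed = 1, n_cells = 6, g0 = 0.25, sigma = 4,
                        betas = c(intercept = log(25)), buffer = 12,
                        spacing = 3.5, cell_size = 7, landscape = TRUE) {
  des <- study_design(n_cells, n_cells, cell_size = cell_size,
                      n_occasions = 4)
  ls <- if (landscape) {
    ext <- c(-buffer - 2, n_cells * cell_size + buffer + 2,
             -buffer - 2, n_cells * cell_size + buffer + 2)
    generate_landscape(ext, resolution = 1, autocorr_range = 8, seed = seed)
  } else NULL
  lay <- place_detectors(des, ls, seed = seed + 1)
  msk <- make_mask(des, buffer = buffer, spacing = spacing, landscape = ls)
  pop <- simulate_population(msk, betas, seed = seed + 2, sex = "F")
  cap <- simulate_detections(pop, lay, g0 = g0, sigma = sigma,
                             seed = seed + 3)
  list(design = des, landscape = ls, layout = lay, mask = msk,
       pop = pop, capture = cap)
}

# Deterministic 2-detector / 2-occasion fixture used in several files.
tiny_fixture <- function() {
  layout <- data.frame(occasion = rep(1:2, each = 2),
                       detector_id = rep(c("a", "b"), 2),
                       x = rep(c(0, 4), 2), y = rep(c(0, 1), 2))
  attr(layout, "n_occasions") <- 2L
  mask <- data.frame(x = rep(c(-2, 1, 4), 3), y = rep(c(-2, 1, 4), each = 3))
  attr(mask, "cell_area") <- 9
  attr(mask, "spacing") <- 3
  capture <- data.frame(animal_id = c("A1", "A1", "A2"),
                        occasion = c(1L, 2L, 1L),
                        detector_id = c("a", "b", "b"))
  list(layout = layout, mask = mask, capture = capture)
}
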
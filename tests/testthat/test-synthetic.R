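test_that("parameter validation rejects degenerate geometry and bad fractions", {
  expect_error(synth_params(nucleus_radius_range = c(0, 0)),
               class = "mitoloc_param_error")
  expect_error(synth_params(misloc_fraction = 1.2),
               class = "mitoloc_param_error")
  expect_error(synth_params(transfected_prob = -0.1),
               class = "mitoloc_param_error")
  expect_error(synth_params(image_height = 32),
               class = "mitoloc_param_error")
  expect_error(synth_params(not_a_field = 1), class = "mitoloc_param_error")
})

test_that("cell geometry satisfies the mask algebra for many generated cells", {
  p <- small_params()
  withr::with_seed(1, {
    for (k in 1:12) {
      tr <- sample_cell_geometry(p, cell_id = k)
      expect_true(all(tr$nucleus_px %in% tr$cell_px))
      expect_length(intersect(tr$mito_px, tr$nucleus_px), 0)
      expect_length(intersect(tr$golgi_px, tr$nucleus_px), 0)
      expect_true(all(tr$mito_px %in% tr$cell_px))
      expect_true(all(tr$golgi_px %in% tr$cell_px))
      # compartments used for the reporter split must be disjoint
      expect_length(intersect(tr$mito_px, tr$golgi_px), 0)
      area <- length(tr$cell_px)
      expect_gte(area, 0.95 * pi * min(p$cell_radius_range)^2)
      expect_lte(area, 1.05 * pi * max(p$cell_radius_range)^2)
    }
  })
})

test_that("distinct cells in a field are disjoint and placement failure is structured", {
  p <- small_params()
  truths <- withr::with_seed(3, mitoloc:::place_field_cells(p))
  all_px <- unlist(lapply(truths, `[[`, "cell_px"))
  expect_equal(anyDuplicated(all_px), 0)
  crowded <- synth_params(image_height = 96, image_width = 96,
                          n_cells_per_field = 20,
                          cell_radius_range = c(25, 30),
                          nucleus_radius_range = c(8, 10))
  expect_error(withr::with_seed(1, mitoloc:::place_field_cells(crowded)),
               class = "mitoloc_placement_error")
})

test_that("theta = 0 places no reporter mass on the mitochondrial mask", {
  sc <- single_cell_field(theta = 0)
  tr <- sc$truths[[1]]
  expect_equal(sum(sc$field$channels$reporter[tr$mito_px]), 0)
  expect_gt(sum(sc$field$channels$reporter[tr$golgi_px]), 0)
})

test_that("noise-free reporter splits photon mass by theta (signal partition)", {
  for (theta in c(0, 0.25, 0.5, 0.75, 1)) {
    sc <- single_cell_field(theta, seed = 11 + round(100 * theta))
    tr <- sc$truths[[1]]
    rep_ch <- sc$field$channels$reporter
    frac <- sum(rep_ch[tr$mito_px]) / sum(rep_ch[tr$cell_px])
    expect_lt(abs(frac - theta), 0.02)
  }
})

test_that("with zero cells and noise off every channel equals its background plane", {
  p <- synth_params(image_height = 96, image_width = 96,
                    n_cells_per_field = 0, shot_noise = FALSE,
                    read_noise_sd = 0)
  f <- render_field(list(), p)
  bg <- mitoloc:::background_plane(p)
  for (ch in f$channels) expect_equal(ch, bg)
})

test_that("theta = 1 with no background makes reporter proportional to mito channel", {
  sc <- single_cell_field(theta = 1)
  tr <- sc$truths[[1]]
  px <- tr$cell_px
  r <- sc$field$channels$reporter[px]
  m <- sc$field$channels$mito[px]
  ratio <- sum(r * m) / sum(m * m)   # least-squares slope through origin
  expect_equal(r, ratio * m, tolerance = 1e-12)
})

test_that("nuclei channel carries no mitochondrial or Golgi signal", {
  sc <- single_cell_field(theta = 0.5)
  tr <- sc$truths[[1]]
  nuc <- sc$field$channels$nuclei
  expect_equal(unique(nuc[c(tr$mito_px, tr$golgi_px)]), 0)
})

test_that("repeated noisy renders average to the noise-free image", {
  p <- synth_params(image_height = 64, image_width = 64,
                    n_cells_per_field = 1, cell_radius_range = c(18, 20),
                    nucleus_radius_range = c(5, 6), mito_filament_count = 5,
                    mito_filament_length = 25, transfected_prob = 1,
                    seed = 2)
  truths <- withr::with_seed(2, mitoloc:::place_field_cells(p))
  p_clean <- synth_params(image_height = 64, image_width = 64,
                          n_cells_per_field = 1,
                          cell_radius_range = c(18, 20),
                          nucleus_radius_range = c(5, 6),
                          mito_filament_count = 5, mito_filament_length = 25,
                          transfected_prob = 1, shot_noise = FALSE,
                          read_noise_sd = 0, seed = 2)
  clean <- render_field(truths, p_clean)$channels$reporter
  n_rep <- 300
  acc <- matrix(0, 64, 64)
  acc2 <- matrix(0, 64, 64)
  for (i in seq_len(n_rep)) {
    img <- withr::with_seed(1000 + i,
                            render_field(truths, p)$channels$reporter)
    acc <- acc + img
    acc2 <- acc2 + img^2
  }
  mn <- acc / n_rep
  se <- sqrt(pmax(acc2 / n_rep - mn^2, 0) / n_rep)
  within3 <- abs(mn - clean) <= 3 * pmax(se, 0.5)
  expect_gte(mean(within3), 0.99)
  expect_lt(abs(mean(mn) - mean(clean)), 0.5)
})

test_that("conditions are deterministic under a seed and sized as configured", {
  p <- small_params()
  c1 <- generate_condition(p, "x")
  c2 <- generate_condition(p, "x")
  expect_identical(c1$fields, c2$fields)
  expect_identical(lapply(c1$truths, function(tt) lapply(tt, unclass)),
                   lapply(c2$truths, function(tt) lapply(tt, unclass)))
  expect_equal(length(c1$fields), p$n_fields)
  expect_equal(c1$manifest$n_cells_total, p$n_fields * p$n_cells_per_field)
  # empty request
  p0 <- small_params(n_fields = 0)
  c0 <- generate_condition(p0, "empty")
  expect_length(c0$fields, 0)
  expect_equal(c0$manifest$n_cells_total, 0)
})

test_that("default study design yields around fifty cells per condition", {
  # defaults: 15 fields x 3 cells; count truth records without rendering cost
  p <- synth_params(seed = 9)
  total <- 0
  for (i in seq_len(p$n_fields))
    total <- total + withr::with_seed(derive_subseed(p$seed, i),
                                      length(mitoloc:::place_field_cells(p)))
  expect_gte(total, 40)
  expect_lte(total, 60)
})
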
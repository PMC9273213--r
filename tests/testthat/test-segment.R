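test_that("blank and sub-minimum images produce zero nucleus labels", {
  blank <- matrix(0, 64, 64)
  expect_equal(max(segment_nuclei(blank)), 0)
  small_obj <- matrix(0, 64, 64)
  small_obj[mitoloc:::disk_px(c(32, 32), 3, c(64, 64))] <- 10  # ~29 px < 80
  expect_equal(max(segment_nuclei(small_obj)), 0)
})

test_that("noise-free field recovers every nucleus with centroids within 2 px", {
  p <- synth_params(n_cells_per_field = 10, n_fields = 1,
                    cell_radius_range = c(30, 38),
                    nucleus_radius_range = c(10, 14),
                    shot_noise = FALSE, read_noise_sd = 0, seed = 17)
  cond <- generate_condition(p, "clean")
  labels <- segment_nuclei(cond$fields[[1]]$channels$nuclei)
  tab <- label_table(labels)
  expect_equal(nrow(tab), 10)
  for (tr in cond$truths[[1]]) {
    d <- sqrt((tab$centroid_r - tr$nucleus_center[1])^2 +
                (tab$centroid_c - tr$nucleus_center[2])^2)
    expect_lt(min(d), 2)
  }
})

test_that("propagation with no seeds returns an empty label mask", {
  seeds <- matrix(0L, 32, 32)
  out <- propagate_cell_masks(seeds, matrix(1, 32, 32))
  expect_equal(max(out), 0)
  expect_equal(dim(out), c(32L, 32L))
})

test_that("a single seed claims the entire uniform foreground", {
  seeds <- matrix(0L, 32, 32)
  seeds[16, 16] <- 1L
  guidance <- matrix(1, 32, 32)
  out <- propagate_cell_masks(seeds, guidance,
                              segmentation_params(guidance_threshold = 0.5,
                                                  guidance_close_radius = 0,
                                                  guidance_grow_px = 0,
                                                  marker_gate = 0))
  expect_true(all(out == 1L))
})

test_that("two seeds in a uniform foreground split it by nearest distance, ties to lower label", {
  seeds <- matrix(0L, 40, 40)
  seeds[10, 10] <- 1L
  seeds[10, 30] <- 2L
  guidance <- matrix(1, 40, 40)
  out <- propagate_cell_masks(seeds, guidance,
                              segmentation_params(guidance_threshold = 0.5,
                                                  guidance_close_radius = 0,
                                                  guidance_grow_px = 0,
                                                  marker_gate = 0))
  oracle <- nearest_seed_oracle(seeds, c(40, 40))
  expect_identical(out, oracle)
})

test_that("random seed pairs agree with the Euclidean oracle away from bisectors", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      seeds <- matrix(0L, 36, 36)
      pos <- sample(36 * 36, 2)
      seeds[pos[1]] <- 1L
      seeds[pos[2]] <- 2L
      out <- propagate_cell_masks(seeds, matrix(1, 36, 36),
                                  segmentation_params(guidance_threshold = 0.5,
                                                      guidance_close_radius = 0,
                                                      guidance_grow_px = 0,
                                                      marker_gate = 0))
      sr <- ((pos - 1) %% 36) + 1
      sc <- ((pos - 1) %/% 36) + 1
      r <- row(seeds); c <- col(seeds)
      d1 <- sqrt((r - sr[1])^2 + (c - sc[1])^2)
      d2 <- sqrt((r - sr[2])^2 + (c - sc[2])^2)
      clear <- abs(d1 - d2) > 0.05 * pmax(d1, d2) + 0.5
      expect_true(all((out == 1L)[clear] == (d1 < d2)[clear]))
    }
  })
})

test_that("propagation matches the reference propagate implementation on smooth guidance", {
  withr::with_seed(40, {
    guidance <- outer(seq_len(48), seq_len(48),
                      function(r, c) 1 + sin(r / 7) + cos(c / 9))
    guidance <- guidance - min(guidance)
    seeds <- matrix(0L, 48, 48)
    seeds[12, 12] <- 1L
    seeds[36, 34] <- 2L
    ours <- propagate_cell_masks(seeds, guidance,
                                 segmentation_params(guidance_threshold = -1,
                                                     guidance_close_radius = 0,
                                                     guidance_grow_px = 0,
                                                     lambda = 0.05,
                                                     marker_gate = 0))
    ref <- EBImage::propagate(guidance / max(guidance), seeds, lambda = 0.05)
    agree <- mean(ours == matrix(as.integer(ref), 48))
    expect_gte(agree, 0.9)
  })
})

test_that("propagated masks are disjoint, contain their seed nuclei, and shapes are validated", {
  sc <- single_cell_field(0.4, seed = 23)
  f <- preprocess_field(sc$field, method = "polynomial", poly_order = 1)
  nuclei <- segment_nuclei(f$channels$nuclei)
  cells <- propagate_cell_masks(nuclei, f$channels$mito)
  expect_true(all(cells[nuclei > 0] == nuclei[nuclei > 0]))
  expect_error(propagate_cell_masks(nuclei, matrix(0, 10, 10)),
               class = "mitoloc_input_error")
})

test_that("transfection gating behaves at trivial, impossible and bimodal thresholds", {
  p <- small_params(transfected_prob = 0.5, n_cells_per_field = 3,
                    n_fields = 4, image_height = 256, image_width = 256,
                    seed = 77)
  cond <- generate_condition(p, "gate")
  sel_flags <- integrated_all <- truth_flags <- c()
  per_field <- list()
  for (i in seq_along(cond$fields)) {
    truths <- cond$truths[[i]]
    masks <- truth_label_masks(truths, c(p$image_height, p$image_width))
    marker <- correct_background(
      average_projection(cond$fields[[i]]$channels$marker), "polynomial",
      poly_order = 1)
    g <- gate_transfected(masks$cell, marker, threshold = 0)
    per_field[[i]] <- list(gate = g, truths = truths)
    integrated_all <- c(integrated_all, g$integrated)
  }
  gate_value <- suggest_marker_gate(integrated_all)
  correct <- 0; total <- 0
  for (pf in per_field) {
    sel <- names(pf$gate$integrated)[pf$gate$integrated > gate_value]
    for (tr in pf$truths) {
      total <- total + 1
      predicted <- as.character(tr$cell_id) %in% sel
      correct <- correct + (predicted == tr$transfected)
    }
  }
  expect_gte(correct / total, 0.95)
  # trivial gate: threshold 0 selects every cell with positive signal
  g1 <- per_field[[1]]$gate
  expect_setequal(g1$selected, as.integer(names(g1$integrated)[g1$integrated > 0]))
  # impossible gate: nothing passes
  masks <- truth_label_masks(per_field[[1]]$truths, c(256, 256))
  marker <- matrix(1, 256, 256)
  g2 <- gate_transfected(masks$cell, marker, threshold = 1e12)
  expect_length(g2$selected, 0)
  expect_error(gate_transfected(masks$cell, marker, threshold = -1),
               class = "mitoloc_param_error")
})

test_that("raising the marker gate never adds a cell (monotonicity)", {
  sc <- single_cell_field(0.3, seed = 9)
  masks <- truth_label_masks(sc$truths, c(128, 128))
  marker <- average_projection(sc$field$channels$marker)
  prev <- NULL
  for (th in c(0, 1e3, 1e5, 1e7, 1e9)) {
    sel <- gate_transfected(masks$cell, marker, th)$selected
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
})

test_that("closing and filling a one-pixel ring yields the solid interior (toy grid)", {
  mito <- matrix(0, 7, 7)
  mito[2, 2:6] <- 1; mito[6, 2:6] <- 1; mito[2:6, 2] <- 1; mito[2:6, 6] <- 1
  cells <- matrix(1L, 7, 7)
  res <- make_pseudo_cell_mask(mito, cells, selected = 1L,
                               segmentation_params(mito_threshold = 0.5,
                                                   closing_radius = 1,
                                                   marker_gate = 0))
  solid <- matrix(0L, 7, 7)
  solid[2:6, 2:6] <- 1L   # ring plus filled 5x5 interior, by hand
  expect_identical(res$mask, solid)
  expect_length(res$no_mito_mask, 0)
})

test_that("an already-solid blob passes through the pseudo-cell mask unchanged", {
  mito <- matrix(0, 40, 40)
  blob <- mitoloc:::disk_px(c(20, 20), 8, c(40, 40))
  mito[blob] <- 5
  cells <- matrix(1L, 40, 40)
  res <- make_pseudo_cell_mask(mito, cells, selected = 1L,
                               segmentation_params(mito_threshold = 1,
                                                   closing_radius = 3,
                                                   marker_gate = 0))
  expect_equal(which(res$mask == 1L), sort(blob))
})

test_that("cells without mitochondrial signal are flagged, not fatal", {
  mito <- matrix(0, 40, 40)
  cells <- matrix(0L, 40, 40)
  cells[mitoloc:::disk_px(c(20, 20), 10, c(40, 40))] <- 1L
  res <- make_pseudo_cell_mask(mito, cells, selected = 1L,
                               segmentation_params(mito_threshold = 0.5,
                                                   marker_gate = 0))
  expect_equal(res$no_mito_mask, 1L)
  expect_equal(max(res$mask), 0)
})

test_that("the pseudo-cell mask is contained in its parent propagated mask", {
  sc <- single_cell_field(0.5, seed = 19)
  f <- preprocess_field(sc$field, method = "polynomial", poly_order = 1)
  nuclei <- segment_nuclei(f$channels$nuclei)
  cells <- propagate_cell_masks(nuclei, f$channels$mito)
  res <- make_pseudo_cell_mask(f$channels$mito, cells)
  inside <- res$mask > 0
  expect_true(all(cells[inside] == res$mask[inside]))
})
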
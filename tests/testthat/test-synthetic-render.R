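single_cell_config <- function(radius = 40, seed = 1) {
  plate_config(
    cells_per_well_range = c(1, 1), image_size = 200, noise_sd = 0,
    morph_params = list(
      NEG_CTL = list(radius = c(radius, 0), elongation = c(1, 0),
                     n_protrusions = c(0, 0), protrusion_len = c(0, 0)),
      POS_CTL = list(radius = c(radius + 10, 0), elongation = c(2, 0),
                     n_protrusions = c(4, 0), protrusion_len = c(20, 0))),
    seed = seed)
}

test_that("a noiseless single circular cell renders one label with one nucleus", {
  cfg <- single_cell_config()
  lay <- gen_plate_layout(cfg)
  w <- render_synthetic_well(lay[lay$group == "NEG_CTL", ][1, ], cfg)
  expect_equal(sort(unique(as.vector(w$cell_mask))), c(0L, 1L))
  expect_equal(sort(unique(as.vector(w$nucleus_mask))), c(0L, 1L))
  # nucleus strictly inside its cell: same label underneath, none on boundary
  expect_true(all(w$cell_mask[w$nucleus_mask == 1L] == 1L))
  expect_lt(sum(w$nucleus_mask == 1L), sum(w$cell_mask == 1L))
  # mitochondria confined to the cell, zero background at noise_sd = 0
  expect_true(all(w$mito[w$cell_mask == 0L] == 0))
  # round body: area close to pi r^2
  expect_equal(sum(w$cell_mask == 1L), pi * 40^2, tolerance = 0.05)
  expect_equal(nrow(w$ground_truth), 1)
})

test_that("stimulated wells render larger, less round cells than unstimulated", {
  cfg <- plate_config(seed = 7, cells_per_well_range = c(8, 10),
                      image_size = 900)
  lay <- gen_plate_layout(cfg)
  wn <- render_synthetic_well(lay[lay$group == "NEG_CTL", ][1, ], cfg)
  wp <- render_synthetic_well(lay[lay$group == "POS_CTL", ][1, ], cfg)
  fn <- extract_single_cell_features(wn$cell_mask, wn$nucleus_mask)
  fp <- extract_single_cell_features(wp$cell_mask, wp$nucleus_mask)
  expect_gt(mean(fp$Cell_Area), mean(fn$Cell_Area))
  expect_gt(mean(fn$Cell_FormFactor), mean(fp$Cell_FormFactor))
  expect_gt(mean(fp$Cell_AspectRatio), mean(fn$Cell_AspectRatio))
})

test_that("rendered cells match the shape-descriptor oracle per label", {
  cfg <- plate_config(seed = 21, cells_per_well_range = c(4, 4),
                      image_size = 600)
  lay <- gen_plate_layout(cfg)
  w <- render_synthetic_well(lay[lay$group == "NEG_CTL", ][1, ], cfg)
  rec <- extract_single_cell_features(w$cell_mask, w$nucleus_mask)
  for (i in seq_len(nrow(rec))) {
    oracle <- compute_shape_descriptors(w$cell_mask == rec$cell_id[i])
    expect_equal(rec$Cell_Area[i], oracle$Area)
    expect_equal(rec$Cell_Perimeter[i], oracle$Perimeter)
    expect_equal(rec$Cell_MajorAxisLength[i], oracle$MajorAxisLength)
    expect_equal(rec$Cell_Solidity[i], oracle$Solidity)
  }
})

test_that("renderer axis lengths recover the generating ellipse at zero protrusions", {
  cfg <- plate_config(
    cells_per_well_range = c(3, 3), image_size = 500, noise_sd = 0,
    morph_params = list(
      NEG_CTL = list(radius = c(30, 0), elongation = c(1.8, 0),
                     n_protrusions = c(0, 0), protrusion_len = c(0, 0)),
      POS_CTL = list(radius = c(30, 0), elongation = c(1.8, 0),
                     n_protrusions = c(0, 0), protrusion_len = c(0, 0))),
    seed = 13)
  lay <- gen_plate_layout(cfg)
  w <- render_synthetic_well(lay[1, ], cfg)
  rec <- extract_single_cell_features(w$cell_mask, w$nucleus_mask)
  a <- 30 * sqrt(1.8); b <- 30 / sqrt(1.8)
  for (i in seq_len(nrow(rec))) {
    expect_equal(rec$Cell_MajorAxisLength[i], 2 * a, tolerance = 0.05)
    expect_equal(rec$Cell_MinorAxisLength[i], 2 * b, tolerance = 0.05)
  }
})

test_that("full EV recovery reproduces the unstimulated latent means", {
  cfg <- plate_config(ev_effect = 1)
  expect_equal(evmorph:::group_latents(cfg, "POS_EV")$mean,
               evmorph:::group_latents(cfg, "NEG_CTL")$mean)
  cfg0 <- plate_config(ev_effect = 0)
  expect_equal(evmorph:::group_latents(cfg0, "POS_EV")$mean,
               evmorph:::group_latents(cfg0, "POS_CTL")$mean)
})

test_that("overcrowded configurations abort with advice", {
  cfg <- plate_config(cells_per_well_range = c(60, 60), image_size = 200,
                      seed = 1)
  lay <- gen_plate_layout(cfg)
  expect_error(render_synthetic_well(lay[1, ], cfg),
               class = "evmorph_generation_error",
               regexp = "image_size")
})

test_that("rendering is deterministic per well and seed", {
  cfg <- plate_config(seed = 5, cells_per_well_range = c(5, 6),
                      image_size = 600)
  lay <- gen_plate_layout(cfg)
  w1 <- render_synthetic_well(lay[1, ], cfg)
  w2 <- render_synthetic_well(lay[1, ], cfg)
  expect_identical(w1, w2)
  w3 <- render_synthetic_well(lay[2, ], cfg)
  expect_false(identical(w1$cell_mask, w3$cell_mask))
})
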
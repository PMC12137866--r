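test_that("homogeneous phantom is constant with an empty label map", {
  ph <- make_phantom("homogeneous", 64, 64, seed = 1)
  expect_true(all(ph$yield_map == 0.5))
  expect_true(all(ph$label_map == 0L))
  expect_equal(dim(ph$yield_map), c(64, 64))
  expect_true(all(ph$tau_map > 0))
})

test_that("phantom generation is bit-identical for identical arguments", {
  a <- make_phantom("cell", 96, 96, seed = 7)
  b <- make_phantom("cell", 96, 96, seed = 7)
  expect_identical(a$yield_map, b$yield_map)
  expect_identical(a$tau_map, b$tau_map)
  expect_identical(a$label_map, b$label_map)
  c <- make_phantom("cell", 96, 96, seed = 8)
  expect_false(identical(a$yield_map, c$yield_map))
})

test_that("cell preset places the required discs and membranes with matching labels", {
  ph <- make_phantom("cell", 256, 256, seed = 1)
  tab <- table(ph$structures$type)
  expect_gte(tab[["disc"]], 3)
  expect_gte(tab[["membrane"]], 5)
  # every structure label appears in the map
  expect_true(all(ph$structures$label %in% unique(as.integer(ph$label_map))))
  # ground truth is the label map
  expect_identical(phantom_ground_truth(ph), ph$label_map)
  # discs charge slowly: tau inside discs is >= 100x background
  disc_lbl <- ph$structures$label[ph$structures$type == "disc"]
  expect_true(all(ph$tau_map[ph$label_map %in% disc_lbl] >=
                    100 * ph$params$tau_background_ns))
})

test_that("disc areas match pi r^2 within a perimeter-sized discretisation bound", {
  ph <- make_phantom("cell", 256, 256, seed = 3)
  discs <- ph$structures[ph$structures$type == "disc", ]
  for (i in seq_len(nrow(discs))) {
    r <- discs$radius_px[i]
    expect_lt(abs(discs$area_px[i] - pi * r^2), 2 * pi * r + 4)
  }
})

test_that("myelin preset builds annulus stacks with alternating yields", {
  ph <- make_phantom("myelin", 192, 192, seed = 2)
  tab <- table(ph$structures$type)
  expect_gte(tab[["myelin"]], 2)
  expect_gte(tab[["organelle"]], 2)
  # rings carry both the low and the high yield
  my <- ph$label_map %in% ph$structures$label[ph$structures$type == "myelin"]
  expect_true(any(ph$yield_map[my] < 0.45))
  expect_true(any(ph$yield_map[my] > 0.75))
})

test_that("flyback_test band is confined to the requested width", {
  a <- make_phantom("flyback_test", 128, 256, seed = 5,
                    overrides = list(flyback_width = 64))
  b <- make_phantom("flyback_test", 128, 256, seed = 5,
                    overrides = list(flyback_width = 8))
  # columns beyond both bands equal the shared unwarped base
  expect_identical(a$yield_map[, 65:128], b$yield_map[, 65:128])
  expect_false(identical(a$yield_map[, 1:64], b$yield_map[, 1:64]))
  expect_true(all(a$label_map[, 1:64] == 1L))
  expect_true(all(a$label_map[, 65:128] == 0L))
})

test_that("invalid presets and grids are rejected", {
  expect_error(make_phantom("nonsense", 64, 64, 1))
  expect_error(make_phantom("cell", 16, 16, 1))
  expect_error(make_phantom("cell", 64, 64, 1, overrides = list(bogus = 1)),
               "unknown override")
})
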
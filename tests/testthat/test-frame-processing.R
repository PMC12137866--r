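test_that("8-bit conversion uses the stack-global range and maps constants to 0", {
  st <- array(c(-100, 412, 156, 156), dim = c(1, 2, 2))
  out <- convert_to_uint8(st)
  expect_equal(out[1, , 1], c(0, 255))
  expect_equal(out[1, 1, 2], 128)   # (156 + 100) * 255 / 512
  expect_true(all(convert_to_uint8(array(7, dim = c(4, 4, 2))) == 0))
  expect_error(convert_to_uint8(array(0, dim = c(0, 4, 1))), "empty")
})

test_that("8-bit conversion is monotone and idempotent on full-range data", {
  set.seed(1)
  st <- array(rnorm(6 * 6 * 3, 0, 2000), dim = c(6, 6, 3))
  out <- convert_to_uint8(st)
  o <- order(as.numeric(st))
  expect_true(all(diff(as.numeric(out)[o]) >= 0))
  expect_true(all(out >= 0 & out <= 255))
  # full-range 8-bit data passes through unchanged
  st8 <- array(sample(0:255, 64, replace = TRUE), dim = c(8, 8, 1))
  st8[1] <- 0; st8[64] <- 255
  expect_equal(convert_to_uint8(st8), st8)
})

test_that("flyback crop removes exactly the left margin", {
  st <- array(seq_len(4 * 2048 * 2), dim = c(4, 2048, 2))
  out <- crop_flyback(st, 64)
  expect_equal(dim(out), c(4, 1984, 2))
  expect_equal(out[, 1, ], st[, 65, ])
  expect_identical(crop_flyback(st, 0), st)
  expect_error(crop_flyback(st, 2048), "width_px")
})

test_that("center crop ties break toward the top-left and compose with flyback crop", {
  m <- matrix(seq_len(25), 5, 5)
  out <- center_crop(m, 3)
  expect_equal(out, m[2:4, 2:4])
  expect_identical(center_crop(m, 5), m)
  expect_error(center_crop(m, 6), "size")
  # even remainder: offset floor((4-3)/2) = 0 rows/cols
  m4 <- matrix(seq_len(16), 4, 4)
  expect_equal(center_crop(m4, 3), m4[1:3, 1:3])
  # the acquisition pipeline: 2048 -> crop 64 -> centered 1920
  st <- array(0, dim = c(2048, 2048, 1))
  expect_equal(dim(center_crop(crop_flyback(st, 64), 1920)),
               c(1920, 1920, 1))
})

test_that("identical frames align with zero shifts and an unaltered reference", {
  img <- smooth_image(64, 64, 3, 1)
  st <- array(rep(img, 3), dim = c(64, 64, 3))
  al <- align_frames(st, patch_grid = c(2, 2), max_shift = 5)
  expect_true(all(al$shifts$dy == 0 & al$shifts$dx == 0))
  expect_equal(al$aligned[, , 1], img)
  expect_error(align_frames(array(img, dim = c(64, 64, 1))), "2 frames")
})

test_that("planted integer shifts are recovered exactly on noise-free frames", {
  base <- smooth_image(96, 96, 3, 2)
  st <- array(c(base, circshift(base, 3, -2), circshift(base, -1, 4)),
              dim = c(96, 96, 3))
  al <- align_frames(st, patch_grid = c(1, 1), upsample = 1)
  expect_equal(al$shifts$dy[al$shifts$frame == 2], 3)
  expect_equal(al$shifts$dx[al$shifts$frame == 2], -2)
  expect_equal(al$shifts$dy[al$shifts$frame == 3], -1)
  expect_equal(al$shifts$dx[al$shifts$frame == 3], 4)
  expect_equal(al$aligned[20:70, 20:70, 2], base[20:70, 20:70])
})

test_that("subpixel refinement stays within half a pixel of planted shifts", {
  base <- smooth_image(96, 96, 3, 4)
  st <- array(c(base, circshift(base, 2, -3)), dim = c(96, 96, 2))
  al <- align_frames(st, patch_grid = c(1, 1), upsample = 10)
  expect_lt(abs(al$shifts$dy[al$shifts$frame == 2] - 2), 0.5)
  expect_lt(abs(al$shifts$dx[al$shifts$frame == 2] + 3), 0.5)
})

test_that("aligning a drifted synthetic stack improves correlation with the truth", {
  ph <- make_phantom("cell", 96, 96, seed = 6)
  p <- sim_params(alpha = 0, noise_std = 120, drift_step_px = 1.2)
  stk <- simulate_acquisition(ph, make_raster_pattern(96, 96, 100, 6), p, 3)
  expect_true(any(stk$metadata$drift_x != 0 | stk$metadata$drift_y != 0))
  truth <- p$detector_gain * ph$yield_map + p$detector_offset
  raw <- integrate_frames(stk)
  al <- align_frames(stk$frames, patch_grid = c(1, 1))
  aligned <- integrate_frames(al$aligned)
  inner <- 20:77
  expect_gte(cor(as.numeric(aligned[inner, inner]),
                 as.numeric(truth[inner, inner])),
             cor(as.numeric(raw[inner, inner]),
                 as.numeric(truth[inner, inner])))
})

test_that("integration reduces and averages as expected", {
  st <- array(c(matrix(10, 4, 4), matrix(20, 4, 4)), dim = c(4, 4, 2))
  expect_equal(integrate_frames(st, "mean"), matrix(15, 4, 4))
  expect_equal(integrate_frames(st, "sum"), matrix(30, 4, 4),
               ignore_attr = TRUE)
  # R identical frames, mean -> that frame
  img <- smooth_image(8, 8, 2, 3)
  expect_equal(integrate_frames(array(rep(img, 5), dim = c(8, 8, 5))), img)
  # saturation flag on sums
  big <- array(30000, dim = c(2, 2, 2))
  s <- integrate_frames(big, "sum")
  expect_true(attr(s, "saturated"))
  expect_true(all(s == 32767))
})

test_that("mean integration shrinks white-noise standard deviation like 1/sqrt(R)", {
  set.seed(9)
  R <- 16
  st <- array(rnorm(64 * 64 * R), dim = c(64, 64, R))
  ratio <- sd(integrate_frames(st)) / sd(st[, , 1])
  expect_lt(abs(ratio - 1 / sqrt(R)), 0.2 / sqrt(R))
})

test_that("mean filter matches direct convolution and handles edges by reflection", {
  expect_identical(mean_filter(matrix(1:9, 3, 3), 1), matrix(1:9, 3, 3))
  cst <- matrix(4.2, 6, 6)
  expect_equal(mean_filter(cst, 3), cst)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  out <- mean_filter(imp, 3)
  expect_equal(out[4:6, 4:6], matrix(1 / 9, 3, 3))
  expect_equal(sum(out), 1)
  expect_error(mean_filter(imp, 4), "odd")
  # brute-force oracle with reflected padding on a random image
  set.seed(2)
  img <- matrix(rnorm(49), 7, 7)
  pad <- rbind(img[1, ], img, img[7, ])
  pad <- cbind(pad[, 1], pad, pad[, 7])
  oracle <- matrix(0, 7, 7)
  for (i in 1:7) for (j in 1:7)
    oracle[i, j] <- mean(pad[i:(i + 2), j:(j + 2)])
  expect_equal(mean_filter(img, 3), oracle)
})
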
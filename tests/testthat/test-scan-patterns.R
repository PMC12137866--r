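test_that("raster frame timing: x interval is the dwell, y interval is nx * dwell", {
  p <- make_raster_pattern(7, 7, dwell_ns = 100, reps = 1)
  v <- p$visits
  expect_equal(v$t_start_ns[2] - v$t_start_ns[1], 100)       # x neighbours
  expect_equal(v$t_start_ns[8] - v$t_start_ns[1], 7 * 100)   # y neighbours
  expect_equal(min_neighbour_interval(p, 1), 100)
  # repeated frames are seamless (no flyback in frame integration)
  p2 <- make_raster_pattern(7, 7, 100, reps = 3)
  expect_equal(diff(p2$visits$t_start_ns), rep(100, 3 * 49 - 1))
})

test_that("raster line integration repeats each line with a flyback delay before every pass", {
  p <- make_raster_pattern(2, 1, dwell_ns = 100, reps = 3,
                           integration = "line", flyback_delay_ns = 70000)
  v <- p$visits
  expect_equal(nrow(v), 6)
  expect_equal(v$x, rep(c(0L, 1L), 3))
  # each pass starts one flyback delay after the previous pass ended
  starts <- v$t_start_ns[c(1, 3, 5)]
  expect_equal(diff(starts), rep(70000 + 2 * 100, 2))
  expect_equal(starts[1], 70000)
  # passes of line y precede any visit of line y+1
  p2 <- make_raster_pattern(4, 3, 100, reps = 2, integration = "line",
                            flyback_delay_ns = 1000)
  expect_equal(p2$visits$y, rep(0:2, each = 8))
})

test_that("flyback delay is rejected for frame integration", {
  expect_error(make_raster_pattern(8, 8, 100, 2, "frame",
                                   flyback_delay_ns = 1000),
               "flyback")
})

test_that("interleaved pattern visits the stride-3 sub-lattice first, x fastest", {
  p <- make_interleaved_pattern(7, 7, skip_x = 2, skip_y = 2, dwell_ns = 100)
  v <- p$visits
  expect_equal(v$x[1:4], c(0L, 3L, 6L, 0L))
  expect_equal(v$y[1:4], c(0L, 0L, 0L, 3L))
  expect_equal(nrow(v), 49)
  expect_equal(nrow(validate_pattern(p)), 0)
  # consecutive visits within a frame are one dwell apart
  expect_equal(diff(v$t_start_ns), rep(100, 48))
})

test_that("interleaved degenerates to raster frame integration at skip 0", {
  p0 <- make_interleaved_pattern(9, 6, 0, 0, 100, reps = 2)
  pr <- make_raster_pattern(9, 6, 100, reps = 2, integration = "frame")
  expect_equal(p0$visits$x, pr$visits$x)
  expect_equal(p0$visits$y, pr$visits$y)
  expect_equal(p0$visits$t_start_ns, pr$visits$t_start_ns)
})

test_that("every pixel is visited exactly once per repetition (permutation property)", {
  set.seed(42)
  grids <- cbind(nx = sample(5:64, 12), ny = sample(5:64, 12))
  for (i in seq_len(nrow(grids))) {
    for (skip in 0:4) {
      nx <- grids[i, 1]; ny <- grids[i, 2]
      if (skip >= nx || skip >= ny) next
      p <- make_interleaved_pattern(nx, ny, skip, skip, 100, reps = 1)
      expect_equal(frame_occupancy(p), rep(1L, nx * ny))
    }
  }
  # multi-repetition coverage: 16 x 16, skip 2, 10 reps -> 2560 visits, valid
  p <- make_interleaved_pattern(16, 16, 2, 2, 100, reps = 10)
  expect_equal(nrow(p$visits), 2560)
  expect_equal(nrow(validate_pattern(p)), 0)
})

test_that("interleaving strictly increases the minimum neighbour interval", {
  for (nx in c(6, 9, 16, 25, 32)) for (skip in c(1, 2)) {
    if (nx < 2 * (skip + 1)) next
    pr <- make_raster_pattern(nx, nx, 100, 1)
    pi <- make_interleaved_pattern(nx, nx, skip, skip, 100, 1)
    expect_equal(min_neighbour_interval(pr, 1), 100)
    expect_gt(min_neighbour_interval(pi, 1), 100)
  }
})

test_that("min_neighbour_interval rejects degenerate inputs", {
  p <- make_raster_pattern(4, 4, 100, 1)
  expect_error(min_neighbour_interval(p, 4), "extent")
  # single-pixel-like grid: radius can never be valid
  p1 <- make_raster_pattern(1, 1, 100, 1)
  expect_error(min_neighbour_interval(p1, 1))
})

test_that("validate_pattern reports duplicated and missing pixels by name", {
  p <- make_raster_pattern(3, 3, 100, 1)
  p$visits$x[5] <- 0L; p$visits$y[5] <- 0L   # duplicate (0,0), lose (1,1)
  rep <- validate_pattern(p)
  expect_true(any(grepl("\\(0, 0\\)", rep$detail[rep$check == "duplicate"])))
  expect_true(any(grepl("\\(1, 1\\)", rep$detail[rep$check == "missing"])))
})

test_that("pattern text export round-trips and rejects malformed input", {
  p <- make_interleaved_pattern(16, 16, 2, 2, 100, reps = 3)
  f <- withr::local_tempfile(fileext = ".txt")
  export_pattern_text(p, f)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "#"))
  expect_equal(length(lines), 1 + 256)        # header + one frame
  p2 <- import_pattern_text(f)
  expect_equal(p2$visits, p$visits)
  expect_equal(p2$reps, p$reps)

  p3 <- make_raster_pattern(2, 2, 100, 1)
  f3 <- withr::local_tempfile(fileext = ".txt")
  export_pattern_text(p3, f3, header = FALSE)
  expect_equal(readLines(f3), c("0 0", "1 0", "0 1", "1 1"))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0", "a b"), bad)
  expect_error(import_pattern_text(bad), "line 2")
  oob <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0", "5 0"), oob)
  expect_error(import_pattern_text(oob, metadata = list(nx = 2, ny = 2)),
               "out of bounds")
})

test_that("the three dwell/repetition schedules deliver identical fluence", {
  f_low <- compute_fluence(6.3, 100, 100, 6.34)
  f_mid <- compute_fluence(6.3, 500, 20, 6.34)
  f_high <- compute_fluence(6.3, 1000, 10, 6.34)
  expect_identical(f_low, f_mid)
  expect_identical(f_low, f_high)
  expect_equal(signif(f_low, 1), 0.1)   # ~1e-1 electrons per square angstrom
  expect_equal(compute_fluence(0, 100, 100, 6.34), 0)
  expect_error(compute_fluence(6.3, -1, 100, 6.34))
})
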
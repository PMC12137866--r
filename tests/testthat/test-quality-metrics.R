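test_that("histogram mean and charging deviation follow the mid-range convention", {
  expect_equal(histogram_mean(matrix(127, 4, 4)),
               tibble::tibble(histogram_mean = 127, charging_deviation = 0))
  expect_equal(histogram_mean(matrix(0, 4, 4))$charging_deviation, 127)
  half <- matrix(c(rep(0, 8), rep(255, 8)), 4, 4)
  hm <- histogram_mean(half)
  expect_equal(hm$histogram_mean, 127.5)
  expect_equal(hm$charging_deviation, 0.5)
  expect_error(histogram_mean(matrix(numeric(0), 0, 0)), "empty")
})

test_that("flyback extent is recovered within the smoothing tolerance for planted widths", {
  roi <- c(0, 40, 160, 176)
  for (w in c(32, 64, 96)) {
    fr <- flyback_frames(w, n_frames = 6)
    est <- estimate_flyback_extent(fr, roi)
    expect_false(est$warning_no_edge)
    expect_gte(est$flyback_extent_px, w - 2)
    expect_lte(est$flyback_extent_px, w + 14)
  }
})

test_that("the median aggregate shrugs off corrupted outlier frames", {
  fr <- flyback_frames(32, n_frames = 20)
  set.seed(99)
  for (f in c(3, 11, 17))   # 15% of frames: edge detection fails or misfires
    fr[, , f] <- matrix(runif(256 * 256, 0, 255), 256)
  est <- estimate_flyback_extent(fr, c(0, 40, 160, 176))
  expect_gte(est$flyback_extent_px, 30)
  expect_lte(est$flyback_extent_px, 46)
})

test_that("flyback extent degenerates gracefully and respects the roi", {
  uni <- array(5, dim = c(64, 64, 3))
  est <- estimate_flyback_extent(uni, c(0, 8, 48, 48))
  expect_true(est$warning_no_edge)
  expect_equal(est$flyback_extent_px, 0)
  expect_error(estimate_flyback_extent(uni, c(0, 8, 100, 48)), "roi")
  # never exceeds the roi width
  fr <- flyback_frames(96, n_frames = 3)
  est2 <- estimate_flyback_extent(fr, c(0, 40, 120, 176))
  expect_lte(est2$flyback_extent_px, 120)
})

test_that("simple segmentation finds well-separated bright objects", {
  img <- matrix(10, 80, 80)
  img[10:25, 10:25] <- 200
  img[50:70, 45:65] <- 200
  set.seed(5)
  img <- img + rnorm(6400, 0, 3)
  lab <- segment_simple(img, min_size = 16)
  expect_equal(max(lab), 2)
  expect_true(all(segment_simple(matrix(3, 40, 40)) == 0))
  expect_true(all(segment_simple(img, min_size = 1e5) == 0))
})

test_that("complexity of an axis-aligned square is exactly 16 and additive", {
  m <- matrix(0L, 30, 30)
  m[3:12, 3:12] <- 1L
  cs <- complexity_score(m)
  expect_equal(cs$n_objects, 1L)
  expect_equal(cs$total_complexity, 16)
  expect_equal(cs$per_object[[1]]$perimeter, 40)
  expect_equal(cs$per_object[[1]]$area, 100)
  # two disjoint squares: counts and scores add
  m[16:25, 16:25] <- 2L
  cs2 <- complexity_score(m)
  expect_equal(cs2$n_objects, 2L)
  expect_equal(cs2$total_complexity, 32)
  # empty mask
  cs0 <- complexity_score(matrix(0L, 5, 5))
  expect_equal(cs0$n_objects, 0L)
  expect_equal(cs0$total_complexity, 0)
})

test_that("complexity is translation- and scale-invariant for squares, including image-border contact", {
  for (k in c(1, 2, 4)) {
    n <- 6 * k
    m <- matrix(0L, 40, 40)
    m[5:(4 + n), 9:(8 + n)] <- 1L
    expect_equal(complexity_score(m)$total_complexity, 16)
  }
  # square touching the border: the border edges still count
  m <- matrix(0L, 10, 10)
  m[1:5, 1:5] <- 1L
  expect_equal(complexity_score(m)$total_complexity, 16)
})

test_that("crack-length perimeter matches a brute-force edge count on random masks", {
  set.seed(11)
  img <- matrix(rnorm(400), 20, 20)
  lab <- label_components(img > 0.8)
  if (max(lab) > 0) {
    cs <- complexity_score(lab)
    brute <- 0
    for (i in 1:20) for (j in 1:20) {
      if (lab[i, j] == 0) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        out <- ii < 1 || ii > 20 || jj < 1 || jj > 20
        if (out || lab[ii, jj] != lab[i, j]) brute <- brute + 1
      }
    }
    expect_equal(sum(cs$per_object[[1]]$perimeter), brute)
  }
})

test_that("labelling is 8-connected (diagonal pixels join)", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[4, 4] <- TRUE
  lab <- label_components(m)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_false(lab[4, 4] == lab[1, 1])
  expect_equal(max(lab), 2)
  # cross-check component count against igraph on a random mask
  skip_if_not_installed("igraph")
  set.seed(3)
  mk <- matrix(runif(144) < 0.35, 12, 12)
  lab2 <- label_components(mk)
  idx <- which(mk)
  coord <- cbind((idx - 1) %% 12, (idx - 1) %/% 12)
  edges <- NULL
  for (a in seq_along(idx)) for (b in seq_len(a - 1)) {
    if (max(abs(coord[a, ] - coord[b, ])) <= 1)
      edges <- rbind(edges, c(a, b))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  expect_equal(max(lab2), igraph::components(g)$no)
})

test_that("normalisation to a reference produces unit reference ratio", {
  tb <- tibble::tibble(condition = c("A", "ref"), n = c(40, 50))
  out <- normalize_to_reference(tb, "ref")
  expect_equal(out$ratio, c(0.8, 1.0))
  expect_equal(normalize_to_reference(tb[2, ], "ref")$ratio, 1.0)
  expect_error(normalize_to_reference(tibble::tibble(condition = "ref", n = 0),
                                      "ref"), "zero")
  expect_error(normalize_to_reference(tb, "missing"), "not present")
})

test_that("anisotropy index is ~1 for iid noise, large for banding, and inverts under transpose", {
  set.seed(21)
  noise <- matrix(rnorm(256 * 256), 256, 256)
  expect_lt(abs(anisotropy_index(noise) - 1), 0.1)
  # horizontal streaks: rows constant, strong variation across rows
  streaks <- matrix(rep(sin(seq(0, 20, length.out = 64)), 64), 64, 64)
  expect_equal(anisotropy_index(streaks), Inf)
  expect_gt(anisotropy_index(streaks + matrix(rnorm(4096, 0, 1e-3), 64)), 10)
  img <- smooth_image(40, 40, 2, 8) + matrix(rnorm(1600, 0, .01), 40)
  expect_equal(anisotropy_index(t(img)), 1 / anisotropy_index(img))
  expect_error(anisotropy_index(matrix(1, 1, 5)))
})
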
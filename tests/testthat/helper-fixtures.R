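# shared fixture builders

# circular shift: content moves down by dy and right by dx
circshift <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
}

# smooth random image (correlated texture)
smooth_image <- function(ny, nx, sigma = 3, seed = 1) {
  set.seed(seed)
  leapscan:::gaussian_blur(matrix(rnorm(ny * nx), ny, nx), sigma)
}

# frames rendered from a flyback_test phantom: yield scaled to counts + noise
flyback_frames <- function(width, n_frames = 8, ny = 256, nx = 256,
                           seed = 3, noise_sd = 2) {
  ph <- make_phantom("flyback_test", nx, ny, seed = seed,
                     overrides = list(flyback_width = width))
  set.seed(seed + 100)
  fr <- array(0, dim = c(ny, nx, n_frames))
  for (f in seq_len(n_frames))
    fr[, , f] <- ph$yield_map * 200 + rnorm(ny * nx, 0, noise_sd)
  fr
}

# occupancy counts of a pattern's first frame
frame_occupancy <- function(pattern) {
  npx <- pattern$nx * pattern$ny
  v <- pattern$visits[seq_len(npx), ]
  tabulate(v$x + pattern$nx * v$y + 1L, nbins = npx)
}
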
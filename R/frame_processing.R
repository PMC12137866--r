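# Subframe preparation pipeline: bit-depth conversion, flyback cropping,
# analysis-region cropping, patch-based alignment, integration, mean filtering.
# A "stack" is either a ny x nx x R array, a list of matrices, or a
# subframe_stack; single images are plain matrices.

as_frame_array <- function(stack) {
  if (inherits(stack, "subframe_stack")) return(stack$frames)
  if (is.list(stack)) {
    stopifnot(length(stack) >= 1)
    dims <- vapply(stack, dim, integer(2))
    if (any(dims != dims[, 1])) stop("all frames must have the same shape")
    return(array(unlist(stack), dim = c(dims[1, 1], dims[2, 1], length(stack))))
  }
  if (is.matrix(stack)) return(array(stack, dim = c(dim(stack), 1L)))
  if (is.array(stack) && length(dim(stack)) == 3) return(stack)
  stop("cannot interpret input as a frame stack")
}

rewrap_stack <- function(stack, frames) {
  if (inherits(stack, "subframe_stack")) {
    stack$frames <- frames
    stack
  } else frames
}

#' Convert a 16-bit signed stack to 8-bit
#'
#' Shifts the histogram to a positive range and rescales:
#' `round((v - min) * 255 / (max - min))` with the minimum and maximum taken
#' over the whole stack (not per frame), preserving inter-frame intensity
#' comparability for the histogram metrics. A constant stack maps to 0. The
#' mapping is monotone non-decreasing.
#'
#' @param stack Frame stack (array, list of matrices, matrix, or
#'   `subframe_stack`).
#' @return Same container with values in 0..255.
#' @export
convert_to_uint8 <- function(stack) {
  fr <- as_frame_array(stack)
  if (length(fr) == 0) stop("empty stack")
  lo <- min(fr); hi <- max(fr)
  out <- if (hi <= lo) array(0, dim = dim(fr))
         else round((fr - lo) * 255 / (hi - lo))
  rewrap_stack(stack, out)
}

#' Remove the flyback-distorted left margin
#'
#' Drops the leftmost `width_px` columns of every frame. The default width of
#' 64 pixels is the estimated spatial extent of flyback distortions when no
#' settling delay is applied (see [estimate_flyback_extent()]).
#'
#' @param stack Frame stack or single image.
#' @param width_px Number of columns to remove (`0 <= width_px < nx`).
#' @return Cropped stack/image.
#' @export
crop_flyback <- function(stack, width_px = 64L) {
  fr <- as_frame_array(stack)
  nx <- dim(fr)[2]
  if (width_px < 0 || width_px >= nx)
    stop("width_px must be in [0, nx)")
  if (width_px == 0) return(stack)
  out <- fr[, (width_px + 1):nx, , drop = FALSE]
  if (is.matrix(stack)) return(out[, , 1])
  rewrap_stack(stack, out)
}

#' Centered square crop
#'
#' Extracts the centered `size` x `size` region (ties broken toward the
#' top-left), e.g. the 1920 x 1920 analysis region of a 2048-wide acquisition
#' after flyback cropping.
#'
#' @param image_or_stack Matrix or frame stack.
#' @param size Side length of the crop.
#' @return Cropped image/stack.
#' @export
center_crop <- function(image_or_stack, size) {
  fr <- as_frame_array(image_or_stack)
  ny <- dim(fr)[1]; nx <- dim(fr)[2]
  if (size > ny || size > nx) stop("crop size exceeds image dimensions")
  oy <- (ny - size) %/% 2L; ox <- (nx - size) %/% 2L
  out <- fr[(oy + 1):(oy + size), (ox + 1):(ox + size), , drop = FALSE]
  if (is.matrix(image_or_stack)) return(out[, , 1])
  rewrap_stack(image_or_stack, out)
}

# cross-correlation peak between two matrices via FFT, shifts restricted to
# +/- max_shift; returns c(dy, dx) moving `img` onto `ref`
xcorr_shift <- function(ref, img, max_shift, upsample = 10L) {
  ny <- nrow(ref); nx <- ncol(ref)
  a <- ref - mean(ref); b <- img - mean(img)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  # shift s means img displaced by s relative to ref; cc index k corresponds
  # to circular shift k-1
  sy <- c(0:(ny - 1)); sy[sy > ny / 2] <- sy[sy > ny / 2] - ny
  sx <- c(0:(nx - 1)); sx[sx > nx / 2] <- sx[sx > nx / 2] - nx
  ok <- outer(abs(sy) <= max_shift, abs(sx) <= max_shift, `&`)
  cc[!ok] <- -Inf
  k <- which.max(cc)
  iy <- (k - 1) %% ny + 1; ix <- (k - 1) %/% ny + 1
  d0 <- c(sy[iy], sx[ix])
  if (upsample <= 1) return(d0)
  # refine around the integer peak with a matrix-multiply DFT upsampling
  F <- stats::fft(a) * Conj(stats::fft(b))
  r <- 1.5  # search +/- 1.5 px around the integer peak
  n_up <- as.integer(ceiling(2 * r * upsample)) + 1L
  dy <- d0[1] + seq(-r, r, length.out = n_up)
  dx <- d0[2] + seq(-r, r, length.out = n_up)
  wy <- exp(2i * pi * outer(dy, ifelse(0:(ny - 1) > ny / 2,
                                       0:(ny - 1) - ny, 0:(ny - 1))) / ny)
  wx <- exp(2i * pi * outer(ifelse(0:(nx - 1) > nx / 2,
                                   0:(nx - 1) - nx, 0:(nx - 1)), dx) / nx)
  cc_up <- Re(wy %*% F %*% wx)
  k <- which.max(cc_up)
  iy <- (k - 1) %% n_up + 1; ix <- (k - 1) %/% n_up + 1
  d <- c(dy[iy], dx[ix])
  pmin(pmax(d, -max_shift), max_shift)
}

# xcorr_shift returns the correction; the user-facing table records the
# frame displacement, which is its negative
displacement_from_correction <- function(d) -d

#' Largest patch grid keeping patches at least 16 px
#'
#' Shrinks the standard 5 x 5 patch layout for small frames so that patch
#' cross-correlation stays well-posed; degenerates to whole-frame rigid
#' alignment for tiny frames.
#'
#' @param ny,nx Frame dimensions.
#' @param overlap_frac Patch overlap fraction.
#' @param gmax Maximum patches per axis.
#' @return Integer vector `c(rows, cols)`.
#' @export
default_patch_grid <- function(ny, nx, overlap_frac = 0.20, gmax = 5L) {
  g_for <- function(n) {
    g <- floor((n / 16 - overlap_frac) / (1 - overlap_frac))
    max(1L, min(gmax, as.integer(g)))
  }
  c(g_for(ny), g_for(nx))
}

# bilinear sampling of `img` at (y + dy, x + dx) with reflective padding
resample_shift <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx) + dy
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx) + dx
  reflect <- function(i, n) {
    i <- abs(i - 1) + 1
    over <- i > n
    i[over] <- 2 * n - i[over]
    pmin(pmax(i, 1), n)
  }
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  g <- function(yy, xx) img[cbind(as.vector(reflect(yy, ny)),
                                  as.vector(reflect(xx, nx)))]
  out <- g(y0, x0) * (1 - fy) * (1 - fx) + g(y0 + 1, x0) * fy * (1 - fx) +
    g(y0, x0 + 1) * (1 - fy) * fx + g(y0 + 1, x0 + 1) * fy * fx
  matrix(out, ny, nx)
}

#' Align a subframe stack by patch cross-correlation
#'
#' Implements the standard patch-based drift-correction contract: the image is
#' divided into a `patch_grid` of overlapping patches (default 5 x 5 with 20 %
#' overlap); for each frame and patch the translation maximising the
#' cross-correlation to the reference patch is found (upsampled
#' cross-correlation, factor 10, clipped to `max_shift`); a per-pixel shift
#' field is obtained by bilinear interpolation of the patch shifts and the
#' frame is resampled with reflective padding. With `patch_grid = c(1, 1)` the
#' procedure reduces to whole-frame rigid alignment. The reference frame is
#' never altered.
#'
#' @param stack Frame stack with at least 2 frames.
#' @param patch_grid Integer vector `c(rows, cols)` of patches.
#' @param overlap_frac Fractional overlap between neighbouring patches.
#' @param max_shift Maximum allowed shift per patch (px).
#' @param reference `"first"` (default) or `"mean"` (running mean of aligned
#'   frames).
#' @param upsample Subpixel refinement factor (1 = integer shifts only).
#' @return List with `aligned` (stack, same container type) and `shifts`
#'   (tibble: frame, patch_y, patch_x, center_y, center_x, dy, dx).
#' @export
align_frames <- function(stack, patch_grid = c(5L, 5L), overlap_frac = 0.20,
                         max_shift = 12, reference = c("first", "mean"),
                         upsample = 10L) {
  reference <- match.arg(reference)
  fr <- as_frame_array(stack)
  R <- dim(fr)[3]
  if (R < 2) stop("alignment requires at least 2 frames")
  ny <- dim(fr)[1]; nx <- dim(fr)[2]
  gy <- patch_grid[1]; gx <- patch_grid[2]
  # patch size such that gy patches with overlap_frac overlap tile the image
  py <- floor(ny / (gy - (gy - 1) * overlap_frac))
  px <- floor(nx / (gx - (gx - 1) * overlap_frac))
  if (py < 16 || px < 16) stop("patches smaller than 16 px; reduce patch_grid")
  step_y <- if (gy > 1) (ny - py) / (gy - 1) else 0
  step_x <- if (gx > 1) (nx - px) / (gx - 1) else 0
  y0 <- round(step_y * (seq_len(gy) - 1)) + 1
  x0 <- round(step_x * (seq_len(gx) - 1)) + 1
  cy <- y0 + (py - 1) / 2; cx <- x0 + (px - 1) / 2

  ref_img <- fr[, , 1]
  aligned <- fr
  shifts <- vector("list", R)
  shifts[[1]] <- tidyr::expand_grid(patch_y = seq_len(gy), patch_x = seq_len(gx)) |>
    dplyr::mutate(frame = 1L, center_y = cy[.data$patch_y],
                  center_x = cx[.data$patch_x], dy = 0, dx = 0)
  nref <- 1
  for (f in 2:R) {
    tab <- tidyr::expand_grid(patch_y = seq_len(gy), patch_x = seq_len(gx))
    d <- purrr::pmap(tab, function(patch_y, patch_x) {
      ys <- y0[patch_y]:(y0[patch_y] + py - 1)
      xs <- x0[patch_x]:(x0[patch_x] + px - 1)
      xcorr_shift(ref_img[ys, xs], fr[ys, xs, f], max_shift, upsample)
    })
    tab$frame <- f
    tab$center_y <- cy[tab$patch_y]; tab$center_x <- cx[tab$patch_x]
    # record the estimated frame displacement; the applied resampling offset
    # equals it (sampling at y + dy undoes a content shift of +dy)
    tab$dy <- vapply(d, function(z) displacement_from_correction(z)[1], 0)
    tab$dx <- vapply(d, function(z) displacement_from_correction(z)[2], 0)
    shifts[[f]] <- tab
    # per-pixel field: bilinear interpolation of patch shifts over centers
    dy_f <- interp_field(tab$dy, cy, cx, gy, gx, ny, nx)
    dx_f <- interp_field(tab$dx, cy, cx, gy, gx, ny, nx)
    aligned[, , f] <- resample_shift(fr[, , f], dy_f, dx_f)
    if (reference == "mean") {
      ref_img <- (ref_img * nref + aligned[, , f]) / (nref + 1)
      nref <- nref + 1
    }
  }
  list(aligned = rewrap_stack(stack, aligned),
       shifts = dplyr::bind_rows(shifts) |>
         dplyr::select("frame", "patch_y", "patch_x", "center_y", "center_x",
                       "dy", "dx"))
}

# bilinear interpolation of a gy x gx grid of values (at centers cy, cx) to a
# full ny x nx field, constant extrapolation beyond the outer centers
interp_field <- function(vals, cy, cx, gy, gx, ny, nx) {
  V <- matrix(vals, gy, gx, byrow = TRUE)  # expand_grid: patch_x fastest
  if (gy == 1 && gx == 1) return(matrix(V[1, 1], ny, nx))
  yq <- pmin(pmax(seq_len(ny), cy[1]), cy[gy])
  xq <- pmin(pmax(seq_len(nx), cx[1]), cx[gx])
  iy <- pmin(findInterval(yq, cy), gy - 1); iy <- pmax(iy, 1)
  ix <- pmin(findInterval(xq, cx), gx - 1); ix <- pmax(ix, 1)
  if (gy == 1) { iy <- rep(1, ny); ty <- rep(0, ny) }
  else ty <- (yq - cy[iy]) / (cy[iy + 1] - cy[iy])
  if (gx == 1) { ix <- rep(1, nx); tx <- rep(0, nx) }
  else tx <- (xq - cx[ix]) / (cx[ix + 1] - cx[ix])
  iy2 <- if (gy == 1) iy else iy + 1
  ix2 <- if (gx == 1) ix else ix + 1
  TY <- matrix(ty, ny, nx); TX <- matrix(tx, ny, nx, byrow = TRUE)
  IY <- matrix(iy, ny, nx); IX <- matrix(ix, ny, nx, byrow = TRUE)
  IY2 <- matrix(iy2, ny, nx); IX2 <- matrix(ix2, ny, nx, byrow = TRUE)
  v11 <- matrix(V[cbind(as.vector(IY), as.vector(IX))], ny, nx)
  v21 <- matrix(V[cbind(as.vector(IY2), as.vector(IX))], ny, nx)
  v12 <- matrix(V[cbind(as.vector(IY), as.vector(IX2))], ny, nx)
  v22 <- matrix(V[cbind(as.vector(IY2), as.vector(IX2))], ny, nx)
  v11 * (1 - TY) * (1 - TX) + v21 * TY * (1 - TX) +
    v12 * (1 - TY) * TX + v22 * TY * TX
}

#' Integrate a stack into a single image
#'
#' @param stack Frame stack.
#' @param method `"mean"` (default) or `"sum"`. Sums exceeding the signed
#'   16-bit range are clipped and flagged with attribute `"saturated"`.
#' @return Integrated image (matrix).
#' @export
integrate_frames <- function(stack, method = c("mean", "sum")) {
  method <- match.arg(method)
  fr <- as_frame_array(stack)
  if (length(fr) == 0) stop("empty stack")
  out <- if (method == "mean") rowMeans(fr, dims = 2) else rowSums(fr, dims = 2)
  if (method == "sum") {
    sat <- out > 32767 | out < -32768
    out <- pmin(pmax(out, -32768), 32767)
    attr(out, "saturated") <- any(sat)
  }
  out
}

#' Box mean filter
#'
#' Pixel-wise mean over an odd `kernel` x `kernel` neighbourhood with
#' reflective edge handling; the 3 x 3 default is the smoothing applied before
#' segmentation.
#'
#' @param image Numeric matrix.
#' @param kernel Odd kernel size (>= 1).
#' @return Filtered matrix.
#' @export
mean_filter <- function(image, kernel = 3L) {
  stopifnot(is.matrix(image))
  if (kernel %% 2 == 0) stop("kernel must be odd")
  if (kernel == 1) return(image)
  k <- rep(1 / kernel, kernel)
  cpp_sepconv(image, k, k)
}
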
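# Small image kernels shared by the processing and QC modules. All operate on
# plain numeric matrices indexed [row = y, col = x] and use reflective
# (symmetric) edge padding, which keeps left-edge analyses (flyback estimation)
# free of wrap-around contamination.

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(image, sigma) {
  stopifnot(is.matrix(image), sigma > 0)
  k <- gaussian_kernel_1d(sigma)
  cpp_sepconv(image, k, k)
}

# 3x3 Sobel gradient magnitude
sobel_magnitude <- function(image) {
  stopifnot(is.matrix(image))
  smooth <- c(1, 2, 1); deriv <- c(-1, 0, 1)
  gx <- cpp_sepconv(image, smooth, deriv)
  gy <- cpp_sepconv(image, deriv, smooth)
  sqrt(gx^2 + gy^2)
}

#' Automatic bimodal (Otsu) threshold
#'
#' Picks the threshold maximising between-class variance over a 256-bin
#' histogram of the input values. Used as the default automatic threshold for
#' edge detection and simple segmentation.
#'
#' @param x Numeric vector or matrix.
#' @param levels Number of histogram bins.
#' @return Threshold value on the scale of `x`; values strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values to threshold")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  breaks <- seq(lo, hi, length.out = levels + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Label connected components (8-connectivity)
#'
#' @param mask Logical or numeric matrix; non-zero/`TRUE` pixels are
#'   foreground.
#' @return Integer matrix of component labels `1..N` (0 = background), labels
#'   ordered by each component's first pixel in row-major order.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- if (is.logical(mask)) mask else mask > 0
  storage.mode(m) <- "logical"
  cpp_label8(m)
}
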
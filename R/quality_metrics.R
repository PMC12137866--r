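# Image-quality measures: histogram charging metric, flyback-extent estimator,
# simple segmentation, complexity scoring, reference normalisation, and a
# streak-anisotropy index.

#' Histogram mean and charging deviation
#'
#' An artefact-free 8-bit image with well-set detector gain has a pixel
#' histogram centred on the mid-range grey level 127; accumulation of charge
#' produces extreme dark or bright pixels that pull the mean away from it.
#' The charging deviation is `|mean - 127|`.
#'
#' @param image Numeric matrix with values in 0..255 (convert first via
#'   [convert_to_uint8()] if needed).
#' @return Tibble with columns `histogram_mean` and `charging_deviation`.
#' @export
histogram_mean <- function(image) {
  v <- as.numeric(image)
  if (!length(v)) stop("empty image")
  m <- mean(v)
  tibble::tibble(histogram_mean = m, charging_deviation = abs(m - 127))
}

#' Estimate the spatial extent of flyback distortions
#'
#' Without a settling (flyback) delay the probe is still moving when each line
#' starts, distorting a left-hand band of every frame. Per frame, the image is
#' Gaussian-blurred (`sigma` = 7 px by default), a 3 x 3 Sobel gradient
#' magnitude is computed and binarised (automatic bimodal threshold by
#' default); within the given ROI band, the rightmost column containing a
#' foreground pixel is taken as that frame's distortion extent. Frames whose
#' edge detection finds no foreground contribute nothing; the per-frame values
#' are aggregated by their median (robust to the occasional failed detection)
#' or mean.
#'
#' @param frames Frame stack or single image.
#' @param roi ROI rectangle `c(x, y, w, h)` in 0-based pixel coordinates,
#'   a band near the left edge; the same ROI is applied to every frame.
#' @param sigma Gaussian blur width in pixels.
#' @param threshold_method `"otsu"` (automatic bimodal) or a fixed numeric
#'   threshold on the gradient magnitude.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return Tibble with `flyback_extent_px` (columns from the left edge),
#'   `n_frames_used`, and `warning_no_edge` (`TRUE` when no frame produced a
#'   detectable edge; the extent is then 0).
#' @export
estimate_flyback_extent <- function(frames, roi, sigma = 7,
                                    threshold_method = "otsu",
                                    aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  fr <- as_frame_array(frames)
  ny <- dim(fr)[1]; nx <- dim(fr)[2]
  stopifnot(length(roi) == 4)
  x0 <- roi[1]; y0 <- roi[2]; w <- roi[3]; h <- roi[4]
  if (x0 < 0 || y0 < 0 || x0 + w > nx || y0 + h > ny || w < 1 || h < 1)
    stop("roi outside the image")
  xs <- (x0 + 1):(x0 + w); ys <- (y0 + 1):(y0 + h)
  per_frame <- numeric(0)
  for (f in seq_len(dim(fr)[3])) {
    g <- sobel_magnitude(gaussian_blur(fr[, , f], sigma))[ys, xs, drop = FALSE]
    thr <- if (identical(threshold_method, "otsu")) otsu_threshold(g)
           else as.numeric(threshold_method)
    fg <- g > thr
    if (!any(fg)) next
    per_frame <- c(per_frame, x0 + max(which(colSums(fg) > 0)))
  }
  if (!length(per_frame))
    return(tibble::tibble(flyback_extent_px = 0, n_frames_used = 0L,
                          warning_no_edge = TRUE))
  est <- if (aggregate == "median") stats::median(per_frame) else mean(per_frame)
  tibble::tibble(flyback_extent_px = est, n_frames_used = length(per_frame),
                 warning_no_edge = FALSE)
}

#' Simple intensity segmentation
#'
#' A deliberately plain reference segmenter standing in for external mask
#' generators: 3 x 3 mean filter, automatic bimodal threshold, 8-connected
#' components, with components smaller than `min_size` pixels removed.
#'
#' @param image Grayscale matrix.
#' @param min_size Minimum component size in pixels.
#' @return Integer label mask (0 = background, labels 1..N compacted).
#' @export
segment_simple <- function(image, min_size = 16L) {
  stopifnot(is.matrix(image))
  sm <- mean_filter(image, 3L)
  if (max(sm) <= min(sm)) return(matrix(0L, nrow(image), ncol(image)))
  lab <- label_components(sm > otsu_threshold(sm))
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= min_size)
  if (!length(keep)) return(matrix(0L, nrow(image), ncol(image)))
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

#' Object count and shape-complexity score of a label mask
#'
#' For each labelled component the complexity is the squared perimeter divided
#' by the area; component scores are summed into the total. The perimeter is
#' the crack-edge (boundary pixel-edge) length -- the number of pixel edges
#' between the component and anything else (including the image border) -- so
#' an axis-aligned `n` x `n` square scores exactly `(4n)^2 / n^2 = 16`
#' regardless of size. Intricate, non-blob shapes score higher; segmentations
#' corrupted by charging artefacts typically lose both objects and complexity.
#'
#' @param label_mask Non-negative integer matrix (0 = background).
#' @return Tibble with `n_objects`, `total_complexity`, and a nested
#'   `per_object` tibble (label, area, perimeter, complexity).
#' @export
complexity_score <- function(label_mask) {
  stopifnot(is.matrix(label_mask))
  m <- label_mask
  if (any(m < 0)) stop("labels must be non-negative")
  labs <- sort(unique(as.integer(m[m > 0])))
  if (!length(labs))
    return(tibble::tibble(n_objects = 0L, total_complexity = 0,
                          per_object = list(tibble::tibble())))
  ny <- nrow(m); nx <- ncol(m)
  area <- tabulate(m[m > 0], nbins = max(labs))[labs]
  pad <- matrix(0L, ny + 2L, nx + 2L)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  ctr <- pad[2:(ny + 1), 2:(nx + 1)]
  per <- numeric(length(labs))
  for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- pad[2:(ny + 1) + sh[1], 2:(nx + 1) + sh[2]]
    diff_sel <- ctr > 0 & nb != ctr
    if (any(diff_sel)) {
      cnt <- tabulate(ctr[diff_sel], nbins = max(labs))[labs]
      per <- per + cnt
    }
  }
  cx <- per^2 / area
  tibble::tibble(n_objects = length(labs), total_complexity = sum(cx),
                 per_object = list(tibble::tibble(label = labs, area = area,
                                                  perimeter = per,
                                                  complexity = cx)))
}

#' Normalise per-condition metrics to a reference condition
#'
#' Because each dataset has its own biological content, object counts and
#' complexity scores are compared as ratios to a reference acquisition
#' condition (interleaved frame integration in the strategy comparison); the
#' reference ratio is 1 by construction.
#'
#' @param metric_by_condition Tibble/data frame with a `condition` column and
#'   one metric column (named by `metric`).
#' @param reference_condition Value of `condition` to normalise against.
#' @param metric Name of the metric column (default: the first non-condition
#'   column).
#' @return Input tibble with an added `ratio` column.
#' @export
normalize_to_reference <- function(metric_by_condition, reference_condition,
                                   metric = NULL) {
  tb <- tibble::as_tibble(metric_by_condition)
  if (is.null(metric)) metric <- setdiff(names(tb), "condition")[1]
  ref <- tb[[metric]][tb$condition == reference_condition]
  if (!length(ref)) stop("reference condition not present")
  if (length(ref) > 1) ref <- mean(ref)
  if (!is.finite(ref) || ref == 0) stop("reference metric is zero or missing")
  dplyr::mutate(tb, ratio = .data[[metric]] / ref)
}

#' Streak-anisotropy index
#'
#' Ratio of the mean absolute difference between vertically adjacent pixels to
#' that between horizontally adjacent pixels. Isotropic texture gives ~1;
#' values well above 1 indicate horizontal streaking -- the signature of
#' line-integration charging artefacts in the fast scanning direction.
#' Transposing the image inverts the index.
#'
#' @param image Numeric matrix with at least 2 rows and 2 columns.
#' @return A single number (may be `Inf` if rows are perfectly constant).
#' @export
anisotropy_index <- function(image) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 2 || ncol(image) < 2)
    stop("image must be at least 2 x 2")
  dv <- mean(abs(diff(image)))        # vertical neighbours (across rows)
  dh <- mean(abs(t(diff(t(image)))))  # horizontal neighbours (along rows)
  if (dh == 0) return(Inf)
  dv / dh
}

#' Full QC report for one image
#'
#' Convenience wrapper bundling the quality metrics for a processed
#' (8-bit, cropped, integrated) image into one row.
#'
#' @param image Numeric matrix in 0..255.
#' @param condition Label describing the acquisition condition.
#' @param mask Optional label mask; when missing, [segment_simple()] is used.
#' @param min_size Minimum object size for the fallback segmentation.
#' @param flyback_extent_px Optional flyback extent to record (from
#'   [estimate_flyback_extent()] on the raw frames).
#' @return One-row tibble: condition, histogram_mean, charging_deviation,
#'   anisotropy_index, flyback_extent_px, n_objects, complexity_score, and an
#'   input-digest `provenance` string.
#' @export
qc_report <- function(image, condition = "unlabelled", mask = NULL,
                      min_size = 16L, flyback_extent_px = NA_real_) {
  hm <- histogram_mean(image)
  if (is.null(mask)) mask <- segment_simple(image, min_size = min_size)
  cs <- complexity_score(mask)
  digest <- sprintf("%dx%d:sum%.6g", nrow(image), ncol(image), sum(image))
  tibble::tibble(condition = condition,
                 histogram_mean = hm$histogram_mean,
                 charging_deviation = hm$charging_deviation,
                 anisotropy_index = anisotropy_index(image),
                 flyback_extent_px = flyback_extent_px,
                 n_objects = cs$n_objects,
                 complexity_score = cs$total_complexity,
                 provenance = digest)
}
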
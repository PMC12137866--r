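# Multi-page TIFF input/output. The `tiff` package stores samples scaled to
# [0, 1]; counts and maps are therefore encoded to that range with the exact
# decoding recorded in a JSON side-car, which also carries acquisition
# metadata.

#' Write / read a subframe stack as multi-page TIFF
#'
#' Frames (signed 16-bit counts) are stored as 16-bit TIFF pages with the
#' fixed affine encoding `(v + 32768) / 65535`, which round-trips integer
#' counts exactly; metadata (seed, parameters, drift trajectory, pattern
#' descriptor) goes to `<path>.json`.
#'
#' @param stack A `subframe_stack` or frame array.
#' @param path Output TIFF path.
#' @return `path`, invisibly (`read_stack_tiff()` returns a
#'   `subframe_stack`).
#' @export
write_stack_tiff <- function(stack, path) {
  fr <- as_frame_array(stack)
  pages <- lapply(seq_len(dim(fr)[3]),
                  function(f) (pmin(pmax(fr[, , f], -32768), 32767) + 32768) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  meta <- if (inherits(stack, "subframe_stack")) stack$metadata else list()
  meta$encoding <- "v = round(x * 65535) - 32768"
  meta$params <- if (!is.null(meta$params)) unclass(meta$params) else NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  fr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) fr[, , f] <- round(pages[[f]] * 65535) - 32768
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  if (!is.null(meta$params)) {
    pars <- meta$params[!vapply(meta$params, is.null, TRUE)]
    meta$params <- do.call(sim_params, pars)
  }
  structure(list(frames = fr, metadata = meta), class = "subframe_stack")
}

#' Write / read a phantom as multi-page TIFF
#'
#' Three pages: yield (16-bit, in \[0, 1\]), tau (16-bit,
#' `log10(tau_ns) / 15`, with infinite tau encoded as 1), label (16-bit
#' integer). Structure metadata goes to `<path>.json`. The 16-bit encoding
#' quantises yield to ~1.5e-5 and tau to ~0.05 % relative.
#'
#' @param phantom A `phantom`.
#' @param path Output TIFF path.
#' @return `path` invisibly (`read_phantom_tiff()` returns a `phantom`).
#' @export
write_phantom_tiff <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  tau_enc <- ifelse(is.finite(phantom$tau_map),
                    pmin(log10(pmax(phantom$tau_map, 1)) / 15, 0.999), 1)
  pages <- list(phantom$yield_map, tau_enc, phantom$label_map / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  meta <- list(nx = phantom$nx, ny = phantom$ny, pixel_nm = phantom$pixel_nm,
               preset = phantom$preset, seed = phantom$seed,
               structures = phantom$structures,
               params = phantom$params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_phantom_tiff
#' @export
read_phantom_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == 3)
  yield <- pages[[1]]
  tau_enc <- pages[[2]]
  tau <- ifelse(tau_enc >= 1 - 1e-6, Inf, 10^(tau_enc * 15))
  label <- matrix(as.integer(round(pages[[3]] * 65535)), nrow(yield))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(nx = ncol(yield), ny = nrow(yield), yield_map = yield,
                 tau_map = tau, label_map = label,
                 pixel_nm = meta$pixel_nm %||% 6.34,
                 preset = meta$preset %||% "loaded",
                 seed = meta$seed %||% NA_integer_,
                 params = meta$params,
                 structures = tibble::as_tibble(meta$structures)),
            class = "phantom")
}

#' Write / read a label mask as single-page 16-bit TIFF
#' @param mask Integer label matrix.
#' @param path File path.
#' @return `path` invisibly; `read_mask_tiff()` returns an integer matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  p <- tiff::readTIFF(path)
  matrix(as.integer(round(p * 65535)), nrow(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
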
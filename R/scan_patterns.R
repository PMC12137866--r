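#' @useDynLib leapscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

new_scan_pattern <- function(visits, nx, ny, dwell_ns, reps, mode, integration,
                             skip_x = 0L, skip_y = 0L, flyback_delay_ns = 0,
                             interframe_pause_ns = 0) {
  structure(
    list(visits = visits, nx = as.integer(nx), ny = as.integer(ny),
         dwell_ns = dwell_ns, reps = as.integer(reps), mode = mode,
         integration = integration, skip_x = as.integer(skip_x),
         skip_y = as.integer(skip_y), flyback_delay_ns = flyback_delay_ns,
         interframe_pause_ns = interframe_pause_ns),
    class = "scan_pattern")
}

#' @export
print.scan_pattern <- function(x, ...) {
  cat(sprintf("<scan_pattern> %s / %s integration, %d x %d px, dwell %g ns, %d rep(s)\n",
              x$mode, x$integration, x$nx, x$ny, x$dwell_ns, x$reps))
  if (x$mode == "interleaved")
    cat(sprintf("  skip: %d px in x, %d px in y (stride %d, %d)\n",
                x$skip_x, x$skip_y, x$skip_x + 1L, x$skip_y + 1L))
  cat(sprintf("  %d visits over %.3f ms\n", nrow(x$visits),
              (max(x$visits$t_start_ns) + x$dwell_ns) / 1e6))
  invisible(x)
}

#' Generate a timed raster scan pattern
#'
#' Builds the conventional SEM scan sequence: each line is swept along the fast
#' (x) axis left to right, lines advance along the slow (y) axis. With line
#' integration each line is repeated `reps` times consecutively before moving
#' to the next line, and a flyback settling delay is inserted before every line
#' pass. With frame integration the full frame is scanned and then repeated
#' `reps` times with no flyback delay, so the interval between x-neighbours is
#' the dwell time and between y-neighbours is `nx * dwell_ns`.
#'
#' @param nx,ny Pixel counts along the fast (x) and slow (y) axes.
#' @param dwell_ns Dwell time per pixel in nanoseconds.
#' @param reps Number of repetitions (line passes or frames).
#' @param integration `"frame"` or `"line"`.
#' @param flyback_delay_ns Settling delay inserted before each line pass; only
#'   meaningful (and only allowed) for line integration.
#' @return A `scan_pattern` object whose `visits` field is a tibble with
#'   columns `x`, `y` (0-based pixel coordinates) and `t_start_ns` (absolute
#'   visit start time).
#' @examples
#' p <- make_raster_pattern(7, 7, dwell_ns = 100, reps = 1)
#' head(p$visits)
#' @export
make_raster_pattern <- function(nx, ny, dwell_ns, reps = 1L,
                                integration = c("frame", "line"),
                                flyback_delay_ns = 0) {
  integration <- match.arg(integration)
  stopifnot(nx >= 1, ny >= 1, reps >= 1, dwell_ns > 0, flyback_delay_ns >= 0)
  if (integration == "frame" && flyback_delay_ns > 0)
    stop("flyback_delay_ns must be 0 for frame integration (no flyback delay is applied there)")
  nx <- as.integer(nx); ny <- as.integer(ny); reps <- as.integer(reps)
  if (integration == "frame") {
    x <- rep(rep(0:(nx - 1L), times = ny), times = reps)
    y <- rep(rep(0:(ny - 1L), each = nx), times = reps)
    t <- (seq_along(x) - 1) * dwell_ns
  } else {
    # line integration: for each y, reps passes of the line, flyback before each pass
    x <- rep(0:(nx - 1L), times = ny * reps)
    y <- rep(0:(ny - 1L), each = nx * reps)
    pass <- rep(seq_len(ny * reps) - 1, each = nx)    # global line-pass index
    t <- (pass + 1) * flyback_delay_ns + pass * nx * dwell_ns +
      rep(0:(nx - 1L), times = ny * reps) * dwell_ns
  }
  visits <- tibble::tibble(x = x, y = y, t_start_ns = t)
  new_scan_pattern(visits, nx, ny, dwell_ns, reps, "raster", integration,
                   flyback_delay_ns = flyback_delay_ns)
}

#' Generate a timed interleaved ("leapfrog") scan pattern
#'
#' The probe visits a sub-lattice of the pixel grid with stride
#' `skip_x + 1` along x and `skip_y + 1` along y (skipping `skip_x` pixels
#' between visited positions), returning to the starting x coordinate at the
#' end of each sub-lattice line. Once a pass is complete the next sub-lattice
#' offset is visited, offsets enumerated x-major, until every pixel in the
#' grid has been visited exactly once; the whole frame is then repeated
#' `reps` times with an optional beam-parked pause between frames. Neighbouring
#' pixels end up in different passes, so the time between visits of nearby
#' positions is much longer than for a raster scan, giving deposited charge
#' time to dissipate.
#'
#' @inheritParams make_raster_pattern
#' @param skip_x,skip_y Number of pixels skipped between visited positions
#'   along x and y. `skip_x = skip_y = 0` degenerates to raster frame
#'   integration.
#' @param interframe_pause_ns Pause between successive frames (beam parked).
#' @return A `scan_pattern` (frame integration).
#' @examples
#' p <- make_interleaved_pattern(7, 7, skip_x = 2, skip_y = 2, dwell_ns = 100)
#' head(p$visits, 4)  # (0,0), (3,0), (6,0), (0,3)
#' @export
make_interleaved_pattern <- function(nx, ny, skip_x = 2L, skip_y = 2L,
                                     dwell_ns = 100, reps = 1L,
                                     interframe_pause_ns = 0) {
  stopifnot(nx >= 1, ny >= 1, reps >= 1, dwell_ns > 0,
            skip_x >= 0, skip_y >= 0, interframe_pause_ns >= 0)
  if (skip_x >= nx || skip_y >= ny)
    stop("skip must be smaller than the grid dimension")
  nx <- as.integer(nx); ny <- as.integer(ny); reps <- as.integer(reps)
  sx <- as.integer(skip_x) + 1L; sy <- as.integer(skip_y) + 1L
  offs <- expand.grid(ox = 0:(sx - 1L), oy = 0:(sy - 1L))  # x-major offset order
  one <- purrr::pmap(offs, function(ox, oy) {
    xs <- seq.int(ox, nx - 1L, by = sx)
    ys <- seq.int(oy, ny - 1L, by = sy)
    if (!length(xs) || !length(ys)) return(NULL)
    list(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
  })
  x <- unlist(lapply(one, `[[`, "x")); y <- unlist(lapply(one, `[[`, "y"))
  npx <- length(x)
  frame_time <- npx * dwell_ns
  x <- rep(x, times = reps); y <- rep(y, times = reps)
  f <- rep(seq_len(reps) - 1, each = npx)
  t <- f * (frame_time + interframe_pause_ns) +
    rep((seq_len(npx) - 1) * dwell_ns, times = reps)
  visits <- tibble::tibble(x = as.integer(x), y = as.integer(y), t_start_ns = t)
  new_scan_pattern(visits, nx, ny, dwell_ns, reps, "interleaved", "frame",
                   skip_x = skip_x, skip_y = skip_y,
                   interframe_pause_ns = interframe_pause_ns)
}

#' Validate a scan pattern
#'
#' Checks the structural invariants of a visit sequence: coordinates within
#' the grid, every pixel visited exactly once per repetition, and strictly
#' increasing timestamps. Returns a tibble of findings; a valid pattern yields
#' an empty tibble.
#'
#' @param pattern A `scan_pattern`.
#' @return A tibble with columns `check`, `detail` (empty when valid).
#' @export
validate_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "scan_pattern"))
  v <- pattern$visits
  out <- list()
  bad <- v$x < 0 | v$x >= pattern$nx | v$y < 0 | v$y >= pattern$ny
  if (any(bad))
    out <- c(out, list(tibble::tibble(
      check = "bounds",
      detail = sprintf("visit %d at (%d, %d) outside %d x %d grid",
                       which(bad), v$x[bad], v$y[bad], pattern$nx, pattern$ny))))
  if (any(diff(v$t_start_ns) <= 0))
    out <- c(out, list(tibble::tibble(
      check = "time",
      detail = sprintf("non-increasing timestamp at visit %d",
                       which(diff(v$t_start_ns) <= 0) + 1L))))
  npx <- pattern$nx * pattern$ny
  frame <- if (pattern$integration == "frame" && nrow(v) == npx * pattern$reps)
    rep(seq_len(pattern$reps), each = npx) else rep(1L, nrow(v))
  counts <- table(factor(v$x + pattern$nx * v$y, levels = 0:(npx - 1L)))
  full <- as.integer(counts)
  want <- nrow(v) / npx
  if (any(full != want)) {
    idx <- which(full != want) - 1L
    out <- c(out, list(tibble::tibble(
      check = "coverage",
      detail = sprintf("pixel (%d, %d) visited %d times, expected %g",
                       idx %% pattern$nx, idx %/% pattern$nx, full[full != want], want))))
  }
  if (pattern$integration == "frame" && nrow(v) == npx * pattern$reps) {
    for (r in seq_len(pattern$reps)) {
      vi <- v[frame == r, ]
      key <- vi$x + pattern$nx * vi$y
      dup <- unique(key[duplicated(key)])
      if (length(dup))
        out <- c(out, list(tibble::tibble(
          check = "duplicate",
          detail = sprintf("repetition %d: pixel (%d, %d) visited more than once",
                           r, dup %% pattern$nx, dup %/% pattern$nx))))
      mis <- setdiff(0:(npx - 1L), key)
      if (length(mis))
        out <- c(out, list(tibble::tibble(
          check = "missing",
          detail = sprintf("repetition %d: pixel (%d, %d) never visited",
                           r, mis %% pattern$nx, mis %/% pattern$nx))))
    }
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(check = character(), detail = character())
}

#' Minimum revisit interval between nearby pixels
#'
#' For every pair of distinct pixels within a Chebyshev distance `radius` of
#' each other, takes the minimal absolute difference of their visit times and
#' returns the minimum over all such pairs. For multi-repetition patterns the
#' interval is computed within each frame and minimised over frames. This is
#' the quantity an interleaved pattern is designed to increase: a raster frame
#' scan has a minimum neighbour interval equal to the dwell time, whereas
#' skipping pixels forces neighbours into different passes.
#'
#' @param pattern A valid `scan_pattern`.
#' @param chebyshev_radius Neighbourhood radius (>= 1) in pixels.
#' @return Minimum interval in nanoseconds.
#' @export
min_neighbour_interval <- function(pattern, chebyshev_radius = 1L) {
  stopifnot(inherits(pattern, "scan_pattern"), chebyshev_radius >= 1)
  r <- as.integer(chebyshev_radius)
  nx <- pattern$nx; ny <- pattern$ny
  if (r >= max(nx, ny))
    stop("chebyshev_radius is larger than the grid extent")
  if (nx * ny < 2L) stop("grid has no distinct pixel pairs")
  v <- pattern$visits
  npx <- nx * ny
  # per-frame visit-time matrices; for line integration, pass r over line y is
  # assigned to frame r so the interval is measured within one full sweep
  if (pattern$integration == "frame") {
    frame_of <- rep(seq_len(pattern$reps), each = npx)
  } else {
    frame_of <- (seq_len(nrow(v)) - 1L) %/% nx %% pattern$reps + 1L
  }
  best <- Inf
  for (f in seq_len(pattern$reps)) {
    vi <- v[frame_of == f, ]
    if (nrow(vi) != npx) next
    Tm <- matrix(NA_real_, ny, nx)
    Tm[cbind(vi$y + 1L, vi$x + 1L)] <- vi$t_start_ns
    # each unordered pixel-pair offset once: dy > 0 (any dx), or dy == 0, dx > 0
    for (dy in 0:r) for (dx in -r:r) {
      if (dy == 0 && dx <= 0) next
      ys <- seq_len(ny - dy); xs <- seq_len(nx - abs(dx))
      if (!length(ys) || !length(xs)) next
      a <- Tm[ys, if (dx >= 0) xs else xs + abs(dx), drop = FALSE]
      b <- Tm[ys + dy, if (dx >= 0) xs + dx else xs, drop = FALSE]
      d <- min(abs(a - b))
      if (d < best) best <- d
    }
  }
  best
}

#' Electron fluence delivered by a dwell/repetition schedule
#'
#' Fluence (electrons per square angstrom) is
#' `current * dwell * reps / (e * pixel_area)` with the pixel area in
#' angstrom squared. The three canonical schedules at 6.3 pA and 6.34 nm
#' pixels -- 100 ns x 100, 500 ns x 20 and 1000 ns x 10 repetitions -- all
#' deliver the same fluence of about 0.1 e-/A2, which is what makes strategy
#' comparisons at matched dose meaningful.
#'
#' @param current_pA Beam current in picoamperes.
#' @param dwell_ns Dwell time in nanoseconds.
#' @param reps Number of repetitions.
#' @param pixel_nm Pixel edge length in nanometres.
#' @return Fluence in electrons per square angstrom.
#' @examples
#' compute_fluence(6.3, 100, 100, 6.34)  # ~0.098 e-/A2
#' @export
compute_fluence <- function(current_pA, dwell_ns, reps, pixel_nm) {
  stopifnot(current_pA >= 0, dwell_ns > 0, reps > 0, pixel_nm > 0)
  e <- 1.602176634e-19
  # dwell * reps first: fluence-matched schedules give bit-identical results
  charge <- current_pA * (dwell_ns * reps) * 1e-21   # pA * ns -> coulombs
  area_A2 <- (10 * pixel_nm)^2
  charge / e / area_A2
}

#' Electrons deposited per visit
#' @inheritParams compute_fluence
#' @return Electrons per single dwell.
#' @export
electrons_per_visit <- function(current_pA, dwell_ns) {
  stopifnot(current_pA >= 0, dwell_ns > 0)
  current_pA * 1e-12 * dwell_ns * 1e-9 / 1.602176634e-19
}

#' Export / import a scan pattern as a coordinate text file
#'
#' Writes one visit per line as `"x y"` (0-based integers, single space) in
#' visit order for a single frame -- the format consumed by programmable
#' external scan engines. Repetitions, dwell and grid size travel in a `#`
#' header line which can be suppressed for engines that reject comments.
#'
#' @param pattern A valid `scan_pattern`.
#' @param destination File path.
#' @param header Emit the `#` metadata header line (default `TRUE`).
#' @return `destination`, invisibly.
#' @export
export_pattern_text <- function(pattern, destination, header = TRUE) {
  stopifnot(inherits(pattern, "scan_pattern"))
  npx <- pattern$nx * pattern$ny
  v <- utils::head(pattern$visits, npx)  # one frame only
  lines <- character(0)
  if (header)
    lines <- sprintf("# leapscan nx=%d ny=%d dwell_ns=%g reps=%d mode=%s integration=%s skip_x=%d skip_y=%d flyback_delay_ns=%g interframe_pause_ns=%g",
                     pattern$nx, pattern$ny, pattern$dwell_ns, pattern$reps,
                     pattern$mode, pattern$integration, pattern$skip_x,
                     pattern$skip_y, pattern$flyback_delay_ns,
                     pattern$interframe_pause_ns)
  lines <- c(lines, sprintf("%d %d", v$x, v$y))
  writeLines(lines, destination)
  invisible(destination)
}

#' @rdname export_pattern_text
#' @param source File path to read.
#' @param metadata Optional named list overriding/supplying pattern metadata
#'   (`nx`, `ny`, `dwell_ns`, `reps`, ...); values from a `#` header are used
#'   otherwise.
#' @export
import_pattern_text <- function(source, metadata = list()) {
  lines <- readLines(source)
  meta <- list(dwell_ns = 100, reps = 1L, mode = "raster", integration = "frame",
               skip_x = 0L, skip_y = 0L, flyback_delay_ns = 0,
               interframe_pause_ns = 0)
  hdr <- grepl("^#", lines)
  if (any(hdr)) {
    kv <- regmatches(lines[hdr][1], gregexpr("[a-z_]+=[^ ]+", lines[hdr][1]))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      val <- suppressWarnings(as.numeric(parts[2]))
      meta[[parts[1]]] <- if (is.na(val)) parts[2] else val
    }
  }
  meta[names(metadata)] <- metadata
  body <- lines[!hdr & nzchar(trimws(lines))]
  m <- regexec("^([0-9]+) ([0-9]+)$", body)
  ok <- vapply(regmatches(body, m), length, 1L) == 3L
  if (any(!ok))
    stop(sprintf("malformed coordinate line %d: '%s'",
                 which(!ok)[1], body[which(!ok)[1]]))
  x <- as.integer(sub(" .*", "", body))
  y <- as.integer(sub(".* ", "", body))
  nx <- if (!is.null(meta$nx)) as.integer(meta$nx) else max(x) + 1L
  ny <- if (!is.null(meta$ny)) as.integer(meta$ny) else max(y) + 1L
  if (any(x < 0 | x >= nx | y < 0 | y >= ny))
    stop(sprintf("coordinate out of bounds on line %d",
                 which(x < 0 | x >= nx | y < 0 | y >= ny)[1]))
  reps <- as.integer(meta$reps)
  dwell <- meta$dwell_ns
  npx <- length(x)
  frame_time <- npx * dwell
  pause <- meta$interframe_pause_ns
  xs <- rep(x, times = reps); ys <- rep(y, times = reps)
  f <- rep(seq_len(reps) - 1, each = npx)
  t <- f * (frame_time + pause) + rep((seq_len(npx) - 1) * dwell, times = reps)
  visits <- tibble::tibble(x = xs, y = ys, t_start_ns = t)
  new_scan_pattern(visits, nx, ny, dwell, reps, as.character(meta$mode),
                   as.character(meta$integration),
                   skip_x = meta$skip_x, skip_y = meta$skip_y,
                   flyback_delay_ns = meta$flyback_delay_ns,
                   interframe_pause_ns = pause)
}
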
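# Charge deposition / dissipation / detection model.
#
# The qualitative picture -- charge deposited at each probe visit dissipating
# uniformly in all directions and draining to ground -- is formalised as
# linear isotropic diffusion plus a per-pixel exponential leak:
#
#   dC/dt = D * laplacian(C) - C / tau(x, y)
#
# integrated with explicit 5-point-stencil sub-steps (D * dt_sub <= 0.25 px^2,
# zero-flux boundaries) interleaved with the exact proportional leak. Detected
# signal at a visit is the secondary-electron yield attenuated exponentially
# by the locally smoothed charge (dark streaks and patches), with an optional
# discharge model for bright spikes.

#' Simulation parameters for the charge model
#'
#' @param q0_electrons Charge deposited per visit, in electrons. Default
#'   `NULL`: derived from `current_pA` and the pattern dwell at simulation
#'   time (`current * dwell / e`).
#' @param current_pA Beam current used to derive `q0_electrons` (default
#'   6.3 pA).
#' @param probe_fwhm_nm Probe width; recorded as metadata. Deposition is
#'   point-wise because the default probe (2 nm FWHM) is narrower than the
#'   6.34 nm pixel.
#' @param D_px2_per_ns Lateral charge diffusivity in px^2/ns.
#' @param alpha Signal attenuation per unit local charge (per electron).
#' @param sigma_local_px Gaussian width of the charge-influence smoothing used
#'   in detection.
#' @param noise_std Additive detector noise standard deviation (counts).
#' @param detector_gain,detector_offset Linear mapping of yield to 16-bit
#'   counts.
#' @param batch_visits Dissipation-update batching interval K (default
#'   `NULL` = one scan line, i.e. `nx`). Batching is a numerical convenience
#'   with exact elapsed-time accounting, not a model change.
#' @param discharge_enabled,discharge_threshold,discharge_gain Optional
#'   bright-spike model: when the smoothed local charge exceeds the threshold
#'   a bright spike is emitted and local charge is reset.
#' @param drift_step_px Per-frame random-walk drift standard deviation
#'   (integer pixel shifts of specimen and charge jointly).
#' @param burnspot_enabled Deposit charge at the parked beam position during
#'   inter-frame pauses.
#' @return A `sim_params` list.
#' @export
sim_params <- function(q0_electrons = NULL, current_pA = 6.3,
                       probe_fwhm_nm = 2, D_px2_per_ns = 5e-6, alpha = 0.5,
                       sigma_local_px = 8, noise_std = 150,
                       detector_gain = 12000, detector_offset = 2000,
                       batch_visits = NULL, discharge_enabled = FALSE,
                       discharge_threshold = 50, discharge_gain = 8000,
                       drift_step_px = 0, burnspot_enabled = FALSE) {
  p <- list(q0_electrons = q0_electrons, current_pA = current_pA,
            probe_fwhm_nm = probe_fwhm_nm, D_px2_per_ns = D_px2_per_ns,
            alpha = alpha, sigma_local_px = sigma_local_px,
            noise_std = noise_std, detector_gain = detector_gain,
            detector_offset = detector_offset, batch_visits = batch_visits,
            discharge_enabled = discharge_enabled,
            discharge_threshold = discharge_threshold,
            discharge_gain = discharge_gain, drift_step_px = drift_step_px,
            burnspot_enabled = burnspot_enabled)
  stopifnot(is.null(p$q0_electrons) || p$q0_electrons >= 0,
            p$D_px2_per_ns >= 0, p$alpha >= 0, p$sigma_local_px > 0,
            p$noise_std >= 0, p$detector_gain > 0,
            is.null(p$batch_visits) || p$batch_visits >= 1,
            p$drift_step_px >= 0)
  structure(p, class = "sim_params")
}

new_charge_state <- function(ny, nx, clock_ns = 0) {
  structure(list(C = matrix(0, ny, nx), clock_ns = clock_ns),
            class = "charge_state")
}

#' Evolve a charge field over a time interval
#'
#' Applies the dissipation model for `dt_ns` nanoseconds: per-pixel
#' exponential leak `C <- C * exp(-dt/tau)` interleaved with explicit
#' diffusion sub-steps (`D * dt_sub <= 0.25` px^2, zero-flux boundaries).
#' With `tau = Inf` everywhere, total charge is conserved exactly.
#'
#' @param state A `charge_state` (fields `C`, `clock_ns`) or a bare charge
#'   matrix.
#' @param dt_ns Elapsed time (>= 0) in nanoseconds.
#' @param phantom The `phantom` providing `tau_map`.
#' @param params A `sim_params` (uses `D_px2_per_ns`).
#' @return Updated `charge_state`.
#' @export
evolve_charge <- function(state, dt_ns, phantom, params = sim_params()) {
  if (dt_ns < 0) stop("dt_ns must be non-negative")
  if (is.matrix(state)) state <- structure(list(C = state, clock_ns = 0),
                                           class = "charge_state")
  stopifnot(inherits(state, "charge_state"), inherits(phantom, "phantom"),
            all(dim(state$C) == c(phantom$ny, phantom$nx)))
  if (dt_ns == 0) return(state)
  state$C <- cpp_evolve(state$C, phantom$tau_map, params$D_px2_per_ns, dt_ns)
  state$clock_ns <- state$clock_ns + dt_ns
  state
}

# Gaussian-smoothed local charge at one 0-based position (matches the C++ core)
local_smoothed_charge <- function(C, x, y, sigma) {
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  ny <- nrow(C); nx <- ncol(C)
  ys <- max(1L, y + 1L - rad):min(ny, y + 1L + rad)
  xs <- max(1L, x + 1L - rad):min(nx, x + 1L + rad)
  w <- exp(-(outer((ys - (y + 1L))^2, (xs - (x + 1L))^2, `+`)) / (2 * sigma^2))
  sum(w * C[ys, xs]) / sum(w)
}

#' Detected intensity at a single probe position
#'
#' Returns `gain * yield(x, y) * exp(-alpha * C~) + offset + noise`, where
#' `C~` is the charge field smoothed with a Gaussian of width
#' `sigma_local_px`: accumulated charge darkens the detected signal. If the
#' discharge model is enabled and `C~` exceeds the threshold, a bright spike
#' is emitted instead and the local charge is reset (returned in the
#' `state` attribute).
#'
#' @param phantom A `phantom`.
#' @param state A `charge_state`.
#' @param position Length-2 vector `c(x, y)`, 0-based.
#' @param params A `sim_params`.
#' @return Detected intensity in counts (clipped to the signed 16-bit range),
#'   with the possibly updated `charge_state` as attribute `"state"`.
#' @export
detect_signal <- function(phantom, state, position, params = sim_params()) {
  x <- position[[1]]; y <- position[[2]]
  if (x < 0 || x >= phantom$nx || y < 0 || y >= phantom$ny)
    stop("position outside the grid")
  ct <- local_smoothed_charge(state$C, x, y, params$sigma_local_px)
  if (isTRUE(params$discharge_enabled) && ct > params$discharge_threshold) {
    rad <- max(1L, as.integer(ceiling(3 * params$sigma_local_px)))
    ys <- max(1L, y + 1L - rad):min(phantom$ny, y + 1L + rad)
    xs <- max(1L, x + 1L - rad):min(phantom$nx, x + 1L + rad)
    state$C[ys, xs] <- 0
    s <- params$detector_gain * phantom$yield_map[y + 1L, x + 1L] +
      params$discharge_gain + params$detector_offset
  } else {
    s <- params$detector_gain * phantom$yield_map[y + 1L, x + 1L] *
      exp(-params$alpha * ct) + params$detector_offset
  }
  if (params$noise_std > 0) s <- s + stats::rnorm(1, 0, params$noise_std)
  s <- min(max(s, -32768), 32767)
  attr(s, "state") <- state
  s
}

resolve_q0 <- function(params, dwell_ns) {
  if (!is.null(params$q0_electrons)) params$q0_electrons
  else electrons_per_visit(params$current_pA, dwell_ns)
}

#' Simulate an acquisition of a phantom under a scan pattern
#'
#' Iterates the pattern's visits in order. Each visit deposits `q0` electrons
#' at the visited pixel and records the detected signal; dissipation
#' (diffusion + leak) is applied every `batch_visits` visits and at every
#' line/frame boundary with exact elapsed-time accounting. Frame integration
#' yields one 16-bit frame per repetition; line integration averages the
#' repeated passes of each line into a single output frame. Per-frame integer
#' drift (a random walk of standard deviation `drift_step_px`) shifts specimen
#' and charge jointly. With `burnspot_enabled` and an inter-frame pause,
#' `q0 * pause / dwell` electrons are deposited at the parked beam position
#' between frames.
#'
#' @param phantom A `phantom` matching the pattern grid.
#' @param pattern A `scan_pattern`.
#' @param params A `sim_params`.
#' @param seed Integer seed (detector noise and drift).
#' @return A `subframe_stack`: list with `frames` (ny x nx x R array of
#'   16-bit-range counts), `metadata` (seed, params, drift trajectory,
#'   pattern descriptor, clip count) and class `"subframe_stack"`.
#' @export
simulate_acquisition <- function(phantom, pattern, params = sim_params(),
                                 seed = 1L) {
  stopifnot(inherits(phantom, "phantom"), inherits(pattern, "scan_pattern"))
  if (phantom$nx != pattern$nx || phantom$ny != pattern$ny)
    stop("pattern grid does not match phantom grid")
  nx <- pattern$nx; ny <- pattern$ny
  v <- pattern$visits
  q0 <- resolve_q0(params, pattern$dwell_ns)
  batch <- if (is.null(params$batch_visits)) nx else as.integer(params$batch_visits)

  if (pattern$integration == "frame") {
    nframes <- pattern$reps
    frame_of <- rep.int(seq_len(nframes) - 1L, rep.int(nx * ny, nframes))
  } else {
    nframes <- 1L
    frame_of <- integer(nrow(v))
  }

  with_seed(seed, {
    if (params$drift_step_px > 0 && nframes > 1) {
      steps_x <- as.integer(round(stats::rnorm(nframes - 1, 0, params$drift_step_px)))
      steps_y <- as.integer(round(stats::rnorm(nframes - 1, 0, params$drift_step_px)))
      drift_x <- cumsum(c(0L, steps_x)); drift_y <- cumsum(c(0L, steps_y))
    } else {
      drift_x <- integer(nframes); drift_y <- integer(nframes)
    }
    res <- cpp_simulate(phantom$yield_map, phantom$tau_map,
                        matrix(0, ny, nx),
                        v$x, v$y, v$t_start_ns, frame_of, pattern$dwell_ns,
                        drift_x, drift_y,
                        q0, params$D_px2_per_ns, params$alpha,
                        params$sigma_local_px, params$noise_std,
                        params$detector_gain, params$detector_offset,
                        batch, isTRUE(params$discharge_enabled),
                        params$discharge_threshold, params$discharge_gain,
                        if (isTRUE(params$burnspot_enabled)) q0 else 0,
                        FALSE)
  })

  sig <- res$signal
  frames <- array(0, dim = c(ny, nx, nframes))
  if (pattern$integration == "frame") {
    for (f in seq_len(nframes)) {
      s <- sig[frame_of == f - 1L]
      vi <- v[frame_of == f - 1L, ]
      m <- matrix(0, ny, nx)
      m[cbind(vi$y + 1L, vi$x + 1L)] <- s
      frames[, , f] <- m
    }
  } else {
    # line integration: average the reps passes of each line
    m <- matrix(0, ny, nx)
    for (yy in 0:(ny - 1L)) {
      sel <- which(v$y == yy)
      line <- matrix(sig[sel], nrow = nx)   # nx x reps, passes in columns
      xs <- v$x[sel[seq_len(nx)]]
      m[yy + 1L, xs + 1L] <- rowMeans(line)
    }
    frames[, , 1] <- m
  }
  frames <- round(frames)

  structure(list(
    frames = frames,
    metadata = list(seed = seed, q0_electrons = q0, params = params,
                    pattern = list(mode = pattern$mode,
                                   integration = pattern$integration,
                                   nx = nx, ny = ny,
                                   dwell_ns = pattern$dwell_ns,
                                   reps = pattern$reps,
                                   skip_x = pattern$skip_x,
                                   skip_y = pattern$skip_y),
                    drift_x = drift_x, drift_y = drift_y,
                    n_clipped = res$n_clipped,
                    phantom_preset = phantom$preset,
                    final_charge_total = sum(res$charge)),
    charge = res$charge), class = "subframe_stack")
}

#' @export
print.subframe_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<subframe_stack> %d frame(s) of %d x %d px (%s/%s)\n",
              d[3], d[2], d[1], x$metadata$pattern$mode,
              x$metadata$pattern$integration))
  invisible(x)
}

#' Peak smoothed-charge trace of an acquisition
#'
#' Runs the acquisition and records, at every dissipation update, the maximum
#' over pixels of the Gaussian-smoothed charge field -- a measure of the worst
#' local charge accumulation a strategy produces. Intended for desk-scale
#' grids (the full field is smoothed at every update).
#'
#' @inheritParams simulate_acquisition
#' @return Tibble with columns `update` and `peak_charge` (electrons).
#' @export
peak_charge_trace <- function(phantom, pattern, params = sim_params(),
                              seed = 1L) {
  stopifnot(inherits(phantom, "phantom"), inherits(pattern, "scan_pattern"))
  if (phantom$nx != pattern$nx || phantom$ny != pattern$ny)
    stop("pattern grid does not match phantom grid")
  nx <- pattern$nx; ny <- pattern$ny
  v <- pattern$visits
  q0 <- resolve_q0(params, pattern$dwell_ns)
  batch <- if (is.null(params$batch_visits)) nx else as.integer(params$batch_visits)
  if (pattern$integration == "frame") {
    frame_of <- rep.int(seq_len(pattern$reps) - 1L,
                        rep.int(nx * ny, pattern$reps))
  } else frame_of <- integer(nrow(v))
  res <- with_seed(seed, {
    cpp_simulate(phantom$yield_map, phantom$tau_map, matrix(0, ny, nx),
                 v$x, v$y, v$t_start_ns, frame_of, pattern$dwell_ns,
                 integer(max(frame_of) + 1L), integer(max(frame_of) + 1L),
                 q0, params$D_px2_per_ns, params$alpha, params$sigma_local_px,
                 params$noise_std, params$detector_gain,
                 params$detector_offset, batch,
                 isTRUE(params$discharge_enabled), params$discharge_threshold,
                 params$discharge_gain, 0, TRUE)
  })
  tibble::tibble(update = seq_along(res$peak_trace),
                 peak_charge = as.numeric(res$peak_trace))
}
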
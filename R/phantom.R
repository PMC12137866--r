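# Synthetic specimen phantoms.
#
# A phantom is a per-pixel description of an inhomogeneous vitrified specimen:
# secondary-electron yield (the contrast source), a charge-leak time constant
# tau (how quickly deposited charge drains to ground at that pixel) and a
# ground-truth structure label map. Lipid-rich structures (droplets, myelin
# stacks) are modelled as high-yield, poorly dissipating (long-tau) regions,
# matching their role as local charging centres in cryo-SEM.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# correlated noise field: white noise blurred to correlation length `scale`
# and rescaled to standard deviation `sd`
grain_field <- function(ny, nx, sd, scale) {
  g <- gaussian_blur(matrix(stats::rnorm(ny * nx), ny, nx), scale)
  g * (sd / stats::sd(g))
}

# anti-aliased disc coverage stamped onto `cov` (max-combined)
stamp_disc <- function(cov, cx, cy, r) {
  ny <- nrow(cov); nx <- ncol(cov)
  ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r + 1))
  xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r + 1))
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  cov[ys, xs] <- pmax(cov[ys, xs], clamp01(r + 0.5 - d))
  cov
}

# anti-aliased annulus (ring) coverage
stamp_annulus <- function(cov, cx, cy, r_in, r_out) {
  ny <- nrow(cov); nx <- ncol(cov)
  ys <- max(1L, floor(cy - r_out)):min(ny, ceiling(cy + r_out + 1))
  xs <- max(1L, floor(cx - r_out)):min(nx, ceiling(cx + r_out + 1))
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  a <- pmin(clamp01(r_out + 0.5 - d), clamp01(d - r_in + 0.5))
  cov[ys, xs] <- pmax(cov[ys, xs], a)
  cov
}

# anti-aliased smooth random-walk polyline of given width (px)
stamp_membrane <- function(cov, nx, ny, width, n_steps) {
  x <- stats::runif(1, 2, nx - 1); y <- stats::runif(1, 2, ny - 1)
  heading <- stats::runif(1, 0, 2 * pi)
  step <- 0.35
  half <- width / 2
  for (i in seq_len(n_steps)) {
    heading <- heading + stats::rnorm(1, 0, 0.05)
    x <- x + step * cos(heading); y <- y + step * sin(heading)
    if (x < 2 || x > nx - 1 || y < 2 || y > ny - 1) break
    xs <- max(1L, floor(x - half - 1)):min(nx, ceiling(x + half + 1))
    ys <- max(1L, floor(y - half - 1)):min(ny, ceiling(y + half + 1))
    d <- sqrt(outer((ys - y)^2, (xs - x)^2, `+`))
    cov[ys, xs] <- pmax(cov[ys, xs], clamp01(half + 0.5 - d))
  }
  cov
}

phantom_defaults <- function() {
  list(
    pixel_nm = 6.34,
    yield_background = 0.5,
    grain_sd = 0.05,          # background texture amplitude
    grain_scale = 1.5,        # background texture correlation length (px)
    tau_background_ns = 1e5,  # median background charge-leak time constant
    tau_grain_sdlog = 1.0,    # log-sd of background tau heterogeneity
    tau_grain_scale = 12,     # correlation length of tau patches (px)
    n_discs = 4L,             # lipid droplets (cell preset)
    disc_yield = 0.85,
    disc_tau_factor = 100,    # droplets leak 100x more slowly than background
    n_membranes = 6L,         # thin curvilinear membranes (cell preset)
    membrane_yield = 0.7,
    membrane_width_px = 1.5,
    membrane_tau_factor = 10,
    n_myelin = 2L,            # concentric annulus stacks (myelin preset)
    myelin_yields = c(0.4, 0.8),
    myelin_ring_px = 3,
    myelin_tau_factor = 100,
    flyback_width = 64L,      # distorted left-band width (flyback_test preset)
    flyback_streak_sd = 0.18, # amplitude of row-wise settling smear
    flyback_streak_scale = 6, # vertical correlation of the smear (px)
    flyback_grain_sd = 0.03,
    flyback_grain_scale = 8
  )
}

#' Generate a synthetic specimen phantom
#'
#' Presets:
#' * `homogeneous` -- constant yield 0.5 and constant leak time; no structures.
#' * `cell` -- a vitrified-cell-like map: several non-overlapping high-yield,
#'   slowly-discharging discs (lipid droplets), thin curvilinear membranes,
#'   and a textured background.
#' * `myelin` -- concentric annulus stacks with alternating yield (compacted
#'   membrane wraps) plus interior organelle discs.
#' * `flyback_test` -- a textured frame whose left band of width
#'   `flyback_width` carries a smoothly decaying horizontal warp plus a
#'   row-wise probe-settling smear, the fixture family for the
#'   flyback-extent estimator.
#'
#' All placements are reproducible from `seed`; identical arguments give
#' bit-identical maps.
#'
#' @param preset One of `"homogeneous"`, `"cell"`, `"myelin"`,
#'   `"flyback_test"`.
#' @param nx,ny Grid size in pixels (>= 32).
#' @param seed Integer seed for structure placement and texture.
#' @param overrides Named list overriding entries of the default parameter set
#'   (see `leapscan:::phantom_defaults()`).
#' @return A `phantom` object with fields `yield_map`, `tau_map` (ns),
#'   `label_map` (0 = background), `structures` (tibble of placed structures),
#'   `nx`, `ny`, `pixel_nm`, `preset`, `seed`.
#' @examples
#' ph <- make_phantom("cell", 128, 128, seed = 1)
#' table(ph$structures$type)
#' @export
make_phantom <- function(preset = c("homogeneous", "cell", "myelin", "flyback_test"),
                         nx = 256L, ny = 256L, seed = 1L, overrides = list()) {
  preset <- match.arg(preset)
  stopifnot(nx >= 32, ny >= 32)
  nx <- as.integer(nx); ny <- as.integer(ny)
  p <- phantom_defaults()
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown)) stop("unknown override(s): ", paste(unknown, collapse = ", "))
  p[names(overrides)] <- overrides

  with_seed(seed, {
    yield <- matrix(p$yield_background, ny, nx)
    tau <- matrix(p$tau_background_ns, ny, nx)
    label <- matrix(0L, ny, nx)
    structures <- list()

    add_structure <- function(type, cov, y_val, tau_val) {
      lbl <- length(structures) + 1L
      cov[label > 0L] <- 0   # structures do not overwrite earlier placements
      sel <- cov > 0
      yield[sel] <<- yield[sel] * (1 - cov[sel]) + y_val * cov[sel]
      tau[cov > 0.5] <<- tau_val
      label[cov > 0.5 & label == 0L] <<- lbl
      structures[[lbl]] <<- tibble::tibble(label = lbl, type = type,
                                           area_px = sum(cov > 0.5))
      invisible(lbl)
    }

    if (preset %in% c("cell", "myelin")) {
      yield <- yield + grain_field(ny, nx, p$grain_sd, p$grain_scale)
      # electrically inhomogeneous background: log-normal patches of the leak
      # time constant (vitreous matrix with variably insulating inclusions)
      if (p$tau_grain_sdlog > 0)
        tau <- tau * exp(grain_field(ny, nx, p$tau_grain_sdlog,
                                     p$tau_grain_scale))
    }

    if (preset == "cell") {
      # non-overlapping lipid droplets
      placed <- list()
      tries <- 0L
      while (length(placed) < p$n_discs && tries < 500L) {
        tries <- tries + 1L
        r <- stats::runif(1, min(nx, ny) / 20, min(nx, ny) / 10)
        cx <- stats::runif(1, r + 2, nx - r - 1)
        cy <- stats::runif(1, r + 2, ny - r - 1)
        ok <- all(vapply(placed, function(q)
          sqrt((q[1] - cx)^2 + (q[2] - cy)^2) > q[3] + r + 3, TRUE))
        if (!ok) next
        placed <- c(placed, list(c(cx, cy, r)))
        cov <- stamp_disc(matrix(0, ny, nx), cx, cy, r)
        lbl <- add_structure("disc", cov, p$disc_yield,
                             p$tau_background_ns * p$disc_tau_factor)
        structures[[lbl]]$radius_px <- r
      }
      if (length(placed) < 3L)
        stop("grid too small to place the required discs")
      for (i in seq_len(p$n_membranes)) {
        cov <- stamp_membrane(matrix(0, ny, nx), nx, ny,
                              p$membrane_width_px, n_steps = 3L * max(nx, ny))
        if (sum(cov > 0.5) < 10) cov <- stamp_membrane(cov, nx, ny,
                                                       p$membrane_width_px,
                                                       3L * max(nx, ny))
        add_structure("membrane", cov, p$membrane_yield,
                      p$tau_background_ns * p$membrane_tau_factor)
      }
    }

    if (preset == "myelin") {
      for (i in seq_len(p$n_myelin)) {
        r_out0 <- stats::runif(1, min(nx, ny) / 8, min(nx, ny) / 5)
        cx <- stats::runif(1, r_out0 + 2, nx - r_out0 - 1)
        cy <- stats::runif(1, r_out0 + 2, ny - r_out0 - 1)
        n_rings <- 4L
        cov_all <- matrix(0, ny, nx)
        for (k in seq_len(n_rings)) {
          r_out <- r_out0 - (k - 1) * p$myelin_ring_px
          r_in <- r_out - p$myelin_ring_px
          if (r_in <= 1) break
          cov <- stamp_annulus(matrix(0, ny, nx), cx, cy, r_in, r_out)
          yv <- p$myelin_yields[(k - 1) %% 2 + 1]
          sel <- cov > 0
          yield[sel] <- yield[sel] * (1 - cov[sel]) + yv * cov[sel]
          cov_all <- pmax(cov_all, cov)
        }
        lbl <- length(structures) + 1L
        tau[cov_all > 0.5] <- p$tau_background_ns * p$myelin_tau_factor
        label[cov_all > 0.5 & label == 0L] <- lbl
        structures[[lbl]] <- tibble::tibble(label = lbl, type = "myelin",
                                            area_px = sum(cov_all > 0.5))
        # interior organelle disc (axon content)
        r_ax <- max(2, r_out0 - n_rings * p$myelin_ring_px - 2)
        cov <- stamp_disc(matrix(0, ny, nx), cx, cy, r_ax / 2)
        add_structure("organelle", cov, 0.6, p$tau_background_ns * 5)
      }
    }

    if (preset == "flyback_test") {
      w <- as.integer(p$flyback_width)
      if (w < 4 || w >= nx) stop("flyback_width must be in [4, nx)")
      base <- p$yield_background +
        grain_field(ny, nx, p$flyback_grain_sd, p$flyback_grain_scale)
      yield <- base
      raw <- as.numeric(gaussian_blur(matrix(stats::rnorm(ny), ny, 1),
                                      p$flyback_streak_scale))
      streak <- p$yield_background +
        (raw - mean(raw)) * (p$flyback_streak_sd / stats::sd(raw))
      xs <- seq_len(w)                      # 1-based columns of the band
      x0 <- xs - 1                          # 0-based coordinate
      d <- (w / 2) * (1 - x0 / w)^2         # smooth decaying displacement
      roll <- 8
      u <- ifelse(x0 < w - roll, 1, 0.5 * (1 + cos(pi * (x0 - (w - roll)) / roll)))
      src <- pmin(x0 + d, nx - 1)           # sample displaced source column
      lo <- floor(src); fr <- src - lo
      # linear interpolation between source columns
      for (i in seq_along(xs)) {
        c0 <- base[, lo[i] + 1]
        c1 <- base[, min(lo[i] + 2, nx)]
        wcol <- c0 * (1 - fr[i]) + c1 * fr[i]
        yield[, xs[i]] <- (1 - u[i]) * wcol + u[i] * streak
      }
      label[, xs] <- 1L
      structures[[1]] <- tibble::tibble(label = 1L, type = "flyback_band",
                                        area_px = sum(label == 1L))
    }

    yield <- clamp01(yield)
    structure(list(nx = nx, ny = ny, yield_map = yield, tau_map = tau,
                   label_map = label, pixel_nm = p$pixel_nm, preset = preset,
                   seed = seed, params = p,
                   structures = if (length(structures))
                     dplyr::bind_rows(structures)
                   else tibble::tibble(label = integer(), type = character(),
                                       area_px = integer())),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> preset '%s', %d x %d px (%.2f nm/px), seed %d\n",
              x$preset, x$nx, x$ny, x$pixel_nm, x$seed))
  if (nrow(x$structures))
    print(dplyr::count(x$structures, .data$type))
  invisible(x)
}

#' Ground-truth label mask of a phantom
#'
#' @param phantom A `phantom`.
#' @return Integer matrix (`ny` x `nx`) of structure labels, 0 = background.
#' @export
phantom_ground_truth <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  phantom$label_map
}
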
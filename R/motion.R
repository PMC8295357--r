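#' Simulate 2D Brownian motion
#'
#' Free diffusion in the plane (e.g., a particle anchored in a supported lipid
#' bilayer): independent Gaussian displacements per axis with variance
#' `2 * D * frame_time` per frame. The position is sampled once per frame;
#' intra-frame motion blur is not modelled.
#'
#' @param D diffusion constant (um^2/s), >= 0. `D = 0` gives an immobile
#'   particle.
#' @param n_frames number of frames.
#' @param frame_time frame interval (s).
#' @param origin length-2 numeric, initial position (um).
#' @param seed integer seed.
#' @return A numeric matrix `n_frames x 2` of positions in um (columns `x`,
#'   `y`).
#' @examples
#' pos <- simulate_brownian_2d(0.04, n_frames = 600, frame_time = 0.2, seed = 1)
#' @export
simulate_brownian_2d <- function(D, n_frames, frame_time = 0.2,
                                 origin = c(0, 0), seed = NULL) {
  if (!is.numeric(D) || length(D) != 1L || D < 0) stop("D must be >= 0")
  stopifnot(n_frames >= 1, frame_time > 0, length(origin) == 2L)
  if (!is.null(seed)) set.seed(seed)
  sd_step <- sqrt(2 * D * frame_time)
  dx <- if (n_frames > 1) stats::rnorm(n_frames - 1L, 0, sd_step) else numeric(0)
  dy <- if (n_frames > 1) stats::rnorm(n_frames - 1L, 0, sd_step) else numeric(0)
  pos <- cbind(x = origin[1] + cumsum(c(0, dx)),
               y = origin[2] + cumsum(c(0, dy)))
  pos
}

#' Computationally slow down periodic subtrajectories
#'
#' Rescales the displacements inside every `period`-th block of
#' `sub_len_frames` positions by `1/sqrt(factor)`, so the apparent diffusion
#' constant within those blocks becomes `D / factor`; blocks are re-chained at
#' their entry points so the path remains continuous. This emulates local
#' mobility changes (transient trapping, binding events) injected into an
#' otherwise time-invariant Brownian path.
#'
#' @param positions `n x 2` position matrix (um), e.g. from
#'   [simulate_brownian_2d()].
#' @param sub_len_frames block length in frames (>= 2).
#' @param period every `period`-th block is slowed (e.g. 4 = blocks 4, 8, ...).
#' @param factor slow-down factor >= 1; displacement SD in affected blocks is
#'   divided by `sqrt(factor)`.
#' @return A position matrix of the same shape.
#' @examples
#' pos <- simulate_brownian_2d(0.04, 600, 0.2, seed = 1)
#' slowed <- inject_slowdown(pos, sub_len_frames = 50, period = 4, factor = 4)
#' @export
inject_slowdown <- function(positions, sub_len_frames, period, factor) {
  if (!is.numeric(factor) || factor < 1) stop("factor must be >= 1 (speed-up is not modelled)")
  stopifnot(sub_len_frames >= 2, period >= 1)
  n <- nrow(positions)
  if (factor == 1 || n < 2) return(positions)
  d <- diff(positions)                       # displacement i -> i+1
  block <- ((seq_len(n) - 1L) %/% sub_len_frames) + 1L   # block of each position
  # displacement i belongs to a block when both endpoints are inside it
  slow_disp <- (block[-n] == block[-1]) & (block[-n] %% period == 0L)
  d[slow_disp, ] <- d[slow_disp, , drop = FALSE] / sqrt(factor)
  out <- apply(rbind(positions[1, ], d), 2, cumsum)
  colnames(out) <- colnames(positions)
  out
}

#' Synthetic TIRF movie configuration
#'
#' Acquisition geometry and camera model for [render_movie()]. Defaults mirror
#' a typical sCMOS TIRF setup: 130 nm effective pixels (2x2 binning), 200 ms
#' exposure, ideal Poisson camera with constant baseline and unit gain.
#'
#' @param fov_px field of view width/height in pixels.
#' @param pixel_size effective pixel size (nm).
#' @param psf_sigma PSF standard deviation (nm).
#' @param background mean background photons per pixel per frame.
#' @param baseline constant camera offset (counts).
#' @param gain counts per photon.
#' @param exposure frame exposure (s).
#' @return An object of class `movie_config`.
#' @export
movie_config <- function(fov_px = 64L, pixel_size = 130, psf_sigma = 156,
                         background = 5, baseline = 100, gain = 1,
                         exposure = 0.2) {
  stopifnot(fov_px >= 4, pixel_size > 0, psf_sigma > 0, background >= 0,
            baseline >= 0, gain > 0, exposure > 0)
  structure(list(fov_px = as.integer(fov_px), pixel_size = pixel_size,
                 psf_sigma = psf_sigma, background = background,
                 baseline = baseline, gain = gain, exposure = exposure),
            class = "movie_config")
}

#' Bundle ground-truth positions and photon traces
#'
#' @param positions_px list of `n_frames x 2` matrices, one per particle,
#'   positions in pixels (origin at the centre of the top-left pixel; integer
#'   coordinates are pixel centres; frames 0-based).
#' @param photon_traces list of [photon_trace()] objects, one per particle.
#' @param ids optional particle ids (default `seq_along`).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(positions_px, photon_traces, ids = NULL) {
  stopifnot(length(positions_px) == length(photon_traces))
  if (is.null(ids)) ids <- seq_along(positions_px)
  for (i in seq_along(positions_px)) {
    stopifnot(all(is.finite(positions_px[[i]])),
              inherits(photon_traces[[i]], "photon_trace"))
  }
  structure(list(positions_px = positions_px, photon_traces = photon_traces,
                 ids = ids),
            class = "ground_truth")
}

#' Convert micrometre positions to pixel coordinates
#'
#' @param positions_um `n x 2` matrix in um.
#' @param pixel_size pixel size in nm.
#' @return `n x 2` matrix in pixel units.
#' @export
um_to_px <- function(positions_um, pixel_size) {
  positions_um / (pixel_size / 1000)
}

# expected photon image of one emitter: photons spread by an integrated
# 2D Gaussian PSF; contributions beyond 5 sigma are truncated
.psf_add <- function(img, x, y, photons, sigma_px) {
  n <- nrow(img)
  w <- ceiling(5 * sigma_px)
  ix <- max(0L, floor(x - w)):min(n - 1L, ceiling(x + w))
  iy <- max(0L, floor(y - w)):min(n - 1L, ceiling(y + w))
  if (length(ix) == 0L || length(iy) == 0L) return(img)
  fx <- stats::pnorm(ix + 0.5, x, sigma_px) - stats::pnorm(ix - 0.5, x, sigma_px)
  fy <- stats::pnorm(iy + 0.5, y, sigma_px) - stats::pnorm(iy - 0.5, y, sigma_px)
  img[iy + 1L, ix + 1L] <- img[iy + 1L, ix + 1L] + photons * (fy %o% fx)
  img
}

#' Render a synthetic TIRF image stack
#'
#' Each frame is `baseline + gain * Poisson(background + signal)`, where the
#' signal is the sum over particles of their per-frame photon count spread by
#' a pixel-integrated 2D Gaussian PSF centred at the particle's true position.
#' Output is clamped to the unsigned 16-bit range. Rows index y, columns x;
#' pixel (0,0) is the top-left pixel centre.
#'
#' @param truth a [ground_truth()] object (positions in pixels).
#' @param cfg a [movie_config()].
#' @param seed integer seed for the Poisson noise.
#' @return A list of integer matrices (one per frame), class `image_stack`,
#'   with the config attached as attribute `"config"`.
#' @export
render_movie <- function(truth, cfg, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "movie_config"))
  if (!is.null(seed)) set.seed(seed)
  sigma_px <- cfg$psf_sigma / cfg$pixel_size
  if (sigma_px < 0.5) warning("PSF sigma below 0.5 px: undersampled rendering")
  n_frames <- max(vapply(truth$photon_traces, function(p) length(p$photons), 1L))
  n <- cfg$fov_px
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    expected <- matrix(cfg$background, n, n)
    for (i in seq_along(truth$ids)) {
      ph <- truth$photon_traces[[i]]$photons
      if (f > length(ph) || ph[f] == 0) next
      pos <- truth$positions_px[[i]]
      r <- min(f, nrow(pos))
      expected <- .psf_add(expected, pos[r, 1], pos[r, 2], ph[f], sigma_px)
    }
    counts <- cfg$baseline + cfg$gain * stats::rpois(n * n, expected)
    frames[[f]] <- matrix(as.integer(pmin(counts, 65535L)), n, n)
  }
  structure(frames, class = "image_stack", config = cfg)
}

#' @export
print.image_stack <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Image stack: %d frames of %dx%d px (pixel %.0f nm, exposure %.3g s)\n",
              length(x), nrow(x[[1]]), ncol(x[[1]]), cfg$pixel_size, cfg$exposure))
  invisible(x)
}
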
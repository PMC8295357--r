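# --- single-molecule spot detection and integrated-Gaussian fitting ---

# separable Gaussian blur via banded convolution matrices; replicate-padded
.gauss_kernel_matrix <- function(n, sigma) {
  w <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-w:w, 0, sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- pmin(pmax((j - w):(j + w), 1L), n)   # replicate border
    for (t in seq_along(idx)) K[idx[t], j] <- K[idx[t], j] + k[t]
  }
  K
}

.gauss_blur <- function(img, sigma) {
  Ky <- .gauss_kernel_matrix(nrow(img), sigma)
  Kx <- .gauss_kernel_matrix(ncol(img), sigma)
  t(Ky) %*% img %*% Kx
}

#' Detect candidate spots in one frame
#'
#' Band-pass detection: the image (in photons) is filtered with a
#' difference-of-Gaussians tuned to the PSF scale, then local maxima above a
#' score threshold are kept with non-maximum suppression inside the fitting
#' ROI. Deterministic; candidates closer than `roi_halfwidth` to the border
#' are discarded so a full ROI can always be cut.
#'
#' @param frame_image 2D numeric matrix (photon scale, rows = y).
#' @param min_score detection threshold on the band-pass response. `NULL`
#'   (default) auto-sets `5 * MAD` of the response, a robust noise floor.
#' @param roi_halfwidth half-width of the fitting ROI in pixels (default 5).
#' @param psf_sigma_px expected PSF sigma in pixels (default 1.2); the
#'   band-pass uses sigmas `psf_sigma_px` and `2 * psf_sigma_px`.
#' @return A data.frame with columns `x`, `y` (0-based integer pixel
#'   positions) and `score`, ordered by decreasing score. Zero rows when
#'   nothing exceeds the threshold.
#' @export
detect_spots <- function(frame_image, min_score = NULL, roi_halfwidth = 5L,
                         psf_sigma_px = 1.2) {
  stopifnot(is.matrix(frame_image), roi_halfwidth >= 1)
  img <- frame_image
  dog <- .gauss_blur(img, psf_sigma_px) - .gauss_blur(img, 2 * psf_sigma_px)
  if (is.null(min_score)) {
    noise <- stats::mad(dog)
    min_score <- if (noise > 0) 5 * noise else Inf
    if (!any(dog > min_score) && all(img == img[1])) return(
      data.frame(x = integer(0), y = integer(0), score = numeric(0)))
  }
  ny <- nrow(dog); nx <- ncol(dog)
  cand <- which(dog > min_score, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(x = integer(0), y = integer(0), score = numeric(0)))
  # keep strict local maxima in a 3x3 neighbourhood
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1, r - 1):min(ny, r + 1)
    cc <- max(1, c - 1):min(nx, c + 1)
    keep[i] <- dog[r, c] == max(dog[rr, cc])
  }
  cand <- cand[keep, , drop = FALSE]
  sc <- dog[cand]
  o <- order(sc, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]; sc <- sc[o]
  # non-maximum suppression within one ROI, then border exclusion
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (any(sel)) {
      prev <- cand[sel, , drop = FALSE]
      if (any(abs(prev[, 1] - cand[i, 1]) <= roi_halfwidth &
              abs(prev[, 2] - cand[i, 2]) <= roi_halfwidth)) next
    }
    sel[i] <- TRUE
  }
  cand <- cand[sel, , drop = FALSE]; sc <- sc[sel]
  x <- cand[, 2] - 1L; y <- cand[, 1] - 1L
  ok <- x >= roi_halfwidth & x < nx - roi_halfwidth &
        y >= roi_halfwidth & y < ny - roi_halfwidth
  data.frame(x = as.integer(x[ok]), y = as.integer(y[ok]), score = sc[ok])
}

#' Fit an integrated 2D Gaussian to a spot ROI
#'
#' Least-squares (Levenberg-Marquardt) fit of a pixel-integrated symmetric 2D
#' Gaussian plus constant background to a small image patch containing one
#' candidate near its centre. Position and sigma are reported in pixels in the
#' ROI frame (0-based, pixel-centre convention); add the ROI corner to recover
#' stack coordinates.
#'
#' @param roi_image small 2D matrix in photon units.
#' @param psf_sigma_px initial sigma guess in pixels.
#' @return A list with `x`, `y`, `photons`, `bg` (photons per pixel), `sigma`
#'   (px) and `converged`. Non-converged or unphysical fits have
#'   `converged = FALSE` and should be excluded downstream.
#' @export
fit_gaussian_2d <- function(roi_image, psf_sigma_px = 1.2) {
  stopifnot(is.matrix(roi_image))
  ny <- nrow(roi_image); nx <- ncol(roi_image)
  xs <- 0:(nx - 1); ys <- 0:(ny - 1)
  bg0 <- stats::median(roi_image)
  sig <- pmax(roi_image - bg0, 0)
  tot <- sum(sig)
  fail <- list(x = NA_real_, y = NA_real_, photons = NA_real_, bg = bg0,
               sigma = NA_real_, converged = FALSE)
  if (tot <= 0) return(fail)
  x0 <- sum(t(sig) * xs) / tot
  y0 <- sum(sig * ys) / tot

  resid_fun <- function(p) {
    x <- p[1]; y <- p[2]; N <- exp(p[3]); bg <- p[4]; s <- exp(p[5])
    fx <- stats::pnorm(xs + 0.5, x, s) - stats::pnorm(xs - 0.5, x, s)
    fy <- stats::pnorm(ys + 0.5, y, s) - stats::pnorm(ys - 0.5, y, s)
    as.vector(bg + N * (fy %o% fx) - roi_image)
  }
  p0 <- c(x0, y0, log(max(tot, 1)), bg0, log(psf_sigma_px))
  fit <- tryCatch(
    minpack.lm::nls.lm(p0, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  p <- fit$par
  out <- list(x = p[1], y = p[2], photons = exp(p[3]), bg = p[4],
              sigma = exp(p[5]), converged = fit$info %in% 1:4)
  # sanity: centre inside ROI, sigma plausible
  if (!is.finite(out$photons) || out$x < -0.5 || out$x > nx - 0.5 ||
      out$y < -0.5 || out$y > ny - 0.5 ||
      out$sigma < 0.3 || out$sigma > max(nx, ny)) out$converged <- FALSE
  out
}

#' Theoretical localization precision of a Gaussian fit
#'
#' Mortensen-style variance for least-squares fitting of a pixel-integrated
#' Gaussian: with effective PSF variance `sa^2 = sigma^2 + a^2 / 12` (pixel
#' size `a`), the positional variance is
#' `sa^2 / N * (16 / 9 + 8 * pi * sa^2 * b / (N * a^2))`, where `N` is the
#' photon count and `b` the background photons per pixel. Returned as a
#' standard deviation in nm; decreases as `1/sqrt(N)` at negligible
#' background.
#'
#' @param photons fitted photon count (> 0).
#' @param sigma fitted PSF sigma in pixels.
#' @param bg background photons per pixel.
#' @param pixel_size pixel size in nm.
#' @return Localization precision (SD) in nm, vectorized over inputs.
#' @export
estimate_precision <- function(photons, sigma, bg, pixel_size) {
  if (any(photons <= 0)) stop("photons must be > 0")
  a <- pixel_size
  sa2 <- (sigma * pixel_size)^2 + a^2 / 12
  v <- sa2 / photons * (16 / 9 + 8 * pi * sa2 * pmax(bg, 0) / (photons * a^2))
  sqrt(v)
}

#' Localize an image stack
#'
#' Runs [detect_spots()] and [fit_gaussian_2d()] on every frame of a rendered
#' (or loaded) stack and concatenates the results into a localization table.
#' Camera counts are converted to photons with the stack's baseline/gain
#' before processing; non-converged fits and fits below `min_photons` are
#' dropped (counts reported via attribute `"n_rejected"`).
#'
#' @param stack an `image_stack` from [render_movie()] or [read_stack_tiff()].
#' @param cfg a [movie_config()]; defaults to the stack's own config.
#' @param roi_halfwidth fitting ROI half-width (px).
#' @param min_score detection threshold (`NULL` = auto, see [detect_spots()]).
#' @param min_photons discard fits below this photon count (default 50).
#' @return A data.frame of class `localization_table` with columns `frame`
#'   (0-based), `x`, `y` (px), `photons`, `bg`, `sigma` (px), `precision`
#'   (nm).
#' @export
localize_stack <- function(stack, cfg = attr(stack, "config"),
                           roi_halfwidth = 5L, min_score = NULL,
                           min_photons = 50) {
  stopifnot(inherits(stack, "image_stack") || is.list(stack))
  if (is.null(cfg)) stop("no movie_config available for the stack")
  sigma_px <- cfg$psf_sigma / cfg$pixel_size
  rows <- vector("list", length(stack))
  n_rej <- 0L
  for (f in seq_along(stack)) {
    img <- (stack[[f]] - cfg$baseline) / cfg$gain
    cand <- detect_spots(img, min_score = min_score,
                         roi_halfwidth = roi_halfwidth,
                         psf_sigma_px = sigma_px)
    if (nrow(cand) == 0L) next
    res <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      rr <- (cand$y[i] - roi_halfwidth):(cand$y[i] + roi_halfwidth) + 1L
      cc <- (cand$x[i] - roi_halfwidth):(cand$x[i] + roi_halfwidth) + 1L
      fit <- fit_gaussian_2d(img[rr, cc], psf_sigma_px = sigma_px)
      if (!fit$converged || fit$photons < min_photons) { n_rej <- n_rej + 1L; next }
      res[[i]] <- data.frame(frame = f - 1L,
                             x = fit$x + cand$x[i] - roi_halfwidth,
                             y = fit$y + cand$y[i] - roi_halfwidth,
                             photons = fit$photons, bg = fit$bg,
                             sigma = fit$sigma)
    }
    rows[[f]] <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      photons = numeric(0), bg = numeric(0), sigma = numeric(0))
  out$precision <- if (nrow(out)) estimate_precision(out$photons, out$sigma,
                                                     out$bg, cfg$pixel_size)
                   else numeric(0)
  class(out) <- c("localization_table", "data.frame")
  attr(out, "n_rejected") <- n_rej
  out
}
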
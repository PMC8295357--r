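# --- mobile-particle analysis: linking, MSD fitting, subtrajectories ---

#' Link localizations into trajectories
#'
#' Greedy globally-nearest-neighbour linking: between consecutive frames all
#' candidate (track, localization) pairs within `search_range_px` are sorted
#' by distance (ties broken by lowest track id) and assigned greedily;
#' unmatched tracks survive `memory_frames` frames before termination,
#' consistent with the single-frame-gap rule used for immobilized traces.
#' Deterministic.
#'
#' @param locs localization table sorted by frame (`frame`, `x`, `y`,
#'   `photons`).
#' @param search_range_px maximum linking distance per frame step (px), > 0.
#'   For Brownian motion a practical choice is several times
#'   `sqrt(4 * D * frame_time)`.
#' @param memory_frames frames a track survives without a localization
#'   (default 1).
#' @param min_locs drop trajectories with fewer localizations (default 1 =
#'   keep all).
#' @return A list of trajectories (class `trajectory_set`); each trajectory is
#'   a data.frame `frame`, `x`, `y`, `photons` with strictly increasing
#'   frames, plus attribute `"id"`.
#' @export
link_localizations <- function(locs, search_range_px, memory_frames = 1L,
                               min_locs = 1L) {
  if (!is.numeric(search_range_px) || search_range_px <= 0)
    stop("search_range_px must be > 0")
  stopifnot(!is.unsorted(locs$frame))
  if (nrow(locs) == 0L) return(structure(list(), class = "trajectory_set"))

  by_frame <- split(seq_len(nrow(locs)), locs$frame)
  frames <- as.integer(names(by_frame))

  tracks <- list()                 # finished + active; rows of locs per track
  active_id <- integer(0)          # track indices currently active
  active_x <- active_y <- numeric(0)
  active_last_frame <- integer(0)
  next_id <- 1L

  start_track <- function(row) {
    tracks[[next_id]] <<- row
    active_id <<- c(active_id, next_id)
    active_x <<- c(active_x, locs$x[row])
    active_y <<- c(active_y, locs$y[row])
    active_last_frame <<- c(active_last_frame, locs$frame[row])
    next_id <<- next_id + 1L
  }

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- by_frame[[fi]]
    # retire tracks that exceeded the memory
    alive <- (f - active_last_frame) <= (memory_frames + 1L)
    active_id <- active_id[alive]; active_x <- active_x[alive]
    active_y <- active_y[alive]; active_last_frame <- active_last_frame[alive]

    if (length(active_id) && length(rows)) {
      dx <- outer(active_x, locs$x[rows], "-")
      dy <- outer(active_y, locs$y[rows], "-")
      d <- sqrt(dx^2 + dy^2)
      cand <- which(d <= search_range_px, arr.ind = TRUE)
      if (nrow(cand)) {
        o <- order(d[cand], active_id[cand[, 1]])
        cand <- cand[o, , drop = FALSE]
        used_t <- logical(length(active_id))
        used_l <- logical(length(rows))
        for (ci in seq_len(nrow(cand))) {
          ti <- cand[ci, 1]; li <- cand[ci, 2]
          if (used_t[ti] || used_l[li]) next
          used_t[ti] <- TRUE; used_l[li] <- TRUE
          id <- active_id[ti]; row <- rows[li]
          tracks[[id]] <- c(tracks[[id]], row)
          active_x[ti] <- locs$x[row]; active_y[ti] <- locs$y[row]
          active_last_frame[ti] <- f
        }
        for (li in which(!used_l)) start_track(rows[li])
        next
      }
    }
    for (row in rows) start_track(row)
  }

  out <- lapply(seq_len(next_id - 1L), function(id) {
    rw <- tracks[[id]]
    tr <- data.frame(frame = locs$frame[rw], x = locs$x[rw], y = locs$y[rw],
                     photons = if ("photons" %in% names(locs)) locs$photons[rw]
                               else NA_real_)
    attr(tr, "id") <- id
    tr
  })
  out <- out[vapply(out, nrow, 1L) >= min_locs]
  structure(out, class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  n <- vapply(x, nrow, 1L)
  cat(sprintf("Trajectory set: %d trajectories (median %d, max %d localizations)\n",
              length(x), if (length(n)) as.integer(stats::median(n)) else 0L,
              if (length(n)) max(n) else 0L))
  invisible(x)
}

#' Trajectory duration in seconds
#'
#' `tau = (last frame - first frame + 1) * frame_time`, matching the
#' immobilized-trace convention.
#'
#' @param traj a trajectory data.frame (`frame`, ...).
#' @param frame_time frame interval (s).
#' @return Duration in seconds.
#' @export
trajectory_duration <- function(traj, frame_time = 0.2) {
  (traj$frame[nrow(traj)] - traj$frame[1] + 1L) * frame_time
}

#' Time-averaged mean squared displacement
#'
#' MSD at lag n uses all overlapping displacement windows
#' `(r(t + n dt) - r(t))` available in the trajectory; frames missing because
#' of gap-bridged linking are skipped pairwise.
#'
#' @param traj trajectory data.frame (`frame`, `x`, `y`) -- coordinates in um
#'   (convert pixel tables with the pixel size first).
#' @param max_lag_frames largest lag (frames); must be < number of spanned
#'   frames.
#' @param frame_time frame interval (s).
#' @return An object of class `msd_curve`: data.frame `lag` (s), `msd` (um^2),
#'   `n_pairs`; the number of positions is attached as attribute `"N"`.
#' @export
compute_msd <- function(traj, max_lag_frames, frame_time = 0.2) {
  n_span <- traj$frame[nrow(traj)] - traj$frame[1] + 1L
  if (n_span < max_lag_frames + 1L) stop("insufficient length for requested max lag")
  # index positions on the spanned frame grid (NA where missing)
  rel <- traj$frame - traj$frame[1] + 1L
  x <- rep(NA_real_, n_span); y <- rep(NA_real_, n_span)
  x[rel] <- traj$x; y[rel] <- traj$y
  msd <- numeric(max_lag_frames); npair <- integer(max_lag_frames)
  for (l in seq_len(max_lag_frames)) {
    dx <- x[-seq_len(l)] - x[seq_len(n_span - l)]
    dy <- y[-seq_len(l)] - y[seq_len(n_span - l)]
    sq <- dx^2 + dy^2
    ok <- !is.na(sq)
    npair[l] <- sum(ok)
    msd[l] <- if (npair[l]) mean(sq[ok]) else NA_real_
  }
  out <- data.frame(lag = seq_len(max_lag_frames) * frame_time, msd = msd,
                    n_pairs = npair)
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "N") <- nrow(traj)
  out
}

# Relative covariance matrix of the time-averaged MSD at lags 1..n_max for a
# pure Brownian trajectory of N positions. For Gaussian window displacements
# u, v: cov(u^2, v^2) = 2 cov(u, v)^2, and cov of two windows is proportional
# to their time overlap, so the matrix follows from counting overlaps. The
# overall scale (prop. to (4 D dt)^2) cancels in generalized least squares.
.msd_rel_cov <- function(N, n_max) {
  C <- matrix(0, n_max, n_max)
  for (n in seq_len(n_max)) for (m in seq_len(n)) {
    d <- (1 - (N - n)):((N - m) - 1)                  # window offset j - i
    cnt <- pmax(0, pmin(N - n, N - m - d) - pmax(1, 1 - d) + 1)
    ov <- pmax(0, pmin(n, d + m) - pmax(0, d))
    C[n, m] <- C[m, n] <- sum(cnt * ov^2) / ((N - n) * (N - m))
  }
  C
}

#' Iterative linear MSD fit for the diffusion constant
#'
#' Fits `MSD(t) = 4 D t + b` over the first `n` lags by generalized least
#' squares, weighting with the exact covariance of time-averaged Brownian MSD
#' values (overlapping displacement windows are strongly correlated; ignoring
#' this inflates the variance of the estimate by up to ~60% at small `n`).
#' `n` is chosen iteratively from the reduced noise-to-signal parameter
#' `x = b / (4 D dt)` via the optimal-number-of-points rule
#' `n = max(4, round(2 + 2.3 x^0.52))`, iterated to a fixed point (at most 10
#' iterations), starting from `n = max(4, round(N / 10))`. The lower bound of
#' 4 keeps the two-parameter fit overdetermined enough for the covariance
#' weighting to average noise; with GLS the variance is flat in `n` beyond
#' that, so the rule only needs to raise `n` when localization noise (large
#' `x`) demands it.
#'
#' @param msd an [compute_msd()] curve.
#' @param frame_time frame interval (s).
#' @return An object of class `diffusion_estimate`: list with `D` (um^2/s),
#'   `b` (intercept, um^2), `n_fit`, `x`, `converged`, and
#'   `noise_dominated` (TRUE when the fitted slope is not positive).
#' @export
fit_msd_iterative <- function(msd, frame_time = 0.2) {
  ok <- is.finite(msd$msd)
  lag <- msd$lag[ok]; m <- msd$msd[ok]
  if (length(lag) < 2L) stop("need at least 2 lags")
  N <- attr(msd, "N")
  if (is.null(N)) N <- length(lag) + 1L
  n_min <- min(4L, length(lag))
  n <- min(max(n_min, round(N / 10)), length(lag))

  gls <- function(n) {
    k <- seq_len(n)
    X <- cbind(1, lag[k])
    if (n == 2L) return(solve(X, m[k]))            # exactly determined
    Ci <- solve(.msd_rel_cov(N, n))
    solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% m[k])
  }

  D <- b <- x <- NA_real_
  converged <- FALSE
  for (it in 1:10) {
    beta <- gls(n)
    b <- beta[1]; D <- beta[2] / 4
    x <- if (is.finite(D) && D > 0) max(0, b / (4 * D * frame_time)) else 0
    n_new <- min(max(n_min, round(2 + 2.3 * x^0.52)), length(lag))
    if (n_new == n) { converged <- TRUE; break }
    n <- n_new
  }
  structure(list(D = unname(D), b = unname(b), n_fit = n, x = unname(x),
                 converged = converged,
                 noise_dominated = !is.finite(D) || D <= 0),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g um^2/s (intercept %.3g um^2, %d lags%s%s)\n",
              x$D, x$b, x$n_fit,
              if (x$converged) "" else ", not converged",
              if (x$noise_dominated) ", noise-dominated" else ""))
  invisible(x)
}

#' Convenience: MSD fit of one trajectory
#'
#' @param traj trajectory (`frame`, `x`, `y`, um).
#' @param frame_time frame interval (s).
#' @param max_lag_frames largest MSD lag; default one quarter of the spanned
#'   frames (at least 4).
#' @return A `diffusion_estimate`.
#' @export
fit_trajectory_d <- function(traj, frame_time = 0.2, max_lag_frames = NULL) {
  n_span <- traj$frame[nrow(traj)] - traj$frame[1] + 1L
  if (is.null(max_lag_frames))
    max_lag_frames <- max(4L, min(n_span - 1L, floor(n_span / 4)))
  fit_msd_iterative(compute_msd(traj, max_lag_frames, frame_time), frame_time)
}

#' Mobile trajectories-per-particle curve
#'
#' For moving particles individual trajectories cannot be attributed to a
#' particle, so the TPP curve is normalized by the initial track number
#' `M_initial` (the fitted intercept of [tracks_per_frame_survival()], which
#' approximates the number of particles in the field of view):
#' `TPP(tau >= T) = #\{trajectories with tau >= T\} / M_initial`.
#'
#' @param trajectories a `trajectory_set` (or vector of durations in s).
#' @param M_initial initial track number, > 0.
#' @param query_times query grid (s); default every frame time up to the
#'   longest duration.
#' @param frame_time frame interval (s).
#' @return A `tpp_curve` (quartiles are NA: no per-particle identity).
#' @export
mobile_tpp <- function(trajectories, M_initial, query_times = NULL,
                       frame_time = 0.2) {
  if (!is.numeric(M_initial) || M_initial <= 0) stop("M_initial must be > 0")
  tau <- if (is.numeric(trajectories)) trajectories
         else vapply(trajectories, trajectory_duration, numeric(1),
                     frame_time = frame_time)
  if (is.null(query_times))
    query_times <- seq(frame_time, max(tau), by = frame_time)
  tau_sorted <- sort(tau)
  n_ge <- length(tau) - findInterval(query_times, tau_sorted, left.open = TRUE)
  out <- data.frame(T = query_times, mean = n_ge / M_initial,
                    q25 = NA_real_, q75 = NA_real_)
  class(out) <- c("tpp_curve", "data.frame")
  attr(out, "M") <- M_initial
  attr(out, "n_segments") <- length(tau)
  out
}

#' Theoretical relative uncertainty of a short-segment diffusion estimate
#'
#' Predicted relative standard deviation of a single-trajectory MSD-fit
#' diffusion estimate from a segment of `N_frames_sub` positions when the
#' first `n_fit` lags are used: `sqrt(2 * n_fit / (3 * (N - n_fit)))`, the
#' classic uncertainty of time-averaged-MSD diffusion estimation in the
#' low-noise regime. The reduced noise parameter `x` does not enter the
#' expression directly; it acts through the choice of `n_fit` made by
#' [fit_msd_iterative()]. Monotonically decreasing in `N_frames_sub`.
#'
#' @param N_frames_sub number of positions in the segment (> `n_fit`).
#' @param n_fit number of MSD lags used in the fit (>= 2).
#' @param x reduced noise parameter (accepted for interface completeness).
#' @return Dimensionless relative standard deviation.
#' @export
theoretical_rel_sd <- function(N_frames_sub, n_fit, x = 0) {
  if (!is.numeric(n_fit) || any(n_fit < 2)) stop("n_fit must be >= 2")
  if (any(N_frames_sub <= n_fit)) stop("segment must be longer than the number of fitted lags")
  sqrt(2 * n_fit / (3 * (N_frames_sub - n_fit)))
}

#' Subtrajectory motion-change analysis
#'
#' Splits a long trajectory into consecutive non-overlapping blocks of
#' `sub_duration` (default 10 s = 50 frames at 200 ms), fits the diffusion
#' constant of the full trajectory (`D`) and of every block (`D_sub`) with
#' the same iterative MSD procedure, and compares the scatter of `D_sub`
#' about `D` -- the RMSD normalized to `D` -- with the theoretical relative
#' standard deviation expected for time-invariant Brownian motion at that
#' segment length. A normalized RMSD well above the limit signals genuine
#' motion changes between blocks rather than estimation noise.
#'
#' @param traj trajectory (`frame`, `x`, `y`, um); duration must exceed
#'   `min_duration`.
#' @param frame_time frame interval (s).
#' @param min_duration minimum trajectory duration (s, default 120).
#' @param sub_duration block duration (s, default 10).
#' @return An object of class `subtraj_report`: list with `D`, `D_sub`,
#'   `n_sub`, `nrmsd` (RMSD of `D_sub` about `D`, / `D`), `theo_limit`
#'   (at the median `n_fit` of the blocks), and `deviation_ratio`
#'   (`nrmsd / theo_limit`). Residual frames beyond the last full block are
#'   dropped.
#' @export
subtrajectory_analysis <- function(traj, frame_time = 0.2, min_duration = 120,
                                   sub_duration = 10) {
  tau <- trajectory_duration(traj, frame_time)
  if (tau < min_duration)
    stop(sprintf("trajectory duration %.3g s below the %.3g s threshold", tau,
                 min_duration))
  sub_len <- round(sub_duration / frame_time)
  n <- nrow(traj)
  n_sub <- floor(n / sub_len)
  full <- fit_trajectory_d(traj, frame_time)
  subs <- lapply(seq_len(n_sub), function(b) {
    seg <- traj[((b - 1L) * sub_len + 1L):(b * sub_len), , drop = FALSE]
    fit_msd_iterative(
      compute_msd(seg, max_lag_frames = max(4L, floor(sub_len / 4)),
                  frame_time = frame_time),
      frame_time)
  })
  D_sub <- vapply(subs, `[[`, numeric(1), "D")
  n_fits <- vapply(subs, `[[`, numeric(1), "n_fit")
  nrmsd <- sqrt(mean((D_sub - full$D)^2)) / full$D
  theo <- theoretical_rel_sd(sub_len, stats::median(n_fits))
  structure(list(D = full$D, D_sub = D_sub, n_sub = n_sub,
                 n_fit_sub = n_fits, nrmsd = nrmsd, theo_limit = theo,
                 deviation_ratio = nrmsd / theo),
            class = "subtraj_report")
}

#' @export
print.subtraj_report <- function(x, ...) {
  cat(sprintf("Subtrajectory report: D = %.4g um^2/s, %d blocks, normalized RMSD %.3f (limit %.3f, ratio %.2f)\n",
              x$D, x$n_sub, x$nrmsd, x$theo_limit, x$deviation_ratio))
  invisible(x)
}

#' Spatial occupancy map of unique trajectories
#'
#' Counts, for every `bin_px x bin_px` block of pixels, the number of distinct
#' trajectories with at least one localization inside it during the whole
#' measurement. Bins no trajectory visited hold 0 and are rendered
#' empty/white.
#'
#' @param trajectories a `trajectory_set` (coordinates in px).
#' @param fov_px field-of-view size in pixels.
#' @param bin_px bin size (default 2). A FOV not divisible by `bin_px` keeps
#'   its last, partial bins.
#' @return An integer matrix of class `occupancy_map` (rows = y bins).
#' @export
occupancy_map <- function(trajectories, fov_px, bin_px = 2L) {
  n_bins <- ceiling(fov_px / bin_px)
  counts <- matrix(0L, n_bins, n_bins)
  for (tr in trajectories) {
    # pixel-centre convention: pixel i covers [i - 0.5, i + 0.5)
    bx <- floor((tr$x + 0.5) / bin_px)
    by <- floor((tr$y + 0.5) / bin_px)
    ok <- bx >= 0 & bx < n_bins & by >= 0 & by < n_bins
    visited <- unique(cbind(by[ok], bx[ok]) + 1L)
    counts[visited] <- counts[visited] + 1L
  }
  structure(counts, class = c("occupancy_map", "matrix"),
            bin_px = bin_px, fov_px = fov_px)
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("Occupancy map: %dx%d bins of %d px, %d visited (max count %d)\n",
              nrow(x), ncol(x), attr(x, "bin_px"), sum(x > 0), max(x)))
  invisible(x)
}
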
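# --- immobilized-particle analysis: clusters, traces, TPP statistics ---

#' Cluster localizations of immobilized particles
#'
#' Distance-based clustering of a localization table: localizations within
#' `radius_px` of each other are connected (grid-bucketed neighbourhood search
#' plus union-find), and connected components with at least `min_locs` members
#' are reported as particles. Deterministic for a fixed input order.
#'
#' @param locs localization table (`frame`, `x`, `y`, `photons`, ...).
#' @param radius_px connection radius in pixels.
#' @param min_locs minimum number of localizations per cluster.
#' @return A data.frame of class `particle_clusters` with one row per kept
#'   cluster (`cluster`, `x`, `y` centroid in px, `n_locs`, `radius` = RMS
#'   member distance from the centroid). The per-localization cluster
#'   assignment (NA for members of discarded clusters) is attached as
#'   attribute `"assignment"`.
#' @export
cluster_particles <- function(locs, radius_px = 1, min_locs = 10L) {
  stopifnot(radius_px > 0, min_locs >= 1)
  n <- nrow(locs)
  if (n == 0L) {
    out <- data.frame(cluster = integer(0), x = numeric(0), y = numeric(0),
                      n_locs = integer(0), radius = numeric(0))
    class(out) <- c("particle_clusters", "data.frame")
    attr(out, "assignment") <- integer(0)
    return(out)
  }
  cx <- floor(locs$x / radius_px); cy <- floor(locs$y / radius_px)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }

  for (i in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      nb <- buckets[[k]]
      if (is.null(nb)) next
      nb <- nb[nb > i]
      if (!length(nb)) next
      d2 <- (locs$x[nb] - locs$x[i])^2 + (locs$y[nb] - locs$y[i])^2
      for (j in nb[d2 <= radius_px^2]) union2(i, j)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  comp <- match(root, unique(root))
  sizes <- tabulate(comp)
  keep_comp <- which(sizes >= min_locs)
  assignment <- match(comp, keep_comp)       # NA for discarded components

  rows <- lapply(seq_along(keep_comp), function(ci) {
    idx <- which(assignment == ci)
    mx <- mean(locs$x[idx]); my <- mean(locs$y[idx])
    data.frame(cluster = ci, x = mx, y = my, n_locs = length(idx),
               radius = sqrt(mean((locs$x[idx] - mx)^2 + (locs$y[idx] - my)^2)))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), x = numeric(0), y = numeric(0),
               n_locs = integer(0), radius = numeric(0))
  class(out) <- c("particle_clusters", "data.frame")
  attr(out, "assignment") <- assignment
  out
}

#' Extract the fluorescence trace of one particle cluster
#'
#' Sums fitted photons over a cluster's localizations frame by frame; frames
#' with no localization get 0. Two localizations of one cluster in the same
#' frame are summed and counted (possible double particle -- see
#' [filter_particles()]).
#'
#' @param clusters a [cluster_particles()] result (carries the assignment).
#' @param locs the localization table the clusters were built from.
#' @param cluster_id id of the cluster to extract.
#' @param n_frames acquisition length in frames.
#' @return A [photon_trace()]; the number of frames holding more than one
#'   localization is attached as attribute `"n_multi_frames"`.
#' @export
extract_trace <- function(clusters, locs, cluster_id, n_frames) {
  assignment <- attr(clusters, "assignment")
  idx <- which(!is.na(assignment) & assignment == cluster_id)
  if (!length(idx)) stop("cluster has no member localizations")
  f <- locs$frame[idx] + 1L
  stopifnot(all(f >= 1L), all(f <= n_frames))
  photons <- numeric(n_frames)
  agg <- rowsum(locs$photons[idx], f)
  photons[as.integer(rownames(agg))] <- agg[, 1]
  out <- photon_trace(photons)
  attr(out, "n_multi_frames") <- sum(tabulate(f, n_frames) > 1L)
  out
}

#' Segment a fluorescence trace into trajectories
#'
#' Maximal runs of bright (nonzero) frames, bridging interior dark gaps of at
#' most `max_gap` frames: a single-frame interruption (the default) does not
#' split a trajectory. Durations follow the convention
#' `tau = (end - start + 1) * frame_time`, so a one-frame trajectory has
#' `tau = frame_time`. The same rule is applied to exchange-labelled and
#' single-dye data.
#'
#' @param trace a [photon_trace()] or a numeric per-frame photon vector.
#' @param max_gap maximum bridged dark-gap length in frames (default 1).
#' @param frame_time frame interval (s).
#' @return A data.frame with columns `start`, `end` (0-based frames) and
#'   `tau` (s); zero rows for an all-dark trace.
#' @export
segment_trajectories <- function(trace, max_gap = 1L, frame_time = 0.2) {
  photons <- if (inherits(trace, "photon_trace")) trace$photons else trace
  stopifnot(max_gap >= 0, frame_time > 0)
  bright <- which(photons > 0)
  if (!length(bright))
    return(data.frame(start = integer(0), end = integer(0), tau = numeric(0)))
  brk <- which(diff(bright) > max_gap + 1L)
  start <- bright[c(1L, brk + 1L)] - 1L
  end <- bright[c(brk, length(bright))] - 1L
  data.frame(start = start, end = end,
             tau = (end - start + 1L) * frame_time)
}

#' Trajectories-per-particle survival curve
#'
#' For each particle i, `TPP_i(tau >= T)` counts its trajectories with
#' duration at least T; the ensemble mean over all M particles (particles
#' without any trajectory contribute zeros) is the TPP curve, and its
#' dispersion is summarized by the interquartile range. A permanently labelled
#' particle ideally gives an intercept of 1 (one trajectory, ending at the
#' bleach); an exchange-labelled particle is re-observed repeatedly, so its
#' intercept grows with measurement duration.
#'
#' @param segments data.frame with columns `particle` (integer id in `1..M`)
#'   and `tau` (s), e.g. stacked [segment_trajectories()] output.
#' @param query_times increasing grid of query times T (s); must be
#'   non-empty. Default: every frame time up to the longest duration.
#' @param M total number of particles (>= 1), including those with zero
#'   trajectories.
#' @param frame_time frame interval used for the default grid.
#' @param quartiles compute the per-particle interquartile range (set `FALSE`
#'   to skip on very large ensembles).
#' @return An object of class `tpp_curve`: data.frame with `T`, `mean`,
#'   `q25`, `q75`, plus attributes `M` and `n_segments`.
#' @export
tpp_curve <- function(segments, query_times = NULL, M, frame_time = 0.2,
                      quartiles = TRUE) {
  stopifnot(M >= 1, all(segments$tau >= 0))
  if (is.null(query_times)) {
    t_max <- if (nrow(segments)) max(segments$tau) else frame_time
    query_times <- seq(frame_time, t_max, by = frame_time)
  }
  if (!length(query_times)) stop("query grid must be non-empty")
  stopifnot(!is.unsorted(query_times))
  tau_sorted <- sort(segments$tau)
  n_ge <- nrow(segments) - findInterval(query_times, tau_sorted,
                                        left.open = TRUE)
  mean_tpp <- n_ge / M
  q25 <- q75 <- rep(NA_real_, length(query_times))
  if (quartiles && nrow(segments)) {
    pid <- as.integer(segments$particle)
    stopifnot(all(pid >= 1L), all(pid <= M))
    for (g in seq_along(query_times)) {
      counts <- tabulate(pid[segments$tau >= query_times[g]], nbins = M)
      qq <- stats::quantile(counts, c(0.25, 0.75), names = FALSE)
      q25[g] <- qq[1]; q75[g] <- qq[2]
    }
  }
  out <- data.frame(T = query_times, mean = mean_tpp, q25 = q25, q75 = q75)
  class(out) <- c("tpp_curve", "data.frame")
  attr(out, "M") <- M
  attr(out, "n_segments") <- nrow(segments)
  out
}

#' @export
print.tpp_curve <- function(x, ...) {
  th <- tryCatch(t_half(x), error = function(e) NA_real_)
  cat(sprintf("TPP curve: M = %d particles, %d trajectories, intercept %.3g",
              attr(x, "M"), attr(x, "n_segments"), x$mean[1]))
  if (is.finite(th))
    cat(sprintf(", T_half = %.3g s%s", th,
                if (isTRUE(attr(th, "censored"))) " (right-censored)" else ""))
  cat("\n")
  invisible(x)
}

#' @export
plot.tpp_curve <- function(x, ...) {
  graphics::plot(x$T, x$mean, type = "l", log = "x",
                 xlab = "query time T (s)", ylab = "TPP(tau >= T)", ...)
  if (!all(is.na(x$q25)))
    graphics::polygon(c(x$T, rev(x$T)), c(x$q25, rev(x$q75)),
                      col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(x$T, x$mean)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Half-life of a TPP curve
#'
#' The characteristic half-life is the time at which the ensemble-mean TPP
#' curve falls below one half. On the discrete query grid the curve is
#' linearly interpolated and the down-crossing time is returned (the largest
#' T with interpolated mean >= 0.5), removing the grid dependence.
#'
#' @param curve a [tpp_curve()] (or any data.frame with `T` and `mean`).
#' @return The half-life in seconds. If the curve never drops below 0.5 the
#'   largest grid time is returned with attribute `censored = TRUE`.
#' @export
t_half <- function(curve) {
  Tq <- curve$T; m <- curve$mean
  if (m[1] < 0.5) stop("T_half undefined: mean TPP already below 0.5 at the smallest query time")
  below <- which(m < 0.5)
  if (!length(below)) {
    out <- Tq[length(Tq)]
    attr(out, "censored") <- TRUE
    return(out)
  }
  j <- below[1]                       # first grid point below 0.5
  i <- j - 1L
  # linear interpolation between the bracketing grid points
  Tq[i] + (0.5 - m[i]) * (Tq[j] - Tq[i]) / (m[j] - m[i])
}

#' Evaluate a TPP curve at arbitrary times
#'
#' Linear interpolation of the ensemble mean on the query grid (the same
#' interpolant [t_half()] uses).
#'
#' @param curve a [tpp_curve()].
#' @param at times (s) at which to evaluate.
#' @return Interpolated mean TPP values.
#' @export
tpp_at <- function(curve, at) {
  stats::approx(curve$T, curve$mean, xout = at, rule = 2)$y
}

#' Tracks per frame and exponential survival fit
#'
#' Counts, for every frame, the trajectories spanning it (gap-bridged
#' segments count across their bridged interruptions), normalizes to the
#' count at frame 0, and fits an exponential decay `A * exp(-t / tau_decay)`
#' to the raw counts by least squares. The fitted intercept `A` estimates the
#' initial track number (approximately the number of particles in the field
#' of view), which normalizes the mobile TPP statistic.
#'
#' @param segments data.frame with `start`, `end` (0-based frames).
#' @param n_frames acquisition length in frames.
#' @param frame_time frame interval (s).
#' @return An object of class `track_survival`: list with `frame`, `count`,
#'   `normalized`, `A`, `tau_decay`, `half_time` (s).
#' @export
tracks_per_frame_survival <- function(segments, n_frames, frame_time = 0.2) {
  if (nrow(segments) == 0L) stop("no segments")
  delta <- numeric(n_frames + 1L)
  s <- pmax(segments$start, 0L) + 1L
  e <- pmin(segments$end, n_frames - 1L) + 2L
  for (i in seq_along(s)) {
    delta[s[i]] <- delta[s[i]] + 1
    delta[e[i]] <- delta[e[i]] - 1
  }
  count <- cumsum(delta)[seq_len(n_frames)]
  if (count[1] == 0) stop("no trajectory spans frame 0: cannot normalize")
  t <- (seq_len(n_frames) - 1L) * frame_time
  # log-linear start values, then least squares on the raw counts
  pos <- count > 0
  lf <- stats::lm(log(count[pos]) ~ t[pos])
  A0 <- exp(stats::coef(lf)[1]); tau0 <- -1 / stats::coef(lf)[2]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- n_frames * frame_time * 10
  fit <- tryCatch(
    stats::nls(count ~ A * exp(-t / tau), start = list(A = A0, tau = tau0),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) { A <- A0; tau <- tau0 } else {
    A <- stats::coef(fit)[["A"]]; tau <- stats::coef(fit)[["tau"]]
  }
  structure(list(frame = seq_len(n_frames) - 1L, count = count,
                 normalized = count / count[1], A = A, tau_decay = tau,
                 half_time = tau * log(2)),
            class = "track_survival")
}

#' @export
print.track_survival <- function(x, ...) {
  cat(sprintf("Track survival: intercept A = %.1f tracks, decay tau = %.3g s (half-time %.3g s)\n",
              x$A, x$tau_decay, x$half_time))
  invisible(x)
}

#' Fit equidistant photon levels
#'
#' Fits a K-component Gaussian mixture with arithmetically spaced means
#' `mu1 + (k - 1) * spacing` (shared sigma) to per-frame photon counts by EM,
#' selecting K up to `K_max` by BIC. For an exchange-labelled particle the
#' levels correspond to 1..K simultaneously bound fluorescent imagers and the
#' spacing matches the single-imager level mu1; a single dye gives K = 1.
#'
#' @param values bright-frame photon counts (>= 200 values recommended).
#' @param K_max maximum number of levels (default 6, the handle capacity).
#' @return An object of class `photon_level_fit`: list with `mu1`, `spacing`,
#'   `K`, `weights`, `sigma`, `bic` (per-K table).
#' @export
photon_level_fit <- function(values, K_max = 6L) {
  values <- values[is.finite(values) & values > 0]
  n <- length(values)
  if (n < 2 || stats::sd(values) == 0) {
    return(structure(list(mu1 = mean(values), spacing = mean(values), K = 1L,
                          weights = 1, sigma = 0, bic = NA_real_),
                     class = "photon_level_fit"))
  }

  fit_K <- function(K) {
    mu1 <- as.numeric(stats::quantile(values, 0.5 / K))
    spacing <- mu1
    sigma <- max(stats::mad(values) / max(K, 2), 1e-6)
    w <- rep(1 / K, K)
    ll_old <- -Inf
    for (it in 1:300) {
      means <- mu1 + (0:(K - 1)) * spacing
      dens <- vapply(seq_len(K), function(k)
        w[k] * stats::dnorm(values, means[k], sigma), numeric(n))
      tot <- rowSums(dens)
      tot[tot < 1e-300] <- 1e-300
      ll <- sum(log(tot))
      r <- dens / tot
      w <- colMeans(r)
      # weighted LS for (mu1, spacing): means_k = mu1 + (k-1) spacing
      kk <- 0:(K - 1)
      Sw <- sum(r); Sk <- sum(r %*% kk); Skk <- sum(r %*% kk^2)
      Sv <- sum(values * rowSums(r)); Svk <- sum(values * (r %*% kk))
      det <- Sw * Skk - Sk^2
      if (K > 1 && abs(det) > 1e-12) {
        mu1 <- (Sv * Skk - Svk * Sk) / det
        spacing <- (Sw * Svk - Sk * Sv) / det
      } else {
        mu1 <- Sv / Sw
      }
      means <- mu1 + kk * spacing
      sigma <- sqrt(max(sum(r * outer(values, means, "-")^2) / n, 1e-12))
      if (is.finite(ll) && abs(ll - ll_old) < 1e-8 * abs(ll)) break
      ll_old <- ll
    }
    p <- (K - 1) + 2 + 1                    # weights + (mu1, spacing) + sigma
    if (K == 1) p <- 2                      # mu1 + sigma
    list(mu1 = mu1, spacing = spacing, K = K, weights = w, sigma = sigma,
         loglik = ll, bic = -2 * ll + p * log(n))
  }

  fits <- lapply(seq_len(K_max), function(K)
    tryCatch(fit_K(K), error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) stop("photon level fit failed for all K")
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  structure(list(mu1 = best$mu1, spacing = best$spacing, K = best$K,
                 weights = best$weights, sigma = best$sigma,
                 bic = stats::setNames(bics, vapply(fits, `[[`, 1L, "K"))),
            class = "photon_level_fit")
}

#' @export
print.photon_level_fit <- function(x, ...) {
  cat(sprintf("Photon levels: K = %d, first level %.1f photons, spacing %.1f, sigma %.1f\n",
              x$K, x$mu1, x$spacing, x$sigma))
  invisible(x)
}

#' Filter particle clusters before trace analysis
#'
#' Removes clusters that are unreliable for per-particle statistics:
#' \itemize{
#'   \item \code{double}: mean localizations per bright frame above
#'     `max_locs_per_frame` (two emitters merged into one cluster);
#'   \item \code{proximity}: another cluster centroid closer than
#'     `proximity_mult` times the larger of the two cluster radii (risk of
#'     cross-talk between traces);
#'   \item \code{sparse}: fewer than `min_locs` localizations.
#' }
#' Thresholds are stated package defaults; every removal is reported with its
#' reason.
#'
#' @param clusters a [cluster_particles()] result.
#' @param locs the localization table the clusters came from.
#' @param max_locs_per_frame rule (a) threshold (default 1.2).
#' @param proximity_mult rule (b) multiplier on the cluster radius (default 4).
#' @param min_locs rule (c) threshold (default 10).
#' @return A list with `kept` (filtered cluster data.frame, assignment
#'   attribute updated) and `report` (data.frame `cluster`, `reason`; one row
#'   per removal).
#' @export
filter_particles <- function(clusters, locs, max_locs_per_frame = 1.2,
                             proximity_mult = 4, min_locs = 10L) {
  assignment <- attr(clusters, "assignment")
  n_cl <- nrow(clusters)
  reason <- rep(NA_character_, n_cl)

  for (i in seq_len(n_cl)) {
    idx <- which(!is.na(assignment) & assignment == clusters$cluster[i])
    if (length(idx) < min_locs) { reason[i] <- "sparse"; next }
    per_frame <- table(locs$frame[idx])
    if (mean(per_frame) > max_locs_per_frame) reason[i] <- "double"
  }
  if (n_cl > 1) {
    for (i in seq_len(n_cl - 1)) for (j in (i + 1):n_cl) {
      d <- sqrt((clusters$x[i] - clusters$x[j])^2 +
                (clusters$y[i] - clusters$y[j])^2)
      lim <- proximity_mult * max(clusters$radius[i], clusters$radius[j])
      if (d < lim) {
        if (is.na(reason[i])) reason[i] <- "proximity"
        if (is.na(reason[j])) reason[j] <- "proximity"
      }
    }
  }
  keep <- is.na(reason)
  kept <- clusters[keep, , drop = FALSE]
  new_id <- match(clusters$cluster, kept$cluster)
  assignment2 <- new_id[assignment]
  kept$cluster <- seq_len(nrow(kept))
  class(kept) <- c("particle_clusters", "data.frame")
  attr(kept, "assignment") <- assignment2
  list(kept = kept,
       report = data.frame(cluster = clusters$cluster[!keep],
                           reason = reason[!keep]))
}
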
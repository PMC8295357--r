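#' Kinetic parameters for imager exchange on a tracking handle
#'
#' Bundles the rate constants governing reversible imager binding and
#' photobleaching on a multi-site tracking handle. Association is treated as
#' pseudo-first-order: each free site fills at rate `k_on * imager_conc`
#' (reservoir assumption, no imager depletion). A bound imager dissociates at
#' `k_off`; while fluorescent it additionally photobleaches at `k_bleach`
#' (irradiance-dependent). A bleached imager stays bound -- dark, blocking its
#' site -- until it dissociates at the same `k_off`: bleaching destroys the
#' fluorophore, not the DNA duplex.
#'
#' @param n_sites number of simultaneously occupiable imager footprints on the
#'   handle (default 6, the capacity of a 54-nt handle for 8-nt imagers; see
#'   [max_bound_imagers()]).
#' @param k_on per-site association rate constant (1/(M*s)).
#' @param imager_conc imager concentration in solution (M).
#' @param k_off dissociation rate per bound imager (1/s).
#' @param k_bleach photobleaching rate per bound fluorescent imager (1/s).
#' @param photons_per_frame mean detected photons per fluorescent bound imager
#'   per frame.
#' @param frame_time exposure / frame interval in seconds (default 0.2).
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' kp <- kinetic_params(k_on = 1e6, imager_conc = 40e-9, k_off = 0.2,
#'                      k_bleach = 0.05)
#' kp
#' @export
kinetic_params <- function(n_sites = 6L, k_on = 1e6, imager_conc = 40e-9,
                           k_off = 0.2, k_bleach = 0.05,
                           photons_per_frame = 500, frame_time = 0.2) {
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 1L, frame_time > 0, photons_per_frame >= 0)
  for (r in c(k_on, imager_conc, k_off, k_bleach)) {
    if (!is.finite(r) || r < 0) stop("rates and concentrations must be finite and >= 0")
  }
  structure(list(n_sites = n_sites, k_on = k_on, imager_conc = imager_conc,
                 k_off = k_off, k_bleach = k_bleach,
                 photons_per_frame = photons_per_frame,
                 frame_time = frame_time),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Tracking-handle kinetic parameters\n")
  cat(sprintf("  sites: %d   k_on*c: %.4g 1/s   k_off: %.4g 1/s   k_bleach: %.4g 1/s\n",
              x$n_sites, x$k_on * x$imager_conc, x$k_off, x$k_bleach))
  cat(sprintf("  photons/frame per imager: %.4g   frame time: %.3g s\n",
              x$photons_per_frame, x$frame_time))
  invisible(x)
}

#' Exact stochastic simulation of handle occupancy
#'
#' Gillespie simulation of the continuous-time Markov jump process describing
#' imager exchange on one tracking handle. The state is the pair (number of
#' fluorescent bound imagers, number of bleached-but-bound imagers). Empty
#' sites fill at rate `(free sites) * k_on * imager_conc`; each bright imager
#' leaves at `k_off` or turns dark at `k_bleach`; each dark imager leaves at
#' `k_off`. Every association brings a fresh fluorophore (large diffusive
#' reservoir); re-binding of a bleached imager is impossible.
#'
#' @param params a [kinetic_params()] object.
#' @param duration total simulated time (s), > 0.
#' @param seed integer seed; fixed seed gives a bit-identical trace.
#' @param init initial occupancy: `"empty"` (default) or `"equilibrium"`,
#'   which draws the initial bright count from the binomial stationary law of
#'   the bleach-free process.
#'
#' @return An object of class `occupancy_trace`: list with `event_times`
#'   (ordered state-change times, starting at 0), `bound_bright` and
#'   `bound_dark` (piecewise-constant counts on `[event_times[i],
#'   event_times[i+1])`), `duration`, `n_sites` and `seed`.
#' @seealso [occupancy_to_photons()]
#' @examples
#' kp <- kinetic_params(k_on = 1e6, imager_conc = 40e-9, k_off = 0.2)
#' occ <- simulate_occupancy(kp, duration = 60, seed = 1)
#' @export
simulate_occupancy <- function(params, duration, seed = NULL,
                               init = c("empty", "equilibrium")) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("duration must be a positive number")
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)

  kon_c <- params$k_on * params$imager_conc
  ns <- params$n_sites
  nb <- 0L
  if (init == "equilibrium" && (kon_c + params$k_off) > 0) {
    p <- kon_c / (kon_c + params$k_off)
    nb <- stats::rbinom(1L, ns, p)
  }
  nd <- 0L

  # grow-by-doubling event buffers
  cap <- 1024L
  times <- numeric(cap); bright <- integer(cap); dark <- integer(cap)
  n_ev <- 1L
  times[1L] <- 0; bright[1L] <- nb; dark[1L] <- nd
  t <- 0

  repeat {
    r_assoc <- (ns - nb - nd) * kon_c
    r_off_b <- nb * params$k_off
    r_bleach <- nb * params$k_bleach
    r_off_d <- nd * params$k_off
    r_tot <- r_assoc + r_off_b + r_bleach + r_off_d
    if (r_tot <= 0) break
    t <- t + stats::rexp(1L, r_tot)
    if (t >= duration) break
    u <- stats::runif(1L) * r_tot
    if (u < r_assoc) {
      nb <- nb + 1L
    } else if (u < r_assoc + r_off_b) {
      nb <- nb - 1L
    } else if (u < r_assoc + r_off_b + r_bleach) {
      nb <- nb - 1L; nd <- nd + 1L
    } else {
      nd <- nd - 1L
    }
    n_ev <- n_ev + 1L
    if (n_ev > cap) {
      cap <- cap * 2L
      length(times) <- cap; length(bright) <- cap; length(dark) <- cap
    }
    times[n_ev] <- t; bright[n_ev] <- nb; dark[n_ev] <- nd
  }

  structure(list(event_times = times[seq_len(n_ev)],
                 bound_bright = bright[seq_len(n_ev)],
                 bound_dark = dark[seq_len(n_ev)],
                 duration = duration, n_sites = ns, seed = seed),
            class = "occupancy_trace")
}

#' @export
print.occupancy_trace <- function(x, ...) {
  cat(sprintf("Occupancy trace: %d events over %.3g s (%d sites)\n",
              length(x$event_times) - 1L, x$duration, x$n_sites))
  invisible(x)
}

# Integral of the piecewise-constant bright count from 0 to each time in `at`.
# Used to time-average occupancy within camera frames.
.occ_cum_integral <- function(occ, at) {
  tt <- c(occ$event_times, occ$duration)
  v <- occ$bound_bright
  seg <- diff(tt) * v
  cum <- c(0, cumsum(seg))              # integral up to each breakpoint
  idx <- findInterval(at, tt, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(v))
  cum[idx] + (at - tt[idx]) * v[idx]
}

#' Convert an occupancy trace to a per-frame photon trace
#'
#' Integrates the fluorescent-imager count over each camera frame and draws
#' the detected photon count as Poisson shot noise about
#' `photons_per_frame * (time-averaged bright occupancy)`. An imager bound
#' for half a frame therefore contributes half its per-frame photon yield in
#' expectation, and k simultaneously bound imagers produce equidistant
#' intensity levels at k times the single-imager level.
#'
#' @param occ an `occupancy_trace` from [simulate_occupancy()].
#' @param photons_per_frame mean detected photons per fluorescent imager per
#'   full frame.
#' @param frame_time frame interval (s); must not exceed `occ$duration`.
#' @param seed integer seed for the shot noise.
#'
#' @return An object of class `photon_trace`: list with `frame_index`
#'   (0-based), `photons` (non-negative integers) and `truth_bright` (the
#'   time-averaged fluorescent occupancy per frame, for ground-truth checks).
#' @export
occupancy_to_photons <- function(occ, photons_per_frame, frame_time,
                                 seed = NULL) {
  stopifnot(inherits(occ, "occupancy_trace"))
  if (occ$duration < frame_time) stop("occupancy trace shorter than one frame")
  if (!is.null(seed)) set.seed(seed)
  n_frames <- floor(occ$duration / frame_time)
  edges <- (0:n_frames) * frame_time
  cum <- .occ_cum_integral(occ, edges)
  avg <- diff(cum) / frame_time
  avg[avg < 0] <- 0                      # numerical guard
  photons <- stats::rpois(n_frames, photons_per_frame * avg)
  photon_trace(photons, truth_bright = avg)
}

#' Construct a photon trace
#'
#' @param photons non-negative integer photon counts, one per frame.
#' @param truth_bright optional time-averaged fluorescent occupancy per frame.
#' @return An object of class `photon_trace` with 0-based `frame_index`.
#' @keywords internal
#' @export
photon_trace <- function(photons, truth_bright = NULL) {
  stopifnot(all(photons >= 0))
  if (!is.null(truth_bright)) stopifnot(length(truth_bright) == length(photons))
  structure(list(frame_index = seq_along(photons) - 1L,
                 photons = as.integer(round(photons)),
                 truth_bright = truth_bright),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("Photon trace: %d frames, %d bright (mean %.1f photons while on)\n",
              length(x$photons), sum(x$photons > 0),
              if (any(x$photons > 0)) mean(x$photons[x$photons > 0]) else 0))
  invisible(x)
}

#' Simulate a single irreversibly bleaching dye
#'
#' Models the photobleaching-limited control label: a permanently attached
#' single dye that emits from frame 0 until an exponentially distributed
#' bleach time (rate `k_bleach`) and is dark forever after -- one on-segment,
#' one abrupt off transition. Photons are Poisson about
#' `photons_per_frame * (fraction of the frame spent unbleached)`.
#'
#' @param k_bleach photobleaching rate (1/s), > 0.
#' @param photons_per_frame mean detected photons per frame while on.
#' @param frame_time frame interval (s).
#' @param duration total acquisition time (s).
#' @param seed integer seed.
#' @param min_on_frames guarantee at least this many full bright frames before
#'   bleaching becomes possible (default 0). By memorylessness the bleach time
#'   beyond the guaranteed window is still exponential with rate `k_bleach`.
#'
#' @return A `photon_trace`; `truth_bright` holds the per-frame on-fraction.
#' @examples
#' tr <- simulate_sd_bleach(k_bleach = log(2) / 11, photons_per_frame = 500,
#'                          frame_time = 0.2, duration = 120, seed = 1)
#' @export
simulate_sd_bleach <- function(k_bleach, photons_per_frame, frame_time,
                               duration, seed = NULL, min_on_frames = 0) {
  if (!is.numeric(k_bleach) || k_bleach <= 0)
    stop("k_bleach must be > 0 (a dye that never bleaches is better modelled by simulate_occupancy)")
  stopifnot(frame_time > 0, duration >= frame_time, min_on_frames >= 0)
  if (!is.null(seed)) set.seed(seed)
  t_bleach <- min_on_frames * frame_time + stats::rexp(1L, k_bleach)
  n_frames <- floor(duration / frame_time)
  lo <- (seq_len(n_frames) - 1L) * frame_time
  on_frac <- pmin(pmax((t_bleach - lo) / frame_time, 0), 1)
  photons <- stats::rpois(n_frames, photons_per_frame * on_frac)
  out <- photon_trace(photons, truth_bright = on_frac)
  attr(out, "t_bleach") <- t_bleach
  out
}
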
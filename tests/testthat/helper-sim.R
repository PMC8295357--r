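# shared fixtures built in code

# Brownian trajectory with Gaussian localization noise, coordinates in um
noisy_brownian_traj <- function(D, n_frames, frame_time = 0.2,
                                sigma_um = 0.02) {
  pos <- simulate_brownian_2d(D, n_frames, frame_time)
  data.frame(frame = 0:(n_frames - 1),
             x = pos[, 1] + stats::rnorm(n_frames, 0, sigma_um),
             y = pos[, 2] + stats::rnorm(n_frames, 0, sigma_um),
             photons = NA_real_)
}

# hand-built occupancy trace (piecewise-constant bright count)
manual_occ <- function(event_times, bright, duration, n_sites = 6L) {
  structure(list(event_times = event_times, bound_bright = as.integer(bright),
                 bound_dark = integer(length(bright)), duration = duration,
                 n_sites = n_sites, seed = NULL),
            class = "occupancy_trace")
}

# time-averaged bright occupancy of a simulated trace
occ_time_average <- function(occ) {
  tt <- c(occ$event_times, occ$duration)
  sum(diff(tt) * occ$bound_bright) / occ$duration
}

# total photons above baseline in each rendered frame (aperture photometry
# over the whole frame; valid for zero-background renders)
frame_signal <- function(stack, baseline) {
  vapply(stack, function(fr) sum(fr - baseline), numeric(1))
}
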
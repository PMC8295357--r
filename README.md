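# thtrack

Single-particle tracking (SPT) with a conventional label ends when its one
dye photobleaches. An *exchange label* replaces the dye continuously: a
single-stranded DNA "tracking handle" (TH) attached 1:1 to the target is
transiently bound by short dye-labelled oligonucleotides ("imagers") from a
large solution reservoir, so bleached fluorophores dissociate and fresh ones
take their place. `thtrack` is an R toolkit for studying this labeling
scheme end to end in simulation and for analyzing localization data produced
by it (or by any SPT pipeline that can export `frame, x, y, photons`
tables). It is aimed at single-molecule microscopists who want to quantify
what exchange labeling buys — more trajectories per particle, longer
observation, richer statistics — and at method developers who need a tested,
ground-truth-driven SPT analysis chain.

## What it implements

* **Imager-exchange kinetics** — exact stochastic (Gillespie) simulation of
  association (`k_on·c` per free site), dissociation (`k_off`) and
  photobleaching (`k_bleach`) on an `n_sites`-capacity handle, plus the
  irreversibly bleaching single-dye (SD) control, down to per-frame
  shot-noise photon traces. The default handle is the 54-nt poly-(TCC)
  repeat bound by the 8-nt imager `5'-GAGGAGGA-3'`; footprint enumeration
  (`max_bound_imagers()`) caps it at 6 simultaneous imagers.
* **Synthetic TIRF movies** — immobile or 2D Brownian ground truth
  (`x,y` increments of variance `2·D·Δt`), optional injected slowdowns, and
  16-bit movie rendering with pixel-integrated Gaussian PSF, Poisson shot
  noise and camera baseline (defaults: 130 nm pixels, 200 ms frames).
* **Localization** — difference-of-Gaussians detection, integrated-Gaussian
  least-squares fitting, Mortensen precision estimates.
* **Trajectories-per-particle (TPP) statistics** — traces are segmented into
  trajectories bridging single-frame dark gaps; for particle *i*,
  `TPP_i(τ ≥ T)` counts its trajectories of duration at least `T`, the
  ensemble mean over `M` particles defines the TPP curve, and the half-life
  `T½` is the interpolated time where the mean falls below 0.5. Per-frame
  track-survival curves with exponential fits supply the initial track
  number `M` that normalizes the mobile-case TPP.
* **Diffusion estimation** — nearest-neighbour trajectory linking with one
  frame of memory; per-trajectory `D` from `MSD(t) = 4Dt + b` fitted by
  generalized least squares with the exact Brownian MSD covariance, the
  number of fitted lags chosen iteratively from the reduced noise parameter
  `x = b/(4DΔt)`.
* **Subtrajectory motion-change analysis** — trajectories ≥ 120 s are split
  into 50-frame blocks; the RMSD of block-wise `D_sub` about `D`, normalized
  to `D`, is compared with the theoretical relative standard deviation
  `sqrt(2n/(3(N−n)))` of a short-segment estimate. Time-invariant Brownian
  motion sits near that limit; genuine motion changes (e.g. a fourfold
  slowdown in every fourth block) violate it and produce a second `D_sub`
  mode.
* **Spatial occupancy maps** — unique trajectories per 2×2-binned pixel.
* **IO and pipeline** — CSV localization/trace tables, multi-page TIFF
  stacks, YAML configs, JSON reports/manifests, and a command-line driver
  (`inst/cli/thtrack.R`) with `simulate | localize | track |
  analyze-immobile | analyze-mobile | report` stages and per-stage seeds.

## Worked example

Simulate one tracking handle for 10 minutes, convert to a photon trace, and
segment it; then compare TPP curves of 300 simulated SD and TH particles:

```r
library(thtrack)

kp <- kinetic_params(k_on = 1e6, imager_conc = 40e-9, k_off = 0.2,
                     k_bleach = 0.05, photons_per_frame = 500)
occ <- simulate_occupancy(kp, duration = 600, seed = 1)
trace <- occupancy_to_photons(occ, 500, 0.2, seed = 2)
occ
#> Occupancy trace: 254 events over 600 s (6 sites)
trace
#> Photon trace: 3000 frames, 1740 bright (mean 636.4 photons while on)
nrow(segment_trajectories(trace, max_gap = 1, frame_time = 0.2))
#> [1] 60
```

One handle yielded 60 trajectories in 10 min — imagers kept arriving after
every fully-dark interruption longer than one frame. Ensembles make the
contrast with a single dye explicit:

```r
sd_segs <- do.call(rbind, lapply(1:300, function(i) {
  tr <- simulate_sd_bleach(log(2) / 11, 500, 0.2, 120, seed = 5000 + i)
  s <- segment_trajectories(tr)
  if (nrow(s)) cbind(particle = i, s) else NULL
}))
tpp_curve(sd_segs, M = 300, frame_time = 0.2)
#> TPP curve: M = 300 particles, 300 trajectories, intercept 1, T_half = 12.2 s

th_segs <- do.call(rbind, lapply(1:300, function(i) {
  o <- simulate_occupancy(kp, 600, seed = 7000 + i)
  tr <- occupancy_to_photons(o, 500, 0.2, seed = 8000 + i)
  s <- segment_trajectories(tr)
  if (nrow(s)) cbind(particle = i, s) else NULL
}))
tpp_curve(th_segs, M = 300, frame_time = 0.2)
#> TPP curve: M = 300 particles, 15841 trajectories, intercept 52.8, T_half = 35 s
```

Each single-dye particle produced exactly one trajectory (intercept 1) with
half-life `ln 2 / k_bleach ≈ 11 s`, while each exchange-labelled particle
produced ~53 trajectories with a threefold longer half-life under these
kinetics — the qualitative regime exchange labeling is designed to reach.
The methods vignette (`vignettes/tracking-handle-spt.Rmd`) documents the
model assumptions, parameter defaults, numerical choices and limitations.

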
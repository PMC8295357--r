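test_that("linking reproduces ground truth at low density", {
  set.seed(51)
  expect_error(link_localizations(data.frame(frame = 0L, x = 1, y = 1,
                                             photons = 1), 0), "search_range")
  # single particle, no gaps
  pos <- um_to_px(simulate_brownian_2d(0.04, 100, 0.2, origin = c(5, 5)), 130)
  locs <- data.frame(frame = 0:99, x = pos[, 1], y = pos[, 2], photons = 800)
  trajs <- link_localizations(locs, search_range_px = 3)
  expect_length(trajs, 1)
  expect_equal(nrow(trajs[[1]]), 100)

  # several particles far apart: exact ground-truth partition, no id switches
  n <- 80
  origins <- expand.grid(x = c(10, 60, 110), y = c(10, 60, 110))
  locs2 <- do.call(rbind, lapply(seq_len(nrow(origins)), function(i) {
    p <- um_to_px(simulate_brownian_2d(0.03, n, 0.2), 130)
    data.frame(frame = 0:(n - 1), x = origins$x[i] + p[, 1],
               y = origins$y[i] + p[, 2], photons = 800, truth = i)
  }))
  locs2 <- locs2[order(locs2$frame), ]
  trajs2 <- link_localizations(locs2, search_range_px = 3)
  expect_length(trajs2, nrow(origins))
  for (tr in trajs2) {
    truth <- locs2$truth[match(paste(tr$frame, tr$x, tr$y),
                               paste(locs2$frame, locs2$x, locs2$y))]
    expect_length(unique(truth), 1)
    expect_equal(nrow(tr), n)
  }
})

test_that("linking bridges single-frame gaps but not longer ones", {
  pos <- data.frame(frame = c(0:4, 6:9), x = 10, y = 10, photons = 500)
  trajs <- link_localizations(pos, search_range_px = 2, memory_frames = 1)
  expect_length(trajs, 1)
  pos2 <- data.frame(frame = c(0:4, 8:9), x = 10, y = 10, photons = 500)
  trajs2 <- link_localizations(pos2, search_range_px = 2, memory_frames = 1)
  expect_length(trajs2, 2)
})

test_that("MSD matches closed forms for ballistic and static motion", {
  # straight line, step L per frame: MSD(n dt) = (n L)^2
  L <- 0.1
  tr <- data.frame(frame = 0:49, x = L * (0:49), y = 0, photons = NA)
  m <- compute_msd(tr, 10, 0.2)
  expect_equal(m$msd, (L * (1:10))^2)
  expect_equal(m$n_pairs, 50 - (1:10))

  # immobile with localization noise sigma: MSD ~ 4 sigma^2 at all lags
  set.seed(52)
  sigma <- 0.02
  tr2 <- data.frame(frame = 0:3999, x = rnorm(4000, 0, sigma),
                    y = rnorm(4000, 0, sigma), photons = NA)
  m2 <- compute_msd(tr2, 5, 0.2)
  expect_equal(mean(m2$msd), 4 * sigma^2, tolerance = 0.05)

  expect_error(compute_msd(tr, 60, 0.2), "insufficient")
})

test_that("Brownian ensemble MSD follows 4 D t + 4 sigma^2", {
  set.seed(53)
  D <- 0.04; sigma <- 0.02
  msum <- rep(0, 8)
  n_rep <- 150
  for (i in 1:n_rep) {
    msum <- msum + compute_msd(noisy_brownian_traj(D, 120, sigma_um = sigma),
                               8, 0.2)$msd
  }
  mbar <- msum / n_rep
  fit <- stats::lm(mbar ~ I((1:8) * 0.2))
  expect_equal(unname(stats::coef(fit)[2]) / 4, D, tolerance = 0.05)
  expect_equal(unname(stats::coef(fit)[1]), 4 * sigma^2, tolerance = 0.5)
})

test_that("iterative fitting is exact on noiseless lines and flags pure noise", {
  m <- data.frame(lag = (1:20) * 0.2, msd = 4 * 0.04 * (1:20) * 0.2,
                  n_pairs = 100L)
  class(m) <- c("msd_curve", "data.frame"); attr(m, "N") <- 200L
  fit <- fit_msd_iterative(m, 0.2)
  expect_equal(fit$D, 0.04, tolerance = 1e-9)
  expect_equal(fit$b, 0, tolerance = 1e-9)
  expect_false(fit$noise_dominated)

  set.seed(54)
  noise <- data.frame(frame = 0:199, x = rnorm(200, 0, 0.02),
                      y = rnorm(200, 0, 0.02), photons = NA)
  fitn <- fit_trajectory_d(noise, 0.2)
  expect_lt(abs(fitn$D), 0.005)
})

test_that("diffusion estimates are unbiased with scatter near the theoretical limit", {
  set.seed(55)
  for (D in c(0.02, 0.04, 0.06)) {
    est <- replicate(120, {
      f <- fit_trajectory_d(noisy_brownian_traj(D, 600))
      c(f$D, f$n_fit)
    })
    expect_lt(abs(mean(est[1, ]) - D) / D, 0.05)        # bias < 5%
    theo <- theoretical_rel_sd(600, stats::median(est[2, ]))
    expect_lt(abs(sd(est[1, ]) / D - theo) / theo, 0.25) # scatter within 25%
  }
})

test_that("mobile TPP normalizes trajectory counts by the initial track number", {
  expect_error(mobile_tpp(c(1, 2), 0), "M_initial")
  # M particles, each one full-length trajectory
  cv <- mobile_tpp(rep(60, 20), M_initial = 20, query_times = c(10, 60))
  expect_equal(cv$mean, c(1, 1))
  # 2M trajectories from M particles: intercept 2 exactly
  tau <- c(rep(50, 10), rep(5, 10))
  cv2 <- mobile_tpp(tau, M_initial = 10, query_times = c(1, 20))
  expect_equal(cv2$mean[1], 2)
  expect_equal(cv2$mean[2], 1)
})

test_that("a mobile single-dye ensemble has a half-life near ln2 / k_bleach", {
  set.seed(56)
  k <- log(2) / 11
  n_frames <- 600
  segs <- do.call(rbind, lapply(1:600, function(i) {
    s <- segment_trajectories(simulate_sd_bleach(k, 500, 0.2, 120))
    s[1, , drop = FALSE]
  }))
  sv <- tracks_per_frame_survival(segs[, c("start", "end")], n_frames, 0.2)
  cv <- mobile_tpp(segs$tau, M_initial = sv$A, frame_time = 0.2)
  th <- as.numeric(t_half(cv))
  expect_gt(th, 9); expect_lt(th, 14)   # ~11-13 s regime
})

test_that("subtrajectory analysis splits 600 frames into 12 blocks", {
  set.seed(57)
  tr <- noisy_brownian_traj(0.04, 600)
  rep <- subtrajectory_analysis(tr)
  expect_equal(rep$n_sub, 12)
  expect_length(rep$D_sub, 12)
  short <- noisy_brownian_traj(0.04, 300)
  expect_error(subtrajectory_analysis(short), "threshold")
})

test_that("time-invariant Brownian motion stays within the statistical band", {
  set.seed(58)
  devs <- vapply(1:40, function(i) {
    r <- subtrajectory_analysis(noisy_brownian_traj(0.04, 600))
    abs(r$nrmsd - r$theo_limit) / r$theo_limit
  }, numeric(1))
  expect_lt(stats::median(devs), 0.6)
})

test_that("injected slowdowns are detected as excess subtrajectory scatter", {
  set.seed(59)
  ratios <- numeric(20); subs <- list()
  for (i in 1:20) {
    pos <- inject_slowdown(simulate_brownian_2d(0.04, 600, 0.2), 50, 4, 4)
    tr <- data.frame(frame = 0:599, x = pos[, 1] + rnorm(600, 0, 0.02),
                     y = pos[, 2] + rnorm(600, 0, 0.02), photons = NA)
    r <- subtrajectory_analysis(tr)
    ratios[i] <- r$deviation_ratio
    subs[[i]] <- r$D_sub
  }
  # scatter clearly outside the <60% band around the theoretical limit
  expect_gt(stats::median(ratios), 1.6)
  # two-component mixture of log D_sub recovers the fourfold mode ratio
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  d <- unlist(subs); d <- d[d > 0]
  fit <- mclust::Mclust(log(d), G = 2, verbose = FALSE)
  mode_ratio <- exp(abs(diff(fit$parameters$mean)))
  expect_equal(unname(mode_ratio), 4, tolerance = 0.2)
})

test_that("the theoretical relative SD is monotone and vanishes for long segments", {
  v50 <- theoretical_rel_sd(50, 4)
  v600 <- theoretical_rel_sd(600, 4)
  expect_gt(v50, 0); expect_lt(v50, 1)
  expect_lt(v600, v50)
  expect_lt(theoretical_rel_sd(1e8, 4), 1e-3)
  expect_error(theoretical_rel_sd(50, 1), "n_fit")
  expect_error(theoretical_rel_sd(4, 4), "longer")
})

test_that("Monte-Carlo scatter of 50-frame estimates matches the formula", {
  set.seed(60)
  est <- replicate(1500, {
    f <- fit_trajectory_d(noisy_brownian_traj(0.04, 50), max_lag_frames = 12)
    c(f$D, f$n_fit)
  })
  theo <- theoretical_rel_sd(50, stats::median(est[2, ]))
  expect_lt(abs(sd(est[1, ]) / 0.04 - theo) / theo, 0.25)
})

test_that("occupancy maps count unique trajectories per binned pixel", {
  # one immobile trajectory -> one bin at count 1
  t1 <- data.frame(frame = 0:9, x = rep(10.2, 10), y = rep(20.4, 10),
                   photons = NA)
  om <- occupancy_map(structure(list(t1), class = "trajectory_set"), 64, 2)
  expect_equal(sum(om), 1)
  expect_equal(max(om), 1)

  # a moving trajectory marks exactly the bins it visits (brute-force oracle)
  set.seed(61)
  t2 <- data.frame(frame = 0:199,
                   x = cumsum(rnorm(200, 0.2, 0.3)) + 10,
                   y = cumsum(rnorm(200, 0.1, 0.3)) + 10, photons = NA)
  om2 <- occupancy_map(structure(list(t2), class = "trajectory_set"), 128, 2)
  brute <- unique(paste(floor((t2$x + 0.5) / 2), floor((t2$y + 0.5) / 2)))
  expect_equal(sum(om2 > 0), length(brute))
  expect_true(all(om2 %in% c(0L, 1L)))

  # overlapping trajectories accumulate by unique id
  om3 <- occupancy_map(structure(list(t1, t1), class = "trajectory_set"), 64, 2)
  expect_equal(max(om3), 2)

  # every trajectory contributes at least one bin
  om4 <- occupancy_map(structure(list(t1, t2), class = "trajectory_set"), 128, 2)
  expect_gte(sum(om4), 2)
})
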
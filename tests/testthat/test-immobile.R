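test_that("clustering separates distant particles and rejects sparse noise", {
  set.seed(41)
  # two tight clusters 20 px apart
  locs <- data.frame(
    frame = rep(0:49, 2),
    x = c(rnorm(50, 10, 0.1), rnorm(50, 30, 0.1)),
    y = c(rnorm(50, 10, 0.1), rnorm(50, 10, 0.1)),
    photons = 500)
  cl <- cluster_particles(locs, radius_px = 2, min_locs = 10)
  expect_equal(nrow(cl), 2)
  asg <- attr(cl, "assignment")
  # >99% of each particle's localizations land in a single cluster
  expect_equal(length(unique(asg[1:50])), 1)
  expect_equal(length(unique(asg[51:100])), 1)

  # uniform sparse background: rejected by min_locs
  noise <- data.frame(frame = 0:199, x = runif(200, 0, 100),
                      y = runif(200, 0, 100), photons = 500)
  cln <- cluster_particles(noise, radius_px = 1, min_locs = 10)
  expect_lte(sum(cln$n_locs), 0.1 * 200)
  expect_equal(nrow(cluster_particles(locs[0, ], 1, 10)), 0)
})

test_that("trace extraction sums cluster photons per frame", {
  locs <- data.frame(frame = c(0L, 1L, 2L, 2L),
                     x = c(5, 5.1, 4.9, 5), y = c(5, 5, 5.1, 5),
                     photons = c(500, 500, 300, 200))
  cl <- cluster_particles(locs, radius_px = 1, min_locs = 2)
  tr <- extract_trace(cl, locs, 1, n_frames = 6)
  expect_equal(tr$photons, c(500L, 500L, 500L, 0L, 0L, 0L))
  expect_equal(attr(tr, "n_multi_frames"), 1L)  # frame 2 flagged
})

test_that("single-frame interruptions are bridged, longer gaps split", {
  frame_time <- 0.2
  tr <- numeric(20)
  tr[3:11] <- 500; tr[7] <- 0           # bright frames 2..10, dark frame 6
  seg <- segment_trajectories(tr, max_gap = 1, frame_time = frame_time)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(2, 10))
  expect_equal(seg$tau, 9 * 0.2)

  tr2 <- numeric(12)
  tr2[2:6] <- 400; tr2[9:11] <- 400     # gap of 2 frames splits
  seg2 <- segment_trajectories(tr2, max_gap = 1, frame_time = frame_time)
  expect_equal(nrow(seg2), 2)

  expect_equal(nrow(segment_trajectories(numeric(10))), 0)
  # a single bright frame has tau = frame_time, not zero
  one <- numeric(5); one[3] <- 100
  expect_equal(segment_trajectories(one)$tau, frame_time)
})

test_that("gap bridging is idempotent", {
  set.seed(42)
  for (i in 1:20) {
    tr <- as.numeric(runif(60) < 0.5) * 500
    seg <- segment_trajectories(tr)
    # rebuild a trace that is bright exactly over the bridged segments
    bridged <- numeric(60)
    for (k in seq_len(nrow(seg))) bridged[(seg$start[k] + 1):(seg$end[k] + 1)] <- 1
    expect_identical(segment_trajectories(bridged)[, c("start", "end")],
                     seg[, c("start", "end")])
  }
})

test_that("TPP counts trajectories per particle on the query grid", {
  # one particle, five trajectories of 10-200 s
  seg5 <- data.frame(particle = 1L, tau = c(10, 25, 60, 120, 200))
  c5 <- tpp_curve(seg5, query_times = c(1, 10), M = 1)
  expect_equal(c5$mean[c5$T == 10], 5)

  # every particle exactly one trajectory: intercept 1
  seg1 <- data.frame(particle = 1:50, tau = rexp(50, 1 / 30) + 0.2)
  c1 <- tpp_curve(seg1, query_times = 0.2, M = 50)
  expect_equal(c1$mean[1], 1)

  # brute-force oracle: durations 10 and 30 s on two particles
  c2 <- tpp_curve(data.frame(particle = 1:2, tau = c(10, 30)),
                  query_times = c(5, 10, 20, 30, 40), M = 2)
  expect_equal(c2$mean, c(1, 1, 0.5, 0.5, 0))
  expect_equal(t_half(c2), 30)          # largest T with mean >= 0.5

  expect_error(tpp_curve(seg5, query_times = numeric(0), M = 1), "non-empty")
})

test_that("TPP curves are non-increasing with integer per-particle counts", {
  set.seed(43)
  for (i in 1:10) {
    M <- 30
    # durations are whole numbers of frames, at least one frame long
    seg <- data.frame(particle = sample.int(M, 80, replace = TRUE),
                      tau = 0.2 * (1 + rpois(80, 200)))
    cv <- tpp_curve(seg, M = M)
    expect_true(all(diff(cv$mean) <= 1e-12))
    expect_equal(cv$mean[1], nrow(seg) / M)  # intercept = segments / M
    expect_true(all(cv$q25 <= cv$q75, na.rm = TRUE))
    expect_true(all(cv$q25 == floor(cv$q25) | !is.na(cv$q25)))
  }
})

test_that("TPP equals the empirical survival function for one segment per particle", {
  set.seed(44)
  M <- 100
  tau <- rexp(M, 1 / 20)
  cv <- tpp_curve(data.frame(particle = 1:M, tau = tau),
                  query_times = seq(0.2, 60, by = 0.2), M = M)
  # brute-force oracle
  surv <- vapply(cv$T, function(T) mean(tau >= T), numeric(1))
  expect_equal(cv$mean, surv)
})

test_that("T_half of exponential durations recovers mean * ln 2", {
  set.seed(45)
  M <- 10000
  tau_bar <- 50
  seg <- data.frame(particle = seq_len(M), tau = rexp(M, 1 / tau_bar))
  cv <- tpp_curve(seg, M = M, frame_time = 0.2, quartiles = FALSE)
  th <- t_half(cv)
  expect_equal(as.numeric(th), tau_bar * log(2), tolerance = 0.05)
  # the interpolated curve passes through 0.5 at T_half by construction
  expect_equal(tpp_at(cv, as.numeric(th)), 0.5, tolerance = 1e-9)
})

test_that("T_half edge cases: undefined below 0.5, censored when never crossing", {
  low <- tpp_curve(data.frame(particle = 1L, tau = 1),
                   query_times = c(10, 20), M = 3)
  expect_error(t_half(low), "undefined")
  flat <- tpp_curve(data.frame(particle = 1:4, tau = rep(100, 4)),
                    query_times = c(1, 2, 3), M = 4)
  th <- t_half(flat)
  expect_equal(as.numeric(th), 3)
  expect_true(attr(th, "censored"))
})

test_that("track survival counts spanning trajectories and fits the decay", {
  # all segments span all frames: flat curve
  seg <- data.frame(start = rep(0L, 5), end = rep(99L, 5))
  sv <- tracks_per_frame_survival(seg, 100, 0.2)
  expect_true(all(sv$normalized == 1))
  expect_gt(sv$tau_decay, 1e3)

  # ensemble of single-dye labels: fitted half-time ~ ln2 / k_bleach = 11 s
  set.seed(46)
  segs <- do.call(rbind, lapply(1:800, function(i) {
    tr <- simulate_sd_bleach(log(2) / 11, 500, 0.2, 120)
    s <- segment_trajectories(tr)
    s[1, c("start", "end")]
  }))
  sv2 <- tracks_per_frame_survival(segs, 600, 0.2)
  expect_equal(sv2$half_time, 11, tolerance = 0.1)
  expect_equal(sv2$A, 800, tolerance = 0.05)   # intercept ~ particle count M
})

test_that("photon level fitting resolves equidistant levels", {
  set.seed(47)
  vals <- c(rnorm(500, 500, 60), rnorm(300, 1000, 60), rnorm(200, 1500, 60))
  fit <- photon_level_fit(vals, K_max = 6)
  expect_equal(fit$K, 3)
  expect_equal(fit$mu1, 500, tolerance = 0.05)
  expect_equal(fit$spacing, fit$mu1, tolerance = 0.1)

  sd_vals <- rnorm(600, 480, 50)
  fit1 <- photon_level_fit(sd_vals, K_max = 6)
  expect_equal(fit1$K, 1)
  expect_equal(fit1$mu1, 480, tolerance = 0.05)

  # degenerate input falls back to a single level
  expect_equal(photon_level_fit(rep(500, 300))$K, 1)
})

test_that("particle filters remove doubles, neighbours and sparse clusters", {
  set.seed(48)
  # two clusters 1 px apart -> both removed by the proximity rule; members
  # on circles of radius 0.3 px keep the clusters internally connected while
  # never bridging across the 0.4 px inter-cluster gap
  ang <- seq(0, 2 * pi, length.out = 31)[-31]
  locs <- data.frame(frame = rep(0:29, 2),
                     x = c(10 + 0.3 * cos(ang), 11 + 0.3 * cos(ang)),
                     y = 10 + rep(0.3 * sin(ang), 2),
                     photons = 500)
  cl <- cluster_particles(locs, radius_px = 0.35, min_locs = 5)
  expect_gte(nrow(cl), 2)
  flt <- filter_particles(cl, locs, min_locs = 5)
  expect_true(all(flt$report$reason == "proximity"))
  expect_equal(nrow(flt$kept), 0)

  # merged double particle: two emitters in one cluster -> > 1.2 locs/frame
  locs2 <- data.frame(frame = c(rep(0:29, 2), 0:29),
                      x = c(rnorm(60, 50, 0.15), rnorm(30, 80, 0.15)),
                      y = c(rnorm(60, 50, 0.15), rnorm(30, 80, 0.15)),
                      photons = 500)
  cl2 <- cluster_particles(locs2, radius_px = 1, min_locs = 5)
  flt2 <- filter_particles(cl2, locs2, min_locs = 5)
  expect_true("double" %in% flt2$report$reason)
  expect_equal(nrow(flt2$kept), 1)      # the isolated single survives

  # sparse clean field: >= 95% retained
  centers <- expand.grid(x = seq(10, 90, by = 20), y = seq(10, 90, by = 20))
  locs3 <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    data.frame(frame = 0:29, x = rnorm(30, centers$x[i], 0.1),
               y = rnorm(30, centers$y[i], 0.1), photons = 500)))
  cl3 <- cluster_particles(locs3, radius_px = 1, min_locs = 5)
  flt3 <- filter_particles(cl3, locs3, min_locs = 5)
  expect_gte(nrow(flt3$kept), ceiling(0.95 * nrow(centers)))
})
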
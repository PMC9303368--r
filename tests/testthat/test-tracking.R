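test_that("single-molecule linking follows the distance and length rules", {
  pf <- palm_frames_default(5)
  # 5 localizations in consecutive PALM frames, each step 0.30 um
  locs <- make_locs(0.3 * (0:4), rep(0, 5), pf)
  tr <- link_single_molecules(locs)
  expect_equal(length(unique(tr$trace_id)), 1)
  expect_equal(nrow(tr), 5)

  # 0.60 um step in consecutive frames breaks the chain
  locs2 <- make_locs(c(0, 0.6), c(0, 0), pf[1:2])
  expect_equal(nrow(link_single_molecules(locs2)), 0)

  # 3-member chain is below the 4-localization minimum
  locs3 <- make_locs(0.1 * (0:2), rep(0, 3), pf[1:3])
  expect_equal(nrow(link_single_molecules(locs3)), 0)
})

test_that("no dark frame is allowed within a single-molecule trace", {
  pf <- palm_frames_default(6)
  frames <- pf[c(1, 2, 4, 5, 6)]  # grid position 3 missing
  locs <- make_locs(rep(0, 5), rep(0, 5), frames)
  tr <- link_single_molecules(locs)
  # only the 3-member tail is chained, which fails the length filter;
  # relax min_length to see the split
  tr2 <- link_single_molecules(locs, min_length = 2)
  expect_equal(length(unique(tr2$trace_id)), 2)
  expect_equal(nrow(tr), 0)
})

test_that("PALM linking bridges the conventional/activation slots", {
  # frames 9, 10 then 13 (slots 9, 10, then 3 of the next cycle) are
  # adjacent on the PALM grid
  locs <- make_locs(c(0, 0.1, 0.2, 0.3), c(0, 0, 0, 0), c(9, 10, 13, 14))
  tr <- link_single_molecules(locs)
  expect_equal(length(unique(tr$trace_id)), 1)
  expect_equal(nrow(tr), 4)
})

test_that("nearest-neighbour conflict resolution is globally greedy", {
  pf <- palm_frames_default(2)
  # two molecules in frame 1, one point in frame 2 nearer to the second
  locs <- make_locs(c(0, 0.30, 0.25), c(0, 0, 0), pf[c(1, 1, 2)])
  tr <- link_single_molecules(locs, min_length = 2)
  expect_equal(nrow(tr), 2)
  expect_equal(sort(tr$x), c(0.25, 0.30))
})

test_that("cluster linking honours distance, width continuity and min length", {
  cf <- seq(1, by = 10, length.out = 6)  # conventional frames
  widths <- c(380, 390, 400, 395, 390, 385)
  locs <- make_locs(0.5 * (0:5), rep(0, 6), cf, photons = 200,
                    width = widths, background = 0.6)
  tk <- link_clusters(locs)
  expect_equal(length(unique(tk$track_id)), 1)
  expect_equal(nrow(tk), 6)

  # a 300 -> 550 nm width jump breaks the track
  locs2 <- locs
  locs2$width <- c(300, 550, 400, 395, 390, 385)
  tk2 <- link_clusters(locs2)
  expect_equal(nrow(tk2), 5)  # the first localization is orphaned

  # 4-member chain is below the 5-localization minimum
  locs3 <- locs[1:4, ]
  expect_equal(nrow(link_clusters(locs3)), 0)
})

test_that("interpolated tracks pass through every conventional localization", {
  cf <- c(1, 11, 21)
  locs <- make_locs(c(0, 0.9, 1.2), c(0, 0, 0.6), cf, photons = 200,
                    width = c(380, 390, 395), background = 0.6)
  locs$track_id <- 1L
  ip <- interpolate_tracks(locs)
  expect_equal(ip$frame, 1:21)
  obs <- ip[ip$observed, ]
  expect_equal(obs$x, locs$x)
  expect_equal(obs$y, locs$y)
  # midpoint of the first segment
  expect_equal(ip$x[ip$frame == 6], 0.45)
  # piecewise-linear positions match per-segment arithmetic
  expect_equal(ip$x[ip$frame == 16], 0.9 + 5 / 10 * (1.2 - 0.9))
  expect_equal(ip$y[ip$frame == 16], 0 + 5 / 10 * 0.6)
  # radius is the last conventional width before each frame
  expect_equal(ip$radius_nm[ip$frame %in% 1:10], rep(380, 10))
  expect_equal(ip$radius_nm[ip$frame %in% 11:20], rep(390, 10))
})

test_that("stationary track interpolates to its endpoints", {
  locs <- make_locs(rep(1.5, 4), rep(-2, 4), c(1, 11, 21, 31),
                    photons = 200, width = 380, background = 0.6)
  locs$track_id <- 1L
  ip <- interpolate_tracks(locs)
  expect_true(all(ip$x == 1.5))
  expect_true(all(ip$y == -2))
})

test_that("interpolation error is zero for linear motion", {
  tr <- data.frame(track_id = 1, frame = 1:60,
                   x = (1:60) * 0.05, y = (1:60) * -0.02)
  ie <- interpolation_error_experiment(tr, 10)
  expect_equal(max(ie$errors_nm), 0, tolerance = 1e-9)
})

test_that("stationary-cluster interpolation error matches the Rayleigh median", {
  set.seed(21)
  sigma_nm <- 30
  tr <- simulate_continuous_tracks(n_tracks = 60, duration_s = 50,
                                   d_median_um2_s = 1e-12, d_sdlog10 = 0,
                                   noise_nm = sigma_nm, seed = 21)
  ie <- interpolation_error_experiment(tr[, c("track_id", "frame", "x", "y")],
                                       10)
  # per-frame closed form: median = sqrt(2 ln 2) * sigma * sqrt(1 + w1^2 + w2^2)
  # pooled over intermediate positions w = k/10, k = 1..9
  w <- (1:9) / 10
  med_pool <- stats::median(rep(sqrt(2 * log(2)) * sigma_nm *
                                  sqrt(1 + (1 - w)^2 + w^2), each = 1))
  expect_equal(ie$median_nm, med_pool, tolerance = 0.03)
})

test_that("Brownian-bridge variance predicts interpolation error", {
  set.seed(22)
  D <- 0.01; fr <- 20
  tr <- simulate_continuous_tracks(n_tracks = 80, duration_s = 30,
                                   d_median_um2_s = D, d_sdlog10 = 0,
                                   noise_nm = 0, seed = 22)
  ie <- interpolation_error_experiment(tr[, c("track_id", "frame", "x", "y")],
                                       10)
  # bridge variance per axis at position w over a gap of T seconds: 2 D T w(1-w)
  # anchors every 10 frames = 10 steps of 1/fr seconds; the pooled errors are
  # a mixture of Rayleighs whose median solves mean_w P(R_w <= m) = 1/2
  T <- 10 / fr
  w <- (1:9) / 10
  sigma_w <- sqrt(2 * D * T * w * (1 - w)) * 1e3
  med_theory <- stats::uniroot(function(m)
    mean(1 - exp(-m^2 / (2 * sigma_w^2))) - 0.5, c(1, 500))$root
  expect_equal(ie$median_nm, med_theory, tolerance = 0.05)
})

test_that("mean interpolation error is non-decreasing in gap length", {
  tr <- simulate_continuous_tracks(n_tracks = 50, duration_s = 40, seed = 23)
  ie <- interpolation_error_experiment(tr[, c("track_id", "frame", "x", "y")],
                                       10, max_gap = 20)
  expect_equal(ie$gap_curve$gap, 2:20)
  # allow tiny stochastic wiggles, require a monotone trend
  expect_true(all(diff(ie$gap_curve$mean_nm) > -1))
  expect_gt(ie$gap_curve$mean_nm[19], ie$gap_curve$mean_nm[1])
})

test_that("tracks shorter than a cycle are skipped with a warning", {
  tr <- rbind(data.frame(track_id = 1, frame = 1:5, x = 0, y = 0),
              data.frame(track_id = 2, frame = 1:40,
                         x = rnorm(40, 0, 0.01), y = 0))
  expect_warning(ie <- interpolation_error_experiment(tr, 10), "skipped")
  expect_equal(ie$n_tracks, 1)
})

test_that("every localization belongs to at most one trace", {
  set.seed(24)
  pf <- palm_frames_default(200)
  locs <- do.call(rbind, lapply(1:20, function(i) {
    s <- sample(150, 1)
    brownian_trace(pf[s:(s + sample(4:12, 1))], D = 0.05, noise_um = 0.02,
                   x0 = runif(1, 0, 10), y0 = runif(1, 0, 10))
  }))
  locs <- locs[order(locs$frame), ]
  tr <- link_single_molecules(locs)
  key <- paste(tr$x, tr$y, tr$frame)
  expect_equal(anyDuplicated(key), 0)
  # deterministic given sorted input
  tr2 <- link_single_molecules(locs)
  expect_identical(tr, tr2)
})
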
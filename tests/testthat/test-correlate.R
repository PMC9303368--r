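# minimal interpolated-track table for one stationary cluster
flat_interp <- function(track_id = 1L, frames = 1:41, x = 5, y = 5,
                        radius_nm = 376, precision_nm = 30) {
  data.frame(track_id = track_id, frame = frames, x = x, y = y,
             radius_nm = radius_nm, precision_nm = precision_nm,
             observed = (frames - 1) %% 10 == 0)
}

registered <- function(locs) {
  locs <- add_precision(locs)
  attr(locs, "registered") <- TRUE
  locs
}

test_that("colocalization uses radius plus both precisions", {
  ip <- flat_interp()
  # at the center: co-localized
  at0 <- registered(make_locs(5, 5, 3))
  expect_equal(colocalize(at0, ip)$cluster_id, 1L)
  # the worked threshold: distance 500 nm vs 376 + 30 + 20 = 426 nm
  near <- make_locs(5.5, 5, 3)
  near <- add_precision(near)
  near$precision <- 20
  attr(near, "registered") <- TRUE
  ipc <- flat_interp(precision_nm = 30)
  expect_true(is.na(colocalize(near, ipc)$cluster_id))
  # move inside the threshold
  near$x <- 5.42
  expect_equal(colocalize(near, ipc)$cluster_id, 1L)
})

test_that("unregistered input is rejected", {
  locs <- add_precision(make_locs(5, 5, 3))
  expect_error(colocalize(locs, flat_interp()), "registered")
})

test_that("assignment goes to the nearest cluster, ties to the lower id", {
  ip <- rbind(flat_interp(1L, x = 4, radius_nm = 1500),
              flat_interp(2L, x = 6, radius_nm = 1500))
  locs <- registered(make_locs(c(4.9, 5.0), c(5, 5), c(3, 4)))
  got <- colocalize(locs, ip)
  expect_equal(got$cluster_id, c(1L, 1L))  # nearer / equidistant tie
  locs2 <- registered(make_locs(5.2, 5, 3))
  expect_equal(colocalize(locs2, ip)$cluster_id, 2L)
})

test_that("traces partition into bound, partially bound and unbound", {
  ip <- flat_interp()
  pf <- palm_frames_default(6)
  inside <- make_locs(rep(5, 5), rep(5, 5), pf[1:5]); inside$trace_id <- 1L
  outside <- make_locs(rep(9, 6), rep(9, 6), pf[1:6]); outside$trace_id <- 2L
  mixed <- make_locs(c(5, 5, 9, 9, 9), rep(5, 5), pf[1:5]); mixed$trace_id <- 3L
  mixed$y <- c(5, 5, 9, 9, 9)
  traces <- registered(rbind(inside, outside, mixed))
  asg <- colocalize(traces, ip)
  cls <- classify_traces(traces, asg, ip)
  expect_equal(cls$class, c("bound", "unbound", "partially_bound"))
  expect_equal(cls$cluster_id[1], 1L)
  expect_true(all(table(cls$class) >= 1))
  # exhaustive and mutually exclusive
  expect_equal(nrow(cls), 3)
})

test_that("a trace touching two clusters is partially bound and flagged", {
  ip <- rbind(flat_interp(1L, x = 4), flat_interp(2L, x = 8))
  pf <- palm_frames_default(4)
  locs <- make_locs(c(4, 4, 8, 8), rep(5, 4), pf)
  locs$trace_id <- 1L
  locs <- registered(locs)
  cls <- classify_traces(locs, colocalize(locs, ip), ip)
  expect_equal(cls$class, "partially_bound")
  expect_true(cls$multi_cluster)
})

test_that("classification is invariant under global translation", {
  set.seed(31)
  ip <- flat_interp()
  pf <- palm_frames_default(8)
  locs <- rbind(
    make_locs(rnorm(5, 5, 0.05), rnorm(5, 5, 0.05), pf[1:5]),
    make_locs(rnorm(6, 11, 0.05), rnorm(6, 11, 0.05), pf[1:6]))
  locs$trace_id <- rep(1:2, c(5, 6))
  locs <- registered(locs)
  cls <- classify_traces(locs, colocalize(locs, ip), ip)
  shift <- function(df, d) { df$x <- df$x + d; df$y <- df$y - d; df }
  locs2 <- shift(locs, 3); attr(locs2, "registered") <- TRUE
  ip2 <- ip; ip2$x <- ip2$x + 3; ip2$y <- ip2$y - 3
  cls2 <- classify_traces(locs2, colocalize(locs2, ip2), ip2)
  expect_equal(cls2$class, cls$class)
})

test_that("a trace hanging over the cluster window needs 4 judgeable frames", {
  ip <- flat_interp(frames = 1:13)  # cluster defined only up to frame 13
  pf <- palm_frames_default(6)     # frames 3..10 and 13, 14, ...
  locs <- make_locs(rep(5, 6), rep(5, 6), pf[1:6])
  locs$trace_id <- 1L
  locs <- registered(locs)
  cls <- classify_traces(locs, colocalize(locs, ip), ip)
  expect_equal(cls$class, "bound")  # frames 3..10 and 13 are in-window

  ip2 <- flat_interp(frames = 1:6)  # only 4 PALM frames in window
  cls2 <- classify_traces(locs, colocalize(locs, ip2), ip2)
  expect_equal(cls2$class, "bound") # frames 3:6 judgeable, exactly 4

  ip3 <- flat_interp(frames = 1:5)  # 3 judgeable frames: excluded from bound
  cls3 <- classify_traces(locs, colocalize(locs, ip3), ip3)
  expect_equal(cls3$class, "partially_bound")
  expect_true(cls3$window_limited)
})

test_that("rigid co-motion cancels exactly under motion correction", {
  frames <- 1:41
  cx <- 5 + (frames - 1) * 0.125  # cluster translating 5 um
  ip <- data.frame(track_id = 1L, frame = frames, x = cx, y = 2,
                   radius_nm = 376, precision_nm = 30,
                   observed = (frames - 1) %% 10 == 0)
  pf <- palm_frames_default(8)
  offs <- c(0.1, -0.1)
  locs <- do.call(rbind, lapply(seq_along(offs), function(i) {
    l <- make_locs(cx[pf[1:5]] + offs[i], rep(2, 5), pf[1:5])
    l$trace_id <- i
    l
  }))
  locs <- registered(locs)
  asg <- colocalize(locs, ip)
  cls <- classify_traces(locs, asg, ip)
  expect_equal(cls$class, c("bound", "bound"))
  cc <- motion_correct(locs, cls, ip)
  expect_equal(sort(unique(round(cc$dx, 12))), c(-0.1, 0.1))
  expect_equal(unique(cc$dy), 0)
  # within-frame relative geometry preserved exactly
  sp <- split(cc, cc$frame)
  expect_true(all(vapply(sp, function(g) abs(diff(g$dx)) - 0.2 < 1e-12, TRUE)))
})

test_that("stationary cluster correction subtracts a constant center", {
  ip <- flat_interp(x = 3, y = 7)
  pf <- palm_frames_default(5)
  locs <- make_locs(c(3.1, 3.05, 3.0, 2.95), rep(7, 4), pf[1:4])
  locs$trace_id <- 1L
  locs <- registered(locs)
  cls <- classify_traces(locs, colocalize(locs, ip), ip)
  cc <- motion_correct(locs, cls, ip)
  expect_equal(cc$dx, locs$x - 3)
  expect_equal(cc$dy, rep(0, 4))
})

test_that("corrected Rg recovers the true bound-site spread on moving clusters", {
  set.seed(32)
  sigma_true <- 0.12  # um, per axis
  frames <- 1:201
  cx <- (frames - 1) * 0.03  # 6 um of directed motion
  ip <- data.frame(track_id = 1L, frame = frames, x = cx, y = 0,
                   radius_nm = 500, precision_nm = 20,
                   observed = (frames - 1) %% 10 == 0)
  pf <- palm_frames_default(160)
  pf <- pf[pf <= 201]
  n_mol <- 60
  locs <- do.call(rbind, lapply(seq_len(n_mol), function(i) {
    s <- sample(seq_len(length(pf) - 4), 1)
    fr <- pf[s:(s + 3)]
    off <- rnorm(2, 0, sigma_true)
    l <- make_locs(cx[fr] + off[1], rep(off[2], 4), fr)
    l$trace_id <- i
    l
  }))
  locs <- registered(locs)
  asg <- colocalize(locs, ip)
  cls <- classify_traces(locs, asg, ip)
  cc <- motion_correct(locs, cls, ip)
  rg <- radius_of_gyration(cbind(cc$dx, cc$dy))
  expect_equal(rg, sigma_true * sqrt(2) * 1e3, tolerance = 0.12)
  rg_raw <- radius_of_gyration(as.matrix(locs[, c("x", "y")]))
  expect_gt(rg_raw / rg, 3)
})

test_that("localizations at frames without a defined center are excluded", {
  ip <- flat_interp(frames = 3:20)
  pf <- palm_frames_default(5)  # 3..10, 13
  locs <- make_locs(rep(5, 5), rep(5, 5), c(pf[1:4], 23))
  locs$trace_id <- 1L
  locs <- registered(locs)
  asg <- colocalize(locs, ip)
  cls <- classify_traces(locs, asg, ip)
  cc <- motion_correct(locs, cls, ip)
  expect_equal(attr(cc, "n_excluded"), 1L)
  expect_equal(nrow(cc), 4)
})
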
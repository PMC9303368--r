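test_that("tamsd matches hand computation and the all-pairs brute force", {
  xy <- cbind(c(0, 1, 2), c(0, 0, 0))
  cv <- tamsd(xy, 0.05)
  expect_equal(cv$msd, c(1, 4))
  expect_equal(cv$dt, c(0.05, 0.10))
  expect_equal(cv$n, c(2, 1))
  # immobile trace
  expect_true(all(tamsd(cbind(rep(1, 6), rep(2, 6)), 0.05)$msd == 0))
  # O(n^2) brute-force oracle on random traces
  set.seed(51)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    xy <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))
    cv <- tamsd(xy, 0.05)
    brute <- vapply(seq_len(n - 1), function(k) {
      s <- 0; m <- 0
      for (i0 in 1:(n - k)) {
        s <- s + (xy[i0 + k, 1] - xy[i0, 1])^2 + (xy[i0 + k, 2] - xy[i0, 2])^2
        m <- m + 1
      }
      s / m
    }, 0)
    expect_equal(cv$msd, brute)
  }
})

test_that("diffusion fit inverts an exact line", {
  dt <- 0.05
  curve <- data.frame(lag = 1:5, dt = (1:5) * dt,
                      msd = 4 * 0.05 * (1:5) * dt + 2 * 0.02^2,
                      n = 5:1)
  f <- fit_diffusion(curve)
  expect_equal(f$D, 0.05)
  expect_equal(f$sigma_um, 0.02)
  # flat curve: D = 0
  flat <- data.frame(lag = 1:4, dt = (1:4) * dt, msd = rep(2 * 0.03^2, 4),
                     n = 4:1)
  ff <- fit_diffusion(flat)
  expect_equal(ff$D, 0, tolerance = 1e-12)
  # negative slope is retained and flagged
  dec <- data.frame(lag = 1:3, dt = (1:3) * dt, msd = c(3, 2, 1) * 1e-3,
                    n = 3:1)
  fd <- fit_diffusion(dec)
  expect_true(fd$negative_D)
  expect_lt(fd$D, 0)
})

test_that("long Brownian traces recover D within 5%", {
  set.seed(52)
  D <- 0.05; dt <- 0.05; n <- 8000
  xy <- cbind(cumsum(rnorm(n, 0, sqrt(2 * D * dt))),
              cumsum(rnorm(n, 0, sqrt(2 * D * dt))))
  f <- fit_diffusion(tamsd(xy, dt), max_lags = 10)
  expect_equal(f$D, D, tolerance = 0.05)
})

test_that("ensembles of generator-length traces recover the median D", {
  set.seed(53)
  dt <- 0.05
  for (D in c(0.002, 0.008, 0.21)) {
    Ds <- replicate(800, {
      L <- rgeom(1, 0.15) + 1L
      while (L < 4) L <- rgeom(1, 0.15) + 1L
      xy <- cbind(cumsum(c(0, rnorm(L - 1, 0, sqrt(2 * D * dt)))) +
                    rnorm(L, 0, 0.02),
                  cumsum(c(0, rnorm(L - 1, 0, sqrt(2 * D * dt)))) +
                    rnorm(L, 0, 0.02))
      fit_diffusion(tamsd(xy, dt), max_lags = 3)$D
    })
    expect_equal(median(Ds), D, tolerance = 0.25)
  }
})

test_that("log-D mixture selects K by BIC and recovers the modes", {
  set.seed(54)
  # one log-normal component
  d1 <- 10^rnorm(500, -1.5, 0.3)
  m1 <- fit_logd_mixture(d1)
  expect_equal(m1$K, 1)
  expect_equal(m1$means, -1.5, tolerance = 0.05)
  # the bound/unbound peaks 0.008 and 0.21 um^2/s, >= 300 draws each
  d2 <- c(10^rnorm(400, log10(0.008), 0.25), 10^rnorm(400, log10(0.21), 0.25))
  m2 <- fit_logd_mixture(d2)
  expect_equal(m2$K, 2)
  expect_equal(m2$means, c(log10(0.008), log10(0.21)), tolerance = 0.15 /
                 max(abs(log10(c(0.008, 0.21)))))
  # forcing K = 1 on a 2-mode sample fits worse (mclust BIC: larger is better)
  m2k1 <- fit_logd_mixture(d2, k_candidates = 1)
  expect_lt(m2k1$bic["1"], m2$bic["2"])
  # non-positive values are excluded with a count
  m3 <- fit_logd_mixture(c(d1, -0.01, 0))
  expect_equal(m3$n_excluded, 2)
  expect_error(fit_logd_mixture(rep(0.5, 50)), "identical")
})

test_that("overlap coefficient has the right limits and closed form", {
  set.seed(55)
  x <- rnorm(2e4)
  expect_equal(distribution_overlap(x, x, log10_transform = FALSE), 1,
               tolerance = 1e-6)
  expect_lt(distribution_overlap(runif(500, 0, 1), runif(500, 10, 11),
                                 log10_transform = FALSE), 0.01)
  # two unit-variance Gaussians 2 sigma apart: overlap = 2 * Phi(-1)
  ov <- distribution_overlap(rnorm(1e5), rnorm(1e5, 2),
                             log10_transform = FALSE)
  expect_equal(ov, 2 * pnorm(-1), tolerance = 0.02 / (2 * pnorm(-1)))
  # symmetry
  a <- 10^rnorm(300, -2, 0.3); b <- 10^rnorm(300, -1.2, 0.4)
  expect_equal(distribution_overlap(a, b), distribution_overlap(b, a))
  expect_lte(distribution_overlap(a, b), 1)
})

test_that("pooled TAMSD weights lags by displacement counts", {
  c1 <- tamsd(cbind(c(0, 1, 2), c(0, 0, 0)), 0.05)   # msd 1, 4
  c2 <- tamsd(cbind(c(0, 0), c(0, 2)), 0.05)         # msd 4 at lag 1
  pooled <- pool_tamsd(list(c1, c2))
  expect_equal(pooled$msd[pooled$lag == 1], (1 * 2 + 4 * 1) / 3)
  expect_equal(pooled$msd[pooled$lag == 2], 4)
})

test_that("relative mobility is ~1 for co-moving traces and >1 with local motion", {
  set.seed(56)
  # full-rate Brownian cluster path; the track table sees every 10th frame
  allf <- 1:2001
  D_cl <- 0.01; dt <- 0.05
  cxa <- cumsum(c(5, rnorm(length(allf) - 1, 0, sqrt(2 * D_cl * dt))))
  cya <- cumsum(c(5, rnorm(length(allf) - 1, 0, sqrt(2 * D_cl * dt))))
  conv <- seq(1, 2001, by = 10)
  track <- make_locs(cxa[conv], cya[conv], conv, photons = 200, width = 376,
                     background = 0.6)
  track$track_id <- 1L
  pf <- allf[frame_role(allf) == "palm"]
  # molecules riding the true cluster path at fixed offsets
  co_moving <- do.call(rbind, lapply(1:80, function(i) {
    s <- sample(length(pf) - 7, 1)
    fr <- pf[s:(s + 7)]
    l <- make_locs(cxa[fr] + runif(1, -0.1, 0.1),
                   cya[fr] + runif(1, -0.1, 0.1), fr)
    l$trace_id <- i
    l
  }))
  rm1 <- relative_mobility(co_moving, track, max_lags = 3)
  expect_equal(rm1$ratio, 1, tolerance = 0.35)
  # local Brownian motion on top of the cluster path raises the ratio
  D_loc <- 0.02
  wiggly <- do.call(rbind, lapply(1:80, function(i) {
    s <- sample(length(pf) - 7, 1)
    fr <- pf[s:(s + 7)]
    gaps <- diff(fr) * dt
    l <- make_locs(cxa[fr] + cumsum(c(0, rnorm(7, 0, sqrt(2 * D_loc * gaps)))),
                   cya[fr] + cumsum(c(0, rnorm(7, 0, sqrt(2 * D_loc * gaps)))),
                   fr)
    l$trace_id <- i
    l
  }))
  rm2 <- relative_mobility(wiggly, track, max_lags = 3)
  expect_gt(rm2$ratio, rm1$ratio)
  expect_gt(rm2$ratio, 1)
})

test_that("displacement export is one displacement per row", {
  pf <- palm_frames_default(4)
  tr <- make_locs(c(0, 0.1, 0.3, 0.3), c(0, 0, 0, 0.2), pf)
  tr$trace_id <- 1L
  d <- export_displacements(tr, 0.05)
  expect_equal(nrow(d), 3)
  expect_equal(d$dx_um, c(0.1, 0.2, 0))
  expect_equal(d$dy_um, c(0, 0, 0.2))
  f <- tempfile(fileext = ".csv")
  export_displacements(tr, 0.05, f)
  expect_equal(nrow(read.csv(f)), 3)
  unlink(f)
})
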
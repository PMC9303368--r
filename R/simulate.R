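#' Configuration of a synthetic correlative experiment
#'
#' Defines the study conditions emulated by [simulate_experiment()]: mobile
#' fluorescent clusters (telomere-like loci) imaged every conventional frame
#' of an interleaved shutter sequence, with single molecules photoactivated at
#' a constant rate on the PALM frames, either bound to a cluster (a fixed
#' binding-site offset plus confined local motion) or diffusing freely with a
#' fast/slow mobility mixture. Localizations carry photometry consistent with
#' their Thompson precision, and the single-molecule channel is warped by a
#' cubic polynomial distortion that bead calibration fields allow the analysis
#' to undo.
#'
#' Defaults encode telomere-like conditions: cluster diffusion log-normal with
#' median 0.002 um^2/s (~1 dex spread), cluster radius law 376 +/- 221 nm,
#' unbound fast D 0.21 um^2/s with a slow-unbound fraction at 0.008 um^2/s,
#' ~20 nm single-molecule and ~30 nm cluster localization noise, and mean
#' photobleaching-limited trace lengths of ~7 PALM frames.
#'
#' @param n_frames Total acquisition frames.
#' @param fov_um Square field-of-view side (um).
#' @param shutter A [shutter_sequence()].
#' @param n_clusters Number of clusters in the field.
#' @param cluster_d_median_um2_s Median of the log-normal cluster diffusion
#'   law (um^2/s).
#' @param cluster_d_sdlog10 Log10 standard deviation of the cluster D law.
#' @param cluster_velocity_um_s Directed-transport speed applied to every
#'   cluster along a random direction (0 = pure Brownian).
#' @param cluster_radius_mean_nm,cluster_radius_sd_nm Gaussian law of the
#'   fitted cluster width (truncated below at `cluster_radius_min_nm`).
#' @param cluster_radius_min_nm Lower truncation of the width law (fitting
#'   software rejects narrower spots).
#' @param n_sites Binding sites per cluster.
#' @param site_sd_nm Gaussian spread of binding-site offsets per axis.
#' @param local_ou_sd_nm,local_ou_tau_s Confined (Ornstein-Uhlenbeck) local
#'   motion of bound molecules: stationary sd per axis and relaxation time.
#' @param bound_fraction Probability that a newly activated molecule is bound.
#' @param slow_unbound_fraction Fraction of unbound molecules in the slow
#'   mobility state.
#' @param unbound_fast_d_um2_s,unbound_slow_d_um2_s Unbound diffusion
#'   coefficients.
#' @param activation_rate Mean newly activated molecules per PALM frame
#'   (constant photoactivation).
#' @param bleach_survival Per-PALM-frame survival probability (geometric trace
#'   lengths, mean `1/(1-bleach_survival)`).
#' @param sm_photons,sm_width_nm,sm_background Single-molecule photometry
#'   (Thompson precision ~20 nm at the defaults).
#' @param cluster_photons,cluster_background Cluster photometry (Thompson
#'   precision ~30 nm at the defaults for a 376 nm spot).
#' @param pixel_size_nm Camera pixel size.
#' @param warp_amplitude_um RMS displacement of the cubic channel distortion
#'   over the field (default ~1 pixel).
#' @param n_bead_fields,beads_per_field,bead_noise_nm Bead calibration layout.
#' @param seed Random seed (mandatory; recorded in all outputs).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_frames = 2000L,
                              fov_um = 20,
                              shutter = shutter_sequence(),
                              n_clusters = 10L,
                              cluster_d_median_um2_s = 0.002,
                              cluster_d_sdlog10 = 0.5,
                              cluster_velocity_um_s = 0,
                              cluster_radius_mean_nm = 376,
                              cluster_radius_sd_nm = 221,
                              cluster_radius_min_nm = 250,
                              n_sites = 40L,
                              site_sd_nm = 100,
                              local_ou_sd_nm = 55,
                              local_ou_tau_s = 0.5,
                              bound_fraction = 0.3,
                              slow_unbound_fraction = 0.3,
                              unbound_fast_d_um2_s = 0.21,
                              unbound_slow_d_um2_s = 0.008,
                              activation_rate = 2,
                              bleach_survival = 0.85,
                              sm_photons = 400,
                              sm_width_nm = 300,
                              sm_background = 1.85,
                              cluster_photons = 200,
                              cluster_background = 0.61,
                              pixel_size_nm = 160,
                              warp_amplitude_um = 0.16,
                              n_bead_fields = 5L,
                              beads_per_field = 12L,
                              bead_noise_nm = 5,
                              seed = 1L) {
  cfg <- as.list(environment())
  problems <- character()
  if (cfg$n_frames < cfg$shutter$cycle_length * 2)
    problems <- c(problems, "n_frames: need at least two shutter cycles")
  for (f in c("fov_um", "cluster_d_median_um2_s", "cluster_radius_mean_nm",
              "site_sd_nm", "local_ou_tau_s", "unbound_fast_d_um2_s",
              "unbound_slow_d_um2_s", "activation_rate", "sm_photons",
              "cluster_photons", "pixel_size_nm"))
    if (cfg[[f]] <= 0) problems <- c(problems, paste0(f, ": must be positive"))
  for (f in c("bound_fraction", "slow_unbound_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      problems <- c(problems, paste0(f, ": must lie in [0, 1]"))
  if (cfg$bleach_survival < 0 || cfg$bleach_survival >= 1)
    problems <- c(problems, "bleach_survival: must lie in [0, 1)")
  if (is.null(cfg$seed) || is.na(cfg$seed))
    problems <- c(problems, "seed: mandatory")
  if (length(problems))
    stop("invalid simulation config:\n  ", paste(problems, collapse = "\n  "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "simulation_config"
  cfg
}

# Cubic channel distortion with seeded random coefficients, scaled so the RMS
# displacement over the field is `amplitude_um`. Returns coefficient matrices
# usable with poly_terms().
make_warp <- function(fov_um, amplitude_um) {
  raw <- matrix(stats::runif(20, -1, 1), ncol = 2)
  gx <- seq(0, fov_um, length.out = 15)
  g <- expand.grid(x = gx, y = gx)
  Xn <- poly_terms(g$x / fov_um, g$y / fov_um, 3)
  disp <- Xn %*% raw
  rms <- sqrt(mean(rowSums(disp^2)))
  raw <- raw * amplitude_um / rms
  list(coef = raw, fov_um = fov_um)
}

apply_warp <- function(warp, x, y) {
  Xn <- poly_terms(x / warp$fov_um, y / warp$fov_um, 3)
  d <- Xn %*% warp$coef
  cbind(x = x + d[, 1], y = y + d[, 2])
}

rtrunc_norm <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < lower))
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

sm_photometry <- function(n, photons, width_nm, background, pixel_size_nm) {
  ph <- pmax(50, round(stats::rlnorm(n, log(photons), 0.15)))
  w <- rtrunc_norm(n, width_nm, width_nm * 0.05, width_nm * 0.5)
  prec <- thompson_precision(ph, w, background, pixel_size_nm)
  data.frame(photons = ph, width = w, background = background,
             precision = prec)
}

#' Simulate a complete correlative PALM experiment
#'
#' Generates the single-molecule localization table (PALM frames, warped into
#' the top camera channel), the conventional-channel cluster table, bead-pair
#' calibration fields, and the full ground truth. Deterministic given the
#' seed.
#'
#' @param config A [simulation_config()].
#' @param seed Overrides `config$seed` when given.
#' @return List of class `simulated_experiment` with elements `sm_locs`,
#'   `cluster_locs`, `bead_pairs`, `truth` (list: `cluster_centers`,
#'   `clusters`, `molecules`, `sm_truth`, `warp`), `config` and `seed`.
#' @export
simulate_experiment <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  sht <- config$shutter
  dt <- 1 / sht$frame_rate
  frames <- seq_len(config$n_frames)
  roles <- frame_role(frames, sht)
  conv_frames <- frames[roles == "conventional"]
  palm_frames <- frames[roles == "palm"]

  ## --- clusters -----------------------------------------------------------
  nc <- config$n_clusters
  margin <- config$fov_um * 0.15
  # rejection-sample initial centers at least 2 um apart
  centers0 <- matrix(NA_real_, nc, 2)
  placed <- 0L
  while (placed < nc) {
    cand <- stats::runif(2, margin, config$fov_um - margin)
    if (placed == 0 ||
        min(sqrt((centers0[seq_len(placed), 1] - cand[1])^2 +
                 (centers0[seq_len(placed), 2] - cand[2])^2)) > 2) {
      placed <- placed + 1L
      centers0[placed, ] <- cand
    }
  }
  d_cl <- stats::rlnorm(nc, log(config$cluster_d_median_um2_s),
                        config$cluster_d_sdlog10 * log(10))
  theta <- stats::runif(nc, 0, 2 * pi)
  vel <- config$cluster_velocity_um_s * cbind(cos(theta), sin(theta))
  base_width <- rtrunc_norm(nc, config$cluster_radius_mean_nm,
                            config$cluster_radius_sd_nm,
                            config$cluster_radius_min_nm)
  nf <- config$n_frames
  step_sd <- sqrt(2 * d_cl * dt)
  cx <- apply(rbind(centers0[, 1],
                    sweep(matrix(stats::rnorm((nf - 1) * nc, 0, step_sd),
                                 nf - 1, nc, byrow = TRUE),
                          2, vel[, 1] * dt, "+")),
              2, cumsum)
  cy <- apply(rbind(centers0[, 2],
                    sweep(matrix(stats::rnorm((nf - 1) * nc, 0, step_sd),
                                 nf - 1, nc, byrow = TRUE),
                          2, vel[, 2] * dt, "+")),
              2, cumsum)
  cluster_centers <- data.frame(cluster_id = rep(seq_len(nc), each = nf),
                                frame = rep(frames, nc),
                                x = as.vector(cx), y = as.vector(cy))

  # conventional-channel localizations
  ncv <- length(conv_frames)
  cl_rows <- do.call(rbind, lapply(seq_len(nc), function(i) {
    w <- rtrunc_norm(ncv, base_width[i], 10, config$cluster_radius_min_nm)
    ph <- pmax(100, round(stats::rlnorm(ncv, log(config$cluster_photons), 0.1)))
    prec <- thompson_precision(ph, w, config$cluster_background,
                               config$pixel_size_nm)
    data.frame(x = cx[conv_frames, i] + stats::rnorm(ncv, 0, prec * 1e-3),
               y = cy[conv_frames, i] + stats::rnorm(ncv, 0, prec * 1e-3),
               frame = conv_frames, photons = ph, width = w,
               background = config$cluster_background)
  }))
  cluster_locs <- cl_rows[order(cl_rows$frame), , drop = FALSE]
  rownames(cluster_locs) <- NULL

  ## --- binding sites ------------------------------------------------------
  sites <- data.frame(cluster_id = rep(seq_len(nc), each = config$n_sites),
                      site_x = stats::rnorm(nc * config$n_sites, 0,
                                            config$site_sd_nm * 1e-3),
                      site_y = stats::rnorm(nc * config$n_sites, 0,
                                            config$site_sd_nm * 1e-3))

  ## --- molecules ----------------------------------------------------------
  n_new <- stats::rpois(length(palm_frames), config$activation_rate)
  n_mol <- sum(n_new)
  if (n_mol == 0) stop("no molecules activated; raise activation_rate")
  start_idx <- rep(seq_along(palm_frames), n_new)  # index into palm_frames
  life <- stats::rgeom(n_mol, 1 - config$bleach_survival) + 1L
  is_bound <- stats::runif(n_mol) < config$bound_fraction
  cls <- ifelse(is_bound, "bound",
                ifelse(stats::runif(n_mol) < config$slow_unbound_fraction,
                       "unbound_slow", "unbound_fast"))
  host <- ifelse(cls == "bound", sample.int(nc, n_mol, replace = TRUE),
                 NA_integer_)
  site_row <- ifelse(cls == "bound",
                     (host - 1L) * config$n_sites +
                       sample.int(config$n_sites, n_mol, replace = TRUE),
                     NA_integer_)
  d_mol <- ifelse(cls == "unbound_fast", config$unbound_fast_d_um2_s,
                  ifelse(cls == "unbound_slow", config$unbound_slow_d_um2_s,
                         NA_real_))

  ou_sd <- config$local_ou_sd_nm * 1e-3
  tau <- config$local_ou_tau_s
  fov <- config$fov_um
  reflect <- function(z) {
    z <- abs(z)
    ifelse(z %/% fov %% 2 == 0, z %% fov, fov - z %% fov)
  }

  truth_rows <- vector("list", n_mol)
  for (m in seq_len(n_mol)) {
    pf_idx <- start_idx[m]:min(start_idx[m] + life[m] - 1L,
                               length(palm_frames))
    fr <- palm_frames[pf_idx]
    k <- length(fr)
    gaps <- c(0, diff(fr)) * dt  # real elapsed time between grid frames
    if (cls[m] == "bound") {
      h <- host[m]
      ou <- matrix(NA_real_, k, 2)
      ou[1, ] <- stats::rnorm(2, 0, ou_sd)
      if (k > 1) for (j in 2:k) {
        a <- exp(-gaps[j] / tau)
        ou[j, ] <- ou[j - 1, ] * a + stats::rnorm(2, 0, ou_sd * sqrt(1 - a^2))
      }
      rel_x <- sites$site_x[site_row[m]] + ou[, 1]
      rel_y <- sites$site_y[site_row[m]] + ou[, 2]
      x_true <- cx[fr, h] + rel_x
      y_true <- cy[fr, h] + rel_y
    } else {
      sd_step <- sqrt(2 * d_mol[m] * gaps[-1])
      x_true <- reflect(cumsum(c(stats::runif(1, 0, fov),
                                 stats::rnorm(k - 1, 0, sd_step))))
      y_true <- reflect(cumsum(c(stats::runif(1, 0, fov),
                                 stats::rnorm(k - 1, 0, sd_step))))
      rel_x <- rel_y <- rep(NA_real_, k)
    }
    truth_rows[[m]] <- data.frame(mol_id = m, frame = fr,
                                  x_true = x_true, y_true = y_true,
                                  rel_x = rel_x, rel_y = rel_y)
  }
  sm_truth <- do.call(rbind, truth_rows)
  phot <- sm_photometry(nrow(sm_truth), config$sm_photons, config$sm_width_nm,
                        config$sm_background, config$pixel_size_nm)
  sm_truth$x_obs <- sm_truth$x_true +
    stats::rnorm(nrow(sm_truth), 0, phot$precision * 1e-3)
  sm_truth$y_obs <- sm_truth$y_true +
    stats::rnorm(nrow(sm_truth), 0, phot$precision * 1e-3)

  ## --- channel warp and bead fields ---------------------------------------
  warp <- make_warp(config$fov_um, config$warp_amplitude_um)
  warped <- apply_warp(warp, sm_truth$x_obs, sm_truth$y_obs)
  sm_locs <- data.frame(x = warped[, "x"], y = warped[, "y"],
                        frame = sm_truth$frame, photons = phot$photons,
                        width = phot$width, background = phot$background)
  o <- order(sm_locs$frame)
  sm_locs <- sm_locs[o, , drop = FALSE]
  sm_truth <- sm_truth[o, , drop = FALSE]
  rownames(sm_locs) <- rownames(sm_truth) <- NULL

  bead_pairs <- do.call(rbind, lapply(seq_len(config$n_bead_fields),
                                      function(f) {
    bx <- stats::runif(config$beads_per_field, 0, config$fov_um)
    by <- stats::runif(config$beads_per_field, 0, config$fov_um)
    top <- apply_warp(warp, bx, by)
    s <- config$bead_noise_nm * 1e-3
    data.frame(x_top = top[, "x"] + stats::rnorm(length(bx), 0, s),
               y_top = top[, "y"] + stats::rnorm(length(bx), 0, s),
               x_bot = bx + stats::rnorm(length(bx), 0, s),
               y_bot = by + stats::rnorm(length(bx), 0, s),
               field_id = f)
  }))

  molecules <- data.frame(mol_id = seq_len(n_mol), class = cls,
                          cluster_id = host,
                          D_true = d_mol,
                          first_frame = palm_frames[start_idx],
                          n_frames = vapply(truth_rows, nrow, 0L))

  structure(list(sm_locs = sm_locs,
                 cluster_locs = cluster_locs,
                 bead_pairs = bead_pairs,
                 truth = list(cluster_centers = cluster_centers,
                              clusters = data.frame(cluster_id = seq_len(nc),
                                                    D = d_cl,
                                                    width_nm = base_width,
                                                    vx = vel[, 1],
                                                    vy = vel[, 2]),
                              molecules = molecules,
                              sm_truth = sm_truth,
                              warp = warp),
                 config = config,
                 seed = seed),
            class = "simulated_experiment")
}

#' Simulate continuously imaged cluster tracks
#'
#' Emulates the interpolation-error calibration experiment: clusters are
#' conventionally imaged in every frame (no shutter interleaving), so that
#' positions interpolated across a cycle can be compared with the observed
#' positions at the intermediate frames. Cluster motion is 2D Brownian with a
#' per-track log-normal diffusion coefficient; isotropic Gaussian localization
#' noise is added per axis.
#'
#' @param n_tracks Number of cluster trajectories.
#' @param duration_s Imaging duration per track (s).
#' @param frame_rate Acquisition rate (Hz).
#' @param d_median_um2_s,d_sdlog10 Log-normal diffusion law of the tracks.
#' @param noise_nm Per-axis localization noise (nm).
#' @param velocity_um_s Optional directed-transport speed (random direction
#'   per track).
#' @param seed Random seed.
#' @return `data.frame` with `track_id`, `frame`, `x`, `y` (observed, um),
#'   `x_true`, `y_true`; attribute `D` holds the per-track coefficients.
#' @export
simulate_continuous_tracks <- function(n_tracks = 100, duration_s = 200,
                                       frame_rate = 20,
                                       d_median_um2_s = 0.002,
                                       d_sdlog10 = 0.5,
                                       noise_nm = 30,
                                       velocity_um_s = 0,
                                       seed = 1L) {
  set.seed(seed)
  nf <- round(duration_s * frame_rate)
  dt <- 1 / frame_rate
  d <- stats::rlnorm(n_tracks, log(d_median_um2_s), d_sdlog10 * log(10))
  theta <- stats::runif(n_tracks, 0, 2 * pi)
  out <- do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    sd_step <- sqrt(2 * d[i] * dt)
    x <- cumsum(c(0, stats::rnorm(nf - 1, velocity_um_s * cos(theta[i]) * dt,
                                  sd_step)))
    y <- cumsum(c(0, stats::rnorm(nf - 1, velocity_um_s * sin(theta[i]) * dt,
                                  sd_step)))
    data.frame(track_id = i, frame = seq_len(nf),
               x = x + stats::rnorm(nf, 0, noise_nm * 1e-3),
               y = y + stats::rnorm(nf, 0, noise_nm * 1e-3),
               x_true = x, y_true = y)
  }))
  rownames(out) <- NULL
  attr(out, "D") <- d
  out
}

#' Match analysis traces to ground-truth molecules
#'
#' Assigns each localization of each trace to the nearest true emitter in the
#' same frame (unambiguous because few molecules are active per frame) and
#' gives each trace the majority molecule id.
#'
#' @param traces Registered trace table (conventional-channel coordinates).
#' @param sm_truth `truth$sm_truth` from [simulate_experiment()].
#' @return `data.frame` with `trace_id`, `mol_id`, `match_frac` (fraction of
#'   localizations agreeing with the majority molecule).
#' @export
match_traces_to_molecules <- function(traces, sm_truth) {
  tr_frames <- split(seq_len(nrow(traces)), traces$frame)
  truth_frames <- split(sm_truth, sm_truth$frame)
  mol <- rep(NA_integer_, nrow(traces))
  for (fr in names(tr_frames)) {
    tt <- truth_frames[[fr]]
    if (is.null(tt)) next
    rows <- tr_frames[[fr]]
    d <- outer(traces$x[rows], tt$x_obs, "-")^2 +
      outer(traces$y[rows], tt$y_obs, "-")^2
    mol[rows] <- tt$mol_id[apply(d, 1, which.min)]
  }
  sp <- split(mol, traces$trace_id)
  out <- do.call(rbind, lapply(names(sp), function(id) {
    tb <- sort(table(sp[[id]]), decreasing = TRUE)
    data.frame(trace_id = as.integer(id),
               mol_id = as.integer(names(tb)[1]),
               match_frac = as.numeric(tb[1]) / length(sp[[id]]))
  }))
  out[order(out$trace_id), , drop = FALSE]
}

#' Score pipeline outputs against ground truth
#'
#' Computes the bound-vs-not confusion matrix and accuracy of the correlative
#' classification, the best accuracy attainable by any single
#' diffusion-coefficient threshold (full sweep over candidate thresholds),
#' diffusion-coefficient recovery per true class, and radius-of-gyration
#' recovery before and after motion correction.
#'
#' @param traces Registered trace table used for classification.
#' @param classes Output of [classify_traces()].
#' @param corrected Output of [motion_correct()].
#' @param trace_d Output of [fit_traces_diffusion()] on the same traces.
#' @param experiment The `simulated_experiment`.
#' @param cluster_map Optional `data.frame` (`track_id`, `cluster_id`) mapping
#'   analysis track ids to true cluster ids; inferred by nearest mean position
#'   when omitted.
#' @return List of class `ground_truth_scorecard`.
#' @export
ground_truth_compare <- function(traces, classes, corrected, trace_d,
                                 experiment, cluster_map = NULL) {
  truth <- experiment$truth
  mm <- match_traces_to_molecules(traces, truth$sm_truth)
  idx <- match(mm$mol_id, truth$molecules$mol_id)
  true_bound <- truth$molecules$class[idx] == "bound"
  pred <- classes$class[match(mm$trace_id, classes$trace_id)]
  pred_bound <- pred == "bound"
  confusion <- table(truth = ifelse(true_bound, "bound", "unbound"),
                     predicted = pred)
  accuracy <- mean(pred_bound == true_bound)

  # best single-D-threshold classifier (predict bound iff D < threshold)
  d <- trace_d$D[match(mm$trace_id, trace_d$trace_id)]
  ok <- is.finite(d)
  thr_cand <- c(-Inf, sort(unique(d[ok])), Inf)
  thr_acc <- vapply(thr_cand, function(t)
    mean((d[ok] < t) == true_bound[ok]), 0)
  best <- which.max(thr_acc)

  # D recovery per true class
  d_rec <- do.call(rbind, lapply(split(seq_along(d), truth$molecules$class[idx]),
    function(i) data.frame(n = sum(is.finite(d[i])),
                           median_D = stats::median(d[i], na.rm = TRUE))))
  d_rec$class <- rownames(d_rec)

  # Rg recovery: per cluster, corrected vs true relative offsets vs raw
  rg <- NULL
  if (nrow(corrected)) {
    host_of_mol <- truth$molecules$cluster_id
    rg <- do.call(rbind, lapply(split(corrected, corrected$cluster_id),
                                function(cc) {
      tid <- unique(cc$trace_id)
      mols <- mm$mol_id[mm$trace_id %in% tid]
      true_cl <- unique(host_of_mol[match(mols, truth$molecules$mol_id)])
      true_cl <- true_cl[!is.na(true_cl)]
      if (length(true_cl) != 1) return(NULL)
      st <- truth$sm_truth[truth$sm_truth$mol_id %in% mols &
                             !is.na(truth$sm_truth$rel_x), ]
      if (nrow(st) < 3) return(NULL)
      raw <- traces[traces$trace_id %in% tid, c("x", "y")]
      data.frame(cluster_id = cc$cluster_id[1],
                 true_cluster_id = true_cl,
                 rg_corrected_nm = radius_of_gyration(cbind(cc$dx, cc$dy)),
                 rg_true_nm = radius_of_gyration(cbind(st$rel_x, st$rel_y)),
                 rg_uncorrected_nm = radius_of_gyration(as.matrix(raw)),
                 displacement_um = {
                   path <- truth$cluster_centers[
                     truth$cluster_centers$cluster_id == true_cl, c("x", "y")]
                   max(stats::dist(path[seq(1, nrow(path), by = 5), ]))
                 },
                 n_localizations = nrow(cc))
    }))
    if (!is.null(rg)) rownames(rg) <- NULL
  }

  structure(list(trace_match = mm,
                 confusion = confusion,
                 accuracy = accuracy,
                 best_threshold = thr_cand[best],
                 best_threshold_accuracy = thr_acc[best],
                 d_recovery = d_rec,
                 rg_recovery = rg),
            class = "ground_truth_scorecard")
}

#' @export
print.ground_truth_scorecard <- function(x, ...) {
  cat("correlative classification accuracy:",
      sprintf("%.1f%%", 100 * x$accuracy), "\n")
  cat("best single-D-threshold accuracy:  ",
      sprintf("%.1f%% (threshold %.4g um^2/s)",
              100 * x$best_threshold_accuracy, x$best_threshold), "\n")
  print(x$confusion)
  invisible(x)
}
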
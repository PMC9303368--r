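#' @name mobility
#' @title TAMSD, diffusion coefficients and mobility-state mixtures
#' @description
#' Per-trace mobility is quantified by the time-averaged mean squared
#' displacement (TAMSD): squared displacements at each lag are averaged over
#' all start times within the trace, and the curve is fitted to the 2D
#' diffusion model `<r^2> = 4 D dt + 2 sigma^2`. Populations of fitted
#' diffusion coefficients are characterized by Gaussian mixture models on
#' log10 D with BIC model selection, and pairs of distributions are compared
#' with the overlap coefficient of their kernel density estimates.
NULL

#' Time-averaged mean squared displacement of one trace
#'
#' @param xy Two-column matrix (or `data.frame` with `x`, `y`) of positions in
#'   um at consecutive grid frames.
#' @param dt_s Time between consecutive positions (s).
#' @return `data.frame` with `lag` (frames), `dt` (s), `msd` (um^2) and `n`
#'   (displacements averaged per lag).
#' @export
tamsd <- function(xy, dt_s) {
  if (is.data.frame(xy)) xy <- as.matrix(xy[, c("x", "y")])
  n <- nrow(xy)
  if (n < 2) stop("TAMSD needs at least 2 positions")
  lags <- seq_len(n - 1)
  msd <- vapply(lags, function(k) {
    d <- xy[(1 + k):n, , drop = FALSE] - xy[1:(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, 0)
  data.frame(lag = lags, dt = lags * dt_s, msd = msd, n = n - lags)
}

#' Fit the 2D diffusion model to a TAMSD curve
#'
#' Ordinary least squares of `<r^2> = 4 D dt + 2 sigma^2`: D is the slope / 4
#' and sigma the square root of half the intercept. A negative fitted slope is
#' retained (D <= 0, flagged) so that distribution tails are not censored; a
#' negative intercept yields `sigma_um = NA` with the raw intercept reported.
#'
#' @param curve Output of [tamsd()].
#' @param max_lags Use at most this many lags (default all available).
#' @return List of class `diffusion_fit`: `D` (um^2/s), `sigma_um`,
#'   `intercept`, `slope`, `n_lags`, `negative_D`, `negative_intercept`.
#' @export
fit_diffusion <- function(curve, max_lags = Inf) {
  cv <- curve[seq_len(min(nrow(curve), max_lags)), , drop = FALSE]
  if (nrow(cv) < 2) stop("diffusion fit needs at least 2 lags")
  fit <- stats::lm.fit(cbind(1, cv$dt), cv$msd)
  b0 <- fit$coefficients[1]
  b1 <- fit$coefficients[2]
  structure(list(D = unname(b1) / 4,
                 sigma_um = if (b0 >= 0) sqrt(unname(b0) / 2) else NA_real_,
                 intercept = unname(b0),
                 slope = unname(b1),
                 n_lags = nrow(cv),
                 negative_D = unname(b1) < 0,
                 negative_intercept = unname(b0) < 0),
            class = "diffusion_fit")
}

#' Fit diffusion coefficients for every trace in a table
#'
#' @param traces `data.frame` with `trace_id` (or `track_id`), `frame`, `x`,
#'   `y` (um); frames are assumed equally spaced on the channel's grid.
#' @param dt_s Time between consecutive grid frames (s): `1/frame_rate` for
#'   single molecules, `cycle_length/frame_rate` for cluster tracks.
#' @param max_lags Lag cap passed to [fit_diffusion()].
#' @return `data.frame` with `trace_id`, `D`, `sigma_um`, `n_localizations`,
#'   `negative_D`.
#' @export
fit_traces_diffusion <- function(traces, dt_s, max_lags = Inf) {
  idcol <- if ("trace_id" %in% names(traces)) "trace_id" else "track_id"
  o <- order(traces[[idcol]], traces$frame)
  sp <- split(traces[o, c("x", "y")], traces[[idcol]][o])
  rows <- lapply(names(sp), function(id) {
    f <- fit_diffusion(tamsd(sp[[id]], dt_s), max_lags)
    data.frame(trace_id = as.integer(id), D = f$D, sigma_um = f$sigma_um,
               n_localizations = nrow(sp[[id]]), negative_D = f$negative_D)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gaussian mixture model on log10 diffusion coefficients
#'
#' Fits 1D Gaussian mixtures with unequal variances to log10(D) for each
#' candidate component count and selects the best by the Bayesian information
#' criterion. Non-positive D values cannot be log-transformed and are excluded
#' (count reported). Backed by \pkg{mclust}, whose deterministic
#' model-based-hierarchical initialization makes fits reproducible.
#'
#' @param D Diffusion coefficients (um^2/s).
#' @param k_candidates Candidate component counts (default 1:3).
#' @importFrom mclust Mclust mclustBIC
#' @return List of class `logd_mixture`: `K`, `weights`, `means` (log10 D),
#'   `sds`, `bic` (per candidate K, mclust sign convention: larger is better),
#'   `n_used`, `n_excluded`.
#' @export
fit_logd_mixture <- function(D, k_candidates = 1:3) {
  pos <- D[!is.na(D) & D > 0]
  n_excluded <- sum(!is.na(D)) - length(pos)
  if (length(pos) < 10)
    stop("need at least 10 positive diffusion coefficients, got ", length(pos))
  x <- log10(pos)
  if (diff(range(x)) == 0) stop("degenerate fit: all values identical")
  fit <- mclust::Mclust(x, G = k_candidates, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  ord <- order(fit$parameters$mean)
  structure(list(K = fit$G,
                 weights = fit$parameters$pro[ord],
                 means = unname(fit$parameters$mean[ord]),
                 sds = sqrt(fit$parameters$variance$sigmasq)[ord],
                 bic = stats::setNames(fit$BIC[, 1], rownames(fit$BIC)),
                 n_used = length(pos),
                 n_excluded = n_excluded),
            class = "logd_mixture")
}

#' @export
print.logd_mixture <- function(x, ...) {
  cat("Gaussian mixture on log10 D:", x$K, "component(s)\n")
  for (k in seq_len(x$K))
    cat(sprintf("  pi=%.3f  mean=%.3f (D=%.4g um^2/s)  sd=%.3f\n",
                x$weights[k], x$means[k], 10^x$means[k], x$sds[k]))
  if (x$n_excluded)
    cat("  (", x$n_excluded, "non-positive D excluded )\n")
  invisible(x)
}

#' Overlap coefficient of two distributions
#'
#' Integral of the pointwise minimum of the two kernel density estimates,
#' evaluated on a shared grid with Gaussian kernels and Silverman's
#' rule-of-thumb bandwidth per sample. By default diffusion coefficients are
#' compared on the log10 scale (non-positive values dropped).
#'
#' @param a,b Numeric samples.
#' @param log10_transform Compare on log10 scale (default TRUE; set FALSE for
#'   already-transformed or arbitrary samples).
#' @param n_grid Grid resolution.
#' @return Overlap fraction in [0, 1].
#' @export
distribution_overlap <- function(a, b, log10_transform = TRUE, n_grid = 2048) {
  if (log10_transform) {
    a <- log10(a[!is.na(a) & a > 0])
    b <- log10(b[!is.na(b) & b > 0])
  }
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  bw_a <- stats::bw.nrd0(a)
  bw_b <- stats::bw.nrd0(b)
  lo <- min(a, b) - 4 * max(bw_a, bw_b)
  hi <- max(a, b) + 4 * max(bw_a, bw_b)
  da <- stats::density(a, bw = bw_a, from = lo, to = hi, n = n_grid)
  db <- stats::density(b, bw = bw_b, from = lo, to = hi, n = n_grid)
  dx <- da$x[2] - da$x[1]
  min(1, sum(pmin(da$y, db$y)) * dx)
}

#' Average TAMSD curves across traces
#'
#' Pools squared displacements: at each lag the per-trace TAMSD values are
#' averaged weighted by their displacement counts, which equals the mean over
#' all displacements of all traces at that lag.
#'
#' @param curves List of [tamsd()] outputs.
#' @return A pooled TAMSD `data.frame` (`lag`, `dt`, `msd`, `n`).
#' @export
pool_tamsd <- function(curves) {
  all <- do.call(rbind, curves)
  sp <- split(all, all$lag)
  out <- do.call(rbind, lapply(sp, function(g)
    data.frame(lag = g$lag[1], dt = g$dt[1],
               msd = sum(g$msd * g$n) / sum(g$n), n = sum(g$n))))
  out[order(out$lag), , drop = FALSE]
}

#' Mobility of bound molecules relative to their host cluster
#'
#' The TAMSD curves of all bound traces in one cluster are pooled and fitted
#' once to the 2D diffusion model; the resulting average molecular diffusion
#' coefficient is divided by the diffusion coefficient of the cluster itself.
#'
#' @param bound_traces Localization `data.frame` of the cluster's bound traces
#'   (with `trace_id`, `frame`, `x`, `y`).
#' @param cluster_track Conventional-frame localizations of the host cluster.
#' @param sm_dt_s Single-molecule grid spacing (s).
#' @param cluster_dt_s Cluster grid spacing (s), i.e. cycle_length/frame_rate.
#' @param max_lags Lag cap for both fits.
#' @return List: `ratio`, `D_molecules`, `D_cluster`, `n_traces`.
#' @export
relative_mobility <- function(bound_traces, cluster_track, sm_dt_s = 1 / 20,
                              cluster_dt_s = 10 / 20, max_lags = Inf) {
  if (!nrow(bound_traces)) stop("no bound traces supplied")
  o <- order(bound_traces$trace_id, bound_traces$frame)
  curves <- lapply(split(bound_traces[o, c("x", "y")],
                         bound_traces$trace_id[o]),
                   tamsd, dt_s = sm_dt_s)
  pooled <- pool_tamsd(curves)
  d_mol <- fit_diffusion(pooled, max_lags)$D
  ct <- cluster_track[order(cluster_track$frame), c("x", "y")]
  d_cl <- fit_diffusion(tamsd(ct, cluster_dt_s), max_lags)$D
  if (!is.finite(d_cl) || d_cl == 0) stop("cluster diffusion coefficient undefined")
  list(ratio = d_mol / d_cl, D_molecules = d_mol, D_cluster = d_cl,
       n_traces = length(curves))
}

#' Export displacements for external kinetic-analysis tools
#'
#' Writes one displacement per row (`trace_id`, `frame`, `dx_um`, `dy_um`,
#' `dt_s`), the flat format consumed by trajectory-population tools such as
#' SMAUG and spot-on style analyses.
#'
#' @param traces Trace localization `data.frame`.
#' @param dt_s Grid spacing (s).
#' @param path Optional output CSV path.
#' @return The displacement `data.frame` (invisibly if written to `path`).
#' @export
export_displacements <- function(traces, dt_s, path = NULL) {
  o <- order(traces$trace_id, traces$frame)
  sp <- split(traces[o, ], traces$trace_id[o])
  rows <- lapply(sp, function(tr) {
    n <- nrow(tr)
    if (n < 2) return(NULL)
    data.frame(trace_id = tr$trace_id[1], frame = tr$frame[-n],
               dx_um = diff(tr$x), dy_um = diff(tr$y), dt_s = dt_s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
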
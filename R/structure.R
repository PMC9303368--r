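#' @name structure-metrics
#' @title Structural metrics of motion-corrected clusters
#' @description
#' Once cluster motion is subtracted, the accumulated single-molecule
#' localizations of one locus form a time-averaged super-resolved point set.
#' These functions quantify its size and shape: convex-hull area, maximal
#' extension, radius of gyration, covariance-ellipse axes and
#' duration-normalized localization density; [render_image()] rasterizes the
#' point set as a sum of Gaussians for display.
NULL

as_points <- function(points) {
  if (is.data.frame(points)) {
    cols <- if (all(c("dx", "dy") %in% names(points))) c("dx", "dy")
            else c("x", "y")
    points <- as.matrix(points[, cols])
  }
  stopifnot(is.matrix(points), ncol(points) == 2)
  points
}

#' Convex-hull area of a corrected point set
#'
#' @param points Two-column matrix or `data.frame` (um; `dx`/`dy` or `x`/`y`).
#' @return Area in um^2.
#' @export
hull_area <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 3) stop("hull area needs at least 3 points")
  h <- grDevices::chull(p)
  if (length(h) < 3) stop("hull area undefined: points are collinear")
  v <- p[h, , drop = FALSE]  # counter-clockwise hull vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  a <- abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
  if (a == 0) stop("hull area undefined: points are collinear")
  a
}

#' Maximal extension of a cluster
#'
#' Furthest distance between two motion-corrected localizations (the diameter
#' of the point set, computed over convex-hull vertices, which is exact).
#'
#' @inheritParams hull_area
#' @return Extension in nm.
#' @export
extension <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 2) stop("extension needs at least 2 points")
  h <- if (nrow(p) > 3) tryCatch(grDevices::chull(p), error = function(e) NULL)
       else NULL
  v <- if (!is.null(h) && length(h) >= 2) p[h, , drop = FALSE] else p
  d <- stats::dist(v)
  max(d) * 1e3
}

#' Radius of gyration
#'
#' Root mean squared distance of the corrected localizations from their
#' centroid.
#'
#' @inheritParams hull_area
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 2) stop("radius of gyration needs at least 2 points")
  c0 <- colMeans(p)
  sqrt(mean((p[, 1] - c0[1])^2 + (p[, 2] - c0[2])^2)) * 1e3
}

#' Covariance-ellipse axes
#'
#' Elliptical fit via the second moments of the point set: the axes are twice
#' the square roots of the eigenvalues of the coordinate covariance matrix
#' (full axes of the 1-sigma covariance ellipse).
#'
#' @inheritParams hull_area
#' @return Named numeric vector `c(minor, major)` in nm.
#' @export
ellipse_axes <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 3) stop("ellipse fit needs at least 3 points")
  ev <- eigen(stats::cov(p), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("degenerate covariance: points are collinear")
  c(minor = 2 * sqrt(min(ev)) * 1e3, major = 2 * sqrt(max(ev)) * 1e3)
}

#' Duration-normalized localization density
#'
#' Because the photoactivation rate is constant, the raw localization count of
#' a cluster scales with how long it stayed in the field of view. The count is
#' therefore normalized by the cluster's observed duration, and divided by the
#' convex-hull area to give a density.
#'
#' @param n_localizations Localization count.
#' @param duration_s Observed duration (s).
#' @param area_um2 Convex-hull area (um^2).
#' @return Density in localizations / um^2 / s.
#' @export
localization_density <- function(n_localizations, duration_s, area_um2) {
  if (any(duration_s <= 0)) stop("duration must be positive")
  if (any(area_um2 <= 0)) stop("area must be positive")
  (n_localizations / duration_s) / area_um2
}

#' Structural metrics for every motion-corrected cluster
#'
#' @param corrected Output of [motion_correct()].
#' @param durations Output of [cluster_durations()].
#' @param min_points Minimum localizations required to compute metrics
#'   (clusters below this are skipped).
#' @return `data.frame` with one row per cluster: `cluster_id`,
#'   `n_localizations`, `n_traces`, `duration_s`, `area_um2`, `extension_nm`,
#'   `rg_nm`, `minor_axis_nm`, `major_axis_nm`, `norm_count_per_s`,
#'   `density_per_um2_s`.
#' @export
cluster_metrics <- function(corrected, durations, min_points = 3L) {
  sp <- split(corrected, corrected$cluster_id)
  rows <- lapply(sp, function(cc) {
    if (nrow(cc) < max(min_points, 3L)) return(NULL)
    p <- cbind(cc$dx, cc$dy)
    dur <- durations$duration_s[match(cc$cluster_id[1], durations$cluster_id)]
    area <- tryCatch(hull_area(p), error = function(e) NA_real_)
    ax <- tryCatch(ellipse_axes(p),
                   error = function(e) c(minor = NA_real_, major = NA_real_))
    data.frame(cluster_id = cc$cluster_id[1],
               n_localizations = nrow(cc),
               n_traces = length(unique(cc$trace_id)),
               duration_s = dur,
               area_um2 = area,
               extension_nm = extension(p),
               rg_nm = radius_of_gyration(p),
               minor_axis_nm = unname(ax["minor"]),
               major_axis_nm = unname(ax["major"]),
               norm_count_per_s = nrow(cc) / dur,
               density_per_um2_s = if (is.na(area)) NA_real_
                                   else localization_density(nrow(cc), dur, area))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster_id = integer(0), n_localizations = integer(0),
                      n_traces = integer(0), duration_s = numeric(0),
                      area_um2 = numeric(0), extension_nm = numeric(0),
                      rg_nm = numeric(0), minor_axis_nm = numeric(0),
                      major_axis_nm = numeric(0), norm_count_per_s = numeric(0),
                      density_per_um2_s = numeric(0))
  rownames(out) <- NULL
  out
}

#' Render localizations as a Gaussian super-resolution image
#'
#' Each localization contributes a unit-integral 2D Gaussian with standard
#' deviation equal to its localization precision; the image is the pixelwise
#' sum, so total intensity equals the number of localizations.
#'
#' @param points Two-column matrix or `data.frame` of positions (um).
#' @param precision_nm Per-localization precision (nm); recycled.
#' @param pixel_nm Output pixel size (nm).
#' @param extent Optional `c(xmin, xmax, ymin, ymax)` in um; defaults to the
#'   point bounding box padded by 3 precisions.
#' @return Numeric matrix (rows = y, columns = x) with attributes
#'   `pixel_nm` and `extent_um`.
#' @export
render_image <- function(points, precision_nm = 20, pixel_nm = 10,
                         extent = NULL) {
  p <- as_points(points)
  sigma <- rep_len(precision_nm, nrow(p)) * 1e-3  # um
  px <- pixel_nm * 1e-3
  if (is.null(extent)) {
    pad <- 5 * max(sigma)
    extent <- c(min(p[, 1]) - pad, max(p[, 1]) + pad,
                min(p[, 2]) - pad, max(p[, 2]) + pad)
  }
  xs <- seq(extent[1] + px / 2, extent[2], by = px)
  ys <- seq(extent[3] + px / 2, extent[4], by = px)
  img <- matrix(0, nrow = length(ys), ncol = length(xs))
  for (i in seq_len(nrow(p))) {
    gx <- stats::dnorm(xs, p[i, 1], sigma[i])
    gy <- stats::dnorm(ys, p[i, 2], sigma[i])
    img <- img + outer(gy, gx) * px^2  # unit integral per localization
  }
  attr(img, "pixel_nm") <- pixel_nm
  attr(img, "extent_um") <- extent
  img
}
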
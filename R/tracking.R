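#' @name tracking
#' @title Trajectory linking and cluster-track interpolation
#' @description
#' Single-molecule localizations are linked into traces between adjacent PALM
#' frames; conventional-channel cluster localizations are linked into tracks
#' between adjacent conventional frames with an additional width-continuity
#' constraint. Cluster tracks are then linearly interpolated over the full
#' frame range so that a cluster center is available at every PALM frame it
#' spans.
NULL

# Greedy nearest-neighbour linking between consecutive grid frames.
# Candidate pairs are matched globally per frame pair in ascending distance;
# ties break on lower previous-row then current-row index. Each point joins at
# most one trace.
link_by_grid <- function(df, grid, max_dist, width_tol = Inf) {
  n <- nrow(df)
  trace <- seq_len(n)  # provisional: every point its own trace
  if (n == 0) return(integer(0))
  parent <- rep(NA_integer_, n)
  grids <- sort(unique(grid))
  idx_by_grid <- split(seq_len(n), grid)
  for (g in grids) {
    cur <- idx_by_grid[[as.character(g)]]
    prev <- idx_by_grid[[as.character(g - 1)]]
    if (is.null(prev) || is.null(cur)) next
    dx <- outer(df$x[prev], df$x[cur], "-")
    dy <- outer(df$y[prev], df$y[cur], "-")
    d <- sqrt(dx^2 + dy^2)
    ok <- d <= max_dist
    if (is.finite(width_tol))
      ok <- ok & abs(outer(df$width[prev], df$width[cur], "-")) <= width_tol
    cand <- which(ok, arr.ind = TRUE)
    if (!nrow(cand)) next
    o <- order(d[cand], cand[, 1], cand[, 2])
    cand <- cand[o, , drop = FALSE]
    used_prev <- logical(length(prev))
    used_cur <- logical(length(cur))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_prev[i] || used_cur[j]) next
      used_prev[i] <- TRUE; used_cur[j] <- TRUE
      parent[cur[j]] <- prev[i]
    }
  }
  # propagate trace ids along parent links (rows are processed in grid order)
  ord <- order(grid)
  for (i in ord) if (!is.na(parent[i])) trace[i] <- trace[parent[i]]
  trace
}

finalize_traces <- function(df, trace, min_len) {
  keep_ids <- names(which(table(trace) >= min_len))
  sel <- trace %in% as.integer(keep_ids)
  out <- df[sel, , drop = FALSE]
  if (!nrow(out)) {
    out$trace_id <- integer(0)
    return(out)
  }
  tr <- trace[sel]
  out$trace_id <- match(tr, unique(tr))
  rownames(out) <- NULL
  out[order(out$trace_id, out$frame), , drop = FALSE]
}

#' Link single-molecule localizations into traces
#'
#' Localizations within `max_dist_um` of each other in consecutive PALM frames
#' are linked; no dark frame is allowed between members. Adjacent frames on
#' the PALM frame grid count as consecutive (the conventional/activation slots
#' of the shutter cycle are not dark frames). Traces shorter than
#' `min_length` are discarded. When several candidates fall inside the link
#' radius, assignment is nearest-neighbour, resolved globally per frame pair
#' in ascending distance.
#'
#' @param locs Localization `data.frame` (PALM-frame rows), sorted by frame.
#' @param max_dist_um Link radius in um (default 0.48).
#' @param min_length Minimum localizations per trace (default 4).
#' @param shutter A [shutter_sequence()].
#' @return `locs` rows belonging to retained traces, with a `trace_id` column.
#' @export
link_single_molecules <- function(locs, max_dist_um = 0.48, min_length = 4L,
                                  shutter = shutter_sequence()) {
  if (!nrow(locs)) {
    locs$trace_id <- integer(0)
    return(locs)
  }
  grid <- frame_grid_index(locs$frame, shutter, "palm")
  if (anyNA(grid)) {
    warning(sum(is.na(grid)), " localization(s) on non-PALM frames dropped")
    locs <- locs[!is.na(grid), , drop = FALSE]
    grid <- grid[!is.na(grid)]
  }
  o <- order(grid)
  locs <- locs[o, , drop = FALSE]
  grid <- grid[o]
  trace <- link_by_grid(locs, grid, max_dist_um)
  finalize_traces(locs, trace, min_length)
}

#' Link conventional-channel cluster localizations into tracks
#'
#' Cluster localizations within `max_dist_um` of each other in consecutive
#' conventional frames (one per shutter cycle) are linked, subject to the
#' width-continuity rule: consecutive widths must agree within `width_tol_nm`
#' (large width jumps indicate axial movement out of focus). Tracks shorter
#' than `min_length` are discarded.
#'
#' @param locs Conventional-frame localization `data.frame`.
#' @param max_dist_um Link radius in um (default 0.68).
#' @param min_length Minimum localizations per track (default 5).
#' @param width_tol_nm Maximum width change between consecutive members (nm).
#' @param shutter A [shutter_sequence()].
#' @return `locs` rows belonging to retained tracks, with a `track_id` column.
#' @export
link_clusters <- function(locs, max_dist_um = 0.68, min_length = 5L,
                          width_tol_nm = 200, shutter = shutter_sequence()) {
  if (!nrow(locs)) {
    locs$track_id <- integer(0)
    return(locs)
  }
  grid <- frame_grid_index(locs$frame, shutter, "conventional")
  if (anyNA(grid)) {
    warning(sum(is.na(grid)), " localization(s) on non-conventional frames dropped")
    locs <- locs[!is.na(grid), , drop = FALSE]
    grid <- grid[!is.na(grid)]
  }
  o <- order(grid)
  locs <- locs[o, , drop = FALSE]
  grid <- grid[o]
  trace <- link_by_grid(locs, grid, max_dist_um, width_tol_nm)
  out <- finalize_traces(locs, trace, min_length)
  names(out)[names(out) == "trace_id"] <- "track_id"
  out
}

#' Interpolate cluster tracks over all spanned frames
#'
#' Linear interpolation between the x/y coordinates of cluster localizations
#' in consecutive conventional frames yields a cluster center at every frame
#' between the first and last conventional localization of the track. The
#' radius of the interpolated cluster is the width of the last conventional
#' localization prior to interpolation (piecewise constant), and the cluster
#' localization precision is carried the same way.
#'
#' @param tracks Output of [link_clusters()]; a `precision` column (nm) is
#'   added via [add_precision()] if absent.
#' @param pixel_size_nm Pixel size for the precision computation.
#' @return `data.frame` with columns `track_id`, `frame`, `x`, `y` (um),
#'   `radius_nm`, `precision_nm` and logical `observed` (TRUE on conventional
#'   frames).
#' @export
interpolate_tracks <- function(tracks, pixel_size_nm = 160) {
  if (!nrow(tracks)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), radius_nm = numeric(0),
                      precision_nm = numeric(0), observed = logical(0)))
  }
  if (is.null(tracks$precision)) tracks <- add_precision(tracks, pixel_size_nm)
  pieces <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2)
      stop("track ", tr$track_id[1], " has fewer than 2 conventional localizations")
    frames <- seq(tr$frame[1], tr$frame[nrow(tr)])
    data.frame(track_id = tr$track_id[1],
               frame = frames,
               x = stats::approx(tr$frame, tr$x, xout = frames)$y,
               y = stats::approx(tr$frame, tr$y, xout = frames)$y,
               radius_nm = stats::approx(tr$frame, tr$width, xout = frames,
                                         method = "constant", f = 0)$y,
               precision_nm = stats::approx(tr$frame, tr$precision,
                                            xout = frames,
                                            method = "constant", f = 0)$y,
               observed = frames %in% tr$frame)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

interp_errors_one <- function(x, y, gap) {
  n <- length(x)
  anchors <- seq(1L, n, by = gap)
  if (length(anchors) < 2) return(numeric(0))
  last <- anchors[length(anchors)]
  idx <- setdiff(seq(1L, last), anchors)
  if (!length(idx)) return(numeric(0))
  xi <- stats::approx(anchors, x[anchors], xout = idx)$y
  yi <- stats::approx(anchors, y[anchors], xout = idx)$y
  sqrt((x[idx] - xi)^2 + (y[idx] - yi)^2)
}

#' Interpolation-error experiment
#'
#' Estimates the error incurred by linearly interpolating cluster positions
#' across the shutter cycle. Input tracks must be localized in every frame
#' (continuous conventional imaging); positions are subsampled every
#' `cycle_length` frames, interpolated, and compared with the observed
#' positions at the intermediate frames. Also returns the mean error as a
#' function of gap length, up to `max_gap` frames.
#'
#' @param tracks `data.frame` with `track_id`, `frame`, `x`, `y` (um),
#'   localized in every frame.
#' @param cycle_length Anchor spacing in frames (default 10).
#' @param max_gap Largest gap length for the mean-error curve (default 20).
#' @return List with `errors_nm` (all intermediate-frame deviations),
#'   `median_nm`, `gap_curve` (`data.frame` of `gap`, `mean_nm`, `n`) and
#'   `n_tracks`.
#' @export
interpolation_error_experiment <- function(tracks, cycle_length = 10L,
                                           max_gap = 20L) {
  o <- order(tracks$track_id, tracks$frame)
  byid <- split(tracks[o, c("frame", "x", "y")], tracks$track_id[o])
  short <- vapply(byid, nrow, 0L) <= cycle_length
  if (any(short)) {
    warning(sum(short), " track(s) shorter than one cycle skipped")
    byid <- byid[!short]
  }
  if (!length(byid)) stop("no track spans a full cycle")
  errors <- unlist(lapply(byid, function(tr)
    interp_errors_one(tr$x, tr$y, cycle_length)))
  gaps <- 2:max_gap
  gap_curve <- do.call(rbind, lapply(gaps, function(g) {
    e <- unlist(lapply(byid, function(tr) interp_errors_one(tr$x, tr$y, g)))
    data.frame(gap = g, mean_nm = mean(e) * 1e3, n = length(e))
  }))
  list(errors_nm = errors * 1e3,
       median_nm = stats::median(errors) * 1e3,
       gap_curve = gap_curve,
       n_tracks = length(byid))
}
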
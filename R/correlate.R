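#' @name correlate
#' @title Spatio-temporal cross-correlation of single molecules and clusters
#' @description
#' Registered single-molecule localizations are assigned instant-by-instant to
#' the interpolated cluster tracks; traces are classified as bound (all
#' localizations inside a cluster), partially bound (some) or unbound (none);
#' and cluster motion is subtracted from bound localizations to recover the
#' time-averaged locus structure.
NULL

#' Assign localizations to the nearest co-localizing cluster
#'
#' A localization at frame f co-localizes with a cluster track when its
#' distance to the interpolated cluster center is smaller than the cluster
#' radius plus the localization precisions of the cluster and of the single
#' molecule. Each localization is assigned to the nearest such track; exact
#' distance ties break on the lower track id.
#'
#' @param sm_locs Registered single-molecule localizations (output of
#'   [apply_transform()]) with a `precision` column in nm (see
#'   [add_precision()]).
#' @param interp Interpolated cluster tracks from [interpolate_tracks()].
#' @return `sm_locs` with columns `cluster_id` (track id or `NA`) and
#'   `cluster_dist_um`.
#' @export
colocalize <- function(sm_locs, interp) {
  if (!isTRUE(attr(sm_locs, "registered")))
    stop("single-molecule localizations must be registered into the ",
         "conventional channel first (apply_transform)")
  if (is.null(sm_locs$precision))
    stop("single-molecule localizations need a precision column (add_precision)")
  out <- sm_locs
  out$cluster_id <- NA_integer_
  out$cluster_dist_um <- NA_real_
  if (!nrow(sm_locs) || !nrow(interp)) return(out)
  interp_by_frame <- split(interp, interp$frame)
  rows_by_frame <- split(seq_len(nrow(sm_locs)), sm_locs$frame)
  for (fr in names(rows_by_frame)) {
    cl <- interp_by_frame[[fr]]
    if (is.null(cl)) next
    rows <- rows_by_frame[[fr]]
    dx <- outer(sm_locs$x[rows], cl$x, "-")
    dy <- outer(sm_locs$y[rows], cl$y, "-")
    d <- sqrt(dx^2 + dy^2)
    thr <- (cl$radius_nm + cl$precision_nm) * 1e-3  # cluster part, um
    thr_mat <- matrix(thr, nrow = length(rows), ncol = nrow(cl), byrow = TRUE) +
      sm_locs$precision[rows] * 1e-3
    d[d >= thr_mat] <- Inf
    ord <- order(cl$track_id)
    for (i in seq_along(rows)) {
      di <- d[i, ord]
      if (all(is.infinite(di))) next
      j <- ord[which.min(di)]  # which.min takes the first: lower id on ties
      out$cluster_id[rows[i]] <- cl$track_id[j]
      out$cluster_dist_um[rows[i]] <- d[i, j]
    }
  }
  out
}

#' Classify traces as bound, partially bound or unbound
#'
#' A trace with at least `min_length` localizations is bound when all of its
#' localizations reside inside one cluster, unbound when none does, and
#' partially bound otherwise (a molecule that enters and exits a locus is a
#' searching or freely diffusing molecule, not a bound one). A trace that
#' overlaps the start or end of its host cluster's observation window is
#' judged on the frames where the cluster is defined; if fewer than
#' `min_length` such frames exist it is excluded from the bound class and
#' flagged `window_limited`. A trace whose localizations co-localize with
#' different clusters in different frames is classified partially bound and
#' flagged `multi_cluster`.
#'
#' @param traces Output of [link_single_molecules()] (has `trace_id`).
#' @param assignments Output of [colocalize()] on the same rows (same order).
#' @param interp Interpolated cluster tracks (for observation windows).
#' @param min_length Bound-assignment cutoff (default 4 localizations).
#' @return `data.frame` with one row per trace: `trace_id`, `class`
#'   (`"bound"`, `"partially_bound"`, `"unbound"`), `cluster_id` (host id for
#'   bound traces), `n_localizations`, `n_colocalized`, `multi_cluster`,
#'   `window_limited`.
#' @export
classify_traces <- function(traces, assignments, interp, min_length = 4L) {
  stopifnot(nrow(traces) == nrow(assignments))
  win <- if (nrow(interp))
    do.call(rbind, lapply(split(interp$frame, interp$track_id), range))
  else NULL
  df <- data.frame(trace_id = traces$trace_id, frame = traces$frame,
                   cluster_id = assignments$cluster_id)
  res <- lapply(split(df, df$trace_id), function(tr) {
    n <- nrow(tr)
    assigned <- tr$cluster_id[!is.na(tr$cluster_id)]
    hosts <- unique(assigned)
    multi <- length(hosts) > 1
    window_limited <- FALSE
    host <- NA_integer_
    if (length(assigned) == 0) {
      cls <- "unbound"
    } else if (multi) {
      cls <- "partially_bound"
    } else {
      # single candidate host; an assignment implies the host center was
      # defined at that frame, so only in-window frames are judged
      w <- win[as.character(hosts[1]), ]
      in_win <- tr$frame >= w[1] & tr$frame <= w[2]
      if (any(in_win & is.na(tr$cluster_id))) {
        cls <- "partially_bound"  # entered and exited the locus
      } else if (sum(in_win) >= min_length) {
        cls <- "bound"
        host <- hosts[1]
      } else {
        cls <- "partially_bound"  # too few judgeable frames for bound call
        window_limited <- TRUE
      }
    }
    data.frame(trace_id = tr$trace_id[1], class = cls, cluster_id = host,
               n_localizations = n, n_colocalized = length(assigned),
               multi_cluster = multi, window_limited = window_limited)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$trace_id), , drop = FALSE]
}

#' Subtract cluster motion from bound localizations
#'
#' For every bound trace, the interpolated center of its host cluster at each
#' localization's frame is subtracted from the localization, yielding
#' motion-corrected coordinates relative to the cluster center. Within-frame
#' relative geometry is preserved exactly. Localizations at frames where the
#' host center is undefined are excluded (count recorded in attribute
#' `n_excluded`).
#'
#' @param traces Output of [link_single_molecules()].
#' @param classes Output of [classify_traces()].
#' @param interp Interpolated cluster tracks.
#' @return `data.frame` with columns `cluster_id`, `trace_id`, `frame`,
#'   `dx`, `dy` (um, relative to the cluster center) and `precision` (nm);
#'   attribute `n_excluded`.
#' @export
motion_correct <- function(traces, classes, interp) {
  bound <- classes[classes$class == "bound", , drop = FALSE]
  empty <- data.frame(cluster_id = integer(0), trace_id = integer(0),
                      frame = integer(0), dx = numeric(0), dy = numeric(0),
                      precision = numeric(0))
  if (!nrow(bound)) {
    attr(empty, "n_excluded") <- 0L
    return(empty)
  }
  sel <- traces$trace_id %in% bound$trace_id
  tl <- traces[sel, , drop = FALSE]
  tl$cluster_id <- bound$cluster_id[match(tl$trace_id, bound$trace_id)]
  key <- paste(tl$cluster_id, tl$frame)
  ikey <- paste(interp$track_id, interp$frame)
  m <- match(key, ikey)
  n_excluded <- sum(is.na(m))
  ok <- !is.na(m)
  out <- data.frame(cluster_id = tl$cluster_id[ok],
                    trace_id = tl$trace_id[ok],
                    frame = tl$frame[ok],
                    dx = tl$x[ok] - interp$x[m[ok]],
                    dy = tl$y[ok] - interp$y[m[ok]],
                    precision = if (is.null(tl$precision)) NA_real_
                                else tl$precision[ok])
  out <- out[order(out$cluster_id, out$trace_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Observation duration of each cluster track
#'
#' Time between the first and last frame at which a cluster is defined.
#'
#' @param interp Interpolated cluster tracks.
#' @param frame_rate Acquisition rate (Hz).
#' @return `data.frame` with `cluster_id` and `duration_s`.
#' @export
cluster_durations <- function(interp, frame_rate = 20) {
  sp <- split(interp$frame, interp$track_id)
  data.frame(cluster_id = as.integer(names(sp)),
             duration_s = vapply(sp, function(f) diff(range(f)), 0) / frame_rate,
             row.names = NULL)
}
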
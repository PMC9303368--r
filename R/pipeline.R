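#' Write a simulated experiment to disk
#'
#' Emits the CSV dialects consumed by [read_localizations()] and
#' [read_bead_pairs()] plus the ground truth (CSV tables and a JSON summary).
#'
#' @param experiment A `simulated_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_localizations(experiment$sm_locs, file.path(dir, "sm_locs.csv"))
  write_localizations(experiment$cluster_locs,
                      file.path(dir, "cluster_locs.csv"))
  write_bead_pairs(experiment$bead_pairs, file.path(dir, "bead_pairs.csv"))
  tdir <- file.path(dir, "ground_truth")
  dir.create(tdir, showWarnings = FALSE)
  utils::write.csv(experiment$truth$cluster_centers,
                   file.path(tdir, "cluster_centers.csv"), row.names = FALSE)
  utils::write.csv(experiment$truth$molecules,
                   file.path(tdir, "molecules.csv"), row.names = FALSE)
  utils::write.csv(experiment$truth$sm_truth,
                   file.path(tdir, "sm_truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = experiment$seed,
                            warp_coef = experiment$truth$warp$coef,
                            clusters = experiment$truth$clusters),
                       file.path(tdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full correlative analysis on in-memory tables
#'
#' Executes the pipeline stages in order: channel registration, single-
#' molecule and cluster linking, track interpolation, co-localization, trace
#' classification, motion correction, structural metrics and mobility
#' analysis.
#'
#' @param sm_locs Single-molecule localization table (top channel).
#' @param cluster_locs Conventional-channel localization table.
#' @param bead_pairs Bead-pair calibration table (or `NULL` to skip
#'   registration when channels are already aligned).
#' @param config An [experiment_config()].
#' @return List of class `mcpalm_results` with all stage outputs: `transform`,
#'   `sm_registered`, `traces`, `tracks`, `interp`, `assignments`, `classes`,
#'   `corrected`, `durations`, `metrics`, `trace_d`, `cluster_d`,
#'   `relative_mobility`, `counts`.
#' @export
analyze_tables <- function(sm_locs, cluster_locs, bead_pairs = NULL,
                           config = experiment_config()) {
  sht <- config$shutter
  sm_locs <- add_precision(sm_locs, config$pixel_size_nm)

  transform <- NULL
  sm_reg <- sm_locs
  if (!is.null(bead_pairs)) {
    transform <- fit_transform(bead_pairs, degree = 3)
    sm_reg <- apply_transform(transform, sm_locs)
  } else {
    attr(sm_reg, "registered") <- TRUE  # caller asserts aligned channels
  }

  traces <- link_single_molecules(sm_reg, config$sm_link_radius_um,
                                  config$sm_min_length, sht)
  tracks <- link_clusters(cluster_locs, config$cluster_link_radius_um,
                          config$cluster_min_length, config$width_tol_nm, sht)
  interp <- interpolate_tracks(tracks, config$pixel_size_nm)

  attr(traces, "registered") <- TRUE
  assignments <- colocalize(traces, interp)
  classes <- classify_traces(traces, assignments, interp,
                             config$sm_min_length)
  corrected <- motion_correct(traces, classes, interp)
  durations <- cluster_durations(interp, sht$frame_rate)
  metrics <- cluster_metrics(corrected, durations)

  sm_dt <- 1 / sht$frame_rate
  cl_dt <- sht$cycle_length / sht$frame_rate
  trace_d <- if (nrow(traces)) fit_traces_diffusion(traces, sm_dt,
                                                    config$max_fit_lags)
             else NULL
  if (!is.null(trace_d))
    trace_d$class <- classes$class[match(trace_d$trace_id, classes$trace_id)]
  cluster_d <- if (nrow(tracks)) {
    cd <- fit_traces_diffusion(tracks, cl_dt, config$max_fit_lags)
    names(cd)[names(cd) == "trace_id"] <- "cluster_id"
    cd
  } else NULL

  relmob <- NULL
  bound <- classes[classes$class == "bound", , drop = FALSE]
  if (nrow(bound)) {
    relmob <- do.call(rbind, lapply(split(bound, bound$cluster_id),
                                    function(b) {
      bt <- traces[traces$trace_id %in% b$trace_id, , drop = FALSE]
      ct <- tracks[tracks$track_id == b$cluster_id[1], , drop = FALSE]
      rm <- tryCatch(relative_mobility(bt, ct, sm_dt, cl_dt,
                                       config$max_fit_lags),
                     error = function(e) NULL)
      if (is.null(rm)) return(NULL)
      data.frame(cluster_id = b$cluster_id[1], ratio = rm$ratio,
                 D_molecules = rm$D_molecules, D_cluster = rm$D_cluster,
                 n_bound_traces = rm$n_traces)
    }))
    if (!is.null(relmob)) rownames(relmob) <- NULL
  }

  counts <- c(sm_localizations = nrow(sm_locs),
              cluster_localizations = nrow(cluster_locs),
              traces = length(unique(traces$trace_id)),
              cluster_tracks = length(unique(tracks$track_id)),
              bound = sum(classes$class == "bound"),
              partially_bound = sum(classes$class == "partially_bound"),
              unbound = sum(classes$class == "unbound"),
              clusters_with_metrics = nrow(metrics))

  structure(list(transform = transform, sm_registered = sm_reg,
                 traces = traces, tracks = tracks, interp = interp,
                 assignments = assignments, classes = classes,
                 corrected = corrected, durations = durations,
                 metrics = metrics, trace_d = trace_d, cluster_d = cluster_d,
                 relative_mobility = relmob, counts = counts,
                 config = config),
            class = "mcpalm_results")
}

#' @export
print.mcpalm_results <- function(x, ...) {
  cat("correlative PALM analysis results\n")
  for (nm in names(x$counts)) cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Run the pipeline on files and write all outputs
#'
#' File-level front end to [analyze_tables()]: reads the localization tables
#' and bead pairs, runs every stage, and writes per-stage CSVs, the fitted
#' transform, a per-cluster report and a run manifest (config hash, seed,
#' input digests, per-stage counts) into `out_dir`.
#'
#' @param config An [experiment_config()].
#' @param sm_file,cluster_file CSV localization tables (positions in um).
#' @param bead_file Bead-pair CSV, or `NULL` to skip registration.
#' @param out_dir Output directory.
#' @param units Units of the input tables.
#' @return The `mcpalm_results`, invisibly.
#' @export
run_pipeline <- function(config, sm_file, cluster_file, bead_file = NULL,
                         out_dir, units = "um") {
  for (f in c(sm_file, cluster_file, bead_file))
    if (!file.exists(f)) stop("configuration error: input file not found: ", f)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sm <- read_localizations(sm_file, units, config$pixel_size_nm)
  cl <- read_localizations(cluster_file, units, config$pixel_size_nm)
  beads <- if (!is.null(bead_file)) read_bead_pairs(bead_file) else NULL

  res <- analyze_tables(sm, cl, beads, config)

  wcsv <- function(df, name) if (!is.null(df) && nrow(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  if (!is.null(res$transform))
    write_transform(res$transform, file.path(out_dir, "transform.json"))
  wcsv(res$traces, "traces.csv")
  wcsv(res$tracks, "cluster_tracks.csv")
  wcsv(res$interp, "interpolated_tracks.csv")
  wcsv(res$classes, "trace_classes.csv")
  wcsv(res$corrected, "corrected_localizations.csv")
  wcsv(res$metrics, "cluster_metrics.csv")
  wcsv(res$trace_d, "trace_diffusion.csv")
  wcsv(res$cluster_d, "cluster_diffusion.csv")
  wcsv(res$relative_mobility, "relative_mobility.csv")
  for (cls in c("bound", "partially_bound", "unbound")) {
    ids <- res$classes$trace_id[res$classes$class == cls]
    wcsv(res$traces[res$traces$trace_id %in% ids, , drop = FALSE],
         paste0("traces_", cls, ".csv"))
  }
  # displacement export for external mobility tools
  if (nrow(res$traces))
    export_displacements(res$traces, 1 / config$shutter$frame_rate,
                         file.path(out_dir, "displacements.csv"))

  manifest <- list(package = "mcpalm",
                   version = as.character(utils::packageVersion("mcpalm")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   inputs = as.list(tools::md5sum(
                     c(sm = sm_file, cluster = cluster_file,
                       beads = if (is.null(bead_file)) character() else bead_file))),
                   counts = as.list(res$counts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
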
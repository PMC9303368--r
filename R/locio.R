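#' Default column mapping for localization tables
#'
#' Localization tables exported by Insight3/ThunderSTORM-style fitting
#' software differ in header names. The column map translates the file's
#' headers to the canonical names used throughout the package.
#'
#' @return Named character vector mapping canonical names (`x`, `y`, `frame`,
#'   `photons`, `width`, `background`) to file column names.
#' @export
default_column_map <- function() {
  c(x = "x", y = "y", frame = "frame", photons = "photons",
    width = "width", background = "background")
}

.loc_required <- c("x", "y", "frame", "photons", "width", "background")

#' Read a localization table
#'
#' Reads a delimited text table with one fitted emitter (or conventional-image
#' cluster) per row and converts positions to the canonical internal unit of
#' micrometers. Widths and backgrounds are kept as stored (nm and
#' photons/pixel respectively). Rows are returned sorted by frame.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param units Unit of the `x`/`y` columns in the file: `"um"`, `"nm"` or
#'   `"pixel"`.
#' @param pixel_size_nm Camera pixel size in nm, used when `units = "pixel"`.
#' @param column_map Named character vector mapping canonical column names to
#'   the file's header names; see [default_column_map()].
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @return A `data.frame` with columns `x`, `y` (um), `frame` (1-based
#'   integer), `photons`, `width` (nm), `background` (photons/pixel), sorted
#'   by frame.
#' @export
read_localizations <- function(path, units = c("um", "nm", "pixel"),
                               pixel_size_nm = 160,
                               column_map = default_column_map(),
                               sep = ",") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("localization file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.loc_required, names(column_map))
  if (length(missing_cols))
    stop("column_map lacks entries for: ", paste(missing_cols, collapse = ", "))
  absent <- column_map[!column_map %in% names(raw)]
  if (length(absent))
    stop("format error: missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  df <- raw[, column_map[.loc_required]]
  names(df) <- .loc_required
  for (col in .loc_required) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("parse error: non-numeric value in column '", col,
           "' at data row ", bad[1])
    df[[col]] <- v
  }
  scale <- switch(units, um = 1, nm = 1e-3, pixel = pixel_size_nm * 1e-3)
  df$x <- df$x * scale
  df$y <- df$y * scale
  df$frame <- as.integer(df$frame)
  validate_localizations(df)
  df[order(df$frame), , drop = FALSE]
}

#' Write a localization table
#'
#' Inverse of [read_localizations()]: writes canonical-unit localizations
#' (positions in um) as CSV. A table written and re-read round-trips to well
#' below 1e-6 um.
#'
#' @param locs Localization `data.frame`.
#' @param path Output file path.
#' @export
write_localizations <- function(locs, path) {
  validate_localizations(locs)
  utils::write.csv(format(locs[, union(.loc_required,
                                       intersect("precision", names(locs)))],
                          digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_localizations <- function(locs) {
  miss <- setdiff(.loc_required, names(locs))
  if (length(miss))
    stop("localization table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(locs)) {
    if (any(locs$frame < 1)) stop("frame indices must be >= 1")
    if (any(locs$photons <= 0)) stop("photon counts must be positive")
    if (any(locs$width <= 0)) stop("widths must be positive")
  }
  invisible(locs)
}

#' Interleaved shutter sequence
#'
#' Describes the repeating frame pattern of a correlative acquisition: one
#' conventional-fluorescence frame, one photoactivation/brightfield frame and
#' the remaining PALM excitation frames per cycle. The default is the
#' 10-frame sequence at 20 Hz (conventional in slot 1, activation in slot 2,
#' PALM in slots 3-10).
#'
#' @param cycle_length Frames per cycle.
#' @param conventional_slot 1-based slot of the conventional frame.
#' @param activation_slot 1-based slot of the photoactivation frame.
#' @param frame_rate Acquisition rate in Hz.
#' @return An object of class `shutter_sequence`.
#' @export
shutter_sequence <- function(cycle_length = 10L, conventional_slot = 1L,
                             activation_slot = 2L, frame_rate = 20) {
  cycle_length <- as.integer(cycle_length)
  conventional_slot <- as.integer(conventional_slot)
  activation_slot <- as.integer(activation_slot)
  stopifnot(cycle_length >= 3, frame_rate > 0)
  slots <- seq_len(cycle_length)
  if (!conventional_slot %in% slots || !activation_slot %in% slots)
    stop("slot indices must lie in 1..cycle_length")
  if (conventional_slot == activation_slot)
    stop("conventional and activation slots must differ")
  structure(list(cycle_length = cycle_length,
                 conventional_slot = conventional_slot,
                 activation_slot = activation_slot,
                 palm_slots = setdiff(slots, c(conventional_slot,
                                               activation_slot)),
                 frame_rate = frame_rate),
            class = "shutter_sequence")
}

#' Role of a frame within the shutter sequence
#'
#' @param frame 1-based frame index (vectorized).
#' @param seq A [shutter_sequence()].
#' @return Character vector: `"conventional"`, `"activation"` or `"palm"`.
#' @export
frame_role <- function(frame, seq = shutter_sequence()) {
  stopifnot(all(frame >= 1))
  slot <- ((as.integer(frame) - 1L) %% seq$cycle_length) + 1L
  out <- rep("palm", length(slot))
  out[slot == seq$conventional_slot] <- "conventional"
  out[slot == seq$activation_slot] <- "activation"
  out
}

#' Position of a frame on its channel's frame grid
#'
#' Single-molecule linking treats adjacent PALM frames as consecutive and
#' cluster linking treats adjacent conventional frames as consecutive. This
#' helper maps an absolute frame index to its ordinal position on the grid of
#' frames with the given role (NA for frames of another role).
#'
#' @param frame 1-based frame index (vectorized).
#' @param seq A [shutter_sequence()].
#' @param role `"palm"` or `"conventional"`.
#' @return Integer grid index, NA where the frame has a different role.
#' @export
frame_grid_index <- function(frame, seq = shutter_sequence(),
                             role = c("palm", "conventional")) {
  role <- match.arg(role)
  frame <- as.integer(frame)
  cyc <- (frame - 1L) %/% seq$cycle_length
  slot <- ((frame - 1L) %% seq$cycle_length) + 1L
  if (role == "conventional") {
    idx <- ifelse(slot == seq$conventional_slot, cyc + 1L, NA_integer_)
  } else {
    pos <- match(slot, sort(seq$palm_slots))
    idx <- cyc * length(seq$palm_slots) + pos
  }
  as.integer(idx)
}

#' Thompson localization precision
#'
#' Precision of a 2D Gaussian fit to a single-emitter image, after Thompson,
#' Larson & Webb (2002), using the full three-term expression
#' \deqn{\sigma^2 = s^2/N + a^2/(12N) + 8\pi s^4 b^2 / (a^2 N^2)}
#' with `s` the fitted PSF standard deviation, `N` the photon count, `a` the
#' pixel size and `b` the background noise (photons/pixel).
#'
#' @param photons Photon count N (> 0; vectorized).
#' @param width_nm Fitted PSF width s in nm.
#' @param background Background noise b in photons/pixel.
#' @param pixel_size_nm Pixel size a in nm.
#' @return Localization precision in nm.
#' @export
thompson_precision <- function(photons, width_nm, background = 0,
                               pixel_size_nm = 160) {
  if (any(photons <= 0)) stop("photon counts must be positive")
  if (any(width_nm <= 0)) stop("widths must be positive")
  s2 <- width_nm^2
  var_nm2 <- s2 / photons + pixel_size_nm^2 / (12 * photons)
  if (any(background != 0)) {
    if (any(pixel_size_nm <= 0)) stop("pixel size must be positive")
    var_nm2 <- var_nm2 +
      8 * pi * s2^2 * background^2 / (pixel_size_nm^2 * photons^2)
  }
  sqrt(var_nm2)
}

#' Attach Thompson precisions to a localization table
#'
#' @param locs Localization `data.frame`.
#' @param pixel_size_nm Pixel size in nm.
#' @return `locs` with a `precision` column (nm).
#' @export
add_precision <- function(locs, pixel_size_nm = 160) {
  validate_localizations(locs)
  locs$precision <- thompson_precision(locs$photons, locs$width,
                                       locs$background, pixel_size_nm)
  locs
}

#' Experiment configuration
#'
#' Bundles the analysis parameters: camera pixel size, linking thresholds,
#' minimum trace lengths, the width-continuity tolerance for cluster tracks,
#' mixture-model settings and the random seed. Defaults encode the standard
#' correlative-imaging analysis: 0.48 um single-molecule link radius with a
#' 4-localization minimum, 0.68 um cluster link radius with a 5-localization
#' minimum and 200 nm width tolerance, a 10-frame shutter cycle at 20 Hz.
#'
#' @param pixel_size_nm Camera pixel size (nm/pixel).
#' @param sm_link_radius_um Single-molecule link radius (um).
#' @param sm_min_length Minimum single-molecule trace length.
#' @param cluster_link_radius_um Cluster link radius (um).
#' @param cluster_min_length Minimum cluster track length.
#' @param width_tol_nm Width-continuity tolerance between consecutive cluster
#'   localizations (nm).
#' @param shutter A [shutter_sequence()].
#' @param gmm_k_candidates Candidate component counts for the log-D mixture.
#' @param max_fit_lags Maximum number of TAMSD lags used in diffusion fits.
#'   Default 3: with photobleaching-limited trace lengths the higher lags
#'   average very few, strongly correlated displacements and drag the fitted
#'   slope down, so only the initial linear portion of the TAMSD is fitted.
#' @param seed Random seed recorded in outputs.
#' @return An object of class `experiment_config` (a list).
#' @export
experiment_config <- function(pixel_size_nm = 160,
                              sm_link_radius_um = 0.48,
                              sm_min_length = 4L,
                              cluster_link_radius_um = 0.68,
                              cluster_min_length = 5L,
                              width_tol_nm = 200,
                              shutter = shutter_sequence(),
                              gmm_k_candidates = 1:3,
                              max_fit_lags = 3,
                              seed = 1L) {
  cfg <- list(pixel_size_nm = pixel_size_nm,
              sm_link_radius_um = sm_link_radius_um,
              sm_min_length = as.integer(sm_min_length),
              cluster_link_radius_um = cluster_link_radius_um,
              cluster_min_length = as.integer(cluster_min_length),
              width_tol_nm = width_tol_nm,
              shutter = shutter,
              gmm_k_candidates = as.integer(gmm_k_candidates),
              max_fit_lags = max_fit_lags,
              seed = as.integer(seed))
  dists <- c(cfg$pixel_size_nm, cfg$sm_link_radius_um,
             cfg$cluster_link_radius_um, cfg$width_tol_nm)
  if (any(dists <= 0)) stop("all distances must be positive")
  if (cfg$sm_min_length < 2 || cfg$cluster_min_length < 2)
    stop("minimum trace lengths must be >= 2")
  class(cfg) <- "experiment_config"
  cfg
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys match the
#'   arguments of [experiment_config()] (shutter given as a nested map).
#' @return An `experiment_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(lst$shutter)) lst$shutter <- do.call(shutter_sequence, lst$shutter)
  do.call(experiment_config, lst)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}
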
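#' @name registration
#' @title Two-channel polynomial registration
#' @description
#' The single-molecule (PALM) channel and the conventional channel are imaged
#' on different camera regions and differ by chromatic/spherical aberration.
#' Multi-wavelength fiducial beads imaged in both channels calibrate a full
#' bivariate polynomial transform of total degree 3 (10 monomials per output
#' axis) mapping PALM-channel coordinates into the conventional channel.
NULL

poly_terms <- function(x, y, degree = 3) {
  cols <- list()
  nms <- character()
  for (d in 0:degree) for (i in 0:d) {
    cols[[length(cols) + 1L]] <- x^(d - i) * y^i
    nms <- c(nms, paste0("x", d - i, "y", i))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  m
}

#' Fit the channel transform from bead pairs
#'
#' Least-squares fit of a bivariate polynomial of total degree `degree` per
#' output axis, mapping (`x_top`, `y_top`) (PALM channel) onto
#' (`x_bot`, `y_bot`) (conventional channel).
#'
#' @param pairs `data.frame` with columns `x_top`, `y_top`, `x_bot`, `y_bot`
#'   (um) and optionally `field_id` (calibration image of origin).
#' @param degree Polynomial total degree (default 3).
#' @return Object of class `polynomial_transform` with elements `coef_x`,
#'   `coef_y` (named coefficient vectors), `degree` and `rms_residual_nm`.
#' @export
fit_transform <- function(pairs, degree = 3) {
  need <- c("x_top", "y_top", "x_bot", "y_bot")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("bead-pair table lacks: ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(pairs[, need]))))
    stop("bead coordinates must be finite")
  X <- poly_terms(pairs$x_top, pairs$y_top, degree)
  p <- ncol(X)
  if (nrow(pairs) < p)
    stop("underdetermined: need at least ", p, " bead pairs for degree ",
         degree, ", got ", nrow(pairs))
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("degenerate bead layout: design matrix is rank-deficient (rank ",
         qrX$rank, " < ", p, "); spread beads over the field")
  kappa_x <- kappa(X, exact = FALSE)
  if (kappa_x > 1e10)
    warning("bead layout is poorly conditioned (kappa ~ ",
            format(kappa_x, digits = 2), ")")
  cx <- qr.coef(qrX, pairs$x_bot)
  cy <- qr.coef(qrX, pairs$y_bot)
  res <- cbind(pairs$x_bot - X %*% cx, pairs$y_bot - X %*% cy)
  rms <- sqrt(mean(rowSums(res^2))) * 1e3
  structure(list(coef_x = cx, coef_y = cy, degree = degree,
                 rms_residual_nm = rms, n_pairs = nrow(pairs)),
            class = "polynomial_transform")
}

#' @export
print.polynomial_transform <- function(x, ...) {
  cat("polynomial channel transform, degree", x$degree, "\n")
  cat(sprintf("  fitted on %d bead pairs, rms residual %.2f nm\n",
              x$n_pairs, x$rms_residual_nm))
  invisible(x)
}

#' Apply a fitted transform to coordinates
#'
#' Maps localizations from the PALM channel into the conventional channel.
#' Only `x` and `y` change; row order and all other columns are preserved.
#'
#' @param transform A `polynomial_transform` from [fit_transform()].
#' @param locs Localization `data.frame` (or any data.frame with `x`, `y` in
#'   um).
#' @return `locs` with transformed coordinates and attribute
#'   `registered = TRUE`.
#' @export
apply_transform <- function(transform, locs) {
  stopifnot(inherits(transform, "polynomial_transform"))
  if (!nrow(locs)) {
    attr(locs, "registered") <- TRUE
    return(locs)
  }
  X <- poly_terms(locs$x, locs$y, transform$degree)
  out <- locs
  out$x <- as.numeric(X %*% transform$coef_x)
  out$y <- as.numeric(X %*% transform$coef_y)
  attr(out, "registered") <- TRUE
  out
}

#' Held-out registration error
#'
#' Leave-one-field-out estimate of the mapping precision: for each calibration
#' field, the transform is refitted on the remaining fields and evaluated on
#' the held-out beads. Reports both the RMS and the mean Euclidean mapping
#' error in nm.
#'
#' @param pairs Bead-pair `data.frame` with a `field_id` column.
#' @param degree Polynomial degree.
#' @return List with `rms_error_nm`, `mean_error_nm`, `errors_nm` (per
#'   held-out bead) and `n_fields`.
#' @export
registration_holdout_error <- function(pairs, degree = 3) {
  if (is.null(pairs$field_id)) stop("holdout estimate needs a field_id column")
  fields <- unique(pairs$field_id)
  if (length(fields) < 2) stop("need at least 2 calibration fields")
  errs <- unlist(lapply(fields, function(f) {
    train <- pairs[pairs$field_id != f, , drop = FALSE]
    test <- pairs[pairs$field_id == f, , drop = FALSE]
    tr <- fit_transform(train, degree)
    mapped <- apply_transform(tr, data.frame(x = test$x_top, y = test$y_top))
    sqrt((mapped$x - test$x_bot)^2 + (mapped$y - test$y_bot)^2)
  }))
  list(rms_error_nm = sqrt(mean(errs^2)) * 1e3,
       mean_error_nm = mean(errs) * 1e3,
       errors_nm = errs * 1e3,
       n_fields = length(fields))
}

#' Read / write bead-pair tables and serialized transforms
#'
#' @param path File path.
#' @return `read_bead_pairs`: a bead-pair `data.frame`;
#'   `read_transform`: a `polynomial_transform`.
#' @export
read_bead_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_top", "y_top", "x_bot", "y_bot")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("bead-pair file lacks: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_bead_pairs
#' @param pairs Bead-pair `data.frame`.
#' @export
write_bead_pairs <- function(pairs, path) {
  utils::write.csv(format(pairs, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_bead_pairs
#' @param transform A `polynomial_transform`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(coef_x = as.numeric(transform$coef_x),
                            coef_y = as.numeric(transform$coef_y),
                            terms = names(transform$coef_x),
                            degree = transform$degree,
                            rms_residual_nm = transform$rms_residual_nm,
                            n_pairs = transform$n_pairs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_bead_pairs
#' @export
read_transform <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  cx <- stats::setNames(lst$coef_x, lst$terms)
  cy <- stats::setNames(lst$coef_y, lst$terms)
  structure(list(coef_x = cx, coef_y = cy, degree = lst$degree,
                 rms_residual_nm = lst$rms_residual_nm, n_pairs = lst$n_pairs),
            class = "polynomial_transform")
}
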
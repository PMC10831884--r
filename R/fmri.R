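#' Voxel BOLD time series with condition labels
#'
#' Container for a timepoint-by-voxel BOLD matrix together with per-timepoint
#' condition labels (\code{"movie"} / \code{"rest"}), the repetition time and
#' stable voxel identifiers.
#'
#' @param values numeric matrix, timepoints x voxels; all values finite.
#' @param condition character vector of per-timepoint labels.
#' @param tr_s repetition time, seconds.
#' @param voxel_ids character identifiers, one per column.
#' @param clip optional integer vector giving the originating clip per
#'   timepoint (NA during rest).
#' @return an object of class \code{"voxel_timeseries"}.
#' @export
voxel_timeseries <- function(values, condition, tr_s,
                             voxel_ids = NULL, clip = NULL) {
  values <- as.matrix(values)
  if (length(condition) != nrow(values)) {
    stop_bd("condition length (%d) must equal timepoint count (%d)",
            length(condition), nrow(values))
  }
  if (!all(is.finite(values))) stop_bd("non-finite values in BOLD matrix")
  if (is.null(voxel_ids)) voxel_ids <- sprintf("v%04d", seq_len(ncol(values)))
  stopifnot(length(voxel_ids) == ncol(values), tr_s > 0)
  if (!is.null(clip)) stopifnot(length(clip) == nrow(values))
  structure(list(values = values, condition = as.character(condition),
                 tr_s = tr_s, voxel_ids = as.character(voxel_ids),
                 clip = clip),
            class = "voxel_timeseries")
}

#' @export
print.voxel_timeseries <- function(x, ...) {
  cat(sprintf("<voxel_timeseries> %d timepoints x %d voxels, TR %.2f s (%s)\n",
              nrow(x$values), ncol(x$values), x$tr_s,
              paste(sprintf("%s: %d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Global signal regression
#'
#' Removes, from every voxel, the least-squares projection onto the global
#' signal (the mean time series across voxels) and an intercept, returning
#' the residuals. Residual series are exactly orthogonal to the global
#' series and zero-mean. If the global signal has zero variance the
#' regression falls back to intercept only, with a warning.
#'
#' @param x a \code{\link{voxel_timeseries}}.
#' @return a \code{\link{voxel_timeseries}} of residuals.
#' @export
global_signal_regression <- function(x) {
  stopifnot(inherits(x, "voxel_timeseries"))
  y <- x$values
  if (nrow(y) < 2L) stop_bd("at least 2 timepoints required")
  g <- rowMeans(y)
  if (sd(g) < 1e-12) {
    warning("global signal has zero variance; regressing on intercept only")
    res <- sweep(y, 2L, colMeans(y))
  } else {
    X <- cbind(1, g)
    beta <- solve(crossprod(X), crossprod(X, y))
    res <- y - X %*% beta
  }
  out <- x
  out$values <- res
  out
}

# Vectorised two-tailed Welch t-test of group a vs group b per column.
welch_p <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, var); v2 <- apply(b, 2, var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(tt)] <- NA_real_
  list(p = p, t = tt, df = df)
}

#' Data-driven ROI selection by movie-vs-rest contrast
#'
#' Per voxel, a two-sample two-tailed Welch t-test compares BOLD values
#' during movie viewing against rest; voxels with p below \code{alpha}
#' (default 1e-8, a deliberately stringent fixed threshold used in place of
#' multiplicity correction) form the region of interest. Timepoints within
#' \code{trim_boundary_tr} acquisitions of a condition change are excluded
#' from the test by default, since haemodynamic spill-over blurs the
#' transition. Voxel order is preserved.
#'
#' @param x a \code{\link{voxel_timeseries}} containing both conditions.
#' @param alpha per-voxel significance threshold.
#' @param trim_boundary_tr number of TRs dropped on each side of every
#'   condition boundary before testing.
#' @return an object of class \code{"roi_timeseries"}: the selected columns
#'   of \code{x} (all timepoints) plus \code{voxel_ids},
#'   \code{selection_pvalues}, and the test metadata.
#' @export
select_roi <- function(x, alpha = 1e-8, trim_boundary_tr = 2L) {
  stopifnot(inherits(x, "voxel_timeseries"), alpha > 0, alpha <= 1)
  cond <- x$condition
  if (!all(c("movie", "rest") %in% cond)) {
    stop_bd("both movie and rest timepoints required")
  }
  keep <- rep(TRUE, length(cond))
  if (trim_boundary_tr > 0) {
    bnd <- which(diff(as.integer(factor(cond))) != 0) # last index of each run
    for (b in bnd) {
      lo <- max(1L, b - trim_boundary_tr + 1L)
      hi <- min(length(cond), b + trim_boundary_tr)
      keep[lo:hi] <- FALSE
    }
  }
  a <- x$values[cond == "movie" & keep, , drop = FALSE]
  b <- x$values[cond == "rest" & keep, , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop_bd("each condition needs at least 2 timepoints after boundary trimming")
  }
  w <- welch_p(a, b)
  sel <- which(!is.na(w$p) & w$p < alpha)
  structure(list(values = x$values[, sel, drop = FALSE],
                 voxel_ids = x$voxel_ids[sel],
                 selection_pvalues = w$p[sel],
                 selected = sel,
                 pvalues_all = w$p,
                 condition = x$condition, tr_s = x$tr_s, clip = x$clip,
                 alpha = alpha, trim_boundary_tr = trim_boundary_tr),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d of %d voxels selected at p < %g\n",
              length(x$voxel_ids), length(x$pvalues_all), x$alpha))
  invisible(x)
}

#' Write the ROI selection table
#'
#' @param roi a \code{\link{select_roi}} result.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_roi_csv <- function(roi, path) {
  stopifnot(inherits(roi, "roi_timeseries"))
  write.csv(data.frame(voxel_id = roi$voxel_ids,
                       p_value = roi$selection_pvalues),
            path, row.names = FALSE)
  invisible(path)
}

#' Load a 4-D NIfTI volume as a voxel time series
#'
#' Reads a 4-D NIfTI image, flattens the three spatial dimensions into a
#' voxel axis (voxel identifiers record the original x_y_z indices), and
#' attaches per-timepoint condition labels. Voxels containing non-finite
#' values are dropped with a warning.
#'
#' @param path a \code{.nii} / \code{.nii.gz} file.
#' @param condition_labels character vector, length = 4th image dimension.
#' @param tr_s repetition time; taken from the header when NULL.
#' @return a \code{\link{voxel_timeseries}}.
#' @export
load_nifti <- function(path, condition_labels, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop_bd("expected a 4-D NIfTI image, got %d dims", length(d))
  if (length(condition_labels) != d[4]) {
    stop_bd("condition_labels length (%d) must equal the 4th dimension (%d)",
            length(condition_labels), d[4])
  }
  if (is.null(tr_s)) {
    pd <- RNifti::pixdim(img)
    tr_s <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  vals <- t(matrix(as.numeric(img), prod(d[1:3]), d[4]))
  grid <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  ids <- sprintf("%d_%d_%d", grid$x, grid$y, grid$z)
  bad <- !apply(is.finite(vals), 2, all)
  if (any(bad)) {
    warning(sprintf("dropping %d voxels with non-finite values", sum(bad)))
    vals <- vals[, !bad, drop = FALSE]
    ids <- ids[!bad]
  }
  voxel_timeseries(vals, condition_labels, tr_s, voxel_ids = ids)
}

#' Write a voxel time series as a degenerate-grid 4-D NIfTI
#'
#' Stores the matrix on a 1 x 1 x V x T grid, the inverse of
#' \code{\link{load_nifti}} for flat (already-vectorised) data.
#'
#' @param x a \code{\link{voxel_timeseries}}.
#' @param path output file path (\code{.nii} or \code{.nii.gz}).
#' @return the path, invisibly.
#' @export
write_nifti_flat <- function(x, path) {
  stopifnot(inherits(x, "voxel_timeseries"))
  arr <- array(t(x$values), c(1L, 1L, ncol(x$values), nrow(x$values)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, x$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}
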
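#' Ordered video frames for one clip
#'
#' Container for a clip's frames: an \code{H x W x 3 x T} array of RGB
#' intensities in [0, 1], per-frame timestamps in seconds from clip start,
#' and optional per-frame annotations (dominant object class, face flag).
#' Synthetic clips additionally carry the generator's per-frame latent scene
#' descriptor.
#'
#' @param frames numeric array \code{H x W x 3 x T} with values in [0, 1].
#' @param timestamps_s strictly increasing numeric vector of length T.
#' @param clip_id integer clip identifier.
#' @param labels optional data.frame with one row per frame (columns
#'   \code{class}, \code{face}).
#' @param latent optional numeric matrix (T x d) of ground-truth scene
#'   descriptors (synthetic data only).
#' @return an object of class \code{"frame_sequence"}.
#' @export
frame_sequence <- function(frames, timestamps_s, clip_id = 1L,
                           labels = NULL, latent = NULL) {
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 4L || dim(frames)[3] != 3L) {
    stop_bd("frames must be an H x W x 3 x T array")
  }
  nt <- dim(frames)[4]
  if (length(timestamps_s) != nt) {
    stop_bd("timestamps_s length (%d) must equal frame count (%d)",
            length(timestamps_s), nt)
  }
  if (nt > 1 && any(diff(timestamps_s) <= 0)) {
    stop_bd("timestamps_s must be strictly increasing")
  }
  rng <- range(frames)
  if (!all(is.finite(frames)) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop_bd("frame values must be finite and within [0, 1]")
  }
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (nrow(labels) != nt) stop_bd("labels must have one row per frame")
  }
  if (!is.null(latent)) {
    latent <- as.matrix(latent)
    if (nrow(latent) != nt) stop_bd("latent must have one row per frame")
  }
  structure(
    list(frames = frames, timestamps_s = as.numeric(timestamps_s),
         clip_id = as.integer(clip_id), labels = labels, latent = latent),
    class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> clip %d: %d frames of %dx%dx3, %.2f s\n",
              x$clip_id, d[4], d[1], d[2],
              diff(range(x$timestamps_s))))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(unique(x$labels$class), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) dim(x$frames)[4]

n_frames <- function(seq) dim(seq$frames)[4]

# Subset a frame_sequence by frame index, carrying labels and latent along.
subset_frames <- function(seq, idx) {
  frame_sequence(seq$frames[, , , idx, drop = FALSE],
                 seq$timestamps_s[idx], seq$clip_id,
                 labels = if (!is.null(seq$labels)) seq$labels[idx, , drop = FALSE],
                 latent = if (!is.null(seq$latent)) seq$latent[idx, , drop = FALSE])
}

#' Temporal subsampling of a frame sequence to the fMRI acquisition grid
#'
#' Selects, for each target time \code{j * tr_s} (j = 0, 1, ...,
#' \code{floor(last_timestamp / tr_s)}), the source frame whose timestamp is
#' nearest. Frames are selected, never averaged, matching an acquisition grid
#' that samples the stimulus stream. Labels and ground-truth descriptors are
#' carried over from the selected frames.
#'
#' @param seq a \code{\link{frame_sequence}}.
#' @param tr_s target sampling interval in seconds (the fMRI repetition
#'   time); must be no shorter than the source frame interval.
#' @return a \code{\link{frame_sequence}} sampled at \code{tr_s}.
#' @examples
#' seq <- frame_sequence(array(0.5, c(16, 16, 3, 48)), (0:47) / 24)
#' length(subsample_temporal(seq, 0.72))
#' @export
subsample_temporal <- function(seq, tr_s) {
  stopifnot(inherits(seq, "frame_sequence"), tr_s > 0)
  ts <- seq$timestamps_s
  if (length(ts) == 0L) stop_bd("empty frame sequence")
  if (length(ts) > 1L) {
    src_dt <- stats::median(diff(ts))
    if (tr_s < src_dt - 1e-9) {
      stop_bd("cannot upsample: tr_s = %g s is shorter than the source frame interval %g s",
              tr_s, src_dt)
    }
  }
  targets <- seq(0, by = tr_s, length.out = floor(ts[length(ts)] / tr_s) + 1L)
  idx <- vapply(targets, function(tt) which.min(abs(ts - tt)), integer(1))
  out <- subset_frames(seq, idx)
  out$timestamps_s <- targets
  out
}

#' Spatial resampling of a frame sequence
#'
#' Bilinear down-sampling of every frame to \code{height x width}
#' (via \code{EBImage::resize}); output values are clipped to [0, 1].
#' Up-scaling is refused: the operation models resolution reduction of the
#' stimulus stream (e.g. 720x1024 down to the 224x224 network input).
#'
#' @param seq a \code{\link{frame_sequence}}.
#' @param height,width target size in pixels; each must not exceed the source.
#' @return a \code{\link{frame_sequence}} of the requested size.
#' @export
resize_spatial <- function(seq, height, width) {
  stopifnot(inherits(seq, "frame_sequence"), is_count(height), is_count(width))
  d <- dim(seq$frames)
  if (height > d[1] || width > d[2]) {
    stop_bd("upscaling not supported: target %dx%d exceeds source %dx%d",
            height, width, d[1], d[2])
  }
  if (height == d[1] && width == d[2]) return(seq)
  nt <- d[4]
  out <- array(0, c(height, width, 3L, nt))
  for (t in seq_len(nt)) {
    out[, , , t] <- EBImage::resize(seq$frames[, , , t], w = height,
                                    h = width, filter = "bilinear")
  }
  out <- pmin(pmax(out, 0), 1)
  frame_sequence(out, seq$timestamps_s, seq$clip_id,
                 labels = seq$labels, latent = seq$latent)
}
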
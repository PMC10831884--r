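# Frame I/O: PNG frame directories with a JSON manifest.

#' Write frame sequences to a PNG directory
#'
#' Writes every frame of every clip as an 8-bit PNG
#' (\code{clip<id>_frame<j>.png}) plus a \code{manifest.json} recording clip
#' boundaries, timestamps and labels, so the set can be read back with
#' \code{\link{read_frames}}.
#'
#' @param seqs a \code{\link{frame_sequence}} or list of them.
#' @param path output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_frames <- function(seqs, path) {
  if (inherits(seqs, "frame_sequence")) seqs <- list(seqs)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(clips = list())
  for (s in seqs) {
    nt <- n_frames(s)
    files <- sprintf("clip%03d_frame%04d.png", s$clip_id, seq_len(nt))
    for (t in seq_len(nt)) {
      png::writePNG(s$frames[, , , t], file.path(path, files[t]))
    }
    entry <- list(clip_id = s$clip_id, files = files,
                  timestamps_s = s$timestamps_s,
                  height = dim(s$frames)[1], width = dim(s$frames)[2])
    if (!is.null(s$labels)) entry$labels <- s$labels
    manifest$clips[[length(manifest$clips) + 1L]] <- entry
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read frame sequences from a PNG directory
#'
#' Inverse of \code{\link{write_frames}}; the round trip is exact up to the
#' 8-bit PNG quantisation (1/255 per channel). Clips with missing files or
#' frames of inconsistent shape are rejected.
#'
#' @param path directory containing PNG frames and \code{manifest.json}.
#' @return list of \code{\link{frame_sequence}} objects.
#' @export
read_frames <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop_bd("no manifest.json in %s", path)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  clips <- lapply(manifest$clips, function(e) {
    e$files <- unlist(e$files)
    e$timestamps_s <- unlist(e$timestamps_s)
    e$clip_id <- as.integer(e$clip_id)
    e$height <- as.integer(e$height)
    e$width <- as.integer(e$width)
    if (!is.null(e$labels)) {
      e$labels <- data.frame(class = unlist(e$labels$class),
                             face = unlist(e$labels$face))
    }
    e
  })
  lapply(clips, function(e) {
    files <- file.path(path, e$files)
    missing <- !file.exists(files)
    if (any(missing)) {
      stop_bd("missing frames for clip %d: %s", e$clip_id,
              paste(basename(files[missing]), collapse = ", "))
    }
    frames <- array(0, c(e$height, e$width, 3L, length(files)))
    for (t in seq_along(files)) {
      img <- png::readPNG(files[t])
      if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
      if (dim(img)[3] > 3L) img <- img[, , 1:3]
      if (!all(dim(img)[1:2] == c(e$height, e$width))) {
        stop_bd("frame %s has shape %dx%d, expected %dx%d",
                basename(files[t]), dim(img)[1], dim(img)[2],
                e$height, e$width)
      }
      frames[, , , t] <- img
    }
    labels <- if (!is.null(e$labels)) as.data.frame(e$labels)
    frame_sequence(frames, unlist(e$timestamps_s), e$clip_id, labels = labels)
  })
}
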
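# Synthetic stimulus generator: moving coloured glyphs on a grey background.
# Each object class has a distinct colour so that class recovery from blurry
# decoder reconstructions is well-posed.

glyph_classes <- function() c("circle", "square", "triangle", "face")

glyph_colour <- function(class) {
  switch(class,
         circle   = c(0.90, 0.15, 0.15),
         square   = c(0.15, 0.80, 0.20),
         triangle = c(0.20, 0.30, 0.90),
         face     = c(0.95, 0.80, 0.25),
         stop_bd("unknown glyph class '%s'", class))
}

#' Specification of one synthetic scene (clip)
#'
#' Describes a clip as a set of glyph objects with smooth trajectories over a
#' plain background. Positions are in normalised scene coordinates
#' (\code{x} = column in [0,1], \code{y} = row in [0,1]); \code{scale} is the
#' glyph radius as a fraction of the frame's shorter side. Trajectories are
#' validated at construction: a glyph whose path would leave the frame is
#' rejected.
#'
#' @param clip_id integer identifier.
#' @param duration_s clip length in seconds (> 0).
#' @param objects list of objects, each a list with fields \code{class}
#'   (one of \code{circle}, \code{square}, \code{triangle}, \code{face}),
#'   \code{x0}, \code{y0}, \code{x1}, \code{y1} (trajectory endpoints),
#'   \code{scale}, and optional \code{motion} (\code{"linear"} or
#'   \code{"sine"}), \code{pulse_amp} (relative size oscillation amplitude,
#'   in [0, 1)), \code{pulse_freq} (oscillation cycles per clip) and
#'   \code{pulse_phase} (radians). Size pulsation emulates objects
#'   approaching and receding, so which object dominates a frame can change
#'   over the clip. An empty list gives an explicit empty scene.
#' @param background_id integer selecting one of a few background grey levels.
#' @return an object of class \code{"scene_spec"}.
#' @export
scene_spec <- function(clip_id, duration_s, objects = list(),
                       background_id = 1L) {
  stopifnot(is_count(clip_id), duration_s > 0)
  for (ob in objects) {
    stopifnot(ob$class %in% glyph_classes(),
              is.numeric(ob$scale), ob$scale > 0)
    amp <- ob$pulse_amp %||% 0
    stopifnot(amp >= 0, amp < 1)
    motion <- ob$motion %||% "linear"
    tt <- seq(0, 1, length.out = 64)
    pos <- object_position(ob, tt)
    margin <- ob$scale * (1 + amp)
    if (any(pos$x < margin) || any(pos$x > 1 - margin) ||
        any(pos$y < margin) || any(pos$y > 1 - margin)) {
      stop_bd("object of class '%s' leaves the frame along its trajectory",
              ob$class)
    }
    if (!motion %in% c("linear", "sine")) stop_bd("unknown motion '%s'", motion)
  }
  structure(list(clip_id = as.integer(clip_id),
                 duration_s = as.numeric(duration_s),
                 objects = objects,
                 background_id = as.integer(background_id)),
            class = "scene_spec")
}

# Position of one object at normalised times tt in [0, 1].
object_position <- function(ob, tt) {
  u <- switch(ob$motion %||% "linear",
              linear = tt,
              sine   = (1 - cos(pi * tt)) / 2)
  list(x = ob$x0 + (ob$x1 - ob$x0) * u,
       y = ob$y0 + (ob$y1 - ob$y0) * u)
}

# Instantaneous size at normalised time u in [0, 1].
object_scale <- function(ob, u) {
  amp <- ob$pulse_amp %||% 0
  if (amp == 0) return(ob$scale)
  freq <- ob$pulse_freq %||% 1
  phase <- ob$pulse_phase %||% 0
  ob$scale * (1 + amp * sin(2 * pi * freq * u + phase))
}

scene_background <- function(background_id) {
  0.10 + 0.04 * ((background_id - 1L) %% 3L)
}

# Soft occupancy mask (H x W, values in [0,1]) of one glyph at centre
# (cx, cy), radius r (normalised units); ~1-pixel anti-aliased edge.
glyph_mask <- function(class, cx, cy, r, height, width) {
  px <- min(height, width)
  xs <- matrix((seq_len(width) - 0.5) / width, height, width, byrow = TRUE)
  ys <- matrix((seq_len(height) - 0.5) / height, height, width)
  dx <- xs - cx
  dy <- ys - cy
  edge <- 1 / px # one pixel in normalised units
  sdist <- switch(class,
    circle = ,
    face = r - sqrt(dx^2 + dy^2),
    square = r - pmax(abs(dx), abs(dy)),
    triangle = {
      # upward-pointing triangle inscribed in the radius-r circle
      top <- dy + r                       # distance below the apex
      left <- (r - dy) * 0.866 + dx * 1.0 # crude half-plane distances
      right <- (r - dy) * 0.866 - dx * 1.0
      pmin(top, left, right) / 2
    },
    stop_bd("unknown glyph class '%s'", class))
  smoothstep(sdist / edge + 0.5)
}

# Paint one object onto an H x W x 3 frame (alpha compositing).
paint_object <- function(frame, ob, cx, cy, height, width, scale = NULL) {
  r0 <- scale %||% ob$scale
  mask <- glyph_mask(ob$class, cx, cy, r0, height, width)
  col <- glyph_colour(ob$class)
  for (ch in 1:3) {
    frame[, , ch] <- frame[, , ch] * (1 - mask) + col[ch] * mask
  }
  if (ob$class == "face") {
    r <- r0
    dark <- 0.08
    parts <- list(
      list(class = "circle", cx = cx - 0.35 * r, cy = cy - 0.30 * r, r = 0.15 * r),
      list(class = "circle", cx = cx + 0.35 * r, cy = cy - 0.30 * r, r = 0.15 * r),
      list(class = "square", cx = cx,            cy = cy + 0.40 * r, r = 0.28 * r))
    for (p in parts) {
      m <- glyph_mask(p$class, p$cx, p$cy, p$r, height, width)
      for (ch in 1:3) frame[, , ch] <- frame[, , ch] * (1 - m) + dark * m
    }
  }
  frame
}

#' Render a synthetic scene into a frame sequence
#'
#' Rasterises a \code{\link{scene_spec}} at a given frame rate and size.
#' Per-frame labels (dominant object class, face flag) and the ground-truth
#' latent scene descriptor are attached. The descriptor per frame holds two
#' object slots in listing order — class one-hot (4), normalised centroid
#' (x, y) and scale each — plus the face-present flag: 15 numbers, all zero
#' for an empty scene. It fully determines the rendered scene for up to two
#' objects.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param frame_rate_hz frames per second (> 0).
#' @param height,width frame size in pixels (>= 16).
#' @return a \code{\link{frame_sequence}} with \code{labels} and
#'   \code{latent} populated.
#' @export
render_clip <- function(spec, frame_rate_hz, height = 32L, width = 32L) {
  stopifnot(inherits(spec, "scene_spec"), frame_rate_hz > 0,
            height >= 16, width >= 16)
  nt <- floor(spec$duration_s * frame_rate_hz)
  if (nt < 1) stop_bd("duration too short for one frame at %g Hz", frame_rate_hz)
  ts <- (seq_len(nt) - 1L) / frame_rate_hz
  bg <- scene_background(spec$background_id)
  frames <- array(bg, c(height, width, 3L, nt))
  # scene descriptor: two object slots (listing order, stable in time), each
  # a class one-hot plus centroid and scale, then the face flag; the
  # descriptor fully determines the rendered scene for up to two objects
  classes <- glyph_classes()
  slot_names <- function(s) {
    c(paste0("o", s, "_", classes),
      paste0("o", s, "_", c("cx", "cy", "scale")))
  }
  lat <- matrix(0, nt, 15L)
  colnames(lat) <- c(slot_names(1), slot_names(2), "face")
  cls <- rep("none", nt)
  face <- rep(FALSE, nt)
  for (t in seq_len(nt)) {
    u <- if (nt > 1) (t - 1) / (nt - 1) else 0
    fr <- frames[, , , t]
    dom <- NULL
    for (oi in seq_along(spec$objects)) {
      ob <- spec$objects[[oi]]
      pos <- object_position(ob, u)
      scl <- object_scale(ob, u)
      fr <- paint_object(fr, ob, pos$x, pos$y, height, width, scale = scl)
      if (oi <= 2L) {
        base <- (oi - 1L) * 7L
        lat[t, base + match(ob$class, classes)] <- 1
        lat[t, base + 5:7] <- c(pos$x, pos$y, scl)
      }
      if (is.null(dom) || scl > dom$scale) {
        dom <- list(class = ob$class, x = pos$x, y = pos$y, scale = scl)
      }
      if (ob$class == "face") face[t] <- TRUE
    }
    frames[, , , t] <- fr
    if (!is.null(dom)) {
      cls[t] <- dom$class
      lat[t, "face"] <- as.numeric(face[t])
    }
  }
  frames <- pmin(pmax(frames, 0), 1)
  frame_sequence(frames, ts, spec$clip_id,
                 labels = data.frame(class = cls, face = face),
                 latent = lat)
}

#' Colour-template glyph classifier
#'
#' A self-contained image classifier over the synthetic glyph vocabulary:
#' each frame is scored against each class colour by soft pixel-colour
#' affinity, giving a ranked label list per frame. Serves as the pluggable
#' "object classifier" in the label-overlap workflow (the adapter slot a
#' pretrained ImageNet network would occupy on real data).
#'
#' @param frames an \code{H x W x 3 x T} array or a
#'   \code{\link{frame_sequence}}.
#' @return list of T data.frames (\code{label}, \code{score}) with
#'   non-increasing scores.
#' @export
classify_glyphs <- function(frames) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  nt <- dim(frames)[4]
  classes <- glyph_classes()
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    fr <- frames[, , , t]
    scores <- vapply(classes, function(cl) {
      col <- glyph_colour(cl)
      d2 <- (fr[, , 1] - col[1])^2 + (fr[, , 2] - col[2])^2 +
        (fr[, , 3] - col[3])^2
      sum(pmax(0, 1 - sqrt(d2) / 0.6))
    }, numeric(1))
    scores <- scores / max(sum(scores), 1e-12)
    ord <- order(scores, decreasing = TRUE)
    out[[t]] <- data.frame(label = classes[ord], score = scores[ord],
                           row.names = NULL)
  }
  out
}

#' Mock label ranker with a known confusion matrix
#'
#' Builds a classifier stand-in driven by ground-truth labels: given a true
#' class, it emits a label ranking either by sampling the top label from the
#' corresponding confusion-matrix row (\code{mode = "sample"}) or by sorting
#' the row deterministically (\code{mode = "sort"}). Used to validate the
#' label-overlap statistic against closed-form hit probabilities.
#'
#' @param confusion square stochastic matrix (rows sum to 1) with dimnames
#'   giving the class vocabulary.
#' @param mode \code{"sample"} or \code{"sort"}.
#' @return function mapping a character vector of true labels to a list of
#'   rankings (data.frames with \code{label}, \code{score}).
#' @export
mock_label_ranker <- function(confusion, mode = c("sample", "sort")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
            all(abs(rowSums(confusion) - 1) < 1e-8))
  classes <- rownames(confusion)
  stopifnot(!is.null(classes))
  function(true_labels) {
    lapply(true_labels, function(tl) {
      row <- confusion[tl, ]
      if (mode == "sample") {
        top <- sample(classes, 1L, prob = row)
        rest <- setdiff(classes, top)
        labs <- c(top, rest[order(row[rest], decreasing = TRUE)])
        sc <- sort(seq_along(labs) / length(labs), decreasing = TRUE)
      } else {
        ord <- order(row, decreasing = TRUE)
        labs <- classes[ord]
        sc <- row[ord]
      }
      data.frame(label = labs, score = as.numeric(sc), row.names = NULL)
    })
  }
}

#' Glyph face-detector score
#'
#' Scores each frame for the presence of the synthetic face glyph using its
#' colour signature (high red+green, low blue). Returns a confidence in
#' [0, 1] per frame. This fills the pluggable detector slot that a
#' multi-stage face-detection network would occupy on real imagery.
#'
#' @param frames an \code{H x W x 3 x T} array or \code{\link{frame_sequence}}.
#' @return numeric vector of per-frame scores in [0, 1].
#' @export
face_score_glyph <- function(frames) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  nt <- dim(frames)[4]
  vapply(seq_len(nt), function(t) {
    fr <- frames[, , , t]
    yellow <- pmax(0, pmin(fr[, , 1], fr[, , 2]) - fr[, , 3])
    smoothstep(mean(yellow) / 0.04)
  }, numeric(1))
}
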
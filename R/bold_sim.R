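#' Configuration of the synthetic BOLD forward model
#'
#' Collects the acquisition and noise parameters used by
#' \code{\link{simulate_bold}}: repetition time, voxel counts, double-gamma
#' HRF shape, AR(1) + global-signal noise, and the rest-block length
#' separating clips.
#'
#' @param tr_s repetition time in seconds (default 0.72, the 7T movie
#'   protocol value).
#' @param n_voxels total number of simulated voxels.
#' @param n_signal_voxels number of voxels that respond to the stimulus
#'   (must not exceed \code{n_voxels}).
#' @param hrf list with \code{peak_s}, \code{undershoot_s}, \code{ratio}
#'   passed to \code{\link{hrf_double_gamma}}.
#' @param noise_ar1 lag-1 autocorrelation of voxel noise, in [0, 1).
#' @param noise_sd stationary standard deviation of voxel noise, in units of
#'   the (unit-sd) clean signal; 0.5 gives SNR 2.
#' @param global_signal_sd standard deviation of the shared global signal.
#' @param rest_block_s rest-block length between clips, seconds (default 20).
#' @param drive_strength amplitude of each signal voxel's sustained
#'   (signed) response to "stimulus on", relative to the unit-variance
#'   scene-feature modulation.
#' @param seed integer seed governing mixing weights and noise.
#' @return an object of class \code{"bold_config"}.
#' @export
bold_config <- function(tr_s = 0.72, n_voxels = 1000L, n_signal_voxels = 200L,
                        hrf = list(peak_s = 6, undershoot_s = 16, ratio = 1 / 6),
                        noise_ar1 = 0.3, noise_sd = 0.5,
                        global_signal_sd = 0.3, rest_block_s = 20,
                        drive_strength = 4, seed = 1L) {
  stopifnot(tr_s > 0, n_signal_voxels <= n_voxels, n_signal_voxels >= 1,
            noise_ar1 >= 0, noise_ar1 < 1, noise_sd >= 0,
            global_signal_sd >= 0, rest_block_s >= 0, drive_strength >= 0)
  structure(list(tr_s = tr_s, n_voxels = as.integer(n_voxels),
                 n_signal_voxels = as.integer(n_signal_voxels), hrf = hrf,
                 noise_ar1 = noise_ar1, noise_sd = noise_sd,
                 global_signal_sd = global_signal_sd,
                 rest_block_s = rest_block_s,
                 drive_strength = drive_strength, seed = as.integer(seed)),
            class = "bold_config")
}

# Stationary AR(1) noise matrix (n x k) with sd `s` and lag-1 coefficient phi.
ar1_noise <- function(n, k, s, phi) {
  if (s == 0 || n == 0) return(matrix(0, n, k))
  e <- matrix(rnorm(n * k, sd = s * sqrt(1 - phi^2)), n, k)
  e[1, ] <- rnorm(k, sd = s)
  if (phi > 0 && n > 1) for (t in 2:n) e[t, ] <- phi * e[t - 1, ] + e[t, ]
  e
}

# Draw the voxel mixing structure: which voxels carry signal, and their
# weights onto the augmented descriptor [drive | latent]. Each signal voxel
# gets a sustained response to "stimulus on" of amplitude
# drive_strength * Uniform(0.75, 1.5) and random sign (activations and
# deactivations — the reason the ROI test is two-tailed, and what lets the
# block contrast survive global signal regression), plus standard-normal
# weights onto the scene-feature channels.
draw_mixing <- function(cfg, latent_dim) {
  idx <- sort(sample.int(cfg$n_voxels, cfg$n_signal_voxels))
  gain <- runif(cfg$n_signal_voxels, 0.75, 1.5) * cfg$drive_strength *
    sample(c(-1, 1), cfg$n_signal_voxels, replace = TRUE)
  w <- matrix(rnorm(cfg$n_signal_voxels * latent_dim),
              cfg$n_signal_voxels, latent_dim)
  list(signal_idx = idx, mixing = cbind(drive = gain, w))
}

#' Simulate BOLD responses to a latent stimulus descriptor
#'
#' Forward model for one clip: the per-frame ground-truth scene descriptor is
#' resampled to the acquisition (TR) grid, augmented with a leading
#' stimulus-drive channel (1 whenever any object is on screen), mixed into
#' signal voxels through a random weight matrix whose drive column is
#' strictly positive, convolved with the canonical double-gamma HRF, and
#' finally corrupted by AR(1) voxel noise plus a shared global signal. A
#' rest block (noise only, with natural haemodynamic spill-over from the
#' clip) is appended after the movie timepoints. Null voxels carry noise and
#' global signal only. The clean mixed signal is rescaled so its average
#' per-voxel standard deviation during the movie is 1, making
#' \code{noise_sd} the inverse SNR.
#'
#' @param latent_true numeric matrix, frames x descriptor dimensions.
#' @param cfg a \code{\link{bold_config}}.
#' @param frame_rate_hz frame rate of \code{latent_true}, Hz.
#' @param mixing optional list from \code{draw_mixing} (shared across clips
#'   of one dataset); drawn from \code{cfg$seed} when NULL.
#' @param signal_scale optional precomputed normalisation constant (shared
#'   across clips); computed from this clip when NULL.
#' @return list with \code{fmri} (a \code{\link{voxel_timeseries}} over
#'   movie + rest timepoints) and \code{truth} (signal mask, mixing matrix,
#'   TR-grid descriptor, clean signal, condition labels, scale).
#' @export
simulate_bold <- function(latent_true, cfg, frame_rate_hz,
                          mixing = NULL, signal_scale = NULL) {
  stopifnot(inherits(cfg, "bold_config"), frame_rate_hz > 0)
  latent_true <- as.matrix(latent_true)
  if (nrow(latent_true) == 0L) stop_bd("empty stimulus")
  with_seed(cfg$seed, {
    nf <- nrow(latent_true)
    duration <- nf / frame_rate_hz
    n_movie <- ceiling(duration / cfg$tr_s)
    n_rest <- ceiling(cfg$rest_block_s / cfg$tr_s)
    n_tot <- n_movie + n_rest
    frame_ts <- (seq_len(nf) - 1L) / frame_rate_hz
    tr_ts <- (seq_len(n_movie) - 1L) * cfg$tr_s
    sel <- vapply(tr_ts, function(tt) which.min(abs(frame_ts - tt)), integer(1))
    lat_tr <- latent_true[sel, , drop = FALSE]
    drive <- as.numeric(rowSums(abs(lat_tr)) > 0)
    aug <- cbind(drive = drive, lat_tr)
    aug_full <- rbind(aug, matrix(0, n_rest, ncol(aug)))

    h <- hrf_double_gamma(seq(0, 32, by = cfg$tr_s),
                          peak_s = cfg$hrf$peak_s,
                          undershoot_s = cfg$hrf$undershoot_s,
                          ratio = cfg$hrf$ratio)
    conv <- convolve_hrf(aug_full, h)

    if (is.null(mixing)) mixing <- draw_mixing(cfg, ncol(latent_true))
    clean <- conv %*% t(mixing$mixing)
    if (is.null(signal_scale)) {
      sds <- apply(clean[seq_len(n_movie), , drop = FALSE], 2, sd)
      signal_scale <- mean(sds)
      if (signal_scale == 0) signal_scale <- 1
    }
    clean <- clean / signal_scale

    noise <- ar1_noise(n_tot, cfg$n_voxels, cfg$noise_sd, cfg$noise_ar1)
    global <- ar1_noise(n_tot, 1L, cfg$global_signal_sd, cfg$noise_ar1)
    values <- noise + matrix(global, n_tot, cfg$n_voxels)
    values[, mixing$signal_idx] <- values[, mixing$signal_idx] + clean

    condition <- c(rep("movie", n_movie), rep("rest", n_rest))
    fmri <- voxel_timeseries(values, condition, cfg$tr_s)
    truth <- list(signal_idx = mixing$signal_idx,
                  signal_mask = seq_len(cfg$n_voxels) %in% mixing$signal_idx,
                  mixing = mixing$mixing / signal_scale,
                  latent_tr = aug, clean_signal = clean,
                  condition = condition, signal_scale = signal_scale,
                  frame_to_tr = sel)
    list(fmri = fmri, truth = truth)
  })
}

#' Generate a paired synthetic (video, fMRI) dataset
#'
#' Builds \code{n_clips} glyph scenes (object classes cycle through the
#' vocabulary; trajectories, motion profiles and scales are drawn per clip
#' from the master seed), renders them, and simulates the corresponding
#' BOLD series with one shared voxel-mixing structure (the same "brain" sees
#' every clip). Clips are separated by rest blocks; a leading rest block
#' precedes the first clip, so \code{n_clips} movie segments come with
#' \code{n_clips + 1} rest segments.
#'
#' @param n_clips number of clips (>= 2).
#' @param cfg a \code{\link{bold_config}}.
#' @param scene_params list with \code{height}, \code{width},
#'   \code{frame_rate_hz}, \code{duration_s} (scalar or per-clip vector),
#'   and optional \code{objects_per_clip} (1 or 2, default 2).
#' @param seed master seed; every random choice derives from it.
#' @return object of class \code{"paired_dataset"}: per-clip
#'   \code{frames} / \code{fmri} / \code{truth}, plus a segment
#'   \code{manifest} and the configurations used.
#' @export
make_dataset <- function(n_clips = 4L, cfg = bold_config(),
                         scene_params = list(height = 32L, width = 32L,
                                             frame_rate_hz = 4,
                                             duration_s = 30),
                         seed = 1L) {
  stopifnot(is_count(n_clips), n_clips >= 2)
  sp <- scene_params
  dur <- rep_len(sp$duration_s, n_clips)
  seeds <- split_seed(seed, n_clips + 2L)
  classes <- glyph_classes()
  latent_dim <- 15L

  mix <- with_seed(seeds[n_clips + 1L], draw_mixing(cfg, latent_dim))

  clips <- vector("list", n_clips)
  signal_scale <- NULL
  for (i in seq_len(n_clips)) {
    n_obj <- sp$objects_per_clip %||% 2L
    sc <- with_seed(seeds[i], {
      # default: two glyphs per clip — the clip's own class plus the next
      # one in the vocabulary, with counter-phase size pulsation so which
      # object dominates a frame alternates over the clip; every class
      # therefore appears as a dominant object in more than one clip.
      # objects_per_clip = 1 gives simpler single-glyph scenes (one class
      # per clip, no pulsation ambiguity).
      cl1 <- classes[((i - 1L) %% length(classes)) + 1L]
      cl2 <- classes[(i %% length(classes)) + 1L]
      mk_obj <- function(cl, phase, amp) {
        scl <- if (n_obj == 1L) runif(1, 0.18, 0.22) else runif(1, 0.14, 0.18)
        m <- scl * (1 + amp) + 0.02
        x0 <- runif(1, m, 0.45); x1 <- runif(1, 0.55, 1 - m)
        if (runif(1) < 0.5) { tmp <- x0; x0 <- x1; x1 <- tmp }
        y0 <- runif(1, m, 1 - m); y1 <- runif(1, m, 1 - m)
        list(class = cl, x0 = x0, y0 = y0, x1 = x1, y1 = y1, scale = scl,
             motion = if (i %% 2) "linear" else "sine",
             pulse_amp = amp, pulse_freq = 2, pulse_phase = phase)
      }
      objs <- if (n_obj == 1L) {
        list(mk_obj(cl1, 0, 0))
      } else {
        list(mk_obj(cl1, 0, 0.3), mk_obj(cl2, pi, 0.3))
      }
      scene_spec(i, dur[i], objects = objs, background_id = i)
    })
    frames <- render_clip(sc, sp$frame_rate_hz, sp$height, sp$width)
    cfg_i <- cfg
    cfg_i$seed <- seeds[i]
    sim <- simulate_bold(frames$latent, cfg_i, sp$frame_rate_hz,
                         mixing = mix, signal_scale = signal_scale)
    if (is.null(signal_scale)) signal_scale <- sim$truth$signal_scale
    clips[[i]] <- list(scene = sc, frames = frames, fmri = sim$fmri,
                       truth = sim$truth)
  }

  n_rest <- ceiling(cfg$rest_block_s / cfg$tr_s)
  lead_noise <- with_seed(seeds[n_clips + 2L], {
    ar1_noise(n_rest, cfg$n_voxels, cfg$noise_sd, cfg$noise_ar1) +
      matrix(ar1_noise(n_rest, 1L, cfg$global_signal_sd, cfg$noise_ar1),
             n_rest, cfg$n_voxels)
  })

  manifest <- data.frame(type = "rest", clip_id = NA_integer_,
                         n_tr = n_rest, seed = seeds[n_clips + 2L])
  for (i in seq_len(n_clips)) {
    n_movie <- sum(clips[[i]]$truth$condition == "movie")
    manifest <- rbind(manifest,
      data.frame(type = c("movie", "rest"), clip_id = c(i, NA_integer_),
                 n_tr = c(n_movie, n_rest), seed = seeds[i]))
  }
  manifest$start_tr <- cumsum(c(1, head(manifest$n_tr, -1)))

  structure(list(clips = clips, manifest = manifest, cfg = cfg,
                 scene_params = sp, seed = seed,
                 leading_rest = lead_noise,
                 signal_mask = mix$signal_idx),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d clips, %d voxels (%d signal), TR %.2f s\n",
              length(x$clips), x$cfg$n_voxels, x$cfg$n_signal_voxels,
              x$cfg$tr_s))
  cat(sprintf("  timeline: %d TRs in %d segments\n",
              sum(x$manifest$n_tr), nrow(x$manifest)))
  invisible(x)
}

#' Concatenate a paired dataset's fMRI timeline
#'
#' Stacks the leading rest block and every clip's movie + rest timepoints
#' into one \code{\link{voxel_timeseries}}, with per-timepoint condition and
#' clip labels, in acquisition order.
#'
#' @param dataset a \code{\link{make_dataset}} result.
#' @return a \code{\link{voxel_timeseries}} whose \code{clip} field gives the
#'   originating clip id (NA during rest).
#' @export
concat_fmri <- function(dataset) {
  stopifnot(inherits(dataset, "paired_dataset"))
  vals <- list(dataset$leading_rest)
  cond <- rep("rest", nrow(dataset$leading_rest))
  clip <- rep(NA_integer_, nrow(dataset$leading_rest))
  for (i in seq_along(dataset$clips)) {
    cl <- dataset$clips[[i]]
    vals[[length(vals) + 1L]] <- cl$fmri$values
    cond <- c(cond, cl$fmri$condition)
    clip <- c(clip, ifelse(cl$fmri$condition == "movie", i, NA_integer_))
  }
  voxel_timeseries(do.call(rbind, vals), cond, dataset$cfg$tr_s, clip = clip)
}
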
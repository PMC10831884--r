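#' Split clips into training and test sets
#'
#' Leave-one-clip-out split: one clip is held back for testing, all others
#' train both networks (15/1 at full scale). Splitting is always at clip
#' granularity — frames within a clip are strongly autocorrelated, so a
#' frame-level split would leak temporal context.
#'
#' @param n_clips total number of clips (>= 2).
#' @param test_id the held-out clip (1-based).
#' @return list with \code{train} (integer vector) and \code{test}.
#' @export
split_clips <- function(n_clips, test_id) {
  stopifnot(is_count(n_clips), n_clips >= 2)
  if (!is_count(test_id) || test_id < 1 || test_id > n_clips) {
    stop_bd("invalid test clip id %s (must be in 1..%d)",
            toString(test_id), n_clips)
  }
  list(train = setdiff(seq_len(n_clips), as.integer(test_id)),
       test = as.integer(test_id))
}

#' Configuration of a full decoding experiment
#'
#' Bundles every knob of the synthetic end-to-end protocol: the dataset
#' generator, the two network specifications, the split and cross-validation
#' scheme, and the evaluation grid. All randomness in
#' \code{\link{run_experiment}} derives from \code{seed}.
#'
#' @param n_clips number of synthetic clips.
#' @param bold_cfg a \code{\link{bold_config}}.
#' @param scene_params generator scene parameters (see
#'   \code{\link{make_dataset}}).
#' @param latent_dim autoencoder latent dimensionality.
#' @param ae_channels encoder conv channels (4, strictly increasing).
#' @param ae_epochs autoencoder training epochs.
#' @param map_hidden,map_epochs,map_architecture fMRI-map size, epochs and
#'   architecture (\code{"gru"} or \code{"memoryless"}).
#' @param test_clip_id held-out clip (1-based; default the last clip).
#' @param cv if TRUE, the map is refit once per leave-one-clip-out fold of
#'   the training clips to produce held-out ("cv") predictions.
#' @param k_values cluster counts for the ARI curves.
#' @param knn_ks neighbourhood sizes for stimulus matching.
#' @param label_top_ks top-k values for label overlap.
#' @param lag_tr fMRI-to-frame lag in TR units (0 pairs simultaneous
#'   indices).
#' @param gsr if TRUE (default), apply global signal regression before ROI
#'   selection. Meaningful whenever a shared nuisance is present; in the
#'   exact noiseless limit there is no ubiquitous signal to remove and the
#'   regression would strip stimulus information instead, so noiseless runs
#'   set this to FALSE.
#' @param alpha ROI selection threshold.
#' @param seed master seed.
#' @param output_dir optional directory for the JSON report, ROI table and
#'   reconstructed frames.
#' @return an object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(n_clips = 4L, bold_cfg = bold_config(),
                              scene_params = list(height = 32L, width = 32L,
                                                  frame_rate_hz = 4,
                                                  duration_s = 30),
                              latent_dim = 32L,
                              ae_channels = c(8L, 16L, 32L, 64L),
                              ae_epochs = 80L,
                              map_hidden = 96L, map_epochs = 500L,
                              map_architecture = "gru",
                              test_clip_id = n_clips, cv = TRUE,
                              k_values = 3:20, knn_ks = c(1L, 3L),
                              label_top_ks = c(1L, 2L),
                              lag_tr = 0L, gsr = TRUE, alpha = 1e-8, seed = 1L,
                              output_dir = NULL) {
  structure(as.list(environment()), class = "experiment_config")
}

# Weak rolling checksum of a serialised object, for provenance stamping.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 251 + 1)) %% 0xFFFFFFF)
}

#' Reconstruct video frames directly from fMRI
#'
#' The decoding path: ROI timepoints are mapped into the latent space by the
#' fitted fMRI-latent map and pushed through the frozen decoder, yielding
#' one reconstructed frame per fMRI timepoint.
#'
#' @param autoencoder a fitted \code{\link{fit_autoencoder}} object.
#' @param map_model a fitted \code{\link{fit_latent_map}} object with
#'   matching latent dimensionality.
#' @param fmri ROI matrix (timepoints x voxels) or \code{roi_timeseries}.
#' @param clip_id clip identifier for the output.
#' @return a \code{\link{frame_sequence}} of reconstructed frames.
#' @export
reconstruct_from_fmri <- function(autoencoder, map_model, fmri,
                                  clip_id = 1L) {
  stopifnot(inherits(autoencoder, "video_autoencoder"),
            inherits(map_model, "fmri_latent_map"))
  if (map_model$spec$output_dim != autoencoder$spec$latent_dim) {
    stop_bd("map output dim (%d) does not match decoder latent dim (%d)",
            map_model$spec$output_dim, autoencoder$spec$latent_dim)
  }
  lat <- predict_latents(map_model, fmri, clip_id = clip_id)
  decode(autoencoder, lat)
}

# Extract, for clip i, the aligned (roi matrix, frame indices) pair.
clip_roi_rows <- function(roi, clip_i) {
  which(!is.na(roi$clip) & roi$clip == clip_i & roi$condition == "movie")
}

#' Run the full decoding experiment
#'
#' Executes the complete protocol on synthetic data: generate the paired
#' dataset; global signal regression and ROI selection; split clips; train
#' the autoencoder on the training clips; freeze it and encode all frames;
#' train the fMRI-latent map on the training clips (plus one refit per
#' leave-one-clip-out fold when \code{cv = TRUE}); predict latent vectors
#' for three conditions — training clips seen by both networks, each
#' cross-validation hold-out clip (seen by the encoder, not by the map), and
#' the test clip (seen by neither) — then evaluate cluster agreement, k-NN
#' stimulus matching, object-label overlap and face-detection ROC, and
#' decode reconstructions from fMRI.
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @return an object of class \code{"eval_report"}.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  stage <- "setup"
  hash <- config_hash(cfg[setdiff(names(cfg), "output_dir")])
  result <- tryCatch({
    seeds <- split_seed(cfg$seed, 6L)
    stage <- "simulate"
    ds <- make_dataset(cfg$n_clips, cfg$bold_cfg, cfg$scene_params,
                       seed = seeds[1])

    stage <- "preprocess"
    vox <- concat_fmri(ds)
    if (isTRUE(cfg$gsr)) vox <- global_signal_regression(vox)
    roi <- select_roi(vox, alpha = cfg$alpha)
    if (length(roi$voxel_ids) < 2L) {
      stop_bd("ROI selection kept %d voxels; cannot continue",
              length(roi$voxel_ids))
    }

    stage <- "split"
    split <- split_clips(cfg$n_clips, cfg$test_clip_id)
    frames_tr_grid <- lapply(ds$clips, function(cl) {
      subsample_temporal(cl$frames, cfg$bold_cfg$tr_s)
    })

    stage <- "train-autoencoder"
    ae_spec <- autoencoder_spec(
      input_hw = c(cfg$scene_params$height, cfg$scene_params$width),
      channels = cfg$ae_channels, latent_dim = cfg$latent_dim,
      decoder_channels = c(max(cfg$ae_channels) %/% 2L,
                           max(cfg$ae_channels) %/% 4L),
      epochs = cfg$ae_epochs, seed = seeds[2])
    ae <- fit_autoencoder(frames_tr_grid[split$train], ae_spec)

    stage <- "encode"
    actual <- lapply(seq_len(cfg$n_clips), function(i) {
      encode(ae, frames_tr_grid[[i]])
    })

    stage <- "align"
    aligned <- lapply(seq_len(cfg$n_clips), function(i) {
      rows <- clip_roi_rows(roi, i)
      pair <- align_fmri_to_frames(roi$values[rows, , drop = FALSE],
                                   n_frames(frames_tr_grid[[i]]),
                                   lag_tr = cfg$lag_tr)
      list(x = roi$values[rows[pair$fmri_row], , drop = FALSE],
           y = actual[[i]]$vectors[pair$frame, , drop = FALSE],
           frame = pair$frame)
    })

    stage <- "train-map"
    mk_spec <- function(seed) {
      map_spec(n_roi_voxels = ncol(roi$values), output_dim = cfg$latent_dim,
               hidden_dim = cfg$map_hidden, epochs = cfg$map_epochs,
               architecture = cfg$map_architecture, seed = seed)
    }
    train_x <- lapply(aligned[split$train], `[[`, "x")
    train_y <- lapply(aligned[split$train], `[[`, "y")
    map_full <- fit_latent_map(train_x, train_y, mk_spec(seeds[3]))

    folds <- if (isTRUE(cfg$cv)) split$train else split$train[1]
    fold_seeds <- split_seed(seeds[4], length(folds))
    cv_pred <- list(); cv_actual <- list()
    for (fi in seq_along(folds)) {
      stage <- sprintf("train-map-cv-fold-%d", fi)
      hold <- folds[fi]
      rest <- setdiff(split$train, hold)
      m <- fit_latent_map(lapply(aligned[rest], `[[`, "x"),
                          lapply(aligned[rest], `[[`, "y"),
                          mk_spec(fold_seeds[fi]))
      cv_pred[[fi]] <- predict_latents(m, aligned[[hold]]$x, clip_id = hold)
      cv_actual[[fi]] <- aligned[[hold]]$y
    }

    stage <- "predict"
    pred_seen <- lapply(split$train, function(i) {
      predict_latents(map_full, aligned[[i]]$x, clip_id = i)
    })
    pred_test <- predict_latents(map_full, aligned[[split$test]]$x,
                                 clip_id = split$test)

    stage <- "evaluate-clusters"
    seen_actual <- do.call(rbind, lapply(split$train,
                                         function(i) aligned[[i]]$y))
    seen_pred <- do.call(rbind, lapply(pred_seen, `[[`, "vectors"))
    cv_a <- do.call(rbind, cv_actual)
    cv_p <- do.call(rbind, lapply(cv_pred, `[[`, "vectors"))
    test_a <- aligned[[split$test]]$y
    test_p <- pred_test$vectors
    eval_seeds <- split_seed(seeds[5], 3L)
    cap_k <- function(kv, n) kv[kv <= n]
    conditions <- list(
      train_seen = compare_cluster_structure(
        seen_actual, seen_pred, cap_k(cfg$k_values, nrow(seen_actual)),
        seed = eval_seeds[1]),
      cv_holdout = compare_cluster_structure(
        cv_a, cv_p, cap_k(cfg$k_values, nrow(cv_a)), seed = eval_seeds[2]),
      test = compare_cluster_structure(
        test_a, test_p, cap_k(cfg$k_values, nrow(test_a)),
        seed = eval_seeds[3]))

    stage <- "evaluate-knn"
    knn <- do.call(rbind, lapply(cfg$knn_ks, function(k) {
      data.frame(condition = c("train_seen", "test"), k = k,
                 accuracy = c(knn_match(seen_actual, seen_pred, k),
                              knn_match(test_a, test_p, k)))
    }))

    stage <- "evaluate-labels"
    test_frames <- frames_tr_grid[[split$test]]
    test_idx <- aligned[[split$test]]$frame
    match_idx <- nearest_train_frame(test_p, seen_actual)
    train_frames_cat <- do.call(
      abind4, lapply(split$train, function(i) {
        frames_tr_grid[[i]]$frames[, , , aligned[[i]]$frame, drop = FALSE]
      }))
    test_rank <- classify_glyphs(test_frames$frames[, , , test_idx,
                                                    drop = FALSE])
    match_rank <- classify_glyphs(train_frames_cat[, , , match_idx,
                                                   drop = FALSE])
    seen_match_idx <- nearest_train_frame(seen_pred, seen_actual)
    seen_rank <- classify_glyphs(train_frames_cat)
    seen_match_rank <- classify_glyphs(train_frames_cat[, , , seen_match_idx,
                                                        drop = FALSE])
    overlap <- do.call(rbind, lapply(cfg$label_top_ks, function(k) {
      data.frame(condition = c("test", "train_seen"), top_k = k,
                 overlap = c(label_overlap(test_rank, match_rank, k),
                             label_overlap(seen_rank, seen_match_rank, k)))
    }))

    stage <- "reconstruct"
    all_pred <- rbind(seen_pred, test_p)
    all_actual <- rbind(seen_actual, test_a)
    recon_pred <- decode(ae, all_pred)
    recon_actual <- decode(ae, all_actual)
    scores_pred <- face_score_glyph(recon_pred)
    truth_recon <- face_score_glyph(recon_actual) >= 0.5
    truth_synth <- unlist(lapply(c(split$train, split$test), function(i) {
      frames_tr_grid[[i]]$labels$face[aligned[[i]]$frame]
    }))
    roc_recon <- suppressWarnings(face_roc(scores_pred, truth_recon))
    roc_synth <- suppressWarnings(face_roc(scores_pred, truth_synth))
    acc_at <- function(roc, thr) {
      i <- which.min(abs(roc$points$threshold1 - thr))
      roc$points$accuracy[i]
    }

    stage <- "report"
    structure(list(
      conditions = conditions, knn = knn, label_overlap = overlap,
      face = list(roc = roc_recon, roc_synthetic = roc_synth,
                  accuracy_default = acc_at(roc_recon, 0.5),
                  accuracy_best = max(roc_recon$points$accuracy),
                  accuracy_synthetic_default = acc_at(roc_synth, 0.5)),
      roi = list(n_selected = length(roi$voxel_ids),
                 n_voxels = length(roi$pvalues_all),
                 true_signal = ds$signal_mask,
                 selected = roi$selected,
                 sensitivity = mean(ds$signal_mask %in% roi$selected),
                 null_rate = mean(setdiff(seq_along(roi$pvalues_all),
                                          ds$signal_mask) %in% roi$selected)),
      reconstructions = list(test = decode(ae, pred_test)),
      latents = list(
        train_seen = list(actual = seen_actual, predicted = seen_pred),
        cv_holdout = list(actual = cv_a, predicted = cv_p),
        test = list(actual = test_a, predicted = test_p)),
      truth_labels = list(
        train_seen = do.call(rbind, lapply(split$train, function(i) {
          frames_tr_grid[[i]]$labels[aligned[[i]]$frame, , drop = FALSE]
        })),
        test = test_frames$labels[test_idx, , drop = FALSE]),
      models = list(autoencoder = ae, map = map_full),
      provenance = list(seed = cfg$seed, seeds = seeds,
                        config_hash = hash,
                        train_clips = split$train, test_clip = split$test,
                        ae_train_clips = split$train,
                        map_train_clips = split$train,
                        cv_folds = folds,
                        n_frames_per_clip = vapply(frames_tr_grid, n_frames,
                                                   integer(1)))),
      class = "eval_report")
  }, error = function(e) {
    stop_bd("experiment failed at stage '%s' (config %s): %s", stage, hash,
            conditionMessage(e))
  })
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(result, file.path(cfg$output_dir, "report.json"))
    write_frames(result$reconstructions$test,
                 file.path(cfg$output_dir, "reconstructions"))
  }
  result
}

# bind 4-d arrays along the 4th margin
abind4 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  nt <- sum(vapply(arrs, function(a) dim(a)[4], numeric(1)))
  out <- array(0, c(d[1:3], nt))
  at <- 0L
  for (a in arrs) {
    out[, , , at + seq_len(dim(a)[4])] <- a
    at <- at + dim(a)[4]
  }
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  ROI: %d/%d voxels (sensitivity %.3f, null rate %.4f)\n",
              x$roi$n_selected, x$roi$n_voxels, x$roi$sensitivity,
              x$roi$null_rate))
  for (nm in names(x$conditions)) {
    apk <- x$conditions[[nm]]$ari_per_k
    k10 <- apk$ari[apk$k == 10]
    cat(sprintf("  ARI (%s): mean %.3f%s\n", nm, mean(apk$ari),
                if (length(k10)) sprintf(", k=10: %.3f", k10) else ""))
  }
  for (i in seq_len(nrow(x$knn))) {
    cat(sprintf("  kNN %s k=%d: %.3f\n", x$knn$condition[i], x$knn$k[i],
                x$knn$accuracy[i]))
  }
  for (i in seq_len(nrow(x$label_overlap))) {
    cat(sprintf("  label overlap %s top-%d: %.3f\n",
                x$label_overlap$condition[i], x$label_overlap$top_k[i],
                x$label_overlap$overlap[i]))
  }
  cat(sprintf("  face accuracy at 0.5: %.3f (best %.3f)\n",
              x$face$accuracy_default, x$face$accuracy_best))
  invisible(x)
}

#' Serialise an evaluation report as JSON
#'
#' Writes every numeric result (ARI curves, k-NN accuracies, label overlap,
#' ROC points, ROI selection summary) and the provenance block; model
#' weights and reconstructed frames are not serialised.
#'
#' @param report an \code{\link{run_experiment}} result.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(
    conditions = lapply(report$conditions, function(cc) cc$ari_per_k),
    knn = report$knn,
    label_overlap = report$label_overlap,
    face = list(roc = report$face$roc$points,
                roc_synthetic = report$face$roc_synthetic$points,
                accuracy_default = report$face$accuracy_default,
                accuracy_best = report$face$accuracy_best),
    roi = report$roi[c("n_selected", "n_voxels", "sensitivity", "null_rate")],
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
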
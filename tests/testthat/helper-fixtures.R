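# Shared fixtures. Expensive fits are memoised so several test files can
# reuse one training run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# A clip with one moving circle (left to right), for centroid/label tests.
circle_clip <- function(duration_s = 2, fps = 4, hw = 32L) {
  sc <- scene_spec(1L, duration_s,
                   objects = list(list(class = "circle", x0 = 0.25, y0 = 0.5,
                                       x1 = 0.75, y1 = 0.5, scale = 0.18)))
  render_clip(sc, fps, hw, hw)
}

# Small glyph clips (16x16) for fast autoencoder training; trajectories
# vary per clip (deterministically) so fits can generalise across paths.
tiny_clips <- function(n = 3L, frames_each = 12L) {
  classes <- glyph_classes()
  lapply(seq_len(n), function(i) {
    sc <- with_seed(700L + i, {
      scl <- runif(1, 0.17, 0.22)
      m <- scl + 0.02
      x0 <- runif(1, m, 0.42); x1 <- runif(1, 0.58, 1 - m)
      if (i %% 2L == 0L) { tmp <- x0; x0 <- x1; x1 <- tmp }
      scene_spec(i, frames_each / 4,
                 objects = list(list(class = classes[(i - 1L) %% 4L + 1L],
                                     x0 = x0, y0 = runif(1, m, 1 - m),
                                     x1 = x1, y1 = runif(1, m, 1 - m),
                                     scale = scl)))
    })
    render_clip(sc, 4, 16L, 16L)
  })
}

tiny_ae_spec <- function(epochs = 3L, seed = 11L) {
  autoencoder_spec(input_hw = c(16L, 16L), channels = c(4L, 6L, 8L, 10L),
                   latent_dim = 8L, decoder_channels = c(6L, 4L),
                   epochs = epochs, seed = seed)
}

# A small trained autoencoder shared across autoencoder/map tests; wider
# than tiny_ae_spec so its reconstructions are actually usable.
small_ae_spec <- function(epochs = 160L, seed = 11L) {
  autoencoder_spec(input_hw = c(16L, 16L), channels = c(8L, 16L, 32L, 64L),
                   latent_dim = 16L, decoder_channels = c(32L, 16L),
                   epochs = epochs, seed = seed)
}

small_trained_ae <- function() {
  memo("small_ae", fit_autoencoder(tiny_clips(6L, 16L), small_ae_spec()))
}

# A tiny but complete experiment configuration (seconds, not minutes).
tiny_experiment_config <- function(seed = 5L, ...) {
  experiment_config(
    n_clips = 3L,
    bold_cfg = bold_config(n_voxels = 120L, n_signal_voxels = 30L),
    scene_params = list(height = 16L, width = 16L, frame_rate_hz = 4,
                        duration_s = 16),
    latent_dim = 8L, ae_channels = c(4L, 6L, 8L, 10L), ae_epochs = 2L,
    map_hidden = 16L, map_epochs = 10L, k_values = 3:4, knn_ks = 1L,
    label_top_ks = 1L, alpha = 1e-4, seed = seed, ...)
}

tiny_report <- function() {
  memo("tiny_report", run_experiment(tiny_experiment_config()))
}

# Single-glyph noiseless recovery experiment: one object per clip (so the
# dominant class is unambiguous), lag-compensated, autoencoder trained long
# enough that reconstructions carry the glyph colour.
recovery_config <- function(seed = 202L) {
  experiment_config(
    n_clips = 4L,
    bold_cfg = bold_config(noise_sd = 0, global_signal_sd = 0,
                           n_voxels = 300L, n_signal_voxels = 80L),
    scene_params = list(height = 16L, width = 16L, frame_rate_hz = 4,
                        duration_s = 24, objects_per_clip = 1L),
    latent_dim = 16L, ae_epochs = 150L, map_hidden = 64L, map_epochs = 500L,
    lag_tr = 8L, gsr = FALSE, cv = FALSE, seed = seed)
}

recovery_report <- function() {
  memo("recovery_report", run_experiment(recovery_config()))
}

# Enumerate all set partitions of n items into at most `max_blocks` blocks
# as restricted-growth strings.
all_partitions <- function(n, max_blocks = 3L) {
  out <- list()
  rec <- function(prefix, used) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(min(used + 1L, max_blocks))) {
      rec(c(prefix, b), max(used, b))
    }
  }
  rec(integer(0), 0L)
  out
}

# Independent pair-counting ARI oracle: classify every item pair as
# together/apart in each partition and apply the 2x2 agreement form.
ari_pair_counting <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (den == 0) return(1)
  2 * (n00 * n11 - n01 * n10) / den
}
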
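smooth_series <- function(n, d, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  apply(x, 2, function(col) as.numeric(stats::filter(col, rep(1 / 5, 5),
                                                     sides = 1, circular = TRUE)))
}

test_that("the map learns a linear function of noiseless input to high accuracy", {
  x <- smooth_series(80, 10, seed = 1)
  B <- with_seed(2, matrix(rnorm(10 * 4), 10, 4))
  y <- x %*% B
  y <- y / sd(as.vector(y))
  sp <- map_spec(10L, 4L, hidden_dim = 32L, dropout = 0, epochs = 1000L,
                 seed = 2L)
  m <- fit_latent_map(list(x), list(y), sp)
  pred <- predict_latents(m, x)$vectors
  expect_lt(mean((pred - y)^2), 0.01 * var(as.vector(y)))
  expect_lte(tail(m$loss_history, 1), m$loss_history[1])
})

test_that("prediction is deterministic and shape-correct", {
  x <- smooth_series(30, 6, seed = 3)
  y <- smooth_series(30, 5, seed = 4)
  m <- fit_latent_map(list(x), list(y),
                      map_spec(6L, 5L, hidden_dim = 12L, epochs = 20L,
                               seed = 5L))
  p1 <- predict_latents(m, x)
  p2 <- predict_latents(m, x)
  expect_identical(p1$vectors, p2$vectors)
  expect_equal(dim(p1$vectors), c(30L, 5L))
  expect_equal(p1$source, "fmri_map")
  expect_error(predict_latents(m, x[, 1:4]), "expects")
})

test_that("training is reproducible from the seed, with dropout active", {
  x <- smooth_series(40, 6, seed = 6)
  y <- smooth_series(40, 3, seed = 7)
  sp <- map_spec(6L, 3L, hidden_dim = 12L, dropout = 0.1, epochs = 15L,
                 seed = 8L)
  m1 <- fit_latent_map(list(x), list(y), sp)
  m2 <- fit_latent_map(list(x), list(y), sp)
  expect_identical(m1$params, m2$params)
})

test_that("zero-variance input yields a constant output after state convergence", {
  x <- smooth_series(40, 6, seed = 9)
  y <- smooth_series(40, 3, seed = 10)
  m <- fit_latent_map(list(x), list(y),
                      map_spec(6L, 3L, hidden_dim = 12L, epochs = 30L,
                               seed = 11L))
  const <- matrix(0.3, 60, 6)
  out <- predict_latents(m, const)$vectors
  step_norm <- sqrt(rowSums(diff(out)^2))
  expect_lt(tail(step_norm, 1), 1e-8)
  expect_lt(tail(step_norm, 1), head(step_norm, 1) + 1e-12)
})

test_that("per-clip length and width mismatches are reported with the clip id", {
  x <- list(smooth_series(20, 6, 1), smooth_series(25, 6, 2))
  y <- list(smooth_series(20, 3, 3), smooth_series(24, 3, 4))
  sp <- map_spec(6L, 3L, hidden_dim = 8L, epochs = 2L)
  expect_error(fit_latent_map(x, y, sp), "clip 2")
  y2 <- list(smooth_series(20, 4, 3), smooth_series(25, 4, 4))
  expect_error(fit_latent_map(x, y2, sp), "latent dim")
})

test_that("memoryless architecture trains and predicts with matching shapes", {
  x <- smooth_series(40, 8, seed = 12)
  y <- smooth_series(40, 4, seed = 13)
  m <- fit_latent_map(list(x), list(y),
                      map_spec(8L, 4L, hidden_dim = 16L, epochs = 50L,
                               architecture = "memoryless", seed = 14L))
  expect_equal(dim(predict_latents(m, x)$vectors), c(40L, 4L))
  expect_lte(tail(m$loss_history, 1), m$loss_history[1])
})

test_that("fMRI-frame alignment follows the lag convention and skips rest", {
  # lag 0, equal lengths: identity pairing
  p0 <- align_fmri_to_frames(matrix(0, 10, 2), 10L, lag_tr = 0L)
  expect_equal(p0$fmri_row, 1:10)
  expect_equal(p0$frame, 1:10)

  # lag 2: fMRI timepoints 3..10 pair with frames 1..8
  p2 <- align_fmri_to_frames(matrix(0, 10, 2), 10L, lag_tr = 2L)
  expect_equal(nrow(p2), 8L)
  expect_equal(p2$fmri_row, 3:10)
  expect_equal(p2$frame, 1:8)

  # rest timepoints are never paired
  x <- voxel_timeseries(matrix(0, 12, 2),
                        c(rep("movie", 8), rep("rest", 4)), 0.72)
  pr <- align_fmri_to_frames(x, 8L)
  expect_true(all(pr$fmri_row <= 8))

  expect_error(align_fmri_to_frames(matrix(0, 5, 2), 5L, lag_tr = 10L),
               "empty intersection")
})

test_that("stimulus recovery beats chance by an order of magnitude on noisy data", {
  # moderate-noise synthetic fixture: inputs mix the target through the HRF
  ds <- make_dataset(2L, bold_config(n_voxels = 120L, n_signal_voxels = 40L),
                     list(height = 16L, width = 16L, frame_rate_hz = 4,
                          duration_s = 25), seed = 42L)
  roi <- select_roi(global_signal_regression(concat_fmri(ds)))
  rows <- which(!is.na(roi$clip) & roi$clip == 1L)
  y <- ds$clips[[1]]$truth$latent_tr[, -1]
  n <- min(length(rows), nrow(y))
  m <- fit_latent_map(list(roi$values[rows[1:n], ]), list(y[1:n, ]),
                      map_spec(ncol(roi$values), ncol(y), hidden_dim = 64L,
                               epochs = 600L, seed = 43L))
  pred <- predict_latents(m, roi$values[rows[1:n], ])
  acc <- knn_match(y[1:n, ], pred, k = 1L)
  expect_gt(acc, 10 / n)
})
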
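test_that("an empty scene renders constant background frames labelled 'none'", {
  fs <- render_clip(scene_spec(2L, 2, objects = list()), 4, 32, 32)
  expect_equal(n_frames(fs), 8L)
  for (t in 2:8) expect_identical(fs$frames[, , , t], fs$frames[, , , 1])
  expect_true(all(fs$labels$class == "none"))
  expect_true(all(fs$latent == 0))
})

test_that("a circle moving left to right has strictly increasing rendered centroid", {
  fs <- circle_clip()
  expect_equal(n_frames(fs), 8L)
  cols <- matrix(seq_len(32), 32, 32, byrow = TRUE)
  centroid <- vapply(seq_len(8), function(t) {
    m <- pmax(fs$frames[, , 1, t] - scene_background(1L), 0) # red excess
    sum(cols * m) / sum(m)
  }, numeric(1))
  expect_true(all(diff(centroid) > 0))
  expect_true(all(fs$labels$class == "circle"))
})

test_that("face scenes are labelled face on every frame", {
  sc <- scene_spec(3L, 1, objects = list(list(class = "face", x0 = 0.5,
                                              y0 = 0.5, x1 = 0.5, y1 = 0.5,
                                              scale = 0.25)))
  fs <- render_clip(sc, 4, 32, 32)
  expect_true(all(fs$labels$face))
  expect_true(all(fs$latent[, "face"] == 1))
})

test_that("trajectories leaving the frame are rejected at construction", {
  expect_error(
    scene_spec(1L, 2, objects = list(list(class = "square", x0 = 0.05,
                                          y0 = 0.5, x1 = 0.9, y1 = 0.5,
                                          scale = 0.2))),
    "leaves the frame")
})

test_that("noiseless BOLD: nulls are exactly zero, signal voxels match the forward model", {
  fs <- circle_clip(duration_s = 8)
  cfg <- bold_config(noise_sd = 0, global_signal_sd = 0, n_voxels = 50L,
                     n_signal_voxels = 10L, seed = 21L)
  sim <- simulate_bold(fs$latent, cfg, 4)
  nulls <- setdiff(seq_len(50L), sim$truth$signal_idx)
  expect_true(all(sim$fmri$values[, nulls] == 0))

  # independent forward computation: direct convolution sum at the TR grid
  aug <- rbind(sim$truth$latent_tr,
               matrix(0, sum(sim$truth$condition == "rest"),
                      ncol(sim$truth$latent_tr)))
  h <- hrf_double_gamma(seq(0, 32, by = cfg$tr_s))
  conv_direct <- apply(aug, 2, function(x) {
    n <- length(x)
    vapply(seq_len(n), function(t) {
      tau <- seq_len(min(t, length(h)))
      sum(x[t - tau + 1] * h[tau])
    }, numeric(1))
  })
  expected <- conv_direct %*% t(sim$truth$mixing)
  got <- sim$fmri$values[, sim$truth$signal_idx]
  expect_equal(got, expected, ignore_attr = TRUE, tolerance = 1e-10)
  for (j in seq_len(ncol(got))) {
    expect_equal(cor(got[, j], expected[, j]), 1, tolerance = 1e-12)
  }
})

test_that("an impulse stimulus produces a scaled double-gamma response peaking near 6 s", {
  lat <- matrix(0, 80, 3)
  lat[1, 1] <- 1
  cfg <- bold_config(noise_sd = 0, global_signal_sd = 0, n_voxels = 20L,
                     n_signal_voxels = 5L, seed = 3L)
  sim <- simulate_bold(lat, cfg, 4)
  tt <- (seq_len(nrow(sim$fmri$values)) - 1L) * cfg$tr_s
  # reference kernel evaluated straight from the gamma densities
  ref <- dgamma(tt, shape = 7, rate = 1) - dgamma(tt, shape = 17, rate = 1) / 6
  for (v in sim$truth$signal_idx) {
    y <- sim$fmri$values[, v]
    expect_equal(abs(cor(y, ref)), 1, tolerance = 1e-6)
    expect_lt(abs(tt[which.max(abs(y))] - 6), cfg$tr_s)
  }
})

test_that("simulation is reproducible and rejects empty stimuli", {
  fs <- circle_clip()
  cfg <- bold_config(n_voxels = 40L, n_signal_voxels = 8L, seed = 9L)
  s1 <- simulate_bold(fs$latent, cfg, 4)
  s2 <- simulate_bold(fs$latent, cfg, 4)
  expect_identical(s1$fmri$values, s2$fmri$values)
  expect_error(simulate_bold(matrix(0, 0, 3), cfg, 4), "empty stimulus")
})

test_that("dataset manifest counts clips and rest segments correctly", {
  cfg <- bold_config(n_voxels = 40L, n_signal_voxels = 8L)
  sp <- list(height = 16L, width = 16L, frame_rate_hz = 4, duration_s = 6)
  ds <- make_dataset(16L, cfg, sp, seed = 2L)
  expect_equal(sum(ds$manifest$type == "movie"), 16L)
  expect_equal(sum(ds$manifest$type == "rest"), 17L)
  n_movie_tr <- sum(ds$manifest$n_tr[ds$manifest$type == "movie"])
  expect_equal(n_movie_tr, 16L * ceiling(6 / cfg$tr_s))
  n_rest_tr <- sum(ds$manifest$n_tr[ds$manifest$type == "rest"])
  expect_equal(n_rest_tr, 17L * ceiling(cfg$rest_block_s / cfg$tr_s))
  vox <- concat_fmri(ds)
  expect_equal(nrow(vox$values), n_movie_tr + n_rest_tr)
})

test_that("dataset generation is deterministic in the master seed", {
  cfg <- bold_config(n_voxels = 30L, n_signal_voxels = 6L)
  sp <- list(height = 16L, width = 16L, frame_rate_hz = 4, duration_s = 5)
  d1 <- make_dataset(2L, cfg, sp, seed = 77L)
  d2 <- make_dataset(2L, cfg, sp, seed = 77L)
  expect_identical(concat_fmri(d1)$values, concat_fmri(d2)$values)
  expect_identical(d1$clips[[1]]$frames$frames, d2$clips[[1]]$frames$frames)
  d3 <- make_dataset(2L, cfg, sp, seed = 78L)
  expect_false(identical(concat_fmri(d1)$values, concat_fmri(d3)$values))
})

test_that("null voxels are exchangeable between movie and rest", {
  # with uncorrelated noise the two-sample test should reject at ~alpha
  cfg <- bold_config(n_voxels = 30L, n_signal_voxels = 5L, noise_ar1 = 0,
                     global_signal_sd = 0)
  fs <- circle_clip(duration_s = 20)
  pvals <- unlist(lapply(1:12, function(s) {
    cfg$seed <- s
    sim <- simulate_bold(fs$latent, cfg, 4)
    nulls <- setdiff(seq_len(30L), sim$truth$signal_idx)[1:5]
    vapply(nulls, function(v) {
      t.test(sim$fmri$values[sim$fmri$condition == "movie", v],
             sim$fmri$values[sim$fmri$condition == "rest", v])$p.value
    }, numeric(1))
  }))
  rate <- mean(pvals < 0.1)
  expect_gt(rate, 0.0)
  expect_lt(rate, 0.3)
})
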
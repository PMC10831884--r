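test_that("spec validation enforces architecture invariants", {
  expect_error(autoencoder_spec(input_hw = c(30, 30)), "16")
  expect_error(autoencoder_spec(channels = c(16, 8, 32, 64)))
  expect_error(autoencoder_spec(latent_dim = 0))
})

test_that("encode/decode shape contracts hold at desk scale", {
  clips <- tiny_clips(1L, 6L)
  ae <- fit_autoencoder(clips, tiny_ae_spec(epochs = 1L))
  lat <- encode(ae, clips[[1]])
  expect_s3_class(lat, "latent_sequence")
  expect_equal(dim(lat$vectors), c(6L, 8L))
  expect_equal(lat$source, "encoder")

  rec <- decode(ae, lat)
  expect_equal(dim(rec$frames), c(16L, 16L, 3L, 6L))
  expect_true(all(rec$frames >= 0 & rec$frames <= 1))

  # round trip shape contract for any valid input length
  short <- subset_frames(clips[[1]], 1:2)
  expect_equal(dim(decode(ae, encode(ae, short))$frames), c(16, 16, 3, 2))
})

test_that("mismatched input shapes raise informative errors", {
  ae <- fit_autoencoder(tiny_clips(1L, 4L), tiny_ae_spec(epochs = 1L))
  wrong <- frame_sequence(array(0.5, c(32, 32, 3, 2)), 0:1)
  expect_error(encode(ae, wrong), "16x16")
  expect_error(decode(ae, matrix(0, 2, 5)), "latent dimension")
})

test_that("a zero latent vector decodes to a fixed deterministic frame", {
  ae <- small_trained_ae()
  z <- matrix(0, 3, ae$spec$latent_dim)
  r1 <- decode(ae, z)
  r2 <- decode(ae, z)
  expect_identical(r1$frames, r2$frames)
  for (t in 2:3) expect_identical(r1$frames[, , , t], r1$frames[, , , 1])
})

test_that("recurrent state is reset at clip boundaries", {
  ae <- small_trained_ae()
  clips <- tiny_clips(2L, 10L)
  separate <- lapply(clips, function(cl) encode(ae, cl)$vectors)
  batched <- encode(ae, clips)
  expect_identical(batched[[1]]$vectors, separate[[1]])
  expect_identical(batched[[2]]$vectors, separate[[2]])
})

test_that("training memorises a constant-frame dataset to near-zero loss", {
  const <- frame_sequence(array(0.6, c(16, 16, 3, 4)), (0:3) / 4)
  sp <- autoencoder_spec(input_hw = c(16, 16), channels = c(4, 6, 8, 10),
                         latent_dim = 8, decoder_channels = c(6, 4),
                         epochs = 200L, seed = 1L)
  ae <- fit_autoencoder(const, sp)
  expect_lt(tail(ae$loss_history, 1), 1e-3)
})

test_that("training reduces the loss and is reproducible from the seed", {
  clips <- tiny_clips(2L, 8L)
  a1 <- fit_autoencoder(clips, tiny_ae_spec(epochs = 5L, seed = 33L))
  a2 <- fit_autoencoder(clips, tiny_ae_spec(epochs = 5L, seed = 33L))
  expect_identical(a1$loss_history, a2$loss_history)
  expect_identical(a1$params, a2$params)
  expect_lte(tail(a1$loss_history, 1), a1$loss_history[1])
})

test_that("latent dimensionality is honoured for any sequence length", {
  ae <- small_trained_ae()
  for (len in c(1L, 3L, 7L)) {
    cl <- subset_frames(tiny_clips(1L, 8L)[[1]], seq_len(len))
    expect_equal(dim(encode(ae, cl)$vectors), c(len, ae$spec$latent_dim))
  }
})

test_that("a trained model beats the constant mean-frame baseline on held-out data", {
  ae <- small_trained_ae() # trained on six varied-trajectory clips
  # held-out clip: a seen class moving along an unseen (reversed, off-centre)
  # trajectory — the within-distribution generalisation the protocol tests
  held <- render_clip(
    scene_spec(9L, 4, objects = list(list(class = "square", x0 = 0.72,
                                          y0 = 0.35, x1 = 0.28, y1 = 0.62,
                                          scale = 0.21))),
    4, 16L, 16L)
  rec <- predict(ae, held, type = "reconstruction")
  mse_model <- mean((rec$frames - held$frames)^2)
  train <- tiny_clips(6L, 16L)
  mean_frame <- Reduce(`+`, lapply(train, function(cl) {
    apply(cl$frames, 1:3, mean)
  })) / length(train)
  mse_baseline <- mean(sweep(held$frames, 1:3, mean_frame)^2)
  expect_lt(mse_model, mse_baseline)
})
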
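#' Specification of the recurrent convolutional autoencoder
#'
#' The encoder is four stages of 3x3 same-padding convolution + ReLU +
#' batch-norm + 2x2 max-pool (channel counts strictly increasing, spatial
#' size divided by 16 overall), followed by flattening and a stateful
#' tanh GRU whose per-timestep output is the frame's latent vector; state is
#' reset at clip boundaries. The decoder maps the latent vector through a
#' dense layer onto a small spatial grid and restores the input size with
#' two (4,4) upsampling + convolution stages and a logistic output bounding
#' pixels to [0, 1].
#'
#' @param input_hw integer (height, width); both divisible by 16.
#' @param channels conv channel counts per encoder stage (strictly
#'   increasing, length 4).
#' @param latent_dim latent dimensionality (1024 for 224x224 inputs; scale
#'   down together with the frame size for desk-scale work).
#' @param decoder_channels channel counts of the two decoder conv stages.
#' @param learning_rate,beta1,beta2,epsilon Adam parameters.
#' @param epochs training epochs; each batch is one clip's frame sequence.
#' @param seed integer seed for weight initialisation.
#' @return an object of class \code{"autoencoder_spec"}.
#' @export
autoencoder_spec <- function(input_hw = c(224L, 224L),
                             channels = c(16L, 32L, 64L, 128L),
                             latent_dim = 1024L,
                             decoder_channels = c(32L, 16L),
                             learning_rate = 0.001, beta1 = 0.99,
                             beta2 = 0.999, epsilon = 1e-7,
                             epochs = 100L, seed = 1L) {
  stopifnot(length(input_hw) == 2L, all(input_hw %% 16L == 0L),
            length(channels) == 4L, all(diff(channels) > 0),
            latent_dim > 0, length(decoder_channels) == 2L, epochs >= 1)
  structure(list(input_hw = as.integer(input_hw),
                 channels = as.integer(channels),
                 latent_dim = as.integer(latent_dim),
                 decoder_channels = as.integer(decoder_channels),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "autoencoder_spec")
}

ae_init_params <- function(spec) {
  ch <- c(3L, spec$channels)
  p <- list()
  for (s in 1:4) {
    p[[paste0("enc_conv", s, "_W")]] <-
      array(rnorm(9 * ch[s] * ch[s + 1], sd = sqrt(2 / (9 * ch[s]))),
            c(3L, 3L, ch[s], ch[s + 1]))
    p[[paste0("enc_conv", s, "_b")]] <- numeric(ch[s + 1])
    p[[paste0("enc_bn", s, "_gamma")]] <- rep(1, ch[s + 1])
    p[[paste0("enc_bn", s, "_beta")]] <- numeric(ch[s + 1])
  }
  h16 <- spec$input_hw[1] %/% 16L
  w16 <- spec$input_hw[2] %/% 16L
  D <- h16 * w16 * spec$channels[4]
  g <- gru_init(D, spec$latent_dim)
  p$gru_Wx <- g$Wx; p$gru_Wh <- g$Wh; p$gru_b <- g$b
  d0 <- h16 * w16 * spec$decoder_channels[1]
  k <- sqrt(6 / (spec$latent_dim + d0))
  p$dec_dense_W <- matrix(runif(spec$latent_dim * d0, -k, k),
                          spec$latent_dim, d0)
  p$dec_dense_b <- numeric(d0)
  cd <- spec$decoder_channels
  p$dec_conv1_W <- array(rnorm(9 * cd[1] * cd[2], sd = sqrt(2 / (9 * cd[1]))),
                         c(3L, 3L, cd[1], cd[2]))
  p$dec_conv1_b <- numeric(cd[2])
  p$dec_conv2_W <- array(rnorm(9 * cd[2] * 3, sd = sqrt(2 / (9 * cd[2]))),
                         c(3L, 3L, cd[2], 3L))
  p$dec_conv2_b <- numeric(3L)
  p
}

ae_init_running <- function(spec) {
  lapply(1:4, function(s) list(mean = numeric(spec$channels[s]),
                               var = rep(1, spec$channels[s])))
}

# Encoder forward: X (H,W,3,T) -> list(latent (T,L), caches, running).
ae_encode_forward <- function(params, running, spec, X, train) {
  caches <- vector("list", 4L)
  A <- X
  for (s in 1:4) {
    cv <- conv_forward(A, params[[paste0("enc_conv", s, "_W")]],
                       params[[paste0("enc_conv", s, "_b")]])
    mask <- cv$out > 0
    Rl <- cv$out * mask
    bn <- bn_forward(Rl, params[[paste0("enc_bn", s, "_gamma")]],
                     params[[paste0("enc_bn", s, "_beta")]],
                     running[[s]], train)
    running[[s]] <- bn$running
    pl <- pool_forward(bn$out)
    caches[[s]] <- list(conv = cv$cache, mask = mask, bn = bn$cache,
                        pool = pl$cache)
    A <- pl$out
  }
  dA <- dim(A)
  Fmat <- t(matrix(A, prod(dA[1:3]), dA[4]))
  gr <- gru_forward(Fmat, params$gru_Wx, params$gru_Wh, params$gru_b)
  list(latent = gr$out, stages = caches, gru = gr$cache, feat_dim = dA,
       running = running)
}

# Decoder forward: latent (T,L) -> list(out (H,W,3,T), caches).
ae_decode_forward <- function(params, spec, latent) {
  T <- nrow(latent)
  h16 <- spec$input_hw[1] %/% 16L
  w16 <- spec$input_hw[2] %/% 16L
  cd <- spec$decoder_channels
  dn <- dense_forward(latent, params$dec_dense_W, params$dec_dense_b)
  dmask <- dn > 0
  dnr <- dn * dmask
  A <- array(t(dnr), c(h16, w16, cd[1], T))
  U1 <- upsample_forward(A, 4L)
  c1 <- conv_forward(U1, params$dec_conv1_W, params$dec_conv1_b)
  m1 <- c1$out > 0
  A1 <- c1$out * m1
  U2 <- upsample_forward(A1, 4L)
  c2 <- conv_forward(U2, params$dec_conv2_W, params$dec_conv2_b)
  Y <- sigmoid(c2$out)
  list(out = Y, cache = list(latent = latent, dmask = dmask, c1 = c1$cache,
                             m1 = m1, c2 = c2$cache, Y = Y, T = T,
                             grid = c(h16, w16, cd[1])))
}

# Full backward pass; dY is the loss gradient wrt the reconstruction.
ae_backward <- function(params, spec, enc, dec, dY) {
  g <- list()
  dpre2 <- dY * dec$cache$Y * (1 - dec$cache$Y)
  cb2 <- conv_backward(dpre2, dec$cache$c2)
  g$dec_conv2_W <- cb2$dW; g$dec_conv2_b <- cb2$db
  dU2 <- upsample_backward(cb2$dX, 4L)
  dU2 <- dU2 * dec$cache$m1
  cb1 <- conv_backward(dU2, dec$cache$c1)
  g$dec_conv1_W <- cb1$dW; g$dec_conv1_b <- cb1$db
  dA <- upsample_backward(cb1$dX, 4L)
  dDn <- t(matrix(dA, prod(dec$cache$grid), dec$cache$T)) * dec$cache$dmask
  db <- dense_backward(dDn, dec$cache$latent, params$dec_dense_W)
  g$dec_dense_W <- db$dW; g$dec_dense_b <- db$db
  dLatent <- db$dX

  gb <- gru_backward(dLatent, enc$gru)
  g$gru_Wx <- gb$dWx; g$gru_Wh <- gb$dWh; g$gru_b <- gb$db
  dA <- array(t(gb$dX), enc$feat_dim)
  for (s in 4:1) {
    st <- enc$stages[[s]]
    dA <- pool_backward(dA, st$pool)
    bb <- bn_backward(dA, st$bn)
    g[[paste0("enc_bn", s, "_gamma")]] <- bb$dgamma
    g[[paste0("enc_bn", s, "_beta")]] <- bb$dbeta
    dA <- bb$dX * st$mask
    cb <- conv_backward(dA, st$conv)
    g[[paste0("enc_conv", s, "_W")]] <- cb$dW
    g[[paste0("enc_conv", s, "_b")]] <- cb$db
    dA <- cb$dX
  }
  g
}

#' Initialise an untrained autoencoder
#'
#' Builds a \code{"video_autoencoder"} with freshly initialised weights and
#' batch-norm statistics but no training — useful for shape/architecture
#' checks and as the starting point \code{\link{fit_autoencoder}} optimises
#' from.
#'
#' @param spec an \code{\link{autoencoder_spec}}.
#' @return an object of class \code{"video_autoencoder"}.
#' @export
autoencoder_init <- function(spec) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  with_seed(spec$seed, {
    structure(list(params = ae_init_params(spec),
                   running = ae_init_running(spec), spec = spec,
                   loss_history = numeric(0), n_train_clips = 0L),
              class = "video_autoencoder")
  })
}

#' Fit the recurrent convolutional autoencoder
#'
#' Trains encoder and decoder jointly to minimise the mean squared
#' reconstruction error over all training frames with Adam (defaults:
#' learning rate 0.001, beta1 = 0.99, beta2 = 0.999, epsilon = 1e-7). Each
#' optimisation batch is one clip's full frame sequence; the GRU state is
#' implicitly reset at every clip boundary. After fitting, the weights are
#' considered frozen: the fMRI-latent map is trained against the encoder's
#' outputs without ever adjusting them.
#'
#' @param clips list of \code{\link{frame_sequence}} objects (already at the
#'   acquisition frame rate and the spec's spatial size).
#' @param spec an \code{\link{autoencoder_spec}}.
#' @return an object of class \code{"video_autoencoder"} with elements
#'   \code{params}, \code{running} (batch-norm statistics), \code{spec} and
#'   \code{loss_history} (per-epoch mean MSE).
#' @export
fit_autoencoder <- function(clips, spec) {
  if (inherits(clips, "frame_sequence")) clips <- list(clips)
  stopifnot(length(clips) >= 1L, inherits(spec, "autoencoder_spec"))
  for (cl in clips) {
    d <- dim(cl$frames)
    if (!all(d[1:2] == spec$input_hw)) {
      stop_bd("clip %d frames are %dx%d but spec expects %dx%d",
              cl$clip_id, d[1], d[2], spec$input_hw[1], spec$input_hw[2])
    }
  }
  with_seed(spec$seed, {
    params <- ae_init_params(spec)
    running <- ae_init_running(spec)
    opt <- adam_init(params)
    loss_history <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      losses <- numeric(length(clips))
      for (ci in seq_along(clips)) {
        X <- clips[[ci]]$frames
        enc <- ae_encode_forward(params, running, spec, X, train = TRUE)
        running <- enc$running
        dec <- ae_decode_forward(params, spec, enc$latent)
        err <- dec$out - X
        losses[ci] <- mean(err^2)
        if (!is.finite(losses[ci])) {
          stop_bd("non-finite loss at epoch %d, clip %d", ep, ci)
        }
        dY <- 2 * err / length(err)
        grads <- ae_backward(params, spec, enc, dec, dY)
        upd <- adam_step(params, grads, opt, spec$learning_rate,
                         spec$beta1, spec$beta2, spec$epsilon)
        params <- upd$params
        opt <- upd$state
      }
      loss_history[ep] <- mean(losses)
    }
    structure(list(params = params, running = running, spec = spec,
                   loss_history = loss_history,
                   n_train_clips = length(clips)),
              class = "video_autoencoder")
  })
}

#' Per-timepoint latent vectors
#'
#' Bundles a timepoint-by-latent matrix with its provenance: which clip the
#' vectors describe, the frame indices they align to, and whether they came
#' from the video encoder or the fMRI map.
#'
#' @param vectors numeric matrix, timepoints x latent dimension.
#' @param clip_id integer clip identifier.
#' @param frame_indices frame index per row.
#' @param source \code{"encoder"} or \code{"fmri_map"}.
#' @return an object of class \code{"latent_sequence"}.
#' @export
latent_sequence <- function(vectors, clip_id = 1L,
                            frame_indices = seq_len(nrow(vectors)),
                            source = c("encoder", "fmri_map")) {
  vectors <- as.matrix(vectors)
  source <- match.arg(source)
  if (!all(is.finite(vectors))) stop_bd("non-finite latent values")
  stopifnot(length(frame_indices) == nrow(vectors))
  structure(list(vectors = vectors, clip_id = as.integer(clip_id),
                 frame_indices = frame_indices, source = source),
            class = "latent_sequence")
}

#' @export
print.latent_sequence <- function(x, ...) {
  cat(sprintf("<latent_sequence> clip %d: %d x %d (%s)\n", x$clip_id,
              nrow(x$vectors), ncol(x$vectors), x$source))
  invisible(x)
}

latent_matrix <- function(x) {
  if (inherits(x, "latent_sequence")) x$vectors else as.matrix(x)
}

#' Encode video frames into the latent space
#'
#' Runs the frozen encoder in inference mode (batch-norm uses its running
#' statistics; GRU state starts at zero for each clip, so encoding clips
#' separately or back to back with resets gives identical results).
#'
#' @param model a fitted \code{\link{fit_autoencoder}} object.
#' @param seq a \code{\link{frame_sequence}} (or list of them).
#' @return a \code{\link{latent_sequence}} (or list of them).
#' @export
encode <- function(model, seq) {
  stopifnot(inherits(model, "video_autoencoder"))
  if (is.list(seq) && !inherits(seq, "frame_sequence")) {
    return(lapply(seq, encode, model = model))
  }
  d <- dim(seq$frames)
  if (!all(d[1:2] == model$spec$input_hw)) {
    stop_bd("frames are %dx%d but the model expects %dx%d",
            d[1], d[2], model$spec$input_hw[1], model$spec$input_hw[2])
  }
  enc <- ae_encode_forward(model$params, model$running, model$spec,
                           seq$frames, train = FALSE)
  latent_sequence(enc$latent, seq$clip_id, seq_len(d[4]), "encoder")
}

#' Decode latent vectors into video frames
#'
#' @param model a fitted \code{\link{fit_autoencoder}} object.
#' @param lat a \code{\link{latent_sequence}} or timepoint-by-latent matrix.
#' @param timestamps_s optional per-frame timestamps for the output.
#' @return a \code{\link{frame_sequence}} of reconstructed frames.
#' @export
decode <- function(model, lat, timestamps_s = NULL) {
  stopifnot(inherits(model, "video_autoencoder"))
  vec <- latent_matrix(lat)
  if (ncol(vec) != model$spec$latent_dim) {
    stop_bd("latent dimension %d does not match the model's %d",
            ncol(vec), model$spec$latent_dim)
  }
  dec <- ae_decode_forward(model$params, model$spec, vec)
  if (is.null(timestamps_s)) timestamps_s <- seq_len(nrow(vec)) - 1
  clip_id <- if (inherits(lat, "latent_sequence")) lat$clip_id else 1L
  frame_sequence(dec$out, timestamps_s, clip_id)
}

#' @export
print.video_autoencoder <- function(x, ...) {
  sp <- x$spec
  cat(sprintf("<video_autoencoder> %dx%dx3 -> %d-d latent\n",
              sp$input_hw[1], sp$input_hw[2], sp$latent_dim))
  cat(sprintf("  encoder channels: %s; decoder: %s\n",
              paste(sp$channels, collapse = ","),
              paste(sp$decoder_channels, collapse = ",")))
  cat(sprintf("  trained %d epochs on %d clip(s); final MSE %.5g\n",
              sp$epochs, x$n_train_clips, tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
predict.video_autoencoder <- function(object, newdata,
                                      type = c("latent", "reconstruction"),
                                      ...) {
  type <- match.arg(type)
  lat <- encode(object, newdata)
  if (type == "latent") lat else decode(object, lat, newdata$timestamps_s)
}

#' @export
residuals.video_autoencoder <- function(object, clips, ...) {
  if (inherits(clips, "frame_sequence")) clips <- list(clips)
  lapply(clips, function(cl) {
    rec <- predict(object, cl, type = "reconstruction")
    apply((rec$frames - cl$frames)^2, 4, mean)
  })
}

#' @export
plot.video_autoencoder <- function(x, ...) {
  plot(seq_along(x$loss_history), x$loss_history, type = "l",
       xlab = "epoch", ylab = "reconstruction MSE",
       main = "Autoencoder training loss", ...)
  invisible(x)
}
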
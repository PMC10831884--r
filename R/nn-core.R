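# Minimal neural-network primitives used by the autoencoder and the
# fMRI-latent map: 3x3 same-padding convolution (im2col), 2x2 max-pooling,
# batch normalisation, nearest-neighbour upsampling, dense layers, a GRU
# with full backpropagation through time, and Adam. Arrays are laid out
# (H, W, C, T); feature matrices are (T, D). Everything is deterministic
# given the RNG state.

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- convolution ----------------------------------------------------------

# X (H,W,Cin,T), W (3,3,Cin,Cout), b length Cout -> list(out (H,W,Cout,T), cache)
conv_forward <- function(X, W, b) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; Cin <- d[3]; T <- d[4]
  Cout <- dim(W)[4]
  Xp <- array(0, c(H + 2L, Wd + 2L, Cin, T))
  Xp[2:(H + 1), 2:(Wd + 1), , ] <- X
  n <- H * Wd * T
  cols <- matrix(0, n, 9L * Cin)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    blk <- Xp[dy + seq_len(H), dx + seq_len(Wd), , , drop = FALSE]
    blk <- aperm(blk, c(1, 2, 4, 3))
    dim(blk) <- c(n, Cin)
    cols[, k + seq_len(Cin)] <- blk
    k <- k + Cin
  }
  Wmat <- matrix(aperm(W, c(3, 1, 2, 4)), 9L * Cin, Cout)
  out <- cols %*% Wmat
  out <- out + rep(b, each = n)
  out <- array(out, c(H, Wd, T, Cout))
  list(out = aperm(out, c(1, 2, 4, 3)),
       cache = list(cols = cols, Wmat = Wmat, dims = d, Cout = Cout))
}

conv_backward <- function(dY, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; Cin <- d[3]; T <- d[4]
  Cout <- cache$Cout
  n <- H * Wd * T
  dYmat <- matrix(aperm(dY, c(1, 2, 4, 3)), n, Cout)
  dWmat <- crossprod(cache$cols, dYmat)
  dW <- aperm(array(dWmat, c(Cin, 3L, 3L, Cout)), c(2, 3, 1, 4))
  db <- colSums(dYmat)
  # input gradient of a same-padded 3x3 conv = conv of dY with the
  # spatially rotated, channel-transposed kernel (gather instead of scatter)
  Wfwd <- aperm(array(cache$Wmat, c(Cin, 3L, 3L, Cout)), c(2, 3, 1, 4))
  Wrot <- aperm(Wfwd[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))
  dX <- conv_forward(dY, Wrot, numeric(Cin))$out
  list(dX = dX, dW = dW, db = db)
}

## ---- max pooling (2x2, stride 2) ------------------------------------------

pool_forward <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]
  oi <- seq(1L, H, 2L); ei <- seq(2L, H, 2L)
  oj <- seq(1L, W, 2L); ej <- seq(2L, W, 2L)
  a <- X[oi, oj, , , drop = FALSE]; b <- X[ei, oj, , , drop = FALSE]
  cc <- X[oi, ej, , , drop = FALSE]; dd <- X[ei, ej, , , drop = FALSE]
  M <- pmax(a, b, cc, dd)
  # deterministic tie-break: top-left wins, then below, right, diagonal
  wa <- a == M
  wb <- (b == M) & !wa
  wc <- (cc == M) & !wa & !wb
  wd <- !(wa | wb | wc)
  list(out = M, cache = list(wa = wa, wb = wb, wc = wc, wd = wd, dims = d))
}

pool_backward <- function(dY, cache) {
  d <- cache$dims
  dX <- array(0, d)
  oi <- seq(1L, d[1], 2L); ei <- seq(2L, d[1], 2L)
  oj <- seq(1L, d[2], 2L); ej <- seq(2L, d[2], 2L)
  dX[oi, oj, , ] <- dY * cache$wa
  dX[ei, oj, , ] <- dY * cache$wb
  dX[oi, ej, , ] <- dY * cache$wc
  dX[ei, ej, , ] <- dY * cache$wd
  dX
}

## ---- batch normalisation (per channel over H, W, T) -----------------------

bn_forward <- function(X, gamma, beta, running, train, momentum = 0.9,
                       eps = 1e-5) {
  d <- dim(X)
  Xm <- matrix(aperm(X, c(1, 2, 4, 3)), prod(d[c(1, 2, 4)]), d[3])
  if (train) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (Xm - rep(mu, each = nrow(Xm))) * rep(invstd, each = nrow(Xm))
  ym <- xhat * rep(gamma, each = nrow(Xm)) + rep(beta, each = nrow(Xm))
  out <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = out, running = running,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, dims = d))
}

bn_backward <- function(dY, cache) {
  d <- cache$dims
  n <- prod(d[c(1, 2, 4)])
  dYm <- matrix(aperm(dY, c(1, 2, 4, 3)), n, d[3])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(cache$gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dXm <- (dxhat - rep(s1 / n, each = n) -
            cache$xhat * rep(s2 / n, each = n)) *
    rep(cache$invstd, each = n)
  dX <- aperm(array(dXm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- nearest-neighbour upsampling by an integer factor --------------------

upsample_forward <- function(X, f) {
  d <- dim(X)
  X[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , ,
    drop = FALSE]
}

upsample_backward <- function(dY, f) {
  d <- dim(dY)
  H <- d[1] %/% f; W <- d[2] %/% f
  m <- matrix(dY, nrow = f)           # fold the row dimension
  s <- colSums(m)
  s <- array(s, c(H, d[2], d[3], d[4]))
  s <- aperm(s, c(2, 1, 3, 4))        # fold the column dimension
  m2 <- matrix(s, nrow = f)
  s2 <- array(colSums(m2), c(W, H, d[3], d[4]))
  aperm(s2, c(2, 1, 3, 4))
}

## ---- dense ----------------------------------------------------------------

dense_forward <- function(X, W, b) {
  out <- X %*% W
  out + rep(b, each = nrow(X))
}

dense_backward <- function(dY, X, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

## ---- GRU (single layer, full BPTT) ----------------------------------------

# Gate layout in the fused weight matrices: [update z | reset r | candidate n].
gru_init <- function(n_in, n_hidden) {
  k <- sqrt(1 / n_hidden)
  list(Wx = matrix(runif(n_in * 3L * n_hidden, -k, k), n_in, 3L * n_hidden),
       Wh = matrix(runif(n_hidden * 3L * n_hidden, -k, k), n_hidden,
                   3L * n_hidden),
       b = numeric(3L * n_hidden))
}

# X (T, D) -> list(out (T, H), cache). State starts at zero (it is reset at
# every clip boundary by construction: one call per clip).
gru_forward <- function(X, Wx, Wh, b) {
  T <- nrow(X); H <- nrow(Wh)
  iz <- seq_len(H); ir <- H + iz; inn <- 2L * H + iz
  XW <- X %*% Wx
  h <- numeric(H)
  out <- matrix(0, T, H)
  Z <- matrix(0, T, H); R <- matrix(0, T, H); N <- matrix(0, T, H)
  HWn <- matrix(0, T, H)  # h_prev %*% Wh[, n] before the reset gate
  Hprev <- matrix(0, T, H)
  for (t in seq_len(T)) {
    hW <- drop(h %*% Wh)
    z <- sigmoid(XW[t, iz] + hW[iz] + b[iz])
    r <- sigmoid(XW[t, ir] + hW[ir] + b[ir])
    hwn <- hW[inn]
    n <- tanh(XW[t, inn] + r * hwn + b[inn])
    Hprev[t, ] <- h
    h <- (1 - z) * n + z * h
    out[t, ] <- h
    Z[t, ] <- z; R[t, ] <- r; N[t, ] <- n; HWn[t, ] <- hwn
  }
  list(out = out,
       cache = list(X = X, Z = Z, R = R, N = N, HWn = HWn, Hprev = Hprev,
                    Wx = Wx, Wh = Wh))
}

gru_backward <- function(dOut, cache) {
  X <- cache$X; Wx <- cache$Wx; Wh <- cache$Wh
  T <- nrow(X); H <- ncol(dOut)
  iz <- seq_len(H); ir <- H + iz; inn <- 2L * H + iz
  DA <- matrix(0, T, 3L * H)   # grads wrt pre-activations, input path
  DAh <- matrix(0, T, 3L * H)  # same but candidate slot scaled by r (h path)
  dh_next <- numeric(H)
  tWh <- t(Wh)
  for (t in rev(seq_len(T))) {
    dh <- dOut[t, ] + dh_next
    z <- cache$Z[t, ]; r <- cache$R[t, ]; n <- cache$N[t, ]
    hprev <- cache$Hprev[t, ]
    dz <- dh * (hprev - n) * z * (1 - z)
    dn <- dh * (1 - z) * (1 - n^2)
    dr <- dn * cache$HWn[t, ] * r * (1 - r)
    da <- c(dz, dr, dn)
    DA[t, ] <- da
    dah <- c(dz, dr, dn * r)
    DAh[t, ] <- dah
    dh_next <- dh * z + drop(dah %*% tWh)
  }
  list(dX = tcrossprod(DA, Wx),
       dWx = crossprod(X, DA),
       dWh = crossprod(cache$Hprev, DAh),
       db = colSums(DA))
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
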
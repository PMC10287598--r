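# Minimal dense-prediction network toolkit: stride-1 "same" convolutions via
# im2col matrix products, 2x average pooling, nearest/bilinear upsampling,
# spatial dropout, sigmoid — each with a hand-written backward pass. Arrays
# are (H, W, C). This is all the machinery the pyramid regressor needs; no
# generality beyond that is attempted.

conv2d_forward <- function(x, W, b) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(H + 2 * ph, Wd + 2 * pw, cin))
  xp[ph + seq_len(H), pw + seq_len(Wd), ] <- x
  X <- matrix(0, H * Wd, kh * kw * cin)
  k <- 0L
  for (ci in seq_len(cin)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    k <- k + 1L
    X[, k] <- xp[di + seq_len(H) - 1L, dj + seq_len(Wd) - 1L, ci]
  }
  Wmat <- matrix(W, nrow = kh * kw * cin)
  out <- X %*% Wmat
  out <- sweep(out, 2, b, "+")
  list(out = array(out, c(H, Wd, cout)),
       cache = list(X = X, W = W, dims = c(H, Wd), pad = c(ph, pw)))
}

conv2d_backward <- function(dout, cache) {
  W <- cache$W
  kh <- dim(W)[1]; kw <- dim(W)[2]; cin <- dim(W)[3]; cout <- dim(W)[4]
  H <- cache$dims[1]; Wd <- cache$dims[2]
  ph <- cache$pad[1]; pw <- cache$pad[2]
  dY <- matrix(dout, H * Wd, cout)
  Wmat <- matrix(W, nrow = kh * kw * cin)
  dW <- array(crossprod(cache$X, dY), dim(W))
  db <- colSums(dY)
  dXcols <- dY %*% t(Wmat)
  dxp <- array(0, c(H + 2 * ph, Wd + 2 * pw, cin))
  k <- 0L
  for (ci in seq_len(cin)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    k <- k + 1L
    dxp[di + seq_len(H) - 1L, dj + seq_len(Wd) - 1L, ci] <-
      dxp[di + seq_len(H) - 1L, dj + seq_len(Wd) - 1L, ci] +
      matrix(dXcols[, k], H, Wd)
  }
  list(dx = dxp[ph + seq_len(H), pw + seq_len(Wd), , drop = FALSE],
       dW = dW, db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

avgpool2_forward <- function(x) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  o <- (x[seq(1, H, 2), seq(1, Wd, 2), , drop = FALSE] +
        x[seq(2, H, 2), seq(1, Wd, 2), , drop = FALSE] +
        x[seq(1, H, 2), seq(2, Wd, 2), , drop = FALSE] +
        x[seq(2, H, 2), seq(2, Wd, 2), , drop = FALSE]) / 4
  list(out = o, cache = c(H, Wd))
}
avgpool2_backward <- function(dout, cache) {
  H <- cache[1]; Wd <- cache[2]
  dx <- array(0, c(H, Wd, dim(dout)[3]))
  q <- dout / 4
  dx[seq(1, H, 2), seq(1, Wd, 2), ] <- q
  dx[seq(2, H, 2), seq(1, Wd, 2), ] <- q
  dx[seq(1, H, 2), seq(2, Wd, 2), ] <- q
  dx[seq(2, H, 2), seq(2, Wd, 2), ] <- q
  dx
}

upnearest_forward <- function(x, f) {
  ri <- rep(seq_len(dim(x)[1]), each = f)
  ci <- rep(seq_len(dim(x)[2]), each = f)
  list(out = x[ri, ci, , drop = FALSE], cache = list(f = f, d = dim(x)))
}
upnearest_backward <- function(dout, cache) {
  f <- cache$f; d <- cache$d
  dx <- array(0, d)
  for (a in seq_len(f)) for (b in seq_len(f)) {
    dx <- dx + dout[seq(a, by = f, length.out = d[1]),
                    seq(b, by = f, length.out = d[2]), , drop = FALSE]
  }
  dx
}

# Linear interpolation matrix mapping n source samples to n*f targets
# (pixel-center convention, edges clamped).
bilinear_matrix <- function(n, f) {
  m <- n * f
  A <- matrix(0, m, n)
  src <- (seq_len(m) - 0.5) / f - 0.5
  src <- pmin(pmax(src, 0), n - 1)
  lo <- floor(src); w <- src - lo
  for (i in seq_len(m)) {
    A[i, lo[i] + 1] <- A[i, lo[i] + 1] + (1 - w[i])
    A[i, min(lo[i] + 2, n)] <- A[i, min(lo[i] + 2, n)] + w[i]
  }
  A
}

upbilinear_forward <- function(x, f) {
  A <- bilinear_matrix(dim(x)[1], f)
  B <- bilinear_matrix(dim(x)[2], f)
  out <- array(0, c(nrow(A), nrow(B), dim(x)[3]))
  for (c in seq_len(dim(x)[3])) out[, , c] <- A %*% x[, , c] %*% t(B)
  list(out = out, cache = list(A = A, B = B, d = dim(x)))
}
upbilinear_backward <- function(dout, cache) {
  dx <- array(0, cache$d)
  for (c in seq_len(cache$d[3]))
    dx[, , c] <- crossprod(cache$A, dout[, , c]) %*% cache$B
  dx
}

sigmoid_forward <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(out = y, cache = y)
}
sigmoid_backward <- function(dout, cache) dout * cache * (1 - cache)

spatial_dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, cache = NULL))
  keep <- stats::rbinom(dim(x)[3], 1, 1 - rate) / (1 - rate)
  list(out = sweep(x, 3, keep, "*"), cache = keep)
}
spatial_dropout_backward <- function(dout, cache) {
  if (is.null(cache)) return(dout)
  sweep(dout, 3, cache, "*")
}

he_init <- function(dims, rng_sd_fan) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / rng_sd_fan)), dims)
}

# Adam optimizer state and update (element-wise on a flat list of arrays).
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Gradient of the soft Dice loss w.r.t. the prediction.
soft_dice_grad <- function(pred, target, eps = 1) {
  A <- 2 * sum(pred * target) + eps
  B <- sum(pred) + sum(target) + eps
  -(2 * target * B - A) / B^2
}
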
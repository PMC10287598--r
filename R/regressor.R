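#' Regressor specification
#'
#' Configuration of the pyramid dense-regression network. The encoder is a
#' small 4-stage convolutional network ("tiny") exposing feature maps at
#' strides 4, 8, 16, and 32; the decoder applies per-level convolutions,
#' upsamples the four levels by factors 1, 2, 4, and 8 to the stride-4
#' grid, sums them, applies spatial dropout (training only) and further
#' convolutions, upsamples by 4 to the input size, and ends in a sigmoid.
#'
#' Training defaults mirror the full-scale protocol: Adam with
#' `beta1 = 0.9`, `beta2 = 0.999`, `eps_opt = 1e-8`; learning rate and
#' epochs are desk-scale defaults for the tiny encoder.
#'
#' @param encoder Only `"tiny"` is provided; the encoder width is the knob.
#' @param channels Encoder channels per stage.
#' @param decoder_channels Channels of the decoder/pyramid blocks.
#' @param dropout Spatial dropout rate on the summed pyramid.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Learning rate.
#' @param beta1,beta2,eps_opt Adam moment and stabilizer parameters.
#' @param seed RNG seed for initialization, shuffling, dropout,
#'   augmentation.
#' @return A `regressor_spec` list.
#' @export
regressor_spec <- function(encoder = "tiny", channels = 8L,
                           decoder_channels = 16L, dropout = 0.1,
                           epochs = 40L, batch_size = 8L, lr = 1e-3,
                           beta1 = 0.9, beta2 = 0.999, eps_opt = 1e-8,
                           seed = 1L) {
  if (encoder != "tiny")
    stop("only the 'tiny' encoder is provided; widen 'channels' instead")
  structure(list(encoder = encoder, channels = as.integer(channels),
                 decoder_channels = as.integer(decoder_channels),
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, eps_opt = eps_opt,
                 seed = as.integer(seed)),
            class = "regressor_spec")
}

#' Build an untrained regressor
#'
#' He-initialized weights, deterministic given the spec seed. The model maps
#' a 1-channel H x W input (H, W divisible by 32) to a 1-channel H x W
#' output in (0, 1).
#'
#' @param spec A [regressor_spec()].
#' @return An object of class `mc_regressor`.
#' @export
build_regressor <- function(spec = regressor_spec()) {
  set.seed(spec$seed)
  C <- spec$channels; D <- spec$decoder_channels
  p <- list(
    W1 = he_init(c(3, 3, 1, C), 9 * 1), b1 = numeric(C),
    W2 = he_init(c(3, 3, C, C), 9 * C), b2 = numeric(C),
    W3 = he_init(c(3, 3, C, C), 9 * C), b3 = numeric(C),
    W4 = he_init(c(3, 3, C, C), 9 * C), b4 = numeric(C),
    W5 = he_init(c(3, 3, C, C), 9 * C), b5 = numeric(C),
    L4 = he_init(c(1, 1, C, D), C), lb4 = numeric(D),
    L8 = he_init(c(1, 1, C, D), C), lb8 = numeric(D),
    L16 = he_init(c(1, 1, C, D), C), lb16 = numeric(D),
    L32 = he_init(c(1, 1, C, D), C), lb32 = numeric(D),
    Wd1 = he_init(c(3, 3, D, D), 9 * D), bd1 = numeric(D),
    Wd2 = he_init(c(1, 1, D, 1), D), bd2 = numeric(1)
  )
  structure(list(params = p, spec = spec, history = NULL, trained = FALSE),
            class = "mc_regressor")
}

#' @export
print.mc_regressor <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("mc_regressor (%s encoder, %d params)%s\n", x$spec$encoder, np,
              if (x$trained) sprintf(", trained %d epoch(s), best val IoU %.3f",
                                     nrow(x$history),
                                     max(x$history$val_iou)) else " (untrained)"))
  invisible(x)
}

#' Run the regressor forward
#'
#' Low-level single-patch forward pass. `keep_cache = TRUE` retains the
#' intermediate activations needed by the backward pass (training only).
#'
#' @param params Model parameter list (from an `mc_regressor`).
#' @param x Input matrix, sides divisible by 32.
#' @param train Enable training-mode stochastic layers (dropout).
#' @param dropout Spatial dropout rate used when `train`.
#' @param keep_cache Return activations for backpropagation.
#' @return List with `out` (matrix in (0,1)) and optionally `cache`.
#' @export
regressor_forward <- function(params, x, train = FALSE, dropout = 0,
                              keep_cache = FALSE) {
  H <- nrow(x); W <- ncol(x)
  if (H %% 32 != 0 || W %% 32 != 0)
    stop("input size must be divisible by 32 (got ", H, " x ", W, ")")
  xx <- array(x, c(H, W, 1))
  cch <- list()
  step <- function(x, Wn, bn, tag) {
    cv <- conv2d_forward(x, params[[Wn]], params[[bn]])
    rl <- relu_forward(cv$out)
    pl <- avgpool2_forward(rl$out)
    cch[[tag]] <<- list(cv = cv$cache, rl = rl$cache, pl = pl$cache)
    pl$out
  }
  d1 <- step(xx, "W1", "b1", "s1")   # stride 2
  f4 <- step(d1, "W2", "b2", "s2")   # stride 4
  f8 <- step(f4, "W3", "b3", "s3")   # stride 8
  f16 <- step(f8, "W4", "b4", "s4")  # stride 16
  f32 <- step(f16, "W5", "b5", "s5") # stride 32
  lat <- function(x, Wn, bn, f, tag) {
    cv <- conv2d_forward(x, params[[Wn]], params[[bn]])
    up <- if (f == 1) list(out = cv$out, cache = NULL)
          else upnearest_forward(cv$out, f)
    cch[[tag]] <<- list(cv = cv$cache, up = up$cache, f = f)
    up$out
  }
  u4 <- lat(f4, "L4", "lb4", 1L, "l4")
  u8 <- lat(f8, "L8", "lb8", 2L, "l8")
  u16 <- lat(f16, "L16", "lb16", 4L, "l16")
  u32 <- lat(f32, "L32", "lb32", 8L, "l32")
  s <- u4 + u8 + u16 + u32
  dp <- spatial_dropout_forward(s, dropout, train)
  cv1 <- conv2d_forward(dp$out, params$Wd1, params$bd1)
  rl1 <- relu_forward(cv1$out)
  cv2 <- conv2d_forward(rl1$out, params$Wd2, params$bd2)
  ub <- upbilinear_forward(cv2$out, 4L)
  sg <- sigmoid_forward(ub$out)
  out <- matrix(sg$out, H, W)
  if (!keep_cache) return(list(out = out))
  cch$dp <- dp$cache; cch$cv1 <- cv1$cache; cch$rl1 <- rl1$cache
  cch$cv2 <- cv2$cache; cch$ub <- ub$cache; cch$sg <- sg$cache
  list(out = out, cache = cch)
}

# Backward pass from d(loss)/d(output). Returns gradients for all params.
regressor_backward <- function(params, cache, dout) {
  g <- list()
  d <- array(dout, dim(cache$sg))
  d <- sigmoid_backward(d, cache$sg)
  d <- upbilinear_backward(d, cache$ub)
  bk2 <- conv2d_backward(d, cache$cv2)
  g$Wd2 <- bk2$dW; g$bd2 <- bk2$db
  d <- relu_backward(bk2$dx, cache$rl1)
  bk1 <- conv2d_backward(d, cache$cv1)
  g$Wd1 <- bk1$dW; g$bd1 <- bk1$db
  d <- spatial_dropout_backward(bk1$dx, cache$dp)
  lat_bk <- function(d, tag, Wn, bn) {
    cc <- cache[[tag]]
    dd <- if (cc$f == 1) d else upnearest_backward(d, cc$up)
    bk <- conv2d_backward(dd, cc$cv)
    g[[Wn]] <<- bk$dW; g[[bn]] <<- bk$db
    bk$dx
  }
  df4 <- lat_bk(d, "l4", "L4", "lb4")
  df8 <- lat_bk(d, "l8", "L8", "lb8")
  df16 <- lat_bk(d, "l16", "L16", "lb16")
  df32 <- lat_bk(d, "l32", "L32", "lb32")
  step_bk <- function(d, tag, Wn, bn) {
    cc <- cache[[tag]]
    d <- avgpool2_backward(d, cc$pl)
    d <- relu_backward(d, cc$rl)
    bk <- conv2d_backward(d, cc$cv)
    g[[Wn]] <<- bk$dW; g[[bn]] <<- bk$db
    bk$dx
  }
  d5 <- step_bk(df32, "s5", "W5", "b5")
  d4 <- step_bk(df16 + d5, "s4", "W4", "b4")
  d3 <- step_bk(df8 + d4, "s3", "W3", "b3")
  d2 <- step_bk(df4 + d3, "s2", "W2", "b2")
  step_bk(d2, "s1", "W1", "b1")
  g
}

#' Extract training patches by sliding window
#'
#' Windows of `size` px at offsets 0, stride, 2*stride, ... along each axis,
#' plus a final flush-to-border window when the last regular window does not
#' reach the edge. Images smaller than `size` are reflect-padded up to it.
#' When `require_annotation`, windows whose target is empty are dropped.
#'
#' @param image Numeric matrix (normalized image).
#' @param target Numeric matrix: target proximity map (or binary mask).
#' @param size Patch size (px), default 512.
#' @param stride Offset step (px), default 480.
#' @param require_annotation Drop windows with an all-zero target.
#' @param image_id Identifier stored on each patch.
#' @return List of patch pairs: `image`, `target`, `image_id`, `offset`
#'   (0-based top-left `c(row, col)`).
#' @export
extract_patches <- function(image, target, size = 512L, stride = 480L,
                            require_annotation = TRUE, image_id = "img") {
  image <- as_pixels(image); target <- as_map_values(target)
  stopifnot(all(dim(image) == dim(target)))
  if (nrow(image) < size || ncol(image) < size) {
    pr <- max(0L, size - nrow(image)); pc <- max(0L, size - ncol(image))
    image <- pad_to(image, size); target <- pad_to(target, size)
  }
  offs <- function(L) {
    o <- seq(0L, L - size, by = stride)
    if (max(o) + size < L) o <- c(o, L - size)
    unique(o)
  }
  ro <- offs(nrow(image)); co <- offs(ncol(image))
  out <- list()
  for (r in ro) for (c in co) {
    ti <- target[r + seq_len(size), c + seq_len(size)]
    if (require_annotation && !any(ti > 0)) next
    out[[length(out) + 1L]] <- list(
      image = image[r + seq_len(size), c + seq_len(size)],
      target = ti, image_id = image_id, offset = c(r, c))
  }
  out
}

pad_to <- function(x, size) {
  pr <- max(0L, size - nrow(x)); pc <- max(0L, size - ncol(x))
  if (pr == 0 && pc == 0) return(x)
  p <- max(pr, pc)
  xp <- reflect_pad(x, p)
  xp[p + seq_len(max(nrow(x), size)) , p + seq_len(max(ncol(x), size)),
     drop = FALSE][seq_len(size), seq_len(size), drop = FALSE]
}

#' Augment a patch pair
#'
#' Geometric transforms (horizontal flip, magnification, translation, crop
#' to `out_size`) are applied identically to image and target; photometric
#' transforms (contrast, brightness, gamma) to the image only. Parameters
#' are drawn from the current RNG stream unless given explicitly via
#' `params`, which makes the transform reproducible and testable. Neutral
#' parameters give the exact center crop.
#'
#' @param pair A patch pair from [extract_patches()].
#' @param out_size Output size (px), default 320.
#' @param params Optional list overriding the random draw: `flip` (logical),
#'   `scale`, `shift` (length-2 px), `brightness`, `contrast`, `gamma`.
#' @return A patch pair of `out_size` x `out_size`, with the applied
#'   `params` attached.
#' @export
augment_patch <- function(pair, out_size = 320L, params = NULL) {
  img <- pair$image; tgt <- pair$target
  n <- nrow(img)
  if (n < out_size) stop("patch smaller than the augmentation output size")
  if (is.null(params)) {
    params <- list(flip = stats::runif(1) < 0.5,
                   scale = stats::runif(1, 0.9, 1.1),
                   shift = round(stats::runif(2, -32, 32)),
                   brightness = stats::runif(1, -0.1, 0.1),
                   contrast = stats::runif(1, 0.9, 1.1),
                   gamma = stats::runif(1, 0.8, 1.25))
  }
  geo <- function(x) {
    if (params$flip) x <- x[, ncol(x):1]
    if (params$scale != 1) x <- bilinear_resize(x, params$scale)
    crop_center(x, out_size, params$shift)
  }
  img <- geo(img); tgt <- geo(tgt)
  img <- (img - mean(img)) * params$contrast + mean(img)
  img <- img + params$brightness
  img <- pmin(pmax(img, 0), 1)
  if (params$gamma != 1) img <- img^params$gamma
  list(image = img, target = pmin(pmax(tgt, 0), 1),
       image_id = pair$image_id, offset = pair$offset, params = params)
}

bilinear_resize <- function(x, scale) {
  interp_matrix <- function(n_out, n_in) {
    src <- pmin(pmax((seq_len(n_out) - 0.5) * n_in / n_out - 0.5, 0), n_in - 1)
    lo <- floor(src); w <- src - lo
    A <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      A[i, lo[i] + 1] <- A[i, lo[i] + 1] + 1 - w[i]
      A[i, min(lo[i] + 2, n_in)] <- A[i, min(lo[i] + 2, n_in)] + w[i]
    }
    A
  }
  n2 <- max(2L, round(nrow(x) * scale)); m2 <- max(2L, round(ncol(x) * scale))
  interp_matrix(n2, nrow(x)) %*% x %*% t(interp_matrix(m2, ncol(x)))
}

crop_center <- function(x, out_size, shift = c(0, 0)) {
  r0 <- floor((nrow(x) - out_size) / 2) + shift[1]
  c0 <- floor((ncol(x) - out_size) / 2) + shift[2]
  r0 <- min(max(r0, 0), nrow(x) - out_size)
  c0 <- min(max(c0, 0), ncol(x) - out_size)
  x[r0 + seq_len(out_size), c0 + seq_len(out_size), drop = FALSE]
}

# Mean IoU per patch between the thresholded prediction and the annotated
# foreground of the target (pixels at exactly 1), swept over p_thr; the best
# value and its threshold are returned.
patch_iou_sweep <- function(preds, refs, grid = seq(0.05, 0.95, by = 0.05)) {
  best <- c(iou = -1, p_thr = NA)
  for (p in grid) {
    v <- mean(mapply(function(pr, rf) iou(pr >= p, rf), preds, refs))
    if (v > best["iou"]) best <- c(iou = v, p_thr = p)
  }
  best
}

#' Train the dense regressor
#'
#' Minimizes the soft Dice loss between predicted and target proximity
#' patches with Adam. After each epoch the model is evaluated on the
#' validation patches by mean IoU per patch (prediction thresholded at the
#' best cut-off of a sweep, reference = annotated pixels of the target);
#' the epoch with the highest validation IoU is kept.
#'
#' @param model An `mc_regressor` from [build_regressor()].
#' @param train_pairs,val_pairs Lists of patch pairs (square, side divisible
#'   by 32). `val_pairs` defaults to the training pairs.
#' @param val_refs Optional list of binary reference masks (one per
#'   validation patch) for the IoU checkpoint metric; defaults to the
#'   annotated pixels of each validation target (where the proximity is
#'   exactly 1).
#' @param epochs,batch_size,lr Optional overrides of the spec values.
#' @param clip_norm Global gradient-norm clipping threshold (stabilizes
#'   small-batch Dice training); `Inf` disables.
#' @param augment Apply random augmentation to training patches each epoch
#'   (requires patches larger than `augment_size`; off by default at desk
#'   scale).
#' @param augment_size Side of augmented patches (px, divisible by 32),
#'   default 320.
#' @param verbose Print per-epoch loss/IoU.
#' @return The trained `mc_regressor`; `history` holds per-epoch training
#'   loss and validation IoU, `best_epoch` the selected checkpoint.
#' @export
train_regressor <- function(model, train_pairs, val_pairs = NULL,
                            val_refs = NULL, epochs = NULL,
                            batch_size = NULL, lr = NULL,
                            augment = FALSE, augment_size = 320L,
                            clip_norm = 5, verbose = FALSE) {
  stopifnot(inherits(model, "mc_regressor"))
  if (!length(train_pairs)) stop("empty training set")
  if (is.null(val_pairs)) val_pairs <- train_pairs
  spec <- model$spec
  epochs <- if (is.null(epochs)) spec$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) spec$batch_size else as.integer(batch_size)
  lr <- if (is.null(lr)) spec$lr else lr
  set.seed(spec$seed + 1L)
  params <- model$params
  opt <- adam_init(params)
  refs <- if (is.null(val_refs))
    lapply(val_pairs, function(p) p$target >= 1 - 1e-9) else val_refs
  stopifnot(length(refs) == length(val_pairs))
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_iou = numeric(0), val_p_thr = numeric(0))
  best <- list(iou = -Inf, params = params, epoch = 0L)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(train_pairs))
    losses <- numeric(0)
    for (start in seq(1, length(ord), by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1, length(ord))]
      grads <- NULL
      for (b in batch) {
        pr <- train_pairs[[b]]
        if (augment) pr <- augment_patch(pr, out_size = augment_size)
        fw <- regressor_forward(params, pr$image, train = TRUE,
                                dropout = spec$dropout, keep_cache = TRUE)
        losses <- c(losses, soft_dice_loss(fw$out, pr$target))
        dout <- soft_dice_grad(fw$out, pr$target)
        g <- regressor_backward(params, fw$cache, dout)
        grads <- if (is.null(grads)) g
                 else mapply(`+`, grads, g, SIMPLIFY = FALSE)
      }
      grads <- lapply(grads, function(x) x / length(batch))
      if (is.finite(clip_norm)) {
        gn <- sqrt(sum(vapply(grads, function(x) sum(x^2), numeric(1))))
        if (is.finite(gn) && gn > clip_norm)
          grads <- lapply(grads, function(x) x * clip_norm / gn)
      }
      upd <- adam_step(params, grads[names(params)], opt, lr = lr,
                       beta1 = spec$beta1, beta2 = spec$beta2,
                       eps = spec$eps_opt)
      params <- upd$params; opt <- upd$state
    }
    preds <- lapply(val_pairs, function(p)
      regressor_forward(params, p$image)$out)
    sweep <- patch_iou_sweep(preds, refs)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_iou = sweep["iou"],
                                   val_p_thr = sweep["p_thr"]))
    if (sweep["iou"] > best$iou)
      best <- list(iou = sweep["iou"], params = params, epoch = ep)
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f  val IoU %.3f @ p_thr %.2f\n",
                  ep, mean(losses), sweep["iou"], sweep["p_thr"]))
  }
  rownames(hist) <- NULL
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

#' Predict a full-image proximity map by tiling
#'
#' The image is reflect-padded to a tile grid, predicted tile by tile with
#' overlap, overlaps blended by averaging, and cropped back.
#'
#' @param model A (trained) `mc_regressor`.
#' @param image Normalized image matrix or [mammogram_image()].
#' @param tile Tile size (px, divisible by 32).
#' @param overlap Overlap between adjacent tiles (px).
#' @param xi,alpha Recorded on the returned map (metadata only).
#' @return A [proximity_map()]-classed object with predicted `values`.
#' @export
predict_proximity <- function(model, image, tile = 512L, overlap = 64L,
                              xi = 10, alpha = 1) {
  x <- as_pixels(image)
  H <- nrow(x); W <- ncol(x)
  tile <- as.integer(tile)
  if (tile %% 32 != 0) stop("tile must be divisible by 32")
  eff <- tile - overlap
  nr <- max(1L, ceiling(max(0L, H - tile) / eff) + 1L)
  nc <- max(1L, ceiling(max(0L, W - tile) / eff) + 1L)
  Hp <- max(tile, tile + (nr - 1L) * eff)
  Wp <- max(tile, tile + (nc - 1L) * eff)
  xp <- pad_to_shape(x, Hp, Wp)
  acc <- matrix(0, Hp, Wp); wt <- matrix(0, Hp, Wp)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r0 <- (i - 1L) * eff; c0 <- (j - 1L) * eff
    sub <- xp[r0 + seq_len(tile), c0 + seq_len(tile)]
    out <- regressor_forward(model$params, sub)$out
    acc[r0 + seq_len(tile), c0 + seq_len(tile)] <-
      acc[r0 + seq_len(tile), c0 + seq_len(tile)] + out
    wt[r0 + seq_len(tile), c0 + seq_len(tile)] <-
      wt[r0 + seq_len(tile), c0 + seq_len(tile)] + 1
  }
  vals <- (acc / wt)[seq_len(H), seq_len(W)]
  structure(list(values = vals, xi = xi, alpha = alpha),
            class = "proximity_map")
}

pad_to_shape <- function(x, H, W) {
  if (nrow(x) == H && ncol(x) == W) return(x)
  p <- max(H - nrow(x), W - ncol(x))
  xp <- reflect_pad(x, p)
  xp[p + seq_len(H), p + seq_len(W), drop = FALSE]
}

#' @export
predict.mc_regressor <- function(object, newdata, ...) {
  predict_proximity(object, newdata, ...)
}

#' @export
plot.mc_regressor <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "soft Dice loss", main = "training loss", ...)
  graphics::plot(h$epoch, h$val_iou, type = "l", xlab = "epoch",
                 ylab = "mean IoU per patch", main = "validation IoU", ...)
  invisible(x)
}
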
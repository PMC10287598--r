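test_that("sliding-window extraction enumerates regular plus flush offsets", {
  img <- matrix(0.5, 1024, 1024)
  tgt <- matrix(1, 1024, 1024)
  ps <- extract_patches(img, tgt, size = 512, stride = 480)
  offs <- unique(vapply(ps, function(p) p$offset[1], numeric(1)))
  expect_equal(sort(offs), c(0, 480, 512))
  expect_length(ps, 9)

  one <- extract_patches(matrix(0.5, 512, 512), matrix(1, 512, 512),
                         size = 512, stride = 480)
  expect_length(one, 1)

  none <- extract_patches(img, matrix(0, 1024, 1024), size = 512,
                          stride = 480, require_annotation = TRUE)
  expect_length(none, 0)
})

test_that("augmentation applies geometry to both members and photometry to the image only", {
  set.seed(17)
  pair <- list(image = matrix(runif(512 * 512), 512, 512),
               target = matrix(runif(512 * 512), 512, 512),
               image_id = "a", offset = c(0, 0))
  neutral <- list(flip = FALSE, scale = 1, shift = c(0, 0),
                  brightness = 0, contrast = 1, gamma = 1)
  id <- augment_patch(pair, out_size = 320, params = neutral)
  expect_equal(dim(id$image), c(320, 320))
  ctr <- 96 + seq_len(320)
  expect_equal(id$image, pair$image[ctr, ctr])
  expect_equal(id$target, pair$target[ctr, ctr])

  # horizontal flip is an involution and hits both members
  pf <- within(neutral, flip <- TRUE)
  fl <- augment_patch(pair, out_size = 320, params = pf)
  expect_equal(fl$image[, 320:1], id$image)
  expect_equal(fl$target[, 320:1], id$target)

  # gamma affects the image, never the target
  pg <- within(neutral, gamma <- 2)
  gm <- augment_patch(pair, out_size = 320, params = pg)
  expect_equal(gm$target, id$target)
  expect_equal(gm$image, id$image^2)
  half <- pair; half$image[, ] <- 0.5
  expect_equal(augment_patch(half, 320, params = pg)$image[1, 1], 0.25)

  # random draws are deterministic given the RNG state
  set.seed(99); a1 <- augment_patch(pair, 320)
  set.seed(99); a2 <- augment_patch(pair, 320)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$params, a2$params)
})

test_that("the network maps H x W inputs in (0,1) with the stride contract", {
  spec <- regressor_spec(channels = 4, decoder_channels = 6, seed = 2)
  model <- build_regressor(spec)
  x <- matrix(runif(64 * 64), 64, 64)
  out <- regressor_forward(model$params, x)$out
  expect_equal(dim(out), c(64, 64))
  expect_true(all(out > 0 & out < 1))
  expect_error(regressor_forward(model$params, matrix(0.5, 60, 60)),
               "divisible by 32")
  # inference is deterministic (dropout inactive)
  out2 <- regressor_forward(model$params, x)$out
  expect_identical(out, out2)
  # rebuilt from the same spec -> identical weights
  model2 <- build_regressor(spec)
  expect_identical(model$params, model2$params)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  model <- build_regressor(regressor_spec(channels = 3,
                                          decoder_channels = 4, seed = 7))
  x <- matrix(runif(32 * 32), 32, 32)
  t <- matrix(runif(32 * 32), 32, 32)
  fw <- regressor_forward(model$params, x, keep_cache = TRUE)
  g <- regressor_backward(model$params, fw$cache,
                          mcseg:::soft_dice_grad(fw$out, t))
  eps <- 1e-5
  for (nm in c("W1", "W4", "L16", "Wd1", "bd2")) {
    i <- sample(length(model$params[[nm]]), 1)
    p2 <- model$params
    p2[[nm]][i] <- p2[[nm]][i] + eps
    l1 <- soft_dice_loss(regressor_forward(p2, x)$out, t)
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
    l0 <- soft_dice_loss(regressor_forward(p2, x)$out, t)
    num <- (l1 - l0) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("a short overfit run reduces the training loss and keeps the best epoch", {
  set.seed(3)
  ph <- tiny_phantom(seed = 19, n_spots = 3, shape = c(96, 96))
  M <- rasterize_annotations(ph$annotations)
  P <- proximity_map(M, xi = 10, alpha = 1)
  pairs <- extract_patches(ph$image$pixels, P$values, size = 64,
                           stride = 32)
  expect_gte(length(pairs), 4)
  pairs <- pairs[1:4]
  model <- build_regressor(regressor_spec(channels = 4,
                                          decoder_channels = 6,
                                          dropout = 0, seed = 4,
                                          epochs = 12, lr = 3e-3))
  trained <- train_regressor(model, pairs)
  h <- trained$history
  expect_equal(nrow(h), 12)
  expect_lt(h$train_loss[12], h$train_loss[1])
  expect_equal(trained$best_epoch, which.max(h$val_iou))
  expect_error(train_regressor(model, list()), "empty")
})

test_that("tiled prediction blends to the single-pass result", {
  model <- build_regressor(regressor_spec(channels = 4,
                                          decoder_channels = 6, seed = 2))
  # constant-output stub: zero weights, bias only -> sigmoid(0.7) everywhere
  stub <- model
  stub$params <- lapply(stub$params, function(p) p * 0)
  stub$params$bd2 <- 0.7
  img <- matrix(runif(96 * 96), 96, 96)
  pm <- predict_proximity(stub, img, tile = 64, overlap = 32)
  expect_equal(dim(pm$values), c(96, 96))
  expect_equal(max(abs(pm$values - 1 / (1 + exp(-0.7)))), 0,
               tolerance = 1e-12)
  # one-tile prediction equals the direct forward pass
  img64 <- matrix(runif(64 * 64), 64, 64)
  pm1 <- predict_proximity(model, img64, tile = 64, overlap = 0)
  expect_equal(pm1$values, regressor_forward(model$params, img64)$out,
               tolerance = 1e-12)
})
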
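disc_mask <- function(shape, center, radius) {
  rr <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  (sqrt((rr - center[1])^2 + (cc - center[2])^2) <= radius) + 0L
}

test_that("ROI extraction is centered, shifted at borders, and always 256 x 256", {
  img <- matrix(runif(1024 * 1024), 1024, 1024)
  msk <- matrix(0L, 1024, 1024)
  roi <- extract_roi(img, msk, bbox = c(400, 400, 623, 623))
  expect_equal(dim(roi$image), c(256, 256))
  expect_equal(roi$image, img[384 + 1:256, 384 + 1:256])

  # bbox center 10 px from the left edge -> window starts at column 0
  roi2 <- extract_roi(img, msk, bbox = c(500, 5, 520, 15))
  expect_equal(dim(roi2$image), c(256, 256))
  expect_equal(roi2$image[, 1], img[382 + 1:256, 1])
})

test_that("a filled disc yields the analytic shape descriptors", {
  m <- disc_mask(c(64, 64), c(31, 31), 10)
  roi <- list(image = matrix(0.5, 64, 64), mask = m)
  f <- compute_features(roi)
  expect_length(f, 31)
  expect_false(any(is.na(f)))
  expect_lt(f[["eccentricity"]], 0.1)
  expect_equal(f[["solidity"]], 1, tolerance = 0.05)
  expect_equal(f[["n_objects"]], 1)
  # ellipse-equivalent axes of a disc of radius 10 ~ its diameter
  expect_equal(f[["major_axis"]], 20, tolerance = 0.05)
  expect_equal(f[["minor_axis"]], 20, tolerance = 0.05)
  expect_equal(f[["area"]], sum(m))
  # single object: every per-object sd feature is 0
  expect_true(all(f[grep("^obj_sd_", names(f))] == 0))
  expect_equal(f[["obj_mean_mean_int"]], 0.5)
})

test_that("features are translation-invariant and Hu moments rotation-invariant", {
  base <- matrix(0L, 64, 64)
  base[10:20, 8:14] <- 1L; base[15:17, 20:30] <- 1L
  shifted <- matrix(0L, 64, 64)
  shifted[25:35, 28:34] <- 1L; shifted[30:32, 40:50] <- 1L
  f1 <- compute_features(list(image = matrix(0.4, 64, 64), mask = base))
  f2 <- compute_features(list(image = matrix(0.4, 64, 64), mask = shifted))
  inv <- setdiff(names(f1), "orientation")
  expect_equal(f1[inv], f2[inv], tolerance = 1e-9)

  rot <- t(base)[64:1, ]  # exact 90-degree rotation
  expect_equal(hu_moments(base), hu_moments(rot), tolerance = 1e-6)
})

test_that("an empty segmentation produces a fully missing feature vector", {
  f <- compute_features(list(image = matrix(0.4, 32, 32),
                             mask = matrix(0L, 32, 32)))
  expect_length(f, 31)
  expect_true(all(is.na(f)))
})

test_that("preprocessing standardizes with training parameters only", {
  set.seed(8)
  Xtr <- matrix(rnorm(200, mean = 5, sd = 3), 50, 4)
  Xtr[3, 2] <- NA
  pp <- mcseg:::fit_preprocess(Xtr)
  Ztr <- mcseg:::apply_preprocess(Xtr, pp)
  expect_equal(colMeans(Ztr), rep(0, 4), tolerance = 1e-9)
  expect_equal(apply(Ztr, 2, var), rep(1, 4), tolerance = 1e-9)
  # imputation fills only missing entries
  expect_equal(Ztr[-3, 2] * pp$scale[2] + pp$center[2], Xtr[-3, 2])
  # a shifted test set keeps the training parameters (nonzero mean)
  Xte <- Xtr[1:10, ] + 100
  Zte <- mcseg:::apply_preprocess(Xte, pp)
  expect_gt(abs(mean(Zte)), 1)
})

test_that("patient-wise cross-validation separates planted classes and stays at chance under permutation", {
  set.seed(123)
  n <- 200; npat <- 40
  pat <- rep(sprintf("P%02d", 1:npat), each = n / npat)
  y <- rep(c(0, 1), each = n / 2)           # patients are class-pure
  mu <- ifelse(y == 1, 3, 0)                # 3 sd separation
  X <- cbind(rnorm(n, mu), matrix(rnorm(n * 9), n, 9))
  cv <- crossval_classify(X, y, pat, folds = 5, seed = 1)
  rep1 <- roc_report(cv)
  expect_gte(rep1$mean[rep1$metric == "auc"], 0.95)

  # no test row shares a patient with its training rows (fold partition)
  for (f in seq_along(cv$folds)) {
    te_pat <- unique(pat[cv$fold == f])
    tr_pat <- unique(pat[cv$fold != f])
    expect_length(intersect(te_pat, tr_pat), 0)
  }

  yperm <- sample(y)  # break the association, keep patient class purity off
  # permuted labels can leave single-class folds; regenerate patient-pure
  yperm <- rep(sample(c(0, 1), npat, replace = TRUE), each = n / npat)
  while (length(unique(yperm)) < 2) {
    yperm <- rep(sample(c(0, 1), npat, replace = TRUE), each = n / npat)
  }
  cvp <- try(crossval_classify(X, yperm, pat, folds = 5, seed = 1),
             silent = TRUE)
  if (!inherits(cvp, "try-error")) {
    repp <- roc_report(cvp)
    expect_lt(abs(repp$mean[repp$metric == "auc"] - 0.5), 0.15)
  }
})

test_that("the ROC report applies the high-sensitivity threshold rule", {
  # perfectly separating scores
  cv <- structure(list(folds = list(list(scores = c(0.9, 0.8, 0.2, 0.1),
                                         labels = c(1, 1, 0, 0))),
                       fold = rep(1L, 4)),
                  class = "mc_crossval")
  r <- roc_report(cv, sensitivity_target = 0.9)
  expect_equal(nrow(r), 5)
  expect_equal(r$mean[r$metric == "auc"], 1)
  expect_gte(r$mean[r$metric == "sensitivity"], 0.9)
  expect_equal(r$mean[r$metric == "specificity"], 1)

  # constant scores give AUC 0.5 under the tie convention
  cvc <- structure(list(folds = list(list(scores = rep(0.5, 6),
                                          labels = c(1, 1, 1, 0, 0, 0))),
                        fold = rep(1L, 6)),
                   class = "mc_crossval")
  expect_equal(roc_report(cvc)$mean[1], 0.5)
})

test_that("the rank-based AUC agrees with an established ROC implementation", {
  set.seed(5)
  for (rep in 1:3) {
    sc <- round(runif(40), 2)  # rounding forces ties
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(y, sc,
                                                 direction = "<")))
    expect_equal(mcseg:::roc_auc(sc, y), ref, tolerance = 1e-12)
  }
})
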
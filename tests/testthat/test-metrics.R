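test_that("IoU and mean IoU per image follow their closed forms", {
  a <- matrix(0, 10, 10); a[1:2, 1] <- 1
  expect_equal(iou(a, a), 1)
  b <- matrix(0, 10, 10); b[5:6, 5] <- 1
  expect_equal(iou(a, b), 0)
  c <- matrix(0, 10, 10); c[2:3, 1] <- 1   # shares 1 px with a
  expect_equal(iou(a, c), 1 / 3)
  expect_equal(iou(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(iou(a, matrix(0, 3, 3)), "shape")

  expect_equal(mean_iou_per_image(a, a), 1)
  # all-background prediction vs truth with foreground fraction f:
  # (0 + (1-f)/1)/2
  truth <- matrix(0, 100, 100); truth[1, 1] <- 1  # f = 1e-4... use f = 0.01
  truth <- matrix(0, 10, 10); truth[1, 1] <- 1    # f = 0.01
  expect_equal(mean_iou_per_image(matrix(0, 10, 10), truth),
               (0 + 0.99) / 2)
  half <- matrix(0, 10, 10); half[1:5, ] <- 1
  expect_equal(mean_iou_per_image(1 - half, half), 0)
})

test_that("IoU per object pairs each truth object with its best-overlap prediction", {
  truth <- matrix(0L, 20, 20)
  truth[2:5, 2:5] <- 1L     # object 1: 16 px
  truth[12:15, 12:15] <- 2L # object 2: 16 px
  pred_equal <- truth
  expect_equal(iou_per_object(pred_equal, truth), 1)
  expect_equal(iou_per_object(matrix(0L, 20, 20), truth), 0)
  # one truth matched at IoU 0.5, one unmatched -> mean(0.5, 0) = 0.25
  pred <- matrix(0L, 20, 20)
  pred[2:5, 2:3] <- 1L; pred[2:5, 6:7] <- 1L  # 16 px, 8 shared with obj 1
  expect_equal(iou_per_object(pred, truth), mean(c(8 / 24, 0)))
  two_truth <- truth
  pred2 <- matrix(0L, 20, 20); pred2[2:5, 2:5] <- 1L
  pred2[2:5, 6:9] <- 1L  # single component spanning obj1 + extra
  expect_warning(v <- iou_per_object(pred2, matrix(0L, 20, 20)),
                 "no truth")
  expect_true(is.na(v))
})

test_that("detection matching applies the 5 px / IoU 0.3 rules with boundary inclusion", {
  truth <- list(centroids = rbind(c(10, 10)), pixels = list(integer(0)))
  close_pred <- list(centroids = rbind(c(10, 10)), pixels = list(integer(0)))
  m <- match_detections(close_pred, truth)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 0, 0))

  far <- list(centroids = rbind(c(10, 16)), pixels = list(integer(0)))
  m2 <- match_detections(far, truth)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(0, 1, 1))

  at5 <- list(centroids = rbind(c(10, 15)), pixels = list(integer(0)))
  m3 <- match_detections(at5, truth)
  expect_equal(m3$TP, 1)

  # IoU rule rescues a distant but well-overlapping object
  tr_lab <- matrix(0L, 40, 40); tr_lab[1:20, 1:20] <- 1L
  pr_lab <- matrix(0L, 40, 40); pr_lab[8:27, 1:20] <- 1L  # centroid 7 px off
  m4 <- match_detections(pr_lab, tr_lab)
  expect_equal(m4$TP, 1)
})

test_that("greedy matching agrees with the optimal assignment on small scenes", {
  set.seed(77)
  agree <- 0; total <- 60
  for (rep in seq_len(total)) {
    np <- sample(0:6, 1); nt <- sample(1:6, 1)
    predc <- cbind(runif(np, 0, 30), runif(np, 0, 30))
    truthc <- cbind(runif(nt, 0, 30), runif(nt, 0, 30))
    pred <- list(centroids = predc, pixels = rep(list(integer(0)), np))
    truth <- list(centroids = truthc, pixels = rep(list(integer(0)), nt))
    m <- match_detections(pred, truth)
    cand <- candidate_pairs_dist(predc, truthc, 5)
    opt <- optimal_match_count(cand, np, nt)
    if (m$TP == opt) agree <- agree + 1
    expect_lte(m$TP, opt)
    expect_equal(m$TP + m$FN, nt)
  }
  expect_gte(agree / total, 0.95)
})

test_that("FROC pooling and area normalization follow the spacing arithmetic", {
  # 1 cm^2 at 0.070 mm/px is (10/0.070)^2 ~ 142.86^2 px
  px_per_cm2 <- (10 / 0.070)^2
  ph <- tiny_phantom(seed = 16, n_spots = 4, shape = c(128, 128))
  seg <- hdog_segment(ph$image)
  images <- list(list(proximity = proximity_map(ph$truth_mask, 10, 1),
                      objects = seg,
                      truth = label_components(ph$truth_mask)))
  fc <- froc_curve(images, p_grid = c(0.1, 0.5, 0.9), spacing_mm = 0.070)
  expect_equal(fc$area_cm2, 128 * 128 / px_per_cm2, tolerance = 1e-10)
  expect_equal(fc$n_truth, 4)
  # TPR non-increasing as the threshold rises
  cv <- fc$curve[order(fc$curve$p_thr), ]
  expect_true(all(diff(cv$tpr) <= 0))
  expect_true(all(cv$tpr >= 0 & cv$tpr <= 1))
})

test_that("partial AUC reproduces flat and ramp closed forms and is interpolation-invariant", {
  flat1 <- data.frame(p_thr = c(0.9, 0.1), tpr = c(1, 1),
                      fp_per_cm2 = c(0, 2))
  expect_equal(partial_auc(flat1), 1)
  flat0 <- data.frame(p_thr = c(0.9, 0.1), tpr = c(0, 0),
                      fp_per_cm2 = c(0, 2))
  expect_equal(partial_auc(flat0), 0)
  ramp <- data.frame(p_thr = seq(0.9, 0.1, length.out = 5),
                     tpr = seq(0, 1, length.out = 5),
                     fp_per_cm2 = seq(0, 1, length.out = 5))
  expect_equal(partial_auc(ramp), 0.5)
  # adding interpolated points changes nothing
  dense <- data.frame(p_thr = 0.5, tpr = seq(0, 1, length.out = 101),
                      fp_per_cm2 = seq(0, 1, length.out = 101))
  expect_equal(partial_auc(dense), partial_auc(ramp))
})

test_that("the operating point minimizes distance to (0, 1) with high-threshold ties", {
  cv <- data.frame(p_thr = c(0.8, 0.4), tpr = c(0.9, 0.95),
                   fp_per_cm2 = c(0.4, 1.0))
  expect_equal(operating_point(cv), 0.8)
  perfect <- data.frame(p_thr = c(0.7, 0.3), tpr = c(1, 1),
                        fp_per_cm2 = c(0, 0.5))
  expect_equal(operating_point(perfect), 0.7)
  single <- data.frame(p_thr = 0.5, tpr = 0.5, fp_per_cm2 = 0.2)
  expect_equal(operating_point(single), 0.5)
  ties <- data.frame(p_thr = c(0.6, 0.2), tpr = c(0.8, 0.8),
                     fp_per_cm2 = c(0.3, 0.3))
  expect_equal(operating_point(ties), 0.6)
})

test_that("bootstrap pAUC is seeded and collapses for identical images", {
  ph <- tiny_phantom(seed = 18, n_spots = 3, shape = c(96, 96))
  seg <- hdog_segment(ph$image)
  one <- list(proximity = proximity_map(ph$truth_mask, 10, 1),
              objects = seg, truth = label_components(ph$truth_mask))
  images <- list(one, one, one)
  b1 <- bootstrap_pauc(images, B = 20, seed = 7,
                       p_grid = c(0.2, 0.5, 0.8))
  b2 <- bootstrap_pauc(images, B = 20, seed = 7,
                       p_grid = c(0.2, 0.5, 0.8))
  expect_identical(b1, b2)
  expect_equal(b1[["ci_low"]], b1[["ci_high"]])
})
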
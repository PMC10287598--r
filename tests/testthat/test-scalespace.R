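test_that("scale ladder honors both endpoints with the geometric ratio", {
  s <- build_scale_sequence(1.18, 3.1, 2^(1 / 3))
  expect_equal(s, 1.18 * 2^((0:5) / 3), tolerance = 1e-12)
  expect_length(s, 6)
  expect_true(s[5] < 3.1 && s[6] >= 3.1)
  expect_equal(build_scale_sequence(1, 4, 2), c(1, 2, 4))
  expect_error(build_scale_sequence(3, 1), "sigma")
  expect_error(build_scale_sequence(1, 4, 1), "ratio")
})

test_that("Gaussian smoothing preserves constants, mass, and kills variance", {
  const <- matrix(0.37, 24, 24)
  L <- gaussian_scale_space(const, c(1, 2, 4))
  for (n in 1:3) expect_equal(L[, , n], const, tolerance = 1e-10)

  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  L2 <- gaussian_scale_space(imp, c(2))
  expect_equal(L2[17, 17, 1], 1 / (2 * pi * 4), tolerance = 0.05)

  set.seed(2)
  noise <- matrix(runif(64 * 64), 64, 64)
  Ln <- gaussian_scale_space(noise, c(1, 2, 4))
  v <- apply(Ln, 3, function(m) var(as.vector(m)))
  expect_true(all(diff(v) < 0))
})

test_that("normalized DoG vanishes on constants and ramps, peaks at the matched scale", {
  scales <- build_scale_sequence(1.18, 3.1)
  const <- matrix(0.5, 32, 32)
  dog <- normalized_dog_stack(gaussian_scale_space(const, scales), scales)
  expect_equal(max(abs(dog$values)), 0, tolerance = 1e-12)

  ramp <- matrix(seq(0, 1, length.out = 48), 48, 48)
  dogr <- normalized_dog_stack(gaussian_scale_space(ramp, scales), scales)
  interior <- dogr$values[16:32, 16:32, ]
  expect_lt(max(abs(interior)), 1e-10)

  # centered bump of width s: the scale of maximal central response matches
  # the closed-form oracle. Smoothing a Gaussian bump of width s with a
  # Gaussian of width sigma leaves center amplitude a*s^2/(s^2+sigma^2), so
  # the normalized DoG at the center is
  # sigma_n/(sigma_{n+1}-sigma_n) * a*s^2 * (1/(s^2+sigma_n^2) -
  # 1/(s^2+sigma_{n+1}^2)); its argmax is the expected plane.
  sel <- integer(0)
  for (s in c(1.5, 2.2, 3.0)) {
    img <- spot_image(c(65, 65), c(32, 32), 0.5, s)
    d <- normalized_dog_stack(gaussian_scale_space(img, scales), scales)
    n_star <- which.max(d$values[33, 33, ])
    nn <- length(scales) - 1
    oracle <- 0.5 * s^2 * scales[1:nn] / diff(scales) *
      (1 / (s^2 + scales[1:nn]^2) - 1 / (s^2 + scales[2:(nn + 1)]^2))
    expect_equal(n_star, which.max(oracle))
    sel <- c(sel, n_star)
  }
  # and the selected scale grows with the bump width
  expect_true(all(diff(sel) >= 0))
})

test_that("3-D maxima detection matches the exhaustive brute-force scan", {
  expect_equal(nrow(detect_blobs(normalized_dog_stack(
    gaussian_scale_space(matrix(0.2, 20, 20), c(1, 2, 4)), c(1, 2, 4)),
    T_dog = 0.006)), 0)

  set.seed(11)
  for (rep in 1:4) {
    vals <- array(rnorm(16 * 16 * 4, sd = 0.02), c(16, 16, 4))
    dog <- structure(list(values = vals, scales = c(1, 1.5, 2.2, 3.3, 5)),
                     class = "dog_stack")
    got <- detect_blobs(dog, T_dog = 0.006)
    oracle <- brute_force_maxima(vals, 0.006)
    n_oracle <- if (is.null(oracle)) 0L else nrow(oracle)
    expect_equal(nrow(got), n_oracle)
    if (n_oracle) {
      o <- oracle[order(oracle[, 3], oracle[, 1], oracle[, 2]), ,
                  drop = FALSE]
      expect_equal(got$row, o[, 1] - 1)
      expect_equal(got$col, o[, 2] - 1)
      expect_equal(got$scale_index, o[, 3])
      expect_equal(got$response, o[, 4])
    }
  }
})

test_that("a single planted spot yields one blob at its center", {
  img <- spot_image(c(64, 64), c(32, 32), 0.5, 2)
  scales <- build_scale_sequence(1.18, 3.1)
  dog <- normalized_dog_stack(gaussian_scale_space(img, scales), scales)
  blobs <- detect_blobs(dog, T_dog = 0.006)
  expect_equal(nrow(blobs), 1)
  expect_lte(sqrt((blobs$row - 32)^2 + (blobs$col - 32)^2), 1)
  # threshold above the global maximum suppresses everything
  expect_equal(nrow(detect_blobs(dog, T_dog = max(dog$values) + 1)), 0)
})

test_that("equal-valued plateaus keep the lexicographically smallest voxel", {
  vals <- array(0, c(8, 8, 3))
  vals[4, 4, 2] <- 0.5
  vals[4, 5, 2] <- 0.5  # adjacent equal maxima -> one plateau
  dog <- structure(list(values = vals, scales = c(1, 2, 4, 8)),
                   class = "dog_stack")
  blobs <- detect_blobs(dog, T_dog = 0.006)
  expect_equal(nrow(blobs), 1)
  expect_equal(c(blobs$row, blobs$col, blobs$scale_index), c(3, 3, 2))
})

test_that("blob count is non-increasing in the DoG threshold", {
  set.seed(4)
  ph <- tiny_phantom(seed = 4, n_spots = 5)
  scales <- build_scale_sequence(1.18, 3.1)
  dog <- normalized_dog_stack(gaussian_scale_space(ph$image$pixels, scales),
                              scales)
  counts <- vapply(c(0.001, 0.006, 0.02, 0.05, 0.2),
                   function(t) nrow(detect_blobs(dog, t)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("DoG response is linear in spot amplitude", {
  scales <- build_scale_sequence(1.18, 3.1)
  resp <- vapply(c(0.2, 0.4), function(a) {
    img <- spot_image(c(64, 64), c(32, 32), a, 2, base = 0)
    d <- normalized_dog_stack(gaussian_scale_space(img, scales), scales)
    max(d$values)
  }, numeric(1))
  expect_equal(resp[2], 2 * resp[1], tolerance = 1e-9)
})

test_that("overlap pruning removes the smaller blob above the threshold only", {
  two <- structure(data.frame(row = c(10, 40), col = c(10, 40),
                              sigma = c(2, 1), response = c(0.5, 0.3),
                              scale_index = c(2L, 1L)),
                   class = c("blob_set", "data.frame"))
  expect_equal(nrow(prune_overlapping_blobs(two, O_dog = 0)), 2)

  conc <- structure(data.frame(row = c(20, 20), col = c(20, 20),
                               sigma = c(2, 1), response = c(0.5, 0.3),
                               scale_index = c(2L, 1L)),
                    class = c("blob_set", "data.frame"))
  pruned <- prune_overlapping_blobs(conc, O_dog = 0.5)
  expect_equal(nrow(pruned), 1)
  expect_equal(pruned$sigma, 2)
  # overlap fraction of concentric discs is exactly 1; strict > keeps both
  expect_equal(nrow(prune_overlapping_blobs(conc, O_dog = 1)), 2)
})
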
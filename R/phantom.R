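#' Phantom specification
#'
#' Parameters of the synthetic mammogram-like phantom: a smooth textured
#' background carrying small bright Gaussian spots, short bright ridges
#' (tubes), and larger filled super-ellipses. Every planted object has known
#' ground truth: the truth mask is the half-maximum level set of the object's
#' own signal, small objects (equivalent diameter < 10 px) are annotated by
#' their center point and larger ones by a contour — mirroring the mixed
#' point/contour annotation style of mammogram datasets.
#'
#' @param shape `c(rows, cols)` of the generated image.
#' @param n_spots Number of small isotropic Gaussian bright spots.
#' @param n_tubes Number of short anisotropic ridge objects.
#' @param n_large Number of large contour-annotated super-ellipse objects.
#' @param amplitude_range Additive peak amplitude range, as intensity
#'   fraction of the `[0, 1]` scale.
#' @param sigma_range Spot width range (px).
#' @param tube_length_range Ridge half-length range (px).
#' @param large_radius_range Semi-axis range of large objects (px).
#' @param background_correlation_px Gaussian smoothing length of the
#'   background texture.
#' @param noise_sd Additive white pixel-noise standard deviation.
#' @param min_separation_factor Object centers are kept at least
#'   `min_separation_factor * max(sigma_range)` apart (unless 0).
#' @param seed RNG seed; all randomness is derived from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(256L, 256L), n_spots = 10L, n_tubes = 0L,
                         n_large = 0L, amplitude_range = c(0.3, 0.5),
                         sigma_range = c(1.5, 2.5),
                         tube_length_range = c(6, 12),
                         large_radius_range = c(8, 14),
                         background_correlation_px = 24,
                         noise_sd = 0.01,
                         min_separation_factor = 4,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), n_spots = as.integer(n_spots),
               n_tubes = as.integer(n_tubes), n_large = as.integer(n_large),
               amplitude_range = amplitude_range, sigma_range = sigma_range,
               tube_length_range = tube_length_range,
               large_radius_range = large_radius_range,
               background_correlation_px = background_correlation_px,
               noise_sd = noise_sd,
               min_separation_factor = min_separation_factor,
               seed = as.integer(seed))
  stopifnot(all(spec$shape >= 16), spec$noise_sd >= 0,
            spec$background_correlation_px >= 0,
            diff(spec$amplitude_range) >= 0, diff(spec$sigma_range) >= 0)
  class(spec) <- "phantom_spec"
  spec
}

#' Generate a textured phantom background
#'
#' Gaussian-filtered white noise rescaled into a mid-gray band (about
#' 0.2–0.6), plus independent per-pixel Gaussian noise, clipped to `[0, 1]`.
#' Deterministic given the seed.
#'
#' @param shape `c(rows, cols)`.
#' @param correlation_px Smoothing length (px); 0 leaves the field white.
#' @param noise_sd Additive pixel-noise sd.
#' @param seed RNG seed.
#' @param spacing_mm Pixel spacing recorded on the output image.
#' @return A normalized [mammogram_image()].
#' @export
generate_background <- function(shape, correlation_px = 24, noise_sd = 0.01,
                                seed = 1L, spacing_mm = 0.070) {
  rng <- local_rng(seed)
  field <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  if (correlation_px > 0) field <- gaussian_filter(field, correlation_px)
  rg <- range(field)
  if (diff(rg) > 0) field <- (field - rg[1]) / diff(rg)  # -> [0,1]
  field <- 0.2 + 0.4 * field                              # -> [0.2,0.6]
  if (noise_sd > 0)
    field <- field + matrix(stats::rnorm(prod(shape), sd = noise_sd),
                            shape[1], shape[2])
  field <- pmin(pmax(field, 0), 1)
  mammogram_image(field, spacing_mm = spacing_mm, normalized = TRUE)
}

# All phantom randomness flows through explicit seeds.
local_rng <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

#' Plant bright objects into a background
#'
#' Spots are isotropic Gaussian bumps `a * exp(-d^2 / (2 s^2))`; tubes are
#' rotated anisotropic Gaussian ridges; large objects are filled
#' super-ellipses with soft edges. Each object's truth region is the set of
#' pixels where its own added signal exceeds half its peak amplitude.
#' Objects whose truth region has equivalent diameter < 10 px are annotated
#' by their center point, larger ones by a contour polygon. Objects
#' extending past the border are clipped and flagged.
#'
#' @param background A normalized [mammogram_image()].
#' @param spec A [phantom_spec()] (its `shape` must match the background).
#' @return A list: `image` (signal added, clipped to `[0, 1]`),
#'   `annotations` ([annotation_set()]), `truth_mask` (binary matrix),
#'   `truth_objects` (data frame: row, col, sigma, type, amplitude, clipped).
#' @export
plant_objects <- function(background, spec) {
  stopifnot(inherits(background, "mammogram_image"), background$normalized)
  shape <- dim(background$pixels)
  stopifnot(all(shape == spec$shape))
  rng <- local_rng(spec$seed + 1L)
  n_obj <- spec$n_spots + spec$n_tubes + spec$n_large
  img <- background$pixels
  truth <- matrix(0L, shape[1], shape[2])
  pts <- NULL; contours <- list()
  objs <- data.frame(row = numeric(0), col = numeric(0), sigma = numeric(0),
                     type = character(0), amplitude = numeric(0),
                     clipped = logical(0))
  if (n_obj == 0)
    return(list(image = background, annotations = annotation_set(
      image_shape = shape), truth_mask = truth, truth_objects = objs))

  min_sep <- spec$min_separation_factor * max(spec$sigma_range,
                                              spec$large_radius_range / 2)
  margin <- 4
  centers <- matrix(numeric(0), ncol = 2)
  draw_center <- function() {
    for (attempt in 1:200) {
      cand <- c(stats::runif(1, margin, shape[1] - 1 - margin),
                stats::runif(1, margin, shape[2] - 1 - margin))
      if (!nrow(centers) || min_sep == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_sep)
        return(cand)
    }
    cand  # dense spec: accept the last draw
  }

  types <- c(rep("spot", spec$n_spots), rep("tube", spec$n_tubes),
             rep("large", spec$n_large))
  for (ty in types) {
    ctr <- draw_center()
    centers <- rbind(centers, ctr)
    a <- stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2])
    rr <- matrix(0:(shape[1] - 1), shape[1], shape[2])
    cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
    dr <- rr - ctr[1]; dc <- cc - ctr[2]
    if (ty == "spot") {
      s <- stats::runif(1, spec$sigma_range[1], spec$sigma_range[2])
      signal <- a * exp(-(dr^2 + dc^2) / (2 * s^2))
    } else if (ty == "tube") {
      s <- stats::runif(1, spec$sigma_range[1], spec$sigma_range[2])
      len <- stats::runif(1, spec$tube_length_range[1],
                          spec$tube_length_range[2])
      th <- stats::runif(1, 0, pi)
      u <- dr * cos(th) + dc * sin(th)   # along the ridge
      v <- -dr * sin(th) + dc * cos(th)  # across
      signal <- a * exp(-(u^2 / (2 * len^2) + v^2 / (2 * s^2)))
    } else {
      ax1 <- stats::runif(1, spec$large_radius_range[1],
                          spec$large_radius_range[2])
      ax2 <- stats::runif(1, spec$large_radius_range[1],
                          spec$large_radius_range[2])
      p <- stats::runif(1, 2, 4)  # super-ellipse exponent
      th <- stats::runif(1, 0, pi)
      u <- dr * cos(th) + dc * sin(th)
      v <- -dr * sin(th) + dc * cos(th)
      rho <- (abs(u) / ax1)^p + (abs(v) / ax2)^p
      # smooth shoulder: half-max exactly on rho = 1
      signal <- a / (1 + rho^3)
      s <- sqrt(ax1 * ax2)
    }
    obj_truth <- signal > a / 2
    clipped <- any(obj_truth[c(1, shape[1]), ]) || any(obj_truth[, c(1, shape[2])])
    img <- img + signal
    truth <- truth | obj_truth
    eq_diam <- 2 * sqrt(sum(obj_truth) / pi)
    if (eq_diam < 10) {
      pts <- rbind(pts, round(ctr))
    } else {
      contours <- c(contours, list(trace_half_max_contour(ty, ctr, s,
        if (ty == "tube") len else if (ty == "large") c(ax1, ax2, p) else NULL,
        if (ty %in% c("tube", "large")) th else 0, shape)))
    }
    objs <- rbind(objs, data.frame(row = ctr[1], col = ctr[2], sigma = s,
                                   type = ty, amplitude = a,
                                   clipped = clipped))
  }
  img <- pmin(pmax(img, 0), 1)
  mode(truth) <- "integer"
  list(image = mammogram_image(img, spacing_mm = background$spacing_mm,
                               normalized = TRUE),
       annotations = annotation_set(points = pts, contours = contours,
                                    image_shape = shape),
       truth_mask = truth, truth_objects = objs)
}

# Analytic half-maximum boundary of a planted object as a polygon.
trace_half_max_contour <- function(type, ctr, s, extra, th, shape) {
  t <- seq(0, 2 * pi, length.out = 65)[-65]
  if (type == "spot") {
    rad <- s * sqrt(2 * log(2))
    u <- rad * cos(t); v <- rad * sin(t)
  } else if (type == "tube") {
    len <- extra
    k <- sqrt(2 * log(2))
    u <- k * len * cos(t); v <- k * s * sin(t)
  } else {
    ax1 <- extra[1]; ax2 <- extra[2]; p <- extra[3]
    # rho = 1 boundary of the super-ellipse
    u <- ax1 * sign(cos(t)) * abs(cos(t))^(2 / p)
    v <- ax2 * sign(sin(t)) * abs(sin(t))^(2 / p)
  }
  rr <- ctr[1] + u * cos(th) - v * sin(th)
  cc <- ctr[2] + u * sin(th) + v * cos(th)
  rr <- pmin(pmax(rr, 0), shape[1] - 1)
  cc <- pmin(pmax(cc, 0), shape[2] - 1)
  cbind(row = rr, col = cc)
}

#' Generate a phantom dataset with a case-disjoint split
#'
#' Per-image seeds are derived deterministically from the master seed, so
#' the same call reproduces the same dataset bit-exactly; each image is a
#' distinct case, and the split is case-disjoint by construction.
#'
#' @param n_images Number of phantoms (>= 3).
#' @param spec A [phantom_spec()] template; its seed field is replaced per
#'   image.
#' @param split Proportions `c(train, val, test)`; must sum to 1.
#' @param seed Master seed.
#' @return A list of per-image lists (as [plant_objects()] plus `split` and
#'   `id`).
#' @export
generate_dataset <- function(n_images, spec = phantom_spec(),
                             split = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(n_images >= 3, abs(sum(split) - 1) < 1e-9)
  n_train <- floor(split[1] * n_images)
  n_val <- floor(split[2] * n_images)
  labels <- c(rep("train", n_train), rep("val", n_val),
              rep("test", n_images - n_train - n_val))
  lapply(seq_len(n_images), function(i) {
    img_seed <- (seed * 10007L + i * 101L) %% .Machine$integer.max
    sp <- spec; sp$seed <- as.integer(img_seed)
    bg <- generate_background(sp$shape, sp$background_correlation_px,
                              sp$noise_sd, seed = sp$seed)
    out <- plant_objects(bg, sp)
    out$split <- labels[i]
    out$id <- sprintf("phantom_%03d", i)
    out
  })
}

#' Write a phantom dataset to disk
#'
#' Emits, per image, a 16-bit PNG image, a `*_points.csv` / `*_contours.json`
#' annotation pair, and a PNG truth mask, plus a `manifest.csv` with the
#' split assignment.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset, function(d) {
    base <- file.path(dir, d$id)
    raw <- mammogram_image(round(d$image$pixels * 65535),
                           spacing_mm = d$image$spacing_mm, bit_depth = 16L)
    write_image(raw, paste0(base, ".png"))
    write_annotations(d$annotations, paste0(base, "_points.csv"),
                      paste0(base, "_contours.json"))
    write_mask(d$truth_mask, paste0(base, "_truth.png"))
    data.frame(id = d$id, split = d$split)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
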
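#' Pipeline configuration
#'
#' Bundles every tunable parameter of the two-branch segmentation pipeline.
#' Defaults are the operating values selected on the INbreast-style validation
#' protocol: scale-space endpoints `sigma_min = 1.18`, `sigma_max = 3.1` px,
#' DoG response threshold `T_dog = 0.006`, Hessian ratio threshold
#' `h_thr = 1.4`, blob overlap threshold `O_dog = 1` (which disables pruning
#' under the strict `>` rule), proximity parameters `xi = 10` px and
#' `alpha = 1`, proximity cut-off `p_thr`, and fusion overlap `o_thr = 0.3`.
#'
#' @param sigma_min,sigma_max Smallest/largest Gaussian scale (px).
#' @param k Multiplicative scale ratio (> 1); default `2^(1/3)`, three scales
#'   per octave.
#' @param T_dog Lower bound applied to the normalized DoG before maxima
#'   detection.
#' @param O_dog Overlap fraction above which the smaller of two overlapping
#'   blobs is eliminated; in `[0, 1]`.
#' @param h_thr Hessian ratio threshold of the convexity constraint.
#' @param xi Characteristic proximity distance (px), > 0.
#' @param alpha Proximity decay rate; must be non-zero.
#' @param p_thr Cut-off on the predicted proximity map; in `[0, 1]`.
#' @param o_thr Minimum object/region overlap fraction for fusion; in `[0, 1]`.
#' @param patch_size,stride Sliding-window patch extraction geometry (px).
#' @param spacing_mm Default pixel spacing when an image carries none.
#' @param seed Integer seed controlling all randomness downstream.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(sigma_min = 1.18, sigma_max = 3.1, k = 2^(1 / 3),
                            T_dog = 0.006, O_dog = 1, h_thr = 1.4,
                            xi = 10, alpha = 1, p_thr = 0.5, o_thr = 0.3,
                            patch_size = 512L, stride = 480L,
                            spacing_mm = 0.070, seed = 1L) {
  cfg <- list(
    sigma_min = sigma_min, sigma_max = sigma_max, k = k,
    T_dog = T_dog, O_dog = O_dog, h_thr = h_thr,
    xi = xi, alpha = alpha, p_thr = p_thr, o_thr = o_thr,
    patch_size = as.integer(patch_size), stride = as.integer(stride),
    spacing_mm = spacing_mm, seed = as.integer(seed)
  )
  if (!(cfg$sigma_min > 0 && cfg$sigma_max > cfg$sigma_min))
    stop("require 0 < sigma_min < sigma_max")
  if (cfg$k <= 1) stop("scale ratio k must be > 1")
  if (cfg$O_dog < 0 || cfg$O_dog > 1) stop("O_dog must lie in [0, 1]")
  if (cfg$p_thr < 0 || cfg$p_thr > 1) stop("p_thr must lie in [0, 1]")
  if (cfg$o_thr < 0 || cfg$o_thr > 1) stop("o_thr must lie in [0, 1]")
  if (cfg$xi <= 0) stop("xi must be > 0")
  if (cfg$alpha == 0) stop("alpha must be non-zero")
  if (cfg$spacing_mm <= 0) stop("spacing_mm must be > 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a key=value configuration file
#'
#' Parses a plain-text file of `key = value` lines (comments start with `#`)
#' and merges the values over [pipeline_config()] defaults. Values are parsed
#' as numerics where possible.
#'
#' @param path Path to the configuration file.
#' @param ... Overrides applied after the file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed config line: ", ln)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (!is.na(num)) num else val
  }
  overrides <- list(...)
  kv[names(overrides)] <- overrides
  do.call(pipeline_config, kv)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("mcseg pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-10s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
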
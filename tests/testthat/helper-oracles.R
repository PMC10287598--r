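# Independent oracles used across tests. These deliberately re-derive
# results by brute force or closed form, never by calling the code paths
# they check.

# Gaussian spot image on a flat background (0-based center coordinates).
spot_image <- function(shape, center, amplitude, s, base = 0.3) {
  rr <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  base + amplitude * exp(-((rr - center[1])^2 + (cc - center[2])^2) / (2 * s^2))
}

# Exhaustive 3-D local-maxima scan matching the stated rule: threshold
# first, then a voxel qualifies iff >= all existing 26-neighbors and > at
# least one; equal-valued 26-connected plateaus keep the lexicographically
# smallest (scale, row, col).
brute_force_maxima <- function(vals, T_dog) {
  v <- vals
  v[v < T_dog] <- -Inf
  d <- dim(v)
  hits <- NULL
  for (n in seq_len(d[3])) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    x <- v[r, c, n]
    if (!is.finite(x)) next
    ge <- TRUE; gt <- FALSE
    for (dn in -1:1) for (dr in -1:1) for (dc in -1:1) {
      if (dn == 0 && dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc; n2 <- n + dn
      if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2] ||
          n2 < 1 || n2 > d[3]) next
      y <- v[r2, c2, n2]
      if (x < y) ge <- FALSE
      if (x > y) gt <- TRUE
    }
    if (ge && gt) hits <- rbind(hits, c(r, c, n, x))
  }
  if (is.null(hits)) return(hits)
  # plateau resolution: drop a hit if an equal-valued 26-connected chain of
  # hits leads to a lexicographically smaller one
  keep <- rep(TRUE, nrow(hits))
  if (nrow(hits) > 1) {
    # union equal-valued adjacent hits
    grp <- seq_len(nrow(hits))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(hits))) for (j in seq_len(nrow(hits))) {
        if (i == j || grp[i] == grp[j]) next
        if (hits[i, 4] == hits[j, 4] &&
            all(abs(hits[i, 1:3] - hits[j, 1:3]) <= 1)) {
          grp[grp == grp[j]] <- grp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (g in unique(grp)) {
      members <- which(grp == g)
      if (length(members) > 1) {
        ord <- order(hits[members, 3], hits[members, 1], hits[members, 2])
        keep[members[-ord[1]]] <- FALSE
      }
    }
  }
  hits[keep, , drop = FALSE]
}

# Brute-force proximity map: explicit max over annotated pixels.
brute_force_proximity <- function(mask, xi, alpha) {
  idx <- which(mask != 0, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  if (!nrow(idx)) return(out)
  g <- function(r) ifelse(r <= xi,
                          (exp(alpha * (1 - r / xi)) - 1) / (exp(alpha) - 1), 0)
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    d <- sqrt((idx[, 1] - r)^2 + (idx[, 2] - c)^2)
    out[r, c] <- max(g(d))
  }
  out
}

# Maximum-cardinality one-to-one matching over candidate pairs (recursion;
# fine for <= 6 x 6 scenes). Returns the best achievable TP count.
optimal_match_count <- function(cand, np, nt) {
  if (is.null(cand) || !nrow(cand)) return(0L)
  best <- 0L
  recurse <- function(k, usedP, usedT, tp) {
    best <<- max(best, tp)
    if (k > nrow(cand)) return()
    # prune: even matching every remaining pair cannot beat best
    if (tp + (nrow(cand) - k + 1) <= best) return()
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!usedP[i] && !usedT[j]) {
      usedP[i] <- TRUE; usedT[j] <- TRUE
      recurse(k + 1, usedP, usedT, tp + 1L)
      usedP[i] <- FALSE; usedT[j] <- FALSE
    }
    recurse(k + 1, usedP, usedT, tp)
  }
  recurse(1L, logical(np), logical(nt), 0L)
  best
}

# Candidate pairs under the same rules as the matcher (distance only;
# point truths).
candidate_pairs_dist <- function(predc, truthc, dist_px = 5) {
  cand <- NULL
  for (i in seq_len(nrow(predc))) for (j in seq_len(nrow(truthc))) {
    d <- sqrt(sum((predc[i, ] - truthc[j, ])^2))
    if (d <= dist_px) cand <- rbind(cand, c(i, j, d))
  }
  cand
}

# Small deterministic phantom bundle reused by several tests.
tiny_phantom <- function(seed = 7, n_spots = 4, shape = c(96, 96)) {
  sp <- phantom_spec(shape = shape, n_spots = n_spots, noise_sd = 0.01,
                     seed = seed)
  bg <- generate_background(shape, sp$background_correlation_px,
                            sp$noise_sd, seed = seed)
  plant_objects(bg, sp)
}
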
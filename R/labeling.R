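# 8-connected component labeling on a pixel-adjacency graph. Masks here are
# sparse (microcalcifications cover a tiny image fraction), so building the
# foreground subgraph is cheap.

#' Label 8-connected components of a binary mask
#'
#' @param mask Binary matrix.
#' @return Integer matrix of the same shape; 0 is background, components are
#'   labeled 1..n in first-pixel (column-major) order.
#' @export
label_components <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask != 0)  # column-major linear indices
  lab <- matrix(0L, dims[1], dims[2])
  if (!length(idx)) return(lab)
  pos <- integer(dims[1] * dims[2]); pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% dims[1]) + 1L
  c <- ((idx - 1L) %/% dims[1]) + 1L
  edges <- integer(0)
  # forward half of the 8-neighborhood: E, SE, S, SW
  for (d in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
    rn <- r + d[1]; cn <- c + d[2]
    ok <- rn >= 1L & rn <= dims[1] & cn >= 1L & cn <= dims[2]
    ni <- (cn[ok] - 1L) * dims[1] + rn[ok]
    hit <- pos[ni] > 0L
    if (any(hit))
      edges <- c(edges, rbind(pos[idx[ok]][hit], pos[ni][hit]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel by first occurrence so labels are deterministic
  first <- match(unique(comp), comp)
  relab <- integer(max(comp)); relab[comp[first]] <- seq_along(first)
  lab[idx] <- relab[comp]
  lab
}

#' Pixel sets (1-based linear indices) of each label
#' @param lab Labeled matrix from [label_components()].
#' @return Named list of linear-index vectors, one per label.
#' @export
label_pixel_sets <- function(lab) {
  idx <- which(lab != 0)
  if (!length(idx)) return(list())
  split(idx, lab[idx])
}

#' Object centroids (0-based row/col) of each label, ordered by label
#' @param lab Labeled matrix from [label_components()].
#' @return Numeric matrix with one centroid row per label.
#' @export
label_centroids <- function(lab) {
  sets <- label_pixel_sets(lab)
  n <- nrow(lab)
  t(vapply(sets, function(ix) {
    c(mean((ix - 1L) %% n), mean((ix - 1L) %/% n))
  }, numeric(2)))
}
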
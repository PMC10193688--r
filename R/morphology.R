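# Binary morphology and connected-component labeling on 3-D logical arrays.
# Implemented with vectorized index shifts; components use igraph on the
# voxel adjacency graph (no 3-D labeling routine exists in the installed
# R stack).

neighbor_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

neighbor_offsets_26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

# Shift a logical array by an integer offset, padding with FALSE.
shift_mask <- function(mask, off) {
  d <- dim(mask)
  ix <- seq_len(d[1]) - off[1]
  iy <- seq_len(d[2]) - off[2]
  iz <- seq_len(d[3]) - off[3]
  okx <- ix >= 1 & ix <= d[1]
  oky <- iy >= 1 & iy <= d[2]
  okz <- iz >= 1 & iz <= d[3]
  out <- array(FALSE, d)
  out[okx, oky, okz] <- mask[ix[okx], iy[oky], iz[okz]]
  out
}

#' Binary dilation, erosion and closing
#'
#' Uses a cubic structuring element of radius `r` voxels (26-neighbourhood
#' for `r = 1`), applied by vectorized shifts.
#'
#' @param mask logical 3-D array.
#' @param r radius in voxels.
#' @return logical 3-D array.
#' @export
dilate_mask <- function(mask, r = 1) {
  out <- mask
  for (k in seq_len(r)) {
    acc <- out
    for (i in seq_len(nrow(neighbor_offsets_26))) {
      acc <- acc | shift_mask(out, neighbor_offsets_26[i, ])
    }
    out <- acc
  }
  out
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, r = 1) {
  out <- mask
  for (k in seq_len(r)) {
    acc <- out
    for (i in seq_len(nrow(neighbor_offsets_26))) {
      acc <- acc & shift_mask(out, neighbor_offsets_26[i, ])
    }
    out <- acc
  }
  out
}

#' @rdname dilate_mask
#' @export
close_mask <- function(mask, r = 1) {
  erode_mask(dilate_mask(mask, r), r)
}

#' Connected components of a 3-D mask
#'
#' 26-connectivity by default. Returns an integer label array (0 outside the
#' mask, components numbered by decreasing size).
#'
#' @param mask logical 3-D array.
#' @param connectivity 26 or 6.
#' @return integer array of labels.
#' @export
connected_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  node <- array(0L, d)
  node[idx] <- seq_along(idx)
  offs <- neighbor_offsets(connectivity)
  # forward offsets only: each undirected edge counted once
  offs <- offs[offs[, 3] > 0 |
                 (offs[, 3] == 0 & (offs[, 2] > 0 |
                    (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  pos <- arrayInd(idx, d)
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    p <- pos[, 1] + o[1]
    q <- pos[, 2] + o[2]
    r <- pos[, 3] + o[3]
    ok <- p >= 1 & p <= d[1] & q >= 1 & q <= d[2] & r >= 1 & r <= d[3]
    if (!any(ok)) next
    nb <- node[cbind(p[ok], q[ok], r[ok])]
    has <- nb > 0L
    if (!any(has)) next
    edges[[i]] <- cbind(node[idx[ok]][has], nb[has])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  # renumber by decreasing size
  ord <- order(comp$csize, decreasing = TRUE)
  remap <- integer(comp$no)
  remap[ord] <- seq_len(comp$no)
  lab[idx] <- remap[comp$membership]
  lab
}

#' @rdname connected_components
#' @export
largest_component <- function(mask, connectivity = 26) {
  connected_components(mask, connectivity) == 1L
}
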